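# Plain-text readers and writers for every file the pipeline consumes or
# emits: gene tables (TSV), gene intervals (BED), gene sets (one symbol per
# line + YAML provenance sidecar), GWAS/PheWAS association tables (TSV),
# sgRNA manifests (CSV), count matrices (TSV), sample sheets (TSV), and
# 4-line FASTQ.

#' Read / write a gene-level pLoF frequency table
#'
#' Tab-separated with header columns `symbol`, `chrom`, `start`, `end`,
#' `strand`, `plof_maf`, `coding`, `misannotated`; intervals are 0-based
#' half-open (BED convention).
#'
#' @param path file path.
#' @return `read_gene_table()` returns the validated data frame.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(tab, GENE_TABLE_COLUMNS, "gene table file")
  tab$coding <- as.logical(tab$coding)
  tab$misannotated <- as.logical(tab$misannotated)
  validate_gene_table(tab)
  tab
}

#' @param gene_table data frame of gene records.
#' @rdname read_gene_table
#' @export
write_gene_table <- function(gene_table, path) {
  utils::write.table(gene_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write gene intervals as BED (chrom, start, end, name, score, strand)
#'
#' @param gene_table data frame with `chrom`, `start`, `end`, `symbol`,
#'   `strand` columns; coordinates 0-based half-open.
#' @param path output path.
#' @export
write_gene_bed <- function(gene_table, path) {
  bed <- data.frame(gene_table$chrom, gene_table$start, gene_table$end,
                    gene_table$symbol, 0L, gene_table$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene intervals from BED
#'
#' @param path BED file (at least 4 columns; strand read from column 6 when
#'   present).
#' @return data frame with `chrom`, `start`, `end`, `symbol`, `strand`.
#' @export
read_gene_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) fail("BED file must have at least 4 columns")
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             symbol = bed[[4]],
             strand = if (ncol(bed) >= 6L) bed[[6]] else "+",
             stringsAsFactors = FALSE)
}

#' Write / read a gene set as a symbol list with YAML provenance sidecar
#'
#' The set itself is one symbol per line; provenance (threshold and
#' per-filter drop counts) goes to `<path>.yaml`.
#'
#' @param gene_set an [lof_gene_set].
#' @param path output path for the symbol list.
#' @export
write_gene_set <- function(gene_set, path) {
  stopifnot(inherits(gene_set, "lof_gene_set"))
  writeLines(gene_set$members, path)
  yaml::write_yaml(list(name = gene_set$name, provenance = gene_set$provenance),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  members <- readLines(path)
  members <- members[nzchar(members)]
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  structure(list(name = meta$name %||% basename(path), members = members,
                 provenance = meta$provenance %||% list()),
            class = "lof_gene_set")
}

GWAS_COLUMNS <- c("study_id", "snp_id", "chromosome", "position",
                  "mapped_gene", "consequence", "mapped_trait",
                  "disease_trait")

#' Read / write a GWAS-catalog-style association table (TSV)
#'
#' Columns: `study_id`, `snp_id`, `chromosome`, `position` (0-based),
#' `mapped_gene` (may be empty), `consequence`, `mapped_trait` (may be
#' empty), `disease_trait`.
#'
#' @param path file path.
#' @export
read_gwas_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  check_columns(tab, GWAS_COLUMNS, "GWAS catalog file")
  tab
}

#' @param catalog data frame of associations.
#' @rdname read_gwas_catalog
#' @export
write_gwas_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

PHEWAS_COLUMNS <- c("dataset_id", "phenotype", "category", "gene",
                    "significant")

#' Read / write a PheWAS association table (TSV)
#'
#' Columns: `dataset_id`, `phenotype`, `category`, `gene`, `significant`.
#'
#' @param path file path.
#' @export
read_phewas_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(tab, PHEWAS_COLUMNS, "PheWAS table file")
  tab$significant <- as.logical(tab$significant)
  tab
}

#' @param table data frame of PheWAS associations.
#' @rdname read_phewas_table
#' @export
write_phewas_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

MANIFEST_COLUMNS <- c("guide_id", "set_id", "target_class", "target_gene",
                      "sequence")

#' Read / write an sgRNA library manifest (CSV)
#'
#' Columns: `guide_id`, `set_id`, `target_class` (`targeting`,
#' `non_targeting`, `safe_harbor`), `target_gene` (empty for non-targeting
#' controls; safe-harbor locus label for safe-harbor guides), `sequence`
#' (20-mer over ACGT).
#'
#' @param path file path.
#' @export
read_guide_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  check_columns(man, MANIFEST_COLUMNS, "guide manifest file")
  validate_guide_manifest(man)
  man
}

#' @param manifest guide manifest data frame.
#' @rdname read_guide_manifest
#' @export
write_guide_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write guide sequences as FASTA
#'
#' @param manifest guide manifest data frame.
#' @param path output path.
#' @export
write_guide_fasta <- function(manifest, path) {
  writeLines(as.vector(rbind(paste0(">", manifest$guide_id),
                             manifest$sequence)), path)
  invisible(path)
}

#' Read / write a guide count matrix (TSV: guide_id + one column per sample)
#'
#' @param path file path.
#' @return `read_count_matrix()` returns an integer matrix with guide ids as
#'   row names.
#' @export
read_count_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "guide_id") fail("first column must be guide_id")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab$guide_id
  m
}

#' @param counts matrix of counts, guide ids as row names.
#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(counts, path) {
  tab <- data.frame(guide_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet (TSV: sample, timepoint, replicate)
#'
#' @param path file path.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(tab, c("sample", "timepoint", "replicate"), "sample sheet")
  tab
}

#' @param samples sample sheet data frame.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write reads as 4-line FASTQ records
#'
#' Fixed quality string ("I" per base), as emitted by the synthetic screen
#' generator.
#'
#' @param reads character vector of read sequences.
#' @param ids character vector of read ids (defaults to `read_1 ...`).
#' @param path output path.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  qual <- strrep("I", nchar(reads))
  writeLines(as.vector(rbind(paste0("@", ids), reads, "+", qual)), path)
  invisible(path)
}

#' Read sequences from a 4-line FASTQ file
#'
#' @param path FASTQ path.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) fail("FASTQ file '%s' is empty", path)
  if (length(lines) %% 4L != 0L) {
    fail("FASTQ file '%s' is not made of 4-line records", path)
  }
  lines[seq(2L, length(lines), by = 4L)]
}
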