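# Synthetic pooled-screen sequencing data: negative-binomial guide counts
# with timepoint-dependent depletion of spiked essential genes, and
# error-free FASTQ emission for the exact-match counter.

# fixed vector flanks around the 20-mer protospacer in emitted reads
.READ_FLANK5 <- "AAACACCG"
.READ_FLANK3 <- "GTTTTAGAGCTAGAAATAGCAA"

#' Construct a screen count container
#'
#' Light container pairing a guides-by-samples integer count matrix with
#' per-sample metadata (timepoint, replicate, optional mapping rate).
#'
#' @param counts non-negative integer matrix, guide ids as row names.
#' @param samples data frame with columns `sample`, `timepoint`,
#'   `replicate` (and optionally `mapping_rate`), one row per count column.
#' @return object of class `screen_counts`.
#' @export
screen_counts <- function(counts, samples) {
  check_columns(samples, c("sample", "timepoint", "replicate"),
                "sample sheet")
  if (is.null(rownames(counts))) fail("counts must have guide ids as row names")
  if (nrow(samples) != ncol(counts)) {
    fail("sample sheet has %d rows but counts has %d columns",
         nrow(samples), ncol(counts))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    fail("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("<screen_counts> %d guides x %d samples (timepoints: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$timepoint), collapse = ", ")))
  invisible(x)
}

#' @export
dim.screen_counts <- function(x) dim(x$counts)

#' Simulate a pooled dropout screen from a library manifest
#'
#' Baseline guide abundances are lognormal around `baseline_mean`
#' (log-scale sd `baseline_sigma`). Counts per sample are negative binomial
#' with mean `multiplier * abundance * depletion` and overdispersion
#' `dispersion` (variance = mu + dispersion * mu^2; 0 gives Poisson). For
#' targeting guides of `essential_genes` the depletion factor at a
#' timepoint with `d` population doublings is `depletion_per_doubling^d`;
#' all other guides — including non-targeting and safe-harbor controls —
#' have depletion factor 1. The sample layout is `n_t0` T0 replicates plus
#' `n_per_timepoint` replicates for each entry of `doublings`.
#'
#' @param manifest guide manifest from [design_library()] (or any validated
#'   manifest).
#' @param config a [sim_config()].
#' @param essential_genes symbols of genes whose knockouts drop out; must
#'   all be targeted by the manifest.
#' @return a [screen_counts()] object with an extra `truth` element
#'   recording abundances, essential genes, size multipliers and the
#'   per-sample depletion matrix.
#' @export
gen_screen_counts <- function(manifest, config,
                              essential_genes = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  validate_guide_manifest(manifest)
  targeted <- unique(manifest$target_gene[manifest$target_class == "targeting"])
  missing <- setdiff(essential_genes, targeted)
  if (length(missing) > 0L) {
    fail("essential gene(s) not targeted by the manifest: %s",
         paste(missing, collapse = ", "))
  }
  set.seed(derive_seed(config$seed, .SIM_OFFSETS["screen"]))

  tps <- c("T0", names(config$doublings))
  reps <- c(config$n_t0, rep(config$n_per_timepoint,
                             length(config$doublings)))
  samples <- data.frame(
    sample = unlist(lapply(seq_along(tps), function(i)
      paste0(tps[i], "_r", seq_len(reps[i])))),
    timepoint = rep(tps, reps),
    replicate = unlist(lapply(reps, seq_len)),
    stringsAsFactors = FALSE)
  n_samples <- nrow(samples)

  mult <- config$library_size_multipliers
  if (is.null(mult)) mult <- rep(1, n_samples)
  if (length(mult) != n_samples) {
    fail("library_size_multipliers has length %d but the layout has %d samples",
         length(mult), n_samples)
  }

  n_guides <- nrow(manifest)
  abundance <- stats::rlnorm(n_guides, meanlog = log(config$baseline_mean),
                             sdlog = config$baseline_sigma)
  doubl <- c(T0 = 0L, config$doublings)[samples$timepoint]
  is_ess_guide <- manifest$target_class == "targeting" &
    manifest$target_gene %in% essential_genes
  # guides x samples depletion factor
  depletion <- outer(ifelse(is_ess_guide, 1, 0), as.numeric(doubl),
                     function(e, d) ifelse(e == 1,
                                           config$depletion_per_doubling^d, 1))
  mu <- abundance * depletion * rep(mult, each = n_guides)
  if (config$dispersion == 0) {
    counts <- stats::rpois(length(mu), lambda = mu)
  } else {
    counts <- stats::rnbinom(length(mu), mu = mu,
                             size = 1 / config$dispersion)
  }
  dim(counts) <- c(n_guides, n_samples)
  rownames(counts) <- manifest$guide_id
  x <- screen_counts(counts, samples)
  x$truth <- list(abundance = stats::setNames(abundance, manifest$guide_id),
                  essential_genes = essential_genes,
                  multipliers = stats::setNames(mult, samples$sample),
                  depletion = depletion)
  x
}

#' Emit screen samples as error-free FASTQ
#'
#' Writes one 4-line-record FASTQ per sample into `dir`. Each guide's read
#' is its exact 20-mer flanked by fixed vector sequence, repeated as many
#' times as its count in that sample; quality is a constant "I". The number
#' of reads in each file therefore equals the column sum of the count
#' matrix, so exact-match counting recovers the matrix exactly.
#'
#' @param x a [screen_counts()] object.
#' @param manifest the matching guide manifest.
#' @param dir output directory (created if needed).
#' @return named character vector of FASTQ paths, one per sample.
#' @export
gen_screen_fastq <- function(x, manifest, dir) {
  stopifnot(inherits(x, "screen_counts"))
  if (!all(rownames(x$counts) == manifest$guide_id)) {
    fail("count matrix rows do not match the manifest guide ids")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  read_seq <- paste0(.READ_FLANK5, manifest$sequence, .READ_FLANK3)
  paths <- character(ncol(x$counts))
  for (j in seq_len(ncol(x$counts))) {
    cnt <- x$counts[, j]
    reads <- rep(read_seq, cnt)
    ids <- paste0(x$samples$sample[j], ":", rep(manifest$guide_id, cnt),
                  ":", sequence(cnt))
    paths[j] <- file.path(dir, paste0(x$samples$sample[j], ".fastq"))
    write_fastq(reads, paths[j], ids = ids)
  }
  stats::setNames(paths, x$samples$sample)
}

#' Write every synthetic input for a full pipeline run
#'
#' Convenience driver for the command-line interface: generates the gene
#' universe (table + BED), GWAS catalog, PheWAS tables, the two-set guide
#' library, screen counts with sample sheet, and the configuration echo
#' (YAML) into one directory.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @param n_essential number of set genes spiked as essential in the screen.
#' @param fastq also emit per-sample FASTQ files.
#' @return invisibly, a named list of the generated objects.
#' @export
simulate_all <- function(config, dir, n_essential = 0L, fastq = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  universe <- gen_gene_universe(config)
  write_gene_table(universe[, GENE_TABLE_COLUMNS],
                   file.path(dir, "gene_table.tsv"))
  write_gene_bed(universe, file.path(dir, "genes.bed"))
  catalog <- gen_gwas_catalog(universe, config)
  write_gwas_catalog(catalog[, GWAS_COLUMNS], file.path(dir, "gwas.tsv"))
  phewas <- gen_phewas_table(universe, config)
  write_phewas_table(phewas, file.path(dir, "phewas.tsv"))

  gene_set <- build_lof_geneset(universe[, GENE_TABLE_COLUMNS],
                                maf_threshold = config$maf_threshold)
  write_gene_set(gene_set, file.path(dir, "gene_set.txt"))
  manifest <- design_library(gene_set, n_ntc = config$n_ntc,
                             n_safeharbor = config$n_safeharbor,
                             seed = derive_seed(config$seed,
                                                .SIM_OFFSETS["library"]))
  write_guide_manifest(manifest, file.path(dir, "manifest.csv"))

  essential <- head(gene_set$members, n_essential)
  counts <- gen_screen_counts(manifest, config, essential_genes = essential)
  write_count_matrix(counts$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(counts$samples, file.path(dir, "samples.tsv"))
  if (length(essential) > 0L) {
    writeLines(essential, file.path(dir, "essential_genes.txt"))
  }
  if (fastq) gen_screen_fastq(counts, manifest, file.path(dir, "fastq"))
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null,
                                           logical(1))],
                   file.path(dir, "config.yaml"))
  invisible(list(universe = universe, catalog = catalog, phewas = phewas,
                 gene_set = gene_set, manifest = manifest, counts = counts))
}
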