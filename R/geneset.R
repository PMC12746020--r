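# Construction and characterization of the common-LoF gene set.
#
# The input is a gene-level table of aggregate predicted loss-of-function
# (pLoF) allele frequencies, of the kind exported from population variant
# databases: one row per gene, with the mean allele frequency of all pLoF
# variants in that gene aggregated across the cohort, plus annotation flags
# for coding status and misannotation.

GENE_TABLE_COLUMNS <- c("symbol", "chrom", "start", "end", "strand",
                        "plof_maf", "coding", "misannotated")

#' Validate a gene-level pLoF frequency table
#'
#' Checks the structural invariants of a gene table: unique symbols,
#' allele frequencies in \[0, 1\], and well-formed half-open intervals
#' (`start < end`, 0-based).
#'
#' @param gene_table data frame with columns `symbol`, `chrom`, `start`,
#'   `end`, `strand`, `plof_maf`, `coding`, `misannotated`.
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending records.
#' @export
validate_gene_table <- function(gene_table) {
  check_columns(gene_table, GENE_TABLE_COLUMNS, "gene table")
  dup <- unique(gene_table$symbol[duplicated(gene_table$symbol)])
  if (length(dup) > 0L) {
    fail("duplicate gene symbol(s): %s", paste(dup, collapse = ", "))
  }
  bad_maf <- gene_table$symbol[
    is.na(gene_table$plof_maf) | gene_table$plof_maf < 0 | gene_table$plof_maf > 1]
  if (length(bad_maf) > 0L) {
    fail("aggregate pLoF MAF outside [0, 1] for record(s): %s",
         paste(bad_maf, collapse = ", "))
  }
  bad_iv <- gene_table$symbol[gene_table$start >= gene_table$end |
                              gene_table$start < 0]
  if (length(bad_iv) > 0L) {
    fail("malformed interval (need 0 <= start < end) for record(s): %s",
         paste(bad_iv, collapse = ", "))
  }
  invisible(gene_table)
}

#' Build the common-LoF gene set from an aggregate pLoF frequency table
#'
#' Retains genes whose aggregate pLoF mean allele frequency strictly exceeds
#' `maf_threshold`, after removing misannotated and non-coding genes. The
#' comparison is strict (`>`), matching the usual "greater than 0.1%"
#' phrasing of common-variant cutoffs. Drop accounting uses a fixed
#' precedence so the per-filter counts are disjoint: misannotated genes are
#' removed first, then non-coding genes, then genes at or below the MAF
#' threshold.
#'
#' @param gene_table data frame as validated by [validate_gene_table()].
#' @param maf_threshold numeric in \[0, 1); genes must exceed this aggregate
#'   pLoF MAF to be retained. Default `0.001` (0.1%).
#' @param name name recorded for the resulting set.
#' @return An object of class `lof_gene_set`: a list with `name`, `members`
#'   (character vector of symbols, input order preserved), and `provenance`
#'   (threshold plus the number of genes dropped by each filter).
#' @examples
#' tab <- data.frame(symbol = c("A", "B", "C"), chrom = "chr1",
#'                   start = c(0, 100, 200), end = c(50, 150, 250),
#'                   strand = "+", plof_maf = c(0.01, 0.0001, 0.02),
#'                   coding = TRUE, misannotated = c(FALSE, FALSE, TRUE))
#' build_lof_geneset(tab)$members   # "A": B fails the MAF cut, C is flagged
#' @export
build_lof_geneset <- function(gene_table, maf_threshold = 0.001,
                              name = "common_lof") {
  if (!is.numeric(maf_threshold) || length(maf_threshold) != 1L ||
      maf_threshold < 0 || maf_threshold >= 1) {
    fail("maf_threshold must be a single number in [0, 1)")
  }
  if (nrow(gene_table) > 0L) validate_gene_table(gene_table)

  keep <- rep(TRUE, nrow(gene_table))
  drop_mis <- keep & gene_table$misannotated
  keep <- keep & !drop_mis
  drop_noncoding <- keep & !gene_table$coding
  keep <- keep & !drop_noncoding
  drop_maf <- keep & gene_table$plof_maf <= maf_threshold
  keep <- keep & !drop_maf

  structure(
    list(
      name = name,
      members = gene_table$symbol[keep],
      provenance = list(
        maf_threshold = maf_threshold,
        n_input = nrow(gene_table),
        n_dropped_misannotated = sum(drop_mis),
        n_dropped_noncoding = sum(drop_noncoding),
        n_dropped_maf = sum(drop_maf)
      )
    ),
    class = "lof_gene_set"
  )
}

#' @export
print.lof_gene_set <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("<lof_gene_set '%s'>: %d genes (of %d input)\n",
              x$name, length(x$members), pv$n_input))
  cat(sprintf("  aggregate pLoF MAF > %g; dropped: %d misannotated, %d non-coding, %d below threshold\n",
              pv$maf_threshold, pv$n_dropped_misannotated,
              pv$n_dropped_noncoding, pv$n_dropped_maf))
  invisible(x)
}

#' @export
length.lof_gene_set <- function(x) length(x$members)

#' Coerce a gene set or character vector to a character vector of symbols
#' @keywords internal
set_members <- function(gene_set) {
  if (inherits(gene_set, "lof_gene_set")) return(gene_set$members)
  if (is.character(gene_set)) return(gene_set)
  fail("gene_set must be an lof_gene_set or a character vector of symbols")
}

# Ensembl consequence terms counted as loss of function: premature stops,
# frameshifts, and disruption of the essential splice dinucleotides.
LOF_CONSEQUENCE_TERMS <- c("stop_gained", "frameshift_variant",
                           "splice_donor_variant", "splice_acceptor_variant")

# Non-LoF Ensembl terms recognized so that genuinely novel vocabulary can be
# counted separately (unknown terms still classify as non-LoF).
KNOWN_NON_LOF_TERMS <- c(
  "missense_variant", "synonymous_variant", "splice_region_variant",
  "splice_donor_region_variant", "splice_donor_5th_base_variant",
  "splice_polypyrimidine_tract_variant", "intron_variant",
  "5_prime_utr_variant", "3_prime_utr_variant", "stop_lost", "start_lost",
  "stop_retained_variant", "start_retained_variant", "inframe_insertion",
  "inframe_deletion", "protein_altering_variant", "coding_sequence_variant",
  "non_coding_transcript_exon_variant", "non_coding_transcript_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant",
  "regulatory_region_variant", "tf_binding_site_variant",
  "mature_mirna_variant")

#' Classify Ensembl consequence terms as loss-of-function or not
#'
#' A term is loss-of-function iff it is one of `stop_gained`,
#' `frameshift_variant`, `splice_donor_variant`, or
#' `splice_acceptor_variant`. Matching is case-insensitive on the
#' whitespace-trimmed term. Terms outside the recognized Ensembl vocabulary
#' classify as non-LoF (real catalogs carry novel terms); the number of such
#' unknown terms is attached as attribute `n_unknown`.
#'
#' @param term character vector of consequence terms; empty or missing terms
#'   are an error.
#' @return data frame with columns `term` and `is_lof`, one row per input
#'   term; attribute `n_unknown` counts terms outside the known vocabulary.
#' @export
classify_consequence <- function(term) {
  if (length(term) == 0L) fail("no consequence terms supplied")
  if (any(is.na(term) | !nzchar(trimws(term)))) {
    fail("empty consequence term at position(s): %s",
         paste(which(is.na(term) | !nzchar(trimws(term))), collapse = ", "))
  }
  norm <- tolower(trimws(term))
  is_lof <- norm %in% LOF_CONSEQUENCE_TERMS
  unknown <- !(norm %in% c(LOF_CONSEQUENCE_TERMS, KNOWN_NON_LOF_TERMS))
  structure(data.frame(term = term, is_lof = is_lof,
                       stringsAsFactors = FALSE),
            n_unknown = sum(unknown))
}

#' Consequence-type frequency difference, set versus complement
#'
#' For each consequence term, compares its share among catalog associations
#' assigned to set members against its share among associations to
#' non-members, as a percent difference `100 * (f_in - f_out) / f_out`.
#' Terms never seen outside the set have an undefined percent difference and
#' are flagged rather than reported as infinite.
#'
#' @param catalog data frame with at least `mapped_gene` and `consequence`
#'   columns (e.g. a GWAS-catalog-style table).
#' @param gene_set [lof_gene_set] or character vector of member symbols.
#' @return data frame with one row per term: `consequence`, `f_in`, `f_out`
#'   (shares within each compartment), `pct_diff`, and logical `undefined`
#'   (`TRUE` where `f_out` is zero; `pct_diff` is `NA` there).
#' @export
consequence_frequency_diff <- function(catalog, gene_set) {
  if (nrow(catalog) == 0L) fail("catalog is empty")
  check_columns(catalog, c("mapped_gene", "consequence"), "catalog")
  members <- set_members(gene_set)
  catalog <- catalog[!is.na(catalog$mapped_gene), , drop = FALSE]
  in_set <- catalog$mapped_gene %in% members
  if (!any(in_set)) fail("no catalog associations map to the gene set")
  if (all(in_set)) fail("no catalog associations map outside the gene set")

  terms <- sort(unique(catalog$consequence))
  tab_in <- table(factor(catalog$consequence[in_set], levels = terms))
  tab_out <- table(factor(catalog$consequence[!in_set], levels = terms))
  f_in <- as.numeric(tab_in) / sum(tab_in)
  f_out <- as.numeric(tab_out) / sum(tab_out)
  undefined <- f_out == 0
  pct <- ifelse(undefined, NA_real_, 100 * (f_in - f_out) / f_out)
  data.frame(consequence = terms, f_in = f_in, f_out = f_out,
             pct_diff = pct, undefined = undefined,
             stringsAsFactors = FALSE)
}
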