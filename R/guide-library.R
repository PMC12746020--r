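# Design of the two-set targeted sgRNA knockout library and the
# representation QC metrics used to accept a synthesized / cloned pool.

#' Validate a guide manifest
#'
#' Invariants: 20-mer ACGT sequences, unique guide ids, unique sequences,
#' targeting guides carry a gene, non-targeting controls do not
#' (safe-harbor guides carry a locus label instead of a set gene).
#'
#' @param manifest manifest data frame (see [read_guide_manifest()]).
#' @return the manifest, invisibly, if valid.
#' @export
validate_guide_manifest <- function(manifest) {
  check_columns(manifest, MANIFEST_COLUMNS, "guide manifest")
  if (anyDuplicated(manifest$guide_id)) {
    fail("duplicate guide_id(s): %s",
         paste(unique(manifest$guide_id[duplicated(manifest$guide_id)]),
               collapse = ", "))
  }
  if (anyDuplicated(manifest$sequence)) {
    fail("duplicate guide sequence(s) for: %s",
         paste(manifest$guide_id[duplicated(manifest$sequence)],
               collapse = ", "))
  }
  bad_seq <- !grepl("^[ACGT]{20}$", manifest$sequence)
  if (any(bad_seq)) {
    fail("sequence is not a 20-mer over ACGT for: %s",
         paste(manifest$guide_id[bad_seq], collapse = ", "))
  }
  bad_class <- !manifest$target_class %in%
    c("targeting", "non_targeting", "safe_harbor")
  if (any(bad_class)) {
    fail("unknown target_class for: %s",
         paste(manifest$guide_id[bad_class], collapse = ", "))
  }
  tg <- manifest$target_class == "targeting"
  if (any(tg & (is.na(manifest$target_gene) | !nzchar(manifest$target_gene)))) {
    fail("targeting guide(s) without a target gene")
  }
  ntc <- manifest$target_class == "non_targeting"
  if (any(ntc & !is.na(manifest$target_gene))) {
    fail("non-targeting control(s) carry a target gene")
  }
  invisible(manifest)
}

#' Draw unique random 20-mers over ACGT
#' @keywords internal
random_guide_sequences <- function(n) {
  if (n > 4^20) fail("cannot draw %d unique 20-mers", n)
  seqs <- character(0)
  while (length(seqs) < n) {
    need <- n - length(seqs)
    fresh <- vapply(seq_len(need), function(i)
      paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
            collapse = ""), character(1))
    seqs <- unique(c(seqs, fresh))
  }
  seqs[seq_len(n)]
}

#' Design a two-set targeted sgRNA library with controls
#'
#' Builds two guide sets (SET1, SET2) that target the same gene list at
#' distinct (synthetic) positions: per set, one targeting guide per gene,
#' `n_ntc` non-targeting controls, and `n_safeharbor` safe-harbor guides
#' distributed over two synthetic safe-harbor loci. Every gene is therefore
#' covered by two guides overall. All sequences are unique random 20-mers;
#' guide-efficacy ranking of real designs is out of scope, so the sequences
#' are synthetic stand-ins.
#'
#' @param gene_set [lof_gene_set] or character vector of target genes.
#' @param n_ntc non-targeting controls per set (default 100).
#' @param n_safeharbor safe-harbor guides per set (default 5).
#' @param seed RNG seed for sequence generation.
#' @return manifest data frame (class `guide_manifest` prepended) with
#'   columns `guide_id`, `set_id`, `target_class`, `target_gene`,
#'   `sequence`; attribute `provenance` records counts and seed.
#' @export
design_library <- function(gene_set, n_ntc = 100L, n_safeharbor = 5L,
                           seed = 1L) {
  genes <- set_members(gene_set)
  if (anyDuplicated(genes)) fail("gene set contains duplicate symbols")
  stopifnot(n_ntc >= 0L, n_safeharbor >= 0L)
  set.seed(derive_seed(seed, 0L))

  one_set <- function(set_id) {
    ids <- c(
      if (length(genes)) paste0(set_id, "_", genes, "_sg"),
      if (n_ntc) sprintf("%s_NTC_%03d", set_id, seq_len(n_ntc)),
      if (n_safeharbor) sprintf("%s_SAFE_%02d", set_id,
                                seq_len(n_safeharbor)))
    data.frame(
      guide_id = ids,
      set_id = set_id,
      target_class = rep(c("targeting", "non_targeting", "safe_harbor"),
                         c(length(genes), n_ntc, n_safeharbor)),
      target_gene = c(genes, rep(NA_character_, n_ntc),
                      if (n_safeharbor)
                        paste0("safe_harbor_locus_",
                               rep_len(1:2, n_safeharbor))),
      stringsAsFactors = FALSE)
  }
  manifest <- rbind(one_set("SET1"), one_set("SET2"))
  manifest$sequence <- random_guide_sequences(nrow(manifest))
  attr(manifest, "provenance") <- list(
    n_genes = length(genes), n_ntc = n_ntc, n_safeharbor = n_safeharbor,
    seed = seed)
  class(manifest) <- c("guide_manifest", "data.frame")
  validate_guide_manifest(manifest)
  manifest
}

#' Library representation QC
#'
#' Computes the representation metrics used to accept a synthesized or
#' cloned guide pool: the Pearson correlation between two aligned count
#' vectors (e.g. oligo pool versus cloned plasmid pool), the ratio of the
#' 90th to the 10th percentile of per-guide counts, and the cumulative
#' read-fraction curve. Percentiles use linear interpolation between order
#' statistics (R quantile type 7). A pool passes the representation
#' criterion when the 90/10 ratio is at most six-fold. A zero 10th
#' percentile is floored at one pseudocount to keep the ratio finite (and
#' flagged).
#'
#' @param counts_a named numeric vector of per-guide counts (names = guide
#'   ids); the vector the percentile ratio and curve are computed on.
#' @param counts_b optional second vector aligned to the same guide ids;
#'   enables the Pearson correlation.
#' @return list of class `library_qc`: `pearson_r` (NA when `counts_b`
#'   absent), `p10`, `p90`, `p90_p10_ratio`, `p10_floored`,
#'   `passes_ratio_criterion`, `summary` (per-guide count summary), and
#'   `cumulative` (data frame `frac_guides`, `frac_reads`, guides sorted by
#'   ascending count).
#' @export
representation_qc <- function(counts_a, counts_b = NULL) {
  if (length(counts_a) == 0L) fail("counts_a is empty")
  pearson_r <- NA_real_
  if (!is.null(counts_b)) {
    if (!is.null(names(counts_a)) && !is.null(names(counts_b))) {
      mismatch <- c(setdiff(names(counts_a), names(counts_b)),
                    setdiff(names(counts_b), names(counts_a)))
      if (length(mismatch) > 0L) {
        fail("guide ids do not align between count vectors: %s",
             paste(unique(mismatch), collapse = ", "))
      }
      counts_b <- counts_b[names(counts_a)]
    } else if (length(counts_b) != length(counts_a)) {
      fail("count vectors have different lengths and no guide ids to align on")
    }
    pearson_r <- stats::cor(counts_a, counts_b, method = "pearson")
  }
  qs <- stats::quantile(counts_a, probs = c(0.1, 0.9), type = 7,
                        names = FALSE)
  p10 <- qs[1]; p90 <- qs[2]
  p10_floored <- p10 == 0
  ratio <- p90 / max(p10, 1)
  sorted <- sort(counts_a)
  n <- length(sorted)
  structure(list(
    pearson_r = pearson_r,
    p10 = p10, p90 = p90,
    p90_p10_ratio = ratio,
    p10_floored = p10_floored,
    passes_ratio_criterion = ratio <= 6,
    summary = summary(counts_a),
    cumulative = data.frame(frac_guides = seq_len(n) / n,
                            frac_reads = cumsum(sorted) / sum(sorted))
  ), class = "library_qc")
}

#' @export
print.library_qc <- function(x, ...) {
  cat(sprintf("<library_qc> P90/P10 = %.2f (%s six-fold criterion)%s\n",
              x$p90_p10_ratio,
              if (x$passes_ratio_criterion) "passes" else "FAILS",
              if (x$p10_floored) " [P10 floored at 1]" else ""))
  if (!is.na(x$pearson_r)) {
    cat(sprintf("  Pearson r (paired pools) = %.4f\n", x$pearson_r))
  }
  invisible(x)
}
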