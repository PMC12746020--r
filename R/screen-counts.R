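# Guide quantification from reads, sample-level QC, and safe-harbor
# control-guide median-of-ratios normalization.

#' Count guides in a FASTQ file by exact 20-mer matching
#'
#' Scans each read for an exact match to a manifest guide sequence. With
#' `offset` given, only the 20-mer starting at that (1-based) position is
#' examined; by default every offset of the read is searched and the first
#' hit is counted. Manifest sequences are unique, so any hit identifies a
#' single guide.
#'
#' @param fastq path to a 4-line-record FASTQ file (must be non-empty).
#' @param manifest guide manifest (validated; sequences must be unique).
#' @param offset optional fixed 1-based position of the guide in the read.
#' @return list: `counts` (named integer vector over all manifest guides),
#'   `mapping_rate` (mapped reads / total reads), `n_reads`.
#' @export
count_guides <- function(fastq, manifest, offset = NULL) {
  validate_guide_manifest(manifest)
  reads <- read_fastq(fastq)
  hit <- rep(NA_integer_, length(reads))
  if (!is.null(offset)) {
    hit <- match(substr(reads, offset, offset + 19L), manifest$sequence)
  } else {
    max_k <- max(nchar(reads)) - 19L
    for (k in seq_len(max(max_k, 0L))) {
      todo <- is.na(hit)
      if (!any(todo)) break
      hit[todo] <- match(substr(reads[todo], k, k + 19L), manifest$sequence)
    }
  }
  counts <- tabulate(hit, nbins = nrow(manifest))
  list(counts = stats::setNames(as.integer(counts), manifest$guide_id),
       mapping_rate = mean(!is.na(hit)),
       n_reads = length(reads))
}

#' Build a count matrix from per-sample FASTQ files
#'
#' @param fastqs named character vector of FASTQ paths (names = sample ids,
#'   matching `samples$sample`).
#' @param manifest guide manifest.
#' @param samples sample sheet data frame (`sample`, `timepoint`,
#'   `replicate`).
#' @param offset passed to [count_guides()].
#' @return a [screen_counts()] object with per-sample `mapping_rate` in its
#'   sample sheet.
#' @export
count_guides_matrix <- function(fastqs, manifest, samples, offset = NULL) {
  if (is.null(names(fastqs))) names(fastqs) <- samples$sample
  stopifnot(all(samples$sample %in% names(fastqs)))
  cols <- lapply(samples$sample,
                 function(s) count_guides(fastqs[[s]], manifest,
                                          offset = offset))
  counts <- do.call(cbind, lapply(cols, `[[`, "counts"))
  colnames(counts) <- samples$sample
  samples$mapping_rate <- vapply(cols, `[[`, numeric(1), "mapping_rate")
  screen_counts(counts, samples)
}

#' Sample-level QC: depth, mapping, and PCA clustering
#'
#' Computes per-sample totals and a principal component analysis of
#' `log1p` depth-normalized counts (guides as features, samples as
#' observations) to assess replicate clustering and timepoint separation.
#' Counts are scaled by total-count size factors (per-sample total over the
#' geometric mean total) before the log transform. A constant matrix yields
#' zero coordinates and zero explained variance.
#'
#' @param x a [screen_counts()] object (at least 2 samples).
#' @return list of class `screen_qc`: `totals`, `mapping_rate` (NA when not
#'   recorded), `pca` (data frame `sample`, `timepoint`, `PC1`, `PC2`), and
#'   `explained_var` (fractions for PC1, PC2).
#' @export
sample_qc <- function(x) {
  stopifnot(inherits(x, "screen_counts"))
  if (ncol(x$counts) < 2L) fail("sample QC needs at least 2 samples")
  totals <- colSums(x$counts)
  sf <- totals / exp(mean(log(pmax(totals, 1))))
  scaled <- sweep(x$counts, 2, pmax(sf, .Machine$double.eps), "/")
  lm <- t(log1p(scaled))  # samples x guides
  keep <- apply(lm, 2, stats::var) > 0
  if (!any(keep)) {
    pca <- data.frame(sample = x$samples$sample,
                      timepoint = x$samples$timepoint,
                      PC1 = 0, PC2 = 0)
    ev <- c(PC1 = 0, PC2 = 0)
  } else {
    pr <- stats::prcomp(lm[, keep, drop = FALSE], center = TRUE,
                        scale. = FALSE)
    k <- min(2L, ncol(pr$x))
    coords <- cbind(pr$x[, seq_len(k), drop = FALSE],
                    matrix(0, nrow = nrow(lm), ncol = 2L - k))
    ev_all <- pr$sdev^2 / sum(pr$sdev^2)
    ev <- c(PC1 = ev_all[1], PC2 = if (k >= 2L) ev_all[2] else 0)
    pca <- data.frame(sample = x$samples$sample,
                      timepoint = x$samples$timepoint,
                      PC1 = coords[, 1], PC2 = coords[, 2])
  }
  structure(list(totals = totals,
                 mapping_rate = x$samples$mapping_rate %||%
                   rep(NA_real_, ncol(x$counts)),
                 pca = pca, explained_var = ev),
            class = "screen_qc")
}

#' @export
print.screen_qc <- function(x, ...) {
  cat(sprintf("<screen_qc> %d samples; depth %s-%s; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$totals), format(min(x$totals), big.mark = ","),
              format(max(x$totals), big.mark = ","),
              100 * x$explained_var[1], 100 * x$explained_var[2]))
  invisible(x)
}

#' Control-guide median-of-ratios size factors
#'
#' Median-of-ratios normalization restricted to control guides (safe-harbor
#' guides in the screen design): the reference for each control guide is its
#' geometric mean count across samples (guides with a zero in any sample are
#' excluded from the reference set); the factor for a sample is the median
#' over controls of count / reference. Factors are reported unscaled.
#'
#' @param x a [screen_counts()] object or a counts matrix with guide id row
#'   names.
#' @param control_ids guide ids to normalize on.
#' @return named positive numeric vector of per-sample size factors.
#' @export
control_size_factors <- function(x, control_ids) {
  counts <- if (inherits(x, "screen_counts")) x$counts else x
  missing <- setdiff(control_ids, rownames(counts))
  if (length(missing) > 0L) {
    fail("control guide(s) absent from the count matrix: %s",
         paste(missing, collapse = ", "))
  }
  ctrl <- counts[control_ids, , drop = FALSE]
  usable <- rowSums(ctrl == 0) == 0L
  if (!any(usable)) {
    fail("no control guide has nonzero counts in every sample")
  }
  ctrl <- ctrl[usable, , drop = FALSE]
  ref <- exp(rowMeans(log(ctrl)))
  apply(ctrl / ref, 2, stats::median)
}
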