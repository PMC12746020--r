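# Guide-level differential abundance between screen timepoints: a two-group
# negative binomial model with size factors as offsets, closed-form fold
# change from size-factor-scaled arm means, method-of-moments dispersion,
# and a Wald test; then Benjamini-Hochberg adjustment per contrast,
# gene-level significance, and the continuous-depletion essentiality call.

#' Two-group negative binomial depletion test
#'
#' For each guide, models counts as negative binomial with mean
#' `mu = q * sizefactor * exp(beta * x)` where `x` indicates the timepoint
#' arm. The fold change estimate is the closed-form ratio of size-factor-
#' scaled arm means (`beta = log(meanB / meanA)`, the maximum likelihood
#' estimate in the Poisson limit); when an arm has zero total count a 0.5
#' pseudocount is added to both arm totals. Per-guide dispersion
#' (variance = mu + alpha * mu^2) is method-of-moments on size-factor-scaled
#' counts pooled across the two arms, then moderated toward the across-guide
#' mean dispersion with weight `df / (df + prior_df)` on the per-guide
#' estimate (with only a handful of residual degrees of freedom per guide
#' the raw estimate is far too noisy for a calibrated Wald test), and
#' finally floored at 1e-8. The standard error comes
#' from the curvature of the likelihood at the estimate,
#' `var(log mean) = 1 / (mean * sum(s)) + alpha * sum(s^2) / sum(s)^2`
#' summed over the two arms; `wald = beta / se`, `p = 2 * pnorm(-|wald|)`.
#' Guides with zero counts in every sample of both arms are flagged
#' not-testable (`NA` statistics) and are excluded from multiplicity
#' adjustment.
#'
#' @param x a [screen_counts()] object or counts matrix with guide id row
#'   names.
#' @param baseline,timepoint character vectors of sample (column) names for
#'   the two arms; each arm needs at least 2 samples.
#' @param size_factors named positive per-sample factors covering both arms
#'   (e.g. from [control_size_factors()]).
#' @param prior_df prior degrees of freedom for dispersion moderation
#'   (default 20); `prior_df = 0` keeps the raw per-guide estimates.
#' @return data frame: `guide_id`, `base_mean` (scaled mean over both
#'   arms), `log2fc`, `se` (of log2fc), `wald`, `p`, `testable`.
#' @export
nb_depletion_test <- function(x, baseline, timepoint, size_factors,
                              prior_df = 20) {
  counts <- if (inherits(x, "screen_counts")) x$counts else x
  miss <- setdiff(c(baseline, timepoint), colnames(counts))
  if (length(miss) > 0L) {
    fail("sample(s) not in the count matrix: %s", paste(miss, collapse = ", "))
  }
  if (length(baseline) < 2L || length(timepoint) < 2L) {
    fail("each arm needs at least 2 samples")
  }
  sf <- size_factors[c(baseline, timepoint)]
  if (any(is.na(sf)) || any(sf <= 0)) {
    fail("size factors must be positive and cover both arms")
  }
  yA <- counts[, baseline, drop = FALSE]
  yB <- counts[, timepoint, drop = FALSE]
  sA <- size_factors[baseline]
  sB <- size_factors[timepoint]

  testable <- rowSums(yA) + rowSums(yB) > 0

  # method-of-moments dispersion per arm on scaled counts:
  # u = y/s has E u = m, Var u = m/s + alpha m^2  =>
  # alpha = (var(u) - m * mean(1/s)) / m^2, pooled over arms by df
  mom_alpha <- function(y, s) {
    u <- sweep(y, 2, s, "/")
    m <- rowMeans(u)
    v <- apply(u, 1, stats::var)
    ifelse(m > 0, (v - m * mean(1 / s)) / m^2, NA_real_)
  }
  aA <- mom_alpha(yA, sA)
  aB <- mom_alpha(yB, sB)
  wA <- length(sA) - 1L
  wB <- length(sB) - 1L
  alpha <- ifelse(is.na(aA) & is.na(aB), NA_real_,
                  (ifelse(is.na(aA), 0, wA * aA) +
                   ifelse(is.na(aB), 0, wB * aB)) /
                  (ifelse(is.na(aA), 0, wA) + ifelse(is.na(aB), 0, wB)))
  # moderate the noisy per-guide estimates toward the across-guide mean
  alpha_bar <- mean(alpha[testable], na.rm = TRUE)
  if (!is.finite(alpha_bar)) alpha_bar <- 0
  df <- wA + wB
  w <- df / (df + prior_df)
  alpha <- pmax((1 - w) * alpha_bar +
                  w * ifelse(is.na(alpha), alpha_bar, alpha), 1e-8)

  TA <- rowSums(yA); TB <- rowSums(yB)
  zero_arm <- (TA == 0 | TB == 0) & testable
  TA <- ifelse(zero_arm, TA + 0.5, TA)
  TB <- ifelse(zero_arm, TB + 0.5, TB)
  mA <- TA / sum(sA)
  mB <- TB / sum(sB)
  beta <- log(mB / mA)
  var_log_mean <- function(m, s, alpha) {
    1 / (m * sum(s)) + alpha * sum(s^2) / sum(s)^2
  }
  se_beta <- sqrt(var_log_mean(mA, sA, alpha) + var_log_mean(mB, sB, alpha))
  wald <- beta / se_beta
  p <- 2 * stats::pnorm(-abs(wald))

  out <- data.frame(
    guide_id = rownames(counts),
    base_mean = (TA + TB) / (sum(sA) + sum(sB)),
    log2fc = beta / log(2),
    se = se_beta / log(2),
    wald = wald,
    p = p,
    testable = testable,
    stringsAsFactors = FALSE)
  out[!testable, c("base_mean", "log2fc", "se", "wald", "p")] <- NA_real_
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment over one contrast's family of
#' testable guides; `NA` p-values (not-testable guides) are excluded from
#' the family and stay `NA`.
#'
#' @param p numeric vector of p-values in (0, 1], possibly with `NA`s.
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Gene-level significance from guide-level results
#'
#' A gene is significant in a contrast iff the minimum adjusted p-value over
#' its testable guides is below `alpha` — i.e. at least one of its guides is
#' significantly differentially selected. Genes with no testable guide are
#' flagged not-testable (`NA`).
#'
#' @param guide_results data frame with `guide_id`, `log2fc`, `padj`
#'   columns for one contrast.
#' @param guide2gene named character vector mapping guide_id to gene symbol
#'   (targeting guides only).
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data frame per gene: `gene`, `n_guides`, `min_padj`, `log2fc`
#'   (of the minimum-padj guide), `significant` (NA when not testable).
#' @export
gene_level_call <- function(guide_results, guide2gene, alpha = 0.05) {
  gr <- guide_results[guide_results$guide_id %in% names(guide2gene), ,
                      drop = FALSE]
  gr$gene <- guide2gene[gr$guide_id]
  by_gene <- split(gr, gr$gene)
  res <- lapply(by_gene, function(g) {
    ok <- !is.na(g$padj)
    if (!any(ok)) {
      return(data.frame(gene = g$gene[1], n_guides = nrow(g),
                        min_padj = NA_real_, log2fc = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    }
    i <- which(ok)[which.min(g$padj[ok])]
    data.frame(gene = g$gene[1], n_guides = nrow(g),
               min_padj = g$padj[i], log2fc = g$log2fc[i],
               significant = g$padj[i] < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Continuous-depletion essentiality call
#'
#' A gene is called essential when its knockout shows increasing depletion
#' across the time course: gene-level log2 fold change negative at both
#' timepoints, depletion magnitude larger at the later timepoint
#' (`|log2fc_late| > |log2fc_early|`), and adjusted p-values below `alpha`
#' in both contrasts. Gene-level log2fc is that of the minimum-padj guide
#' per contrast (see [gene_level_call()]).
#'
#' @param early,late per-gene data frames from [gene_level_call()] for the
#'   early (e.g. T7 vs T0) and late (e.g. T14 vs T0) contrasts.
#' @param alpha adjusted-p threshold applied in both contrasts
#'   (default 0.05).
#' @return data frame per gene: `gene`, `log2fc_early`, `padj_early`,
#'   `log2fc_late`, `padj_late`, `significant_early`, `significant_late`,
#'   `essential` (NA when either contrast is not testable).
#' @export
call_essential <- function(early, late, alpha = 0.05) {
  genes <- sort(union(early$gene, late$gene))
  e <- early[match(genes, early$gene), , drop = FALSE]
  l <- late[match(genes, late$gene), , drop = FALSE]
  testable <- !is.na(e$min_padj) & !is.na(l$min_padj)
  essential <- ifelse(
    testable,
    e$log2fc < 0 & l$log2fc < 0 & abs(l$log2fc) > abs(e$log2fc) &
      e$min_padj < alpha & l$min_padj < alpha,
    NA)
  data.frame(gene = genes,
             log2fc_early = e$log2fc, padj_early = e$min_padj,
             log2fc_late = l$log2fc, padj_late = l$min_padj,
             significant_early = ifelse(testable, e$min_padj < alpha, NA),
             significant_late = ifelse(testable, l$min_padj < alpha, NA),
             essential = essential,
             stringsAsFactors = FALSE)
}

#' Full depletion / essentiality analysis of a screen
#'
#' Orchestrates the guide-level pipeline: safe-harbor control size factors,
#' the negative binomial test for each timepoint-vs-baseline contrast,
#' Benjamini-Hochberg adjustment per contrast, gene-level significance, and
#' the continuous-depletion essentiality call (when two later timepoints
#' are present).
#'
#' @param x a [screen_counts()] object; `timepoint` column must contain
#'   `baseline_tp` and at least one later timepoint.
#' @param manifest the guide manifest (safe-harbor guides define the
#'   normalization controls; targeting guides define the gene map).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param baseline_tp baseline timepoint label (default "T0").
#' @return list of class `depletion_results`: `size_factors`,
#'   `guide_results` (one data frame per contrast, with `padj`),
#'   `gene_results` (per contrast), and `essentiality` (data frame, or NULL
#'   with fewer than two later timepoints).
#' @export
run_depletion_analysis <- function(x, manifest, alpha = 0.05,
                                   baseline_tp = "T0") {
  stopifnot(inherits(x, "screen_counts"))
  validate_guide_manifest(manifest)
  ctrl_ids <- manifest$guide_id[manifest$target_class == "safe_harbor"]
  if (length(ctrl_ids) == 0L) fail("manifest has no safe-harbor guides")
  sf <- control_size_factors(x, ctrl_ids)

  tps <- setdiff(unique(x$samples$timepoint), baseline_tp)
  if (length(tps) == 0L) fail("no timepoint other than the baseline")
  base_samples <- x$samples$sample[x$samples$timepoint == baseline_tp]
  guide2gene <- with(manifest[manifest$target_class == "targeting", ],
                     stats::setNames(target_gene, guide_id))

  guide_results <- list()
  gene_results <- list()
  for (tp in tps) {
    arm <- x$samples$sample[x$samples$timepoint == tp]
    res <- nb_depletion_test(x, base_samples, arm, sf)
    res$padj <- bh_adjust(res$p)
    guide_results[[tp]] <- res
    gene_results[[tp]] <- gene_level_call(res, guide2gene, alpha = alpha)
  }
  essentiality <- NULL
  if (length(tps) >= 2L) {
    ord <- tps[order(match(tps, x$samples$timepoint))]
    essentiality <- call_essential(gene_results[[ord[1]]],
                                   gene_results[[ord[length(ord)]]],
                                   alpha = alpha)
  }
  structure(list(size_factors = sf, guide_results = guide_results,
                 gene_results = gene_results, essentiality = essentiality,
                 alpha = alpha),
            class = "depletion_results")
}

#' @export
print.depletion_results <- function(x, ...) {
  cat("<depletion_results>\n")
  for (tp in names(x$gene_results)) {
    g <- x$gene_results[[tp]]
    cat(sprintf("  %s vs baseline: %d/%d genes significant (padj < %g)\n",
                tp, sum(g$significant, na.rm = TRUE), nrow(g), x$alpha))
  }
  if (!is.null(x$essentiality)) {
    cat(sprintf("  essential (continuous depletion): %d genes\n",
                sum(x$essentiality$essential, na.rm = TRUE)))
  }
  invisible(x)
}
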