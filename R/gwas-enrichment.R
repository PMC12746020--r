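# GWAS-catalog preprocessing and the permutation trait-enrichment statistic:
# nearest-gene assignment for unmapped SNPs, trait standardization,
# exclusion filters, and a z-score comparing the focal set's unique
# gene-trait pair counts with random gene sets of matched size,
# z = (observed - null mean) / null SD, with two-sided normal p-values and
# Benjamini-Hochberg adjustment over traits.

#' Assign unmapped SNPs to the nearest gene
#'
#' For every row whose `mapped_gene` is missing, finds the nearest gene on
#' the same chromosome and fills it in. Distance to a gene with 0-based
#' half-open interval `[start, end)` is 0 when the position lies inside it,
#' otherwise `min(|pos - (end - 1)|, |pos - start|)`. Ties are broken by
#' smaller start, then lexicographic symbol. Rows on chromosomes with no
#' genes are dropped; the drop count is attached as attribute
#' `n_dropped_no_gene`. A `gene_distance` column records the assignment
#' distance (0 for rows that arrived mapped).
#'
#' @param catalog GWAS association data frame (see [read_gwas_catalog()]).
#' @param intervals gene interval table with `chrom`, `start`, `end`,
#'   `symbol` (e.g. from [read_gene_bed()]).
#' @return the catalog with `mapped_gene` filled and `gene_distance` added.
#' @export
assign_nearest_gene <- function(catalog, intervals) {
  check_columns(intervals, c("chrom", "start", "end", "symbol"), "intervals")
  if (any(intervals$start >= intervals$end)) {
    fail("malformed interval(s) (start >= end): %s",
         paste(intervals$symbol[intervals$start >= intervals$end],
               collapse = ", "))
  }
  catalog$gene_distance <- ifelse(is.na(catalog$mapped_gene), NA_real_, 0)
  unmapped <- which(is.na(catalog$mapped_gene))
  if (length(unmapped) == 0L) {
    attr(catalog, "n_dropped_no_gene") <- 0L
    return(catalog)
  }
  drop <- logical(nrow(catalog))
  for (chr in unique(catalog$chromosome[unmapped])) {
    rows <- unmapped[catalog$chromosome[unmapped] == chr]
    genes <- intervals[intervals$chrom == chr, , drop = FALSE]
    if (nrow(genes) == 0L) {
      drop[rows] <- TRUE
      next
    }
    # deterministic tie-break: smaller start, then symbol
    genes <- genes[order(genes$start, genes$symbol), , drop = FALSE]
    for (i in rows) {
      pos <- catalog$position[i]
      inside <- pos >= genes$start & pos < genes$end
      d <- ifelse(inside, 0,
                  pmin(abs(pos - (genes$end - 1)), abs(pos - genes$start)))
      j <- which.min(d)  # first minimum respects the (start, symbol) order
      catalog$mapped_gene[i] <- genes$symbol[j]
      catalog$gene_distance[i] <- d[j]
    }
  }
  out <- catalog[!drop, , drop = FALSE]
  attr(out, "n_dropped_no_gene") <- sum(drop)
  out
}

#' Standardize trait labels
#'
#' Adds a single `trait` column: the whitespace-trimmed `mapped_trait` when
#' present and non-empty, otherwise the trimmed `disease_trait`. Rows with
#' both fields empty are dropped; the count is attached as attribute
#' `n_dropped_no_trait`.
#'
#' @param catalog GWAS association data frame.
#' @return catalog with a `trait` column.
#' @export
standardize_traits <- function(catalog) {
  mt <- trimws(ifelse(is.na(catalog$mapped_trait), "", catalog$mapped_trait))
  dt <- trimws(ifelse(is.na(catalog$disease_trait), "", catalog$disease_trait))
  trait <- ifelse(nzchar(mt), mt, dt)
  keep <- nzchar(trait)
  out <- catalog[keep, , drop = FALSE]
  out$trait <- trait[keep]
  attr(out, "n_dropped_no_trait") <- sum(!keep)
  out
}

#' Apply the catalog exclusion filters
#'
#' Single pass in fixed order: (1) drop studies reporting more than
#' `max_traits_per_study` distinct traits; (2) drop studies reporting more
#' than `max_genes_per_study` distinct genes; (3) drop traits with fewer
#' than `min_genes_per_trait` distinct genes, computed after steps 1-2.
#' No fixpoint iteration.
#'
#' @param catalog catalog with `study_id`, `trait`, `mapped_gene` columns
#'   (traits standardized, genes assigned).
#' @param max_traits_per_study,max_genes_per_study,min_genes_per_trait the
#'   exclusion bounds (defaults 10, 1000, 5).
#' @return filtered catalog; attribute `filter_report` is a data frame with
#'   the rows and entities removed at each step.
#' @export
filter_catalog <- function(catalog, max_traits_per_study = 10L,
                           max_genes_per_study = 1000L,
                           min_genes_per_trait = 5L) {
  check_columns(catalog, c("study_id", "trait", "mapped_gene"), "catalog")
  n_distinct_by <- function(values, by) {
    vapply(split(values, by), function(v) length(unique(v)), integer(1))
  }
  report <- data.frame(step = character(0), entity = character(0),
                       n_entities_removed = integer(0),
                       n_rows_removed = integer(0))
  log_step <- function(step, entity, n_ent, n_rows) {
    rbind(report, data.frame(step = step, entity = entity,
                             n_entities_removed = n_ent,
                             n_rows_removed = n_rows))
  }

  tr_per_study <- n_distinct_by(catalog$trait, catalog$study_id)
  bad <- names(tr_per_study)[tr_per_study > max_traits_per_study]
  keep <- !(catalog$study_id %in% bad)
  report <- log_step("studies_by_traits", "study", length(bad), sum(!keep))
  catalog <- catalog[keep, , drop = FALSE]

  g_per_study <- n_distinct_by(catalog$mapped_gene, catalog$study_id)
  bad <- names(g_per_study)[g_per_study > max_genes_per_study]
  keep <- !(catalog$study_id %in% bad)
  report <- log_step("studies_by_genes", "study", length(bad), sum(!keep))
  catalog <- catalog[keep, , drop = FALSE]

  g_per_trait <- n_distinct_by(catalog$mapped_gene, catalog$trait)
  bad <- names(g_per_trait)[g_per_trait < min_genes_per_trait]
  keep <- !(catalog$trait %in% bad)
  report <- log_step("traits_by_genes", "trait", length(bad), sum(!keep))
  catalog <- catalog[keep, , drop = FALSE]

  attr(catalog, "filter_report") <- report
  catalog
}

#' Permutation trait enrichment of a gene set
#'
#' Counts, per trait, the unique (gene, trait) pairs whose gene belongs to
#' the focal set, restricted to loss-of-function consequences (and, when
#' `intervals` are supplied, to intragenic assignments: SNP position inside
#' the mapped gene's interval). The null distribution comes from random
#' gene sets of matched size — `|set intersect catalog genes|` genes drawn
#' without replacement from all catalog genes — recomputing the per-trait
#' pair counts for each draw. The enrichment statistic is
#' `z = (observed - null mean) / null SD`; `z` is undefined (NA) when the
#' null SD is 0. Two-sided p-values use the normal approximation
#' `p = 2 * pnorm(-|z|)` (an empirical rank p-value is available via
#' `p_method = "empirical"`); q-values are Benjamini-Hochberg over all
#' traits with defined z.
#'
#' @param catalog filtered catalog with `trait`, `mapped_gene`,
#'   `consequence` columns (and `position`/`chromosome` if `intervals` are
#'   given).
#' @param gene_set [lof_gene_set] or character vector of member symbols.
#' @param n_perm number of random sets (default 1000). Ignored when
#'   `exhaustive = TRUE`.
#' @param seed RNG seed for the permutation draws.
#' @param intervals optional gene interval table; when supplied, rows whose
#'   SNP lies outside its mapped gene are excluded before counting.
#' @param lof_only restrict to loss-of-function consequence terms
#'   (default TRUE).
#' @param exhaustive enumerate all subsets of matched size instead of
#'   sampling (only feasible for tiny universes); null mean/SD are then the
#'   exact population values over all subsets.
#' @param p_method `"normal"` (canonical) or `"empirical"`
#'   (rank-based, `(1 + #{|null - mean| >= |obs - mean|}) / (n_perm + 1)`).
#' @return data frame of class `trait_enrichment`: `trait`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p`, `q`, `n_hits`; attribute
#'   `provenance` records seed, draw count and matched set size.
#' @export
permutation_trait_enrichment <- function(catalog, gene_set, n_perm = 1000L,
                                         seed = 1L, intervals = NULL,
                                         lof_only = TRUE,
                                         exhaustive = FALSE,
                                         p_method = c("normal", "empirical")) {
  p_method <- match.arg(p_method)
  check_columns(catalog, c("trait", "mapped_gene", "consequence"), "catalog")
  if (!exhaustive && n_perm < 1L) fail("n_perm must be >= 1")
  members <- set_members(gene_set)

  if (lof_only) {
    catalog <- catalog[classify_consequence(catalog$consequence)$is_lof, ,
                       drop = FALSE]
  }
  if (!is.null(intervals)) {
    iv <- intervals[match(catalog$mapped_gene, intervals$symbol), ,
                    drop = FALSE]
    intragenic <- !is.na(iv$start) & catalog$position >= iv$start &
      catalog$position < iv$end & catalog$chromosome == iv$chrom
    catalog <- catalog[intragenic, , drop = FALSE]
  }
  catalog <- catalog[!is.na(catalog$mapped_gene), , drop = FALSE]
  pairs <- unique(catalog[, c("trait", "mapped_gene")])
  genes <- sort(unique(pairs$mapped_gene))
  traits <- sort(unique(pairs$trait))
  m <- sum(members %in% genes)
  if (m == 0L) fail("gene set shares no genes with the catalog")

  gene_idx <- match(pairs$mapped_gene, genes)
  trait_idx <- match(pairs$trait, traits)
  # trait x gene incidence of unique pairs
  M <- matrix(0, nrow = length(traits), ncol = length(genes))
  M[cbind(trait_idx, gene_idx)] <- 1
  observed <- as.vector(M %*% as.numeric(genes %in% members))

  if (exhaustive) {
    subsets <- utils::combn(length(genes), m)
    n_draws <- ncol(subsets)
    Z <- matrix(0, nrow = length(genes), ncol = n_draws)
    Z[cbind(as.vector(subsets), rep(seq_len(n_draws), each = m))] <- 1
  } else {
    set.seed(derive_seed(seed, 0L))
    n_draws <- n_perm
    Z <- matrix(0, nrow = length(genes), ncol = n_draws)
    for (b in seq_len(n_draws)) {
      Z[sample.int(length(genes), m), b] <- 1
    }
  }
  null_counts <- M %*% Z
  null_mean <- rowMeans(null_counts)
  if (exhaustive) {
    null_sd <- sqrt(rowMeans((null_counts - null_mean)^2))  # population SD
  } else {
    null_sd <- apply(null_counts, 1, stats::sd)
  }
  z <- ifelse(null_sd == 0, NA_real_, (observed - null_mean) / null_sd)
  p <- if (p_method == "normal") {
    2 * stats::pnorm(-abs(z))
  } else {
    vapply(seq_along(z), function(i) {
      if (is.na(z[i])) return(NA_real_)
      (1 + sum(abs(null_counts[i, ] - null_mean[i]) >=
                 abs(observed[i] - null_mean[i]))) / (n_draws + 1)
    }, numeric(1))
  }
  q <- rep(NA_real_, length(p))
  q[!is.na(z)] <- stats::p.adjust(p[!is.na(z)], method = "BH")

  res <- data.frame(trait = traits, observed = observed,
                    null_mean = null_mean, null_sd = null_sd,
                    z = z, p = p, q = q, n_hits = observed,
                    stringsAsFactors = FALSE)
  attr(res, "provenance") <- list(seed = seed, n_draws = n_draws,
                                  matched_set_size = m,
                                  n_catalog_genes = length(genes),
                                  exhaustive = exhaustive,
                                  p_method = p_method)
  class(res) <- c("trait_enrichment", "data.frame")
  res
}

#' Filter enrichment results for reporting
#'
#' Keeps traits (or categories) with at least `min_hits` observed hits and
#' `|z| > z_cut`, sorted by decreasing `|z|`. Results with undefined z are
#' never reported.
#'
#' @param results data frame with `n_hits` and `z` columns (from
#'   [permutation_trait_enrichment()] or [phewas_enrichment()]).
#' @param min_hits minimum observed hits (default 5).
#' @param z_cut |z| must strictly exceed this (default 2).
#' @return the reportable subset, ordered by decreasing |z|.
#' @export
report_traits <- function(results, min_hits = 5L, z_cut = 2) {
  keep <- !is.na(results$z) & results$n_hits >= min_hits &
    abs(results$z) > z_cut
  out <- results[keep, , drop = FALSE]
  out[order(-abs(out$z)), , drop = FALSE]
}
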