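# PheWAS phenotype-category resampling enrichment. Each cohort dataset is
# analysed independently: the observed quantity is the distribution of
# phenotype categories among significant associations involving set genes,
# compared with category proportions of random association draws of the
# same size from the dataset's full significant-association pool.

#' Phenotype-category resampling enrichment per dataset
#'
#' For each dataset: deduplicates (phenotype, gene) associations flagged
#' significant; computes observed per-category proportions among
#' associations whose gene is in the focal set; draws `n_perm` random sets
#' of the same number of association rows, without replacement, from the
#' dataset's full pool and recomputes category proportions;
#' `z = (observed - null mean) / null SD` per category (undefined when the
#' null SD is 0), `p = 2 * pnorm(-|z|)`, Benjamini-Hochberg within the
#' dataset. Datasets with no set-gene association are skipped with a
#' warning. The resampling unit is the association row, matched in count to
#' the observed set-gene rows.
#'
#' @param table PheWAS association data frame (see [read_phewas_table()]);
#'   multiple datasets may be stacked.
#' @param gene_set [lof_gene_set] or character vector of member symbols.
#' @param n_perm number of random draws (default 1000). Ignored when
#'   `exhaustive = TRUE`.
#' @param seed RNG seed.
#' @param exhaustive enumerate all possible draws instead of sampling (tiny
#'   pools only); null mean/SD are then exact population values.
#' @return data frame of class `category_enrichment`: `dataset_id`,
#'   `category`, `observed_prop`, `null_mean`, `null_sd`, `z`, `p`, `q`,
#'   `n_hits` (observed set-gene association rows in the category);
#'   attribute `provenance` records the seed, draw counts, and the
#'   resampling unit.
#' @export
phewas_enrichment <- function(table, gene_set, n_perm = 1000L, seed = 1L,
                              exhaustive = FALSE) {
  check_columns(table, PHEWAS_COLUMNS, "PheWAS table")
  if (!exhaustive && n_perm < 1L) fail("n_perm must be >= 1")
  members <- set_members(gene_set)
  table <- table[table$significant, , drop = FALSE]
  table <- unique(table[, c("dataset_id", "phenotype", "category", "gene")])
  if (any(!nzchar(table$category) | is.na(table$category))) {
    fail("empty phenotype category")
  }

  out <- list()
  n_obs_by_dataset <- integer(0)
  for (d in sort(unique(table$dataset_id))) {
    pool <- table[table$dataset_id == d, , drop = FALSE]
    in_set <- pool$gene %in% members
    n_obs <- sum(in_set)
    if (n_obs == 0L) {
      warning(sprintf("dataset '%s' has no set-gene associations; skipped", d),
              call. = FALSE)
      next
    }
    categories <- sort(unique(pool$category))
    cat_idx <- match(pool$category, categories)
    # category x row indicator
    C <- matrix(0, nrow = length(categories), ncol = nrow(pool))
    C[cbind(cat_idx, seq_len(nrow(pool)))] <- 1
    obs_counts <- as.vector(C %*% as.numeric(in_set))
    observed_prop <- obs_counts / n_obs

    if (exhaustive) {
      draws <- utils::combn(nrow(pool), n_obs)
      n_draws <- ncol(draws)
      Z <- matrix(0, nrow = nrow(pool), ncol = n_draws)
      Z[cbind(as.vector(draws), rep(seq_len(n_draws), each = n_obs))] <- 1
    } else {
      set.seed(derive_seed(seed, 0L) + match(d, sort(unique(table$dataset_id))))
      n_draws <- n_perm
      Z <- matrix(0, nrow = nrow(pool), ncol = n_draws)
      for (b in seq_len(n_draws)) {
        Z[sample.int(nrow(pool), n_obs), b] <- 1
      }
    }
    null_props <- (C %*% Z) / n_obs
    null_mean <- rowMeans(null_props)
    null_sd <- if (exhaustive) {
      sqrt(rowMeans((null_props - null_mean)^2))
    } else {
      apply(null_props, 1, stats::sd)
    }
    z <- ifelse(null_sd == 0, NA_real_, (observed_prop - null_mean) / null_sd)
    p <- 2 * stats::pnorm(-abs(z))
    q <- rep(NA_real_, length(p))
    q[!is.na(z)] <- stats::p.adjust(p[!is.na(z)], method = "BH")
    out[[d]] <- data.frame(dataset_id = d, category = categories,
                           observed_prop = observed_prop,
                           null_mean = null_mean, null_sd = null_sd,
                           z = z, p = p, q = q, n_hits = obs_counts,
                           stringsAsFactors = FALSE)
    n_obs_by_dataset[d] <- n_obs
  }
  if (length(out) == 0L) fail("no dataset has set-gene associations")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "provenance") <- list(seed = seed,
                                  n_draws = if (exhaustive) NA_integer_
                                            else n_perm,
                                  exhaustive = exhaustive,
                                  resampling_unit = "association_row",
                                  n_observed_rows = n_obs_by_dataset)
  class(res) <- c("category_enrichment", "data.frame")
  res
}

#' @rdname report_traits
#' @export
report_categories <- function(results, min_hits = 5L, z_cut = 2) {
  report_traits(results, min_hits = min_hits, z_cut = z_cut)
}
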