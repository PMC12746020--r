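# Configuration object for the synthetic-data generators.
#
# The generators emulate the pipeline's real inputs: a gene-level aggregate
# pLoF frequency table (population variant database export), a GWAS-catalog
# style association table, PheWAS association tables, an sgRNA library
# manifest, and pooled-screen sequencing counts with negative-binomial noise
# and timepoint-dependent depletion of spiked essential genes.

#' Simulation configuration
#'
#' Validated container of every tunable the synthetic-data generators use.
#' Identical configuration plus seed yields byte-identical outputs.
#'
#' @param seed integer RNG seed governing all generators.
#' @param n_genes number of genes in the synthetic universe.
#' @param frac_set fraction of (unflagged) genes given an aggregate pLoF MAF
#'   above `maf_threshold`, i.e. placed in the focal set.
#' @param n_flagged number of genes flagged misannotated/non-coding
#'   (default `round(0.003 * n_genes)`); flagged genes still receive
#'   above-threshold MAF so only the annotation filters remove them.
#' @param maf_threshold the MAF cutoff the universe is built around
#'   (default 0.001, i.e. 0.1%).
#' @param n_chromosomes,gene_length,gene_gap synthetic genome layout: genes
#'   of fixed length placed round-robin on chromosomes with a fixed gap,
#'   non-overlapping, 0-based half-open.
#' @param chromosome_length optional cap on synthetic chromosome length (bp);
#'   an error is raised if the genes cannot be packed within it.
#' @param n_traits,n_enriched_traits,enrichment_effect GWAS generator: number
#'   of traits; the first `n_enriched_traits` traits have their association
#'   rate to set genes multiplied by `enrichment_effect` (>= 1; 1 = null).
#' @param assoc_rate expected number of associations per (trait, gene) pair.
#' @param frac_unmapped fraction of association rows emitted without a mapped
#'   gene, to exercise nearest-gene assignment.
#' @param frac_lof probability an association's consequence term is
#'   loss-of-function.
#' @param n_datasets,n_phenotypes,n_categories PheWAS generator: number of
#'   cohort datasets, phenotypes per dataset, and phenotype categories.
#' @param phewas_rate probability a (phenotype, gene) pair is a significant
#'   association.
#' @param enriched_categories integer indices of categories whose rate for
#'   set genes is multiplied by `category_effect`.
#' @param category_effect multiplier >= 1 for enriched categories.
#' @param n_ntc,n_safeharbor control guide counts per library set.
#' @param baseline_mean expected guide count at T0 (lognormal median).
#' @param baseline_sigma lognormal sd (log scale) of baseline guide
#'   abundance; the default 0.5 keeps a clean library's 90th/10th percentile
#'   count ratio under six-fold.
#' @param dispersion negative-binomial overdispersion alpha
#'   (variance = mu + alpha * mu^2); 0 degenerates to Poisson.
#' @param depletion_per_doubling per-doubling abundance retention for guides
#'   of spiked essential genes, in (0, 1].
#' @param doublings named integer vector of population doublings per
#'   timepoint (default `c(T7 = 7, T14 = 14)`).
#' @param n_t0,n_per_timepoint replicate counts: T0 samples and samples per
#'   later timepoint.
#' @param library_size_multipliers optional positive multiplier per sample
#'   (recycled/validated against the sample layout); default all 1.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       frac_set = 0.1,
                       n_flagged = NULL,
                       maf_threshold = 0.001,
                       n_chromosomes = 5L,
                       gene_length = 2000L,
                       gene_gap = 1000L,
                       chromosome_length = NULL,
                       n_traits = 100L,
                       n_enriched_traits = 0L,
                       enrichment_effect = 1,
                       assoc_rate = 0.1,
                       frac_unmapped = 0.05,
                       frac_lof = 0.5,
                       n_datasets = 2L,
                       n_phenotypes = 200L,
                       n_categories = 10L,
                       phewas_rate = 0.01,
                       enriched_categories = integer(0),
                       category_effect = 1,
                       n_ntc = 100L,
                       n_safeharbor = 5L,
                       baseline_mean = 500,
                       baseline_sigma = 0.5,
                       dispersion = 0.05,
                       depletion_per_doubling = 0.8,
                       doublings = c(T7 = 7L, T14 = 14L),
                       n_t0 = 3L,
                       n_per_timepoint = 4L,
                       library_size_multipliers = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              frac_set = frac_set,
              n_flagged = if (is.null(n_flagged))
                as.integer(round(0.003 * n_genes)) else as.integer(n_flagged),
              maf_threshold = maf_threshold,
              n_chromosomes = as.integer(n_chromosomes),
              gene_length = as.integer(gene_length),
              gene_gap = as.integer(gene_gap),
              chromosome_length = chromosome_length,
              n_traits = as.integer(n_traits),
              n_enriched_traits = as.integer(n_enriched_traits),
              enrichment_effect = enrichment_effect,
              assoc_rate = assoc_rate, frac_unmapped = frac_unmapped,
              frac_lof = frac_lof,
              n_datasets = as.integer(n_datasets),
              n_phenotypes = as.integer(n_phenotypes),
              n_categories = as.integer(n_categories),
              phewas_rate = phewas_rate,
              enriched_categories = as.integer(enriched_categories),
              category_effect = category_effect,
              n_ntc = as.integer(n_ntc),
              n_safeharbor = as.integer(n_safeharbor),
              baseline_mean = baseline_mean, baseline_sigma = baseline_sigma,
              dispersion = dispersion,
              depletion_per_doubling = depletion_per_doubling,
              doublings = doublings,
              n_t0 = as.integer(n_t0),
              n_per_timepoint = as.integer(n_per_timepoint),
              library_size_multipliers = library_size_multipliers)

  with(cfg, {
    stopifnot(n_genes >= 1L, frac_set >= 0, frac_set <= 1,
              n_flagged >= 0L, n_flagged <= n_genes,
              maf_threshold >= 0, maf_threshold < 1,
              n_chromosomes >= 1L, gene_length >= 1L, gene_gap >= 0L,
              n_traits >= 1L, n_enriched_traits >= 0L,
              n_enriched_traits <= n_traits,
              enrichment_effect >= 1, assoc_rate > 0,
              frac_unmapped >= 0, frac_unmapped <= 1,
              frac_lof >= 0, frac_lof <= 1,
              n_datasets >= 1L, n_phenotypes >= 1L, n_categories >= 1L,
              phewas_rate > 0, phewas_rate <= 1,
              all(enriched_categories >= 1L),
              all(enriched_categories <= n_categories),
              category_effect >= 1,
              n_ntc >= 0L, n_safeharbor >= 0L,
              baseline_mean > 0, baseline_sigma >= 0, dispersion >= 0,
              depletion_per_doubling > 0, depletion_per_doubling <= 1,
              all(doublings >= 1L), n_t0 >= 1L, n_per_timepoint >= 1L)
  })
  if (!is.null(cfg$library_size_multipliers) &&
      any(cfg$library_size_multipliers <= 0)) {
    fail("library_size_multipliers must be positive")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed=%d, %d genes (%.0f%% in set, %d flagged)\n",
              x$seed, x$n_genes, 100 * x$frac_set, x$n_flagged))
  cat(sprintf("  GWAS: %d traits (%d enriched x%.1f), rate %.3g; PheWAS: %d datasets, %d phenotypes, %d categories\n",
              x$n_traits, x$n_enriched_traits, x$enrichment_effect,
              x$assoc_rate, x$n_datasets, x$n_phenotypes, x$n_categories))
  cat(sprintf("  screen: mean %g, sigma %g, dispersion %g, depletion %g/doubling\n",
              x$baseline_mean, x$baseline_sigma, x$dispersion,
              x$depletion_per_doubling))
  invisible(x)
}
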