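# Synthetic generators for the gene universe and the GWAS / PheWAS
# association tables. Each generator seeds its own RNG stream from the
# config seed plus a fixed per-generator offset, so outputs are reproducible
# independently of call order.

.SIM_OFFSETS <- c(universe = 11L, gwas = 23L, phewas = 37L, screen = 53L,
                  library = 71L)

#' Generate a synthetic gene universe
#'
#' Places `n_genes` fixed-length genes round-robin on synthetic chromosomes
#' with non-overlapping 0-based half-open intervals. A random fraction
#' `frac_set` of genes receives an aggregate pLoF MAF above
#' `maf_threshold` (the focal set); the rest fall below it. `n_flagged`
#' genes are additionally flagged misannotated or non-coding (alternating),
#' with above-threshold MAF, so that only the annotation filters remove
#' them.
#'
#' @param config a [sim_config()].
#' @return data frame of gene records (columns as in
#'   [read_gene_table()]) plus a logical `in_set` truth column.
#' @export
gen_gene_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, .SIM_OFFSETS["universe"]))
  n <- config$n_genes
  width <- max(4L, nchar(as.character(n)))
  symbol <- sprintf("G%0*d", width, seq_len(n))
  chrom_idx <- rep_len(seq_len(config$n_chromosomes), n)
  slot <- (seq_len(n) - 1L) %/% config$n_chromosomes
  start <- slot * (config$gene_length + config$gene_gap)
  end <- start + config$gene_length
  if (!is.null(config$chromosome_length) &&
      max(end) > config$chromosome_length) {
    fail("cannot pack %d genes of length %d (+%d gap) on %d chromosomes of length %g",
         n, config$gene_length, config$gene_gap, config$n_chromosomes,
         config$chromosome_length)
  }
  flagged <- rep(FALSE, n)
  if (config$n_flagged > 0L) {
    flagged[sample.int(n, config$n_flagged)] <- TRUE
  }
  unflagged_idx <- which(!flagged)
  n_set <- round(config$frac_set * length(unflagged_idx))
  in_set <- rep(FALSE, n)
  if (n_set > 0L) {
    in_set[sample(unflagged_idx, n_set)] <- TRUE
  }
  thr <- config$maf_threshold
  # above threshold: clearly separated from the cutoff; below: up to 90% of it
  maf <- ifelse(in_set | flagged,
                stats::runif(n, min = thr * 1.5, max = 0.05),
                stats::runif(n, min = 0, max = thr * 0.9))
  misannotated <- flagged & (seq_len(n) %% 2L == 0L)
  noncoding <- flagged & !misannotated
  data.frame(symbol = symbol,
             chrom = paste0("chr", chrom_idx),
             start = start, end = end,
             strand = sample(c("+", "-"), n, replace = TRUE),
             plof_maf = maf,
             coding = !noncoding,
             misannotated = misannotated,
             in_set = in_set,
             stringsAsFactors = FALSE)
}

.LOF_TERM_POOL <- c("stop_gained", "frameshift_variant",
                    "splice_donor_variant", "splice_acceptor_variant")
.NON_LOF_TERM_POOL <- c("missense_variant", "synonymous_variant",
                        "splice_region_variant", "intron_variant",
                        "3_prime_UTR_variant", "5_prime_UTR_variant")

#' Generate a synthetic GWAS-catalog-style association table
#'
#' Association counts per (trait, gene) pair are Poisson with rate
#' `assoc_rate`; for the first `n_enriched_traits` traits the rate for
#' set genes is multiplied by `enrichment_effect`. Each association row
#' carries a SNP position uniform within its gene (so every row is
#' intragenic by construction), a consequence term drawn from an LoF /
#' non-LoF mixture (`frac_lof`), and with probability `frac_unmapped` the
#' mapped gene is withheld to exercise nearest-gene assignment. Studies are
#' one per trait, so the catalog passes the study-level exclusion filters by
#' construction.
#'
#' @param universe gene universe from [gen_gene_universe()].
#' @param config a [sim_config()].
#' @return data frame of associations (columns as in
#'   [read_gwas_catalog()]) plus a logical `enriched_trait` truth column.
#' @export
gen_gwas_catalog <- function(universe, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, .SIM_OFFSETS["gwas"]))
  n_genes <- nrow(universe)
  n_traits <- config$n_traits
  width <- max(3L, nchar(as.character(n_traits)))
  traits <- sprintf("trait_%0*d", width, seq_len(n_traits))
  enriched <- seq_len(n_traits) <= config$n_enriched_traits

  rate <- matrix(config$assoc_rate, nrow = n_traits, ncol = n_genes)
  if (any(enriched) && config$enrichment_effect > 1) {
    rate[enriched, universe$in_set] <-
      rate[enriched, universe$in_set] * config$enrichment_effect
  }
  counts <- stats::rpois(length(rate), rate)
  dim(counts) <- dim(rate)
  idx <- which(counts > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(study_id = character(0), snp_id = character(0),
                      chromosome = character(0), position = integer(0),
                      mapped_gene = character(0), consequence = character(0),
                      mapped_trait = character(0), disease_trait = character(0),
                      enriched_trait = logical(0), stringsAsFactors = FALSE))
  }
  trait_i <- rep(idx[, 1], counts[idx])
  gene_i <- rep(idx[, 2], counts[idx])
  n_assoc <- length(gene_i)

  pos <- universe$start[gene_i] +
    floor(stats::runif(n_assoc) * (universe$end[gene_i] - universe$start[gene_i]))
  is_lof <- stats::runif(n_assoc) < config$frac_lof
  consequence <- character(n_assoc)
  consequence[is_lof] <- sample(.LOF_TERM_POOL, sum(is_lof), replace = TRUE)
  consequence[!is_lof] <- sample(.NON_LOF_TERM_POOL, sum(!is_lof),
                                 replace = TRUE)
  unmapped <- stats::runif(n_assoc) < config$frac_unmapped
  mapped_gene <- universe$symbol[gene_i]
  mapped_gene[unmapped] <- NA_character_

  data.frame(study_id = paste0("S_", traits[trait_i]),
             snp_id = sprintf("rs%07d", seq_len(n_assoc)),
             chromosome = universe$chrom[gene_i],
             position = as.integer(pos),
             mapped_gene = mapped_gene,
             consequence = consequence,
             mapped_trait = traits[trait_i],
             disease_trait = paste0("disease of ", traits[trait_i]),
             enriched_trait = enriched[trait_i],
             stringsAsFactors = FALSE)
}

#' Generate synthetic PheWAS association tables
#'
#' For each of `n_datasets` cohorts, phenotypes are assigned round-robin to
#' categories and each (phenotype, gene) pair is a significant association
#' with probability `phewas_rate`; for phenotypes in `enriched_categories`
#' the probability for set genes is multiplied by `category_effect`
#' (capped at 1).
#'
#' @param universe gene universe from [gen_gene_universe()].
#' @param config a [sim_config()].
#' @return data frame of associations (columns as in
#'   [read_phewas_table()]).
#' @export
gen_phewas_table <- function(universe, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, .SIM_OFFSETS["phewas"]))
  n_genes <- nrow(universe)
  n_ph <- config$n_phenotypes
  categories <- sprintf("category_%02d", seq_len(config$n_categories))
  ph_cat_idx <- rep_len(seq_len(config$n_categories), n_ph)
  out <- vector("list", config$n_datasets)
  for (d in seq_len(config$n_datasets)) {
    ph <- sprintf("D%d_pheno_%04d", d, seq_len(n_ph))
    prob <- matrix(config$phewas_rate, nrow = n_ph, ncol = n_genes)
    enr_ph <- ph_cat_idx %in% config$enriched_categories
    if (any(enr_ph) && config$category_effect > 1) {
      prob[enr_ph, universe$in_set] <-
        pmin(1, prob[enr_ph, universe$in_set] * config$category_effect)
    }
    hits <- which(stats::runif(length(prob)) < prob)
    ph_i <- ((hits - 1L) %% n_ph) + 1L
    gene_i <- ((hits - 1L) %/% n_ph) + 1L
    out[[d]] <- data.frame(dataset_id = paste0("dataset_", d),
                           phenotype = ph[ph_i],
                           category = categories[ph_cat_idx[ph_i]],
                           gene = universe$symbol[gene_i],
                           significant = TRUE,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
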