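# GWAS preprocessing (nearest gene, trait standardization, exclusion
# filters) and the permutation trait-enrichment statistic.

test_that("nearest-gene assignment: containment, brute-force distance, ties", {
  iv <- data.frame(chrom = "chr1", start = c(0L, 200L), end = c(100L, 300L),
                   symbol = c("A", "B"), stringsAsFactors = FALSE)
  cat <- toy_catalog(gene = NA_character_, trait = "t",
                     position = c(50L, 120L))
  out <- assign_nearest_gene(cat, iv)
  expect_equal(out$mapped_gene, c("A", "A"))  # 0 inside; 21 vs 80
  expect_equal(out$gene_distance, c(0, 21))
  # brute force over both genes for position 120
  d <- c(min(abs(120 - 99), abs(120 - 0)), min(abs(120 - 299), abs(120 - 200)))
  expect_equal(out$gene_distance[2], min(d))

  # tie at equal distance: smaller start wins, then symbol
  iv2 <- data.frame(chrom = "chr1", start = c(0L, 20L), end = c(10L, 30L),
                    symbol = c("Z", "Y"), stringsAsFactors = FALSE)
  cat2 <- toy_catalog(gene = NA_character_, trait = "t", position = 14L)
  expect_equal(assign_nearest_gene(cat2, iv2)$mapped_gene, "Z")

  # no same-chromosome gene: dropped and counted
  cat3 <- toy_catalog(gene = NA_character_, trait = "t",
                      chromosome = "chrX", position = 5L)
  out3 <- assign_nearest_gene(cat3, iv)
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "n_dropped_no_gene"), 1)

  # malformed interval errors
  iv_bad <- data.frame(chrom = "chr1", start = 10L, end = 10L, symbol = "A")
  expect_error(assign_nearest_gene(cat, iv_bad), "malformed")
})

test_that("trait standardization prefers mapped_trait and drops empty rows", {
  cat <- toy_catalog(gene = "G", trait = "x")
  cat$mapped_trait <- c("bilirubin measurement")
  cat$disease_trait <- "something else"
  expect_equal(standardize_traits(cat)$trait, "bilirubin measurement")

  cat2 <- rbind(cat, cat, cat)
  cat2$mapped_trait <- c("", NA, " gout ")
  cat2$disease_trait <- c("gout", "", "ignored")
  out <- standardize_traits(cat2)
  expect_equal(out$trait, c("gout", "gout"))  # fallback; trim; drop row 2
  expect_equal(attr(out, "n_dropped_no_trait"), 1)
})

test_that("catalog filters apply in order and match manual enumeration", {
  # S1: 2 traits x 6 genes (kept); S2: 11 traits (dropped at step 1);
  # trait "small" in S1 has 4 genes (dropped at step 3)
  s1 <- toy_catalog(gene = sprintf("g%d", 1:6), trait = "big", study = "S1")
  s1b <- toy_catalog(gene = sprintf("g%d", 1:4), trait = "small",
                     study = "S1")
  s2 <- toy_catalog(gene = "g1", trait = sprintf("t%02d", 1:11),
                    study = "S2")
  cat <- standardize_traits(rbind(s1, s1b, s2))
  out <- filter_catalog(cat)
  expect_setequal(out$trait, "big")
  expect_equal(nrow(out), 6)
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_entities_removed, c(1, 0, 1))
  expect_equal(rep$n_rows_removed, c(11, 0, 4))

  # a catalog within all bounds is unchanged
  out2 <- filter_catalog(standardize_traits(s1))
  expect_equal(nrow(out2), 6)
})

test_that("study gene-count filter drops studies with too many genes", {
  big <- toy_catalog(gene = sprintf("g%d", 1:20), trait = "t", study = "SB")
  cat <- standardize_traits(big)
  out <- filter_catalog(cat, max_genes_per_study = 10)
  expect_equal(nrow(out), 0)
})

test_that("sampled permutation null matches an exhaustive enumeration oracle", {
  # 6 genes, 3 traits, set of 2 genes: all C(6,2) = 15 subsets enumerable
  genes <- sprintf("g%d", 1:6)
  pairs <- rbind(
    toy_catalog(gene = genes[1:5], trait = "t1"),
    toy_catalog(gene = genes[c(1, 2, 3)], trait = "t2"),
    toy_catalog(gene = genes[c(4, 6)], trait = "t3"))
  pairs <- standardize_traits(pairs)
  set <- c("g1", "g4")

  # independent oracle: enumerate subsets and count in-set pairs per trait
  subsets <- combn(genes, 2)
  oracle_counts <- sapply(c("t1", "t2", "t3"), function(tr) {
    tg <- unique(pairs$mapped_gene[pairs$trait == tr])
    apply(subsets, 2, function(s) sum(s %in% tg))
  })
  oracle_mean <- colMeans(oracle_counts)
  oracle_sd <- apply(oracle_counts, 2, function(v) sqrt(mean((v - mean(v))^2)))

  exact <- permutation_trait_enrichment(pairs, set, exhaustive = TRUE)
  expect_equal(exact$null_mean, unname(oracle_mean[exact$trait]))
  expect_equal(exact$null_sd, unname(oracle_sd[exact$trait]))

  sampled <- permutation_trait_enrichment(pairs, set, n_perm = 4000, seed = 7)
  se_mean <- oracle_sd / sqrt(4000)
  expect_true(all(abs(sampled$null_mean - oracle_mean[sampled$trait]) <=
                    3 * se_mean[sampled$trait] + 1e-9))
  expect_true(all(abs(sampled$null_sd - oracle_sd[sampled$trait]) < 0.1))

  # observed counts agree between modes and with direct counting
  expect_equal(exact$observed, sampled$observed)
  expect_equal(exact$observed[exact$trait == "t1"], 2)
})

test_that("degenerate and duplicate-row cases behave as specified", {
  genes <- sprintf("g%d", 1:4)
  cat <- standardize_traits(toy_catalog(gene = genes, trait = "t1"))
  # set = whole catalog universe -> SD 0, z undefined, excluded from BH
  res <- permutation_trait_enrichment(cat, genes, n_perm = 50, seed = 1)
  expect_equal(res$null_sd, 0)
  expect_true(is.na(res$z))
  expect_true(is.na(res$q))

  # duplicated SNP rows do not change observed (unique-pair rule)
  dup <- standardize_traits(rbind(toy_catalog(gene = "g1", trait = "t1",
                                              snp = "rs1"),
                                  toy_catalog(gene = "g1", trait = "t1",
                                              snp = "rs1"),
                                  toy_catalog(gene = "g2", trait = "t1")))
  res2 <- permutation_trait_enrichment(dup, "g1", n_perm = 50, seed = 1)
  expect_equal(res2$observed, 1)

  # disjoint set errors
  expect_error(permutation_trait_enrichment(cat, "nope", n_perm = 10,
                                            seed = 1),
               "no genes")
})

test_that("LoF restriction and intragenic restriction are applied", {
  iv <- data.frame(chrom = "chr1", start = c(0L, 200L), end = c(100L, 300L),
                   symbol = c("A", "B"), stringsAsFactors = FALSE)
  cat <- standardize_traits(rbind(
    toy_catalog(gene = "A", trait = "t1", consequence = "stop_gained",
                position = 10L),
    toy_catalog(gene = "A", trait = "t2", consequence = "missense_variant",
                position = 10L),                       # non-LoF: excluded
    toy_catalog(gene = "B", trait = "t3", consequence = "stop_gained",
                position = 150L)))                     # outside B: excluded
  res <- permutation_trait_enrichment(cat, "A", n_perm = 10, seed = 1,
                                      intervals = iv)
  expect_setequal(res$trait, "t1")
})

test_that("adding an in-set gene-trait pair never decreases observed", {
  genes <- sprintf("g%d", 1:8)
  base <- standardize_traits(toy_catalog(gene = genes[1:4], trait = "t1"))
  set <- c("g1", "g5")
  res1 <- permutation_trait_enrichment(base, set, n_perm = 20, seed = 1)
  more <- standardize_traits(rbind(toy_catalog(gene = genes[1:4], trait = "t1"),
                                   toy_catalog(gene = "g5", trait = "t1")))
  res2 <- permutation_trait_enrichment(more, set, n_perm = 20, seed = 1)
  expect_gte(res2$observed, res1$observed)
})

test_that("report_traits applies the hits and z thresholds and sorts by |z|", {
  res <- data.frame(trait = c("a", "b", "c", "d"),
                    n_hits = c(5, 4, 10, 7),
                    z = c(2.1, 9, 1.9, NA))
  out <- report_traits(res)
  expect_equal(out$trait, "a")
  expect_equal(nrow(report_traits(res[0, ])), 0)
  res$z <- NA_real_
  expect_equal(nrow(report_traits(res)), 0)
})

test_that("empirical p option and BH q-values agree with oracles", {
  set.seed(31)
  # BH against the brute-force step-up oracle on random vectors
  for (i in 1:5) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # empirical p is a valid probability and close to normal p for normal-ish nulls
  genes <- sprintf("g%d", 1:8)
  cat <- standardize_traits(rbind(toy_catalog(gene = genes[1:6], trait = "t1"),
                                  toy_catalog(gene = genes[3:8], trait = "t2")))
  res <- permutation_trait_enrichment(cat, c("g1", "g3", "g5"),
                                      n_perm = 500, seed = 3,
                                      p_method = "empirical")
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
})
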