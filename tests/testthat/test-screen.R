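# Guide quantification, sample QC, control-guide normalization, the
# negative-binomial depletion test, and gene-level / essentiality calls.

test_that("count_guides counts exact matches and tracks the mapping rate", {
  man <- toy_manifest(genes = c("A", "B"))
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "s.fastq")
  # one read with guide 1 embedded, one unmappable read
  write_fastq(c(paste0("AAAA", man$sequence[1], "TTTT"),
                strrep("N", 28)), fq)
  res <- count_guides(fq, man)
  expect_equal(unname(res$counts[man$guide_id[1]]), 1)
  expect_equal(sum(res$counts), 1)
  expect_equal(res$mapping_rate, 0.5)
  # fixed-offset mode finds the guide only at the right position
  res5 <- count_guides(fq, man, offset = 5)
  expect_equal(sum(res5$counts), 1)
  res1 <- count_guides(fq, man, offset = 1)
  expect_equal(sum(res1$counts), 0)

  expect_error(suppressWarnings(count_guides(file.path(dir, "missing.fastq"),
                                             man)))
  writeLines(character(0), file.path(dir, "empty.fastq"))
  expect_error(count_guides(file.path(dir, "empty.fastq"), man), "empty")
})

test_that("simulator FASTQ round-trips to the exact count matrix", {
  man <- design_library(sprintf("G%02d", 1:15), n_ntc = 3, n_safeharbor = 3,
                        seed = 4)
  cfg <- sim_config(seed = 5, baseline_mean = 40, n_t0 = 2,
                    n_per_timepoint = 2)
  x <- gen_screen_counts(man, cfg)
  dir <- withr::local_tempdir()
  paths <- gen_screen_fastq(x, man, dir)
  rebuilt <- count_guides_matrix(paths, man, x$samples)
  expect_identical(rebuilt$counts, x$counts)
  expect_true(all(rebuilt$samples$mapping_rate == 1))
})

test_that("sample QC separates timepoints and handles degenerate input", {
  man <- design_library(sprintf("G%02d", 1:30), n_ntc = 0, n_safeharbor = 3,
                        seed = 6)
  cfg <- sim_config(seed = 7, baseline_mean = 300)
  x <- gen_screen_counts(man, cfg,
                         essential_genes = sprintf("G%02d", 1:10))
  qc <- sample_qc(x)
  expect_lte(sum(qc$explained_var), 1)
  # first coordinate separates T0 from T14 (sign-invariant)
  pc1_t0 <- qc$pca$PC1[qc$pca$timepoint == "T0"]
  pc1_t14 <- qc$pca$PC1[qc$pca$timepoint == "T14"]
  expect_true(max(pc1_t0) < min(pc1_t14) || min(pc1_t0) > max(pc1_t14))

  # identical samples project to the same point
  y <- toy_counts(rep(c(5L, 9L, 2L), 2), c("g1", "g2", "g3"), c("a", "b"))
  qc2 <- sample_qc(screen_counts(y, data.frame(sample = c("a", "b"),
                                               timepoint = "T0",
                                               replicate = 1:2)))
  expect_equal(qc2$pca$PC1[1], qc2$pca$PC1[2])

  # constant matrix: zero coordinates, zero explained variance
  z <- toy_counts(rep(4L, 6), c("g1", "g2", "g3"), c("a", "b"))
  qc3 <- sample_qc(screen_counts(z, data.frame(sample = c("a", "b"),
                                               timepoint = "T0",
                                               replicate = 1:2)))
  expect_equal(qc3$pca$PC1, c(0, 0))
  expect_equal(unname(qc3$explained_var), c(0, 0))
})

test_that("control size factors: symmetry, exact scaling, and recovery", {
  ids <- sprintf("c%d", 1:5)
  base <- c(100L, 200L, 50L, 400L, 80L)
  y <- toy_counts(c(base, base), ids, c("a", "b"))
  f <- control_size_factors(y, ids)
  expect_equal(f[["a"]], f[["b"]])

  y2 <- toy_counts(c(base, 2L * base), ids, c("a", "b"))
  f2 <- control_size_factors(y2, ids)
  expect_equal(f2[["b"]] / f2[["a"]], 2)
  # hand computation: ref = sqrt(base * 2 base); factors are medians of
  # base/ref = 1/sqrt(2) and 2 base/ref = sqrt(2)
  expect_equal(unname(f2), c(1 / sqrt(2), sqrt(2)))

  # guides with a zero anywhere are excluded from the reference set
  y3 <- toy_counts(c(0L, base[-1], 10L, 2L * base[-1]), ids, c("a", "b"))
  f3 <- control_size_factors(y3, ids)
  expect_equal(f3[["b"]] / f3[["a"]], 2)

  expect_error(control_size_factors(
    toy_counts(c(0L, 5L), c("c1"), c("a", "b")), "c1"), "nonzero")
  expect_error(control_size_factors(y, c("c1", "nope")), "absent")

  # NB noise, known multipliers 1 / 0.5 / 2, dispersion 0.05:
  # recovered within 10% (25 control guides)
  errs <- sapply(1:5, function(s) {
    set.seed(s)
    mult <- c(1, 0.5, 2)
    mu <- outer(rlnorm(25, log(500), 0.5), mult)
    yy <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), nrow = 25)
    rownames(yy) <- sprintf("c%d", 1:25)
    colnames(yy) <- c("a", "b", "c")
    f <- control_size_factors(yy, rownames(yy))
    fn <- f / exp(mean(log(f)))
    mn <- mult / exp(mean(log(mult)))
    max(abs(fn / mn - 1))
  })
  expect_true(all(errs < 0.15))
  expect_lt(median(errs), 0.1)
})

test_that("scaling one sample's counts scales its factor relative to the others", {
  # the geometric-mean reference moves with the scaled sample, so the
  # invariant is exact on factor ratios (the scale that matters for
  # normalization), not on the unscaled factors themselves
  ids <- sprintf("c%d", 1:5)
  base <- c(100L, 200L, 50L, 400L, 80L)
  y <- toy_counts(c(base, base, base), ids, c("a", "b", "c"))
  f1 <- control_size_factors(y, ids)
  y[, "c"] <- y[, "c"] * 3L
  f2 <- control_size_factors(y, ids)
  expect_equal((f2[["c"]] / f2[["a"]]) / (f1[["c"]] / f1[["a"]]), 3,
               tolerance = 1e-9)
})

test_that("NB test: null identity, closed-form log2fc, Poisson oracle", {
  samples <- c("a1", "a2", "b1", "b2")
  sf <- unit_size_factors(samples)
  # identical arms -> log2fc 0, p ~ 1
  y <- toy_counts(rep(c(30L, 70L), 4), c("g1", "g2"), samples)
  res <- nb_depletion_test(y, c("a1", "a2"), c("b1", "b2"), sf)
  expect_equal(res$log2fc, c(0, 0))
  expect_true(all(res$p > 0.99))

  # dispersion -> 0 limit with arm totals 100 vs 25: log2fc exactly -2
  y2 <- toy_counts(c(50L, 50L, 50L, 50L, 13L, 12L, 12L, 13L),
                   c("g1", "g2"), samples)
  res2 <- nb_depletion_test(y2, c("a1", "a2"), c("b1", "b2"), sf)
  expect_equal(res2$log2fc, c(-2, -2))
  # se in the Poisson limit is sqrt(1/100 + 1/25) on the natural-log scale
  expect_equal(res2$se, rep(sqrt(1 / 100 + 1 / 25) / log(2), 2),
               tolerance = 1e-6)

  # moderate effects: Wald p within 10% of the exact conditional
  # binomial mid-p oracle (Poisson limit, equal exposures)
  midp <- function(yB, n) 2 * (pbinom(yB, n, 0.5) - 0.5 * dbinom(yB, n, 0.5))
  for (tB in c(65L, 70L, 80L)) {
    half <- tB %/% 2L
    y3 <- toy_counts(c(50L, 50L, half, tB - half), "g1", samples)
    res3 <- nb_depletion_test(y3, c("a1", "a2"), c("b1", "b2"), sf)
    oracle <- midp(tB, 100L + tB)
    expect_lt(abs(res3$p - oracle) / oracle, 0.1)
  }
})

test_that("NB test handles zero-total arms and all-zero guides", {
  samples <- c("a1", "a2", "b1", "b2")
  sf <- unit_size_factors(samples)
  y <- toy_counts(c(10L, 0L, 10L, 0L, 0L, 0L, 0L, 0L),
                  c("gz", "gnone"), samples)
  res <- nb_depletion_test(y, c("a1", "a2"), c("b1", "b2"), sf)
  # zero timepoint arm: 0.5 pseudocount on both totals, finite stats
  expect_true(is.finite(res$log2fc[1]))
  expect_lt(res$log2fc[1], 0)
  # all-zero guide flagged not testable, NA stats, excluded from BH
  expect_false(res$testable[2])
  expect_true(is.na(res$p[2]))
  padj <- bh_adjust(res$p)
  expect_true(is.na(padj[2]))
  expect_error(nb_depletion_test(y, "a1", c("b1", "b2"), sf), "at least 2")
})

test_that("BH adjustment matches the step-up oracle and is order-invariant", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(17)
  for (i in 1:5) {
    p <- runif(sample(2:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    o <- sample(seq_along(p))
    expect_equal(bh_adjust(p[o]), bh_adjust(p)[o])
  }
})

test_that("gene-level call: at least one significant guide makes the gene significant", {
  g2g <- c(sg1 = "A", sg2 = "A", sg3 = "B", sg4 = "B", sg5 = "C", sg6 = "C")
  gr <- data.frame(guide_id = names(g2g),
                   log2fc = c(-1, -0.2, -0.5, -0.1, NA, NA),
                   padj = c(0.01, 0.2, 0.2, 0.2, NA, NA))
  out <- gene_level_call(gr, g2g, alpha = 0.05)
  expect_true(out$significant[out$gene == "A"])
  expect_false(out$significant[out$gene == "B"])
  expect_true(is.na(out$significant[out$gene == "C"]))
  # gene-level log2fc comes from the minimum-padj guide
  expect_equal(out$log2fc[out$gene == "A"], -1)
  out2 <- gene_level_call(data.frame(guide_id = c("sg1", "sg2"),
                                     log2fc = c(-1, -1),
                                     padj = c(0.04, 0.04)),
                          g2g[1:2], alpha = 0.05)
  expect_true(out2$significant)
})

test_that("essentiality call requires negative, increasing, significant depletion", {
  mk <- function(lfc, padj) data.frame(gene = "g", n_guides = 2,
                                       min_padj = padj, log2fc = lfc)
  expect_true(call_essential(mk(-1, 0.01), mk(-2, 0.01))$essential)
  expect_false(call_essential(mk(-2, 0.01), mk(-1, 0.01))$essential)
  expect_false(call_essential(mk(1, 0.01), mk(2, 0.01))$essential)
  expect_false(call_essential(mk(-1, 0.2), mk(-2, 0.01))$essential)
  expect_true(is.na(call_essential(mk(-1, NA), mk(-2, 0.01))$essential))
})

test_that("full screen analysis recovers spiked essentials and neutral controls", {
  genes <- sprintf("G%03d", 1:80)
  ess <- genes[1:8]
  man <- design_library(genes, n_ntc = 10, n_safeharbor = 5, seed = 19)
  cfg <- sim_config(seed = 20, baseline_mean = 500, dispersion = 0.05)
  x <- gen_screen_counts(man, cfg, essential_genes = ess)
  res <- run_depletion_analysis(x, man)

  called <- res$essentiality$gene[which(res$essentiality$essential)]
  expect_gte(sum(called %in% ess), 7)          # sensitivity
  expect_lte(sum(!called %in% ess), 1)         # false calls

  # safe-harbor guides stay neutral in every contrast
  sh <- man$guide_id[man$target_class == "safe_harbor"]
  for (tp in names(res$guide_results)) {
    gr <- res$guide_results[[tp]]
    expect_lt(abs(mean(gr$log2fc[gr$guide_id %in% sh])), 0.1)
  }
})
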