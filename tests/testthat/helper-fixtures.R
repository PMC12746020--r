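# Small programmatic fixtures shared across test files.

# minimal gene table; maf/coding/misannotated recycled
toy_gene_table <- function(n = 6, maf = 0.01, coding = TRUE,
                           misannotated = FALSE, chrom = "chr1") {
  data.frame(symbol = sprintf("G%03d", seq_len(n)),
             chrom = rep_len(chrom, n),
             start = (seq_len(n) - 1L) * 1000L,
             end = (seq_len(n) - 1L) * 1000L + 500L,
             strand = rep_len("+", n),
             plof_maf = rep_len(maf, n),
             coding = rep_len(coding, n),
             misannotated = rep_len(misannotated, n),
             stringsAsFactors = FALSE)
}

# catalog rows from parallel vectors (defaults make a valid mapped row)
toy_catalog <- function(gene, trait, consequence = "stop_gained",
                        study = "S1", position = 0L, chromosome = "chr1",
                        snp = NULL) {
  n <- max(length(gene), length(trait), length(consequence),
           length(study), length(position))
  data.frame(study_id = rep_len(study, n),
             snp_id = if (is.null(snp)) sprintf("rs%03d", seq_len(n))
                      else rep_len(snp, n),
             chromosome = rep_len(chromosome, n),
             position = rep_len(position, n),
             mapped_gene = rep_len(gene, n),
             consequence = rep_len(consequence, n),
             mapped_trait = rep_len(trait, n),
             disease_trait = rep_len(trait, n),
             stringsAsFactors = FALSE)
}

toy_manifest <- function(genes = c("A", "B"), n_ntc = 2, n_safeharbor = 2,
                         seed = 42) {
  design_library(genes, n_ntc = n_ntc, n_safeharbor = n_safeharbor,
                 seed = seed)
}

# counts matrix with named dims from a vector (guides x samples)
toy_counts <- function(values, guides, samples) {
  m <- matrix(values, nrow = length(guides), ncol = length(samples))
  rownames(m) <- guides
  colnames(m) <- samples
  storage.mode(m) <- "integer"
  m
}

unit_size_factors <- function(samples) stats::setNames(rep(1, length(samples)),
                                                       samples)

# brute-force Benjamini-Hochberg step-up, written independently of p.adjust:
# q_i = min over j with p_(j) >= p_(i) of min(1, n * p_(j) / j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  adj <- pmin(1, n * p[o] / seq_len(n))
  # enforce monotonicity from the largest p down
  if (n > 1) for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  q[o] <- adj
  q
}
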