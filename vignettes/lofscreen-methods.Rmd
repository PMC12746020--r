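---
title: "Methods: common-LoF gene sets, trait enrichment, and dropout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: common-LoF gene sets, trait enrichment, and dropout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofscreen)
```

# The scientific problem

A small fraction of human genes carries predicted loss-of-function (pLoF)
alleles — premature stops, frameshifts, disrupted essential splice sites —
at appreciable aggregate frequency in the population. Genes whose aggregate
pLoF mean allele frequency exceeds the conventional common-variant cutoff of
0.1% are natural candidates for explaining inter-individual variability in
phenotypes, including susceptibility to chemical exposures: a person
homozygous for such alleles effectively lacks the gene product. `lofscreen`
implements the computational arc of characterizing such a gene set:

1. **Set construction** from a gene-level aggregate pLoF frequency table
   (`build_lof_geneset()`).
2. **Trait over-representation** of the set in GWAS-catalog-style and
   PheWAS-style association tables, against permutation nulls
   (`permutation_trait_enrichment()`, `phewas_enrichment()`).
3. **Targeted CRISPR knockout library design and QC**
   (`design_library()`, `representation_qc()`).
4. **Pooled dropout-screen analysis** from reads to gene-level
   essentiality calls (`count_guides()`, `control_size_factors()`,
   `nb_depletion_test()`, `run_depletion_analysis()`).

A synthetic-data generator (`sim_config()` and the `gen_*()` functions)
emulates every input, so the full pipeline is exercised and validated
without external downloads.

# Gene-set construction

The input table has one row per gene with its aggregate pLoF mean allele
frequency (`plof_maf`, a fraction in [0, 1]), genomic interval (0-based
half-open, BED convention), and two annotation flags (`misannotated`,
`coding`). `build_lof_geneset()` retains genes with
`plof_maf > maf_threshold` (strictly greater, matching the "greater than
0.1%" phrasing of common-variant cutoffs; default threshold 0.001) that are
coding and not misannotated.

Because the source of a removal matters for reporting, drops are accounted
with a fixed precedence — misannotated first, then non-coding, then the MAF
cutoff — so the three counts are disjoint and sum, with the retained set, to
the input size. A gene flagged both misannotated and non-coding is counted
once, as misannotated.

Consequence terms use the Ensembl vocabulary. Exactly four terms are
classified loss-of-function: `stop_gained`, `frameshift_variant`,
`splice_donor_variant`, `splice_acceptor_variant`. Matching is
case-insensitive on the trimmed term. Unknown terms classify as non-LoF —
real catalogs grow new terms, and erroring on them would make the pipeline
brittle — but they are counted (attribute `n_unknown`) so silent vocabulary
drift is visible.

`consequence_frequency_diff()` compares the composition of consequence
types between associations assigned to set members and to all other genes,
as the percent difference `100 * (f_in - f_out) / f_out` of within-group
shares. A term never observed outside the set would divide by zero; it is
reported as a flagged undefined value (`NA` + `undefined = TRUE`) rather
than as an infinity.

# GWAS trait enrichment

## Preprocessing

* **Nearest-gene assignment** (`assign_nearest_gene()`): rows without a
  mapped gene are assigned the nearest same-chromosome gene. Distance to a
  gene `[start, end)` is 0 inside the interval and otherwise
  `min(|pos - (end - 1)|, |pos - start|)`, on 0-based coordinates. Ties
  break deterministically: smaller start, then lexicographic symbol. Rows
  on chromosomes with no genes are dropped and counted.
* **Trait standardization** (`standardize_traits()`): the mapped-trait
  field wins when present; the original disease trait is the fallback; rows
  with neither are dropped and counted. Values are whitespace-trimmed, case
  preserved.
* **Exclusion filters** (`filter_catalog()`): a single pass in a fixed
  order — studies reporting more than 10 distinct traits, then studies
  reporting more than 1,000 distinct genes, then traits left with fewer
  than 5 distinct genes. The order is applied once, without fixpoint
  iteration (re-running step 3 after step 3 could cascade; the
  single-sentence description of these filters reads most naturally as one
  pass). Counts removed at each step are reported.

## The permutation statistic

For the focal set, `observed(trait)` is the number of **unique**
(gene, trait) pairs among loss-of-function, intragenic associations whose
gene belongs to the set — uniqueness avoids double counting traits reported
by multiple SNPs or studies for the same gene. The null resamples gene
sets: `n_perm` draws (default 1,000) of `m` genes without replacement from
all genes present in the filtered catalog, where `m` is the size of the
intersection of the focal set with those catalog genes. Matching on the
intragenic catalog footprint, rather than the nominal set size, is
deliberate: genes absent from the catalog can never produce hits, so
including them would deflate the null. Sets are sampled uniformly,
unmatched on gene length or chromosome.

The statistic is `z = (observed - mean(null)) / sd(null)`. When the null SD
is zero (e.g. the set covers the whole catalog universe) the z-score is
undefined and the trait is excluded from multiplicity adjustment — never
reported as infinite. Two-sided p-values use the normal approximation
`p = 2 * pnorm(-|z|)`, the canonical choice here since z is the reported
effect scale; an empirical rank p-value (`p_method = "empirical"`) is
available when the normal approximation is in doubt. Benjamini–Hochberg
q-values are computed over all traits with defined z. The reporting filter
keeps traits with at least 5 observed hits and `|z| > 2`.

For universes of up to a dozen genes the null can be enumerated exactly
(`exhaustive = TRUE`, all `choose(G, m)` subsets); the test suite checks
the sampled null against an independently coded enumeration oracle.

# PheWAS category enrichment

Each cohort dataset is analysed independently (q-values within dataset).
The observed quantity is the distribution of phenotype categories among
significant associations involving set genes; each of `n_perm` permutations
draws the same **number of association rows** without replacement from the
dataset's full significant-association pool and recomputes category
proportions. The resampling unit — the association row, matched in count to
the observed set-gene rows — is one of two defensible readings of
"sampling the same number of phenotypes"; it is the one that keeps the
observed and null quantities on identical footing (proportions over rows),
and it is recorded in the result's provenance so the alternative
(phenotype-level resampling) could be compared. "Significant" is an input
flag: thresholding upstream association statistics is out of scope, and the
synthetic generator marks rows directly.

Per dataset, the observed and every permuted category-proportion vector
each sum to 1, which the suite asserts. z, p, and the reporting filter
match the GWAS module.

# Library design and representation QC

`design_library()` builds two sets (SET1, SET2) that target the same gene
list at different positions: per set, one targeting guide per gene, 100
non-targeting controls, and 5 safe-harbor guides spread over two synthetic
safe-harbor loci (defaults match the screen design the package models).
Real designs rank candidate guides by predicted efficacy; that scoring is
out of scope here, so sequences are unique random 20-mers over ACGT
(uniqueness by rejection sampling; the 4^20 sequence space makes rejection
negligible).

`representation_qc()` implements the two acceptance metrics for a
synthesized or cloned pool:

* **Pearson correlation** between two aligned count vectors (e.g. oligo
  pool vs cloned pool), computed on raw counts — a log1p variant is easy to
  apply upstream, but raw counts are the canonical scale here.
* **90th/10th percentile ratio** of per-guide counts, with percentiles by
  linear interpolation between order statistics (R quantile type 7 — stated
  explicitly because percentile conventions differ across software). A pool
  passes when the ratio is at most six-fold. A zero 10th percentile is
  floored at one pseudocount and flagged, keeping the ratio finite for
  pathologically skewed pools.

The generator's default baseline abundance spread (`baseline_sigma = 0.5`
on the log scale) was chosen once as a realistic clean-library profile; it
places the 90/10 ratio of simulated pools comfortably under six-fold, while
`baseline_sigma` around 1.5 reliably fails the criterion — the suite checks
both directions.

# Screen analysis

## Quantification and QC

`count_guides()` reimplements guide counting as exact 20-mer matching: each
read is scanned (every offset by default, or a fixed offset) for a manifest
sequence; the first hit is counted; the per-sample mapping rate is
reported. The synthetic FASTQ generator emits error-free reads — each
guide's exact sequence in fixed vector flanks, repeated per sampled count —
so exact matching is the correct oracle and the suite asserts a perfect
round trip. Real reads carry sequencing errors; handling them
(mismatch-tolerant alignment) is deliberately out of scope.

`sample_qc()` reports per-sample totals, mapping rates, and a PCA of
`log1p` depth-normalized counts (guides as features) for replicate
clustering and batch-effect checks; a constant matrix yields zero
coordinates and zero explained variance rather than an error.

## Normalization

Sequencing depth and bottleneck effects are normalized with
**safe-harbor-based median-of-ratios** (`control_size_factors()`): the
reference for each control guide is its geometric mean across samples
(guides with any zero count are excluded from the reference set); a
sample's factor is the median over controls of count/reference. Targeting
guides are excluded from normalization because true depletion would bias
factors; safe-harbor cuts are phenotypically neutral yet control for
Cas9 cutting toxicity. Factors are reported unscaled; since the geometric
mean reference moves with the samples, the meaningful invariant is on
factor ratios (scaling one sample's counts by c scales its factor relative
to the others by exactly c for noise-free controls).

## The depletion test

Per guide and contrast (T7 vs T0, T14 vs T0), counts are modeled as
negative binomial with mean `mu = q * s_j * exp(beta * x_j)` where `s_j` is
the sample's size factor and `x_j` indicates the later-timepoint arm:

* **Fold change**: `beta = log(meanB / meanA)` with `mean = total counts /
  total size factors` per arm — the maximum-likelihood estimate in the
  Poisson limit and the natural moment estimate generally. A zero arm total
  receives a 0.5 pseudocount on both arms. `log2fc = beta / log(2)`.
* **Dispersion** (`variance = mu + alpha * mu^2`): per-guide
  method-of-moments on size-factor-scaled counts, pooled across the two
  arms, then **moderated** toward the across-guide mean with weight
  `df / (df + prior_df)` on the per-guide estimate (`prior_df = 20` by
  default), floored at 1e-8. Moderation is essential: with 3 + 4 samples a
  guide has 5 residual degrees of freedom, and the raw moment estimate is
  so noisy that the Wald test's null type-I error at p < 0.05 roughly
  doubles its nominal level; borrowing strength across guides (the same
  idea as dispersion shrinkage in standard count-model packages) restores
  calibration, which the acceptance suite verifies on 2,000-guide null
  simulations. `prior_df = 0` recovers unmoderated per-guide estimates.
* **Wald test**: `se^2(beta) = sum over arms of [1 / (mean * sum(s)) +
  alpha * sum(s^2) / sum(s)^2]` (the delta-method/observed-information
  variance of a log scaled mean), `wald = beta / se`,
  `p = 2 * pnorm(-|wald|)`. In the dispersion-free limit this reduces to
  `se^2 = 1/totalA + 1/totalB`, and at moderate effect sizes the p-value
  tracks the exact conditional binomial mid-p test within a few percent
  (asserted in the suite). Deep in the tail, normal and exact tail areas
  diverge — a property of every Wald statistic — so significance claims at
  extreme p rest on the BH threshold, not on the literal tail mass.

Guides with zero counts everywhere are flagged not-testable and excluded
from the Benjamini–Hochberg family; adjustment is per contrast, mirroring
one volcano plot per timepoint.

## Gene-level calls

A gene is **significant** in a contrast iff at least one of its (two)
guides has adjusted p below alpha (default 0.05). A gene is **essential**
iff, using the minimum-padj guide per contrast as the gene-level estimate:
`log2fc < 0` at both timepoints, the depletion magnitude increases
(`|log2fc_T14| > |log2fc_T7|` — "increasing depletion" read as magnitude,
since a literal numeric increase of a negative log-fold change would mean
recovery, contradicting the dropout context), and adjusted p < 0.05 in both
contrasts. The minimum-padj guide is used because the best-powered guide
carries the gene-level signal under the one-of-two significance rule; a
mean-of-guides alternative would be a straightforward variant.

# The synthetic-data generator

`sim_config()` fixes the study conditions; identical config + seed gives
byte-identical outputs, each generator seeding its own RNG stream.

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes in the universe |
| `frac_set` | 0.1 | fraction of genes given above-threshold pLoF MAF |
| `maf_threshold` | 0.001 | the 0.1% common-variant cutoff |
| `assoc_rate` | 0.1 | expected GWAS associations per (trait, gene) |
| `frac_lof` | 0.5 | LoF share of consequence terms |
| `enrichment_effect` | 1 | rate multiplier for enriched traits x set genes |
| `phewas_rate` | 0.01 | significant-association probability per (phenotype, gene) |
| `baseline_mean` | 500 | expected guide count at T0 (≈500x coverage) |
| `baseline_sigma` | 0.5 | lognormal log-scale sd of guide abundance |
| `dispersion` | 0.05 | NB overdispersion alpha (variance = mu + alpha mu^2) |
| `depletion_per_doubling` | 0.8 | abundance retention per doubling, essential knockouts |
| `doublings` | T7 = 7, T14 = 14 | population doublings per timepoint |
| `n_t0`, `n_per_timepoint` | 3, 4 | replicates at baseline / per timepoint |

The screen layout (three baseline samples, four per later timepoint, 7 and
14 doublings), the 0.1% threshold, the 1551-of-1555 gene-set fixture, the
two-set library composition (one guide per gene per set, 100 non-targeting
and 5 safe-harbor controls), and the six-fold representation bound are the
study conditions the package models. Where the conditions do not pin a
value (association rates, dispersion, abundance spread, depletion rate) the
defaults above were chosen once as what a practitioner would call a
realistic clean experiment — e.g. dispersion 0.05 is a typical biological
replicate overdispersion for pooled screens, and a 20% fitness cost per
doubling produces the expected `7 * log2(0.8) ≈ -2.25` log2 fold change at
T7 — and are not revisited per analysis.

What the generator deliberately does **not** model: sequencing errors and
PCR jackpots (reads are exact), linkage disequilibrium and population
structure (associations are independent across genes), trait ontology
structure (traits are exchangeable labels), guide-efficacy heterogeneity
(all targeting guides of an essential gene deplete at the same rate), and
copy-number artifacts. Passing tests therefore demonstrate correctness of
the statistics under the stated model, not robustness to these real-data
complications.

# Numerical choices and degenerate inputs

* Strict `>` at the MAF threshold; a gene at exactly 0.1% is excluded.
* Nearest-gene ties: smaller start, then symbol; distances on 0-based
  coordinates.
* Null SD of zero: z undefined (`NA`), excluded from BH — never ±Inf.
* Zero arm totals: +0.5 pseudocount on both arms; dispersion floor 1e-8;
  all-zero guides not-testable.
* P10 of zero in representation QC: floored at 1 count and flagged.
* Percentiles: linear interpolation between order statistics (type 7).
* BH uses `stats::p.adjust`; the suite cross-checks a hand-coded step-up.
* Empty gene tables are valid input (empty set, zero drop counts); empty
  catalogs and FASTQ files are errors.

# Problem sizes used by the test and acceptance suites

Simulations are sized to exercise the asymptotics that matter while running
in seconds: 200 traits x 2,000 genes x 1,000 permutations for null
calibration of the trait z-scores; 2,000 guides for the NB test's type-I
error; 10 seeds x (200 genes, 20 spiked essentials, 610-guide two-set
library, 11 samples) for essentiality recovery; exhaustive enumeration
oracles on 6-8 gene universes. The acceptance script
(`scripts/acceptance.R`) recomputes all headline quantities from scratch at
any seed.

# Known limitations

* The NB estimator is a closed-form two-group contrast, not a full GLM; it
  does not support covariates (batch) beyond the size-factor offset.
* Dispersion moderation uses a single global mean, not an abundance trend.
* Normal-tail p-values understate evidence deep in the tail relative to
  exact tests (see above); ranking and thresholding at conventional alpha
  are unaffected.
* Trait enrichment samples gene sets unmatched on gene length or
  chromosome; catalogs with strong length-biased ascertainment would need
  matched sampling.
* `consequence_frequency_diff()` conditions on the catalog's gene
  assignments; it does not model assignment uncertainty.
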