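---
title: "Rare-variant collapsing, pathway MLP enrichment and boosted SNP screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant collapsing, pathway MLP enrichment and boosted SNP screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Case-control association studies of common variants leave much heritability
unexplained, motivating tests that aggregate *rare* variants (minor allele
frequency, MAF, below a few percent). A single rare allele is carried by too
few subjects to test on its own, but collapsing all rare variants in a region
into one per-subject *carrier indicator* — does the subject carry at least one
rare minor allele in the region? — produces a well-filled 2x2 table whose
carrier proportions can be compared between cases and controls. `rarepath`
implements this collapsing analysis end to end and extends it in two
directions: mapping the region-level p-values onto genes and then onto
biological *pathways* with a mean-log-p (MLP) set statistic, and screening
SNPs empirically with stochastic gradient boosting (SGB).

The pipeline stages are:

1. **QC** — Hardy-Weinberg equilibrium (HWE) filtering in controls and
   population-stratification components from identity-by-state (IBS)
   multidimensional scaling (MDS) after correlated-marker pruning.
2. **Collapsing scan** — carrier tests over gene-based units and overlapping
   sliding windows of 1, 5, 25, 50 and 100 kb, plus allelic chi-square tests
   for common SNPs.
3. **Gene statistics** — five rules mapping unit-level p-values to per-gene
   scores on the $-\log_{10} p$ scale.
4. **MLP enrichment** — pathway statistic equal to the mean member-gene
   score, with a gene-resampling permutation null.
5. **Boosting** — SGB of affection status on preselected SNP dosages, MDS
   components and covariates, with split-gain variable importance and a
   scaled-importance selection cutoff.

A seeded synthetic-cohort generator provides data with known ground truth so
every stage is testable without access-restricted genotypes.

## The synthetic cohort

`simulate_cohort()` emulates the *structure* of a mini-exome case-control
study of 697 subjects (about 30% affected), not any particular dataset's
generating mechanism:

* **Allele-frequency spectrum.** Each variant's ancestral MAF is drawn from a
  three-stratum mixture: very rare ($< 1\%$, weight 0.74), rare (1–5%, weight
  0.13) and common (5–50%, weight 0.13). The weights are the observed
  proportions when a mini-exome's ~24.5k variants split as ~18.1k very rare,
  ~3.2k rare and the remainder common. Within the rare strata a Beta(1, 2)
  shape concentrates mass toward the lower bound; the common stratum is
  uniform.
* **Population structure.** Subjects belong to `n_populations = 3`
  subpopulations whose variant frequencies drift from the ancestral values
  under a Balding–Nichols model with divergence (an $F_{ST}$-like parameter)
  0.10 — enough for three clearly separated MDS clusters, as k-means recovery
  tests confirm. Genotypes are Hardy-Weinberg *within* each population; the
  pooled sample therefore shows a mild, realistic Wahlund deficit of
  heterozygotes, and the HWE filter removes a few percent of the more
  differentiated variants.
* **Genome layout.** 300 genes of 20 kb separated by 5 kb gaps on one
  synthetic chromosome, 12 variants placed uniformly per gene (about the
  variants-per-gene density of a mini-exome panel, at desk scale). Pathways
  are 30 disjoint blocks of 10 consecutive genes, written in GMT format.
* **Phenotype.** Affection is Bernoulli with logit equal to
  `qlogis(base_rate)` plus mean-centered terms: `carrier_effect` (default
  1.4, odds ratio ~4) per causal gene in which the subject carries a rare
  allele, `smoke_effect` (default 0.70, the log odds ratio implied by ~36%
  smoking among cases vs ~22% among controls) and a small population
  intercept (`pop_effect = 0.1`). Centering keeps the marginal case fraction
  at `base_rate` regardless of the effect sizes.
* **Truth.** The causal pathway(s), the causal genes sampled inside them and
  their rare variants are returned, so recovery rates can be measured.

What the generator deliberately omits: linkage-disequilibrium blocks beyond
drift-induced correlation, realistic sequence content, and quantitative
traits. Passing tests therefore demonstrate the statistical machinery under
clean HWE-with-drift sampling, not robustness to LD or genotyping artifacts.

## Numerical and design choices

**HWE test.** A 1-df chi-square goodness-of-fit test against expectations
from the sample allele frequency, with monomorphic variants assigned p = 1.
The chi-square approximation is *anticonservative for very rare variants*:
when the expected count of rare homozygotes is far below one, a single
observed homozygote inflates the statistic past any threshold. This is the
classical motivation for exact HWE tests; here the filter is a QC screen at
$\alpha = 10^{-4}$ in controls, so the effect is a slightly conservative
removal of a fraction of a percent of very rare variants. Null-calibration
properties are stated and tested on common variants, where the approximation
is valid.

**Pruning and MDS.** The pruning rule (drop the lower-MAF member of any pair
with $r^2 > 0.2$ within 50-variant windows advanced by 5) mirrors common
pre-MDS practice; all three parameters are exposed. The subject-pair distance
is $1 - \mathrm{IBS}$ with missing dosages excluded pairwise, followed by
classical (Torgerson) MDS. Component signs are arbitrary — an inherent
eigendecomposition ambiguity — so downstream use is sign-agnostic.

**Carrier tests.** Pearson chi-square (1 df, no continuity correction) when
all four expected cell counts are at least 5 (Cochran's rule,
operationalizing "small cell counts"), otherwise a two-sided Fisher exact
test summing hypergeometric tables with probability not exceeding the
observed one. Units with a degenerate margin are reported untestable rather
than given a p-value. The rare threshold defaults to MAF < 0.05 (strict),
covering both rare strata; the minor allele is defined by the full-sample
frequency. Windows overlap with step = size/2; both the step and the
threshold are configurable because reasonable analyses differ here.

**Gene statistics.** All scores live on the $-\log_{10} p$ scale (the base
affects only the scale, not ranks). A window belongs to a gene if it overlaps
it by at least 1 bp (containment mode available). Genes with no testable unit
are *absent* from the score table rather than imputed at p = 1: imputation
would bias set statistics toward sparsely covered sets, and coverage density
already influences results enough to warrant the explicit universe.

**MLP enrichment.** The set statistic is the arithmetic mean of member gene
scores over the scored universe; significance comes from drawing same-size
gene sets from that universe without replacement (`n_perm` defaults to
10,000 in the pipeline; property tests use 1,000) with the plus-one
correction $(1 + \#\{\text{null} \ge \text{obs}\})/(n_\text{perm} + 1)$,
which avoids zero p-values. Gene-label resampling — not phenotype
permutation — is used so the genome scan need not be rerun per permutation;
phenotype permutation is a documented extension point. Sets with fewer than
3 scored members are skipped (a mean of one or two scores is too unstable to
rank). Ranking is by permutation p ascending with ties broken by larger
observed MLP, then name, so output order is total and deterministic.

**Boosting.** Binomial-deviance SGB: intercept at the log-odds of the case
fraction; each iteration fits a least-squares regression tree to the current
negative gradient on a 50% row subsample drawn without replacement, grown
best-first to at most 8 terminal nodes with splits chosen by squared-error
reduction, leaf values set by a one-step Newton estimate, and the tree added
with shrinkage 0.01. Features are histogram-binned (exact for 0/1/2 dosages;
at most 64 quantile bins for continuous columns). Variable importance sums
split gains per feature and is rescaled so the top predictor scores 100; the
selection cutoff defaults to 7.00 on that scale. A reference
gradient-boosting implementation with matched hyperparameters reproduces the
predictions to within 0.05 mean absolute probability in the test suite; exact
numeric equivalence with any particular proprietary implementation is not
claimed, in particular the importance scale is comparable only after the
max-100 rescaling.

**Pipeline.** One master seed deterministically derives a seed for every
stochastic stage, so a rerun with the same configuration is byte-identical
(verified file-by-file in the test suite); the manifest records each output
file's MD5, stage, seed and wall time. Reruns are cheap at these problem
sizes, so no stage-resume mechanism is implemented — rerunning the whole
pipeline *is* the resume path. Reports round p-values to 4 significant
digits; TSVs keep full precision.

## Problem sizes used in the checks

The calibration and recovery checks run at deliberate desk scale: type-I
error of the carrier test is measured on ≥ 2,000 testable null 5-kb windows
(two 697-subject cohorts with all effects zero, so the null is exact);
Fisher exactness is verified against exhaustive enumeration on all ~240k
2x2 tables with row margins up to 30; MLP null calibration uses 1,000 random
sets of 10 genes against a 400-gene universe at 1,000 permutations;
enrichment recovery uses 100 cohorts of 51 pathways (one causal, fifty
null); boosting recovery uses 50 panels of 505 SNPs with 500 trees. The
vignette states these sizes as the package's own reproducibility choices.

## Worked example

```{r, eval = FALSE}
library(rarepath)

cfg <- pipeline_config(out_dir = "run1", n_perm = 1000,
                       sgb = sgb_params(n_trees = 500), seed = 41)
manifest <- run_pipeline(cfg)

# top pathways for the min-window statistic
res <- read.delim("run1/gene_set_results_min_window.tsv")
head(res)

# selected SNPs with truth annotation
imp <- read.delim("run1/sgb_importance.tsv")
head(subset(imp, selected))
```

## Known limitations

* The chi-square HWE screen is anticonservative for very rare variants (see
  above); an exact HWE test is out of scope.
* Collapsing tests are unadjusted for covariates or stratification;
  population structure enters the analysis only through the MDS components
  handed to the boosting stage, mirroring the staged design the pipeline
  implements. Under strong confounding the carrier tests will inflate.
* Gene-label permutation tests the set against random same-size sets from
  the scored universe (a competitive null); it does not propagate
  genotype-level correlation between neighbouring genes, which overlapping
  windows induce within a set.
* The SGB importance scale is implementation-specific; only the rescaled
  (max = 100) scale, on which the 7.00 cutoff operates, is comparable across
  implementations.
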