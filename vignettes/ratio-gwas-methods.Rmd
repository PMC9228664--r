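---
title: "Ratio-phenotype metabolite GWAS with the p-gain statistic: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-phenotype metabolite GWAS with the p-gain statistic: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiogwas)
```

## The problem

Non-targeted LC--MS metabolomics panels report drug metabolites and other
xenobiotics in only a subset of a cohort: a compound is absent unless the
participant took the drug recently, and even then low-abundance conjugates
fall below the detection limit. Conventional mGWAS practice excludes
metabolites detected in fewer than about half the samples, which removes
exactly the compounds of greatest pharmacogenetic interest. Two properties
of *ratios between biochemically related metabolites* make them attractive
phenotypes in this regime:

1. A ratio of a substrate and product (or of two competing products)
   approximates the relative flux through an enzymatic step, so it is a
   closer proxy for enzyme activity than either abundance alone.
2. Per-sample multiplicative factors — dose, time since ingestion,
   dilution, residual batch effects — enter both metabolites alike and
   cancel exactly in the ratio, removing variance that swamps single-trait
   tests.

`ratiogwas` implements the full analysis: trait construction over a
high-missingness panel, variant QC, covariate-adjusted association, the
p-gain statistic with trait-wide thresholds, and locus clumping with
nearest-gene annotation — together with a synthetic cohort generator that
plants the genetic effect archetypes this design is meant to detect.

## Traits

For a panel of $M$ metabolites with positive relative abundances $m_{ij}$
(sample $i$, metabolite $j$), the trait set is the $M$ natural-log single
traits $\log m_{ij}$ plus all $\binom{M}{2}$ pairwise log-ratios
$\log m_{ij} - \log m_{ik}$, i.e. $T = M + M(M-1)/2$ traits; $T = 45$ for
the nine-metabolite acetaminophen panel shipped as the default
(`acetaminophen_panel()`). Ratio orientation is canonicalized by panel
column order — the association p-value is orientation-invariant and
inverting a ratio only negates its effect estimate.

Samples enter the analysis when at least `min_detected = 5` of the 9
metabolites are detected. Within the trait set, analysis is complete-case
per trait: a single trait is defined where the metabolite was detected, a
ratio where both components were. We deliberately do not impute
non-detected values: non-detection in LC--MS is informative (the latent
abundance is below the limit of detection), and any imputation scheme
would inject the assumed missingness mechanism into the effect estimates.
Natural logs are used without a subsequent rank-based transform so that
effect sizes remain interpretable per allele on the log-abundance scale; an
inverse-normal transform can be applied by the user upstream if marginal
normality is a concern.

## Association models

The default engine is ordinary least squares of the trait on allele dosage
(0/1/2, unstandardized, so betas are per allele) plus age, sex and the
first ten genomic principal components, with two-sided p-values from the t
distribution on the residual degrees of freedom. P-values are floored at
the smallest positive double rather than reported as zero.

For cohorts with relatedness, `lmm_association()` fits
$y = X\beta + g + \varepsilon$ with $g \sim N(0, \sigma_g^2 A)$ and
$\varepsilon \sim N(0, \sigma_e^2 I)$, where $A$ is the genomic
relationship matrix. Variance components are estimated once per trait by
REML, profiling the restricted likelihood over
$\delta = \sigma_g^2/\sigma_e^2$ on the eigenbasis of $A$; each variant is
then tested by generalized least squares under the fitted covariance (the
standard mixed-linear-model association scheme). $\sigma_g^2$ may hit the
zero boundary, at which point the model is exactly OLS; we also evaluate
the boundary explicitly and keep it whenever it is no worse, so the
$A = I$ contract (`lmm == ols` to machine precision) holds by
construction. The GLS step uses the same t-distribution convention as the
OLS engine. The optimizer searches $\log\delta \in [-12, 12]$, which spans
heritabilities from numerically zero to numerically one for any reasonable
trait.

## The p-gain

For a variant's association with the ratio of metabolites $a$ and $b$,

$$\mathrm{pgain} = \frac{\min(p_a, p_b)}{p_{a/b}},$$

the factor by which the ratio sharpens the best single-metabolite
association. A p-gain of 10 corresponds to a single-test alpha of 0.05, a
calibration the package re-derives empirically
(`pgain_null_calibration()`; `analysis/05_null_calibration.R` runs it at
several critical values) rather than assuming. With $T$ traits the
decision rules are: genome- and trait-wide significance when
$p_{a/b} < 5\times10^{-8}/T$ ($1.1\times10^{-9}$ at $T = 45$),
ratio-specific significance when $\mathrm{pgain} > 10\,T$ (450 at
$T = 45$), and a suggestive screen at $p < 10^{-5}$. All comparisons are
strict, so boundary values do not pass. $T$ counts singles *and* ratios:
the nine-metabolite panel yields $9 + 36 = 45$ tested traits, and the same
$T$ enters both thresholds.

Component p-values are computed on each trait's own complete-case sample
set, the standard choice in mGWAS; because the ratio's case set is the
intersection of its components', the three tests can rest on somewhat
different samples. Restricting all three to the ratio's case set is
available by subsetting the panel before `build_traits()` if a strict
comparison is wanted.

## Variant QC

Filters remove strict violations only — MAF < 5%, call rate < 90%,
Hardy-Weinberg exact p < $10^{-6}$, non-autosomal variants, indels — so a
variant at exactly MAF 0.05 survives. The Hardy-Weinberg test is the exact
conditional test: given the observed allele counts, the p-value sums the
probabilities of all heterozygote counts no more probable than the one
observed. We use the standard recurrence construction without a mid-p
correction, matching common QC practice; the test suite checks it against
full closed-form enumeration for every genotype configuration up to
$n = 50$.

LD is the squared Pearson correlation of dosage vectors over
pairwise-complete samples; pairs with undefined correlation (zero
variance) are treated as unlinked. Pruning is greedy within a sliding
window (defaults: $r^2 = 0.5$, window 50 variants, step 5 — window
geometry is a package choice, stated here because only the threshold is
standard), removing the later-positioned variant of an offending pair.
PCs are computed on the pruned set after per-variant mean imputation and
column standardization, with each component's sign fixed by its
largest-magnitude loading. The relationship matrix uses the GCTA-style
standardized-dosage estimator with per-pair averaging over jointly called
variants; PCA and GRM thus use different missing-data policies (imputation
vs pairwise-complete), each the standard one for its computation.

## Loci

Suggestive associations are clumped per trait: the smallest-p unassigned
variant indexes a locus (ties broken by chromosome, then position) and
absorbs unassigned variants with $r^2 \ge 0.1$ to it. Index variants of
distinct loci are therefore pairwise independent at the threshold. A
variant suggestive for several traits yields one association record per
trait; when reporting a cohort-level locus count the union of index
variants is clumped once more, so "$k$ associations at $j \le k$
independent loci" is well defined. Nearest-gene annotation measures
distance to the closest interval edge (0 inside the gene), strand-agnostic,
reporting both genes on an exact tie; BED input (0-based half-open) is
converted to the internal 1-based inclusive convention, a conversion the
tests exercise explicitly. Candidate-gene cross-referencing is
case-insensitive exact name matching.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
restricted cohort data. Its latent model is

$$\log m_{ij} = \mu_j + \textstyle\sum_k \mathrm{effect}_k(g_i)
  + b_{B(i),j} + d_i + \varepsilon_{ij},$$

with per-(run-day, metabolite) batch factors $b$, a per-sample shared
dilution factor $d$, and Gaussian noise. Genetic effect archetypes
(`planted_effect()`):

- **branch** — $+\beta$ on one target and $-\beta$ on the other per
  alternate allele: a shift in the partition between two competing
  conjugation products (glucuronidation vs sulfation). The induced
  per-allele effect on the pairwise log-ratio is exactly $2\beta$.
- **conversion** — $+\beta$ on the product, $-\beta$ on the substrate of
  an enzymatic step (the methylation archetype).
- **dilution** — the same $+\beta$ on every metabolite: a
  genotype-dependent shared factor. It cancels exactly in every ratio, so
  it is the canonical *negative control* for the p-gain: singles associate,
  ratios do not.
- **direct** — $+\beta$ on one metabolite.

After generation, values below the per-metabolite limit-of-detection
quantile are censored (missing-not-at-random; an MCAR mode exists for
calibration experiments), and then each run-day block's detected values
are divided by their median, so the post-normalization batch median is
exactly 1. Censoring before normalization mirrors the real pipeline, where
the normalization only ever sees reported values. The latent matrix is
retained in the returned object so generative claims (dilution
cancellation, censoring below the quantile) are directly testable.

Default conditions mirror the target study design: 520 samples; the nine
acetaminophen metabolites with censoring fractions set to one minus their
observed detection fractions (detection 363--514 of 520); ages uniform on
18--76 and 59.2% female; 10 run-day blocks with log-normal batch factors
of SD 0.2 (platform process variability is on the order of 10--20%);
per-metabolite residual SD 0.5 and shared dilution SD 0.5 on the natural
log scale, our reading of realistic between-person variation for drug
metabolites — dose and time-since-ingestion variability is deliberately
folded into the shared dilution factor rather than modeled
pharmacokinetically, which is exactly the variance component the ratio
design is meant to cancel. LD, when requested, is induced by
copying-with-mutation between adjacent variants in fixed-size blocks; this
produces a step-like correlation structure sufficient to exercise pruning
and clumping, not a realistic recombination map.

Two caveats on what passing simulations do and do not show. First,
left-censoring at a quantile attenuates the conditional regression slope
of a censored trait: the expected slope of a ratio whose components are
censored at fraction $q$ is below the generative $2\beta$ by a factor that
grows with $q$ (about 10% per component at $q \approx 0.02$, about 40% at
$q \approx 0.2$). Parameter-recovery experiments therefore plant the
branch effect on the canonical phase-II branch pair — 4-acetamidophenyl
glucuronide vs 4-acetaminophen sulfate, the glucuronidation/sulfation
partition of the parent drug and the pair with the panel's highest
detection — so the recovery target is the generative effect rather than a
censoring-biased version of it. This bias is a property of MNAR
missingness itself, not of the estimator, and applies equally to real
data: betas for heavily censored metabolites are attenuated. Second, the
generator's metabolites are conditionally independent given the shared
factors; real panels carry correlation from shared pathways beyond any
single planted effect, which inflates p-gain null variability somewhat —
the null calibration here (independent pair) is the configuration in which
the p-gain = 10 ⇔ alpha = 0.05 equivalence was established.

## Numerical choices and degenerate inputs

- Exact-fit regressions (zero residual) report the p-value floor, not NaN.
- Monomorphic-in-subset variants, rank-deficient designs and
  fewer-than-`p+2` cases are flagged untestable rather than erroring; the
  scan never aborts on a single pair.
- All-missing variants get undefined QC statistics and are excluded.
- HWE p-values sum probabilities `<=` the observed one with a relative
  tolerance of 1e-12 to absorb floating-point ties in the recurrence.
- Clumping ties in p break by (chromosome, position); pruning removes the
  later-positioned variant, making both deterministic.
- Reruns are byte-identical: every stochastic step flows from the single
  configured seed, and file writers are deterministic.

## Problem sizes

The shipped analysis scripts and test suite run at desk scale, chosen so
the full workflow completes in minutes on one core while keeping every
statistical check well-powered: 520-sample cohorts with 60 variants for
the end-to-end demo; 2,000-sample single-variant cohorts, 200 replicates,
for parameter recovery; 10,000 replicates at $n = 500$ for the p-gain null
calibration; exhaustive Hardy-Weinberg verification to $n = 50$. The
pipeline itself is size-agnostic; the association scan is the only stage
whose cost grows with traits × variants.

## Limitations

- The LMM uses one variance component and the full GRM (no
  leave-one-chromosome-out), so a variant's own small contribution to the
  GRM induces a slight conservative bias at desk scale.
- No X-chromosome dosage model; non-autosomes are filtered.
- Haplotype-based $r^2$ is not implemented; LD is composite genotype
  correlation, which is what the pruning/clumping thresholds here assume.
- External annotation services (eQTL/pQTL overlap) are out of scope; gene
  annotation is purely positional against a user-supplied track.
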