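---
title: "Dissecting biomarker variation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting biomarker variation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteovar)
```

This vignette is the package's own account of the statistical machinery:
what each stage assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic cohort does and does not
emulate, and where a genuinely open design question was settled by a
package decision.

## 1. The measurement model: Cq to ddCq

A multiplexed PEA panel reports one qPCR quantification cycle (Cq) per
sample and assay. Cq falls by one cycle per doubling of target, so
abundance lives naturally on a log2 scale. We normalize per sample and
assay as

$$\mathrm{dCq} = \mathrm{Cq}_{\text{analyte}} -
  \mathrm{Cq}_{\text{extension control}}, \qquad
  \mathrm{ddCq} = c_{\text{assay}} - \mathrm{dCq},$$

where the extension control is spiked into every sample (cancelling
sample-level amplification shifts — `normalize_ddcq()` is exactly
invariant to adding a constant to a sample's Cq values) and
$c_{\text{assay}}$ is a per-assay constant chosen so ddCq is positive on
a log2 scale. One ddCq unit is approximately a doubling of abundance;
"linearized" comparisons use $100\cdot 2^{\Delta}$ percent
(`linearized_ratio()`). ddCq values are used as-is downstream — they are
already log-scale quantities, and no second log transform is applied.

The **detection limit** of an assay is estimated from the
negative-control well present on every plate: mean negative-control ddCq
across plates plus 3 across-plate standard deviations (0 with a single
plate). Cells at or below the LOD are masked and treated as missing
("at or below": the boundary cell is censored). The 3-SD multiplier is
a manufacturer-style convention and is configurable.

**Sample QC** removes samples whose internal controls (two incubation,
one extension, one detection control) contain an outlier, defined per
control and plate as lying more than 3 robust SDs
($1.4826\cdot\mathrm{MAD}$) from the plate median — a deliberately
parameter-light robust rule, since no published rule exists for this
step. On clean data this rule still flags a small percentage of samples
(MAD is noisy at ~92 samples per plate); that is the price of a
distribution-free screen and mirrors the few-percent sample attrition
typical of real panels. Samples with more than 75% of cells below LOD
(strictly greater) are also removed, and proteins need at least 200
above-LOD observations to enter analysis. QC statistics are always
computed from the stored original panel, which makes `apply_qc()`
idempotent by construction.

## 2. Covariate variance decomposition

Per protein we fit one ordinary least-squares model containing **all**
covariates simultaneously (complete cases; below-LOD cells excluded, so
the analysis n varies by protein) and attribute variance by
**sequential (type-I) ANOVA**: $\text{fraction}(j) = \mathrm{SS}_j /
\mathrm{SS}_{\text{total}}$. Sequential decomposition is
order-dependent; the order is fixed to the covariate-table column order
and recorded in the output. This is a documented caveat, not a bug: for
orthogonal covariates the fractions are order-invariant and equal the
projection fractions $(x_j'y)^2/(\|x_j\|^2\,\mathrm{SS}_{\text{total}})$
(tested against that oracle), and for collinear covariates *no*
order-free attribution exists — the sum of single-covariate fractions
can legitimately exceed the combined-model $R^2$.

Covariates are screened at the Bonferroni level $0.05/m$ over the $m$
covariates tested. Categorical covariates (e.g. ABO group) expand to
treatment contrasts with the alphabetically first level as reference;
constant or aliased covariates are dropped with a warning.

Association-ready phenotypes are residuals on the significant
covariates mapped through the **rank-inverse-normal transform**
$\Phi^{-1}\!\big((r_i - \tfrac12)/n\big)$ with average ranks for ties.
The result is invariant to any strictly monotone transform of the trait
and has mean 0 and variance ≈ 1 by construction.

## 3. Kinship, heritability and the score-test GWAS

**Genotype QC** applies, in order: marker call rate ≥ 0.95, individual
call rate ≥ 0.98, an exact Hardy–Weinberg test at a Bonferroni-corrected
0.05 (hard-call markers only), and a minor-allele count of at least one
chromosome. The HWE test is the exact conditional test (sum of
probabilities of heterozygote counts no more likely than observed, given
the allele counts); the test flavour is a package convention, pinned by
an independent enumeration oracle in the test suite.

The **genomic relationship matrix** is the allele-frequency-standardized
estimator $K_{ij} = L^{-1}\sum_l (g_{il}-2p_l)(g_{jl}-2p_l)/(2p_l(1-p_l))$
with sample allele frequencies over complete cases; its expectation is
twice the kinship coefficient (diagonal 1 for non-inbred individuals).
Some older mixed-model tools use the half-scaled (kinship) matrix
instead; the scale is irrelevant downstream because the polygenic fit
normalizes $K$ by its mean diagonal internally, making $\hat h^2$
exactly invariant to $K \mapsto cK$ (with $\hat\sigma^2_g$ rescaling
inversely). Note the estimator's small finite-sample bias: with $n$
samples the off-diagonal expectation is shifted by about $-1/(n-1)$
because allele frequencies are estimated from the same sample.

**Heritability** is estimated by maximum likelihood (not REML — matching
the two-stage residual approach used downstream; the difference is
second-order at these sample sizes) under
$y = X\beta + u + e$, $u \sim N(0, \sigma^2_g K)$,
$e \sim N(0, \sigma^2_e I)$. One symmetric eigendecomposition of $K$
(eigenvalues floored at $10^{-8}$ for positive definiteness) rotates the
problem to independent observations; $\beta$ and the total variance are
profiled analytically and the likelihood is maximized over
$h^2 \in [10^{-6}, 1-10^{-6}]$ by one-dimensional optimization, with both
boundaries checked explicitly (a flat likelihood, e.g. $K = I$, resolves
to the $h^2 = 0$ boundary). Significance uses the likelihood-ratio
statistic against the $h^2=0$ restriction referred to the boundary
mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; a fit pinned at the
boundary yields $p = 0.5$. Under a null simulation this test rejects at
its nominal 5% rate (the acceptance script recomputes this).

**Association** uses a score test built from the polygenic fit's
residuals $y^* = y - X\hat\beta$ and inverse fitted covariance
$\hat\Omega^{-1}$:

$$\hat\beta_g = \frac{g_c'\hat\Omega^{-1}y^*}{g_c'\hat\Omega^{-1}g_c},
\qquad \mathrm{se} = (g_c'\hat\Omega^{-1}g_c)^{-1/2}, \qquad
\chi^2 = (\hat\beta_g/\mathrm{se})^2,$$

where $g_c$ is the dosage **projected off the fixed-effect design in
the $\hat\Omega^{-1}$ inner product** (for an intercept-only design,
centering at the precision-weighted mean). This choice — rather than
centring at the arithmetic mean — makes the statistic algebraically
identical to the Wald test from a full GLS refit with the marker as an
extra fixed effect at fixed variance components, which is the contract
the test suite enforces to relative $10^{-6}$. Variance components are
*not* re-estimated per marker (the score-test design); conditional
scans *do* refit, with the top marker's dosage appended to the fixed
effects. Per-marker effect size is summarized as variance explained
$\chi^2/N$ on the adjusted phenotype scale, the same identity used to
invert published p-values in the acceptance checks.

The scan runs in three phases: discovery at $0.05/m_{\text{markers}}$,
replication of discovery hits at $0.05/k_{\text{hits}}$, and a combined
scan of the pooled sample at the discovery threshold. The combined
phase refits variance components on the pooled sample (whether the
original analysis pooled or reused cohort fits is not documented; the
pooled refit is the cleaner likelihood and is flagged here as a package
decision). Markers with minor-allele count below 3 in a cohort are
skipped. Genomic inflation is the median-based
$\lambda = \mathrm{median}(\chi^2)/0.4549$ (null median of
$\chi^2_1$ to 4 d.p.; the exact `qchisq(0.5, 1)` is used internally).
Conditional hits use the conventional genome-wide $5\times10^{-8}$
cutoff and rescan only the chromosomes carrying hits.

## 4. ABO typing

Five haplotype lineages (A1, A2, B, O01, O02) are tagged by four SNPs:
the rs505922 minor allele marks the O lineage, rs8176746 marks B,
rs8176704 marks A2, rs574347 separates O02 from O01. Under this tag
table every unordered pair of lineages produces a distinct 4-SNP
genotype vector, so unphased diplotype resolution is deterministic (a
property asserted in the tests). The table ships as editable data
because tag-allele orientations differ between genotyping builds; with a
user-supplied table that *is* ambiguous, ambiguous genotypes fall back
to `unassigned` rather than being guessed. Missing genotypes also yield
`unassigned` and are counted in the assignment rate, so sub-100%
assignment rates arise naturally from missingness.

## 5. Personalized reference intervals

"Cutoff" is operationalized as the stratum-specific central interval of
a fitted normal: per stratum, mean and SD of ddCq, central 95% interval
$\mu \pm 1.96\sigma$ (the percentile is configurable — no numeric
cutoff rule is standardized for this use, so the 95% interval is an
explicit stand-in) and normal-fit IQR $\mu \pm 0.6745\sigma$. Strata
with fewer than 10 individuals are suppressed, exactly at the boundary.
Age enters as tertiles by default — age is continuous, so any binning is
a presentation choice, and tertiles keep every stratum populated at
cohort sizes of a few hundred. Between-stratum contrasts are reported
as linearized ratios ($100\cdot2^{\Delta}$), turning log2 differences
into the percent-of-reference-level statements a clinical reader
expects.

## 6. The synthetic cohort: what it emulates, what it does not

The simulator exists so that every downstream stage has a ground truth.
Its defaults mirror the study conditions the pipeline targets: two
collection rounds of 600 + 300 individuals in 150 nuclear families
(whole families within one round, as when separate villages are
recruited per round), per-protein heritabilities spread over 0.19–0.78,
cis-SNP effects explaining 5–27% of variance on half the panel, an age
effect up to 27%, rare medication indicators (2–54 users per 1,000)
whose prevalence rises with age through a logistic link (so age, blood
pressure and medication are realistically collinear), a
collection-round batch shift, and ~5% below-LOD censoring.

Design choices worth knowing:

* **Gene dropping, not multivariate-normal genotypes.** Founder alleles
  are Bernoulli draws at the marker frequency; children inherit one
  allele per parent. This makes Mendelian constraints and pedigree
  kinship *exactly* testable (the empirical GRM converges to twice the
  path-counting kinship), which an MVN approximation cannot offer.
* **Traits are generated from the same polygenic model the estimator
  assumes**: $y = X\beta + g\beta_{\text{snp}} + u + e$ with
  $u \sim N(0, \sigma^2_g \cdot 2\Phi)$. The residual variance is
  derived from the total-variance budget; a model whose heritability
  plus fixed-effect fractions exceed 1 is rejected at simulation time.
  Realized components are stored so recovery tests compare against
  truth, not against another estimate.
* **Plates are the exact inverse of normalization** for uncensored
  cells, with the negative control placed at the censoring quantile of
  each assay, so the LOD machinery censors the requested fraction.
* **Below-LOD truth is censored to missing**, not imputed: the
  measurement process gives no information about the shape below the
  limit, and the analysis contract is "removed from further analysis".

Not emulated: linkage disequilibrium beyond family co-transmission
(markers are dropped independently), X-chromosome dosage,
imputation-uncertainty (dosages are hard calls), and storage-time
degradation. Consequently, passing tests demonstrate correctness of the
estimators under the stated model — they do not certify behaviour under
LD-driven confounding or dosage uncertainty, and real-data λ and
replication rates will be less tidy than the simulator's.

## 7. Numerical conventions and problem sizes

Ties in ranks take average ranks before the normal quantile map.
Rank-deficient covariate designs drop aliased terms with a warning
rather than failing. Markers numerically collinear with the fixed
effects (projected dosage norm below $10^{-10}$ of the raw norm) report
$\chi^2 = 0$ instead of dividing by near-zero. Eigenvalues of $K$ are
floored at $10^{-8}$; the heritability optimizer tolerance is $10^{-8}$
on $h^2$. Seeds: every generator takes an explicit seed, and the
pipeline derives per-stage seeds from the config seed, making full
reruns byte-identical (asserted by test and acceptance script).

The test and acceptance simulations use cohorts of 900 individuals (150
six-person families) for recovery and calibration, 20,000 markers for
null-scan calibration, 500 replicates for the boundary-LRT rate, and
exhaustive HWE enumeration for small tables plus randomized tables up to
total 200 — sizes chosen so the whole suite completes in a couple of
minutes on one core while keeping Monte-Carlo error well inside the
asserted bounds.
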