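---
title: "Pathway polygenic scores for ventricular and callosal endophenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway polygenic scores for ventricular and callosal endophenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endopgs)
```

## The scientific problem

Enlarged lateral ventricles (LV) and reduced corpus callosum (CC) volume
are two of the most reproducible structural brain findings in
schizophrenia, and the two structures are anatomically and
developmentally coupled. The ratio of CC (subregion or total) volume to
LV volume is therefore a candidate composite endophenotype: a single
number sensitive to coordinated deviations of both structures. This
package implements the analysis chain needed to ask whether such
endophenotypes are (a) shifted in cases, (b) associated with polygenic
risk concentrated in specific neurodevelopmental gene networks — the
MIR137-regulated pathways (ephrin receptor signalling, axon guidance,
long-term potentiation, PKA signalling, and the empirically derived
MIR137 target set), (c) heritable from common SNPs, and (d) correlated
with global functioning and symptoms.

Because multi-site consortium data of this kind are access-restricted,
the package ships a synthetic cohort generator that emulates the
*statistical structure* such data present to the pipeline. Every stage is
tested against that generator plus independent oracles.

## Harmonization

Volumes from different cohorts and scanners are not directly comparable.
Each phenotype is standardized within cohort against the **control**
distribution: `Z = (x − M_HC)/SD_HC` with the sample SD (n−1) of controls
— the conventional reference-group standardization, so controls sit at
mean 0, SD 1 by construction and case means are directly interpretable
as control-SD separations. Outliers are processed in one pass on this
scale: `|Z| >= 6` removed, then remaining `|Z| >= 4` winsorized to ±4,
both bounds inclusive. Ratios are computed on raw volumes before any
standardization (they are scale-free, so a per-cohort multiplicative
scanner factor cancels). Design choices worth stating:

* thresholds reference the control-based Z, not a full-sample SD; the
  operation is a single pass (no re-referencing after removal) and is
  idempotent;
* cross-cohort pooling of raw volumes never occurs anywhere in the
  pipeline;
* covariate residualization (`residualize()`) exists for descriptive
  means only — association models adjust inside the regression instead.

## Pathway polygenic scoring

For each gene set, SNPs within ±20 kb of any member gene (1-based
inclusive interval arithmetic; BED input is converted from 0-based
half-open) are collected once per SNP (union over genes). Discovery
effect alleles are aligned to the dosage-counted allele, accepting
strand-complemented matches and dropping strand-ambiguous (A/T, C/G)
SNPs by default; when the counted allele is the discovery *other*
allele, the dosage is reflected (2 − d). The score is the **sum** of
log(OR)-weighted dosages over SNPs passing each of six discovery
p-value thresholds {5e-8, 1e-6, 1e-5, 1e-4, 1e-3, 0.05} — four of these
are conventional anchors and the remaining two complete a six-point
grid; all are configurable. A per-SNP averaging option exists for
cross-threshold comparability. Missing dosages are imputed at twice the
target-sample allele frequency, which leaves score expectations
unchanged. LD clumping is deliberately off by default (the scoring
contract is plain threshold-and-sum); the `genome_wide` set bypasses
gene windows entirely. The MIR137 gene score is implemented as a
one-gene pathway with the same 20 kb window — scoring only a single
index SNP is possible by restricting the summary statistics, but the
gene-window reading is the default.

## Association and meta-analysis

Within each cohort, OLS of the harmonized phenotype on the
cohort-standardized PRS plus the full covariate set: age (centered),
sex, age², age×sex, age²×sex, total brain volume, scanner dummies, and
4 ancestry components. Standardizing the PRS within cohort makes betas
unit-comparable for pooling. Variance explained is reported as
incremental R² (full minus covariate-only, same complete cases); the
full-model R² is also kept for transparency. Cohort estimates are pooled
by fixed-effects inverse-variance weighting — the stated estimator; a
DerSimonian–Laird random-effects mode is available behind an argument —
with Cochran's Q and I² reported, and the cross-cohort "average R²" as
the unweighted mean.

Multiple testing has two defensible accountings, and both are
implemented without presuming either correct: a **declared** count
(7 scores × 7 volume phenotypes, ratios not counted as independent
phenotypes, thresholds within a score counted once), giving 0.05/49;
and an **effective** count using the Li–Ji eigenvalue rule
`M_eff = Σ 1(λ_i ≥ 1) + (λ_i − ⌊λ_i⌋)` applied to the phenotype and
score correlation matrices separately. The eigenvalue floor uses an
epsilon guard (1e-10) because a rank-deficient matrix can yield an
eigenvalue of 2.99999999999999 whose naive fractional part would
inflate the count by ~1.

## SNP heritability

The cited heritability machinery in this literature is a fast
approximation to the GRM linear mixed model; its proprietary internals
are not reproduced verbatim here. The re-implementation contract is: a
documented moment estimator whose agreement with an exact-likelihood
oracle is enforced by tests. Concretely, K = XX′/M over dosages centered
at 2p̂ and scaled by √(2p̂(1−p̂)) (sample frequencies; MAF floor 0.01,
monomorphic SNPs excluded), the phenotype projected off the covariates
and standardized, and h² estimated as the Haseman–Elston slope of
y_i y_j on K_ij over pairs i<j, computed in closed form from matrix
norms. The SE is the pairwise-regression OLS formula — exact under the
null (cross-product pairs are uncorrelated for independent individuals)
and approximate under heritability; the point estimate is clipped to
[0,1] with the unclipped value retained, and the normal CI is formed
from the unclipped estimate. Permutation inference shuffles the
residualized phenotype and recomputes the slope (add-one p-value).

A practical identifiability note drives one test-design choice: with
~50 *unrelated* individuals the HE sampling SD is ≈ 0.5, so no two
estimators can be expected to agree within 0.1 there. The
oracle-equivalence check therefore uses a small *related* sample (10
families of 5 sharing most genotypes), where the GRM has strong block
structure and both the HE estimator and the exact-likelihood grid are
precise; across 40 pilot seeds their difference never exceeded 0.08.

## The synthetic cohort generator

Defaults encode the world the pipeline is meant for: 3 cohorts (the
smallest structure that exercises meta-analysis) of 200 cases + 200
controls each; 2000 SNPs drawn under Hardy–Weinberg at MAFs uniform on
[0.01, 0.5] (optionally with block-exchangeable AR(1) latent LD); 60
genes partitioned into the named pathway sets; discovery effects
zero-mean normal with half the effect-variance budget on the designated
(ephrin) pathway windows and observed odds ratios/p-values generated at
a discovery sample size of 80,000; volumes built from cohort baselines,
scanner offsets, covariate effects, a genetic component scaled to an
h² target of 0.3, and a diagnosis shift of +0.5 control-SD for LV and
−0.5 for CC volumes — the case/control separation repeatedly reported
for these structures. Clinical measures (GAF-, PANSS-, IQ-like) ride on
Gaussian latents with configurable correlation to the within-cohort
standardized CC:LV ratio (defaults 0.3/−0.25/0.2) plus age/sex
confounding, mapped to their conventional bounded scales.

What the generator does *not* emulate — and hence what a green test does
not establish: realistic LD from reference panels, family structure,
ancestry stratification coupled to genotypes (Gaussian ancestry
covariates by default; a PCA-on-genotypes mode exists), site-specific
segmentation artifacts, or non-Gaussian volume distributions. Three
calibration consequences are worth knowing. The case shift is applied
in units of each cohort's control SD of the *shift-free* volume, so the
post-harmonization case mean lands on the configured value; the total
CC is built from shift-free subregions and then shifted itself
(otherwise summing already-shifted subregions overshoots the configured
separation because subregion noise partially cancels in the sum). The
total CC also inherits a *higher* realized h² than the per-volume
target, because its subregions share one genetic factor while their
noise is partly independent — visible in the worked example (h² ≈ 0.6
for CC total vs 0.2–0.3 elsewhere). And ratio phenotypes realize lower
h² than volumes, as expected for a ratio of two noisy traits.

## Numerical and interface choices

* TSV outputs carry '#' metadata headers (package version, seed);
  readers skip them. Configs are JSON (the environment ships no R YAML
  parser).
* VCF is read through VariantAnnotation (DS preferred, GT counted);
  the writer emits a minimal DS-only VCF 4.2. BED goes through
  rtracklayer; GMT is a minimal hand-rolled reader/writer (no installed
  package provides one).
* Inverse-variance pooling, Q and I² are closed-form and implemented
  directly (the conventional meta-analysis package is not available in
  the target environment); a summation oracle cross-checks it in tests.
* Collinear covariate columns are dropped with a warning (QR rank);
  cohorts with too few complete cases or constant PRS are skipped, not
  imputed. Missingness is handled by listwise deletion per analysis
  cell.
* All generators are seeded from a single config seed with fixed
  per-stage offsets, making every pipeline output byte-reproducible.

## Known limitations

Fixed-effects pooling assumes a common effect; I² is reported but no
heterogeneity-robust inference is attempted beyond the optional
random-effects mode. The HE standard error understates uncertainty for
strongly heritable traits in related samples. Bivariate co-heritability
is not implemented (no usable procedure is specified for it in the
source literature for this design). The Table-1-style `f_from_summary`
reproduces published statistics only up to the rounding of printed
means/SDs (~1%); counts-based χ² is exact.
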