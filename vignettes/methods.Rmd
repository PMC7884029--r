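---
title: "Methods: serum-proteome signatures of extreme longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum-proteome signatures of extreme longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centproteo)
```

This vignette documents the models behind each stage of the pipeline, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design choices made where the methodology was
genuinely open.

## The data and its assumptions

The unit of measurement is an aptamer reagent binding one protein target;
several aptamers may target the same protein, so results are counted both
at aptamer and at unique-protein (gene-symbol) level. Raw abundances are
relative fluorescence units (RFU), strictly positive, and analyzed
throughout on the natural-log scale. The log base is irrelevant for fold
changes — `FC = exp(mean log num − mean log den)` cancels any consistent
choice — but natural log is used consistently so that effects, survival
shifts and noise standard deviations all live on the same scale.

All models are ordinary least squares. Whether the original
three-group screen used plain OLS F-tests or a moderated (empirical-Bayes)
variant is not documented; OLS is implemented because it is fully
specified, exactly matches the nested-model F-test definition, and at 70+
samples per group the moderation of variances would change little. This
gap is a known limitation for transferring q-value thresholds to much
smaller cohorts.

## Differential and survival models

The three-group screen fits, per aptamer, intercept + sex + collection
year + group, and compares it to the model without group by the F-test
with (2, n − k) degrees of freedom. Collection year enters as a linear
term by default; `year_as_factor = TRUE` switches to categorical batches
(the linear default was chosen because the simulated and assumed batch
process is a drift, and a 14-level factor costs 13 df at n = 224).
Constant aptamers return F = 0, p = 1 rather than an error so that
expressionless reagents flow through a genome-scale screen.

Direction calls use the covariate-adjusted group means: an aptamer is "up
in centenarians" only if the adjusted centenarian mean exceeds *both*
younger groups' means, mirroring the observation that the two
fold-change columns of the headline differential table always sit on the
same side of 1. Significant aptamers with discordant adjusted differences
are flagged `mixed` and excluded from the up/down sets.

Survival is deliberately dichotomized, not modeled as time-to-event: the
cutoffs (2 years for centenarians, the life expectancy of a centenarian
of the relevant birth cohort; 10 years for ~70-year-olds) are part of the
method being implemented. The boundary conventions are asymmetric by
design: a centenarian death at exactly 2.0 years counts as *long*
("2 years or more"), a younger death at exactly 10.0 years counts as
*short* ("within 10 years"). Samples alive with follow-up not yet past
their cutoff are unlabeled and excluded. Selection is at nominal
p < 0.005 — at these sample sizes no aptamer survives FDR correction, so
the interesting quantity is the selected count relative to the m·α
expected by chance (`expected_count_ratio()`), and BH q-values are
reported alongside for reference.

## Cross-study concordance and meta-analysis

Tiers (significant / ambiguous / not significant) are assigned *after*
re-running BH within the platform intersection, because a q-value is only
meaningful relative to the family it was computed in; re-tiering on the
compared universe makes the 3×3 cross-table well defined. External
studies are consumed as summary tables (key, effect sign, p, n) — their
raw data are never re-analyzed.

The meta-analysis method used by the original comparison is unstated, and
standard errors are not exchanged, so inverse-variance weighting is not
possible. The documented choice is Stouffer's signed-z combination with
weights sqrt(n): z = sign · Φ⁻¹(1 − p/2) per study (p clipped at 1e-300
before inversion), combined as Σwz / sqrt(Σw²). Restricting to aptamers
with p < 0.2 in both studies before combining reproduces the intended
behavior: concordant weak signals reinforce, discordant ones cancel
exactly.

Two-sided Fisher exact tests use the minimum-likelihood summation
definition (all tables of the same margins whose point probability is at
most the observed one, with a 1 + 1e-7 relative tie tolerance), not tail
doubling. This is the dominant convention and the one that returns p = 1
for a modal observed table — which the senescence-enrichment worked
example requires exactly.

## Enrichment and pathway projection

Over-representation is at gene-symbol (protein) level: multiple aptamers
per symbol count once, and the universe is the full annotated platform
protein set, not the subset that happened to pass variance or
significance filters. Using the platform universe is the convention the
printed senescence-overlap counts imply; using a tested-only universe
would shrink every margin and is not what the worked examples reproduce.

"Pathway projection" is not defined in detail anywhere; the implemented
score is the per-sample mean of member aptamers' z-standardized log-RFU.
It is simple, deterministic, linear in the data, invariant to per-aptamer
affine rescaling, and matches the way projected scores are standardized
by row for display. Pathways with fewer than `min_members = 5` platform
members are dropped with a warning — below that a "pathway score" is
really a single-protein readout.

## Module networks

The network stage is a standard weighted-correlation module pipeline made
fully deterministic:

1. Pearson correlation of log-RFU within the group's samples.
2. Unsigned adjacency |r|^β. Unsigned, because observed modules contain
   both up- and down-regulated proteins. β is the smallest candidate
   whose connectivity distribution reaches a scale-free fit R² ≥ 0.8
   *or* the first power where the R² gain per step flattens below 0.05
   at R² ≥ 0.5 — on planted-block data the scale-free criterion alone
   keeps climbing to powers that erode weakly-loaded module members, so
   the plateau rule acts as a guard.
3. Topological overlap, TOMij = (Σu aiu auj + aij)/(min(ki,kj)+1−aij).
4. Average-linkage clustering of 1 − TOM with a flat cut at 0.995 times
   the largest merge height. A flat cut (rather than the dynamic hybrid
   tree cut) is deterministic and fully specifiable; the 0.995 factor
   cuts just below the narrow band where the unstructured background
   coalesces. Clusters smaller than `min_module_size = 20` dissolve into
   the null module — 20 because observed minimum module sizes in this
   kind of data are 20–21 — and a background filter additionally drops
   any cut cluster whose median internal TOM does not exceed the
   matrix-wide level (median + one MAD), which is what sends a pure-noise
   matrix entirely to the null module.
5. Eigengenes are the first principal component of the z-standardized
   module submatrix, unit variance, sign-oriented to correlate positively
   with the module's mean profile (PCA signs are otherwise arbitrary).

Covariates are *not* regressed out before correlation (the reference
analysis is silent on this); module structure in serum is dominated by
biological co-regulation, and sex/collection-year effects planted by the
generator are small relative to module loadings. The exact published
module counts (29/23 modules, a null module of ~2800 aptamers) are
functions of the restricted cohort data and unpublished settings; only
the qualitative structure — tight planted blocks recovered, noise
unassigned, conserved modules linked across groups — is testable and
tested.

## The synthetic-data generator

`simulate_cohort()` emulates, on the log-RFU scale,

```
log RFU = baseline_j + I(centenarian) log(fc_j) + sex and year terms
          + module loading × latent factor + survival term + N(0, σ)
```

with defaults that are the study conditions: 77/82/65 samples; mean ages
105.7/71.2/70.6 (SD 3.6/9.3/7.8); 66/66/55% female; 4785 aptamers of
which 733 planted up (FC 1.02–3.33, median ≈ 1.26) and 695 down
(0.56–0.97, median ≈ 0.88). Fold changes are drawn from a truncated
exponential on the log scale so the median lands at the reported value
inside the reported range. Specific points:

- **Residual sd.** σ = 0.25 log-units is a calibration choice, not a
  reported value (per-aptamer variances are not published). It implies a
  per-aptamer coefficient of variation of ~25%, typical of aptamer assays
  after normalization, and makes an FC of 1.25 a ~0.9σ effect —
  comfortably detectable at n = 224, marginal in small subgroups, which
  matches the qualitative pattern of the reported results.
- **Covariates are correctly specified by construction.** Sex and
  collection-year effects are additive shifts on log-RFU (per-aptamer
  Gaussian coefficients, sd 0.05 and 0.01/year), exactly the form the
  adjusted models assume. Passing tests therefore show the adjustment
  works when its model is right; they say nothing about misspecified
  batch structure in real data.
- **Survival** is a latent binary class per sample (short-survival
  probability 0.55 in centenarians, 0.3 in the younger groups, roughly
  the reported class splits); observed follow-up is drawn from
  class-conditional uniforms straddling the 2-/10-year cutoffs, with a
  5% unlabeled fraction in the younger groups. The planted survival
  shift (±0.3 log-units on 40 aptamers) enters through the within-group
  *centered* class indicator: the short class is more common in
  centenarians, so an uncentered shift would leak into the group
  contrast and mislabel survival proteins as false positives of the
  differential screen. Centering makes the two planted effect systems
  orthogonal, which is what "planted truth" needs to mean for FDR
  accounting.
- **Modules** are single Gaussian latent factors with shared-sign
  loadings (scale 0.3 × U(0.7, 1.3)), giving within-module correlations
  around 0.6 — coherent modules, as eigengene summaries assume. Real
  serum modules are not single-factor; recovery results on this
  structure are a best case.
- What the generator does **not** emulate: assay normalization and
  hybridization controls, dilution-bin structure, heavy-tailed or
  heteroskedastic noise, age-dependent effect sizes within groups, and
  relatedness between centenarians and their actual offspring.

`simulate_external_study()` emulates a partner cohort on the same
platform by drawing per-aptamer z ~ N(attenuation · log fc ·
sqrt(n)/(2·noise_sd), 1) — the mean a balanced two-arm design of size n
would give — so attenuation = 0 is an exact null with uniform p-values.

## Quality control

The published outlier criterion lives in unavailable supplementary
material; the package's documented stand-in flags samples whose mean
correlation to all other samples has a robust z-score (median/MAD) below
−5, iterating once, and aborts if more than 10% of samples would be
removed — a screen of that aggressiveness indicates a data problem, not
outliers.

## Numerical choices and degenerate inputs

- BH is `p.adjust(method = "BH")`; tests verify it against the literal
  sorted step-up definition.
- Fisher exact works in log space (`dhyper(log = TRUE)` + log-sum-exp);
  the enumeration oracle in the tests uses raw binomial-coefficient
  ratios instead.
- Rank-deficient designs error with the names of the collinear columns;
  constant responses return F = 0 / p = 1; zero-variance aptamers get
  correlation 0 (with a warning) and carry no pathway-score signal.
- Module labels M1, M2, … are assigned by decreasing size, making module
  identity deterministic given the input matrix.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the generator at 150–2000
aptamers and the study's 224-sample cohort shape (20 seeds for null
calibration, 5 seeds for recovery metrics, 200-aptamer two-block fixtures
for module recovery). These sizes were chosen so each property is
measured with comfortable Monte-Carlo margins while the whole suite stays
fast; all of them scale to the full 4785-aptamer platform through the
same code paths.
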