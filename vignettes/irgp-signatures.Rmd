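---
title: "Gene-pair prognostic signatures: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IRGPairs)
```

## The model

For genes $a, b$ measured in sample $s$, the pair score is

$$\mathrm{score}_s(a,b) = \mathbf{1}\{\,x_{a,s} \ge x_{b,s}\,\},$$

a within-sample comparison of two expression values. Any strictly
increasing per-sample transform $f_s$ leaves every score unchanged, so a
model built on these features is insensitive to normalisation choices and
to monotone platform effects — the property that motivates gene-pair
(relative-expression / k-TSP style) signatures in the first place.

The prognostic model is a Cox proportional-hazards model on a linear
combination of pair scores,

$$h(t \mid s) = h_0(t)\,\exp\Big(\sum_i \beta_i\,
\mathrm{score}_s(a_i,b_i)\Big),$$

fitted with an L1 penalty so that most candidate pairs get $\beta_i = 0$
and the surviving pairs form a sparse signature. The per-sample risk
score is the linear predictor $\sum_i \beta_i\,\mathrm{score}_s(a_i,b_i)$;
a sample is called high risk when its score is *strictly greater* than a
cutoff chosen on a time-dependent ROC curve.

Assumptions worth keeping in mind: proportional hazards for the risk
groups; binary pair features (the magnitude of the expression gap carries
no information beyond its sign); and independence of censoring from the
risk score given the model.

## The discovery funnel

`runDiscovery()` executes, in order, with each stage's candidate count
recorded in the run manifest:

1. **Immune-gene restriction** — only genes in the supplied gene list
   (e.g. an ImmPort-style list with functional categories) are analysed.
2. **Variability filter** — genes with raw MAD $\le$ 0.5 are dropped.
   `madRaw()` is the *unscaled* median absolute deviation,
   $\mathrm{median}(|x - \mathrm{median}(x)|)$, with no 1.4826
   consistency factor: the conventional 0.5 threshold is defined against
   the raw statistic, and applying the scaled estimator would silently
   change which genes pass.
3. **Pair enumeration** — all $n(n-1)/2$ unordered pairs, stored with a
   fixed lexicographic orientation (`gene_a < gene_b`). On tie-free data
   the two orientations of a couple carry complementary scores, so only
   one is kept.
4. **Pair scoring** — ties score 1: the rule is "0 when the first gene is
   strictly lower", and on continuous expression data ties have measure
   zero anyway.
5. **Constancy filter** — a pair identical in more than 80% of samples is
   removed; the boundary (exactly 80%) is retained. Such pairs cannot
   stratify a cohort and inflate the lasso's search space.
6. **Univariate screen** — per-pair Cox fit of the binary score; pairs
   with $p < 0.05$ (raw Wald p, no multiplicity adjustment — this is a
   screen, not an inference) proceed. A score-test variant is available
   (`test = "score"`); for a binary covariate the score test *is* the
   log-rank test, an identity the test suite asserts to $10^{-6}$.
7. **Lasso-Cox** — see below.
8. **Cutoff and validation statistics** — time-dependent ROC at the
   horizon, Youden cutoff, stratification, Kaplan–Meier, log-rank, and
   univariable/multivariable Cox with age, sex, stage and risk group.

The MAD filter defines candidates on the discovery cohort only; for
validation the signature genes merely need to be present.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `madThreshold` | 0.5 | expression units (log-like scale) | conventional variability cut for pair construction |
| `maxConstantFraction` | 0.8 | fraction of samples | the "more than 80%" constancy rule |
| `screenAlpha` | 0.05 | p-value | candidate screen level |
| `folds` | 10 | — | CV folds for the Cox partial-likelihood deviance |
| `nRepeats` | 25 | — | CV repeats for penalty stabilisation (see below) |
| `rocHorizon` | 1825 | days | 5-year overall survival, the conventional horizon for colon cancer |

All thresholds are parameters, not constants: candidate-pair counts are
strongly dataset-dependent (they depend on the expression scale through
the MAD filter), so the funnel is meant to be audited per dataset via the
manifest rather than matched to any fixed accounting.

## Repeated cross-validation for the penalty

A single k-fold CV curve for the lasso penalty is noticeably fold-noise
dependent in survival settings. `fitLassoCox()` therefore repeats the CV
`nRepeats` times with re-randomised folds, takes the **median of the
per-repeat optimal penalties**, and evaluates one final lasso path at
that penalty. Two properties follow by construction: the final model is a
genuine lasso solution (coefficients are not averaged across repeats),
and `nRepeats = 1` degenerates exactly to a standard `cv.glmnet` fit.
Per-pair selection frequencies across repeats are stored in the signature
metadata so the stabilisation is auditable; pairs that matter select in
(nearly) every repeat. A paper-faithful run would use `nRepeats = 1000`;
the package default of 25 is ample for stable medians, and the test suite
uses 3–5 repeats on its problem sizes.

The false-selection behaviour of this rule is that of the CV-optimal
penalty: a handful of null pairs typically enter with small coefficients
and low selection frequencies. The recovery tests therefore measure
sensitivity over planted pairs and the false-positive rate over null
candidates, not the FDR among selected pairs.

## Time-dependent ROC and the cutoff

The ROC at horizon $t$ uses cumulative cases (event observed at or before
$t$) and dynamic controls (still at risk after $t$). Censoring before the
horizon is handled by inverse-probability-of-censoring weights taken from
the Kaplan–Meier estimate of the censoring distribution: case $i$ gets
weight $1/\hat G(T_i^-)$, controls $1/\hat G(t)$. This weighting keeps
sensitivity and specificity monotone in the threshold (a property the
suite checks), and with no censoring before the horizon the AUC reduces
exactly to the Mann–Whitney statistic of the score against 5-year status.

Candidate cutoffs are the midpoints of adjacent sorted unique scores —
the only places the empirical curve can change — and `youdenCutoff()`
takes the threshold maximising sensitivity + specificity, breaking ties
toward the **smaller** threshold so the choice is deterministic and the
high-risk group errs larger. `runValidation()` reuses the discovery
cutoff unchanged by default (the stricter reading of external
validation); `recomputeCutoff = TRUE` re-derives it on the new cohort.

## The published signature

`loadPublishedSignature()` returns the packaged 17-pair / 26-gene
colon-cancer model with its coefficients at full printed precision and
cutoff −0.464. Pairs are stored in their published orientation, which is
not always lexicographic; `riskScore()` therefore accepts either an
expression matrix (pairs scored in stored orientation) or a lexicographic
`PairScoreMatrix` (reversed pairs matched by score complementation, valid
on tie-free data). Missing genes are an error listing the genes — never a
silent imputation, since a single absent gene shifts every risk score by
a known coefficient.

## What the synthetic cohorts emulate — and what they do not

`generateCohortPair()` emulates the structure of a two-cohort study: a
discovery cohort (default n = 452) and a validation cohort (default
n = 585) sharing the gene universe and the planted truth but with
independent samples and a different monotone platform distortion
(rank-warp by default, standing in for a microarray re-measurement).

* **Expression**: per-gene Gaussian on a log-like scale, location
  $\mathcal N(5, 2^2)$, scale $\mathcal U(0.3, 1.5)$ — wide enough that
  roughly half to two-thirds of genes pass MAD > 0.5.
* **Survival**: exponential event times with rate
  $\lambda \exp(\sum_i \beta_i\,\mathrm{score}_i + 0.02\,(\text{age}-67))$.
  The baseline $\lambda = 2.5\times10^{-4}$/day reproduces the ~63%
  5-year overall survival of colon cancer at zero risk; the age effect of
  0.02/year corresponds to a plausible HR ≈ 1.02. Age is
  $\mathcal N(67, 10^2)$; sex and stage frequencies mirror typical cohort
  composition (53% male; stages 17/39/28/14/2%).
* **Censoring**: independent $\mathcal U(0, u)$ with $u$ solved by
  root-finding so the *expected* censored fraction equals the target
  (default 0.5); the calibration is exact in expectation and the suite
  checks realised rates within ±0.05 at n = 1000.
* **Planted truth**: effects are planted on pair *scores* (not raw
  expression), among MAD-passing genes whose pair score flips in 35–65%
  of samples — so the planted pairs survive the pipeline's own filters
  and recovery is well defined. The generator returns the planted pairs
  and β, so recovery metrics need no inference. Default β alternates
  ±0.8 (per-pair HR ≈ 2.2).

Not emulated: negative-binomial count noise and library-size effects,
batch structure beyond monotone per-sample warps, correlated gene
modules, non-proportional hazards, informative censoring. Passing tests
on these cohorts therefore demonstrate the *mechanics* and the rank
invariance of the pipeline, and its statistical calibration under a
correctly specified hazard — not performance on real tumour data.

## Numerical choices and degenerate inputs

* Cox fits use the Efron tie approximation throughout (better than
  Breslow under heavy ties, and the default of mainstream survival
  software). Non-convergence and infinite coefficients (complete
  separation) are flagged on the returned object, never silent.
* Stage enters Cox models as ordinal 1–4; "unknown" becomes `NA` and is
  dropped from multivariable fits. Sex is 0/1 (male = 1).
* Scores exactly at the cutoff are low risk ("strictly higher" defines
  high risk).
* Duplicate gene symbols on load collapse to the row with maximal raw
  MAD (the most informative probe, standard microarray practice).
* Degenerate screens: pairs constant after sample alignment are skipped
  with a warning; an empty stage aborts the pipeline naming the stage.
* Signature JSON is written with 17 significant digits so write/read is
  an exact identity on doubles; the test suite asserts byte-identical
  re-runs of the whole discovery flow under a fixed seed.

## Problem sizes in the test suite

The suite exercises: oracle agreement (brute-force product-limit,
log-rank O−E accounting, double-loop pair scoring, exhaustive Youden
search) on small random instances; log-rank type-I error on 2000
permutation replicates at n = 60; Wald CI coverage on 500 replicates at
n = 500; hazard-ratio recovery at n = 1000; lasso recovery with 5
planted among 200 candidate pairs at n = 500; and the end-to-end
discovery → validation flow at the full 452/585 cohort sizes with 300
genes. These sizes give stable Monte-Carlo margins for every asserted
band while keeping a full run of the suite to a few minutes.

## Known limitations

* The constancy and MAD thresholds interact with the (unknown) expression
  scale of a user's data; the manifest exists precisely so users audit
  their own funnel rather than assume any particular candidate count.
* Orientation of a published pair table cannot be verified without the
  original data; the packaged model follows the stated scoring rule
  literally (first gene vs. second gene as printed).
* The IPCW ROC assumes censoring independent of the marker; under
  marker-dependent censoring the cutoff may shift.
* No proportional-hazards diagnostics, competing risks, or elastic-net
  variants; plotting is limited to TSV exports of KM curves and
  forest-plot tables.
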