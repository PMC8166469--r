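# IRGPairs

Rank-based immune-related gene-pair (IRGP) prognostic signatures for colon
cancer expression cohorts.

## The problem

Prognostic gene-expression signatures usually require the discovery and
validation cohorts to be normalised onto a common scale, which is fragile
across platforms (RNA-seq counts vs. microarray intensities). Gene-*pair*
signatures sidestep this: for a pair of immune genes (a, b) and a sample
*s*, the feature is simply

```
score_s(a, b) = 1  if  expr_s(a) >= expr_s(b),   else 0
```

— a within-sample comparison in the spirit of relative expression analysis
and k-TSP classifiers. Because the score depends only on the ordering of
two genes inside one sample, it is invariant to any strictly increasing
per-sample transformation, so a signature fitted on one platform can be
applied verbatim to another.

The prognostic model is a linear risk score over such binary features,

```
risk(s) = Σ_i  β_i · score_s(a_i, b_i)
```

with coefficients β from an L1-penalised (lasso) Cox proportional-hazards
fit. Patients with risk above a cutoff chosen on a time-dependent ROC
curve (the threshold with the greatest sensitivity + specificity) form the
high-risk group.

The package is for researchers who want to (i) apply the published
17-pair / 26-gene colon-cancer signature to their own expression matrix,
or (ii) rebuild a pair signature from scratch on a cohort with survival
data, with every step of the funnel — immune-gene restriction, MAD > 0.5
variability filter, pair enumeration and scoring, removal of pairs
constant in more than 80% of samples, univariate Cox screen at P < 0.05,
repeated-CV lasso-Cox, ROC/Youden cutoff, Kaplan–Meier / log-rank /
multivariable Cox validation — exposed, logged and tested. A synthetic
cohort generator with planted pair-level hazards makes the whole pipeline
reproducible without any external download.

## Worked example

```r
library(IRGPairs)

## the published signature ships with the package
sig <- loadPublishedSignature()
sig
#> IRGPSignature: 17 gene pairs, 26 distinct genes
#>   cutoff: -0.464
#>   gene_a gene_b coefficient
#> 1 CXCL14   BST2 -0.31777335
#> 2   RBP1   STC2 -0.62694387
#> ...

## simulate a discovery/validation cohort pair with planted signal
cp <- generateCohortPair(simConfig(260, nGenes = 100, seed = 17),
                         simConfig(300, nGenes = 100, seed = 1017,
                                   platformTransform = "rankwarp",
                                   samplePrefix = "V"))

## rebuild a signature on the discovery cohort
res <- runDiscovery(cp$discovery$expression, cp$discovery$clinical,
                    cp$geneList, nRepeats = 3, folds = 5, seed = 9)
res$manifest$counts
#>           genes_input          genes_immune        genes_variable
#>                   100                   100                    55
#>      pairs_enumerated pairs_after_constancy    pairs_after_screen
#>                  1485                   619                    80
#>    pairs_in_signature
#>                    31

## validate the locked signature on the second, platform-distorted cohort
val <- runValidation(res$signature, cp$validation$expression,
                     cp$validation$clinical)
signif(val$logrank$p_value, 3)
#> [1] 9.92e-16
print(val$coxMultivariate$table, digits = 3)
#>    covariate     coef    hr ci_low ci_high        p
#> 1        age  0.00972 1.010  0.994   1.026 2.30e-01
#> 2        sex  0.20113 1.223  0.879   1.701 2.32e-01
#> 3      stage -0.18747 0.829  0.692   0.993 4.19e-02
#> 4 risk_group  1.31993 3.743  2.655   5.278 5.09e-14
```

The manifest counts show the filtering funnel (100 genes → 55 variable →
1485 pairs → 619 non-constant → 80 screened → 31 in the fitted model).
The validation fit shows what the method is for: the risk group carries a
large, independent hazard ratio (here 3.7) on a cohort the signature
never saw, measured under a different monotone platform distortion,
while age, sex and stage behave as ordinary covariates.

Scoring your own cohort with the published model needs only an
expression matrix containing the 26 genes:

```r
rt <- stratifyRisk(riskScore(sig, my_expression_matrix),
                   signatureCutoff(sig))   # cutoff -0.464
```

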