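# babymotion

Automated infant movement analysis for cerebral-palsy (CP) risk
screening in very preterm infants.

The General Movements Assessment predicts CP from the quality of an
infant's spontaneous movements at 3–5 months corrected age, but it
demands scarce clinical expertise. `babymotion` implements an automated
surrogate: 2D video of a supine infant is reduced to kinematic summary
features, and a logistic model over four of them ranks CP risk.

**Measurement.** Each frame is skin-segmented with a Gaussian
chrominance model (Mahalanobis threshold in the Cb/Cr plane), dense
inter-frame displacement is estimated with a pyramidal Lucas–Kanade
optical flow, and per frame pair the package computes the *quantity of
motion*

> q(t) = 100 · #{skin pixels with |displacement| > θ} / #{skin pixels},

(θ = 0.5 px/frame by default) together with mean directional velocities
in px/s. Per video these summarize into Q_med, Q_min, Q_max, Q_sd
(movement variability), V_my/V_mx (mean absolute vertical/horizontal
velocity), accelerations and centroid spreads; multiple videos of one
patient are averaged.

**Model.** The published multivariable logistic model is

> logit P(CP) = β₀ + 0.75·V_my + 0.08·Q_med + 1.13·Q_sd − 0.89·Q_min,

shipped as `publishedModel()` (no intercept was published, so it ranks
risk; supply an intercept for absolute probabilities). The full
development/validation protocol is implemented: univariate screening at
p < 0.20, VIF > 4 pruning, backward selection at 0.20, Harrell's
bootstrap optimism correction of the C-statistic, Hosmer–Lemeshow fit,
ROC/Youden threshold choice, and sensitivity/specificity/PPV/NPV with
exact Clopper–Pearson intervals.

Because no clinical data are distributable, the package ships two
simulators: ground-truthed phantom videos (oscillating skin-toned limbs)
and cohort tables drawn from the published coefficients at 11.5%
prevalence.

## Worked example

```r
library(babymotion)

## a ground-truthed phantom video stands in for clinic footage
ph   <- generatePhantomVideo(phantomSpec(duration = 5, seed = 7))
screenQuality(ph$seq, list(min_duration = 5))@passed
#> [1] TRUE

fv <- extractFeatures(ph$seq)
round(fv$Q_med, 1); round(fv$V_my, 1)
#> [1] 90.5
#> [1] 18.5

## rank its risk with the published coefficients
predictRisk(fv, publishedModel())$lp
#> [1] 1.371219

## simulate a development cohort and rebuild the model from scratch
co   <- simulateCohort(cohortSpec(n = 2000, seed = 5))
spec <- fitRiskModel(co)
oddsRatios(spec)
#>   variable        beta        or     lower     upper
#> 1     V_my  0.81902885 2.2682959 1.7966510 2.8637539
#> 2    Q_med  0.06153023 1.0634626 1.0321924 1.0956802
#> 3     Q_sd  1.27177961 3.5671951 2.4482149 5.1976161
#> 4    Q_min -0.53113640 0.5879365 0.4165414 0.8298558

evaluateModel(co, variables(spec), B = 200, seed = 1)
#> EvaluationReport: C apparent 0.734, optimism 0.004, corrected 0.730
#> Hosmer-Lemeshow: chi2 11.69, df 8, p 0.165
#> Threshold 0.1191; confusion TP 158 FN 75 FP 572 TN 1195
#>       metric estimate lower upper    x    n
#>  sensitivity    67.81 61.40 73.76  158  233
#>  specificity    67.63 65.39 69.81 1195 1767
#>          ppv    21.64 18.71 24.81  158  730
#>          npv    94.09 92.65 95.33 1195 1270
#>     accuracy    67.65 65.55 69.70 1353 2000
```

`Q_med` is the median percentage of skin pixels moving per frame;
`V_my` the mean absolute vertical speed in px/s; the odds ratios are
per unit of each feature, with Wald 95% intervals; apparent C is the
probability that a random case outranks a random non-case, and the
bootstrap-corrected value removes the self-testing optimism.

A command-line front end over the same functions lives at
`inst/scripts/babymotion.R` (subcommands `extract`, `fit-skin`,
`simulate`, `fit`, `evaluate`, `predict`). Video input is a directory
of ordered PNG/JPEG frames with an `fps.txt` sidecar.

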