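# petsurv

Multimodal deep survival prediction for non-small cell lung cancer
(NSCLC): clinical covariates, whole-body FDG PET volumes, or both,
mapped to individual survival curves and absolute survival times under
right censoring.

## What it does

Prognosis in NSCLC is conventionally read off TNM stage and a few
clinical covariates with a Cox proportional-hazards (CPH) model, yet
patients within a stage are heterogeneous and PET images carry
prognostic information a covariate table cannot express. `petsurv`
implements and evaluates the full model family for this problem:

| model | input | builder |
|---|---|---|
| multivariate CPH (Efron ties) | clinical table | `fit_cph()` |
| DeepSurv MLP (2 hidden layers, GELU; width 32/64/128) | clinical table | `build_mlp()` |
| ResNet-18/34/50 (2D) | coronal maximum intensity projection | `build_resnet2d()` |
| ResNet3D-10/18/34 (3×3×3 kernels, BN+ReLU, adaptive pooling) | PET volume | `build_resnet3d()` |
| joint fusion: ResNet3D features ⊕ MLP hidden layer → linear head | both | `build_multimodal()` |

Every network emits a log relative hazard h(x) and is trained by Adam
on the Cox negative log partial likelihood (Breslow ties, within-batch
risk sets, L2 penalty):

    L = -(1/D) Σ_{i: E_i=1} [ h_i - log Σ_{j: T_j ≥ T_i} exp(h_j) ] + λ‖W‖²

Risk scores become absolute times through the Breslow baseline hazard
fitted on the training fold: S(t|x) = exp(-H₀(t)·e^h), and the
predicted survival time is the median residual life — the first time
the curve crosses 0.5 (interpolated; exponential-tail extrapolation,
capped at 10 years, when the curve never gets there). Evaluation is
censoring-aware: Harrell's C-index over predicted times, MAE on
uncensored subjects, 2-/5-year status accuracy (subjects censored
before the horizon excluded as unknowable), Kaplan–Meier curves and
log-rank tests, all under stratified k-fold cross-validation with the
baseline hazard and normalization statistics fitted per training fold.

The networks run on a compact reverse-mode engine written for this
package (im2col+GEMM convolutions in C++/Armadillo, fused batch-norm
and ReLU kernels, in-place Adam), so no deep-learning framework is
required. A synthetic cohort generator (`cohort_config()`,
`generate_cohort()`, `simulate_cohort()`) emulates a realistic target cohort —
covariate distributions of a large real-world NSCLC population,
proportional-hazards outcomes with
~31% censoring, and lesion-bearing volumes whose latent burden factor
enters the true hazard independently of the clinical covariates — so
the entire pipeline is testable without restricted hospital data.

## Worked example

```r
library(petsurv)

cfg    <- cohort_config(n_subjects = 500, gamma = 0, seed = 42)
cohort <- generate_cohort(cfg, with_volumes = FALSE)
cohort$records
#> <surv_records> 500 subjects, 346 events (30.8% censored)

cv <- cross_validate(model_spec("mlp", hidden_width = 64),
                     cohort$records, cohort$inputs, k = 5,
                     config = train_config(seed = 1, max_epochs = 60))
cv
#> <cv_result> 5 folds
#>  fold    c_index  mae_days    acc_2yr    acc_5yr
#>     1 0.66903915 278.00293 0.75342466 1.00000000
#>     2 0.48592871 396.39725 0.68354430 0.94366197
#>     3 0.61788840 302.06785 0.71250000 0.94366197
#>     4 0.57767127 330.66784 0.80263158 0.95714286
#>     5 0.52067989 510.71663 0.57894737 0.91428571
#>  mean 0.57424148 363.57050 0.70620958 0.95175050
#>    sd 0.07343604  93.42985 0.08407648 0.03119115
```

Each row is one held-out fold: the concordance between predicted and
observed survival ordering, the mean absolute error in days over the
fold's uncensored subjects, and the 2-/5-year status accuracies; the
footer is the mean ± sd across folds. Per-subject absolute predictions
come from the fold's training-fold baseline hazard:

```r
fold1 <- cv$folds[[1]]
m <- median_survival_time(survival_curve(fold1$baseline,
                                         fold1$test_risks[1]))
#> subject S00001: predicted median OS 432 days (extrapolated: FALSE)
```

With volumes (`gamma = 1` plants an image-borne signal), the same
interface trains the image and fusion models:

```r
cfg <- cohort_config(n_subjects = 400, gamma = 1, seed = 31)
co  <- generate_cohort(cfg)   # 32x32x64 volumes + coronal MIPs
cv_mm <- cross_validate(model_spec("multimodal",
                                   resnet3d = list(layers = 10)),
                        co$records, co$inputs, k = 5,
                        config = train_config(seed = 7, max_epochs = 5,
                                              learning_rate = 1e-3))
```

A command-line wrapper (`inst/cli/petsurv.R`) exposes
`simulate | train | evaluate | predict | mip` over YAML configs for
shell use.

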