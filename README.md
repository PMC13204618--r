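# wsisurv

Survival prediction from histopathology whole-slide images (WSIs)
represented as bags of patch-level feature embeddings, for researchers
comparing aggregation paradigms in computational pathology.

A WSI is tiled into 360×360 px patches at 20× magnification; each patch is
embedded as a feature vector and each slide carries one survival record
(follow-up time, death indicator). `wsisurv` implements the two dominant
ways of turning patch embeddings into a slide-level prognostic risk:

* **Attention-MIL Cox** — a gated-attention network pools patch features
  into a slide representation
  `z_i = Σ_k a_ik φ(x_ik)` (softmax weights `a_ik` summing to 1 per bag),
  a linear head maps it to a risk `r_i`, and everything trains end-to-end
  by minimising the Cox negative partial log-likelihood
  `−Σ_{i:δ_i=1} [r_i − log Σ_{t_j ≥ t_i} exp(r_j)]`
  over slide risks (Breslow ties, max-shift stabilised).
* **Patch-level Cox baseline** — every patch inherits its slide's
  `(time, event)` label, a per-patch scorer trains on the same objective at
  instance level, and the slide risk is the mean patch risk.

Around the models sits the full evaluation pipeline: event-stratified
5-fold cross-validation, fold-wise z-score standardization
`z_i = (r_i − μ_f)/σ_f` pooled into a unified validation set, Harrell's
C-index, Kaplan–Meier curves stratified at the 25th/50th/75th risk
percentiles with binary-group Cox hazard ratios, IPCW cumulative/dynamic
AUC at 1/3/5-year horizons, and bootstrap ΔC model comparison (1000
resamples, percentile CI). Slide bookkeeping covers tile grids, the
3.24 mm² tumor-area exclusion rule (100 patches at 0.5 µm/px), all-tissue
vs tumor-only patch selection, and a tissue-QC CNN (12/24/24 filters, 5×5
kernels, 2×2 max-pooling). A synthetic cohort generator produces slides as
mixtures of patch archetypes (low-/high-grade tumor, necrosis, fibrosis,
normal, artifact) whose composition drives a Cox log-hazard, with
right-censoring and controllable cross-cohort domain shift — so every
stage is testable without real data. See the methods vignette
(`vignettes/attention-mil-survival.Rmd`) for the model, the generator's
assumptions and all numerical choices.

## Worked example

```r
library(wsisurv)
co <- make_cohort(cohort_config(n_slides = 160, beta = 2, seed = 1))
co
#> <wsi_cohort 'synthetic'> 160 slides, 48-80 patches/slide, d=32, 46% events

res <- run_cv(co, paradigm = "mil", tissue = "all", k = 5, seed = 1)
res$report
#> <experiment_report> cv | mil/all | C = 0.8188 (n = 160, events = 74)
round(res$report$metrics$auc, 3)
#>   t12   t36   t60
#> 0.908 0.858 0.890
sapply(res$report$metrics$hr, function(h) round(h$hr, 3))
#>   q25   q50   q75
#> 6.589 9.590 7.379

pt <- run_cv(co, paradigm = "patch", tissue = "tumor", k = 5, seed = 1)
pt$report
#> <experiment_report> cv | patch/tumor | C = 0.8225 (n = 160, events = 74)

m <- match(res$predictions$slide_id, co$survival$slide_id)
bootstrap_delta_c(res$predictions$risk_std,
                  pt$predictions$risk_std[match(res$predictions$slide_id,
                                                pt$predictions$slide_id)],
                  co$survival$time[m], co$survival$event[m],
                  n_iter = 1000, seed = 1)
#> <bootstrap_result> dC = -0.0036, 1000 iters, CI [-0.0311, 0.0227], p = 0.752
```

Reading the numbers: on this synthetic cohort (grade signal β = 2 log-HR
per SD of latent grade, ~46% events) the attention-MIL model reaches a
pooled cross-validated C-index of 0.819 — on the scale of published
WSI-survival results — with time-dependent AUCs near 0.9 and hazard
ratios of 6.6–9.6 between quantile-split risk groups. The tumor-only
patch baseline scores C = 0.823; the bootstrap says the difference
(ΔC = −0.004, CI crossing 0, p = 0.75) is not distinguishable from noise
on 160 slides. The paradigms separate on *all-tissue* bags, where mean
pooling is diluted by uninformative patches while attention is not — the
contrast the acceptance suite checks directionally.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "wsisurv", package = "wsisurv"))')
Rscript $CLI simulate --seed 1 --out cohort_dir
Rscript $CLI cv --cohort cohort_dir --paradigm mil --tissue all --folds 5 \
    --seed 1 --out cv_out     # writes metrics.json, predictions.csv, manifest.json
Rscript $CLI qc --seed 1 --out qc_out
```

Subcommands: `simulate`, `qc`, `cv`, `transfer`, `combined`, `evaluate`,
`heatmap`; see `?wsisurv_cli`.

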