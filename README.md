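# esometh

Diagnostic and prognostic DNA methylation classifiers for esophageal
lesions, built on Illumina 450K-style beta-values.

Early esophageal cancer and its precursor, Barrett's esophagus, lack
specific molecular markers. Non-endoscopic sampling devices make
methylation-based screening attractive, but swallowed/withdrawn
samplers can carry material from the head-and-neck region and the
stomach, so a usable marker must separate the four esophageal tissue
states — normal squamous esophagus (NSE), Barrett's esophagus (BE),
esophageal adenocarcinoma (EAC), esophageal squamous cell carcinoma
(ESCC) — *and* stay silent in adjacent-organ tissue. `esometh`
implements that workflow for analysts working with CpG beta-value
matrices:

- **Diagnostic arm.** Pairwise empirical-Bayes moderated t-statistics
  (variance shrinkage via moment matching on log s², Newton solve of
  the trigamma equation) with Benjamini–Hochberg FDR per comparison; a
  CpG is *tissue-specific* only if significant against **all seven**
  other tissue classes (this rejects markers shared with HNSC/STAD
  contaminants). The marker panel is then chosen by stability
  selection: 10 stratified 2:1 partitions, each fitting a
  grouped-penalty multinomial lasso
  (−(1/n)·loglik + λ·Σ_j ‖β_j·‖₂, FISTA with group soft-thresholding
  and a KKT stopping certificate) at a λ chosen by 10-fold
  cross-validated accuracy with a 1-SE rule; CpGs selected in ≥ 9/10
  partitions form the panel. A ridge-stabilized multinomial model is
  the final classifier, evaluated by confusion matrices
  (Clopper–Pearson 95% CI) and micro-average one-vs-all ROC/AUC.
- **Prognostic arm** (per histology). DMCs from a tumor-vs-NSE contrast
  (|Δβ| > 0.2, FDR < 0.05) → covariate-adjusted Cox screen (age,
  gender, BMI, smoking, alcohol, AJCC stage; CpG Wald p < 0.05) →
  LASSO-Cox stability selection (100 × 75% subsamples, 5-fold CV,
  frequency > 30) → unpenalized Cox risk score with a median split into
  high/low risk, evaluated by Kaplan–Meier/log-rank, Cox tables,
  time-dependent ROC and G1–G4 risk-by-stage stratification.
- **Synthetic-data generator** with planted tissue-specific markers,
  adjacent-organ decoys and prognostic CpGs driving exponential
  proportional-hazards survival, so the whole pipeline runs end to end
  with known ground truth.

See `vignettes/methylation-classifiers.Rmd` for the model details and
design rationale.

## Worked example

```r
library(esometh)

# a full synthetic study: 500 CpGs, 60 samples in each of 8 tissue
# classes, planted markers and survival signal
d <- simulate_dataset(sim_config(seed = 1))

# diagnostic arm end to end (markers + stability selection + model are
# fit on the training cohort only)
rep_diag <- run_diagnostic_pipeline(d$betas, d$samples,
                                    config = grouped_lasso_config(seed = 42))
rep_diag$evaluation$validation$confusion
#> Confusion matrix (rows = hypothesized, cols = true):
#>        NSE BE EAC ESCC
#>   NSE   14  1   0    1
#>   BE     1 13   1    0
#>   EAC    0  0  10    0
#>   ESCC   0  1   4   14
#>
#> Accuracy rate (%):
#>     NSE      BE     EAC    ESCC overall
#>   93.33   86.67   66.67   93.33   85.00
#>
#> Overall: 85.00% (95% CI 73.4%-92.9%), 51/60 correct
rep_diag$evaluation$validation$micro_auc$auc
#> [1] 0.9739815

# prognostic arm for EAC on a cohort with 200 patients
dp <- simulate_dataset(sim_config(
  n_per_class = setNames(c(60, 10, 200, 10, 10, 10, 10, 10),
                         tissue_classes()),
  seed = 5))
rep_prog <- run_prognostic_pipeline(dp$betas, dp$samples, "EAC", seed = 7)
rep_prog$model$cpgs
#> [1] "cg00000029" "cg00000030" "cg00000031"   # exactly the 3 planted CpGs
rep_prog$evaluation$km$p
#> [1] 6.137514e-18                             # log-rank, high vs low risk
```

The confusion matrix reads like the published ones: columns are the
true classes, rows the calls, the diagonal the correct calls; the
micro-average AUC pools every (sample, class) decision. The prognostic
report also carries the per-sample risk-score table, the median cutoff,
univariate/multivariate Cox HR tables, the time-dependent AUC at the
median follow-up, and the G1–G4 risk-by-stage stratification.

(The numbers above are what these exact seeds print on this package
version; other seeds vary within a few percent.)

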