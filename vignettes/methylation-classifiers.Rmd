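---
title: "Diagnostic and prognostic methylation classifiers for esophageal lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic and prognostic methylation classifiers for esophageal lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`esometh` implements a two-stage marker workflow on Illumina
450K-style beta-values (methylated / total intensity, in [0, 1]) for
esophageal disease:

1. **Diagnostic arm** — multiclass discrimination of normal squamous
   esophagus (NSE), Barrett's esophagus (BE), esophageal adenocarcinoma
   (EAC) and esophageal squamous cell carcinoma (ESCC), with marker
   specificity enforced against the adjacent-organ tissues a
   non-endoscopic sampling device can pick up (head-and-neck squamous
   carcinoma and stomach adenocarcinoma, each with matched normals).
2. **Prognostic arm** — per-histology (EAC, ESCC) survival risk scores
   built from differentially methylated CpGs, with a median split into
   high/low risk groups.

Both arms are exercisable end to end on seeded synthetic data with
planted ground truth; no external download is required.

# Diagnostic arm

## Tissue-specific markers

For every pair of the eight tissue classes, each CpG is tested with an
empirical-Bayes **moderated t-statistic** computed directly on
beta-values. The pooled two-sample variance $s^2_g$ (with
$d_g = n_a + n_b - 2$ degrees of freedom) is shrunk toward a global
prior $s_0^2$ with prior degrees of freedom $d_0$:

$$\tilde s^2_g = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g}, \qquad
  t_g = \frac{\Delta\beta_g}{\tilde s_g\sqrt{1/n_a + 1/n_b}},$$

with $t_g$ referred to a $t_{d_0+d_g}$ reference. The hyperparameters
are estimated by moment matching on $\log s^2_g$ using
digamma/trigamma identities, solving the trigamma equation for $d_0$
by Newton iteration; when the observed spread of $\log s^2_g$ does not
exceed its sampling noise, $d_0 = \infty$ and every CpG uses the
log-scale prior variance. Within each pairwise comparison the p-values
are Benjamini–Hochberg adjusted across CpGs (`bh_adjust`, a validated
wrapper around `p.adjust`), and BH is deliberately applied *within*
comparisons, not pooled across all 28 of them.

A CpG is a **tissue-specific marker** for one of the four esophageal
classes when it is significant (adjusted p < 0.05) in *all seven*
comparisons of that class against the other tissues. This intersection
rule is what rejects "contaminant-mimicking" CpGs whose shift is shared
with an adjacent organ: such a CpG fails the one comparison against
that organ.

Working on beta-values (not M-values) is a deliberate choice: the
effect-size rule of the prognostic arm is stated on the beta scale
($|\Delta\beta| > 0.2$), and mixing scales between testing and
thresholding invites inconsistency. Beta-scale variances are
heteroscedastic, which the empirical-Bayes shrinkage absorbs in part;
this is a known trade-off, flagged here rather than hidden.

## Stability selection

On the training esophageal samples restricted to the marker union, the
panel is chosen by repeated-partition stability selection:

- 10 seeded, class-stratified 2:1 train/test partitions;
- in each partition, a **grouped-penalty multinomial lasso**
  $$\min_{B, b_0}\; -\tfrac1n \sum_i \log p_{i,y_i}
    + \lambda \sum_j \lVert \beta_{j\cdot}\rVert_2$$
  (the class coefficients of one CpG form one group, so a CpG enters or
  leaves the model for all classes at once), with features standardized
  on the partition's training statistics and intercepts unpenalized;
- $\lambda$ chosen by stratified 10-fold cross-validated *accuracy*
  with a one-standard-error rule: the largest $\lambda$ whose mean
  accuracy is within one SE (at the maximizing $\lambda$) of the
  maximum — the sparser model wins ties;
- a CpG scores one selection per partition with any nonzero
  coefficient; the final panel is every CpG selected in **at least 9 of
  10** partitions.

The solver is an accelerated proximal-gradient (FISTA) iteration with
group soft-thresholding, gradient-mapping adaptive restart, a step from
the spectral bound $L = \sigma_{\max}([1\,X])^2/2n$, warm starts along
a 100-point log-spaced path from $\lambda_{\max}$ (the group-norm of
the null-model gradient, below which the solution leaves zero) down to
$10^{-3}\lambda_{\max}$, and a KKT-residual stopping certificate
(default $10^{-6}$; $10^{-4}$ inside cross-validation, where only the
accuracy of held-out predictions matters). Tests verify the KKT
conditions of returned solutions directly and compare the attained
objective against a generic numeric minimizer; `glmnet`'s grouped
multinomial path serves as an independent cross-check, never as the
implementation.

Partitions are stratified by class. With only ~60 ESCC samples in a
realistic design, unstratified splits can starve cross-validation folds
of a class entirely; stratification is the standard remedy and is
applied to both the 2:1 partitions and the CV folds.

## Final model

The published procedure refits a plain multinomial logistic model on
the stable panel. On separable training data the unpenalized maximum
likelihood does not exist, so the final fit adds a tiny ridge term
($10^{-6}$ on standardized coefficients, intercepts unpenalized),
optimized by BFGS with analytic gradients. This keeps the model
well-defined under quasi-separation while leaving well-conditioned fits
numerically indistinguishable from the unpenalized solution (verified
against `nnet::multinom`). Test and validation cohorts are projected
with the training scaler; the model serializes to JSON at full text
precision.

Performance reporting uses the K×K confusion matrix (per-class accuracy
= diagonal over the true-class total; overall accuracy with a
Clopper–Pearson exact 95% interval — the printed tables this package
mirrors do not name their interval method, so the exact interval is a
package choice) and the **micro-average one-vs-all ROC/AUC**: every
(sample, class) pair becomes one pooled binary instance scored by the
predicted probability; the AUC is the Mann–Whitney statistic with
mid-rank tie handling. Reported percentages round half up to two
decimals, matching printed tables.

# Prognostic arm

Per histology, candidate CpGs are:

1. **DMCs** from a tumor-vs-NSE moderated-t contrast with strict
   thresholds $|\Delta\beta| > 0.2$ and BH-adjusted p < 0.05;
2. screened by a **covariate-adjusted Cox model** (age, gender, BMI,
   smoking, alcohol use, AJCC stage as advanced III/IV vs early I/II):
   a CpG survives when the Wald p of its own term is < 0.05. This
   "adjusted p" is covariate-adjusted, *not* multiplicity-adjusted — a
   deliberate reading documented here prominently;
3. put through **LASSO-Cox stability selection**: 100 replicates of
   subsampling 75% of patients without replacement, each fit by
   `glmnet::cv.glmnet(family = "cox")` with 5-fold cross-validation on
   partial-likelihood deviance and the 1-SE penalty; CpGs with nonzero
   coefficients in strictly more than 30 replicates are kept.
   Replicates whose subsample carries too few events are redrawn and
   counted.

The **risk score** is the uncentered linear predictor
$\sum_k \hat\beta_k \beta_k$ of an unpenalized multivariable Cox refit
(Efron ties) on the selected CpGs — refit coefficients, not the
penalized ones, since shrunken coefficients understate the hazard
contrast the score is meant to express. Patients split at the median
score of the fitting cohort; scores exactly at the median go to the
low-risk group (a deterministic tie rule), and the cutoff is stored for
external application.

Evaluation: Kaplan–Meier curves with the k-group log-rank test,
univariate + multivariate Cox tables (HR, 95% Wald CI, p) with the
classifier group coded high vs low, a KM-based cumulative/dynamic
**time-dependent ROC** at a horizon defaulting to the median observed
follow-up,

$$se(c,t) = \frac{(1 - S(t \mid X > c))\,P(X > c)}{1 - S(t)}, \qquad
  sp(c,t) = \frac{S(t \mid X \le c)\,P(X \le c)}{S(t)},$$

and a four-level **risk stratification** G1–G4 crossing the risk group
with early (I/II) vs advanced (III/IV) stage. The G1–G4 Cox model
adjusts for age, gender, BMI, smoking and alcohol but *not* stage —
stage is part of the level coding and would be collinear with it. The
trend test is the Wald test of the ordinal 0–3 level coding in the
adjusted model. Monotone partial likelihoods (a group with no finite
MLE) are flagged and the coefficient capped at |15| with a warning
rather than silently reported.

# The synthetic-data generator

`simulate_dataset()` emulates the *structure* of a 450K multi-tissue
study, not any particular cohort:

- **Beta generation on the logit scale.** Each (CpG, class) cell has a
  target mean beta; values are `plogis(mu + sd * Z)`. Because the
  inverse logit is nonlinear, `mu` is corrected (by inverting the
  tabulated logit-normal mean map) so the *expected* beta equals the
  target — otherwise planted shifts would shrink as noise grows, and
  the generator would violate its own contract that class means differ
  by `delta` in expectation.
- **Bimodal baseline.** Background CpG means sit near 0.1 or 0.9
  (mixed 50/50 with logit-scale jitter), the familiar two-mode shape of
  450K beta distributions.
- **Planted tissue-specific CpGs** shift exactly one class upward by
  `delta` (default 0.3) from a mid-range base. The default plants
  **two markers per esophageal class** at a within-class logit-scale sd
  of 1.0 (beta-scale sd roughly 0.15–0.2, the upper range of tumor
  450K heterogeneity). These two choices are coupled and deliberate:
  each planted marker is then individually *necessary* for its class —
  dropping one costs several points of CV accuracy, more than one SE —
  so the stable panel has a well-defined planted truth. With many
  near-duplicate markers per class (or with noise so small that any
  single marker separates its class), lasso-type selection is
  arbitrary among interchangeable features and "recover the planted
  panel" would be meaningless as a property, which is exactly the
  regime the frequency-threshold rule exists to resolve in real data.
- **Decoy CpGs** (default 5 per class) shift an esophageal class *and*
  its adjacent-organ partner (EAC with STAD, ESCC with HNSC, NSE with
  HNSC-normal, BE with STAD-normal) identically; a correct intersection
  rule must reject them.
- **Prognostic CpGs** (default 3) are hypermethylated in EAC/ESCC
  versus all other tissues by at least 0.3 — so they survive the DMC
  gate — and have a wide between-patient dispersion (logit sd 2.0),
  without which a per-beta-unit log hazard ratio of 1.5 would be
  undetectable at n ≈ 200 (the score's standard error scales with
  1/(sd of the covariate × sqrt(events))).
- **Survival** is exponential proportional hazards with linear
  predictor $\sum_k \beta^{\text{plant}}_k \cdot \text{beta}_k$,
  baseline hazard 0.1 per time unit, independent exponential censoring
  (default rate 0.05), observed time = min(event, censoring). Clinical
  covariates are drawn independently of survival: age uniform 40–80,
  gender/smoking/alcohol Bernoulli(0.5), BMI uniform 18–35, stage
  uniform over I–IV for tumor samples.
- **Cohorts** are assigned 50/25/25 train/test/validation, stratified
  by class, echoing the roughly 2:1:1 cohort sizes of the study design
  this emulates (377/187/184).

What the generator does **not** emulate: probe-level chemistry (type
I/II probes), batch or platform effects between cohorts, correlated CpG
blocks, cell-type mixtures, confounding between clinical covariates and
methylation, or non-proportional hazards. Passing tests therefore
demonstrate the *procedures* behave as specified under a clean
generative model — recovery of planted signal, calibration under the
null, determinism — not that real tissue data would yield comparable
accuracy.

# Default problem sizes and numerical choices

The study conditions used by tests and the acceptance script are 500
CpGs and 60 samples per class (50 per class with 50 planted markers
per class for the discovery-rate check), with the full pipeline run on
a 50/25/25 cohort split; the prognostic arm uses 200 EAC patients.
These sizes keep every end-to-end run in the minutes range on one CPU
while leaving each statistical property comfortably powered.

Numerical details worth knowing:

- `compute_beta` is the plain ratio M/(M+U) with no offset; a zero
  total yields `NA`, and CpGs with any missing value are dropped
  (complete-case) before marker discovery unless median imputation is
  requested.
- DMC thresholds are strict inequalities (> 0.2, < 0.05), as printed.
- `cv_select_lambda` breaks accuracy ties toward the largest penalty;
  an all-equal accuracy curve returns the largest grid value.
- The stability-selection threshold "9 of 10" includes ties at 9;
  the LASSO-Cox threshold "more than 30 of 100" is strict.
- Median-split ties go to the low-risk group.
- Probabilities from `predict_proba` row-normalize to 1 within 1e-8;
  class ties in `predict_class` break toward the earlier class label.
- Seeds fan out from one master seed via a deterministic integer map
  (`child_seed`), so each stage is independently reproducible.

# Known limitations

- Cross-dataset harmonization (e.g. between array cohorts processed
  differently) is out of scope; no normalization is applied.
- The moderated t on beta-values inherits beta-scale
  heteroscedasticity; an M-value option is a possible extension.
- The time-dependent ROC uses the Kaplan–Meier cumulative/dynamic
  estimator, which is simple and transparent but not monotone in the
  cutoff under heavy censoring.
- SNP-associated and cross-reactive probe lists are user-supplied;
  none are bundled.
- The G1–G4 trend test relies on an ordinal linear coding; it is a
  test of monotone trend, not of any particular dose-response shape.
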