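#' End-to-end diagnostic pipeline
#'
#' Orchestrates the diagnostic arm on a dataset with train/test/validation
#' cohorts: tissue-specific marker discovery (training cohort, all eight
#' classes), stability selection of the diagnostic panel (training
#' esophageal samples), final multinomial model (training), and confusion
#' matrix + micro-average AUC on every cohort's esophageal samples. No
#' information from the test or validation cohorts reaches marker
#' selection or model fitting. If a fitted \code{model} is supplied,
#' selection and fitting are skipped and the model is only evaluated.
#'
#' @param betas CpG-by-sample matrix.
#' @param samples sample annotation with \code{sample_id},
#'   \code{tissue_class}, \code{cohort}.
#' @param fdr FDR threshold for tissue-specific markers (default 0.05).
#' @param config a \code{\link{grouped_lasso_config}}.
#' @param model optional prefitted \code{diag_model} (validation-only
#'   run).
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @return list of class \code{diag_report}: markers, stability
#'   selection, model, and per-cohort evaluation (confusion summary,
#'   micro AUC).
#' @export
run_diagnostic_pipeline <- function(betas, samples, fdr = 0.05,
                                    config = grouped_lasso_config(),
                                    model = NULL, out_dir = NULL) {
  if (anyDuplicated(samples$sample_id))
    stopf("cohort leakage: duplicated sample id(s): %s",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                collapse = ", "))
  if (!all(samples$cohort %in% c("train", "test", "validation")))
    stopf("cohort must be train/test/validation")
  cls <- factor(as.character(samples$tissue_class), levels = tissue_classes())
  eso <- cls %in% esophageal_classes()
  stability <- NULL; markers <- NULL
  if (is.null(model)) {
    tr <- samples$cohort == "train"
    markers <- tissue_specific_markers(betas[, samples$sample_id[tr]],
                                       cls[tr], fdr = fdr)
    if (!length(markers$union))
      stopf("no tissue-specific markers at FDR %g", fdr)
    tr_eso <- tr & eso
    X <- t(betas[markers$union, samples$sample_id[tr_eso], drop = FALSE])
    y <- droplevels(cls[tr_eso])
    stability <- stability_select(X, y, config)
    if (!length(stability$selected))
      stopf(paste("stability selection kept no CpGs; relax freq_threshold",
                  "or lower fdr"))
    model <- fit_final_multinomial(X[, stability$selected, drop = FALSE], y)
  }
  evaluate_cohort <- function(which_cohort) {
    sel <- samples$cohort == which_cohort & eso
    if (!any(sel)) return(NULL)
    ids <- samples$sample_id[sel]
    Xc <- t(betas[model$features, ids, drop = FALSE])
    truth <- as.character(cls[sel])
    prob <- predict_proba(model, Xc)
    pred <- as.character(predict_class(model, Xc))
    list(confusion = confusion_summary(truth, pred, classes = model$classes),
         micro_auc = micro_average_auc(truth, prob))
  }
  report <- list(markers = markers, stability = stability, model = model,
                 evaluation = list(train = evaluate_cohort("train"),
                                   test = evaluate_cohort("test"),
                                   validation = evaluate_cohort("validation")),
                 fdr = fdr, config = config)
  class(report) <- "diag_report"
  if (!is.null(out_dir)) write_diag_report(report, out_dir)
  report
}

write_diag_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$stability))
    data.table::fwrite(
      data.frame(cpg = names(report$stability$frequency),
                 frequency = as.integer(report$stability$frequency)),
      file.path(out_dir, "stability_frequency.tsv"), sep = "\t")
  write_diag_model(report$model, file.path(out_dir, "diag_model.json"))
  summ <- lapply(report$evaluation, function(ev) {
    if (is.null(ev)) return(NULL)
    list(overall_accuracy = ev$confusion$overall_accuracy,
         per_class_accuracy = as.list(ev$confusion$per_class_accuracy),
         overall_ci = ev$confusion$overall_ci,
         micro_auc = ev$micro_auc$auc)
  })
  jsonlite::write_json(summ, file.path(out_dir, "diagnostic_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' End-to-end prognostic pipeline for one histology
#'
#' Runs the prognostic arm for EAC or ESCC: tumor-vs-NSE moderated-t DMC
#' detection (|delta beta| > 0.2, FDR < 0.05), covariate-adjusted Cox
#' screening, subsampled LASSO-Cox stability selection, risk-score
#' construction with a median split, and evaluation (Kaplan-Meier +
#' log-rank, univariate/multivariate Cox table, time-dependent AUC at
#' \code{horizon}, and G1-G4 risk stratification).
#'
#' @param betas CpG-by-sample matrix.
#' @param samples sample annotation (tissue class, clinical fields,
#'   survival).
#' @param histology "EAC" or "ESCC".
#' @param delta_threshold,fdr DMC thresholds (defaults 0.2, 0.05).
#' @param n_reps,subsample_fraction,n_folds,freq_threshold LASSO-Cox
#'   stability constants (defaults 100, 0.75, 5, 30).
#' @param horizon time-dependent ROC horizon; defaults to the median
#'   observed follow-up.
#' @param seed integer seed.
#' @param out_dir optional artifact directory.
#' @return list of class \code{prog_report}.
#' @export
run_prognostic_pipeline <- function(betas, samples, histology,
                                    delta_threshold = 0.2, fdr = 0.05,
                                    n_reps = 100L, subsample_fraction = 0.75,
                                    n_folds = 5L, freq_threshold = 30L,
                                    horizon = NULL, seed = 1L,
                                    out_dir = NULL) {
  if (!histology %in% c("EAC", "ESCC"))
    stopf("histology must be EAC or ESCC")
  cls <- as.character(samples$tissue_class)
  tum <- which(cls == histology)
  nrm <- which(cls == "NSE")
  if (length(tum) < 2 || length(nrm) < 2)
    stopf("need >= 2 %s and >= 2 NSE samples", histology)
  tum_ids <- samples$sample_id[tum]
  times <- samples$os_time[tum]
  events <- samples$os_event[tum]
  if (sum(events, na.rm = TRUE) < 2) stopf("fewer than 2 events")

  fit <- moderated_t(betas, tum_ids, samples$sample_id[nrm])
  dmcs <- select_dmc(fit, delta_threshold, fdr)
  clinical <- samples[tum, c("age", "gender", "bmi", "smoking", "alcohol",
                             "ajcc_stage")]
  candidates <- independent_prognostic_filter(dmcs,
                                              betas[, tum_ids, drop = FALSE],
                                              clinical, times, events)
  if (length(candidates) < 2)
    stopf("fewer than 2 candidate CpGs passed the adjusted-Cox screen")
  stability <- lasso_cox_stability(t(betas[candidates, tum_ids, drop = FALSE]),
                                   times, events, n_reps = n_reps,
                                   subsample_fraction = subsample_fraction,
                                   n_folds = n_folds,
                                   freq_threshold = freq_threshold,
                                   seed = seed)
  if (!length(stability$selected))
    stopf("no CpG exceeded the stability frequency threshold")
  model <- build_risk_score(stability$selected,
                            betas[, tum_ids, drop = FALSE], times, events)
  horizon <- horizon %||% stats::median(times)
  factors <- data.frame(
    age = clinical$age, gender = clinical$gender, bmi = clinical$bmi,
    smoking = clinical$smoking, alcohol = clinical$alcohol,
    stage_advanced = as.integer(clinical$ajcc_stage %in% c("III", "IV")),
    classifier_high = as.integer(model$group == "high"))
  evaluation <- list(
    km = km_logrank(times, events, model$group),
    cox = cox_table(factors, times, events),
    td_auc = time_dependent_auc(model$risk_score, times, events, horizon),
    stratification = risk_stratify(model$group, clinical$ajcc_stage,
                                   times, events, clinical))
  report <- list(histology = histology, n_dmc = length(dmcs),
                 candidates = candidates, stability = stability,
                 model = model, evaluation = evaluation,
                 horizon = horizon, seed = seed)
  class(report) <- "prog_report"
  if (!is.null(out_dir)) write_prog_report(report, out_dir)
  report
}

write_prog_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(
    data.frame(cpg = names(report$stability$frequency),
               frequency = as.integer(report$stability$frequency)),
    file.path(out_dir, paste0("prognostic_frequency_", report$histology,
                              ".tsv")), sep = "\t")
  data.table::fwrite(
    data.frame(sample_id = names(report$model$risk_score),
               score = report$model$risk_score,
               group = as.character(report$model$group)),
    file.path(out_dir, paste0("risk_table_", report$histology, ".tsv")),
    sep = "\t")
  jsonlite::write_json(
    list(histology = report$histology,
         cpgs = report$model$cpgs,
         coefficients = as.list(report$model$coefficients),
         cutoff = report$model$cutoff,
         logrank_p = report$evaluation$km$p,
         td_auc = report$evaluation$td_auc$auc,
         trend_p = report$evaluation$stratification$trend_p),
    file.path(out_dir, paste0("prognostic_model_", report$histology,
                              ".json")),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Overlap between two prognostic marker panels
#'
#' The EAC and ESCC prognostic arms share no state; this reports the
#' intersection of their selected CpG sets.
#'
#' @param report_a,report_b \code{prog_report} objects (or stability
#'   selections).
#' @return list with the two panels and their intersection.
#' @export
prognostic_overlap <- function(report_a, report_b) {
  sel <- function(x) if (inherits(x, "prog_report")) x$model$cpgs
                     else x$selected
  a <- sel(report_a); b <- sel(report_b)
  list(panel_a = a, panel_b = b, overlap = intersect(a, b))
}
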