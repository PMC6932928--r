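#' Confusion matrix with per-class and overall accuracy
#'
#' Builds the K-by-K count matrix (rows = hypothesized class, columns =
#' true class), per-class accuracy (diagonal over the column total, as a
#' percentage), overall accuracy (trace over total), and a Clopper-Pearson
#' exact 95% binomial interval for the overall accuracy. Percentages are
#' reported raw; \code{round_half_up(x, 2)} matches printed tables.
#'
#' @param truth,predicted equal-length label vectors over the same class
#'   set.
#' @param classes optional class order; defaults to the union of levels.
#' @return object of class \code{confusion_summary}.
#' @export
confusion_summary <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stopf("label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  bad <- setdiff(c(truth, predicted), classes)
  if (length(bad))
    stopf("label(s) outside the class set: %s", paste(bad, collapse = ", "))
  counts <- table(factor(predicted, classes), factor(truth, classes))
  confusion_from_counts(unclass(counts))
}

#' @rdname confusion_summary
#' @param counts K-by-K count matrix, rows = hypothesized class, columns
#'   = true class (e.g. a published confusion table).
#' @export
confusion_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stopf("count matrix must be square")
  total <- sum(counts)
  correct <- sum(diag(counts))
  col_tot <- colSums(counts)
  per_class <- 100 * diag(counts) / col_tot
  overall <- 100 * correct / total
  ci <- as.numeric(stats::binom.test(correct, total)$conf.int)
  structure(list(counts = counts,
                 per_class_accuracy = per_class,
                 overall_accuracy = overall,
                 overall_ci = 100 * ci,
                 n = total, n_correct = correct),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Confusion matrix (rows = hypothesized, cols = true):\n")
  print(x$counts)
  cat("\nAccuracy rate (%):\n")
  print(round_half_up(c(x$per_class_accuracy, overall = x$overall_accuracy)))
  cat(sprintf("\nOverall: %.2f%% (95%% CI %.1f%%-%.1f%%), %d/%d correct\n",
              round_half_up(x$overall_accuracy), x$overall_ci[1],
              x$overall_ci[2], x$n_correct, x$n))
  invisible(x)
}

#' Micro-average one-vs-all ROC and AUC
#'
#' Pools every (sample, class) pair as a binary instance: the indicator
#' of the true class against the predicted probability for that class.
#' The AUC is the Mann-Whitney rank statistic with mid-rank tie
#' correction; ROC points come from a threshold sweep over the pooled
#' scores.
#'
#' @param truth class labels.
#' @param prob sample-by-class probability matrix (rows sum to 1, column
#'   names = classes).
#' @param check_rows verify that rows sum to 1 (disable when scoring
#'   monotone transforms of probabilities; the AUC depends only on the
#'   pooled ranking).
#' @return list with \code{auc} and a \code{roc} data.frame (threshold,
#'   fpr, tpr).
#' @export
micro_average_auc <- function(truth, prob, check_rows = TRUE) {
  truth <- as.character(truth)
  if (is.null(colnames(prob))) stopf("prob needs class column names")
  if (length(unique(truth)) < 2)
    stopf("degenerate single-class truth")
  if (length(setdiff(truth, colnames(prob))))
    stopf("truth label(s) missing from prob columns")
  if (check_rows && any(abs(rowSums(prob) - 1) > 1e-6))
    stopf("probability rows must sum to 1")
  lab <- as.vector(vapply(colnames(prob), function(cl) truth == cl,
                          logical(length(truth))))
  score <- as.vector(prob)
  n_pos <- sum(lab); n_neg <- sum(!lab)
  r <- rank(score)
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- sort(unique(score), decreasing = TRUE)
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(lab[ord]); fp <- cumsum(!lab[ord])
  last <- !duplicated(score[ord], fromLast = TRUE)  # one point per threshold
  roc <- data.frame(threshold = score[ord][last],
                    fpr = fp[last] / n_neg, tpr = tp[last] / n_pos)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  list(auc = auc, roc = roc)
}

#' Kaplan-Meier curves and the k-group log-rank test
#'
#' Product-limit estimates per group (via \code{survival::survfit}) and
#' the log-rank statistic with hypergeometric variance (via
#' \code{survival::survdiff}), with a chi-square p-value on k-1 degrees
#' of freedom.
#'
#' @param times,events survival outcome.
#' @param groups group labels (>= 2 non-empty groups).
#' @return object of class \code{km_logrank}: \code{curves} data.frame
#'   (group, time, n_risk, n_event, surv), \code{observed},
#'   \code{expected}, \code{var} (variance matrix), \code{chisq},
#'   \code{df}, \code{p}.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stopf("need at least two non-empty groups")
  sf <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata_name <- rep(sub("^groups=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = strata_name, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- stats::pchisq(sd_$chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  structure(list(curves = curves, observed = sd_$obs, expected = sd_$exp,
                 var = sd_$var, chisq = sd_$chisq,
                 df = nlevels(groups) - 1, p = p),
            class = "km_logrank")
}

#' Time-dependent (cumulative/dynamic) AUC for a survival risk score
#'
#' At horizon t, cases are patients with an event by t and controls are
#' patients event-free at t. Sensitivity and specificity at a score
#' cutoff c are estimated from Kaplan-Meier survival within the score
#' strata:
#' \deqn{se(c,t) = (1 - S(t | X > c)) P(X > c) / (1 - S(t)),}
#' \deqn{sp(c,t) = S(t | X \le c) P(X \le c) / S(t),}
#' swept over all observed cutoffs; the AUC is the trapezoidal area. With
#' no censoring this reduces to the ordinary Mann-Whitney AUC of scores
#' for events-by-t versus events-after-t. If the overall S(t) is exactly
#' 0 or 1 the quantity is undefined and \code{NA} is returned.
#'
#' @param scores risk scores (higher = higher risk).
#' @param times,events survival outcome.
#' @param horizon evaluation time within the observed follow-up.
#' @return list with \code{auc}, \code{horizon}, and \code{roc} points.
#' @export
time_dependent_auc <- function(scores, times, events, horizon) {
  if (horizon <= 0 || horizon > max(times))
    stopf("horizon must be positive and within observed follow-up")
  km_at <- function(tt, ee, t0) {
    if (!length(tt)) return(NA_real_)
    sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
    s <- c(1, sf$surv)[findInterval(t0, c(0, sf$time))]
    s
  }
  s_all <- km_at(times, events, horizon)
  if (is.na(s_all) || s_all <= 0 || s_all >= 1) {
    return(list(auc = NA_real_, horizon = horizon, roc = NULL))
  }
  cuts <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(cuts, function(cc) {
    hi <- scores > cc
    p_hi <- mean(hi)
    s_hi <- km_at(times[hi], events[hi], horizon)
    s_lo <- km_at(times[!hi], events[!hi], horizon)
    sens <- if (p_hi == 0) 0 else (1 - s_hi) * p_hi / (1 - s_all)
    spec <- if (p_hi == 1) 0 else s_lo * (1 - p_hi) / s_all
    c(fpr = 1 - min(max(spec, 0), 1), tpr = min(max(sens, 0), 1))
  }, c(fpr = 0, tpr = 0)))
  pts <- round(pts, 10)   # snap numerical noise so the path sorts cleanly
  roc <- rbind(c(0, 0), pts, c(1, 1))
  roc <- roc[order(roc[, 1], roc[, 2]), , drop = FALSE]
  auc <- sum(diff(roc[, 1]) * (utils::head(roc[, 2], -1) +
                                 utils::tail(roc[, 2], -1)) / 2)
  list(auc = auc, horizon = horizon,
       roc = data.frame(cutoff = c(Inf, cuts, -Inf), fpr = roc[, 1],
                        tpr = roc[, 2]))
}

#' Univariate and multivariate Cox regression tables
#'
#' One univariate Cox fit per risk factor plus one joint multivariate
#' fit, each reported as HR (95% CI) and Wald p, mirroring published
#' risk-factor tables. Duplicated (aliased) factors are flagged.
#'
#' @param factors data.frame of risk factors (binary factors coded as in
#'   the tables, e.g. classifier group high vs low, stage III/IV vs
#'   I/II).
#' @param times,events survival outcome.
#' @return object of class \code{cox_table}: data.frame with univariate
#'   and multivariate HR, CI and p per term; \code{rank_deficient} flag.
#' @export
cox_table <- function(factors, times, events) {
  factors <- as.data.frame(factors)
  uni <- lapply(names(factors), function(nm) {
    fit <- fit_cox(factors[, nm, drop = FALSE], times, events)
    fit$table
  })
  uni <- do.call(rbind, uni)
  multi_fit <- survival::coxph(
    survival::Surv(times, events) ~ ., data = factors, ties = "efron")
  aliased <- any(is.na(stats::coef(multi_fit)))
  if (aliased)
    warning("rank-deficient multivariate model: aliased term(s) ",
            paste(names(stats::coef(multi_fit))[is.na(stats::coef(multi_fit))],
                  collapse = ", "), call. = FALSE)
  co <- summary(multi_fit)$coefficients
  multi <- data.frame(term = rownames(co), coef_multi = co[, "coef"],
                      hr_multi = exp(co[, "coef"]),
                      ci_lower_multi = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                      ci_upper_multi = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                      p_multi = co[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE, row.names = NULL)
  tab <- merge(stats::setNames(uni, c("term", "coef_uni", "hr_uni",
                                      "ci_lower_uni", "ci_upper_uni",
                                      "se_uni", "p_uni")),
               multi, by = "term", all = TRUE, sort = FALSE)
  structure(list(table = tab, rank_deficient = aliased,
                 multivariate_fit = multi_fit),
            class = "cox_table")
}

#' Four-level risk stratification (classifier group x tumor stage)
#'
#' Assigns G1 = low risk & early stage (I/II), G2 = low risk & advanced
#' stage (III/IV), G3 = high risk & early stage, G4 = high risk &
#' advanced stage. Reports a Kaplan-Meier log-rank across levels, a
#' multivariable Cox model (adjusting for age, gender, BMI, smoking and
#' alcohol use) with G1 as reference, and a trend test (Wald test of the
#' ordinal 0-3 level coding in the adjusted model). Stage itself is not
#' in the adjustment set (it is part of the level coding). Empty levels
#' yield missing contrasts, not an error.
#'
#' @param risk_groups factor low/high from the prognostic classifier.
#' @param stages AJCC stage labels I-IV (or "early"/"advanced").
#' @param times,events survival outcome.
#' @param clinical data.frame with age, gender, bmi, smoking, alcohol.
#' @return object of class \code{risk_stratification}: per-patient
#'   \code{level}, \code{hr_table} (HR vs G1 per level), \code{trend_p},
#'   \code{logrank}.
#' @export
risk_stratify <- function(risk_groups, stages, times, events, clinical) {
  if (anyNA(risk_groups) || anyNA(stages))
    stopf("risk group and stage must be known for all patients")
  advanced <- as.character(stages) %in% c("III", "IV", "advanced")
  high <- as.character(risk_groups) == "high"
  level <- factor(ifelse(!high & !advanced, "G1",
                         ifelse(!high & advanced, "G2",
                                ifelse(high & !advanced, "G3", "G4"))),
                  levels = c("G1", "G2", "G3", "G4"))
  present <- levels(droplevels(level))
  lr <- if (length(present) >= 2)
    km_logrank(times, events, droplevels(level)) else NULL
  adj <- clinical[, c("age", "gender", "bmi", "smoking", "alcohol")]
  df <- cbind(level = droplevels(level), adj)
  fit <- survival::coxph(survival::Surv(times, events) ~ ., data = df,
                         ties = "efron")
  co <- summary(fit)$coefficients
  hr_table <- data.frame(level = c("G2", "G3", "G4"), hr = NA_real_,
                         ci_lower = NA_real_, ci_upper = NA_real_,
                         p = NA_real_, stringsAsFactors = FALSE)
  for (g in c("G2", "G3", "G4")) {
    rn <- paste0("level", g)
    if (rn %in% rownames(co)) {
      i <- which(hr_table$level == g)
      hr_table$hr[i] <- exp(co[rn, "coef"])
      hr_table$ci_lower[i] <- exp(co[rn, "coef"] - 1.96 * co[rn, "se(coef)"])
      hr_table$ci_upper[i] <- exp(co[rn, "coef"] + 1.96 * co[rn, "se(coef)"])
      hr_table$p[i] <- co[rn, "Pr(>|z|)"]
    }
  }
  df_tr <- cbind(level_ord = as.integer(level) - 1L, adj)
  fit_tr <- survival::coxph(survival::Surv(times, events) ~ .,
                            data = df_tr, ties = "efron")
  trend_p <- summary(fit_tr)$coefficients["level_ord", "Pr(>|z|)"]
  structure(list(level = level, hr_table = hr_table, trend_p = trend_p,
                 logrank = lr, adjusted_fit = fit),
            class = "risk_stratification")
}
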