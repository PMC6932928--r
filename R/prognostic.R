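#' Cox proportional-hazards fit with a tidy coefficient table
#'
#' Thin wrapper around \code{survival::coxph} (Efron tie handling)
#' returning per-covariate log hazard ratios, hazard ratios with 95%
#' Wald intervals, and Wald p-values. Monotone-likelihood covariates
#' (no finite MLE, diverging coefficient) are flagged.
#'
#' @param covariates sample-by-covariate data.frame or matrix.
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (>= 1 event required).
#' @return object of class \code{cox_result}: \code{table} (term, coef,
#'   hr, ci_lower, ci_upper, se, p, monotone flag), \code{loglik},
#'   \code{n}, \code{n_events}, and the underlying \code{coxph} fit.
#' @export
fit_cox <- function(covariates, times, events) {
  if (sum(events) < 1) stopf("need at least one event")
  if (any(times <= 0)) stopf("times must be strictly positive")
  df <- as.data.frame(covariates)
  constant <- vapply(df, function(x) length(unique(x)) < 2L, logical(1))
  if (any(constant))
    stopf("constant covariate(s): %s",
          paste(names(df)[constant], collapse = ", "))
  df$.time <- times
  df$.event <- events
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ .,
                    data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  tab <- data.frame(term = rownames(co),
                    coef = co[, "coef"],
                    hr = exp(co[, "coef"]),
                    ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    se = co[, "se(coef)"],
                    p = co[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (monotone) {
    big <- abs(tab$coef) > 15 | tab$se > 100
    tab$coef[big] <- sign(tab$coef[big]) * 15
    tab$hr[big] <- exp(tab$coef[big])
    warning("monotone partial likelihood: coefficient(s) capped at |15|: ",
            paste(tab$term[big], collapse = ", "), call. = FALSE)
  }
  structure(list(table = tab, loglik = fit$loglik[2L], n = s$n,
                 n_events = s$nevent, monotone = monotone, fit = fit),
            class = "cox_result")
}

#' Covariate-adjusted prognostic screen of DMCs
#'
#' For each candidate CpG, fits a Cox model with the CpG beta plus the
#' clinical covariates age, gender, BMI, smoking, alcohol use and AJCC
#' tumor stage (advanced III/IV vs early I/II), and keeps CpGs whose
#' CpG-term Wald p-value is below \code{p_threshold}. The p-value is the
#' covariate-adjusted Wald p of the CpG term, not a multiplicity-adjusted
#' one. Samples with missing clinical fields are excluded (a count is
#' attached as an attribute).
#'
#' @param dmcs candidate CpG ids (e.g. from \code{\link{select_dmc}}).
#' @param betas CpG-by-sample matrix.
#' @param clinical data.frame with columns age, gender, bmi, smoking,
#'   alcohol, ajcc_stage, one row per column of \code{betas} (same
#'   order).
#' @param times,events survival outcome, aligned with \code{clinical}.
#' @param p_threshold Wald cutoff (default 0.05).
#' @return character vector of retained CpG ids, with attributes
#'   \code{p_values} (named) and \code{n_excluded}.
#' @export
independent_prognostic_filter <- function(dmcs, betas, clinical, times,
                                          events, p_threshold = 0.05) {
  if (!length(dmcs)) {
    out <- character(0)
    attr(out, "p_values") <- stats::setNames(numeric(0), character(0))
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  need <- c("age", "gender", "bmi", "smoking", "alcohol", "ajcc_stage")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols))
    stopf("missing clinical field(s): %s",
          paste(missing_cols, collapse = ", "))
  covs <- data.frame(age = clinical$age, gender = clinical$gender,
                     bmi = clinical$bmi, smoking = clinical$smoking,
                     alcohol = clinical$alcohol,
                     stage_advanced = as.integer(clinical$ajcc_stage %in%
                                                   c("III", "IV")))
  keep <- stats::complete.cases(covs) & !is.na(times) & !is.na(events)
  n_excluded <- sum(!keep)
  covs <- covs[keep, , drop = FALSE]
  tt <- times[keep]; ee <- events[keep]
  pvals <- vapply(dmcs, function(cg) {
    d <- cbind(cpg = betas[cg, keep], covs)
    fit <- suppressWarnings(fit_cox(d, tt, ee))
    fit$table$p[fit$table$term == "cpg"]
  }, numeric(1))
  out <- dmcs[pvals < p_threshold]
  attr(out, "p_values") <- pvals
  attr(out, "n_excluded") <- n_excluded
  out
}

#' LASSO-Cox stability selection by repeated subsampling
#'
#' Repeats \code{n_reps} times: subsample \code{subsample_fraction} of the
#' patients without replacement, choose the penalty by
#' \code{n_folds}-fold cross-validation on the partial-likelihood
#' deviance with the 1-SE rule (\code{glmnet::cv.glmnet},
#' \code{lambda.1se}), fit the L1-penalized Cox model, and record the
#' CpGs with nonzero coefficients. CpGs selected in strictly more than
#' \code{freq_threshold} replicates form the stable set. Replicates whose
#' subsample has no events (or on which the penalized fit fails) are
#' redrawn and counted.
#'
#' @param X sample-by-CpG beta matrix of candidates (>= 2 columns).
#' @param times,events survival outcome.
#' @param n_reps,subsample_fraction,n_folds,freq_threshold procedure
#'   constants (defaults 100, 0.75, 5, 30).
#' @param seed integer seed.
#' @return a \code{stability_selection} object (frequency, selected set,
#'   number of redrawn replicates).
#' @export
lasso_cox_stability <- function(X, times, events, n_reps = 100L,
                                subsample_fraction = 0.75, n_folds = 5L,
                                freq_threshold = 30L, seed = 1L) {
  if (ncol(X) < 2) stopf("need >= 2 candidate CpGs for a penalized fit")
  n <- nrow(X)
  freq <- stats::setNames(integer(ncol(X)), colnames(X))
  n_redrawn <- 0L
  r <- 0L; attempt <- 0L
  while (r < n_reps) {
    attempt <- attempt + 1L
    if (attempt > 20L * n_reps)
      stopf("too many failed subsampling replicates; check event counts")
    set.seed(child_seed(seed, attempt))
    idx <- sample(n, round(subsample_fraction * n))
    if (sum(events[idx]) < n_folds) { n_redrawn <- n_redrawn + 1L; next }
    foldid <- stratified_folds(factor(events[idx]), n_folds)
    sel <- tryCatch({
      # glmnet may truncate the path near saturation ("Numerical error
      # at kth lambda"); the returned partial path is still usable
      cv <- withCallingHandlers(
        glmnet::cv.glmnet(X[idx, , drop = FALSE],
                          survival::Surv(times[idx], events[idx]),
                          family = "cox", nfolds = n_folds,
                          foldid = foldid, type.measure = "deviance"),
        warning = function(w) {
          if (grepl("lambda value|solutions for larger", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))
      rownames(cf)[cf[, 1L] != 0]
    }, error = function(e) NULL)
    if (is.null(sel)) { n_redrawn <- n_redrawn + 1L; next }
    freq[sel] <- freq[sel] + 1L
    r <- r + 1L
  }
  structure(list(frequency = freq,
                 selected = names(freq)[freq > freq_threshold],
                 n_reps = n_reps, threshold = freq_threshold,
                 n_redrawn = n_redrawn),
            class = "stability_selection")
}

#' Build the prognostic risk score and median split
#'
#' Fits an unpenalized multivariable Cox model on the selected CpGs; the
#' risk score of a patient is \eqn{\sum_k \hat\beta_k \beta_{k}(patient)}
#' (the uncentered linear predictor). Patients are split at the median
#' score of the fitting cohort; scores equal to the median go to the
#' low-risk group. The cutoff is stored so the score can be applied
#' externally.
#'
#' @param selected nonempty CpG id vector.
#' @param betas CpG-by-sample matrix.
#' @param times,events survival outcome aligned with \code{colnames(betas)}.
#' @return object of class \code{prognostic_model}: CpGs, coefficients,
#'   per-sample \code{risk_score}, \code{cutoff} (median), \code{group}
#'   (factor low/high), and the Cox fit.
#' @export
build_risk_score <- function(selected, betas, times, events) {
  if (!length(selected)) stopf("empty CpG selection")
  Xc <- t(betas[selected, , drop = FALSE])
  fit <- fit_cox(as.data.frame(Xc), times, events)
  beta_hat <- stats::setNames(fit$table$coef, fit$table$term)[selected]
  score <- as.numeric(Xc %*% beta_hat)
  names(score) <- colnames(betas)
  cutoff <- stats::median(score)
  group <- factor(ifelse(score > cutoff, "high", "low"),
                  levels = c("low", "high"))
  structure(list(cpgs = selected, coefficients = beta_hat,
                 risk_score = score, cutoff = cutoff, group = group,
                 cox = fit),
            class = "prognostic_model")
}

#' Apply a stored prognostic model to new samples
#'
#' @param model a \code{prognostic_model}.
#' @param betas CpG-by-sample matrix containing the model CpGs.
#' @return data.frame with sample, score, and group (split at the stored
#'   cutoff; scores equal to the cutoff are low risk).
#' @export
apply_risk_score <- function(model, betas) {
  missing_cpg <- setdiff(model$cpgs, rownames(betas))
  if (length(missing_cpg))
    stopf("missing CpG(s): %s", paste(missing_cpg, collapse = ", "))
  score <- as.numeric(crossprod(betas[model$cpgs, , drop = FALSE],
                                model$coefficients))
  data.frame(sample_id = colnames(betas), score = score,
             group = factor(ifelse(score > model$cutoff, "high", "low"),
                            levels = c("low", "high")),
             stringsAsFactors = FALSE)
}
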