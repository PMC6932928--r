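#' Empirical-Bayes moderated two-sample t-statistics
#'
#' Per-CpG two-group comparison on beta-values with variance shrinkage
#' across CpGs. The pooled two-sample variance \eqn{s^2_g} with
#' \eqn{d_g = n_a + n_b - 2} degrees of freedom is shrunk toward a global
#' prior variance \eqn{s_0^2} with prior degrees of freedom \eqn{d_0},
#' both estimated by moment matching on \eqn{\log s^2_g} using
#' digamma/trigamma identities; \eqn{d_0} is obtained by Newton iteration
#' on the trigamma equation. The moderated statistic is
#' \deqn{t_g = \Delta\beta_g / (\tilde s_g \sqrt{1/n_a + 1/n_b}),\quad
#'   \tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g),}
#' referred to a t distribution with \eqn{d_0 + d_g} degrees of freedom.
#'
#' CpGs with zero pooled variance are excluded from hyperparameter
#' estimation (their statistics still use the shrunken variance). If every
#' CpG has zero variance in both groups the hyperparameters cannot be
#' estimated and an error is raised.
#'
#' @param betas CpG-by-sample matrix.
#' @param group_a,group_b disjoint sample id (or column index) vectors,
#'   each of size >= 2. \code{delta_beta} is mean(a) - mean(b).
#' @param prior_df optional override of the estimated \eqn{d_0}
#'   (\code{0} gives the ordinary pooled-variance t).
#' @return object of class \code{moderated_t_fit}: a list with a per-CpG
#'   data.frame \code{table} (cpg, delta_beta, s2, df, s2_post, t, p_raw,
#'   p_bh) and hyperparameters \code{d0}, \code{s0_2}.
#' @export
moderated_t <- function(betas, group_a, group_b, prior_df = NULL) {
  a <- betas[, group_a, drop = FALSE]
  b <- betas[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stopf("each group needs >= 2 samples")
  if (length(intersect(colnames(a), colnames(b))))
    stopf("groups must be disjoint")
  ma <- rowMeans(a); mb <- rowMeans(b)
  dg <- na + nb - 2L
  ss <- rowSums((a - ma)^2) + rowSums((b - mb)^2)
  s2 <- ss / dg
  if (is.null(prior_df)) {
    hp <- fit_variance_prior(s2, dg)
  } else {
    if (prior_df < 0) stopf("prior_df must be non-negative")
    hp <- list(d0 = prior_df,
               s0_2 = if (prior_df > 0) fit_variance_prior(s2, dg)$s0_2 else NA_real_)
  }
  d0 <- hp$d0
  s2_post <- if (is.infinite(d0)) rep(hp$s0_2, length(s2))
             else if (d0 == 0) s2
             else (d0 * hp$s0_2 + dg * s2) / (d0 + dg)
  delta <- ma - mb
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- ifelse(se == 0, ifelse(delta == 0, 0, sign(delta) * Inf),
                  delta / se)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- list(table = data.frame(cpg = rownames(betas),
                                 delta_beta = delta, s2 = s2,
                                 df = rep(dg, length(s2)),
                                 s2_post = s2_post, t = tstat,
                                 p_raw = p, p_bh = bh_adjust(p),
                                 stringsAsFactors = FALSE,
                                 row.names = NULL),
              d0 = d0, s0_2 = hp$s0_2,
              n_a = na, n_b = nb)
  class(out) <- "moderated_t_fit"
  out
}

# Moment-matching estimate of (d0, s0^2) from sample variances s2 with
# df residual degrees of freedom each. Works on z = log(s2):
#   E[z] = log(s0^2) + psi(d0/2) - log(d0/2) + psi(df/2)... (rearranged via
#   e = z - psi(df/2) + log(df/2)), Var[e] = psi'(d0/2) + psi'(df/2).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok))
    stopf(paste("cannot estimate the variance prior: every CpG has zero",
                "pooled variance; check that the groups contain distinct",
                "beta values"))
  z <- log(s2[ok])
  df <- rep_len(df, length(s2))[ok]
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  G <- length(e)
  if (G < 2) {
    return(list(d0 = Inf, s0_2 = exp(emean)))
  }
  evar <- sum((e - emean)^2) / (G - 1L)
  rhs <- evar - mean(trigamma(df / 2))
  if (rhs <= 0) {
    # observed spread no larger than sampling noise: infinitely strong prior
    return(list(d0 = Inf, s0_2 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(rhs)
  s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# Newton solve of trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: sorted \eqn{p_{(i)} m / i} with a cumulative
#' minimum from the largest rank, capped at 1, returned in input order.
#'
#' @param p vector of p-values in \eqn{[0,1]}.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Tissue-specific marker discovery by all-pairs intersection
#'
#' For each esophageal target class (NSE, BE, EAC, ESCC), a CpG is a
#' tissue-specific marker if it is significantly differentially
#' methylated (BH-adjusted p below \code{fdr}) in \emph{every} pairwise
#' moderated-t comparison of the target class against each of the other
#' seven tissue classes. BH is applied within each pairwise comparison,
#' across CpGs. A CpG whose methylation pattern is shared with an
#' adjacent-organ tissue (e.g. shifted identically in EAC and STAD) fails
#' that pairwise comparison and is excluded.
#'
#' @param betas CpG-by-sample matrix.
#' @param classes factor of tissue classes per sample (all eight classes
#'   present, >= 2 samples each).
#' @param fdr FDR threshold (default 0.05).
#' @return object of class \code{tissue_markers}: list with
#'   \code{per_class} (named list of CpG id sets), \code{union}, and
#'   \code{fdr}.
#' @export
tissue_specific_markers <- function(betas, classes, fdr = 0.05) {
  classes <- factor(as.character(classes), levels = tissue_classes())
  tab <- table(classes)
  missing_cl <- names(tab)[tab < 2]
  if (length(missing_cl))
    stopf("class(es) absent or with < 2 samples: %s",
          paste(missing_cl, collapse = ", "))
  cols <- split(colnames(betas) %||% seq_len(ncol(betas)), classes)
  cache <- new.env(parent = emptyenv())
  pair_sig <- function(c1, c2) {
    key <- paste(sort(c(c1, c2)), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- moderated_t(betas, cols[[c1]], cols[[c2]])
    sig <- fit$table$p_bh < fdr
    cache[[key]] <- sig
    sig
  }
  per_class <- lapply(esophageal_classes(), function(target) {
    sig_all <- rep(TRUE, nrow(betas))
    for (other in setdiff(tissue_classes(), target))
      sig_all <- sig_all & pair_sig(target, other)
    rownames(betas)[sig_all]
  })
  names(per_class) <- esophageal_classes()
  out <- list(per_class = per_class,
              union = sort(unique(unlist(per_class, use.names = FALSE))),
              fdr = fdr)
  class(out) <- "tissue_markers"
  out
}

#' Differentially methylated CpGs by effect size and FDR
#'
#' Returns CpGs with \eqn{|\Delta\beta| >} \code{delta_threshold}
#' (strict) and BH-adjusted p \eqn{<} \code{fdr_threshold} (strict).
#'
#' @param fit a \code{\link{moderated_t}} result.
#' @param delta_threshold minimum absolute mean beta difference
#'   (default 0.2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return character vector of CpG ids.
#' @export
select_dmc <- function(fit, delta_threshold = 0.2, fdr_threshold = 0.05) {
  stopifnot(inherits(fit, "moderated_t_fit"))
  tb <- fit$table
  tb$cpg[abs(tb$delta_beta) > delta_threshold & tb$p_bh < fdr_threshold]
}
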