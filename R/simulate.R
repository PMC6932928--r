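#' Simulation configuration for a 450K-like methylation study
#'
#' Describes a synthetic eight-tissue methylation dataset with planted
#' diagnostic and prognostic signal. The eight tissue classes are the four
#' esophageal types (NSE, BE, EAC, ESCC) plus the adjacent-organ tissues
#' (HNSC, HNSC-normal, STAD, STAD-normal) used to enforce marker
#' specificity.
#'
#' Beta-values are generated on the logit scale: each CpG has a class-wise
#' mean beta, Gaussian noise with standard deviation \code{noise_sd} is
#' added to the logit of that mean, and the inverse logit maps back to
#' \eqn{[0,1]}. Background CpGs draw their baseline mean from a
#' two-component mixture concentrated near 0.1 and 0.9, mimicking the
#' bimodal 450K beta distribution. Planted tissue-specific CpGs shift the
#' mean of exactly one class by \code{delta} (in beta units); planted
#' decoys shift an esophageal class and its paired adjacent-organ class
#' identically, so a correct specificity rule must reject them.
#' Planted prognostic CpGs are hypermethylated in EAC/ESCC relative to all
#' normal tissues (shift \code{max(delta, 0.3)}) and have a wide
#' between-patient dispersion (logit-scale sd \code{prognostic_sd}) so that
#' a per-beta-unit log hazard ratio is estimable.
#'
#' @param n_cpgs total number of CpG probes.
#' @param n_per_class named vector of sample counts; names must be exactly
#'   the eight class labels.
#' @param n_specific_per_class planted tissue-specific CpGs per esophageal
#'   class.
#' @param n_decoys_per_class planted contaminant-mimicking CpGs per
#'   esophageal class (shifted identically in the paired adjacent tissue:
#'   EAC with STAD, ESCC with HNSC, NSE with HNSC-normal, BE with
#'   STAD-normal).
#' @param delta planted mean beta shift, in (0, 1).
#' @param noise_sd within-class dispersion on the logit scale.
#' @param n_prognostic planted survival-associated CpGs.
#' @param cox_betas log hazard ratio per beta unit for each prognostic CpG
#'   (recycled to \code{n_prognostic}).
#' @param prognostic_sd logit-scale dispersion of prognostic CpGs in tumor
#'   samples.
#' @param baseline_hazard exponential baseline hazard rate per time unit.
#' @param censor_rate exponential censoring rate (0 = no censoring).
#' @param cohort_fractions named fractions for train/test/validation
#'   assignment (stratified by class).
#' @param seed integer seed; identical configurations give identical data.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_cpgs = 500L,
                       n_per_class = c(NSE = 60L, BE = 60L, EAC = 60L,
                                       ESCC = 60L, HNSC = 60L,
                                       `HNSC-normal` = 60L, STAD = 60L,
                                       `STAD-normal` = 60L),
                       n_specific_per_class = 2L,
                       n_decoys_per_class = 5L,
                       delta = 0.3,
                       noise_sd = 1.0,
                       n_prognostic = 3L,
                       cox_betas = 1.5,
                       prognostic_sd = 2.0,
                       baseline_hazard = 0.1,
                       censor_rate = 0.05,
                       cohort_fractions = c(train = 0.5, test = 0.25,
                                            validation = 0.25),
                       seed = 1L) {
  if (!setequal(names(n_per_class), tissue_classes()))
    stopf("n_per_class must be named with exactly: %s",
          paste(tissue_classes(), collapse = ", "))
  n_per_class <- n_per_class[tissue_classes()]
  if (any(n_per_class <= 0) || n_cpgs <= 0 || n_specific_per_class <= 0 ||
      n_prognostic <= 0 || n_decoys_per_class < 0)
    stopf("all counts must be positive (decoys may be zero)")
  if (!(delta > 0 && delta < 1))
    stopf("delta must lie in (0, 1); got %g", delta)
  if (noise_sd <= 0 || prognostic_sd <= 0)
    stopf("noise_sd and prognostic_sd must be positive")
  if (baseline_hazard <= 0 || censor_rate < 0)
    stopf("baseline_hazard must be positive and censor_rate non-negative")
  needed <- 4L * (n_specific_per_class + n_decoys_per_class) + n_prognostic
  if (n_cpgs < needed + 1L)
    stopf("n_cpgs = %d too small for %d planted CpGs", n_cpgs, needed)
  if (abs(sum(cohort_fractions) - 1) > 1e-8 ||
      !setequal(names(cohort_fractions), c("train", "test", "validation")))
    stopf("cohort_fractions must be named train/test/validation and sum to 1")
  cfg <- list(n_cpgs = as.integer(n_cpgs),
              n_per_class = as.integer(n_per_class),
              n_specific_per_class = as.integer(n_specific_per_class),
              n_decoys_per_class = as.integer(n_decoys_per_class),
              delta = delta, noise_sd = noise_sd,
              n_prognostic = as.integer(n_prognostic),
              cox_betas = rep_len(cox_betas, n_prognostic),
              prognostic_sd = prognostic_sd,
              baseline_hazard = baseline_hazard,
              censor_rate = censor_rate,
              cohort_fractions = cohort_fractions,
              seed = as.integer(seed))
  names(cfg$n_per_class) <- tissue_classes()
  class(cfg) <- "sim_config"
  cfg
}

#' Tissue class vocabulary
#'
#' @return the eight tissue class labels; the first four are the
#'   esophageal classes used by the diagnostic classifier.
#' @export
tissue_classes <- function() {
  c("NSE", "BE", "EAC", "ESCC", "HNSC", "HNSC-normal", "STAD", "STAD-normal")
}

#' @rdname tissue_classes
#' @export
esophageal_classes <- function() tissue_classes()[1:4]

decoy_partner <- c(NSE = "HNSC-normal", BE = "STAD-normal",
                   EAC = "STAD", ESCC = "HNSC")

# The generator parameterizes each (CpG, class) cell by its MEAN beta.
# Values are drawn as inv_logit(mu + sigma * Z); because the inverse
# logit is nonlinear, mu must be chosen so that E[inv_logit(mu + sigma Z)]
# equals the target mean, otherwise planted shifts shrink as sigma grows.
# The inverse of m(mu) = E[inv_logit(mu + sigma Z)] is tabulated on a
# dense grid (the map is strictly increasing) and interpolated.
logit_mean_corrected <- function(target_mean, sigma) {
  grid_mu <- seq(-16, 16, by = 0.01)
  z <- stats::qnorm(seq(0.0005, 0.9995, by = 0.001))  # quadrature on quantiles
  m_of_mu <- rowMeans(inv_logit(outer(grid_mu, sigma * z, `+`)))
  stats::approx(m_of_mu, grid_mu, xout = target_mean, rule = 2)$y
}

#' Simulate a methylation dataset with planted signal
#'
#' Generates a CpG-by-sample beta matrix, a sample sheet with tissue
#' class, cohort, clinical covariates and survival, a probe annotation
#' table, and the planted ground truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{meth_sim} with elements \code{betas}
#'   (matrix, CpGs x samples), \code{samples} (data.frame),
#'   \code{probes} (data.frame), \code{truth} (list with
#'   \code{specific_cpgs}, \code{decoy_cpgs}, \code{prognostic_cpgs}).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cls <- tissue_classes()
  n_samp <- sum(config$n_per_class)
  classes <- factor(rep(cls, config$n_per_class), levels = cls)
  sample_ids <- sprintf("S%04d", seq_len(n_samp))
  cpg_ids <- sprintf("cg%08d", seq_len(config$n_cpgs))

  # carve up the probe index space: specific, decoy, prognostic, background
  eso <- esophageal_classes()
  idx <- 0L
  take <- function(k) {
    out <- cpg_ids[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  specific <- stats::setNames(
    lapply(eso, function(cl) take(config$n_specific_per_class)), eso)
  decoys <- if (config$n_decoys_per_class > 0L)
    stats::setNames(lapply(eso, function(cl) take(config$n_decoys_per_class)),
                    eso)
  else stats::setNames(rep(list(character(0)), 4L), eso)
  prognostic <- take(config$n_prognostic)

  # class-wise mean beta per CpG
  mu <- matrix(NA_real_, config$n_cpgs, length(cls),
               dimnames = list(cpg_ids, cls))
  base_bg <- inv_logit(stats::rnorm(config$n_cpgs,
                                    logit(ifelse(stats::runif(config$n_cpgs) < 0.5,
                                                 0.1, 0.9)), 0.3))
  mu[] <- base_bg  # every class shares the background mean
  shift_up_base <- function(k) stats::runif(k, 0.05, min(0.6, 0.95 - config$delta))
  for (cl in eso) {
    ids <- specific[[cl]]
    b <- shift_up_base(length(ids))
    mu[ids, ] <- b
    mu[ids, cl] <- b + config$delta
    ids <- decoys[[cl]]
    if (length(ids)) {
      b <- shift_up_base(length(ids))
      mu[ids, ] <- b
      mu[ids, c(cl, decoy_partner[[cl]])] <- b + config$delta
    }
  }
  # prognostic CpGs: hypermethylated in esophageal tumors vs everything else
  prog_shift <- max(config$delta, 0.3)
  b <- stats::runif(config$n_prognostic, 0.08, 0.2)
  mu[prognostic, ] <- b
  mu[prognostic, c("EAC", "ESCC")] <- b + prog_shift

  # draw betas on the logit scale, with the logit-location corrected so
  # that the expected beta equals the target class mean
  mu_logit <- matrix(logit_mean_corrected(mu, config$noise_sd),
                     nrow(mu), ncol(mu), dimnames = dimnames(mu))
  prog_rows <- match(prognostic, cpg_ids)
  mu_logit[prog_rows, c("EAC", "ESCC")] <-
    logit_mean_corrected(mu[prog_rows, c("EAC", "ESCC")],
                         config$prognostic_sd)
  sd_mat <- matrix(config$noise_sd, config$n_cpgs, n_samp)
  tumor_eso <- classes %in% c("EAC", "ESCC")
  sd_mat[prog_rows, tumor_eso] <- config$prognostic_sd
  mu_expanded <- mu_logit[, as.character(classes), drop = FALSE]
  betas <- inv_logit(mu_expanded + stats::rnorm(length(mu_expanded)) * sd_mat)
  dimnames(betas) <- list(cpg_ids, sample_ids)

  samples <- data.frame(
    sample_id = sample_ids,
    tissue_class = classes,
    cohort = assign_cohorts(classes, config$cohort_fractions),
    age = sample(40:80, n_samp, replace = TRUE),
    gender = stats::rbinom(n_samp, 1L, 0.5),
    bmi = stats::runif(n_samp, 18, 35),
    smoking = stats::rbinom(n_samp, 1L, 0.5),
    alcohol = stats::rbinom(n_samp, 1L, 0.5),
    ajcc_stage = NA_character_,
    os_time = NA_real_,
    os_event = NA_integer_,
    stringsAsFactors = FALSE
  )
  tumor <- classes %in% c("EAC", "ESCC", "HNSC", "STAD")
  samples$ajcc_stage[tumor] <- sample(c("I", "II", "III", "IV"),
                                      sum(tumor), replace = TRUE)

  probes <- data.frame(
    cpg_id = cpg_ids,
    gene_symbol = NA_character_,
    chromosome = paste0("chr", sample(1:22, config$n_cpgs, replace = TRUE)),
    genomic_coordinate = sample.int(2e8, config$n_cpgs, replace = TRUE),
    relation_to_island = sample(c("Island", "N_Shore", "S_Shore", "N_Shelf",
                                  "S_Shelf", "OpenSea"),
                                config$n_cpgs, replace = TRUE),
    refgene_group = sample(c("Body", "TSS1500", "TSS200", "5'UTR", "3'UTR",
                             NA_character_), config$n_cpgs, replace = TRUE),
    stringsAsFactors = FALSE
  )

  truth <- list(specific_cpgs = specific,
                decoy_cpgs = decoys,
                prognostic_cpgs = stats::setNames(config$cox_betas, prognostic))
  out <- list(betas = betas, samples = samples, probes = probes,
              truth = truth, config = config)
  class(out) <- "meth_sim"
  out$samples <- simulate_survival(config, betas, truth, out$samples)
  out
}

assign_cohorts <- function(classes, fractions) {
  cohort <- character(length(classes))
  for (cl in levels(classes)) {
    idx <- sample(which(classes == cl))
    n <- length(idx)
    n_train <- round(fractions[["train"]] * n)
    n_test <- round(fractions[["test"]] * n)
    lab <- rep("validation", n)
    lab[seq_len(n_train)] <- "train"
    if (n_test > 0) lab[n_train + seq_len(min(n_test, n - n_train))] <- "test"
    cohort[idx] <- lab
  }
  cohort
}

#' Fill survival fields from a proportional-hazards model
#'
#' Event times are exponential with rate
#' \code{baseline_hazard * exp(lp)}, where the linear predictor is the sum
#' of the planted coefficients times the corresponding beta-values.
#' Censoring times are independent exponentials with rate
#' \code{censor_rate}; the observed time is the minimum. Survival is
#' generated for tumor samples (EAC, ESCC, HNSC, STAD) only.
#'
#' @param config a \code{\link{sim_config}}.
#' @param betas beta matrix containing all prognostic CpGs.
#' @param truth truth list with \code{prognostic_cpgs}.
#' @param samples sample annotation to fill.
#' @return \code{samples} with \code{os_time} and \code{os_event} filled.
#' @export
simulate_survival <- function(config, betas, truth, samples) {
  prog <- names(truth$prognostic_cpgs)
  missing_cpg <- setdiff(prog, rownames(betas))
  if (length(missing_cpg))
    stopf("prognostic CpG(s) absent from matrix: %s",
          paste(missing_cpg, collapse = ", "))
  set.seed(child_seed(config$seed, 97L))
  tumor <- samples$tissue_class %in% c("EAC", "ESCC", "HNSC", "STAD")
  ids <- samples$sample_id[tumor]
  lp <- as.numeric(crossprod(betas[prog, ids, drop = FALSE],
                             truth$prognostic_cpgs))
  event_time <- stats::rexp(length(ids), rate = config$baseline_hazard * exp(lp))
  censor_time <- if (config$censor_rate > 0)
    stats::rexp(length(ids), rate = config$censor_rate) else Inf
  samples$os_time[tumor] <- pmin(event_time, censor_time)
  samples$os_event[tumor] <- as.integer(event_time <= censor_time)
  samples
}
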