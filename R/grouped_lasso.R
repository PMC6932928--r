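# Grouped-penalty multinomial lasso, solved by accelerated proximal
# gradient (FISTA) with group soft-thresholding. The objective, on
# internally standardized features, is
#   f(B, b0) = -(1/n) sum_i log p_{i, y_i} + lambda * sum_j ||B_j.||_2
# with per-class intercepts b0 unpenalized. The group rows B_j. tie the
# class coefficients of one CpG together, so a feature enters or leaves
# the model for all classes at once.

#' Configuration for diagnostic stability selection
#'
#' @param n_partitions number of random 2:1 train/test partitions.
#' @param train_fraction fraction of samples in the training part.
#' @param n_folds cross-validation folds inside each training part.
#' @param freq_threshold minimum selection frequency (out of
#'   \code{n_partitions}) for a CpG to enter the final panel; ties at the
#'   threshold are included.
#' @param n_lambda,lambda_min_ratio penalty grid: \code{n_lambda}
#'   log-spaced values from \eqn{\lambda_{max}} down to
#'   \code{lambda_min_ratio} \eqn{\times \lambda_{max}}.
#' @param seed integer seed controlling partitions and folds.
#' @return a \code{grouped_lasso_config} list.
#' @export
grouped_lasso_config <- function(n_partitions = 10L, train_fraction = 2 / 3,
                                 n_folds = 10L, freq_threshold = 9L,
                                 n_lambda = 100L, lambda_min_ratio = 0.001,
                                 seed = 1L) {
  if (freq_threshold > n_partitions + 1L)
    stopf("freq_threshold cannot exceed n_partitions + 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0,1)")
  structure(list(n_partitions = as.integer(n_partitions),
                 train_fraction = train_fraction,
                 n_folds = as.integer(n_folds),
                 freq_threshold = as.integer(freq_threshold),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed)),
            class = "grouped_lasso_config")
}

gl_standardize <- function(X) {
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  list(Xs = Xs, center = center, scale = scale_)
}

gl_objective <- function(Xs, Y, B, b0, lambda) {
  Z <- sweep(Xs %*% B, 2L, b0, "+")
  ll <- sum(Y * (Z - row_log_sum_exp(Z))) / nrow(Xs)
  -ll + lambda * sum(sqrt(rowSums(B^2)))
}

gl_gradient <- function(Xs, Y, B, b0) {
  n <- nrow(Xs)
  P <- softmax(sweep(Xs %*% B, 2L, b0, "+"))
  R <- (P - Y) / n
  list(B = crossprod(Xs, R), b0 = colSums(R))
}

# KKT residual of the group-lasso stationarity conditions; the solution
# certificate used by the solver's stopping rule and by tests.
gl_kkt_residual <- function(Xs, Y, B, b0, lambda) {
  g <- gl_gradient(Xs, Y, B, b0)
  norms <- sqrt(rowSums(B^2))
  res <- numeric(nrow(B))
  zero <- norms == 0
  if (any(zero))
    res[zero] <- pmax(0, sqrt(rowSums(g$B[zero, , drop = FALSE]^2)) - lambda)
  if (any(!zero)) {
    dir <- B[!zero, , drop = FALSE] / norms[!zero]
    res[!zero] <- sqrt(rowSums((g$B[!zero, , drop = FALSE] + lambda * dir)^2))
  }
  max(res, max(abs(g$b0)))
}

# Smallest penalty at which every feature group is zero: the group-norm
# of the null-model gradient, maximized over features.
gl_lambda_max <- function(Xs, Y) {
  n <- nrow(Xs)
  pbar <- colMeans(Y)
  P0 <- matrix(pbar, n, ncol(Y), byrow = TRUE)
  G <- crossprod(Xs, (P0 - Y) / n)
  max(sqrt(rowSums(G^2)))
}

# FISTA with gradient-mapping adaptive restart for one lambda;
# warm-started. One gradient evaluation per iteration; the KKT
# certificate is checked periodically.
gl_fista <- function(Xs, Y, lambda, B, b0, L, maxit = 2000L, kkt_tol = 1e-6,
                     check_every = 20L) {
  step <- 1 / L
  Bm <- B; b0m <- b0
  th <- 1
  for (it in seq_len(maxit)) {
    g <- gl_gradient(Xs, Y, Bm, b0m)
    Bn <- Bm - step * g$B
    norms <- sqrt(rowSums(Bn^2))
    shrink <- pmax(0, 1 - (step * lambda) / pmax(norms, .Machine$double.eps))
    Bn <- Bn * shrink
    b0n <- b0m - step * g$b0
    restart <- sum((Bm - Bn) * (Bn - B)) + sum((b0m - b0n) * (b0n - b0)) > 0
    th_new <- if (restart) 1 else (1 + sqrt(1 + 4 * th^2)) / 2
    mom <- if (restart) 0 else (th - 1) / th_new
    Bm <- Bn + mom * (Bn - B)
    b0m <- b0n + mom * (b0n - b0)
    B <- Bn; b0 <- b0n; th <- th_new
    if (it %% check_every == 0L || it == maxit) {
      if (gl_kkt_residual(Xs, Y, B, b0, lambda) <= kkt_tol) break
    }
  }
  list(B = B, b0 = b0, objective = gl_objective(Xs, Y, B, b0, lambda),
       iterations = it)
}

# Fit a decreasing lambda path with warm starts (standardized scale).
gl_path <- function(Xs, Y, lambdas, maxit = 2000L, kkt_tol = 1e-6) {
  n <- nrow(Xs); K <- ncol(Y); p <- ncol(Xs)
  L <- (norm(cbind(1, Xs), "2")^2) / (2 * n)
  pbar <- colMeans(Y)
  b0 <- log(pbar) - mean(log(pbar))
  B <- matrix(0, p, K)
  fits <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    f <- gl_fista(Xs, Y, lambdas[i], B, b0, L, maxit = maxit,
                  kkt_tol = kkt_tol)
    B <- f$B; b0 <- f$b0
    fits[[i]] <- f
  }
  fits
}

#' Fit a grouped-penalty multinomial lasso at one penalty value
#'
#' Minimises the negative mean multinomial log-likelihood plus
#' \eqn{\lambda \sum_j \|\beta_{j\cdot}\|_2}, where \eqn{\beta_{j\cdot}}
#' collects the class coefficients of feature j. Features are
#' standardized internally (training mean/sd); intercepts are
#' unpenalized; coefficients are returned on the original feature scale.
#' Solved by accelerated proximal gradient with group soft-thresholding
#' to a KKT tolerance of \code{kkt_tol}.
#'
#' @param X sample-by-feature matrix (column names = CpG ids).
#' @param y class labels (factor or character).
#' @param lambda non-negative penalty weight (on the standardized scale).
#' @param maxit,kkt_tol solver controls.
#' @return object of class \code{grouped_lasso_fit}: coefficients
#'   (feature x class, original scale), intercepts, the standardized-scale
#'   solution, scaler, objective value and KKT residual.
#' @export
fit_grouped_multinomial_lasso <- function(X, y, lambda, maxit = 5000L,
                                          kkt_tol = 1e-6) {
  if (lambda < 0) stopf("lambda must be non-negative")
  if (any(!is.finite(X))) stopf("X contains non-finite values")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stopf("need at least two classes")
  Y <- class_indicator(y)
  sc <- gl_standardize(X)
  fit <- gl_path(sc$Xs, Y, lambda, maxit = maxit, kkt_tol = kkt_tol)[[1L]]
  b0 <- fit$b0 - mean(fit$b0)  # intercept shift-invariance: fix sum to zero
  coef_orig <- fit$B / sc$scale
  icept_orig <- b0 - colSums(fit$B * (sc$center / sc$scale))
  structure(list(classes = levels(y),
                 coefficients = structure(coef_orig,
                                          dimnames = list(colnames(X), levels(y))),
                 intercepts = stats::setNames(icept_orig, levels(y)),
                 B_std = fit$B, b0_std = b0, scaler = sc[c("center", "scale")],
                 lambda = lambda, objective = fit$objective,
                 kkt_residual = gl_kkt_residual(sc$Xs, Y, fit$B, b0, lambda),
                 iterations = fit$iterations),
            class = "grouped_lasso_fit")
}

#' Penalty grid for the grouped multinomial lasso
#'
#' @inheritParams fit_grouped_multinomial_lasso
#' @param n_lambda,lambda_min_ratio grid size and lower end relative to
#'   \eqn{\lambda_{max}} (the smallest penalty with an all-zero solution).
#' @return decreasing vector of penalties.
#' @export
grouped_lasso_grid <- function(X, y, n_lambda = 100L,
                               lambda_min_ratio = 0.001) {
  y <- droplevels(as.factor(y))
  sc <- gl_standardize(X)
  lmax <- gl_lambda_max(sc$Xs, class_indicator(y))
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Choose the penalty by cross-validated accuracy with a 1-SE rule
#'
#' Runs stratified \code{n_folds}-fold cross-validation over a decreasing
#' penalty grid and returns the \emph{largest} penalty whose mean
#' classification accuracy is at least the maximum mean accuracy minus
#' the standard error at the maximising penalty (i.e. accuracy one
#' standard error below the maximum).
#'
#' @inheritParams fit_grouped_multinomial_lasso
#' @param n_folds folds, stratified by class.
#' @param lambda_grid decreasing penalty grid; computed from the data if
#'   NULL.
#' @param seed fold-assignment seed.
#' @param maxit,kkt_tol solver controls.
#' @return list with \code{lambda} (chosen), \code{lambda_max_acc}
#'   (accuracy-maximising), and \code{cv_table} (lambda, mean_accuracy,
#'   se_accuracy).
#' @export
cv_select_lambda <- function(X, y, n_folds = 10L, lambda_grid = NULL,
                             seed = 1L, maxit = 800L, kkt_tol = 1e-4) {
  y <- droplevels(as.factor(y))
  if (is.null(lambda_grid)) lambda_grid <- grouped_lasso_grid(X, y)
  if (is.unsorted(rev(lambda_grid), strictly = TRUE))
    stopf("lambda_grid must be strictly decreasing")
  fold <- stratified_folds(y, n_folds, seed = seed)
  acc <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < nlevels(y))
      stopf("fold %d is missing class(es): %s", f,
            paste(setdiff(levels(y), levels(ytr)), collapse = ", "))
    sc <- gl_standardize(X[tr, , drop = FALSE])
    Ytr <- class_indicator(y[tr])
    fits <- gl_path(sc$Xs, Ytr, lambda_grid, maxit = maxit,
                    kkt_tol = kkt_tol)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, sc$center), 2L,
                 sc$scale, "/")
    yte <- y[!tr]
    for (i in seq_along(fits)) {
      Z <- sweep(Xte %*% fits[[i]]$B, 2L, fits[[i]]$b0, "+")
      pred <- levels(y)[max.col(Z, ties.method = "first")]
      acc[f, i] <- mean(pred == as.character(yte))
    }
  }
  mean_acc <- colMeans(acc)
  se_acc <- apply(acc, 2L, stats::sd) / sqrt(n_folds)
  best <- which.max(mean_acc)             # first index = largest lambda on ties
  cutoff <- mean_acc[best] - se_acc[best]
  chosen <- which(mean_acc >= cutoff)[1L] # grid is decreasing: first = largest
  list(lambda = lambda_grid[chosen],
       lambda_max_acc = lambda_grid[best],
       cv_table = data.frame(lambda = lambda_grid, mean_accuracy = mean_acc,
                             se_accuracy = se_acc))
}

#' Stability selection over repeated 2:1 partitions
#'
#' For each of \code{n_partitions} seeded, class-stratified 2:1
#' train/test splits: select the penalty by \code{\link{cv_select_lambda}}
#' on the training part, fit the grouped multinomial lasso at that
#' penalty, and record the features with any nonzero class coefficient.
#' The selection frequency of a feature is the number of partitions that
#' selected it; features with frequency at or above
#' \code{freq_threshold} form the stable panel.
#'
#' @inheritParams fit_grouped_multinomial_lasso
#' @param config a \code{\link{grouped_lasso_config}}.
#' @return object of class \code{stability_selection}: \code{frequency}
#'   (named integer), \code{selected} (character), \code{n_reps},
#'   \code{threshold}, and per-partition details.
#' @export
stability_select <- function(X, y, config = grouped_lasso_config()) {
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  min_class <- min(table(y))
  if (floor(min_class * config$train_fraction) < config$n_folds)
    stopf("smallest class has %d training samples; need >= n_folds = %d",
          floor(min_class * config$train_fraction), config$n_folds)
  freq <- stats::setNames(integer(ncol(X)), colnames(X))
  details <- vector("list", config$n_partitions)
  for (r in seq_len(config$n_partitions)) {
    seed_r <- child_seed(config$seed, r)
    set.seed(seed_r)
    tr_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
      sample(ix, round(length(ix) * config$train_fraction))
    }), use.names = FALSE)
    Xtr <- X[tr_idx, , drop = FALSE]
    ytr <- y[tr_idx]
    grid <- grouped_lasso_grid(Xtr, ytr, n_lambda = config$n_lambda,
                               lambda_min_ratio = config$lambda_min_ratio)
    cv <- cv_select_lambda(Xtr, ytr, n_folds = config$n_folds,
                           lambda_grid = grid,
                           seed = child_seed(seed_r, 1L))
    fit <- fit_grouped_multinomial_lasso(Xtr, ytr, cv$lambda)
    nz <- rowSums(fit$B_std != 0) > 0
    freq[nz] <- freq[nz] + 1L
    details[[r]] <- list(lambda = cv$lambda, n_selected = sum(nz),
                         selected = colnames(X)[nz])
  }
  structure(list(frequency = freq,
                 selected = names(freq)[freq >= config$freq_threshold],
                 n_reps = config$n_partitions,
                 threshold = config$freq_threshold,
                 partitions = details),
            class = "stability_selection")
}
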