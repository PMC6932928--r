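# Objective recomputed from scratch on the standardized scale (shares no
# code with the solver).
oracle_objective <- function(Xs, y, B, b0, lambda) {
  Y <- outer(as.character(y), colnames(B) %||% levels(as.factor(y)), `==`) * 1
  Z <- sweep(Xs %*% B, 2, b0, `+`)
  lse <- apply(Z, 1, function(z) max(z) + log(sum(exp(z - max(z)))))
  -sum(Y * (Z - lse)) / nrow(Xs) + lambda * sum(sqrt(rowSums(B^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

std <- function(X) scale(X, scale = apply(X, 2, sd))

softmax_prob <- function(fit, X) {
  Z <- sweep(X %*% fit$coefficients, 2, fit$intercepts, `+`)
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

test_that("penalty dominance: at lambda >= lambda_max everything is zero and
           intercepts are class log-frequencies", {
  toy <- make_multiclass_toy(n_per_class = 10, sep = 2)
  lmax <- max(grouped_lasso_grid(toy$X, toy$y, n_lambda = 2))
  fit <- fit_grouped_multinomial_lasso(toy$X, toy$y, lmax * 1.0001)
  expect_true(all(fit$coefficients == 0))
  pbar <- as.numeric(table(toy$y) / length(toy$y))
  expect_equal(unname(fit$intercepts), log(pbar) - mean(log(pbar)),
               tolerance = 1e-5)
  # and strictly below lambda_max at least one group activates
  fit2 <- fit_grouped_multinomial_lasso(toy$X, toy$y, lmax * 0.8)
  expect_gt(sum(rowSums(fit2$B_std^2) > 0), 0)
})

test_that("solutions satisfy the KKT conditions of the grouped objective", {
  toy <- make_multiclass_toy(n_per_class = 12, p_noise = 5, sep = 1.5,
                             seed = 31)
  Xs <- std(toy$X)
  Y <- (outer(as.character(toy$y), levels(toy$y), `==`)) * 1
  for (frac in c(0.6, 0.2, 0.05)) {
    lmax <- max(grouped_lasso_grid(toy$X, toy$y, n_lambda = 2))
    lam <- lmax * frac
    fit <- fit_grouped_multinomial_lasso(toy$X, toy$y, lam)
    # recompute the gradient from scratch
    Z <- sweep(Xs %*% fit$B_std, 2, fit$b0_std, `+`)
    P <- exp(Z - apply(Z, 1, max))
    P <- P / rowSums(P)
    G <- crossprod(Xs, (P - Y) / nrow(Xs))
    norms <- sqrt(rowSums(fit$B_std^2))
    for (j in seq_along(norms)) {
      if (norms[j] == 0) {
        expect_lte(sqrt(sum(G[j, ]^2)), lam + 1e-6)
      } else {
        resid <- G[j, ] + lam * fit$B_std[j, ] / norms[j]
        expect_lte(sqrt(sum(resid^2)), 1e-6)
      }
    }
    expect_lte(max(abs(colSums((P - Y) / nrow(Xs)))), 1e-6)
  }
})

test_that("objective value matches an independent numeric minimizer on a
           tiny instance", {
  set.seed(12)
  n <- 12; p <- 3; K <- 3
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  y <- factor(rep(c("a", "b", "c"), each = 4))
  X[y == "b", 1] <- X[y == "b", 1] + 1.5
  X[y == "c", 2] <- X[y == "c", 2] - 1.5
  lam <- 0.05
  fit <- fit_grouped_multinomial_lasso(X, y, lam, kkt_tol = 1e-8)
  Xs <- std(X)
  f_mine <- oracle_objective(Xs, y, fit$B_std, fit$b0_std, lam)
  expect_equal(f_mine, fit$objective, tolerance = 1e-8)
  # independent minimizer: BFGS on the same objective from two starts
  # (all groups active at this lambda so the objective is smooth near the
  # optimum); also a Nelder-Mead refinement
  obj_par <- function(par) {
    b0 <- par[1:K]
    B <- matrix(par[-(1:K)], p, K, dimnames = list(NULL, levels(y)))
    oracle_objective(Xs, y, B, b0, lam)
  }
  best <- Inf
  for (start in list(rep(0.01, K + p * K),
                     c(fit$b0_std, as.numeric(fit$B_std)) + 0.05)) {
    o1 <- stats::optim(start, obj_par, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-14))
    o2 <- stats::optim(o1$par, obj_par, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o1$value, o2$value)
  }
  expect_equal(fit$objective, best, tolerance = 1e-5)
})

test_that("grouped lasso agrees with glmnet's grouped multinomial on
           predictions", {
  skip_if_not_installed("glmnet")
  toy <- make_multiclass_toy(n_per_class = 20, p_noise = 4, sep = 1.2,
                             seed = 17)
  lmax <- max(grouped_lasso_grid(toy$X, toy$y, n_lambda = 2))
  lam <- 0.3 * lmax
  fit <- fit_grouped_multinomial_lasso(toy$X, toy$y, lam)
  gn <- glmnet::glmnet(toy$X, toy$y, family = "multinomial",
                       type.multinomial = "grouped", lambda = lam,
                       standardize = TRUE, thresh = 1e-12)
  # same active set and closely matching fitted class probabilities
  gn_coef <- do.call(cbind, lapply(glmnet::coef.glmnet(gn, s = lam),
                                   function(m) as.numeric(m)[-1]))
  expect_equal(unname(rowSums(fit$coefficients != 0) > 0),
               unname(rowSums(gn_coef != 0) > 0))
  P_mine <- softmax_prob(fit, toy$X)
  P_gn <- drop(stats::predict(gn, toy$X, s = lam, type = "response"))
  expect_lt(max(abs(P_mine - P_gn)), 0.02)
})

test_that("the 1-SE accuracy rule picks the largest qualifying penalty", {
  toy <- make_multiclass_toy(n_per_class = 20, p_noise = 3, sep = 1.5,
                             seed = 3)
  grid <- grouped_lasso_grid(toy$X, toy$y, n_lambda = 30,
                             lambda_min_ratio = 0.01)
  cv <- cv_select_lambda(toy$X, toy$y, n_folds = 5, lambda_grid = grid,
                         seed = 9)
  tab <- cv$cv_table
  best <- which.max(tab$mean_accuracy)
  cutoff <- tab$mean_accuracy[best] - tab$se_accuracy[best]
  qualifying <- tab$lambda[tab$mean_accuracy >= cutoff]
  expect_equal(cv$lambda, max(qualifying))
  expect_true(cv$lambda >= cv$lambda_max_acc)
  # degenerate grid ordering is rejected
  expect_error(cv_select_lambda(toy$X, toy$y, lambda_grid = rev(grid)),
               "decreasing")
})

test_that("stability selection frequencies behave at the extremes and are
           invariant to feature order", {
  toy <- make_multiclass_toy(n_per_class = 18, p_noise = 3, sep = 2,
                             seed = 13)
  cfg1 <- grouped_lasso_config(n_partitions = 1L, freq_threshold = 1L,
                               n_folds = 3L, n_lambda = 20L,
                               lambda_min_ratio = 0.01, seed = 4L)
  ss1 <- stability_select(toy$X, toy$y, cfg1)
  expect_setequal(ss1$selected, names(which(ss1$frequency == 1)))
  # threshold above n_partitions empties the selection
  cfg_hi <- grouped_lasso_config(n_partitions = 1L, freq_threshold = 2L,
                                 n_folds = 3L, n_lambda = 20L,
                                 lambda_min_ratio = 0.01, seed = 4L)
  expect_length(stability_select(toy$X, toy$y, cfg_hi)$selected, 0)
  # feature order does not change frequencies
  perm <- sample(ncol(toy$X))
  ss_p <- stability_select(toy$X[, perm], toy$y, cfg1)
  expect_equal(ss_p$frequency[colnames(toy$X)], ss1$frequency)
  # a class with fewer training samples than folds is an error
  tiny <- toy$X[1:24, ]
  expect_error(stability_select(tiny, toy$y[1:24],
                                grouped_lasso_config(n_folds = 10L)),
               "n_folds")
})

test_that("final multinomial model fits, predicts, and round-trips", {
  # single separating feature on a tiny toy -> perfect training accuracy
  X1 <- matrix(c(0.1, 0.2, 0.8, 0.9), 4, 1,
               dimnames = list(NULL, "cg1"))
  y1 <- factor(c("low", "low", "high", "high"))
  m1 <- fit_final_multinomial(X1, y1)
  expect_equal(as.character(predict_class(m1, X1)), as.character(y1))

  toy <- make_multiclass_toy(n_per_class = 15, p_noise = 2, sep = 3.5,
                             seed = 23)
  m <- fit_final_multinomial(toy$X, toy$y)
  P <- predict_proba(m, toy$X)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-8)
  expect_gt(mean(predict_class(m, toy$X) == toy$y), 0.95)
  # argmax consistency on random inputs
  Xr <- matrix(rnorm(1000 * ncol(toy$X)), 1000,
               dimnames = list(NULL, colnames(toy$X)))
  Pr <- predict_proba(m, Xr)
  expect_equal(as.character(predict_class(m, Xr)),
               m$classes[max.col(Pr, ties.method = "first")])
  # serialization round trip reproduces predictions to text precision
  path <- withr::local_tempfile(fileext = ".json")
  write_diag_model(m, path)
  m2 <- read_diag_model(path)
  expect_equal(predict_proba(m2, toy$X), predict_proba(m, toy$X),
               tolerance = 1e-12)
  # missing feature errors by name
  expect_error(predict_proba(m, toy$X[, -1]), colnames(toy$X)[1])
  expect_error(fit_final_multinomial(toy$X[, 0], toy$y), "selected")
})

test_that("final model probabilities agree with an unpenalized multinomial
           fit on well-conditioned data", {
  skip_if_not_installed("nnet")
  toy <- make_multiclass_toy(n_per_class = 40, p_noise = 2, sep = 1.0,
                             seed = 29)
  m <- fit_final_multinomial(toy$X, toy$y)
  nn <- nnet::multinom(y ~ ., data = data.frame(y = toy$y, toy$X),
                       trace = FALSE, maxit = 500, reltol = 1e-14)
  P1 <- predict_proba(m, toy$X)
  P2 <- stats::predict(nn, type = "probs")
  expect_lt(max(abs(P1 - P2[, m$classes])), 1e-3)
})
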