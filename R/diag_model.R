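#' Fit the final multinomial diagnostic model
#'
#' Maximum-likelihood multinomial logistic regression on the selected
#' CpGs, with a tiny ridge term (\code{ridge} times the squared Frobenius
#' norm of the standardized coefficients) so the optimum exists even
#' under quasi-separation. Intercepts are unpenalized. Optimised by BFGS
#' with analytic gradients; features are standardized with training
#' statistics and coefficients returned on the original scale.
#'
#' @param X sample-by-feature beta matrix restricted to the selected
#'   CpGs (nonempty).
#' @param y class labels.
#' @param ridge ridge weight on standardized coefficients (default 1e-6).
#' @return object of class \code{diag_model}: classes, intercepts,
#'   feature-by-class coefficient matrix, scaler, training ids.
#' @export
fit_final_multinomial <- function(X, y, ridge = 1e-6) {
  if (is.null(dim(X)) || ncol(X) == 0)
    stopf(paste("no CpGs selected; relax the stability-selection frequency",
                "threshold"))
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  p <- ncol(X)
  n <- nrow(X)
  Y <- class_indicator(y)
  sc <- gl_standardize(X)
  Xs <- sc$Xs
  unpack <- function(par) list(b0 = par[seq_len(K)],
                               B = matrix(par[-seq_len(K)], p, K))
  fn <- function(par) {
    pr <- unpack(par)
    Z <- sweep(Xs %*% pr$B, 2L, pr$b0, "+")
    -sum(Y * (Z - row_log_sum_exp(Z))) / n + ridge * sum(pr$B^2)
  }
  gr <- function(par) {
    pr <- unpack(par)
    P <- softmax(sweep(Xs %*% pr$B, 2L, pr$b0, "+"))
    R <- (P - Y) / n
    c(colSums(R), as.numeric(crossprod(Xs, R) + 2 * ridge * pr$B))
  }
  opt <- stats::optim(rep(0, K + p * K), fn, gr, method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-14))
  pr <- unpack(opt$par)
  b0 <- pr$b0 - mean(pr$b0)
  coef_orig <- pr$B / sc$scale
  icept_orig <- b0 - colSums(pr$B * (sc$center / sc$scale))
  structure(list(classes = levels(y),
                 features = colnames(X),
                 intercepts = stats::setNames(icept_orig, levels(y)),
                 coefficients = structure(coef_orig,
                                          dimnames = list(colnames(X),
                                                          levels(y))),
                 scaler = sc[c("center", "scale")], ridge = ridge,
                 value = opt$value,
                 fitted_on = rownames(X)),
            class = "diag_model")
}

#' Class probabilities from a diagnostic model
#'
#' Softmax of the linear predictors; each row sums to 1.
#'
#' @param model a \code{diag_model}.
#' @param X sample-by-feature matrix containing all model CpGs.
#' @return sample-by-class probability matrix.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "diag_model"))
  missing_f <- setdiff(model$features, colnames(X))
  if (length(missing_f))
    stopf("missing CpG column(s): %s", paste(missing_f, collapse = ", "))
  Xm <- X[, model$features, drop = FALSE]
  Z <- sweep(Xm %*% model$coefficients, 2L, model$intercepts, "+")
  P <- softmax(Z)
  dimnames(P) <- list(rownames(X), model$classes)
  P
}

#' Predicted class labels (probability argmax)
#'
#' @inheritParams predict_proba
#' @return factor of predicted classes (ties broken by class order).
#' @export
predict_class <- function(model, X) {
  P <- predict_proba(model, X)
  factor(model$classes[max.col(P, ties.method = "first")],
         levels = model$classes)
}

#' Serialize / restore a diagnostic model as JSON
#'
#' Numbers are written at full text precision, so a write/read round
#' trip reproduces predictions to within double-rounding of the last
#' digit (~1e-15 relative).
#'
#' @param model a \code{diag_model}.
#' @param path JSON file path.
#' @return \code{read_diag_model} returns the restored model.
#' @export
write_diag_model <- function(model, path) {
  stopifnot(inherits(model, "diag_model"))
  obj <- list(classes = model$classes, features = model$features,
              intercepts = unname(model$intercepts),
              coefficients = unname(model$coefficients),
              center = unname(model$scaler$center),
              scale = unname(model$scaler$scale),
              ridge = model$ridge, value = model$value)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_diag_model
#' @export
read_diag_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef_ <- matrix(unlist(obj$coefficients), length(obj$features),
                  length(obj$classes),
                  dimnames = list(obj$features, obj$classes))
  structure(list(classes = obj$classes, features = obj$features,
                 intercepts = stats::setNames(obj$intercepts, obj$classes),
                 coefficients = coef_,
                 scaler = list(center = stats::setNames(obj$center,
                                                        obj$features),
                               scale = stats::setNames(obj$scale,
                                                       obj$features)),
                 ridge = obj$ridge, value = obj$value,
                 fitted_on = NULL),
            class = "diag_model")
}
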