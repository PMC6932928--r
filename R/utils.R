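# Internal helpers shared across modules.

#' Derive a deterministic child seed
#'
#' Fans one master seed out into independent per-stage seeds while
#' keeping every value a valid 32-bit integer.
#'
#' @param seed integer master seed.
#' @param k stage index.
#' @return an integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

#' Round half away from zero
#'
#' \code{round()} rounds half to even; published tables round half up.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# Row-wise softmax with log-sum-exp stabilisation.
softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

row_log_sum_exp <- function(z) {
  m <- apply(z, 1L, max)
  m + log(rowSums(exp(z - m)))
}

# 0/1 indicator matrix for a factor, columns in level order.
class_indicator <- function(y) {
  y <- as.factor(y)
  k <- nlevels(y)
  m <- matrix(0, length(y), k, dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(y, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
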