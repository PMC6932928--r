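# Shared fixtures, built in code at test time.

# Printed 4x4 confusion tables of the published training, test and
# validation cohorts (rows = hypothesized class, columns = true class).
published_tables <- list(
  train = list(
    counts = matrix(c(90, 2, 3, 1,  2, 64, 3, 0,  3, 4, 143, 2,  1, 0, 2, 57),
                    4, 4, dimnames = list(c("NSE", "BE", "EAC", "ESCC"),
                                          c("NSE", "BE", "EAC", "ESCC"))),
    per_class = c(NSE = 93.75, BE = 92.75, EAC = 94.08, ESCC = 95.00),
    overall = 93.90),
  test = list(
    counts = matrix(c(45, 1, 1, 0,  2, 29, 3, 0,  1, 2, 71, 2,  0, 0, 1, 29),
                    4, 4, dimnames = list(c("NSE", "BE", "EAC", "ESCC"),
                                          c("NSE", "BE", "EAC", "ESCC"))),
    per_class = c(NSE = 95.74, BE = 85.29, EAC = 93.42, ESCC = 96.67),
    overall = 93.05),
  validation = list(
    counts = matrix(c(60, 4, 1, 1,  4, 59, 6, 0,  0, 1, 22, 0,  0, 1, 7, 18),
                    4, 4, dimnames = list(c("NSE", "BE", "EAC", "ESCC"),
                                          c("NSE", "BE", "EAC", "ESCC"))),
    per_class = c(NSE = 90.91, BE = 85.51, EAC = 95.65, ESCC = 69.23),
    overall = 86.41))

# Small two-group beta matrix with known per-CpG structure.
make_two_group <- function(n_cpg = 50, n_a = 6, n_b = 8, shift_first = 0,
                           seed = 42) {
  set.seed(seed)
  m <- matrix(stats::rbeta(n_cpg * (n_a + n_b), 2, 2), n_cpg,
              dimnames = list(sprintf("cg%05d", seq_len(n_cpg)),
                              c(sprintf("A%02d", seq_len(n_a)),
                                sprintf("B%02d", seq_len(n_b)))))
  if (shift_first > 0)
    m[1, seq_len(n_a)] <- pmin(1, m[1, seq_len(n_a)] + shift_first)
  list(betas = m, a = sprintf("A%02d", seq_len(n_a)),
       b = sprintf("B%02d", seq_len(n_b)))
}

# Independent oracle for the moderated-t hyperparameters: direct numeric
# solve of the moment equations (uniroot on the trigamma equation),
# sharing no code with the package's Newton iteration.
oracle_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  df <- rep_len(df, length(s2))[ok]
  e <- z - digamma(df / 2) + log(df / 2)
  G <- length(e)
  evar <- sum((e - mean(e))^2) / (G - 1)
  rhs <- evar - mean(trigamma(df / 2))
  if (rhs <= 0) return(list(d0 = Inf, s0_2 = exp(mean(e))))
  f <- function(y) trigamma(y) - rhs
  y <- stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
  d0 <- 2 * y
  list(d0 = d0, s0_2 = exp(mean(e) + digamma(y) - log(y)))
}

# Brute-force BH: classic step-up rejection set at level q.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# Exhaustive concordant-pair AUC (ties count one half).
oracle_pair_auc <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  pr <- outer(pos, neg, `-`)
  (sum(pr > 0) + 0.5 * sum(pr == 0)) / (length(pos) * length(neg))
}

# Brute-force Cox partial likelihood for an untied toy with all events:
# grid maximization of the written product over risk sets.
oracle_cox_beta <- function(x, times) {
  ord <- order(times)
  x <- x[ord]
  logpl <- function(b) {
    sum(vapply(seq_along(x), function(i) {
      riskset <- i:length(x)
      b * x[i] - log(sum(exp(b * x[riskset])))
    }, numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  vals <- vapply(grid, logpl, numeric(1))
  grid[which.max(vals)]
}

# Simple four-class separable toy for classifier tests.
make_multiclass_toy <- function(n_per_class = 15, p_noise = 3, sep = 3,
                                seed = 7) {
  set.seed(seed)
  classes <- c("NSE", "BE", "EAC", "ESCC")
  y <- factor(rep(classes, each = n_per_class), levels = classes)
  n <- length(y)
  X <- matrix(stats::rnorm(n * (4 + p_noise)), n)
  for (k in 1:4) X[y == classes[k], k] <- X[y == classes[k], k] + sep
  colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  list(X = X, y = y)
}
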