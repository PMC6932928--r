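test_that("published confusion tables reproduce every printed accuracy", {
  for (nm in names(published_tables)) {
    pt <- published_tables[[nm]]
    cs <- confusion_from_counts(pt$counts)
    expect_equal(round_half_up(cs$per_class_accuracy, 2), pt$per_class)
    expect_equal(round_half_up(cs$overall_accuracy, 2), pt$overall)
  }
  # the printed training interval: 93.9% (95% CI 91.0-96.1)
  cs <- confusion_from_counts(published_tables$train$counts)
  expect_equal(round_half_up(cs$overall_ci, 1), c(91.0, 96.1))
})

test_that("confusion_summary counts labels correctly and validates input", {
  truth <- c("A", "A", "B", "B", "C", "C")
  pred <- c("A", "B", "B", "B", "C", "A")
  cs <- confusion_summary(truth, pred)
  expect_equal(sum(cs$counts), 6)
  expect_equal(unname(colSums(cs$counts)), c(2, 2, 2))
  expect_equal(cs$overall_accuracy, 100 * 4 / 6)
  # overall accuracy equals the class-total-weighted mean of per-class
  expect_equal(cs$overall_accuracy,
               sum(cs$per_class_accuracy * colSums(cs$counts)) /
                 sum(cs$counts))
  # identity -> 100% everywhere with CI upper bound at 100
  ident <- confusion_summary(truth, truth)
  expect_true(all(ident$per_class_accuracy == 100))
  expect_equal(ident$overall_ci[2], 100)
  expect_true(all(ident$overall_ci >= ident$overall_accuracy - 100 * 1e-12 |
                    ident$overall_ci <= 100))
  expect_error(confusion_summary(truth, c(pred[-6], "Z"),
                                 classes = c("A", "B", "C")), "Z")
})

test_that("micro-average AUC equals exhaustive concordant-pair counting", {
  set.seed(55)
  # 8-sample toy over 3 classes with ties in the probabilities
  prob <- matrix(sample(seq(0, 1, 0.25), 24, TRUE), 8, 3)
  prob <- prob + 0.01
  prob <- prob / rowSums(prob)
  colnames(prob) <- c("A", "B", "C")
  truth <- sample(c("A", "B", "C"), 8, TRUE)
  truth[1:2] <- c("A", "B")   # guarantee two classes
  res <- micro_average_auc(truth, prob)
  labels <- as.vector(outer(truth, colnames(prob), `==`))
  expect_equal(res$auc, oracle_pair_auc(labels, as.vector(prob)))

  # perfect probabilities -> AUC 1; uniform -> 0.5
  truth4 <- c("A", "B", "C", "A")
  perfect <- matrix(0, 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  perfect[cbind(1:4, match(truth4, colnames(perfect)))] <- 1
  expect_equal(micro_average_auc(truth4, perfect)$auc, 1.0)
  unif <- matrix(1 / 3, 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(micro_average_auc(truth4, unif)$auc, 0.5)

  # invariance under a strictly monotone transform of all probabilities
  res2 <- micro_average_auc(truth, plogis(5 * qlogis(pmin(pmax(prob, 1e-6),
                                                          1 - 1e-6))),
                            check_rows = FALSE)
  expect_equal(res2$auc, res$auc)
  expect_error(micro_average_auc(rep("A", 4), perfect), "single-class")
  expect_error(micro_average_auc(truth4, perfect * 2), "sum to 1")
})

test_that("log-rank observed/expected/variance match hand-worked
           hypergeometric tables", {
  # A: events at 1, 3; B: events at 2, 4; no censoring
  times <- c(1, 3, 2, 4); events <- rep(1, 4)
  groups <- c("A", "A", "B", "B")
  lr <- km_logrank(times, events, groups)
  # hand tables: E_A = 1/2 + 1/3 + 1/2 = 4/3; V = 1/4 + 2/9 + 1/4 = 13/18
  expect_equal(unname(lr$observed), c(2, 2))
  expect_equal(unname(lr$expected)[1], 4 / 3, tolerance = 1e-12)
  expect_equal(unname(lr$var[1, 1]), 13 / 18, tolerance = 1e-12)
  expect_equal(lr$chisq, (2 - 4 / 3)^2 / (13 / 18), tolerance = 1e-12)

  # identical outcome vectors in both groups -> statistic 0, p = 1
  lr0 <- km_logrank(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                    rep(c("A", "B"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # one group, no censoring: KM equals 1 - empirical CDF
  sf <- km_logrank(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "A", "B"))
  a <- sf$curves[sf$curves$group == "A", ]
  expect_equal(a$surv, 1 - seq_len(3) / 3)
  expect_error(km_logrank(c(1, 2), c(1, 1), c("A", "A")), "two")
})

test_that("time-dependent AUC reduces to the static AUC without censoring
           and is calibrated under the null", {
  set.seed(91)
  n <- 120
  scores <- rnorm(n)
  times <- rexp(n, 0.1 * exp(scores))
  horizon <- median(times)
  td <- time_dependent_auc(scores, times, rep(1L, n), horizon)
  static <- oracle_pair_auc(times <= horizon, scores)
  expect_equal(td$auc, static, tolerance = 1e-10)
  # perfectly ranked scores split exactly at the horizon -> AUC 1
  t2 <- c(seq(0.1, 0.9, length.out = 10), seq(2, 5, length.out = 10))
  s2 <- c(rep(2, 10), rep(-2, 10))
  expect_equal(time_dependent_auc(s2, t2, rep(1L, 20), 1)$auc, 1.0)
  # null scores with censoring: AUC near one half over seeds
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    tt <- rexp(300, 0.1); cc <- rexp(300, 0.05)
    time_dependent_auc(rnorm(300), pmin(tt, cc), as.integer(tt <= cc),
                       stats::median(pmin(tt, cc)))$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
  expect_error(time_dependent_auc(scores, times, rep(1L, n), -1), "horizon")
})

test_that("cox_table reports univariate and multivariate rows and flags
           rank deficiency", {
  set.seed(61)
  n <- 300
  f <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  tt <- rexp(n, 0.1); cc <- rexp(n, 0.05)
  ct <- cox_table(f, pmin(tt, cc), as.integer(tt <= cc))
  expect_setequal(ct$table$term, c("a", "b"))
  # independent null factors: univariate and multivariate agree, HR ~ 1
  expect_equal(ct$table$hr_uni, ct$table$hr_multi, tolerance = 0.1)
  expect_equal(ct$table$hr_uni, c(1, 1), tolerance = 0.35)
  expect_false(ct$rank_deficient)
  # duplicated factor under two names is flagged
  f2 <- data.frame(a = f$a, a_copy = f$a)
  expect_warning(ct2 <- cox_table(f2, pmin(tt, cc), as.integer(tt <= cc)),
                 "rank-deficient")
  expect_true(ct2$rank_deficient)
})

test_that("cox_table covers a planted classifier effect", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 250
    grp <- rbinom(n, 1, 0.5)
    f <- data.frame(group = grp, age = sample(40:80, n, TRUE))
    tt <- rexp(n, 0.08 * exp(1.6 * grp)); cc <- rexp(n, 0.02)
    ct <- cox_table(f, pmin(tt, cc), as.integer(tt <= cc))
    row <- ct$table[ct$table$term == "group", ]
    row$ci_lower_multi <= exp(1.6) && exp(1.6) <= row$ci_upper_multi
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("risk stratification assigns G1-G4 and detects monotone hazards", {
  set.seed(41)
  n <- 300
  risk <- factor(sample(c("low", "high"), n, TRUE), c("low", "high"))
  stage <- sample(c("I", "II", "III", "IV"), n, TRUE)
  adv <- stage %in% c("III", "IV")
  level <- 1L + (risk == "high") * 2L + adv
  clinical <- data.frame(age = sample(40:80, n, TRUE),
                         gender = rbinom(n, 1, 0.5), bmi = runif(n, 18, 35),
                         smoking = rbinom(n, 1, 0.5),
                         alcohol = rbinom(n, 1, 0.5))
  tt <- rexp(n, 0.05 * exp(0.6 * (level - 1))); cc <- rexp(n, 0.02)
  rs <- risk_stratify(risk, stage, pmin(tt, cc), as.integer(tt <= cc),
                      clinical)
  expect_equal(unname(as.integer(rs$level)), unname(as.integer(level)))
  expect_true(all(diff(c(1, rs$hr_table$hr)) > -0.5))  # roughly monotone
  expect_lt(rs$trend_p, 0.01)
  expect_lt(rs$logrank$p, 0.01)
  # levels partition the cohort
  expect_equal(sum(table(rs$level)), n)

  # null: trend p not extreme systematically
  tt0 <- rexp(n, 0.05); cc0 <- rexp(n, 0.02)
  rs0 <- risk_stratify(risk, stage, pmin(tt0, cc0),
                       as.integer(tt0 <= cc0), clinical)
  expect_gt(rs0$trend_p, 1e-4)
  # an empty level yields missing contrasts, not an error
  rs1 <- risk_stratify(factor(rep("low", n), c("low", "high")), stage,
                       pmin(tt0, cc0), as.integer(tt0 <= cc0), clinical)
  expect_true(all(is.na(rs1$hr_table$hr[rs1$hr_table$level %in%
                                          c("G3", "G4")])))
  expect_error(risk_stratify(risk, rep(NA, n), pmin(tt0, cc0),
                             as.integer(tt0 <= cc0), clinical), "known")
})
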