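test_that("AUC handles separation, ties, and label flips", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sens_at_cutoff, 1.0)
  expect_equal(r$spec_at_cutoff, 1.0)

  r2 <- roc_auc(c(0.9, 0.5, 0.5, 0.2), c(1, 0, 1, 0))
  expect_equal(r2$auc, 0.875)  # exhaustive pairwise: (1 + 1 + 1 + 0.5)/4

  r3 <- roc_auc(c(0.9, 0.5, 0.5, 0.2), c(0, 1, 0, 1))
  expect_equal(r3$auc, 1 - r2$auc)

  expect_warning(rc <- roc_auc(c(1, 1, 1, 1), c(1, 0, 1, 0)), "constant")
  expect_equal(rc$auc, 0.5)
  expect_equal(youden_cutoff(rc)$j, 0)

  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "non-empty")
})

test_that("threshold-sweep AUC equals the Mann-Whitney oracle exhaustively", {
  set.seed(31)
  for (r in 1:40) {
    n <- sample(4:30, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))[seq_len(n)]
    got <- roc_auc(scores, labels)
    expect_lt(abs(got$auc - oracle_auc(scores, labels == 1)), 1e-10)
    # curve monotone as the cutoff sweeps
    expect_true(all(diff(got$thresholds$sensitivity) <= 1e-12))
    expect_true(all(diff(got$thresholds$specificity) >= -1e-12))
  }
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_lt(abs(ours - theirs), 1e-10)
})

test_that("Youden J stays small for uninformative scores", {
  set.seed(17)
  small <- logical(100)
  for (r in 1:100) {
    sc <- rnorm(200)
    lab <- rbinom(200, 1, 0.5)
    small[r] <- roc_auc(sc, lab)$youden_j < 0.25
  }
  expect_gte(mean(small), 0.9)
})

test_that("Welch comparison matches the textbook formula and degenerates safely", {
  set.seed(23)
  for (r in 1:10) {
    a <- rnorm(sample(5:20, 1)); b <- rnorm(sample(5:20, 1), sd = 2)
    got <- compare_groups(c(a, b), rep(c("g1", "g2"), c(length(a), length(b))))
    orc <- oracle_welch(a, b)
    expect_lt(abs(got$t_statistic - orc$t), 1e-10)
    expect_lt(abs(got$p - orc$p), 1e-10)
  }
  idn <- compare_groups(rep(c(2, 2, 2, 2), 2), rep(c("x", "y"), each = 4))
  expect_equal(idn$t_statistic, 0)
  expect_equal(idn$p, 1)
  expect_error(compare_groups(1:3, c("a", "b", "b")), ">= 2")
})

test_that("Welch test is calibrated under the null", {
  set.seed(29)
  rej <- logical(2000)
  for (r in seq_len(2000)) {
    rej[r] <- compare_groups(rnorm(16), rep(c("a", "b"), each = 8))$p < 0.05
  }
  band <- 2.58 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(rej) - 0.05), band + 1e-9)
})

test_that("KM estimator reproduces hand product-limit values", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 0, 1, 0))
  at <- function(t) km$surv[max(which(km$time <= t))]
  expect_equal(at(1), 0.75)
  expect_equal(at(3), 0.375)

  none <- km_curve(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(none$surv == 1))

  # no censoring: KM equals the empirical survival function
  set.seed(37)
  tms <- sort(sample(1:1000, 20))
  km2 <- km_curve(tms, rep(1, 20))
  for (tt in tms) {
    expect_equal(km2$surv[km2$time == tt], mean(tms > tt))
  }
  expect_true(all(diff(km2$surv) <= 0))
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
})

test_that("log-rank matches the risk-table oracle and detects nothing in mirrored data", {
  times <- c(2, 4, 5, 7, 8, 8, 10, 12, 13, 15)
  events <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1)
  groups <- rep(c("a", "b"), 5)
  got <- logrank_test(times, events, groups)
  orc <- oracle_logrank(times, events, groups)
  expect_lt(abs(got$chi2 - orc$chi2), 1e-10)
  expect_lt(abs(got$p - orc$p), 1e-10)

  # identical survival experience in both groups
  sym <- logrank_test(rep(c(1, 3, 6), 2), rep(c(1, 0, 1), 2),
                      rep(c("a", "b"), each = 3))
  expect_lt(sym$chi2, 1e-10)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("fixed-horizon ROC classifies outcomes and reports exclusions", {
  # all events before the horizon, scores perfectly ranked
  r <- fixed_horizon_roc(scores = c(4, 3, 2, 1), times = c(10, 20, 2000, 3000),
                         events = c(1, 1, 1, 1), horizon = 1095)
  expect_equal(r$auc, 1.0)
  expect_equal(attr(r, "n_excluded"), 0)

  expect_error(fixed_horizon_roc(1:4, times = rep(10, 4), events = rep(0, 4),
                                 horizon = 1095),
               "excluding 4")
  # pre-horizon censored samples are dropped from the comparison
  r2 <- fixed_horizon_roc(c(5, 4, 3, 2, 1), times = c(10, 50, 500, 2000, 3000),
                          events = c(1, 1, 0, 0, 0), horizon = 1095)
  expect_equal(attr(r2, "n_excluded"), 1)
  expect_equal(r2$n_pos + r2$n_neg, 4)
})

test_that("evaluation is invariant under monotone score transforms", {
  set.seed(41)
  sc <- rnorm(80)
  lab <- rbinom(80, 1, 0.4)
  tms <- rexp(80, 1 / 500)
  ev <- rbinom(80, 1, 0.7)
  mono <- function(x) exp(3 * x) + 5
  expect_equal(roc_auc(sc, lab)$auc, roc_auc(mono(sc), lab)$auc)
  expect_equal(roc_auc(sc, lab)$youden_j, roc_auc(mono(sc), lab)$youden_j)
  s1 <- survival_report(sc, tms, ev, horizon = 500)
  s2 <- survival_report(mono(sc), tms, ev, horizon = 500)
  expect_equal(s1$logrank_chi2, s2$logrank_chi2)
  expect_equal(s1$horizon_roc$auc, s2$horizon_roc$auc)
})

test_that("log-rank has power against a planted hazard ratio", {
  rej <- logical(100)
  for (r in seq_len(100)) {
    cfg <- cohort_config(n_case = 150, n_control = 150, seed = 6100 + r)
    ch <- generate_cohort(cfg)
    ph <- attach_survival(ch$phenotypes, ch$truth$latent_scores, cfg)
    hi <- ch$truth$latent_scores > median(ch$truth$latent_scores)
    rej[r] <- logrank_test(ph$time, ph$event, hi)$p < 0.05
  }
  expect_gte(mean(rej), 0.9)
})

test_that("survival report splits scores and carries the horizon ROC", {
  cfg <- cohort_config(seed = 55)
  ch <- generate_cohort(cfg)
  ph <- attach_survival(ch$phenotypes, ch$truth$latent_scores, cfg)
  rep_ <- survival_report(ch$truth$latent_scores, ph$time, ph$event)
  expect_s3_class(rep_$horizon_roc, "ferro_roc")
  expect_gte(rep_$logrank_chi2, 0)
  for (km in rep_$km_curves) {
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_equal(km$surv[1], 1)
  }
})
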