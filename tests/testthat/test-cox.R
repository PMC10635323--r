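test_that("Cox MLE matches the grid-search oracle on toy data", {
  # 4 subjects, all events, binary covariate
  d <- toy_cohort(time = c(1, 2, 3, 4), status = rep(1, 4), er = c(0, 10, 20, 30),
                  xb = c(0, 1, 0, 1))
  fit <- fit_cox(d, "ttr", "xb")
  oracle <- grid_cox_mle(d$ttr_time, d$ttr_event, d$xb)
  expect_lt(abs(unname(fit$beta) - oracle), 1e-4 + 1e-4)

  # a second toy with censoring and a continuous covariate
  d2 <- toy_cohort(time = c(0.5, 1, 1.5, 2.5, 3, 4.5), status = c(1, 0, 1, 1, 0, 1),
                   er = 1:6 * 10, xc = c(0.2, -1, 0.7, 1.3, -0.5, 0.1))
  fit2 <- fit_cox(d2, "ttr", "xc")
  oracle2 <- grid_cox_mle(d2$ttr_time, d2$ttr_event, d2$xc)
  expect_lt(abs(unname(fit2$beta) - oracle2), 2e-4)
})

test_that("degenerate designs raise informative errors", {
  d <- toy_cohort(time = 1:6, status = c(1, 1, 0, 1, 0, 1), er = 1:6 * 10,
                  xb = rep(1, 6))
  expect_error(fit_cox(d, "ttr", "xb"), "constant")

  # complete separation: all events in one arm before any in the other
  d2 <- toy_cohort(time = c(1, 2, 3, 10, 11, 12), status = c(1, 1, 1, 0, 0, 0),
                   er = 1:6 * 10, xb = c(1, 1, 1, 0, 0, 0))
  expect_error(suppressWarnings(fit_cox(d2, "ttr", "xb")),
               "monotone likelihood")
})

test_that("Efron and Breslow agree without ties; HR always inside its CI", {
  set.seed(31)
  n <- 120
  d <- toy_cohort(time = rexp(n), status = rbinom(n, 1, 0.7),
                  er = runif(n, 0, 100), xc = rnorm(n), xb = rbinom(n, 1, 0.4))
  fit <- fit_cox(d, "ttr", c("xc", "xb"))
  fb <- survival::coxph(survival::Surv(ttr_time, ttr_event) ~ xc + xb,
                        data = d, ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(fb)), tolerance = 1e-6)
  expect_true(all(fit$hr >= fit$ci95[, 1] & fit$hr <= fit$ci95[, 2]))
})

test_that("score test at beta = 0 equals the log-rank statistic (two groups)", {
  set.seed(41)
  n <- 150
  d <- toy_cohort(time = rexp(n), status = rbinom(n, 1, 0.6),
                  er = runif(n, 0, 100), g = rbinom(n, 1, 0.5))
  fit <- fit_cox(d, "ttr", "g")
  lr <- log_rank_test(d$ttr_time, d$ttr_event, d$g)
  expect_equal(fit$score_test, lr$statistic, tolerance = 1e-6)
})

test_that("PH test detects a knee-shaped ER effect treated as linear", {
  # complete follow-up: risk-set turnover carries the functional-form
  # violation into the Schoenfeld residual trend
  cfg <- synthetic_config(censoring = list(rate = 1e-9, horizon = Inf),
                          baseline = list(shape = 1.2, scale_ttr = 1,
                                          scale_os = 1))
  set.seed(52)
  reps <- 200; n <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    er <- generate_er(cfg, n)
    s <- generate_survival(cfg, eta = psi_knee(er, 10, 1), endpoint = "ttr")
    d <- toy_cohort(time = s$time, status = s$event, er = er)
    f <- fit_cox(d, "ttr", "er")
    rej[i] <- ph_test(f)$p[1] < 0.05
  }
  expect_gt(mean(rej), 0.8)
})

test_that("backward selection retains signal, drops noise, and is deterministic", {
  set.seed(61)
  reps <- 200
  kept_signal <- logical(reps)
  cfg <- synthetic_config(censoring = list(rate = 0.2, horizon = 14),
                          baseline = list(shape = 1.2, scale_ttr = 3,
                                          scale_os = 3))
  for (i in seq_len(reps)) {
    n <- 1000
    zs <- rbinom(n, 1, 0.5)
    noise <- matrix(rnorm(3 * n), n, 3)
    s <- generate_survival(cfg, eta = log(2) * zs, endpoint = "ttr")
    d <- toy_cohort(time = s$time, status = s$event, er = runif(n, 0, 100),
                    zs = zs, n1 = noise[, 1], n2 = noise[, 2], n3 = noise[, 3])
    fit <- backward_select(d, "ttr", c("zs", "n1", "n2", "n3"))
    kept_signal[i] <- !inherits(fit, "cox_fit_empty") &&
      "zs" %in% attr(fit, "selected")
  }
  expect_gte(mean(kept_signal), 0.95)

  # all-noise candidates: the modal outcome is the empty model
  set.seed(62)
  empty <- logical(100)
  for (i in 1:100) {
    n <- 300
    s <- generate_survival(cfg, eta = rep(0, n), endpoint = "ttr")
    d <- toy_cohort(time = s$time, status = s$event, er = runif(n, 0, 100),
                    n1 = rnorm(n), n2 = rnorm(n))
    empty[i] <- inherits(backward_select(d, "ttr", c("n1", "n2")),
                         "cox_fit_empty")
  }
  expect_gt(mean(empty), 0.5)

  # single-step determinism: the largest-p candidate is removed first
  set.seed(63)
  n <- 400
  zs <- rbinom(n, 1, 0.5); zn <- rnorm(n)
  s <- generate_survival(cfg, eta = 1.2 * zs, endpoint = "ttr")
  d <- toy_cohort(time = s$time, status = s$event, er = runif(n, 0, 100),
                  zs = zs, zn = zn)
  full <- fit_cox(d, "ttr", c("zs", "zn"))
  worst <- c("zs", "zn")[which.max(full$p)]
  sel <- backward_select(d, "ttr", c("zs", "zn"))
  expect_equal(attr(sel, "dropped")[1], worst)
})

test_that("multi-level factors are dropped as a block", {
  set.seed(71)
  ch <- generate_cohort(synthetic_config(n = 600, seed = 71))
  fit <- backward_select(ch, "ttr",
                         c("race", "stage", "lvi", "radiation", "pcr"))
  if (!inherits(fit, "cox_fit_empty") && "race" %in% attr(fit, "dropped")) {
    expect_false(any(grepl("^race", fit$covariate_names)))
  } else if (!inherits(fit, "cox_fit_empty")) {
    # if race is retained, all its contrasts are present
    expect_equal(sum(grepl("^race", fit$covariate_names)), 3)
  }
  succeed()
})

test_that("complete-case exclusion is applied and reported per model", {
  d <- toy_cohort(time = 1:8, status = c(1, 1, 0, 1, 1, 0, 1, 1),
                  er = seq(5, 75, by = 10),
                  xb = c(0, 1, NA, 1, 0, 1, NA, 0))
  fit <- fit_cox(d, "ttr", "xb")
  expect_equal(fit$n_used, 6)
  expect_equal(fit$n_excluded, 2)
})
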