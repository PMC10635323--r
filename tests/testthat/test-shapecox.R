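test_that("constant biomarker reduces the shape fit to the standard Cox fit", {
  set.seed(1)
  n <- 100
  d <- toy_cohort(time = rexp(n), status = rbinom(n, 1, 0.7), er = rep(42, n),
                  zb = rbinom(n, 1, 0.5))
  sfit <- fit_shape_restricted(d, "ttr", z = "zb")
  cfit <- fit_cox(d, "ttr", "zb")
  expect_equal(unname(sfit$beta), unname(cfit$beta), tolerance = 1e-8)
  expect_equal(sfit$curve$psi, 0)
  expect_equal(sfit$loglik, cfit$loglik, tolerance = 1e-8)
})

test_that("constrained fit matches the exhaustive pooling oracle (m = 4, no z)", {
  set.seed(42)
  for (rep in 1:4) {
    n <- 70
    x <- sample(c(0, 5, 15, 50), n, replace = TRUE)
    psi_true <- c(`0` = 0, `5` = -0.3, `15` = -0.8, `50` = -1.0)[as.character(x)]
    time <- rexp(n, exp(psi_true)); status <- rbinom(n, 1, 0.8)
    d <- toy_cohort(time = time, status = status, er = x)
    fit <- fit_shape_restricted(d, "ttr")
    oracle <- pooling_oracle(time, status, x)
    expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
    expect_equal(fit$curve$psi, oracle$psi, tolerance = 1e-3)
  }
})

test_that("constrained fit matches the pooling oracle with covariates (m = 5)", {
  set.seed(43)
  n <- 90
  x <- sample(c(0, 2, 8, 20, 60), n, replace = TRUE)
  zb <- rbinom(n, 1, 0.5)
  eta <- -0.02 * x + 0.6 * zb
  time <- rexp(n, exp(eta)); status <- rbinom(n, 1, 0.8)
  d <- toy_cohort(time = time, status = status, er = x, zb = zb)
  fit <- fit_shape_restricted(d, "ttr", z = "zb")
  oracle <- pooling_oracle(time, status, x, zmat = cbind(zb))
  expect_lt(abs(fit$loglik - oracle$loglik), 1e-4)
})

test_that("when the unconstrained per-level estimates are already monotone,
          the constraint is inactive", {
  set.seed(44)
  # steep true decline dominates noise so the factor fit is usually monotone;
  # keep a draw where it is
  for (attempt in 1:20) {
    n <- 400
    x <- sample(c(0, 10, 40, 90), n, replace = TRUE)
    psi_true <- c(`0` = 0, `10` = -1.2, `40` = -2.4, `90` = -3.6)[as.character(x)]
    time <- rexp(n, exp(psi_true)); status <- rbinom(n, 1, 0.9)
    fx <- factor(x)
    uf <- survival::coxph(survival::Surv(time, status) ~ fx, ties = "efron")
    vals <- c(0, unname(coef(uf)))
    if (all(diff(vals) <= 0)) break
  }
  expect_true(all(diff(vals) <= 0))  # found an already-monotone draw
  d <- toy_cohort(time = time, status = status, er = x)
  fit <- fit_shape_restricted(d, "ttr")
  expect_equal(fit$curve$psi, vals, tolerance = 1e-4)
  expect_lt(abs(fit$loglik - uf$loglik[2]), 1e-6)
})

test_that("shape fit nests any non-positive linear ER effect", {
  set.seed(45)
  for (rep in 1:3) {
    ch <- generate_cohort(synthetic_config(n = 300, seed = 45 + rep))
    lin <- fit_cox(ch, "ttr", "er")
    if (unname(lin$beta) <= 0) {
      sfit <- fit_shape_restricted(ch, "ttr")
      expect_gte(sfit$loglik, lin$loglik - 1e-8)
    }
  }
})

test_that("fitted curves are always feasible and the ascent trace is monotone", {
  set.seed(46)
  for (rep in 1:6) {
    n <- 150
    er <- generate_er(synthetic_config(), n)
    cfg <- synthetic_config(censoring = list(rate = 0.2, horizon = 14),
                            baseline = list(shape = 1.2, scale_ttr = 3,
                                            scale_os = 3))
    s <- generate_survival(cfg, eta = psi_knee(er, 10, 1), endpoint = "ttr")
    d <- toy_cohort(time = s$time, status = s$event, er = er,
                    zb = rbinom(n, 1, 0.3))
    fit <- fit_shape_restricted(d, "ttr", z = "zb")
    expect_true(all(diff(fit$curve$psi) <= 1e-10))
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_equal(fit$curve$psi[1], 0)
  }
})

test_that("curve contrasts behave like hazard ratios under the constraint", {
  set.seed(47)
  ch <- generate_cohort(synthetic_config(n = 400, seed = 47))
  fit <- fit_shape_restricted(ch, "ttr", round_x = TRUE)
  expect_equal(curve_hr(fit, 30, 30), 1.0)
  sup <- fit$curve$support
  for (pair in list(c(0, 10), c(5, 50), c(20, 80))) {
    x0 <- max(min(sup), pair[1]); x1 <- min(max(sup), pair[2])
    expect_lte(curve_hr(fit, x0, x1), 1)
  }
  expect_error(curve_hr(fit, -5, 10), "outside")
  expect_error(curve_hr(fit, 0, 101), "outside")
})

test_that("no-event data is rejected", {
  d <- toy_cohort(time = 1:5, status = rep(0, 5), er = c(0, 10, 20, 50, 80))
  expect_error(fit_shape_restricted(d, "ttr"), "no events")
})
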