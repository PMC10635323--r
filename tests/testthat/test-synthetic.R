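test_that("ER mixture reproduces the configured bin weights", {
  cfg <- synthetic_config(n = 10000, seed = 2)
  set.seed(2)
  er <- generate_er(cfg, 10000)
  expect_true(all(er >= 0 & er <= 100))
  frac <- as.vector(table(assign_er_category(er))) / 10000
  expect_true(all(abs(frac - cfg$er_mixture$weights) < 0.02))
  expect_length(generate_er(cfg, 0), 0)
})

test_that("upper ER component matches the truncated-normal mean by quadrature", {
  cfg <- synthetic_config(er_mixture = list(weights = c(0, 0, 0, 1),
                                            upper_mean = 83.3,
                                            upper_sd = 20.8))
  set.seed(5)
  er <- generate_er(cfg, 5000)
  expect_true(all(er >= 20 & er <= 100))
  # oracle: E[X | 20 <= X <= 100] for X ~ N(83.3, 20.8) by numerical integration
  dens <- function(x) dnorm(x, 83.3, 20.8)
  mass <- integrate(dens, 20, 100)$value
  mu <- integrate(function(x) x * dens(x), 20, 100)$value / mass
  expect_lt(abs(mean(er) - mu), 1.5)
})

test_that("covariates hit the configured prevalences and age range", {
  cfg <- synthetic_config(n = 10000, seed = 3)
  set.seed(3)
  z <- generate_covariates(cfg, 10000)
  expect_lt(abs(mean(z$stage == "III") - 0.435), 0.015)
  expect_lt(abs(mean(z$lvi) - 0.311), 0.015)
  expect_true(all(z$age >= 19 & z$age <= 83))
  # all-reference configuration
  cfg0 <- synthetic_config()
  cfg0$covariates$race <- c(White = 1, Black = 0, Hispanic = 0,
                            `Asian/other` = 0)
  cfg0$covariates$grade_iii <- 1; cfg0$covariates$stage_iii <- 1
  cfg0$covariates$lvi <- 0; cfg0$covariates$radiation <- 0
  cfg0$covariates$chemo <- 0
  set.seed(1)
  z0 <- generate_covariates(cfg0, 50)
  expect_true(all(z0$race == "White" & z0$grade == "III" &
                    z0$stage == "III" & z0$lvi == 0 & z0$radiation == 0))
})

test_that("null-model survival times are Weibull and effects are recoverable", {
  # psi = 0, beta = 0, no censoring: T ~ Weibull(shape, scale)
  cfg <- synthetic_config(baseline = list(shape = 1.2, scale_ttr = 2,
                                          scale_os = 2),
                          censoring = list(rate = 1e-12, horizon = Inf))
  set.seed(7)
  s <- generate_survival(cfg, eta = rep(0, 5000), endpoint = "ttr")
  expect_true(all(s$event == 1))
  ks <- suppressWarnings(ks.test(s$time, function(q)
    pweibull(q, shape = 1.2, scale = 2)))
  expect_lt(unname(ks$statistic), 0.02)

  # single binary covariate with log HR = log 2 is recovered by a Cox fit
  set.seed(8)
  zb <- rbinom(4000, 1, 0.5)
  s2 <- generate_survival(cfg, eta = log(2) * zb, endpoint = "ttr")
  d <- toy_cohort(time = s2$time, status = s2$event, er = runif(4000, 0, 100),
                  zb = zb)
  fit <- fit_cox(d, "ttr", "zb")
  expect_lt(abs(unname(fit$beta) - log(2)), 0.1)

  # degenerate administrative horizon censors everyone at 0
  cfg0 <- synthetic_config(censoring = list(rate = 0.1, horizon = 0))
  set.seed(9)
  s3 <- generate_survival(cfg0, eta = rep(0, 100), endpoint = "os")
  expect_true(all(s3$time == 0) && all(s3$event == 0))

  expect_error(generate_survival(cfg, eta = c(0, NA, 1)), "non-finite")
})

test_that("generate_cohort is deterministic and internally consistent", {
  cfg <- synthetic_config(n = 200, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, p1); write_cohort(b, p2)
  expect_identical(readLines(p1), readLines(p2))

  smoke <- generate_cohort(synthetic_config(n = 10, seed = 1))
  expect_s3_class(smoke, "er_cohort")  # constructor validates all invariants

  # configured truth is non-increasing by construction
  tr <- attr(a, "truth")
  x <- seq(0, 100, by = 0.5)
  for (ep in c("ttr", "os"))
    expect_true(all(diff(psi_knee(x, tr$psi_true[[ep]]$knee,
                                  tr$psi_true[[ep]]$depth)) <= 0))
  expect_error(synthetic_config(psi_true = list(ttr = list(knee = 10,
                                                           depth = -1),
                                                os = list(knee = 20,
                                                          depth = 1))),
               "depth")
  expect_error(synthetic_config(er_mixture = list(weights = c(0.5, 0.5, 0.1,
                                                              0.1))),
               "summing to 1")
})

test_that("default cohort matches the study's scale: events, ER-PR correlation", {
  ch <- generate_cohort(synthetic_config(seed = 31))
  # published cohort: 862 TTR events, 659 deaths among n = 3055 (+/- 15%)
  expect_lt(abs(sum(ch$ttr_event) - 862), 0.15 * 862)
  expect_lt(abs(sum(ch$os_event) - 659), 0.15 * 659)
  expect_lt(abs(spearman_correlation(ch$er, ch$pr) - 0.70), 0.08)
  # endocrine uptake rises steeply with ER, as configured
  uptake <- tapply(ch$endocrine, assign_er_category(ch$er), mean)
  expect_true(all(diff(uptake) > 0))
})
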