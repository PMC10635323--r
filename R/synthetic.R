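#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model for cohorts with the statistical structure of
#' the motivating study population: a large single-institution cohort of
#' stage II-III HER2-negative breast cancer patients treated with neoadjuvant
#' chemotherapy and surgery.  Continuous ER expression follows a four-part
#' mixture (point mass at 0; uniform on \[1,10) and \[10,20); truncated
#' normal on \[20,100\]); covariates are drawn at the study prevalences;
#' event times follow a Weibull-baseline proportional hazards model whose
#' log-hazard in ER is a known non-increasing "knee" function (linear drop of
#' depth `depth` over \[0, knee\], flat beyond), with the TTR knee at 10 and
#' the OS knee at 20; censoring is independent exponential truncated at an
#' administrative horizon.
#'
#' @param n cohort size.
#' @param seed integer seed; equal seeds give identical cohorts.
#' @param er_mixture list with `weights` (four probabilities for the ER bins
#'   `<1`, `1-10`, `10-20`, `>=20`, summing to 1), and `upper_mean`,
#'   `upper_sd` for the component on \[20,100\].
#' @param covariates list of prevalences: `race` (named probabilities),
#'   `grade_iii`, `stage_iii`, `lvi`, `radiation`, `chemo`, per-ER-bin
#'   `endocrine_by_er` and `pcr_by_er`, and `age_mean`, `age_sd`,
#'   `age_range` for truncated-normal age.
#' @param beta_true named lists `ttr` and `os` of true log hazard ratios for
#'   the covariate terms (`age` per year; `race_black`, `race_hispanic`,
#'   `race_asian` vs White; `grade_i_ii` vs III; `stage_ii` vs III; `lvi`;
#'   `radiation`; `pcr`).
#' @param psi_true lists `ttr` and `os` with `knee` (ER percent) and `depth`
#'   (>= 0, total log-hazard drop over \[0, knee\]).
#' @param therapy_hr hazard ratio of adjuvant endocrine therapy by ER level:
#'   `below` applies under ER `< 20`, `ge20` at ER `>= 20`.  The default is
#'   no effect (both 1), so the ER log-hazard curve of the default cohort is
#'   exactly the configured knee; subgroup/interaction experiments set
#'   `ge20` below 1 to emulate the study-like pattern of benefit
#'   concentrated above 20.
#' @param baseline list with Weibull `shape` and per-endpoint `scale_ttr`,
#'   `scale_os` (years); defaults calibrated so that a cohort of n = 3055
#'   yields event counts near the motivating study (862 TTR events, 659
#'   deaths).
#' @param censoring list with exponential `rate` (per year) and
#'   administrative `horizon` (years).
#' @param pr_realism logical; if `TRUE`, PR is generated by a normal copula
#'   on the ER ranks with the same marginal mixture, targeting a Spearman
#'   correlation near 0.70.
#' @param pr_rho copula correlation used when `pr_realism` is `TRUE`.
#' @param round_er logical; round ER to whole percents (coarsens the support
#'   of the nonparametric curve, a speed switch for large fits).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 3055,
                             seed = 1L,
                             er_mixture = list(
                               weights = c(0.305, 0.056, 0.022, 0.617),
                               upper_mean = 83.3, upper_sd = 20.8),
                             covariates = list(
                               race = c(White = 0.627, Black = 0.152,
                                        Hispanic = 0.158, `Asian/other` = 0.063),
                               grade_iii = 0.608, stage_iii = 0.435,
                               lvi = 0.311, radiation = 0.792, chemo = 0.151,
                               endocrine_by_er = c(0.092, 0.251, 0.806, 0.982),
                               pcr_by_er = c(0.263, 0.281, 0.104, 0.068),
                               age_mean = 49, age_sd = 10, age_range = c(19, 83)),
                             beta_true = list(
                               ttr = c(age = -0.018, race_black = 0.030,
                                       race_hispanic = -0.276, race_asian = -0.290,
                                       grade_i_ii = -0.361, stage_ii = -0.829,
                                       lvi = 0.715, radiation = -0.570,
                                       pcr = -1.463),
                               os = c(age = 0, race_black = 0.281,
                                      race_hispanic = -0.081, race_asian = -0.602,
                                      grade_i_ii = -0.351, stage_ii = -0.917,
                                      lvi = 0.615, radiation = -0.582,
                                      pcr = -1.655)),
                             psi_true = list(ttr = list(knee = 10, depth = 1.0),
                                             os = list(knee = 20, depth = 1.0)),
                             therapy_hr = list(below = 1.0, ge20 = 1.0),
                             baseline = list(shape = 1.2,
                                             scale_ttr = 3.1, scale_os = 4.2),
                             censoring = list(rate = 0.178, horizon = 14),
                             pr_realism = TRUE,
                             pr_rho = 0.74,
                             round_er = FALSE) {
  w <- er_mixture$weights
  if (length(w) != 4 || abs(sum(w) - 1) > 1e-9)
    stop("er_mixture$weights must be four probabilities summing to 1")
  if (any(w < 0)) stop("er_mixture weights must be non-negative")
  probs <- c(covariates$grade_iii, covariates$stage_iii, covariates$lvi,
             covariates$radiation, covariates$chemo,
             covariates$endocrine_by_er, covariates$pcr_by_er,
             covariates$race)
  if (any(probs < 0 | probs > 1)) stop("covariate probabilities must lie in [0, 1]")
  if (abs(sum(covariates$race) - 1) > 1e-9) stop("race probabilities must sum to 1")
  for (ep in c("ttr", "os"))
    if (psi_true[[ep]]$depth < 0)
      stop("psi_true depth must be >= 0 (non-increasing log hazard)")
  if (baseline$shape <= 0 || baseline$scale_ttr <= 0 || baseline$scale_os <= 0)
    stop("Weibull shape and scales must be positive")
  if (censoring$horizon < 0) stop("censoring horizon must be non-negative")
  structure(list(n = n, seed = as.integer(seed), er_mixture = er_mixture,
                 covariates = covariates, beta_true = beta_true,
                 psi_true = psi_true, therapy_hr = therapy_hr,
                 baseline = baseline, censoring = censoring,
                 pr_realism = pr_realism, pr_rho = pr_rho,
                 round_er = round_er),
            class = "synthetic_config")
}

#' True monotone log-hazard curve of the generator
#'
#' The "knee" shape: a linear drop of `depth` log-hazard units over ER in
#' \[0, `knee`\], flat beyond; anchored at 0 for ER = 0.
#'
#' @param x ER values.
#' @param knee knee location (ER percent).
#' @param depth total drop (>= 0).
#' @return psi(x), non-increasing in x.
#' @export
psi_knee <- function(x, knee, depth) -depth * pmin(x, knee) / knee

## Quantile function of the ER mixture (inverse CDF), used for inverse
## transform sampling and for the PR copula marginal.
.er_quantile <- function(u, mix) {
  w <- mix$weights
  cw <- cumsum(w)
  out <- numeric(length(u))
  i1 <- u <= cw[1]
  i2 <- !i1 & u <= cw[2]
  i3 <- !i1 & !i2 & u <= cw[3]
  i4 <- u > cw[3]
  out[i1] <- 0
  if (w[2] > 0) out[i2] <- 1 + 9 * (u[i2] - cw[1]) / w[2]
  if (w[3] > 0) out[i3] <- 10 + 10 * (u[i3] - cw[2]) / w[3]
  if (any(i4)) {
    pa <- stats::pnorm(20, mix$upper_mean, mix$upper_sd)
    pb <- stats::pnorm(100, mix$upper_mean, mix$upper_sd)
    v <- (u[i4] - cw[3]) / max(w[4], .Machine$double.eps)
    out[i4] <- stats::qnorm(pa + v * (pb - pa), mix$upper_mean, mix$upper_sd)
  }
  pmin(pmax(out, 0), 100)
}

#' Draw ER expression values
#'
#' Samples from the four-part ER mixture by inverse transform: point mass at
#' 0, uniform on \[1,10) and \[10,20), and a normal truncated to \[20,100\].
#'
#' @param config a [synthetic_config()].
#' @param n number of draws.
#' @return numeric vector in \[0, 100\].
#' @export
generate_er <- function(config, n = config$n) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n == 0) return(numeric(0))
  er <- .er_quantile(stats::runif(n), config$er_mixture)
  if (config$round_er) er <- round(er)
  er
}

#' Draw the clinical covariate table
#'
#' Independent draws at the configured prevalences; age is normal truncated
#' to the configured range.  If `er` is supplied, adjuvant endocrine therapy
#' and pCR are drawn with ER-category-specific probabilities (therapy uptake
#' and pCR rates vary strongly with ER in the motivating study); otherwise
#' the marginal rates implied by the mixture weights are used.
#'
#' @param config a [synthetic_config()].
#' @param n number of records.
#' @param er optional ER vector of length `n`.
#' @return a data frame with columns age, race, grade, stage, lvi,
#'   radiation, chemo, endocrine, pcr.
#' @export
generate_covariates <- function(config, n = config$n, er = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cv <- config$covariates
  if (n == 0)
    return(data.frame(age = numeric(0), race = factor(character(0), .race_levels),
                      grade = factor(character(0), c("III", "I/II")),
                      stage = factor(character(0), c("III", "II")),
                      lvi = integer(0), radiation = integer(0),
                      chemo = integer(0), endocrine = integer(0), pcr = integer(0)))
  rng <- cv$age_range
  pa <- stats::pnorm(rng[1], cv$age_mean, cv$age_sd)
  pb <- stats::pnorm(rng[2], cv$age_mean, cv$age_sd)
  age <- stats::qnorm(pa + stats::runif(n) * (pb - pa), cv$age_mean, cv$age_sd)
  race <- factor(sample(names(cv$race), n, replace = TRUE, prob = cv$race),
                 levels = .race_levels)
  grade <- factor(ifelse(stats::rbinom(n, 1, cv$grade_iii) == 1, "III", "I/II"),
                  levels = c("III", "I/II"))
  stage <- factor(ifelse(stats::rbinom(n, 1, cv$stage_iii) == 1, "III", "II"),
                  levels = c("III", "II"))
  if (is.null(er)) {
    w <- config$er_mixture$weights
    p_end <- sum(w * cv$endocrine_by_er)
    p_pcr <- sum(w * cv$pcr_by_er)
    endocrine <- stats::rbinom(n, 1, p_end)
    pcr <- stats::rbinom(n, 1, p_pcr)
  } else {
    bin <- as.integer(assign_er_category(er))
    endocrine <- stats::rbinom(n, 1, cv$endocrine_by_er[bin])
    pcr <- stats::rbinom(n, 1, cv$pcr_by_er[bin])
  }
  data.frame(age = age, race = race, grade = grade, stage = stage,
             lvi = stats::rbinom(n, 1, cv$lvi),
             radiation = stats::rbinom(n, 1, cv$radiation),
             chemo = stats::rbinom(n, 1, cv$chemo),
             endocrine = endocrine, pcr = pcr)
}

## True covariate linear predictor beta' z for one endpoint, plus the
## ER-dependent therapy effect.
.true_lp <- function(config, endpoint, z) {
  b <- config$beta_true[[endpoint]]
  lp <- b[["age"]] * (z$age - config$covariates$age_mean) +
    b[["race_black"]] * (z$race == "Black") +
    b[["race_hispanic"]] * (z$race == "Hispanic") +
    b[["race_asian"]] * (z$race == "Asian/other") +
    b[["grade_i_ii"]] * (z$grade == "I/II") +
    b[["stage_ii"]] * (z$stage == "II") +
    b[["lvi"]] * z$lvi +
    b[["radiation"]] * z$radiation +
    b[["pcr"]] * z$pcr
  as.numeric(lp)
}

.therapy_lp <- function(config, er, endocrine) {
  log_hr <- ifelse(er >= 20, log(config$therapy_hr$ge20),
                   log(config$therapy_hr$below))
  log_hr * endocrine
}

#' Draw censored survival times from the generative hazard model
#'
#' Event times follow the cumulative hazard
#' `Lambda(t) = (t / scale)^shape * exp(eta)` (inverse transform); censoring
#' is the minimum of an exponential draw and the administrative horizon.
#'
#' @param config a [synthetic_config()].
#' @param eta per-subject log relative hazard (`beta' z + psi(er)`).
#' @param endpoint `"ttr"` or `"os"` (selects the baseline scale).
#' @return a data frame with columns `time` and `event`.
#' @export
generate_survival <- function(config, eta, endpoint = c("ttr", "os")) {
  stopifnot(inherits(config, "synthetic_config"))
  endpoint <- match.arg(endpoint)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  n <- length(eta)
  b <- if (endpoint == "ttr") config$baseline$scale_ttr else config$baseline$scale_os
  k <- config$baseline$shape
  t_event <- b * (stats::rexp(n) * exp(-eta))^(1 / k)
  c_time <- pmin(stats::rexp(n, rate = config$censoring$rate),
                 config$censoring$horizon)
  data.frame(time = pmin(t_event, c_time),
             event = as.integer(t_event <= c_time))
}

#' Generate a full synthetic cohort
#'
#' Composes the ER, covariate and survival generators for both endpoints
#' (TTR with the knee at 10, OS with the knee at 20 by default) and the
#' optional PR copula.  All randomness flows through `config$seed`; equal
#' configurations give bitwise-identical cohorts.
#'
#' @param config a [synthetic_config()].
#' @return an [er_cohort()]; the true generating parameters are attached as
#'   attribute `"truth"` (a list with `beta_true`, `psi_true`, `therapy_hr`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n
  er <- generate_er(config, n)
  z <- generate_covariates(config, n, er = er)
  eta_ttr <- .true_lp(config, "ttr", z) +
    psi_knee(er, config$psi_true$ttr$knee, config$psi_true$ttr$depth) +
    .therapy_lp(config, er, z$endocrine)
  eta_os <- .true_lp(config, "os", z) +
    psi_knee(er, config$psi_true$os$knee, config$psi_true$os$depth) +
    .therapy_lp(config, er, z$endocrine)
  ttr <- generate_survival(config, eta_ttr, "ttr")
  os <- generate_survival(config, eta_os, "os")
  pr <- if (config$pr_realism && n > 0) {
    u_er <- (rank(er, ties.method = "random") - 0.5) / n
    z1 <- stats::qnorm(u_er)
    z2 <- config$pr_rho * z1 + sqrt(1 - config$pr_rho^2) * stats::rnorm(n)
    .er_quantile(stats::pnorm(z2), config$er_mixture)
  } else rep(NA_real_, n)
  out <- data.frame(id = as.character(seq_len(n)),
                    ttr_time = ttr$time, ttr_event = ttr$event,
                    os_time = os$time, os_event = os$event,
                    er = er, pr = pr, z,
                    stringsAsFactors = FALSE)
  cohort <- er_cohort(out, provenance = sprintf("synthetic(seed=%d, n=%d)",
                                                config$seed, n))
  attr(cohort, "truth") <- list(beta_true = config$beta_true,
                                psi_true = config$psi_true,
                                therapy_hr = config$therapy_hr)
  cohort
}

#' Published margins of the motivating cohort
#'
#' Per-ER-category counts for the descriptive characteristics of the
#' motivating cohort of 3055 stage II-III HER2-negative breast cancer
#' patients (ER categories `<1`, `1-10`, `10-20`, `>=20`).  `NA` counts are
#' recorded separately where the published table lists "Unknown" rows.
#'
#' @return a list of named count vectors.
#' @export
cohort_margins <- function() {
  list(
    n = c(932, 171, 67, 1885),
    pcr_yes = c(245, 48, 7, 129),
    endocrine_yes = c(86, 43, 54, 1852),
    radiation_yes = c(695, 121, 53, 1550),
    chemo_yes = c(162, 16, 9, 274),
    stage_iii = c(421, 72, 31, 805),
    lvi_pos = c(254, 36, 20, 605),
    lvi_unknown = c(47, 11, 2, 50),
    grade_iii = c(813, 148, 49, 793),
    grade_unknown = c(28, 4, 3, 54),
    race_white = c(565, 97, 33, 1220),
    race_black = c(197, 35, 15, 216),
    race_hispanic = c(128, 25, 15, 315),
    race_asian = c(42, 14, 4, 134))
}

#' Fixture cohort reproducing the published margins
#'
#' Builds a deterministic cohort whose per-ER-category covariate counts match
#' [cohort_margins()] exactly (variables are assigned independently within
#' category; only the margins are meaningful).  ER values are set to a
#' representative value per category; survival columns are placeholders.
#' Intended for exercising descriptive summaries, not for model fitting.
#'
#' @return an [er_cohort()].
#' @export
margins_fixture_cohort <- function() {
  m <- cohort_margins()
  er_rep <- c(0, 5, 15, 50)
  fill <- function(n, n_yes, n_na = 0) {
    # first n_yes records 1, then 0s, then NAs
    c(rep(1L, n_yes), rep(0L, n - n_yes - n_na), rep(NA_integer_, n_na))
  }
  blocks <- lapply(1:4, function(b) {
    n <- m$n[b]
    race <- c(rep("White", m$race_white[b]), rep("Black", m$race_black[b]),
              rep("Hispanic", m$race_hispanic[b]),
              rep("Asian/other", m$race_asian[b]))
    length(race) <- n  # pad with NA if rows unaccounted for
    grade <- ifelse(is.na(fill(n, m$grade_iii[b], m$grade_unknown[b])), NA,
                    ifelse(fill(n, m$grade_iii[b], m$grade_unknown[b]) == 1,
                           "III", "I/II"))
    data.frame(
      ttr_time = 1, ttr_event = 0L, os_time = 1, os_event = 0L,
      er = er_rep[b],
      race = race,
      grade = grade,
      stage = ifelse(fill(n, m$stage_iii[b]) == 1, "III", "II"),
      lvi = fill(n, m$lvi_pos[b], m$lvi_unknown[b]),
      radiation = fill(n, m$radiation_yes[b]),
      endocrine = fill(n, m$endocrine_yes[b]),
      chemo = fill(n, m$chemo_yes[b]),
      pcr = fill(n, m$pcr_yes[b]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out$id <- as.character(seq_len(nrow(out)))
  er_cohort(out, provenance = "published-margins fixture")
}
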