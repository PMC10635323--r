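# Hand-coded oracles, independent of the package internals and of the
# survival package.  Deliberately slow and explicit.

# Breslow/exact partial log-likelihood for a single covariate with no tied
# event times: sum over events of x_i b - log(sum_{j in risk set} exp(x_j b)).
hand_pl_untied <- function(time, status, x, beta) {
  stopifnot(!anyDuplicated(time[status == 1]))
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# grid-search maximizer of the hand-coded partial likelihood
grid_cox_mle <- function(time, status, x, grid = seq(-5, 5, by = 1e-4)) {
  ll <- vapply(grid, function(b) hand_pl_untied(time, status, x, b), numeric(1))
  grid[which.max(ll)]
}

# hand product-limit estimator: returns S at the distinct event times
hand_km <- function(times, events) {
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    t <- ev_times[k]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out[k] <- s
  }
  list(time = ev_times, surv = out)
}

# hand log-rank chi-squared for k groups: accumulate per-event-time
# hypergeometric observed-minus-expected and covariance, then the quadratic
# form over the first k-1 groups
hand_logrank <- function(times, events, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  ev_times <- sort(unique(times[events == 1]))
  OE <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    n_g <- vapply(levels(g), function(l) sum(at_risk & g == l), numeric(1))
    d_g <- vapply(levels(g), function(l)
      sum(times == t & events == 1 & g == l), numeric(1))
    OE <- OE + d_g - d * n_g / n
    if (n > 1) {
      c_t <- d * (n - d) / (n - 1)
      V <- V + c_t * (diag(n_g / n) - outer(n_g, n_g) / n^2)
    }
  }
  i <- seq_len(k - 1)
  stat <- as.numeric(t(OE[i]) %*% solve(V[i, i, drop = FALSE], OE[i]))
  list(statistic = stat, df = k - 1,
       p = pchisq(stat, k - 1, lower.tail = FALSE),
       observed_minus_expected = OE)
}

# exhaustive monotone-pooling oracle for the shape-restricted fit at small m:
# every contiguous partition of the ordered levels is fitted as an
# unconstrained factor model (pooled levels share a value, optionally with
# covariates z); among partitions whose fitted values are non-increasing, the
# best log partial likelihood is the constrained maximum.
pooling_oracle <- function(time, status, x, zmat = NULL) {
  levs <- sort(unique(x))
  m <- length(levs)
  lev_idx <- match(x, levs)
  best <- -Inf
  best_psi <- NULL
  for (code in 0:(2^(m - 1) - 1)) {
    cuts <- as.logical(bitwAnd(code, 2^(0:(m - 2))) > 0)
    blk <- cumsum(c(1, cuts))[lev_idx]
    nb <- max(blk)
    if (nb == 1) {
      if (is.null(zmat)) {
        f <- survival::coxph(survival::Surv(time, status) ~ 1)
        ll <- f$loglik[1]
      } else {
        f <- survival::coxph(survival::Surv(time, status) ~ zmat,
                             ties = "efron")
        ll <- f$loglik[2]
      }
      vals <- rep(0, nb)
    } else {
      fb <- factor(blk)
      f <- if (is.null(zmat))
        survival::coxph(survival::Surv(time, status) ~ fb, ties = "efron",
                        control = survival::coxph.control(iter.max = 100))
      else
        survival::coxph(survival::Surv(time, status) ~ fb + zmat,
                        ties = "efron",
                        control = survival::coxph.control(iter.max = 100))
      cf <- unname(stats::coef(f))
      vals <- c(0, cf[seq_len(nb - 1)])
      ll <- f$loglik[2]
    }
    if (any(diff(vals) > 1e-9)) next      # infeasible: not non-increasing
    if (is.finite(ll) && ll > best) {
      best <- ll
      best_psi <- vals[cumsum(c(1, cuts))]
    }
  }
  list(loglik = best, psi = best_psi, support = levs)
}

# small deterministic survival frame with both endpoints
toy_cohort <- function(time, status, er, ...) {
  extra <- list(...)
  d <- data.frame(ttr_time = time, ttr_event = status,
                  os_time = time, os_event = status, er = er)
  for (nm in names(extra)) d[[nm]] <- extra[[nm]]
  d
}
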