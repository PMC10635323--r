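## Efron-tie-corrected Cox partial likelihood as a function of the per-subject
## linear predictor eta, together with its gradient and (diagonal) curvature in
## eta.  These are the building blocks of the shape-restricted fit: the monotone
## step function psi enters the model only through eta, so its block update
## needs d l / d eta aggregated over subjects sharing a biomarker level.

## Precompute the ordering and tie structure once per dataset.
## time/status are subject-level vectors; returns an environment-free list.
pl_prepare <- function(time, status) {
  stopifnot(length(time) == length(status), all(status %in% c(0, 1)))
  ord <- order(time, -status)  # within a time, events listed first (cosmetic)
  time <- time[ord]
  status <- status[ord]
  ev_times <- unique(time[status == 1])
  k <- findInterval(time, ev_times)          # last event time index <= t_i
  # death-set index: which distinct event time subject i dies at (0 if none)
  dk <- integer(length(time))
  dk[status == 1] <- match(time[status == 1], ev_times)
  list(ord = ord, time = time, status = status,
       ev_times = ev_times, n_ev_times = length(ev_times),
       risk_k = k, death_k = dk)
}

## Core quantities at a given eta (in the *original* subject order).
## Returns loglik, gradient and negative diagonal Hessian w.r.t. eta,
## both mapped back to the original order.
pl_eval <- function(prep, eta, what = c("loglik", "grad")) {
  what <- match.arg(what, several.ok = TRUE)
  eta_s <- eta[prep$ord]
  status <- prep$status
  m <- prep$n_ev_times
  if (m == 0L) stop("no events in the data")
  w <- exp(eta_s)
  # risk-set sums S_R(t_k): total exp(eta) among time >= t_k.
  # subjects are sorted by time; risk_k[i] >= k  <=>  time_i >= ev_times[k]
  # (every subject with time >= ev_times[k] has last-event index >= k).
  tot <- sum(w)
  # cumulative exp(eta) over subjects with risk_k < k, i.e. time < ev_times[k]
  below <- rowsum_safe(w, prep$risk_k, 0:m)       # sums by risk_k value 0..m
  # cumsum(below)[k] = total exp(eta) among subjects with risk_k <= k-1,
  # i.e. time < ev_times[k]; S_R[k] is the complement.
  S_R <- tot - cumsum(below)[seq_len(m)]
  # death-set sums and sizes
  dsel <- status == 1
  S_D <- rowsum_safe(w[dsel], prep$death_k[dsel], 1:m)
  d_k <- rowsum_safe(rep(1, sum(dsel)), prep$death_k[dsel], 1:m)
  # Efron denominators: for each event time k and l = 0..d_k-1:
  #   denom_{k,l} = S_R[k] - (l/d_k) * S_D[k]
  kk <- rep.int(seq_len(m), d_k)
  ll <- sequence(d_k) - 1
  frac <- ll / d_k[kk]
  denom <- S_R[kk] - frac * S_D[kk]
  if (any(!is.finite(denom) | denom <= 0)) {
    # degenerate linear predictor (overflow/underflow); a loglik-only query
    # reports -Inf so that a line search can reject the point
    if (identical(what, "loglik")) return(list(loglik = -Inf))
    stop("non-positive or non-finite Efron denominator")
  }
  out <- list()
  if ("loglik" %in% what)
    out$loglik <- sum(eta_s[dsel]) - sum(log(denom))
  if ("grad" %in% what) {
    inv <- 1 / denom
    inv2 <- inv * inv
    A <- rowsum_safe(inv,          kk, 1:m)
    B <- rowsum_safe(frac * inv,   kk, 1:m)
    C <- rowsum_safe(inv2,         kk, 1:m)
    E <- rowsum_safe(frac * inv2,  kk, 1:m)
    F_ <- rowsum_safe(frac^2 * inv2, kk, 1:m)
    cumA <- c(0, cumsum(A))[prep$risk_k + 1L]
    cumC <- c(0, cumsum(C))[prep$risk_k + 1L]
    Bi <- Ci2 <- numeric(length(eta_s))
    Bi[dsel] <- B[prep$death_k[dsel]]
    Ci2[dsel] <- (2 * E - F_)[prep$death_k[dsel]]
    g_s <- status - w * (cumA - Bi)
    # negative diagonal second derivative (>= 0 for a concave loglik)
    h_s <- w * (cumA - Bi) - w^2 * (cumC - Ci2)
    g <- h <- numeric(length(eta_s))
    g[prep$ord] <- g_s
    h[prep$ord] <- h_s
    out$grad <- g
    out$neg_hess_diag <- pmax(h, 0)
  }
  out
}

## sum `x` by integer group `g`, over the fixed set of `levels` (zeros where
## a level is absent) -- base rowsum() drops absent levels.
rowsum_safe <- function(x, g, levels) {
  out <- numeric(length(levels))
  if (length(x)) {
    s <- rowsum(x, match(g, levels))
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

## survival's matrix-level Newton fitter (the engine behind coxph), bound
## once at load time; used for the repeated beta updates inside the
## shape-restricted fit where formula processing would dominate.
cox_mat_fit <- NULL
.onLoad <- function(libname, pkgname) {
  cox_mat_fit <<- utils::getFromNamespace("coxph.fit", "survival")
}

## Weighted pooled-adjacent-violators: least-squares projection of y onto
## non-decreasing sequences with weights w > 0.  Stack-based, O(n).
pava_increasing <- function(y, w) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      wsum <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / wsum
      wt[top - 1L] <- wsum
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep.int(val[seq_len(top)], sz[seq_len(top)])
}

## Projection onto non-increasing sequences.
pava_decreasing <- function(y, w) -pava_increasing(-y, w)
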