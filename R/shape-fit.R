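#' Monotone step-function log-hazard curve
#'
#' A non-increasing step function psi(x) = log r(x) on the distinct observed
#' values of the biomarker, anchored so that psi at the smallest support
#' point is exactly 0 (the baseline hazard absorbs the level; exp(psi) is
#' then a hazard ratio relative to the lowest observed biomarker value).
#' Evaluation between support points is a right-continuous step: the value
#' of the nearest support point to the left.
#'
#' @param support strictly increasing distinct biomarker values.
#' @param psi values psi(support), non-increasing.
#' @param weights optional non-negative weights per support point (the
#'   number of subjects observed at each value); used by
#'   [detect_threshold()] so that sparsely observed levels do not dominate
#'   the segment fit.
#' @return an object of class `monotone_curve`.
#' @export
monotone_curve <- function(support, psi, weights = NULL) {
  stopifnot(length(support) == length(psi), length(support) >= 1)
  if (is.unsorted(support, strictly = TRUE))
    stop("support must be strictly increasing")
  if (any(diff(psi) > 1e-10))
    stop("psi must be non-increasing over the support")
  if (!is.null(weights))
    stopifnot(length(weights) == length(support), all(weights >= 0))
  psi <- psi - psi[1]
  structure(list(support = support, psi = psi, weights = weights,
                 anchor = "psi(min support) = 0",
                 direction = "non-increasing"),
            class = "monotone_curve")
}

#' Evaluate a monotone curve
#'
#' @param curve a [monotone_curve()].
#' @param x values within the support range (no extrapolation).
#' @return psi(x).
#' @export
curve_eval <- function(curve, x) {
  stopifnot(inherits(curve, "monotone_curve"))
  rng <- range(curve$support)
  if (any(x < rng[1] | x > rng[2]))
    stop("query outside the curve support [", rng[1], ", ", rng[2], "]")
  curve$psi[findInterval(x, curve$support)]
}

#' Hazard ratio between two biomarker values on the fitted curve
#'
#' Computes exp(psi(x1) - psi(x0)); by the monotone constraint this is
#' at most 1 whenever `x1 >= x0` (higher ER never raises hazard).
#'
#' @param fit a [fit_shape_restricted()] result (or a `monotone_curve`).
#' @param x0,x1 biomarker values within the support range.
#' @return the hazard ratio.
#' @export
curve_hr <- function(fit, x0, x1) {
  curve <- if (inherits(fit, "monotone_curve")) fit else fit$curve
  exp(curve_eval(curve, x1) - curve_eval(curve, x0))
}

#' @export
print.monotone_curve <- function(x, ...) {
  cat("Monotone non-increasing log-hazard curve:",
      length(x$support), "support points on [",
      min(x$support), ",", max(x$support), "]\n")
  cat("  total drop:", round(-min(x$psi), 3), "log-hazard units (HR",
      round(exp(min(x$psi)), 3), "at the top of the range)\n")
  invisible(x)
}

#' @export
plot.monotone_curve <- function(x, xlab = "ER expression (%)",
                                ylab = expression(psi(x) == log~r(x)), ...) {
  graphics::plot(x$support, x$psi, type = "s", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Export a monotone curve as a data frame
#'
#' @param x a `monotone_curve`.
#' @param ... unused.
#' @return data frame with columns x, psi, hr_vs_anchor.
#' @export
as.data.frame.monotone_curve <- function(x, ...) {
  data.frame(x = x$support, psi = x$psi, hr_vs_anchor = exp(x$psi))
}

#' Shape-restricted Cox regression
#'
#' Maximizes the Efron-corrected Cox partial likelihood over (beta, psi),
#' where beta are ordinary log hazard ratios for the covariates `z` and psi
#' is a step function on the distinct observed values of the continuous
#' biomarker `x`, constrained to be non-increasing and anchored at 0 for
#' the smallest observed value.  The hazard model is
#' `lambda(t | x, z) = lambda0(t) exp(beta' z) r(x)` with `psi = log r`.
#'
#' Algorithm: block coordinate ascent.  Given psi, beta is updated by
#' Newton-Raphson on the partial likelihood with psi as an offset; given
#' beta, psi is updated by an iterative-convex-minorant step — the diagonal
#' quadratic approximation of the partial likelihood in psi is projected
#' onto the monotone cone by weighted pooled-adjacent-violators — with
#' step-halving to guarantee ascent.  The log-likelihood trace is recorded
#' and is non-decreasing by construction.
#'
#' @param cohort an [er_cohort()] or data frame.
#' @param endpoint `"ttr"` or `"os"`.
#' @param x name of the continuous biomarker column (default `"er"`).
#' @param z character vector of covariate names (may be empty).
#' @param round_x round the biomarker to whole percents before forming the
#'   support (coarsens the step function; a speed switch for large cohorts).
#' @param tol convergence tolerance on the log-likelihood improvement over a
#'   full sweep.
#' @param max_sweeps maximum number of sweeps.
#' @param init optional warm start: a list (or previous fit) with elements
#'   `beta` and `curve`; used by [bootstrap_inference()] to start replicate
#'   fits at the base estimate.
#' @return an object of class `shape_cox_fit`: `beta`, `curve` (a
#'   [monotone_curve()]), `loglik`, `loglik_trace`, `converged`,
#'   `iterations`, `n_used`, `n_events`; bootstrap fields (`se`, `ci95`,
#'   `p`, `n_boot`) are filled by [bootstrap_inference()].
#' @export
fit_shape_restricted <- function(cohort, endpoint = c("ttr", "os"),
                                 x = "er", z = character(0),
                                 round_x = FALSE,
                                 tol = 1e-8, max_sweeps = 500,
                                 init = NULL) {
  endpoint <- match.arg(endpoint)
  data <- as.data.frame(cohort)
  tv <- paste0(endpoint, "_time"); ev <- paste0(endpoint, "_event")
  stopifnot(all(c(tv, ev, x) %in% names(data)))
  zvars <- unique(unlist(strsplit(z, "[:*]")))
  cc <- stats::complete.cases(data[c(tv, ev, x, zvars)])
  d <- data[cc, , drop = FALSE]
  n <- nrow(d)
  time <- d[[tv]]; status <- d[[ev]]
  if (sum(status) < 1) stop("no events in the data")
  xv <- d[[x]]
  if (round_x) xv <- round(xv)
  support <- sort(unique(xv))
  m <- length(support)
  g <- match(xv, support)
  prep <- pl_prepare(time, status)
  has_z <- length(z) > 0
  if (has_z) {
    fml <- stats::as.formula(paste("~", paste(z, collapse = "+")))
    X <- stats::model.matrix(fml, d)[, -1, drop = FALSE]
    if (qr(X)$rank < ncol(X))
      stop("rank deficiency in z design matrix")
  }
  psi <- numeric(m)
  beta <- if (has_z) numeric(ncol(X)) else numeric(0)
  if (!is.null(init)) {  # warm start, e.g. from the base fit in a bootstrap
    if (!is.null(init$curve)) {
      rng <- range(init$curve$support)
      psi <- curve_eval(init$curve, pmin(pmax(support, rng[1]), rng[2]))
      psi <- rev(cummax(rev(psi)))  # guard monotonicity across re-mapping
      psi <- psi - psi[1]
    }
    if (has_z && !is.null(init$beta) && length(init$beta) == ncol(X))
      beta <- unname(init$beta)
  }
  eta_z <- if (has_z) as.numeric(X %*% beta) else numeric(n)
  ll <- pl_eval(prep, eta_z + psi[g], "loglik")$loglik
  trace <- ll
  converged <- FALSE
  sweeps <- 0L
  sdf <- d  # survival frame for the beta step
  for (sweep in seq_len(max_sweeps)) {
    sweeps <- sweep
    # (a) Newton update of beta with psi as offset (full inner maximization;
    # the matrix-level fitter skips the per-sweep formula/model-frame cost)
    if (has_z) {
      cfit <- cox_mat_fit(X, survival::Surv(time, status), strata = NULL,
                          offset = psi[g], init = beta,
                          control = survival::coxph.control(eps = 1e-9,
                                                            iter.max = 100),
                          weights = NULL, method = "efron", rownames = NULL)
      beta <- unname(cfit$coefficients)
      eta_z <- as.numeric(X %*% beta)
      ll <- pl_eval(prep, eta_z + psi[g], "loglik")$loglik
    }
    # (b) ICM update of psi: diagonal quadratic + weighted PAVA + step-halving
    ev_ <- pl_eval(prep, eta_z + psi[g], c("loglik", "grad"))
    gr_j <- rowsum_safe(ev_$grad, g, seq_len(m))
    # inflating the weight (rather than capping the step) keeps the PAVA
    # projection of psi + g/w an ascent direction while bounding the move
    # for near-empty levels with vanishing curvature
    w_j <- pmax(rowsum_safe(ev_$neg_hess_diag, g, seq_len(m)),
                abs(gr_j) / 5, 1e-10)
    target <- psi + gr_j / w_j
    prop <- pava_decreasing(target, w_j)
    s <- 1
    repeat {
      psi_try <- psi + s * (prop - psi)
      ll_try <- pl_eval(prep, eta_z + psi_try[g], "loglik")$loglik
      if (ll_try >= ll) { psi <- psi_try; ll <- ll_try; break }
      s <- s / 2
      if (s < 1e-12) break  # no ascent possible from this direction
    }
    psi <- psi - psi[1]  # re-anchor (partial likelihood is shift-invariant)
    trace <- c(trace, ll)
    if (trace[length(trace)] - trace[length(trace) - 1] < tol &&
        sweep > 1) { converged <- TRUE; break }
  }
  # enforce exact feasibility against roundoff
  psi <- rev(cummax(rev(psi)))
  psi <- psi - psi[1]
  names(beta) <- if (has_z) colnames(X)
  structure(list(beta = beta, covariate_names = names(beta), covariates = z,
                 curve = monotone_curve(support, psi,
                                        weights = tabulate(g, nbins = m)),
                 loglik = ll, loglik_trace = trace,
                 converged = converged, iterations = sweeps,
                 n_used = n, n_events = sum(status),
                 n_excluded = sum(!cc),
                 endpoint = endpoint, x = x, round_x = round_x,
                 se = rep(NA_real_, length(beta)),
                 ci95 = NULL, p = NULL, n_boot = 0L),
            class = "shape_cox_fit")
}

#' @export
print.shape_cox_fit <- function(x, ...) {
  cat("Shape-restricted Cox fit (", toupper(x$endpoint), "): n =", x$n_used,
      ", events =", x$n_events, "\n")
  cat("  log partial likelihood:", round(x$loglik, 3),
      if (x$converged) paste0("(converged in ", x$iterations, " sweeps)")
      else paste0("(NOT converged after ", x$iterations, " sweeps)"), "\n")
  print(x$curve)
  if (length(x$beta)) {
    if (x$n_boot > 0) {
      cat("  covariates (bootstrap inference, ", x$n_boot, " replicates):\n")
      print(data.frame(term = x$covariate_names,
                       coef = round(x$beta, 3), se = round(x$se, 3),
                       hr = round(exp(x$beta), 3),
                       ci_lower = round(x$ci95[, 1], 3),
                       ci_upper = round(x$ci95[, 2], 3),
                       p = signif(x$p, 3), row.names = NULL),
            row.names = FALSE)
    } else {
      cat("  covariate coefficients (run bootstrap_inference() for SEs):\n")
      print(round(stats::setNames(x$beta, x$covariate_names), 4))
    }
  }
  invisible(x)
}
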