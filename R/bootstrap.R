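#' Bootstrap inference for the shape-restricted Cox fit
#'
#' Nonparametric bootstrap: subjects are resampled with replacement and the
#' shape-restricted model is refit per replicate.  The standard error of
#' each covariate coefficient is the standard deviation of its estimates
#' across replicates; 95\% confidence intervals and two-sided p-values use
#' the normal approximation `beta_hat +/- 1.96 * SE_boot`.  Inference is
#' reported for the parametric coefficients only; the nonparametric curve's
#' pointwise replicate spread is returned as an exploratory band.
#'
#' @param cohort the cohort the base fit was computed on.
#' @param endpoint `"ttr"` or `"os"`.
#' @param x,z as in [fit_shape_restricted()].
#' @param n_boot number of bootstrap replicates (default 200).
#' @param seed integer seed; equal seeds give identical SEs.
#' @param base_fit optional precomputed [fit_shape_restricted()] result.
#' @param round_x,tol,max_sweeps passed to [fit_shape_restricted()].
#' @param max_fail_frac maximum tolerated fraction of non-converged
#'   replicates (dropped and counted) before an error is raised.
#' @return the base `shape_cox_fit` updated with `se`, `ci95`, `p`,
#'   `n_boot`, `n_failed`, `boot_beta` (replicate matrix) and `curve_band`
#'   (exploratory pointwise 2.5/97.5 percentiles of psi on the support).
#' @export
bootstrap_inference <- function(cohort, endpoint = c("ttr", "os"), x = "er",
                                z = character(0), n_boot = 200, seed = 1L,
                                base_fit = NULL, round_x = FALSE,
                                tol = 1e-8, max_sweeps = 500,
                                max_fail_frac = 0.10) {
  endpoint <- match.arg(endpoint)
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (is.null(base_fit))
    base_fit <- fit_shape_restricted(cohort, endpoint, x = x, z = z,
                                     round_x = round_x, tol = tol,
                                     max_sweeps = max_sweeps)
  if (!base_fit$converged)
    stop("base fit did not converge; bootstrap inference not meaningful")
  data <- as.data.frame(cohort)
  n <- nrow(data)
  p <- length(base_fit$beta)
  set.seed(seed)
  boot_beta <- matrix(NA_real_, n_boot, p,
                      dimnames = list(NULL, base_fit$covariate_names))
  boot_psi <- vector("list", n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(
      fit_shape_restricted(data[idx, , drop = FALSE], endpoint, x = x, z = z,
                           round_x = round_x, tol = tol,
                           max_sweeps = max_sweeps, init = base_fit),
      error = function(e) NULL)
    if (is.null(rep_fit) || !rep_fit$converged) { n_failed <- n_failed + 1L; next }
    if (p > 0) boot_beta[b, ] <- rep_fit$beta
    boot_psi[[b]] <- rep_fit$curve
  }
  if (n_failed > max_fail_frac * n_boot)
    stop(n_failed, " of ", n_boot, " bootstrap replicates failed to converge")
  ok <- if (p > 0) stats::complete.cases(boot_beta) else
    !vapply(boot_psi, is.null, logical(1))
  if (p > 0) {
    se <- apply(boot_beta[ok, , drop = FALSE], 2, stats::sd)
    base_fit$se <- se
    base_fit$ci95 <- cbind(lower = exp(base_fit$beta - 1.96 * se),
                           upper = exp(base_fit$beta + 1.96 * se))
    base_fit$p <- 2 * stats::pnorm(-abs(base_fit$beta / se))
    base_fit$hr <- exp(base_fit$beta)
  }
  # exploratory pointwise curve band on the base support
  sup <- base_fit$curve$support
  psi_mat <- t(vapply(boot_psi[ok], function(cv) {
    rng <- range(cv$support)
    xq <- pmin(pmax(sup, rng[1]), rng[2])  # clamp: resampled support may shrink
    curve_eval(cv, xq)
  }, numeric(length(sup))))
  base_fit$curve_band <- data.frame(
    x = sup,
    lower = apply(psi_mat, 2, stats::quantile, 0.025),
    upper = apply(psi_mat, 2, stats::quantile, 0.975))
  base_fit$n_boot <- as.integer(n_boot)
  base_fit$n_failed <- n_failed
  base_fit$boot_beta <- boot_beta[ok, , drop = FALSE]
  base_fit
}
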