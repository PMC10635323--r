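#' Threshold (knee) detection on a fitted monotone curve
#'
#' Locates the biomarker value beyond which the fitted log-hazard curve is
#' approximately flat — the candidate clinical cutoff.
#'
#' `"two_segment"`: fits a continuous two-piece linear function to
#' (support, psi) by least squares, scanning every interior support point as
#' the candidate breakpoint, and returns the SSE-minimizing breakpoint;
#' `flat_beyond` is `TRUE` when the second segment's slope magnitude is
#' below 10\% of the first's.  When the curve carries observation weights
#' (as fitted curves do), the fit is weighted by them, so that thinly
#' populated support levels — where the nonparametric estimate is noisiest
#' — do not dominate the breakpoint choice.  When no breakpoint improves on
#' a single line (e.g. an exactly linear curve), the breakpoint is reported
#' at the upper support boundary with `flat_beyond = FALSE`.
#'
#' `"relative_flatness"`: the smallest support value where the remaining
#' total decrease of psi is below 5\% of its total range.
#'
#' @param curve a [monotone_curve()] (or a `shape_cox_fit`).
#' @param method `"two_segment"` (default) or `"relative_flatness"`.
#' @return an object of class `threshold_estimate`: `cutoff`, `method`,
#'   `criterion` (SSE of the best two-segment fit, or the relative-decrease
#'   fraction), `flat_beyond`, and for `two_segment` the two `slopes`.
#' @export
detect_threshold <- function(curve, method = c("two_segment",
                                               "relative_flatness")) {
  if (inherits(curve, "shape_cox_fit")) curve <- curve$curve
  stopifnot(inherits(curve, "monotone_curve"))
  method <- match.arg(method)
  xs <- curve$support
  ys <- curve$psi
  m <- length(xs)
  if (m < 4) stop("need at least 4 support points for threshold detection")
  if (method == "relative_flatness") {
    total <- ys[1] - ys[m]
    if (total <= 0) {
      return(structure(list(cutoff = xs[m], method = method, criterion = 0,
                            flat_beyond = FALSE),
                       class = "threshold_estimate"))
    }
    remaining <- ys - ys[m]
    j <- which(remaining < 0.05 * total)[1]
    return(structure(list(cutoff = xs[j], method = method,
                          criterion = remaining[j] / total,
                          flat_beyond = TRUE),
                     class = "threshold_estimate"))
  }
  # two-segment continuous piecewise-linear least squares via hinge basis,
  # weighted by per-level observation counts when available
  w <- if (is.null(curve$weights)) rep(1, m) else pmax(curve$weights, 0)
  single <- stats::lm.wfit(cbind(1, xs), ys, w)
  sse1 <- sum(w * single$residuals^2)
  cand <- xs[2:(m - 1)]
  sse <- slope1 <- slope2 <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    h <- pmax(xs - cand[i], 0)
    f <- stats::lm.wfit(cbind(1, xs, h), ys, w)
    sse[i] <- sum(w * f$residuals^2)
    slope1[i] <- f$coefficients[2]
    slope2[i] <- f$coefficients[2] + f$coefficients[3]
  }
  best <- which.min(sse)
  improved <- sse[best] < sse1 - 1e-12 * max(1, sse1)
  if (!improved) {
    return(structure(list(cutoff = xs[m], method = method, criterion = sse1,
                          flat_beyond = FALSE,
                          slopes = c(single$coefficients[2],
                                     single$coefficients[2])),
                     class = "threshold_estimate"))
  }
  structure(list(cutoff = cand[best], method = method, criterion = sse[best],
                 flat_beyond = abs(slope2[best]) < 0.10 * abs(slope1[best]),
                 slopes = c(first = slope1[best], second = slope2[best])),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat("Threshold estimate (", x$method, "): cutoff =", round(x$cutoff, 2),
      if (isTRUE(x$flat_beyond)) "(curve flat beyond the cutoff)"
      else "(no flat segment detected)", "\n")
  invisible(x)
}
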