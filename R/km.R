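#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the survival function.  Censored observations
#' tied with an event time are handled with the standard convention: they
#' remain in the risk set for that event (censored after event).  Greenwood
#' standard errors are stored for optional confidence bands.
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return an object of class `km_curve` with fields `event_times`
#'   (distinct times with at least one event), `survival`, `at_risk`,
#'   `events`, `censored_marks` (censoring times) and `greenwood_se`.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  keep <- sf$n.event > 0
  structure(list(event_times = sf$time[keep],
                 survival = sf$surv[keep],
                 at_risk = sf$n.risk[keep],
                 events = sf$n.event[keep],
                 censored_marks = sort(times[events == 0]),
                 greenwood_se = sf$std.err[keep] * sf$surv[keep],
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", sum(x$events), "events at",
      length(x$event_times), "distinct times\n")
  if (length(x$event_times)) {
    med <- x$event_times[which(x$survival <= 0.5)[1]]
    cat("  median survival:", if (is.na(med)) "not reached" else round(med, 3), "\n")
  }
  invisible(x)
}

#' Evaluate a KM curve at arbitrary times
#'
#' Right-continuous step evaluation of the product-limit estimate.
#'
#' @param curve a [kaplan_meier()] result.
#' @param t times at which to evaluate.
#' @return survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$event_times)
  c(1, curve$survival)[idx + 1L]
}

#' Export a KM curve as a data frame
#'
#' @param x a `km_curve`.
#' @param ... unused.
#' @return data frame with columns time, survival, at_risk, events.
#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$event_times, survival = x$survival,
             at_risk = x$at_risk, events = x$events)
}

#' Log-rank test for group differences in survival
#'
#' Mantel-Haenszel log-rank test pooling the 2 x k tables over distinct
#' event times, with hypergeometric variance; the p-value is from a
#' chi-squared distribution on (groups - 1) degrees of freedom.
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param groups group labels (>= 2 non-empty groups).
#' @return an object of class `log_rank_result` with fields `statistic`,
#'   `df`, `p`, `observed`, `expected` and `degenerate` (`TRUE` when no
#'   events occurred; then the statistic is 0 and p = 1).
#' @export
log_rank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  g <- if (is.factor(groups)) groups else factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("group with zero subjects: ",
                               paste(levels(g)[table(g) == 0], collapse = ", "))
  if (sum(events) == 0) {
    obs <- rep(0, nlevels(g)); names(obs) <- levels(g)
    return(structure(list(statistic = 0, df = nlevels(g) - 1L, p = 1,
                          observed = obs, expected = obs, degenerate = TRUE),
                     class = "log_rank_result"))
  }
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  p <- stats::pchisq(sd_$chisq, df = nlevels(g) - 1L, lower.tail = FALSE)
  structure(list(statistic = unname(sd_$chisq), df = nlevels(g) - 1L, p = p,
                 observed = stats::setNames(as.vector(sd_$obs), levels(g)),
                 expected = stats::setNames(as.vector(sd_$exp), levels(g)),
                 degenerate = FALSE),
            class = "log_rank_result")
}

#' @export
print.log_rank_result <- function(x, ...) {
  cat("Log-rank test: chi-squared =", round(x$statistic, 3), "on", x$df,
      "df, p =", format.pval(x$p, digits = 3), "\n")
  tab <- data.frame(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  invisible(x)
}
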