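#' Standard Cox proportional hazards fit
#'
#' Partial-likelihood fit with the Efron correction for tied event times,
#' Wald inference from the inverse observed information, and stored
#' Schoenfeld residuals for proportional-hazards diagnostics.  Records with
#' missing values in the requested covariates are excluded (complete-case),
#' and the exclusion count is reported in the fit.
#'
#' @param cohort an [er_cohort()] (or a data frame with the canonical
#'   columns).
#' @param endpoint `"ttr"` (time to recurrence or breast-cancer death) or
#'   `"os"` (overall survival).
#' @param covariates character vector of cohort column names entering the
#'   linear predictor (factors contribute one coefficient per non-reference
#'   level).  May be empty only when `offset` is supplied.
#' @param offset optional numeric vector (length = rows of `cohort`) added
#'   to the linear predictor with coefficient fixed at 1, e.g. a known
#'   log-hazard curve evaluated at each subject's ER value.
#' @return an object of class `cox_fit` with elements `beta`, `se`, `hr`,
#'   `ci95` (2-column matrix), `p`, `loglik`, `loglik_null`, `n_used`,
#'   `n_events`, `n_excluded`, `schoenfeld`, `score_test`, `vcov`, `assign`
#'   (term blocks) and the underlying `coxph` object.
#' @export
fit_cox <- function(cohort, endpoint = c("ttr", "os"), covariates,
                    offset = NULL) {
  endpoint <- match.arg(endpoint)
  data <- as.data.frame(cohort)
  tv <- paste0(endpoint, "_time"); ev <- paste0(endpoint, "_event")
  stopifnot(all(c(tv, ev) %in% names(data)))
  cov_vars <- unique(unlist(strsplit(covariates, "[:*]")))  # interaction terms
  missing_cov <- setdiff(cov_vars, names(data))
  if (length(missing_cov))
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  if (!is.null(offset)) {
    stopifnot(length(offset) == nrow(data))
    data$.offset <- offset
  }
  use_cols <- c(tv, ev, cov_vars, if (!is.null(offset)) ".offset")
  cc <- stats::complete.cases(data[use_cols])
  d <- data[cc, , drop = FALSE]
  n_excluded <- sum(!cc)
  if (sum(d[[ev]]) < 1) stop("no events in the data")
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  if (!is.null(offset)) rhs <- paste(rhs, "+ offset(.offset)")
  fml <- stats::as.formula(paste0("survival::Surv(", tv, ", ", ev, ") ~ ", rhs))
  if (length(covariates)) {
    X <- stats::model.matrix(stats::as.formula(paste("~", paste(covariates, collapse = "+"))), d)
    Xc <- X[, -1, drop = FALSE]
    const <- apply(Xc, 2, function(col) length(unique(col)) == 1)
    if (any(const))
      stop("rank deficiency: constant covariate column(s): ",
           paste(colnames(Xc)[const], collapse = ", "))
    if (qr(Xc)$rank < ncol(Xc))
      stop("rank deficiency: design matrix is collinear among: ",
           paste(colnames(Xc), collapse = ", "))
  }
  fit <- survival::coxph(fml, data = d, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100),
                         x = TRUE, y = TRUE, model = TRUE)
  beta <- stats::coef(fit)
  if (length(beta) && any(abs(beta) > 15))
    stop("monotone likelihood (coefficient diverging for: ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "),
         "); consider removing the covariate")
  V <- if (length(beta)) stats::vcov(fit) else matrix(0, 0, 0)
  se <- if (length(beta)) sqrt(diag(V)) else numeric(0)
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  p <- 2 * stats::pnorm(-abs(beta / se))
  sch <- if (length(beta) && sum(d[[ev]]) > 0)
    stats::residuals(fit, type = "schoenfeld") else NULL
  sctest <- if (length(beta)) unname(summary(fit)$sctest["test"]) else NA_real_
  structure(list(covariate_names = names(beta), covariates = covariates,
                 beta = beta, se = se, hr = exp(beta), ci95 = ci, p = p,
                 loglik = fit$loglik[length(fit$loglik)],
                 loglik_null = fit$loglik[1],
                 n_used = fit$n, n_events = fit$nevent,
                 n_excluded = n_excluded,
                 schoenfeld = sch,
                 score_test = sctest,
                 vcov = V,
                 assign = if (length(beta)) fit$assign else list(),
                 endpoint = endpoint, coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit (", toupper(x$endpoint), "): n =", x$n_used, ", events =",
      x$n_events,
      if (x$n_excluded) paste0(" (", x$n_excluded, " excluded, missing data)"),
      "\n")
  if (length(x$beta)) print(cox_table(x), row.names = FALSE)
  else cat("  <empty model>\n")
  cat("log partial likelihood:", round(x$loglik, 3), "\n")
  invisible(x)
}

#' Coefficient table of a Cox fit
#'
#' Presents the fit in the conventional layout: coefficient, SE, HR with
#' 95\% CI, and two-sided Wald p-value.
#'
#' @param fit a `cox_fit` (or `shape_cox_fit`).
#' @return a data frame.
#' @export
cox_table <- function(fit) {
  data.frame(term = fit$covariate_names,
             coef = round(fit$beta, 3),
             se = round(fit$se, 3),
             hr = round(fit$hr, 3),
             ci_lower = round(fit$ci95[, 1], 3),
             ci_upper = round(fit$ci95[, 2], 3),
             p = signif(fit$p, 3),
             row.names = NULL)
}

#' Proportional-hazards diagnostic test
#'
#' Grambsch-Therneau test: the correlation of the scaled Schoenfeld
#' residuals with a transform of event time, giving a score-type
#' chi-squared per covariate and globally.  The default transform is the
#' Kaplan-Meier transform; natural time and log time are available.
#'
#' @param fit a [fit_cox()] result.
#' @param transform `"km"`, `"identity"` or `"log"`.
#' @return a data frame with rows per covariate plus `GLOBAL`, columns
#'   `chisq`, `df`, `p`.
#' @export
ph_test <- function(fit, transform = c("km", "identity", "log")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (fit$n_events < 3) stop("need at least 3 events for the PH test")
  z <- survival::cox.zph(fit$coxph, transform = transform, global = TRUE)
  out <- as.data.frame(z$table)
  out$term <- rownames(z$table)
  rownames(out) <- NULL
  out[c("term", "chisq", "df", "p")]
}

## Per-term p-values for backward selection: single-coefficient terms use the
## Wald z test; multi-level factors are tested as a block (Wald chi-squared).
.term_p_values <- function(fit) {
  terms <- fit$covariates
  vapply(seq_along(terms), function(j) {
    idx <- fit$assign[[j]]
    if (length(idx) == 1) return(unname(fit$p[idx]))
    b <- fit$beta[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    stat <- as.numeric(t(b) %*% solve(V, b))
    stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
  }, numeric(1))
}

#' Backward variable selection for Cox models
#'
#' Iteratively refits the model, dropping the candidate with the largest
#' Wald p-value above `alpha` (multi-level factors are dropped as a block
#' using a block Wald test) until every retained candidate satisfies
#' p <= `alpha`.  Deterministic given the data.
#'
#' @param cohort an [er_cohort()].
#' @param endpoint `"ttr"` or `"os"`.
#' @param candidates character vector of candidate covariates.
#' @param alpha retention threshold (default 0.05).
#' @param forced covariates kept in the model regardless of significance
#'   (e.g. a treatment indicator in subgroup models); never dropped.
#' @return a `cox_fit` for the selected model, with attributes `selected`
#'   (retained candidates) and `dropped` (in drop order).  If every
#'   candidate is dropped and `forced` is empty, an empty-model marker of
#'   class `cox_fit_empty` is returned.
#' @export
backward_select <- function(cohort, endpoint, candidates, alpha = 0.05,
                            forced = character(0)) {
  current <- setdiff(candidates, forced)
  dropped <- character(0)
  repeat {
    covs <- c(forced, current)
    if (!length(covs)) {
      out <- structure(list(endpoint = endpoint, dropped = dropped,
                            message = "all candidates dropped"),
                       class = c("cox_fit_empty"))
      return(out)
    }
    fit <- fit_cox(cohort, endpoint, covs)
    pv <- .term_p_values(fit)
    names(pv) <- covs
    pv_cand <- pv[setdiff(names(pv), forced)]
    if (!length(pv_cand) || max(pv_cand) <= alpha) {
      attr(fit, "selected") <- current
      attr(fit, "dropped") <- dropped
      return(fit)
    }
    worst <- names(pv_cand)[which.max(pv_cand)]
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }
}

#' @export
print.cox_fit_empty <- function(x, ...) {
  cat("Backward selection (", toupper(x$endpoint),
      "): all candidates dropped; empty model.\n")
  cat("drop order:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
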