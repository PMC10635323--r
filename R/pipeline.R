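#' Analysis configuration
#'
#' Bundles everything [run_all()] needs: the input cohort (a CSV path or a
#' [synthetic_config()]), the endpoints, the covariate candidate list, the
#' ER cutpoints for the Kaplan-Meier categories, the modelling cutpoints,
#' the selection threshold, the bootstrap size and the output directory.
#'
#' @param input a cohort CSV path, an [er_cohort()], or a
#'   [synthetic_config()] (the cohort is then generated).
#' @param endpoints endpoints to analyse (subset of `c("ttr", "os")`).
#' @param covariates adjustment covariates for the TTR models; the OS
#'   models drop `"age"` by default, mirroring the motivating analysis
#'   where age was selected for TTR only.
#' @param km_cutpoints ER cutpoints defining the Kaplan-Meier categories.
#' @param model_cutpoints ER cutpoints for the categorical Cox models
#'   (reference = the middle category).
#' @param alpha backward-selection retention threshold.
#' @param n_boot bootstrap replicates for the shape-restricted fit.
#' @param seed integer seed for any randomness (synthetic generation,
#'   bootstrap).
#' @param output_dir where [run_all()] writes tables, JSON and figures.
#' @param round_er round ER to whole percents in the shape-restricted fit.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(input = synthetic_config(),
                            endpoints = c("ttr", "os"),
                            covariates = c("age", "race", "grade", "stage",
                                           "lvi", "radiation", "pcr"),
                            km_cutpoints = c(1, 10, 20),
                            model_cutpoints = c(10, 20),
                            alpha = 0.05, n_boot = 200, seed = 1L,
                            output_dir = "shapecox-output",
                            round_er = TRUE) {
  if (is.unsorted(km_cutpoints, strictly = TRUE) ||
      any(km_cutpoints <= 0 | km_cutpoints >= 100))
    stop("km_cutpoints must be strictly increasing within (0, 100)")
  if (is.unsorted(model_cutpoints, strictly = TRUE))
    stop("model_cutpoints must be strictly increasing")
  structure(list(input = input, endpoints = match.arg(endpoints,
                                                      several.ok = TRUE),
                 covariates = covariates, km_cutpoints = km_cutpoints,
                 model_cutpoints = model_cutpoints, alpha = alpha,
                 n_boot = n_boot, seed = as.integer(seed),
                 output_dir = output_dir, round_er = round_er),
            class = "analysis_config")
}

## endpoint-specific adjustment set: age enters the TTR models only
.adjusters <- function(config, endpoint) {
  if (endpoint == "os") setdiff(config$covariates, "age") else config$covariates
}

.load_cohort <- function(input) {
  if (inherits(input, "er_cohort")) return(input)
  if (inherits(input, "synthetic_config")) return(generate_cohort(input))
  if (is.character(input)) {
    if (!file.exists(input)) stop("input file not found: ", input)
    return(read_cohort(input))
  }
  stop("input must be a path, an er_cohort or a synthetic_config")
}

#' Descriptive characteristics by ER category
#'
#' Summarizes every requested variable across the four ER expression
#' categories: counts with within-category percentages for categorical and
#' binary variables (chi-squared test), mean and SD per category for
#' continuous variables (Kruskal-Wallis test).
#'
#' @param cohort an [er_cohort()].
#' @param variables cohort fields to summarize; defaults to all present
#'   clinical fields.
#' @return a list with `membership` (category sizes), `tables` (one summary
#'   per variable, each with attribute `p`), and `p_values`.
#' @export
run_descriptives <- function(cohort,
                             variables = intersect(
                               c("age", "race", "grade", "stage", "lvi",
                                 "radiation", "endocrine", "chemo", "pcr",
                                 "er", "pr"),
                               names(cohort))) {
  stopifnot(inherits(cohort, "er_cohort"))
  cat4 <- assign_er_category(cohort$er)
  membership <- summarize_by_er_category(cohort, "er_category")
  tables <- list(); p_values <- numeric(0)
  for (v in variables) {
    col <- cohort[[v]]
    if (is.numeric(col) && length(unique(stats::na.omit(col))) > 2) {
      tab <- do.call(rbind, lapply(split(col, cat4), function(xx)
        data.frame(mean = mean(xx, na.rm = TRUE), sd = stats::sd(xx, na.rm = TRUE))))
      tab <- cbind(category = rownames(tab), tab)
      rownames(tab) <- NULL
      p <- tryCatch(stats::kruskal.test(col, cat4)$p.value,
                    error = function(e) NA_real_)
    } else {
      tab <- summarize_by_er_category(cohort, v)
      cnt <- as.matrix(tab[, paste0("n_", er_category_labels())])
      p <- tryCatch(suppressWarnings(stats::chisq.test(cnt)$p.value),
                    error = function(e) NA_real_)
    }
    attr(tab, "p") <- p
    tables[[v]] <- tab
    p_values[v] <- p
  }
  list(membership = membership, tables = tables, p_values = p_values)
}

## ER category factor at arbitrary cutpoints; reference = middle bin when
## there are >= 3 bins (as in the motivating categorical models), else the
## lowest bin.
.er_factor <- function(er, cutpoints) {
  breaks <- c(0, cutpoints, Inf)
  labs <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
  f <- cut(er, breaks = breaks, labels = labs, right = FALSE,
           include.lowest = TRUE)
  ref <- if (nlevels(f) >= 3) 2L else 1L
  stats::relevel(f, ref = levels(f)[ref])
}

#' Categorical ER Cox models
#'
#' Fits the ER effect with indicator contrasts against the middle category
#' (ER in \[10,20) at the default cutpoints), both unadjusted (univariate)
#' and adjusted for the endpoint-specific covariate set.
#'
#' @param cohort an [er_cohort()].
#' @param endpoint `"ttr"` or `"os"`.
#' @param cutpoints ER cutpoints (default `c(10, 20)`).
#' @param adjusters covariates for the multivariable model; default is the
#'   motivating adjustment set (age for TTR only).
#' @return a list with elements `univariate` and `multivariable`
#'   (`cox_fit` objects; ER contrasts are the `er_cat` terms).
#' @export
run_categorical_models <- function(cohort, endpoint = c("ttr", "os"),
                                   cutpoints = c(10, 20),
                                   adjusters = NULL) {
  endpoint <- match.arg(endpoint)
  if (is.null(adjusters)) {
    base <- c("age", "race", "grade", "stage", "lvi", "radiation", "pcr")
    adjusters <- intersect(if (endpoint == "os") setdiff(base, "age") else base,
                           names(cohort))
  }
  d <- as.data.frame(cohort)
  d$er_cat <- .er_factor(d$er, cutpoints)
  ev <- paste0(endpoint, "_event")
  per_cat_events <- tapply(d[[ev]], d$er_cat, sum)
  bad <- names(per_cat_events)[is.na(per_cat_events) | per_cat_events == 0]
  if (length(bad))
    stop("ER category with no subjects or no events: ",
         paste(bad, collapse = ", "))
  list(univariate = fit_cox(d, endpoint, "er_cat"),
       multivariable = fit_cox(d, endpoint, c("er_cat", adjusters)))
}

#' Endocrine-therapy effect within ER subgroups
#'
#' Within each ER bin, the endocrine-therapy indicator is forced into a Cox
#' model whose other adjusters are chosen by backward selection; the
#' therapy hazard ratio, CI and p-value are reported per bin.  Bins without
#' therapy variation are reported as inestimable and the run continues.
#'
#' @param cohort an [er_cohort()].
#' @param endpoint `"ttr"` or `"os"`.
#' @param er_bins list of `c(lower, upper)` ER ranges (lower-inclusive).
#' @param candidates candidate adjusters for backward selection.
#' @param alpha selection threshold.
#' @return a data frame with one row per bin: n, events, therapy HR, CI, p,
#'   retained adjusters, and an `estimable` flag.
#' @export
run_subgroup_therapy <- function(cohort, endpoint = c("ttr", "os"),
                                 er_bins = list(c(1, 10), c(10, 20),
                                                c(20, Inf)),
                                 candidates = NULL, alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  if (is.null(candidates)) {
    base <- c("age", "race", "grade", "stage", "lvi", "radiation", "pcr")
    candidates <- intersect(if (endpoint == "os") setdiff(base, "age") else base,
                            names(cohort))
  }
  d <- as.data.frame(cohort)
  rows <- lapply(er_bins, function(bin) {
    lab <- paste0("[", bin[1], ",", bin[2], ")")
    sub <- d[d$er >= bin[1] & d$er < bin[2], , drop = FALSE]
    ev <- paste0(endpoint, "_event")
    out <- data.frame(bin = lab, n = nrow(sub),
                      events = if (nrow(sub)) sum(sub[[ev]]) else 0L,
                      hr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                      p = NA_real_, adjusters = NA_character_,
                      estimable = FALSE, stringsAsFactors = FALSE)
    if (nrow(sub) == 0 || length(unique(sub$endocrine)) < 2 ||
        sum(sub[[ev]]) == 0)
      return(out)
    fit <- tryCatch(
      suppressWarnings(backward_select(sub, endpoint, candidates,
                                       alpha = alpha, forced = "endocrine")),
      error = function(e) NULL)
    if (is.null(fit) || inherits(fit, "cox_fit_empty")) return(out)
    i <- grep("^endocrine", fit$covariate_names)[1]
    out$hr <- fit$hr[i]; out$ci_lower <- fit$ci95[i, 1]
    out$ci_upper <- fit$ci95[i, 2]; out$p <- fit$p[i]
    out$adjusters <- paste(attr(fit, "selected"), collapse = ", ")
    out$estimable <- TRUE
    out
  })
  do.call(rbind, rows)
}

#' Therapy-by-ER interaction model
#'
#' Single Cox model with endocrine-therapy x ER-category product terms (plus
#' the endpoint-specific adjusters), reporting the Wald p-value of each
#' interaction contrast against the reference (middle) category.
#'
#' @param cohort an [er_cohort()].
#' @param endpoint `"ttr"` or `"os"`.
#' @param cutpoints ER cutpoints defining the categories.
#' @param adjusters adjustment covariates; defaults as in
#'   [run_categorical_models()].
#' @return a list with the full `cox_fit`, `interaction_p` (named vector of
#'   Wald p-values for the product terms) and `global_p` (block Wald test of
#'   all product terms jointly).
#' @export
run_interaction <- function(cohort, endpoint = c("ttr", "os"),
                            cutpoints = c(10, 20), adjusters = NULL) {
  endpoint <- match.arg(endpoint)
  if (is.null(adjusters)) {
    base <- c("age", "race", "grade", "stage", "lvi", "radiation", "pcr")
    adjusters <- intersect(if (endpoint == "os") setdiff(base, "age") else base,
                           names(cohort))
  }
  d <- as.data.frame(cohort)
  d$er_cat <- .er_factor(d$er, cutpoints)
  fit <- fit_cox(d, endpoint, c("er_cat", "endocrine", "er_cat:endocrine",
                                adjusters))
  ix <- grep(":", fit$covariate_names)
  b <- fit$beta[ix]
  V <- fit$vcov[ix, ix, drop = FALSE]
  global <- stats::pchisq(as.numeric(t(b) %*% solve(V, b)), df = length(ix),
                          lower.tail = FALSE)
  list(fit = fit,
       interaction_p = stats::setNames(fit$p[ix], fit$covariate_names[ix]),
       global_p = global)
}

#' Run the full analysis
#'
#' Executes the whole pipeline as in the motivating study: descriptives,
#' Kaplan-Meier curves and log-rank tests by ER category, standard Cox fits
#' with the proportional-hazards test on continuous ER, the
#' shape-restricted fit with bootstrap inference, threshold detection on the
#' fitted curve, categorical ER models, endocrine-therapy subgroup models
#' and the therapy-by-ER interaction model.  Tables are written as CSV,
#' thresholds as JSON, figures as PNG, plus a run log; the run is
#' deterministic given the seed.
#'
#' @param config an [analysis_config()].
#' @param figures draw PNG figures (requires a functional png device).
#' @return (invisibly) a list with all stage results; side effect: files
#'   under `config$output_dir`.
#' @export
run_all <- function(config = analysis_config(), figures = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run-log.txt")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  cat("", file = log_path)  # truncate
  logf("shapecox run: seed=", config$seed,
       " R=", getRversion(), " survival=",
       as.character(utils::packageVersion("survival")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  results <- list()
  cohort <- stage("load", {
    if (inherits(config$input, "synthetic_config"))
      config$input$seed <- config$seed
    .load_cohort(config$input)
  })
  logf("cohort: ", nrow(cohort), " records from ", attr(cohort, "provenance"))
  write_cohort(cohort, file.path(config$output_dir, "cohort.csv"))

  results$descriptives <- stage("descriptives", run_descriptives(cohort))
  utils::write.csv(results$descriptives$membership,
                   file.path(config$output_dir, "er-categories.csv"),
                   row.names = FALSE)

  cat4 <- assign_er_category(cohort$er)
  for (ep in config$endpoints) {
    tv <- paste0(ep, "_time"); evn <- paste0(ep, "_event")
    km <- stage("km", lapply(split(seq_len(nrow(cohort)), cat4), function(i)
      kaplan_meier(cohort[[tv]][i], cohort[[evn]][i])))
    lr <- stage("logrank",
                log_rank_test(cohort[[tv]], cohort[[evn]], cat4))
    logf(toupper(ep), " log-rank: chi2=", round(lr$statistic, 2),
         " p=", format.pval(lr$p, digits = 3))
    adj <- .adjusters(config, ep)
    std <- stage("cox", fit_cox(cohort, ep, c(adj, "er")))
    ph <- stage("ph_test", ph_test(std))
    er_p <- ph$p[ph$term == "er"]
    logf(toupper(ep), " PH test on continuous ER: p=",
         format.pval(er_p, digits = 3))
    shape <- stage("shapecox",
                   bootstrap_inference(cohort, ep, x = "er", z = adj,
                                       n_boot = config$n_boot,
                                       seed = config$seed,
                                       round_x = config$round_er))
    thr <- stage("threshold", detect_threshold(shape$curve))
    logf(toupper(ep), " detected threshold: ", round(thr$cutoff, 2),
         " (flat beyond: ", thr$flat_beyond, ")")
    categ <- stage("categorical",
                   run_categorical_models(cohort, ep,
                                          cutpoints = config$model_cutpoints))
    subg <- stage("subgroup", run_subgroup_therapy(cohort, ep,
                                                   alpha = config$alpha))
    # near-deterministic therapy allocation (98% uptake at high ER) makes
    # the interaction model separation-prone; report it as inestimable and
    # continue, as for inestimable subgroup bins
    inter <- tryCatch(
      suppressWarnings(run_interaction(cohort, ep,
                                       cutpoints = config$model_cutpoints)),
      error = function(e) {
        logf(toupper(ep), " interaction stage inestimable: ",
             conditionMessage(e))
        list(fit = NULL, interaction_p = NULL, global_p = NA_real_,
             inestimable = TRUE)
      })
    results[[ep]] <- list(km = km, logrank = lr, cox = std, ph = ph,
                          shape = shape, threshold = thr,
                          categorical = categ, subgroup = subg,
                          interaction = inter)
    # persisted outputs
    pre <- function(f) file.path(config$output_dir, paste0(ep, "-", f))
    utils::write.csv(cox_table(std), pre("cox.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(shape$curve), pre("curve.csv"),
                     row.names = FALSE)
    utils::write.csv(subg, pre("subgroup.csv"), row.names = FALSE)
    km_df <- do.call(rbind, lapply(names(km), function(gp)
      cbind(group = gp, as.data.frame(km[[gp]]))))
    utils::write.csv(km_df, pre("km.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(endpoint = ep, cutoff = thr$cutoff, method = thr$method,
           flat_beyond = thr$flat_beyond),
      pre("threshold.json"), auto_unbox = TRUE, digits = NA)
    if (figures) {
      grDevices::png(pre("curve.png"), width = 700, height = 500)
      plot(shape$curve, main = paste("Estimated ER effect,", toupper(ep)))
      graphics::abline(v = thr$cutoff, lty = 2)
      grDevices::dev.off()
      grDevices::png(pre("km.png"), width = 700, height = 500)
      graphics::plot(NULL, xlim = c(0, max(cohort[[tv]])), ylim = c(0, 1),
                     xlab = "Years from surgery", ylab = "Survival",
                     main = paste("KM by ER category,", toupper(ep)))
      for (i in seq_along(km))
        graphics::lines(c(0, km[[i]]$event_times),
                        c(1, km[[i]]$survival), type = "s", col = i)
      graphics::legend("bottomleft", legend = names(km), col = seq_along(km),
                       lty = 1)
      grDevices::dev.off()
    }
  }
  logf("run complete")
  invisible(results)
}
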