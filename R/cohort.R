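#' Patient-level survival cohort
#'
#' An `er_cohort` is a data frame of patient records for the two study
#' endpoints — time to recurrence or breast-cancer death (TTR) and overall
#' survival (OS), both clocked from surgery — together with continuous
#' estrogen-receptor (ER) expression (percent of stained tumor cells, 0-100)
#' and the clinical covariates used in the motivating analysis.
#'
#' Canonical columns: `id`, `ttr_time`, `ttr_event`, `os_time`, `os_event`,
#' `er`, and optionally `pr`, `age`, `race`, `grade`, `stage`, `lvi`,
#' `radiation`, `endocrine`, `chemo`, `pcr`.  Factor reference levels are
#' fixed so that fitted contrasts read as in the motivating study:
#' race reference "White", nuclear grade reference "III", clinical stage
#' reference "III".
#'
#' @param data a data frame with the canonical columns above.
#' @param provenance character scalar recording where the records came from
#'   (a file path or a generator seed descriptor).
#' @return an object of class `er_cohort` (a validated data frame).
#' @export
er_cohort <- function(data, provenance = "in-memory") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("ttr_time", "ttr_event", "os_time", "os_event", "er")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(data) == 0L) stop("cohort must contain at least one record")
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) stop("record ids must be unique")
  for (col in c("race", "grade", "stage"))
    if (col %in% names(data)) data[[col]] <- .canonical_factor(col, data[[col]])
  .validate_records(data)
  structure(data, provenance = provenance,
            class = c("er_cohort", "data.frame"))
}

.race_levels <- c("White", "Black", "Hispanic", "Asian/other")
.canonical_factor <- function(col, x) {
  levs <- switch(col,
    race  = .race_levels,
    grade = c("III", "I/II"),     # reference III
    stage = c("III", "II"))       # reference III
  if (is.factor(x)) x <- as.character(x)
  bad <- !is.na(x) & !x %in% levs
  if (any(bad))
    stop("invalid ", col, " value(s): ", paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = levs)
}

.validate_records <- function(data) {
  problems <- character(0)
  chk <- function(cond, msg) {
    bad <- which(!is.na(cond) & cond)
    if (length(bad))
      problems <<- c(problems,
                     paste0("row ", bad[1], if (length(bad) > 1)
                       paste0(" (and ", length(bad) - 1, " more)"), ": ", msg))
  }
  chk(data$ttr_time < 0, "ttr_time must be >= 0")
  chk(data$os_time < 0, "os_time must be >= 0")
  chk(!data$ttr_event %in% c(0, 1), "ttr_event must be 0 or 1")
  chk(!data$os_event %in% c(0, 1), "os_event must be 0 or 1")
  chk(data$er < 0 | data$er > 100, "er must lie in [0, 100]")
  chk(is.na(data$er), "er must not be missing")
  chk(is.na(data$ttr_time) | is.na(data$os_time), "times must not be missing")
  if ("pr" %in% names(data)) chk(data$pr < 0 | data$pr > 100, "pr must lie in [0, 100]")
  if ("age" %in% names(data)) chk(data$age <= 0, "age must be positive")
  for (col in c("lvi", "radiation", "endocrine", "chemo", "pcr"))
    if (col %in% names(data))  # NA allowed: grade/LVI have unknowns
      chk(!is.na(data[[col]]) & !data[[col]] %in% c(0, 1),
          paste0(col, " must be 0 or 1"))
  if (length(problems))
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))
  invisible(data)
}

#' @export
print.er_cohort <- function(x, ...) {
  cat("er_cohort:", nrow(x), "records (", attr(x, "provenance"), ")\n")
  cat("  TTR events:", sum(x$ttr_event), "  OS events:", sum(x$os_event), "\n")
  cat("  ER quartiles:",
      paste(round(stats::quantile(x$er), 1), collapse = " / "), "\n")
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Reads an RFC-4180 CSV with a header row into a validated [er_cohort()].
#' Empty strings and `"NA"` are treated as missing.  Rows violating the
#' record invariants (times >= 0, events in \{0,1\}, ER in \[0,100\]) are
#' reported with their row index.
#'
#' @param path path to the CSV file.
#' @param schema optional named character vector mapping canonical field
#'   names to the column names used in the file, e.g.
#'   `c(er = "er_percent")`.  Unmapped canonical names are looked up
#'   directly.
#' @return an [er_cohort()].
#' @export
read_cohort <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  canonical <- c("id", "ttr_time", "ttr_event", "os_time", "os_event", "er",
                 "pr", "age", "race", "grade", "stage", "lvi", "radiation",
                 "endocrine", "chemo", "pcr")
  out <- list()
  for (field in canonical) {
    col <- if (!is.null(schema) && field %in% names(schema)) schema[[field]] else field
    if (col %in% names(raw)) out[[field]] <- raw[[col]]
  }
  required <- c("ttr_time", "ttr_event", "os_time", "os_event", "er")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols))
    stop("schema error: required column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  er_cohort(as.data.frame(out, stringsAsFactors = FALSE), provenance = path)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writing then reading reproduces the cohort
#' field by field (up to floating-point formatting).
#'
#' @param cohort an [er_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "er_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' ER expression categories
#'
#' Bins continuous ER expression at the clinical cutpoints 1, 10 and 20
#' percent, lower-inclusive: `[0,1)` -> `"<1"`, `[1,10)` -> `"1-10"`,
#' `[10,20)` -> `"10-20"`, `[20,100]` -> `">=20"`.
#'
#' @param er numeric vector of ER percentages in \[0, 100\].
#' @return a factor with levels `c("<1", "1-10", "10-20", ">=20")`.
#' @export
assign_er_category <- function(er) {
  if (any(is.na(er)) || any(er < 0 | er > 100))
    stop("er values must lie in [0, 100]")
  cut(er, breaks = c(0, 1, 10, 20, Inf), labels = er_category_labels(),
      right = FALSE, include.lowest = TRUE)
}

#' @rdname assign_er_category
#' @export
er_category_labels <- function() c("<1", "1-10", "10-20", ">=20")

#' Descriptive summary of a variable by ER category
#'
#' Cross-tabulates a binary or categorical cohort field against the four ER
#' expression categories, reporting counts and within-category percentages
#' (denominator: non-missing records in the category), plus an overall
#' column.  Empty categories are flagged rather than yielding `NaN`.
#'
#' @param cohort an [er_cohort()].
#' @param variable name of a categorical/binary cohort field; the special
#'   value `"er_category"` summarizes category membership itself.
#' @return a data frame with one row per variable level (plus `n` rows),
#'   columns per ER category and `Total`; attribute `empty_categories`
#'   lists categories with zero denominator.
#' @export
summarize_by_er_category <- function(cohort, variable) {
  stopifnot(inherits(cohort, "er_cohort"))
  cat4 <- assign_er_category(cohort$er)
  if (variable == "er_category") {
    counts <- table(cat4)
    total <- length(cat4)
    out <- data.frame(level = "n",
                      t(as.integer(counts)), Total = total,
                      check.names = FALSE)
    names(out)[2:5] <- er_category_labels()
    pct <- data.frame(level = "percent",
                      t(round(100 * as.integer(counts) / total, 1)),
                      Total = 100, check.names = FALSE)
    names(pct)[2:5] <- er_category_labels()
    res <- rbind(out, pct)
    attr(res, "empty_categories") <- er_category_labels()[counts == 0]
    return(res)
  }
  if (!variable %in% names(cohort))
    stop("unknown variable: ", variable)
  v <- cohort[[variable]]
  if (is.numeric(v) && length(unique(stats::na.omit(v))) > 2)
    stop("variable '", variable, "' is not categorical or binary")
  v <- factor(v)
  tab <- unclass(table(v, cat4))
  denom <- colSums(tab)
  pct <- 100 * tab / rep(pmax(denom, 1), each = nrow(tab))
  pct[, denom == 0] <- 0
  overall_n <- rowSums(tab)
  overall_pct <- 100 * overall_n / max(sum(overall_n), 1)
  res <- data.frame(level = rownames(tab),
                    count = tab,
                    percent = round(pct, 1),
                    total_count = unname(overall_n),
                    total_percent = round(unname(overall_pct), 1),
                    check.names = FALSE, row.names = NULL)
  names(res) <- c("level", paste0("n_", er_category_labels()),
                  paste0("pct_", er_category_labels()),
                  "n_total", "pct_total")
  attr(res, "empty_categories") <- er_category_labels()[denom == 0]
  res
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, on pairwise-complete
#' observations; used in the motivating study to quantify ER-PR collinearity.
#'
#' @param a,b numeric vectors of equal length.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
spearman_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  keep <- stats::complete.cases(a, b)
  if (sum(keep) < 3) stop("need at least 3 complete pairs")
  stats::cor(a[keep], b[keep], method = "spearman")
}
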