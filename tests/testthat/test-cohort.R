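test_that("cohort CSV round-trip is the identity on valid cohorts", {
  cfg <- synthetic_config(n = 40, seed = 11)
  ch <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(ch))
  for (col in c("ttr_time", "os_time", "er", "pr", "age"))
    expect_equal(back[[col]], ch[[col]], tolerance = 1e-12)
  for (col in c("ttr_event", "os_event", "race", "grade", "stage", "lvi",
                "radiation", "endocrine", "chemo", "pcr"))
    expect_equal(back[[col]], ch[[col]])
})

test_that("read_cohort honours a schema mapping and rejects bad input", {
  d <- data.frame(t1 = c(1, 2, 3), e1 = c(1, 0, 1), t2 = c(1, 2, 3),
                  e2 = c(0, 0, 1), er_pct = c(0, 50, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  ch <- read_cohort(path, schema = c(ttr_time = "t1", ttr_event = "e1",
                                     os_time = "t2", os_event = "e2",
                                     er = "er_pct"))
  expect_s3_class(ch, "er_cohort")
  expect_equal(nrow(ch), 3)

  # out-of-range ER cites the offending row
  d2 <- d; d2$er_pct[2] <- 150
  write.csv(d2, path, row.names = FALSE)
  expect_error(read_cohort(path, schema = c(ttr_time = "t1", ttr_event = "e1",
                                            os_time = "t2", os_event = "e2",
                                            er = "er_pct")),
               "row 2")

  # missing required column is a schema error
  write.csv(d[, -2], path, row.names = FALSE)
  expect_error(read_cohort(path, schema = c(ttr_time = "t1",
                                            os_time = "t2", os_event = "e2",
                                            er = "er_pct")),
               "ttr_event")
})

test_that("ER binning is lower-inclusive at 1, 10 and 20 and partitions [0,100]", {
  expect_equal(as.character(assign_er_category(c(0, 0.9, 1, 9.99, 10, 19.9,
                                                 20, 100))),
               c("<1", "<1", "1-10", "1-10", "10-20", "10-20",
                 ">=20", ">=20"))
  expect_error(assign_er_category(101), "\\[0, 100\\]")
  expect_error(assign_er_category(-0.1), "\\[0, 100\\]")
  # partition property on a dense grid: exactly one bin each
  grid <- seq(0, 100, by = 0.25)
  cats <- assign_er_category(grid)
  expect_false(anyNA(cats))
  expect_equal(nlevels(cats), 4)
})

test_that("descriptive summaries reproduce the published margins", {
  ch <- margins_fixture_cohort()
  mem <- summarize_by_er_category(ch, "er_category")
  expect_equal(unlist(mem[1, 2:5], use.names = FALSE), c(932, 171, 67, 1885))
  expect_equal(unlist(mem[2, 2:5], use.names = FALSE), c(30.5, 5.6, 2.2, 61.7))

  pcr <- summarize_by_er_category(ch, "pcr")
  yes <- pcr[pcr$level == "1", ]
  expect_equal(unlist(yes[paste0("pct_", er_category_labels())],
                      use.names = FALSE), c(26.3, 28.1, 10.4, 6.8))

  endo <- summarize_by_er_category(ch, "endocrine")
  yes <- endo[endo$level == "1", ]
  expect_equal(unlist(yes[paste0("pct_", er_category_labels())],
                      use.names = FALSE)[2:4], c(25.1, 80.6, 98.2))

  # within-variable percentages sum to 100 per category (up to rounding)
  for (v in c("pcr", "endocrine", "radiation", "race")) {
    tab <- summarize_by_er_category(ch, v)
    sums <- colSums(tab[paste0("pct_", er_category_labels())])
    expect_true(all(abs(sums - 100) <= 0.1))
  }
})

test_that("empty ER categories are flagged, not NaN", {
  d <- toy_cohort(time = 1:4, status = c(1, 0, 1, 0), er = c(0, 0, 50, 60),
                  pcr = c(1, 0, 0, 1))
  ch <- er_cohort(d)
  tab <- summarize_by_er_category(ch, "pcr")
  expect_setequal(attr(tab, "empty_categories"), c("1-10", "10-20"))
  expect_false(any(is.nan(as.matrix(tab[paste0("pct_",
                                               er_category_labels())]))))
})

test_that("spearman correlation matches hand-ranked values", {
  expect_equal(spearman_correlation(c(1, 5, 9, 20), c(1, 5, 9, 20)), 1.0)
  expect_equal(spearman_correlation(c(1, 5, 9, 20), c(20, 9, 5, 1)), -1.0)
  # hand computation: Pearson on ranks of (1,2,3,4) vs (1,3,2,4) = 0.8
  expect_equal(spearman_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_correlation(c(1, 2), c(3, 4)), "at least 3")
})

test_that("cohort validation enforces record invariants", {
  base <- toy_cohort(time = c(1, 2), status = c(1, 0), er = c(5, 50))
  expect_s3_class(er_cohort(base), "er_cohort")
  bad <- base; bad$ttr_time[1] <- -1
  expect_error(er_cohort(bad), "ttr_time")
  bad <- base; bad$ttr_event[2] <- 2
  expect_error(er_cohort(bad), "ttr_event")
  bad <- base; bad$id <- c("a", "a")
  expect_error(er_cohort(bad), "unique")
  expect_error(er_cohort(base[, -1]), "missing required column")
})
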