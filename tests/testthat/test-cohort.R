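test_that("as_cohort validates and derives columns", {
  co <- as_cohort(toy_cohort_df(), provenance = "toy")
  expect_s3_class(co, "cf_cohort")
  expect_equal(co$vaf, co$alt_reads / co$depth)
  expect_false(any(co$recurrent))  # each variant in one participant
  expect_identical(attr(co, "provenance"), "toy")

  # recurrent flag: same variant in two participants
  df <- toy_cohort_df()
  df$variant_id <- "chr1:100:A:G"
  expect_true(all(as_cohort(df)$recurrent))
})

test_that("as_cohort rejects bad read counts and duplicates", {
  df <- toy_cohort_df()
  df$alt_reads[3] <- df$depth[3] + 1
  expect_error(as_cohort(df), class = "cf_validation_error")

  df <- toy_cohort_df()
  df$age_years[2] <- df$age_years[1]
  expect_error(as_cohort(df), class = "cf_validation_error")

  expect_error(as_cohort(toy_cohort_df()[, -1]), class = "cf_schema_error")
})

test_that("zero-depth timepoints are dropped with a warning", {
  df <- toy_cohort_df()
  df$depth[5] <- 0
  df$alt_reads[5] <- 0
  expect_warning(co <- as_cohort(df), "zero depth")
  expect_equal(nrow(co), 7)
})

test_that("cohort TSV round-trips", {
  co <- as_cohort(toy_cohort_df())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  # identical data; provenance records the file it was read from
  expect_equal(tibble::as_tibble(co2), tibble::as_tibble(co),
               ignore_attr = TRUE)
  expect_match(attr(co2, "provenance"), "\\.tsv$")
  expect_error(read_cohort(file.path(tempdir(), "nope.tsv")))
})

test_that("cohort_trajectories nests one row per trajectory", {
  tr <- cohort_trajectories(as_cohort(toy_cohort_df()))
  expect_equal(nrow(tr), 2)
  expect_equal(nrow(tr$data[[1]]), 4)
})

test_that("qc_filter applies coverage, gnomAD and germline rules", {
  df <- toy_cohort_df()
  df$unique_alt_reads <- rep(10L, 8)
  df$gnomad_p <- rep(0.001, 8)
  # participant A: low alt reads everywhere -> coverage reject
  df$alt_reads[1:4] <- 2L
  # add a germline-like trajectory for a third participant
  germ <- toy_cohort_df()[1:4, ]
  germ$participant_id <- "C"
  germ$variant_id <- "chr3:300:G:A"
  germ$alt_reads <- c(990L, 1010L, 1000L, 980L)
  germ$unique_alt_reads <- 10L
  germ$gnomad_p <- 0.001
  co <- as_cohort(dplyr::bind_rows(df, germ))
  out <- qc_filter(co)
  log <- qc_log(out)
  expect_setequal(log$rule, c("coverage", "germline"))
  expect_equal(sort(unique(out$participant_id)), "B")

  # gnomAD rule: common population variant rejected
  df2 <- toy_cohort_df()
  df2$unique_alt_reads <- 10L
  df2$gnomad_p <- ifelse(df2$participant_id == "A", 0.9, 0.001)
  out2 <- qc_filter(as_cohort(df2))
  expect_identical(qc_log(out2)$rule, "gnomad")
})

test_that("qc_filter skips rules whose columns are absent", {
  co <- as_cohort(toy_cohort_df())
  expect_warning(expect_warning(out <- qc_filter(co), "unique_alt_reads"),
                 "gnomad_p")
  expect_equal(nrow(out), nrow(co))
})

test_that("chip_threshold_filter keeps VAF >= 2% trajectories", {
  co <- as_cohort(toy_cohort_df())
  # trajectory A peaks at 80/2000 = 4%; B at 110/2000 = 5.5%
  expect_equal(nrow(chip_threshold_filter(co)), 8)
  expect_equal(nrow(chip_threshold_filter(co, vaf_threshold = 0.05)), 4)
  expect_equal(nrow(chip_threshold_filter(co, min_timepoints = 5)), 0)
  expect_error(chip_threshold_filter(co, vaf_threshold = 0))
  expect_error(chip_threshold_filter(co, vaf_threshold = 1))
})

test_that("vaf_gradient is the first-to-last slope", {
  expect_equal(vaf_gradient(c(70, 76), c(0.01, 0.04)), 0.03 / 6)
  # order-insensitive
  expect_equal(vaf_gradient(c(76, 70), c(0.04, 0.01)), 0.03 / 6)
  expect_error(vaf_gradient(70, 0.01), class = "cf_insufficient_data")
})

test_that("vaf_gradients summarises growing status per trajectory", {
  gr <- vaf_gradients(as_cohort(toy_cohort_df()))
  expect_equal(nrow(gr), 2)
  expect_true(gr$growing[gr$participant_id == "A"])
  expect_equal(gr$gradient[gr$participant_id == "A"],
               (80 - 30) / 2000 / 9)
})

test_that("autoplot on a cohort returns a ggplot", {
  p <- ggplot2::autoplot(as_cohort(toy_cohort_df()))
  expect_s3_class(p, "ggplot")
})
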