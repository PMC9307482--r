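# small mixed cohort: one growing clone, one flat artifact-like trajectory,
# plus synonymous trajectories for calibration; the synonymous background
# spans a range of proportions so the calibrated theta prior covers the
# artifact's level
mixed_cohort <- function(seed = 71) {
  clone <- sim_trajectory(seed, 0.25, 4000)
  clone$participant_id <- "P1"
  clone$protein_change <- "p.R1W"
  clone$consequence <- "missense"
  flat <- {
    depth <- pmax(1, stats::rnbinom(5, mu = 2000, size = 1 / 0.09))
    tibble::tibble(participant_id = "P2", variant_id = "chr9:900:G:A",
                   gene = "GENE2", protein_change = "p.A5V",
                   consequence = "missense", age_years = test_waves,
                   depth = depth,
                   alt_reads = rbinom(5, depth, 0.012))
  }
  syn <- purrr::map_dfr(1:8, function(i) {
    depth <- pmax(1, stats::rnbinom(5, mu = 2000, size = 1 / 0.09))
    tibble::tibble(participant_id = sprintf("S%d", i),
                   variant_id = sprintf("chr2:%d:C:T", 2000 + i),
                   gene = "GENE3", protein_change = "p.L10=",
                   consequence = "synonymous", age_years = test_waves,
                   depth = depth,
                   alt_reads = rbinom(5, depth, runif(1, 0.002, 0.02)))
  })
  as_cohort(dplyr::bind_rows(clone, flat, syn))
}

test_that("lift_classify separates a growing clone from a flat trajectory", {
  lc <- lift_classify(mixed_cohort(), config = cfg_coarse())
  expect_s3_class(lc, "cf_lift")
  # synonymous trajectories are never classified
  expect_false(any(grepl("^S", lc$participant_id)))
  expect_identical(lc$call[lc$participant_id == "P1"], "fit")
  expect_identical(lc$call[lc$participant_id == "P2"], "filtered")
  expect_equal(lc$log_bf, lc$log_ev_clonal - lc$log_ev_artifact)
  expect_equal(lc$bayes_factor, exp(lc$log_bf))
  p <- ggplot2::autoplot(lc)
  expect_s3_class(p, "ggplot")
})

test_that("a Bayes factor exactly at the threshold is called fit", {
  co <- mixed_cohort()
  nz <- calibrate_noise(co)
  lc <- lift_classify(co, noise = nz, config = cfg_coarse())
  bf <- lc$bayes_factor[1]
  lc2 <- lift_classify(co, threshold = bf, noise = nz,
                       config = cfg_coarse())
  expect_identical(lc2$call[lc2$variant_id == lc$variant_id[1]], "fit")
})

test_that("raising the threshold never adds fit calls", {
  co <- mixed_cohort()
  nz <- calibrate_noise(co)
  lc2 <- lift_classify(co, threshold = 2, noise = nz, config = cfg_coarse())
  lc4 <- lift_classify(co, threshold = 4, noise = nz, config = cfg_coarse())
  fit2 <- lc2$variant_id[lc2$call == "fit"]
  fit4 <- lc4$variant_id[lc4$call == "fit"]
  expect_true(all(fit4 %in% fit2))
})

test_that("candidate pre-filter obeys min_timepoints and min_vaf", {
  co <- mixed_cohort()
  lc <- lift_classify(co, min_timepoints = 6, config = cfg_coarse())
  expect_equal(nrow(lc), 0)
  # a very high min_vaf excludes the flat trajectory (max VAF ~1.5%)
  lc2 <- lift_classify(co, min_vaf = 0.03, config = cfg_coarse())
  expect_false("P2" %in% lc2$participant_id)
  expect_error(lift_classify(co, threshold = 0))
})

test_that("flat trajectories at the synonymous noise level favour the artifact model", {
  cfg <- cfg_coarse()
  nz <- structure(list(rho = 0, theta_a = 1, theta_b = 99,
                       n_trajectories = 10L, n_variants = 2L,
                       fallback = FALSE), class = "cf_noise")
  set.seed(610)
  wins <- 0
  for (i in 1:100) {
    depth <- pmax(1, stats::rnbinom(5, mu = 2000, size = 1 / 0.09))
    alt <- rbinom(5, depth, 0.005)
    lec <- clonal_evidence(test_waves, alt, depth, cfg)
    lea <- artifact_evidence(alt, depth, nz, "binomial")
    if (lec < lea) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("expanding clones (s = 0.3, 3 waves) favour the clonal model", {
  cfg <- cfg_coarse()
  nz <- structure(list(rho = 0, theta_a = 1, theta_b = 99,
                       n_trajectories = 10L, n_variants = 2L,
                       fallback = FALSE), class = "cf_noise")
  waves3 <- c(70, 73, 76)
  set.seed(620)
  wins <- 0
  for (i in 1:100) {
    path <- simulate_clone(0.3, 1, 2041, waves3 - 70, n_rep = 1)[1, ]
    v <- vapply(path, function(n) vaf_from_counts(n, 1e5), numeric(1))
    depth <- pmax(1, stats::rnbinom(3, mu = 2000, size = 1 / 0.09))
    alt <- rbinom(3, depth, pmin(v, 0.5))
    lec <- clonal_evidence(waves3, alt, depth, cfg)
    lea <- artifact_evidence(alt, depth, nz, "binomial")
    if (lec > lea) wins <- wins + 1
  }
  expect_gte(wins, 95)
})
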