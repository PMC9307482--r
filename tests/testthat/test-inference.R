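test_that("credible_interval handles point masses and validates mass", {
  d <- c(0, 0, 1, 0)
  expect_equal(credible_interval(d, 1:4), c(3, 3))
  expect_error(credible_interval(d, 1:4, mass = 0))
  expect_error(credible_interval(d, 1:4, mass = 1))
})

test_that("credible_interval is symmetric for a discretised Gaussian", {
  grid <- seq(-5, 5, by = 0.01)
  d <- dnorm(grid)
  d <- d / sum(d)
  ci <- credible_interval(d, grid, 0.90)
  # symmetric unimodal density: interval symmetric about the mode, up to
  # the discreteness of the narrowest-window search (~2 grid steps)
  expect_lt(abs(ci[1] + ci[2]), 0.021)
  expect_lt(abs(mean(ci)), 0.011)
  # mass just reaches 0.90
  expect_gte(sum(d[grid >= ci[1] & grid <= ci[2]]), 0.90)
  expect_lt(sum(d[grid >= ci[1] & grid <= ci[2]]), 0.91)
})

test_that("map_s recovers the generating fitness on noiseless logistic data", {
  cfg <- cfg_coarse()
  n_w <- 1e5
  s <- 0.15
  v <- deterministic_vaf(test_waves, s, n_w, t0 = 40)
  dat <- tibble::tibble(participant_id = "P", variant_id = "v1", gene = "G",
                        age_years = test_waves, depth = 2000,
                        alt_reads = round(2000 * v))
  fit <- infer_posterior(dat, config = cfg)
  expect_s3_class(fit, "cf_fitness")
  expect_lte(abs(fit$clones$map_s - s), 0.01)  # one grid step
  expect_true(fit$clones$ci_lo <= fit$clones$map_s)
  expect_true(fit$clones$ci_hi >= fit$clones$map_s)
  expect_equal(sum(fit$clones$s_density[[1]]), 1)
  expect_equal(sum(fit$n_w_density), 1)
})

test_that("all-zero alt counts give a posterior near the fitness minimum", {
  cfg <- cfg_coarse()
  dat <- tibble::tibble(participant_id = "P", variant_id = "v1", gene = "G",
                        age_years = test_waves, depth = 2000, alt_reads = 0)
  fit <- infer_posterior(dat, config = cfg)
  expect_lte(fit$clones$map_s, 0.02)
})

test_that("infer_posterior validates its inputs", {
  cfg <- cfg_coarse()
  dat <- sim_trajectory(91, 0.2, 4000)
  expect_error(infer_posterior(dplyr::mutate(dat,
                 participant_id = c("A", "A", "B", "B", "B")), config = cfg))
  expect_error(infer_posterior(dat[1, ], config = cfg),
               class = "cf_insufficient_data")
})

test_that("tidy, glance and autoplot summarise a fitness fit", {
  cfg <- cfg_coarse()
  fit <- infer_posterior(sim_trajectory(92, 0.2, 4000), config = cfg)
  td <- generics::tidy(fit)
  expect_identical(td$participant_id, "P")
  expect_identical(td$variants[[1]], "v1")
  expect_true(all(c("map_s", "ci_lo", "ci_hi") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(gl$n_clones, 1)
  expect_true(is.finite(gl$log_evidence))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_output(print(fit), "MAP s")
})

test_that("shared-pool inference suppresses a clone's VAF when a fitter clone expands", {
  # two-clone participant: posterior respects the structure
  cfg <- cfg_structure()
  nw <- 1e5
  set.seed(93)
  p1 <- simulate_clone(0.05, 1, 8000, test_waves - 70, n_rep = 1)[1, ]
  p2 <- simulate_clone(0.30, 1, 8000, test_waves - 70, n_rep = 1)[1, ]
  vs <- sapply(seq_along(test_waves), function(k) {
    vaf_from_counts(c(p1[k], p2[k]), nw)
  })
  dat <- purrr::map_dfr(1:2, function(i) {
    rd <- simulate_reads(pmin(vs[i, ], 0.5), 2000, 0.3)
    tibble::tibble(participant_id = "P", variant_id = paste0("v", i),
                   gene = "G", age_years = test_waves,
                   depth = rd$depth, alt_reads = rd$alt_reads)
  })
  st <- clonal_structure("P", list("v1", "v2"))
  fit <- infer_posterior(dat, st, cfg)
  expect_equal(nrow(fit$clones), 2)
  expect_gt(fit$clones$map_s[2], fit$clones$map_s[1])
})
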