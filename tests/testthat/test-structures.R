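test_that("set partition counts follow the Bell numbers", {
  expect_equal(length(clonefit:::set_partitions(letters[1])), 1)
  expect_equal(length(clonefit:::set_partitions(letters[1:2])), 2)
  expect_equal(length(clonefit:::set_partitions(letters[1:3])), 5)
  expect_equal(length(enumerate_structures(letters[1:8], "P")), 4140)
  expect_error(enumerate_structures(letters[1:9], "P"))
})

test_that("structure prior weight penalises merges", {
  st1 <- clonal_structure("P", list("a", "b", "c"), kappa = 0.5)
  expect_equal(st1$merges, 0)
  expect_equal(st1$prior_log_weight, 0)
  st2 <- clonal_structure("P", list(c("a", "b"), "c"), kappa = 0.5)
  expect_equal(st2$merges, 1)
  expect_equal(st2$prior_log_weight, log(0.5))
  st3 <- clonal_structure("P", list(c("a", "b", "c")), kappa = 0.25)
  expect_equal(st3$merges, 2)
  expect_equal(st3$prior_log_weight, 2 * log(0.25))
})

test_that("structure evidence requires a true partition of the variants", {
  dat <- sim_trajectory(81, 0.2, 4000)
  st <- clonal_structure("P", list("v1", "v2"))
  expect_error(structure_log_evidence(dat, st, cfg_coarse()),
               class = "cf_validation_error")
})

test_that("single-variant structure evidence equals the clonal evidence", {
  cfg <- cfg_coarse()
  dat <- sim_trajectory(82, 0.2, 4000)
  st <- clonal_structure("P", list("v1"))
  ev <- structure_log_evidence(dat, st, cfg)
  expect_equal(ev,
               clonal_evidence(dat$age_years, dat$alt_reads, dat$depth, cfg))
})

test_that("select_structure merges co-moving variants and splits distinct ones", {
  cfg <- cfg_structure()
  nw <- 1e5
  # merged truth: two variants on one clone share the latent path
  set.seed(83)
  path <- simulate_clone(0.2, 1, round(2 * 0.05 * nw / 0.9),
                         test_waves - 70, n_rep = 1)[1, ]
  v <- vapply(path, function(n) vaf_from_counts(n, nw), numeric(1))
  dat_m <- purrr::map_dfr(1:2, function(i) {
    rd <- simulate_reads(pmin(v, 0.5), 2000, 0.3)
    tibble::tibble(participant_id = "P", variant_id = paste0("v", i),
                   gene = "G", age_years = test_waves,
                   depth = rd$depth, alt_reads = rd$alt_reads)
  })
  sel_m <- select_structure(dat_m, cfg)
  expect_s3_class(sel_m, "cf_structure_selection")
  expect_equal(length(sel_m$best$clones), 1)
  expect_equal(nrow(sel_m$candidates), 2)  # Bell(2)
  td <- generics::tidy(sel_m)
  expect_true(any(grepl("\\{v1,v2\\}", td$partition)))
  expect_equal(sum(td$is_best), 1)

  # independent truth: two clones at distinct VAFs and fitnesses
  set.seed(84)
  p1 <- simulate_clone(0.1, 1, round(2 * 0.02 * nw / (1 - 2 * 0.1)),
                       test_waves - 70, n_rep = 1)[1, ]
  p2 <- simulate_clone(0.3, 1, round(2 * 0.08 * nw / (1 - 2 * 0.16)),
                       test_waves - 70, n_rep = 1)[1, ]
  vs <- sapply(seq_along(test_waves), function(k) {
    vaf_from_counts(c(p1[k], p2[k]), nw)
  })
  dat_i <- purrr::map_dfr(1:2, function(i) {
    rd <- simulate_reads(pmin(vs[i, ], 0.5), 2000, 0.3)
    tibble::tibble(participant_id = "P", variant_id = paste0("v", i),
                   gene = "G", age_years = test_waves,
                   depth = rd$depth, alt_reads = rd$alt_reads)
  })
  sel_i <- select_structure(dat_i, cfg)
  expect_equal(length(sel_i$best$clones), 2)
})
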