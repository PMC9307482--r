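# Shared helpers for the test suite.
#
# Inference configurations are deliberately coarser than the package
# defaults so that repeated-simulation tests fit the suite's time budget;
# each was checked for adequacy on the problems it is used for (latent
# resolution in particular: coarse latent grids bias fitness MAPs upward
# when the cell width exceeds the sampling noise, so the calibration tests
# use 200 latent points).

# five sampling waves, three years apart, late life
test_waves <- seq(70, 82, by = 3)

# general-purpose coarse config (LiFT, smoke-level inference)
cfg_coarse <- function() {
  inference_config(s_grid = seq(0, 0.5, by = 0.01),
                   n_w_grid = 10^seq(3, 6, length.out = 7),
                   latent_points = 100)
}

# calibration config: fine enough latent grid for unbiased MAPs
cfg_calibration <- function() {
  inference_config(s_grid = seq(0, 0.25, by = 0.005),
                   n_w_grid = 10^seq(3, 6, length.out = 7),
                   latent_points = 200)
}

# structure-selection config: lean, two-candidate problems
cfg_structure <- function() {
  inference_config(s_grid = seq(0, 0.5, by = 0.02),
                   n_w_grid = 10^seq(3, 6, length.out = 5),
                   latent_points = 100)
}

# One participant, one variant: exact Gillespie latent path against a pool
# of nw_true wild-type cells, binomial reads at ~2000x.
sim_trajectory <- function(seed, s_true, n0, nw_true = 1e5,
                           waves = test_waves, depth_mean = 2000,
                           depth_cv = 0.3) {
  set.seed(seed)
  path <- simulate_clone(s_true, 1, n0, waves - waves[1], n_rep = 1)[1, ]
  v <- vapply(path, function(n) vaf_from_counts(n, nw_true), numeric(1))
  rd <- simulate_reads(pmin(v, 0.5), depth_mean, depth_cv)
  tibble::tibble(participant_id = "P", variant_id = "v1", gene = "GENE",
                 age_years = waves, depth = rd$depth,
                 alt_reads = rd$alt_reads)
}

# Small valid cohort table for IO/QC tests.
toy_cohort_df <- function() {
  tibble::tibble(
    participant_id = rep(c("A", "B"), each = 4),
    variant_id = rep(c("chr1:100:A:G", "chr2:200:C:T"), each = 4),
    gene = rep(c("DNMT3A", "TET2"), each = 4),
    protein_change = rep(c("p.R882H", "p.Q123*"), each = 4),
    consequence = rep(c("missense", "nonsense"), each = 4),
    age_years = rep(c(70, 73, 76, 79), 2),
    depth = rep(2000L, 8),
    alt_reads = c(30L, 45L, 60L, 80L, 100L, 90L, 110L, 105L))
}
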