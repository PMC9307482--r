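#' Simulate sequencing reads at a given VAF
#'
#' Draws a sequencing depth from a negative-binomial depth model (mean
#' `depth_mean`, coefficient of variation `depth_cv`) and variant-supporting
#' reads from binomial sampling at VAF `v`, or beta-binomial sampling with
#' overdispersion `rho` for artifact-like noise.
#'
#' @param v Underlying VAF(s) in `[0, 0.5]`; one draw per element.
#' @param depth_mean,depth_cv Depth model: negative binomial with this mean
#'   and coefficient of variation (defaults 2000 and 0.3); depths below 1
#'   are clamped to 1.
#' @param rho Beta-binomial overdispersion; 0 (default) gives binomial
#'   sampling.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `depth` and `alt_reads`.
#' @export
simulate_reads <- function(v, depth_mean = 2000, depth_cv = 0.3, rho = 0,
                           seed = NULL) {
  if (any(v < 0 | v > 0.5)) abort("`v` must lie in [0, 0.5].")
  if (!is.null(seed)) set.seed(seed)
  n <- length(v)
  depth <- draw_depths(n, depth_mean, depth_cv)
  p <- if (rho > 0) {
    a <- v * (1 - rho) / rho
    b <- (1 - v) * (1 - rho) / rho
    ifelse(v > 0, rbeta(n, a, b), 0)
  } else v
  tibble::tibble(depth = depth, alt_reads = rbinom(n, depth, p))
}

draw_depths <- function(n, depth_mean, depth_cv) {
  if (depth_cv <= 0) return(rep(round(depth_mean), n))
  v <- (depth_cv * depth_mean)^2
  if (v <= depth_mean) {
    return(pmax(1, stats::rpois(n, depth_mean)))
  }
  size <- depth_mean^2 / (v - depth_mean)
  pmax(1, rnbinom(n, size = size, mu = depth_mean))
}

#' Define a synthetic-cohort scenario
#'
#' Describes a cohort to simulate: the sampling design (wave ages roughly
#' three years apart in late life, deep targeted sequencing), a set of true
#' clones with given fitnesses, a set of flat sequencing-artifact
#' trajectories with beta-binomial overdispersion, and a set of synonymous
#' (neutral passenger) trajectories used for noise calibration.
#'
#' @param clones A tibble with one row per clone: `s` (fitness per year),
#'   `n0` (clone size in cells at the first wave) or `t0` (acquisition age
#'   in years, clone then grown from one cell), `n_variants` (markers on
#'   the clone, default 1) and optionally `participant_id` and `gene`.
#'   Clones sharing a `participant_id` compete for one pool.
#' @param waves Sampling ages in years (default five waves, ages 70-82).
#' @param n_artifacts,artifact_theta,artifact_rho Flat artifact
#'   trajectories: count, mean proportion and beta-binomial overdispersion.
#' @param n_synonymous,synonymous_theta Synonymous trajectories: count and
#'   mean proportion (binomially sampled).
#' @param n_w Wild-type pool size (default 1e5).
#' @param lambda Symmetric division rate per year (default 1).
#' @param depth_mean,depth_cv Sequencing depth model (defaults 2000, 0.3).
#' @param seed Mandatory RNG seed.
#' @return A `cf_scenario` list.
#' @export
sim_scenario <- function(clones = tibble::tibble(s = numeric(),
                                                 n0 = numeric(),
                                                 n_variants = integer()),
                         waves = seq(70, 82, by = 3),
                         n_artifacts = 0, artifact_theta = 0.005,
                         artifact_rho = 0.01,
                         n_synonymous = 0, synonymous_theta = 0.005,
                         n_w = 1e5, lambda = 1,
                         depth_mean = 2000, depth_cv = 0.3,
                         seed) {
  if (missing(seed)) abort("`seed` is mandatory for a scenario.")
  if (is.unsorted(waves, strictly = TRUE)) {
    abort("`waves` must be strictly increasing.")
  }
  clones <- tibble::as_tibble(clones)
  if (nrow(clones) > 0) {
    if (!"n_variants" %in% names(clones)) clones$n_variants <- 1L
    if (!"participant_id" %in% names(clones)) {
      clones$participant_id <- sprintf("P%03d", seq_len(nrow(clones)))
    }
    if (!"gene" %in% names(clones)) {
      drivers <- c("DNMT3A", "TET2", "JAK2", "ASXL1", "TP53", "SF3B1",
                   "SRSF2", "U2AF1")
      clones$gene <- drivers[(seq_len(nrow(clones)) - 1) %% length(drivers) + 1]
    }
    if (!"n0" %in% names(clones) && !"t0" %in% names(clones)) {
      abort("`clones` needs an `n0` or `t0` column.")
    }
  }
  structure(list(clones = clones, waves = waves,
                 n_artifacts = n_artifacts, artifact_theta = artifact_theta,
                 artifact_rho = artifact_rho,
                 n_synonymous = n_synonymous,
                 synonymous_theta = synonymous_theta,
                 n_w = n_w, lambda = lambda,
                 depth_mean = depth_mean, depth_cv = depth_cv, seed = seed),
            class = "cf_scenario")
}

#' Simulate a longitudinal cohort with ground truth
#'
#' Latent clone sizes follow exact Gillespie birth-death paths; clones of
#' one participant share the stem-cell pool, so their VAFs are coupled
#' through the joint VAF map. Reads are sampled binomially at the latent
#' VAF (beta-binomially for artifacts). Variants on the same clone share
#' one latent size path and differ only in read sampling. Artifact and
#' synonymous trajectories are flat: a per-variant proportion held constant
#' over waves.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with `cohort` (a `cf_cohort`) and `truth` (a tibble per
#'   variant: `participant_id`, `variant_id`, `type`
#'   (clone/artifact/synonymous), `s_true`, `clone_id`, `theta`,
#'   `started_from`, where clones grown from one cell at `t0` are flagged
#'   distinctly from clones seeded at `n0` cells at the first wave).
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cf_scenario"))
  set.seed(scenario$seed)
  waves <- scenario$waves
  K <- length(waves)
  rows <- list()
  truth <- list()
  vcount <- 0L
  new_vid <- function() {
    vcount <<- vcount + 1L
    sprintf("chr%d:%d:A:G", (vcount - 1L) %% 22 + 1L, 1e6 + vcount * 101L)
  }

  cl <- scenario$clones
  if (nrow(cl) > 0) {
    for (pid in unique(cl$participant_id)) {
      sub <- cl[cl$participant_id == pid, ]
      sub$started_from <- NA_character_
      # latent size path per clone of this participant
      paths <- matrix(0, nrow(sub), K)
      for (ci in seq_len(nrow(sub))) {
        if ("n0" %in% names(sub) && !is.na(sub$n0[ci])) {
          n_start <- sub$n0[ci]
          grid <- waves - waves[1]
          from <- "n0_at_first_wave"
        } else {
          n_start <- 1
          grid <- waves - sub$t0[ci]
          if (any(grid < 0)) abort("`t0` must precede the first wave.")
          from <- "one_cell_at_t0"
        }
        path <- simulate_clone(sub$s[ci], scenario$lambda, n_start,
                               pmax(grid, 1e-9), n_rep = 1)[1, ]
        paths[ci, ] <- path
        sub$started_from[ci] <- from
      }
      # shared-pool VAFs, jointly across this participant's clones
      vafs <- sapply(seq_len(K), function(k) {
        vaf_from_counts(paths[, k], scenario$n_w)
      })
      vafs <- matrix(vafs, nrow = nrow(sub))
      for (ci in seq_len(nrow(sub))) {
        clone_id <- sprintf("%s_c%d", pid, ci)
        for (m in seq_len(sub$n_variants[ci])) {
          vid <- new_vid()
          rd <- simulate_reads(pmin(vafs[ci, ], 0.5),
                               scenario$depth_mean, scenario$depth_cv)
          rows[[length(rows) + 1]] <- tibble::tibble(
            participant_id = pid, variant_id = vid, gene = sub$gene[ci],
            protein_change = sprintf("p.X%dY", vcount),
            consequence = "missense", age_years = waves,
            depth = rd$depth, alt_reads = rd$alt_reads)
          truth[[length(truth) + 1]] <- tibble::tibble(
            participant_id = pid, variant_id = vid, type = "clone",
            s_true = sub$s[ci], clone_id = clone_id, theta = NA_real_,
            started_from = sub$started_from[ci])
        }
      }
    }
  }

  flat_set <- function(n, theta_mean, rho, consequence, type, prefix) {
    for (i in seq_len(n)) {
      pid <- sprintf("%s%03d", prefix, i)
      vid <- new_vid()
      theta <- rbeta(1, 2, 2 / theta_mean - 2) # mean theta_mean, modest spread
      rd <- simulate_reads(rep(theta, K), scenario$depth_mean,
                           scenario$depth_cv, rho = rho)
      rows[[length(rows) + 1]] <<- tibble::tibble(
        participant_id = pid, variant_id = vid,
        gene = sample(c("GENE1", "GENE2", "GENE3"), 1),
        protein_change = if (consequence == "synonymous") {
          sprintf("p.X%d=", vcount)
        } else sprintf("p.X%dY", vcount),
        consequence = consequence, age_years = waves,
        depth = rd$depth, alt_reads = rd$alt_reads)
      truth[[length(truth) + 1]] <<- tibble::tibble(
        participant_id = pid, variant_id = vid, type = type,
        s_true = 0, clone_id = NA_character_, theta = theta,
        started_from = NA_character_)
    }
  }
  flat_set(scenario$n_artifacts, scenario$artifact_theta,
           scenario$artifact_rho, "missense", "artifact", "A")
  flat_set(scenario$n_synonymous, scenario$synonymous_theta, 0,
           "synonymous", "synonymous", "S")

  cohort <- as_cohort(dplyr::bind_rows(rows),
                      provenance = sprintf("simulated (seed %d)",
                                           scenario$seed))
  list(cohort = cohort, truth = dplyr::bind_rows(truth))
}
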