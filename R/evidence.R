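# cached Gauss-Legendre rules, keyed by order
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre01 <- function(order) {
  key <- as.character(order)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(order, 0, 1)
  }
  .gl_cache[[key]]
}

#' Model evidence under the sequencing-artifact model
#'
#' The artifact model holds that a trajectory's reads arise from a single
#' underlying proportion `theta` that does not change over time; the
#' evidence integrates the product of per-timepoint read likelihoods over
#' the calibrated Beta prior on `theta` by fixed-order Gauss-Legendre
#' quadrature. Recurrent variants (seen in several participants) use a
#' beta-binomial read likelihood with the calibrated overdispersion `rho`;
#' unique variants use plain binomial sampling.
#'
#' @param alt,depth Read counts across the trajectory's timepoints.
#'   Zero-depth points are skipped with a warning.
#' @param noise A `cf_noise` from [calibrate_noise()].
#' @param family `"binomial"` (unique variants) or `"beta_binomial"`
#'   (recurrent variants).
#' @param order Quadrature order (default 256).
#' @return Log evidence.
#' @export
artifact_evidence <- function(alt, depth, noise,
                              family = c("binomial", "beta_binomial"),
                              order = 256) {
  family <- match.arg(family)
  if (any(depth == 0)) {
    warn("Skipping zero-depth timepoint(s) in artifact evidence.")
    alt <- alt[depth > 0]
    depth <- depth[depth > 0]
  }
  rho <- if (family == "beta_binomial") noise$rho else 0
  gl <- gauss_legendre01(order)
  li <- vapply(gl$x, function(theta) {
    dbeta(theta, noise$theta_a, noise$theta_b, log = TRUE) +
      sum(dbetabinom(alt, depth, theta, rho, log = TRUE))
  }, numeric(1))
  logsumexp(log(gl$w) + li)
}

#' Model evidence under the clonal-dynamics model
#'
#' Marginal likelihood of a single expanding clone for one trajectory:
#' fitness and pool size are marginalised over their prior grids and latent
#' clone sizes over the forward pass (see [infer_posterior()]).
#'
#' @param ages Observation ages in years (at least two).
#' @param alt,depth Read counts per age.
#' @param config An [inference_config()].
#' @return Log evidence.
#' @export
clonal_evidence <- function(ages, alt, depth, config = inference_config()) {
  keep <- depth > 0
  if (!all(keep)) {
    warn("Skipping zero-depth timepoint(s) in clonal evidence.")
  }
  obs <- tibble::tibble(age = ages[keep], alt = alt[keep],
                        depth = depth[keep])
  if (length(unique(obs$age)) < 2) {
    abort("Clonal evidence needs observations at two or more ages.",
          class = "cf_insufficient_data")
  }
  L <- clone_loglik_grid(obs, config)
  logsumexp(sweep(L + config$log_prior_s, 2, config$log_prior_n_w, `+`))
}

#' LiFT: classify trajectories as fit clones or sequencing artifacts
#'
#' For every candidate trajectory (by default: at least `min_timepoints`
#' timepoints and a maximum VAF above `min_vaf`), compares the evidence of
#' the clonal-dynamics model against the artifact model and calls the
#' trajectory `fit` when the Bayes factor reaches `threshold` (the default
#' of 4 requires the clonal model to be at least four times better
#' supported). Synonymous trajectories are the noise-calibration set and are
#' never classified; they are excluded from the results.
#'
#' @param cohort A `cf_cohort`.
#' @param threshold Bayes-factor threshold (default 4).
#' @param min_timepoints,min_vaf Candidate pre-filter (defaults 2 and 0.01).
#' @param noise A `cf_noise`; when `NULL` it is calibrated from the
#'   cohort's synonymous trajectories (falling back to documented defaults).
#' @param config An [inference_config()] used for the clonal evidence.
#' @param quadrature_order Gauss-Legendre order for the artifact evidence.
#' @return A `cf_lift` tibble, one row per candidate trajectory, with the
#'   log evidences, `bayes_factor`, `log_bf`, `artifact_family` and the
#'   `call` (`"fit"` or `"filtered"`). First/last VAFs and the VAF gradient
#'   are included for plotting.
#' @export
lift_classify <- function(cohort, threshold = 4, min_timepoints = 2,
                          min_vaf = 0.01, noise = NULL,
                          config = inference_config(),
                          quadrature_order = 256) {
  if (threshold <= 0) abort("`threshold` must be positive.")
  if (is.null(noise)) noise <- calibrate_noise(cohort)

  df <- tibble::as_tibble(cohort)
  traj <- dplyr::summarise(
    dplyr::group_by(df, .data$participant_id, .data$variant_id, .data$gene,
                    .data$consequence, .data$recurrent),
    n_tp = dplyr::n_distinct(.data$age_years), max_vaf = max(.data$vaf),
    .groups = "drop")
  cand <- dplyr::filter(traj, .data$n_tp >= min_timepoints,
                        .data$max_vaf > min_vaf,
                        .data$consequence != "synonymous")
  if (nrow(cand) == 0) {
    empty <- tibble::tibble(
      participant_id = character(), variant_id = character(),
      gene = character(), n_timepoints = integer(), max_vaf = numeric(),
      vaf_first = numeric(), gradient = numeric(),
      log_ev_clonal = numeric(), log_ev_artifact = numeric(),
      artifact_family = character(), log_bf = numeric(),
      bayes_factor = numeric(), call = character())
    return(new_lift(empty, threshold, noise))
  }

  res <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    rows <- df[df$participant_id == cand$participant_id[i] &
                 df$variant_id == cand$variant_id[i], ]
    fam <- if (cand$recurrent[i]) "beta_binomial" else "binomial"
    lec <- clonal_evidence(rows$age_years, rows$alt_reads, rows$depth,
                           config)
    lea <- artifact_evidence(rows$alt_reads, rows$depth, noise, fam,
                             order = quadrature_order)
    tibble::tibble(
      participant_id = cand$participant_id[i],
      variant_id = cand$variant_id[i],
      gene = cand$gene[i],
      n_timepoints = cand$n_tp[i],
      max_vaf = cand$max_vaf[i],
      vaf_first = rows$vaf[which.min(rows$age_years)],
      gradient = vaf_gradient(rows$age_years, rows$vaf),
      log_ev_clonal = lec,
      log_ev_artifact = lea,
      artifact_family = fam)
  })
  res$log_bf <- res$log_ev_clonal - res$log_ev_artifact
  res$bayes_factor <- exp(pmin(res$log_bf, 700))
  res$call <- ifelse(res$log_bf >= log(threshold), "fit", "filtered")
  new_lift(res, threshold, noise)
}

new_lift <- function(df, threshold, noise) {
  attr(df, "threshold") <- threshold
  attr(df, "noise") <- noise
  class(df) <- unique(c("cf_lift", class(tibble::tibble())))
  df
}
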