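#' Beta-binomial density parameterised by mean and overdispersion
#'
#' `theta` is the mean success proportion and `rho` the intra-class
#' correlation: the beta mixing distribution is
#' `Beta(theta * (1 - rho) / rho, (1 - theta) * (1 - rho) / rho)`.
#' `rho = 0` reduces exactly to the binomial.
#'
#' @param x Number of successes.
#' @param size Number of trials.
#' @param theta Mean proportion in (0, 1).
#' @param rho Overdispersion in `[0, 1)`.
#' @param log Return log density?
#' @return (Log) probability mass; vectorised over `x`, `size`, `theta`.
#' @export
dbetabinom <- function(x, size, theta, rho, log = FALSE) {
  if (any(rho < 0 | rho >= 1)) abort("`rho` must lie in [0, 1).")
  if (rho == 0) return(dbinom(x, size, theta, log = log))
  a <- theta * (1 - rho) / rho
  b <- (1 - theta) * (1 - rho) / rho
  ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  if (log) ll else exp(ll)
}

#' Calibrate the sequencing-artifact noise model on synonymous variants
#'
#' Synonymous variants confer no fitness advantage, so their read-count
#' trajectories measure the assay's noise. Observations are pooled per
#' variant (each variant has its own constant underlying proportion theta)
#' and a single overdispersion `rho` is estimated by profile maximum
#' likelihood of the beta-binomial. The prior on the artifact proportion is
#' a Beta distribution moment-matched to the per-variant mean VAFs.
#'
#' @param cohort A `cf_cohort`; rows with `consequence == "synonymous"` are
#'   used. A plain tibble of synonymous observations also works.
#' @param min_trajectories Below this many synonymous trajectories the
#'   documented defaults are returned with a warning (default 5).
#' @param default_rho,default_theta_prior Fallback values: `rho = 0.01` and
#'   `Beta(1, 99)` (mean 0.01).
#' @return A `cf_noise` list: `rho`, `theta_a`, `theta_b`, `n_trajectories`,
#'   `n_variants`, `fallback`.
#' @export
calibrate_noise <- function(cohort, min_trajectories = 5,
                            default_rho = 0.01,
                            default_theta_prior = c(1, 99)) {
  df <- tibble::as_tibble(cohort)
  if ("consequence" %in% names(df)) {
    df <- dplyr::filter(df, .data$consequence == "synonymous")
  }
  n_traj <- if (nrow(df) == 0) 0 else {
    nrow(dplyr::distinct(df, .data$participant_id, .data$variant_id))
  }
  fallback <- function() {
    warn(sprintf(
      "Only %d synonymous trajectories (< %d); using default noise model.",
      n_traj, min_trajectories))
    new_noise(default_rho, default_theta_prior[1], default_theta_prior[2],
              n_traj, 0L, fallback = TRUE)
  }
  if (n_traj < min_trajectories) return(fallback())

  groups <- split(df[c("alt_reads", "depth")], df$variant_id)

  profile_ll <- function(rho) {
    sum(vapply(groups, function(g) {
      f <- function(theta) {
        -sum(dbetabinom(g$alt_reads, g$depth, theta, rho, log = TRUE))
      }
      -optimize(f, c(1e-7, 0.5))$objective
    }, numeric(1)))
  }
  # profile likelihood over log(rho); lower bound effectively binomial
  opt <- optimize(function(lr) -profile_ll(exp(lr)),
                  c(log(1e-7), log(0.5)), tol = 1e-4)
  rho <- exp(opt$minimum)
  ll_binom <- profile_ll(0)
  if (ll_binom >= -opt$objective) rho <- 0

  vbar <- vapply(groups, function(g) sum(g$alt_reads) / sum(g$depth),
                 numeric(1))
  m <- mean(vbar)
  v <- stats::var(vbar)
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m) || m <= 0 || m >= 1) {
    a <- default_theta_prior[1]
    b <- default_theta_prior[2]
  } else {
    common <- m * (1 - m) / v - 1
    a <- max(m * common, 1e-2)
    b <- max((1 - m) * common, 1e-2)
  }
  new_noise(rho, a, b, n_traj, length(groups), fallback = FALSE)
}

new_noise <- function(rho, a, b, n_traj, n_var, fallback) {
  structure(list(rho = rho, theta_a = a, theta_b = b,
                 n_trajectories = n_traj, n_variants = n_var,
                 fallback = fallback),
            class = "cf_noise")
}

#' @export
print.cf_noise <- function(x, ...) {
  cat(sprintf(
    "<cf_noise> rho = %.4g, theta ~ Beta(%.3g, %.3g)%s (%d trajectories)\n",
    x$rho, x$theta_a, x$theta_b,
    if (x$fallback) " [defaults]" else "", x$n_trajectories))
  invisible(x)
}
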