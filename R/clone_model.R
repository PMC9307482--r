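#' Conditional clone-size distribution under the birth-death model
#'
#' A mutant clone of hematopoietic stem/progenitor cells is modelled as a
#' linear birth-death process in which every cell divides symmetrically at
#' rate `b = lambda + s` and is lost (death or differentiation) at rate
#' `d = lambda`. The fitness `s` is the excess self-renewal per year, so the
#' expected clone size grows as `exp(s * dt)`. Conditional on a current size
#' `n1`, the size after `dt` years has mean `n1 * exp(s*dt)` and variance
#' `n1 * ((2*lambda + s)/s) * exp(s*dt) * (exp(s*dt) - 1)` (for `s != 0`;
#' the `s -> 0` limit is `2 * lambda * n1 * dt`), and its full distribution
#' is well approximated by a negative binomial matched to these two moments.
#'
#' @param n1 Current clone size in cells (non-negative).
#' @param s Fitness per year. May be negative down to `-lambda`.
#' @param lambda Symmetric division rate per year (default 1).
#' @param dt Elapsed time in years (non-negative).
#'
#' @return A one-row tibble with columns `mean`, `variance`, `family`
#'   (`"negative_binomial"`, `"poisson_fallback"` when the computed variance
#'   does not exceed the mean, or `"point_mass"` when `dt == 0` or
#'   `n1 == 0`), and the negative-binomial parameters `size` and `prob`
#'   (`NA` unless `family == "negative_binomial"`).
#' @examples
#' clone_transition(100, s = 0.1, lambda = 1, dt = 3)
#' @export
clone_transition <- function(n1, s, lambda = 1, dt) {
  if (n1 < 0 || dt < 0) abort("`n1` and `dt` must be non-negative.")
  if (lambda <= 0) abort("`lambda` must be positive.")
  if (lambda + s < 0) abort("`s` must satisfy s > -lambda (birth rate >= 0).")
  mom <- transition_moments(n1, s, lambda, dt)
  m <- mom$mean
  v <- mom$variance
  if (dt == 0 || n1 == 0) {
    family <- "point_mass"
    size <- NA_real_
    prob <- NA_real_
  } else if (v > m) {
    family <- "negative_binomial"
    size <- m^2 / (v - m)
    prob <- m / v
  } else {
    family <- "poisson_fallback"
    size <- NA_real_
    prob <- NA_real_
  }
  tibble::tibble(mean = m, variance = v, family = family,
                 size = size, prob = prob)
}

# Vectorised mean/variance of the conditional birth-death transition.
transition_moments <- function(n1, s, lambda, dt) {
  E <- exp(s * dt)
  if (s == 0) {
    v <- 2 * lambda * n1 * dt
  } else {
    # expm1 keeps (e^{s dt} - 1)/s accurate for small |s dt|
    v <- n1 * ((2 * lambda + s) / s) * E * expm1(s * dt)
  }
  list(mean = n1 * E, variance = v)
}

#' Map clone sizes to variant allele frequencies under a shared pool
#'
#' Heterozygous clones of sizes `n_i` competing over a common pool of
#' `N_w` wild-type stem cells have VAF `v_i = n_i / (2 * (N_w + sum(n)))`.
#' Each VAF lies in `[0, 0.5)` and their total cell count is conserved.
#'
#' @param clone_sizes Numeric vector of clone sizes (cells, non-negative).
#' @param n_w Wild-type stem-cell pool size (>= 1).
#' @return Numeric vector of VAFs, one per clone.
#' @examples
#' vaf_from_counts(c(1e4, 2e4), n_w = 1e5)
#' @export
vaf_from_counts <- function(clone_sizes, n_w) {
  if (any(clone_sizes < 0)) abort("Clone sizes must be non-negative.")
  if (n_w < 1) abort("`n_w` must be at least 1.")
  clone_sizes / (2 * (n_w + sum(clone_sizes)))
}

#' Invert the single-clone VAF map
#'
#' For a single clone against a pool of `n_other` non-member cells,
#' `v = n / (2 * (n_other + n))`, so `n = 2 * n_other * v / (1 - 2 * v)`.
#'
#' @param v VAF in `[0, 0.5)`.
#' @param n_other Cells outside the clone (wild-type pool plus any other
#'   clones).
#' @return Clone size in cells.
#' @export
clone_size_from_vaf <- function(v, n_other) {
  if (any(v < 0 | v >= 0.5)) abort("`v` must lie in [0, 0.5).")
  2 * n_other * v / (1 - 2 * v)
}

#' Binomial sequencing-sampling log likelihood
#'
#' Read sampling at a variant site is approximated as binomial: `alt`
#' variant-supporting reads out of `depth` at underlying VAF `v`.
#'
#' @param alt,depth Read counts with `0 <= alt <= depth`.
#' @param v Underlying VAF in `[0, 1]`.
#' @return Log probability (may be `-Inf`).
#' @export
sampling_loglik <- function(alt, depth, v) {
  if (any(alt > depth) || any(alt < 0)) abort("Require 0 <= alt <= depth.")
  if (any(v < 0 | v > 1)) abort("`v` must lie in [0, 1].")
  dbinom(alt, depth, v, log = TRUE)
}

#' Deterministic (mean-field) VAF growth curve
#'
#' The expected VAF of a single clone founded by one cell at time `t0`
#' follows the logistic curve `v(t) = 1 / (2 + 2 * N_w * exp(-s * (t - t0)))`,
#' rising from `1 / (2 + 2 * N_w)` at `t = t0` towards the heterozygous
#' asymptote of 0.5.
#'
#' @param t Time (years); vectorised.
#' @param s Fitness per year.
#' @param n_w Wild-type pool size.
#' @param t0 Time of mutation acquisition (years).
#' @return VAF values.
#' @export
deterministic_vaf <- function(t, s, n_w, t0) {
  1 / (2 + 2 * n_w * exp(-s * (t - t0)))
}

#' Maximum-likelihood acquisition time for display fits
#'
#' Given point estimates of fitness and pool size, finds the acquisition
#' time `t0` that maximises the binomial likelihood of the observed reads
#' under the deterministic logistic curve. Used only to anchor plotted
#' growth curves; it plays no role in fitness inference.
#'
#' @param ages Observation ages (years).
#' @param alt,depth Read counts per observation.
#' @param s Fitness point estimate (> 0).
#' @param n_w Pool-size point estimate.
#' @param max_lookback Search window before the first observation (years).
#' @return The estimated `t0` in years (at most `min(ages)`).
#' @export
fit_t0_mle <- function(ages, alt, depth, s, n_w, max_lookback = 200) {
  if (s <= 0) abort("`s` must be positive to fit an acquisition time.")
  if (length(ages) < 1) abort("Need at least one observation.")
  nll <- function(t0) {
    -sum(sampling_loglik(alt, depth, deterministic_vaf(ages, s, n_w, t0)))
  }
  lo <- min(ages) - max_lookback
  hi <- min(ages)
  # coarse grid then local refinement: the profile can be flat far from the
  # data, so bracket the optimum first
  grid <- seq(lo, hi, length.out = 512)
  vals <- vapply(grid, nll, numeric(1))
  i <- which.min(vals)
  lo_i <- grid[max(1, i - 1)]
  hi_i <- grid[min(length(grid), i + 1)]
  if (lo_i == hi_i) return(grid[i])
  opt <- optimize(nll, c(lo_i, hi_i), tol = 1e-8)
  if (nll(hi) <= opt$objective) hi else opt$minimum
}

#' Exact stochastic simulation of a clone's growth
#'
#' Samples exact continuous-time birth-death paths (birth rate
#' `lambda + s`, death rate `lambda` per cell) by the Gillespie algorithm,
#' recording clone size at the requested times. This is the reference
#' implementation against which the negative-binomial moment approximation
#' is validated.
#'
#' @param s Fitness per year (>= -lambda).
#' @param lambda Symmetric division rate per year.
#' @param n0 Initial clone size (cells, >= 1).
#' @param t_grid Increasing recording times (years, measured from now).
#' @param n_rep Number of independent replicate paths.
#' @param seed Optional RNG seed applied via [set.seed()].
#' @return A numeric matrix of clone sizes, `n_rep` rows by
#'   `length(t_grid)` columns.
#' @examples
#' simulate_clone(s = 0.1, lambda = 1, n0 = 50, t_grid = c(1, 3), n_rep = 10,
#'                seed = 1)
#' @export
simulate_clone <- function(s, lambda = 1, n0, t_grid, n_rep = 1, seed = NULL) {
  if (n0 < 1) abort("`n0` must be at least 1.")
  if (is.unsorted(t_grid, strictly = TRUE)) {
    abort("`t_grid` must be strictly increasing.")
  }
  if (lambda + s < 0) abort("`s` must satisfy s >= -lambda.")
  if (!is.null(seed)) set.seed(seed)
  cf_gillespie(as.integer(n_rep), as.numeric(n0), lambda + s, lambda,
               as.numeric(t_grid))
}
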