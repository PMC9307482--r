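# Hidden-Markov forward pass over a discretised latent VAF grid.
#
# The latent state of a clone at each observation age is its VAF, discretised
# on a logit-spaced grid spanning [1/(2(N_w+1)), ~0.5). Grid cells map to
# clone sizes through n = 2 v (N_w + M) / (1 - 2 v), where M is the number of
# cells in other clones sharing the pool at that age (0 for a lone clone).
# Between ages the clone size evolves by the negative-binomial transition of
# the birth-death model (Poisson fallback when variance <= mean); at each age
# every member variant's reads are emitted binomially given the latent VAF.

#' Inference configuration: grids and priors
#'
#' Controls the discretisation used by the grid-based posterior: the fitness
#' grid (uniform prior), the wild-type pool-size grid (log-spaced points with
#' uniform weights, i.e. a log-uniform prior), the latent VAF grid
#' resolution, and the symmetric division rate.
#'
#' @param s_grid Ordered fitness values per year (default 0 to 1 in steps of
#'   0.005).
#' @param n_w_grid Pool sizes; default 25 log-spaced points from 1e3 to 1e6.
#' @param latent_points Number of latent VAF grid cells (default 200).
#' @param lambda Symmetric division rate per year (default 1).
#' @param v_max Upper edge of the latent VAF grid, just below the
#'   heterozygous asymptote 0.5.
#' @return A `cf_config` list.
#' @export
inference_config <- function(s_grid = seq(0, 1, by = 0.005),
                             n_w_grid = 10^seq(3, 6, length.out = 25),
                             latent_points = 200,
                             lambda = 1,
                             v_max = 0.499) {
  if (is.unsorted(s_grid, strictly = TRUE) ||
      is.unsorted(n_w_grid, strictly = TRUE)) {
    abort("Grids must be strictly increasing.")
  }
  structure(list(s_grid = s_grid, n_w_grid = n_w_grid,
                 latent_points = latent_points, lambda = lambda,
                 v_max = v_max,
                 log_prior_s = rep(-log(length(s_grid)), length(s_grid)),
                 log_prior_n_w = rep(-log(length(n_w_grid)),
                                     length(n_w_grid))),
            class = "cf_config")
}

# Logit-spaced latent grid (in 2v, the clone fraction scale): cell centres
# and interior cell boundaries, both as VAFs.
latent_vaf_grid <- function(n_w, n_points, v_max = 0.499) {
  u_min <- stats::qlogis(1 / (n_w + 1)) # 2 * v_min
  u_max <- stats::qlogis(2 * v_max)
  centres_u <- seq(u_min, u_max, length.out = n_points)
  bounds_u <- (centres_u[-1] + centres_u[-n_points]) / 2
  list(v = stats::plogis(centres_u) / 2,
       v_bounds = stats::plogis(bounds_u) / 2)
}

# Map latent VAFs to clone sizes given M cells in other clones of the pool.
latent_clone_sizes <- function(v, n_w, m_other = 0) {
  2 * v * (n_w + m_other) / (1 - 2 * v)
}

# Package-level memo for latent transition matrices. A matrix is fully
# determined by scalars (dt, s, lambda, n_w, G, v_max, m_k, m_k1), so calls
# that revisit the same grids -- notably repeated-simulation studies -- reuse
# matrices across trajectories. The cache is cleared wholesale once its
# memory budget is reached; the budget is sized so one full sweep of the
# default grids (201 s-values x 25 pool sizes at 200 latent points, one
# distinct dt) fits, since a sweep that overflows the cache evicts its own
# working set and forces every later trajectory to rebuild all matrices.
.trans_memo <- new.env(parent = emptyenv())

memo_transition <- function(n_src, n_bnd, s, lambda, dt,
                            n_w, G, v_max, m_k, m_k1) {
  key <- paste(format(c(dt, s, lambda, n_w, v_max, m_k, m_k1),
                      digits = 12),
               G, collapse = "|")
  hit <- .trans_memo[[key]]
  if (!is.null(hit)) return(hit)
  P <- latent_transition(n_src, n_bnd, s, lambda, dt)
  cap <- max(1, floor(1.7e9 / (8 * G * G)))
  n <- .trans_memo$.count %||% 0L
  if (n >= cap) {
    rm(list = ls(.trans_memo, all.names = TRUE), envir = .trans_memo)
    n <- 0L
  }
  assign(key, P, envir = .trans_memo)
  .trans_memo$.count <- n + 1L
  P
}

# Transition matrix between latent cells: source sizes n_src (cell centres at
# the earlier age), interior destination boundaries n_bnd (cell edges at the
# later age). Extinction mass is lumped into the lowest cell and the upper
# tail into the highest, so rows sum to one.
latent_transition <- function(n_src, n_bnd, s, lambda, dt) {
  G <- length(n_src)
  if (dt == 0) return(diag(G))
  mom <- transition_moments(n_src, s, lambda, dt)
  m <- mom$mean
  v <- mom$variance
  nb <- length(n_bnd)
  q <- matrix(rep(n_bnd, each = G), nrow = G)
  if (v[1] > m[1]) {
    r <- m^2 / (v - m)
    p <- m / v
    cdf <- matrix(pnbinom(as.vector(q), size = r, prob = p), nrow = G)
  } else {
    cdf <- matrix(ppois(as.vector(q), lambda = m), nrow = G)
  }
  P <- cbind(cdf, 1) - cbind(0, cdf)
  P[P < 0] <- 0
  P
}

# Forward log likelihood of one clone's observations over (s_grid x n_w_grid).
#
# obs: tibble with columns age, alt, depth (several rows may share an age
# when a clone carries several variants). pool_fun(n_w) returns, per distinct
# age, the plug-in number of cells in *other* clones of the same individual.
clone_loglik_grid <- function(obs, config, pool_fun = NULL) {
  ages <- sort(unique(obs$age))
  K <- length(ages)
  if (K < 2) {
    abort("A clone needs observations at two or more ages.",
          class = "cf_insufficient_data")
  }
  s_grid <- config$s_grid
  n_w_grid <- config$n_w_grid
  G <- config$latent_points
  L <- matrix(NA_real_, length(s_grid), length(n_w_grid))

  for (j in seq_along(n_w_grid)) {
    n_w <- n_w_grid[j]
    grid <- latent_vaf_grid(n_w, G, config$v_max)
    m_other <- if (is.null(pool_fun)) rep(0, K) else pool_fun(n_w)

    # emission log-probabilities per age (rows) x latent cell (cols)
    emis <- matrix(0, K, G)
    for (k in seq_len(K)) {
      rows <- obs[obs$age == ages[k], ]
      for (r in seq_len(nrow(rows))) {
        emis[k, ] <- emis[k, ] +
          dbinom(rows$alt[r], rows$depth[r], grid$v, log = TRUE)
      }
    }
    n_src <- lapply(seq_len(K), function(k) {
      latent_clone_sizes(grid$v, n_w, m_other[k])
    })
    n_bnd <- lapply(seq_len(K), function(k) {
      latent_clone_sizes(grid$v_bounds, n_w, m_other[k])
    })

    for (i in seq_along(s_grid)) {
      s <- s_grid[i]
      trans <- vector("list", K - 1)
      for (k in seq_len(K - 1)) {
        trans[[k]] <- memo_transition(
          n_src[[k]], n_bnd[[k + 1]], s, config$lambda,
          ages[k + 1] - ages[k], n_w, G, config$v_max,
          m_other[k], m_other[k + 1])
      }
      # scaled forward recursion; flat prior over latent cells
      c1 <- max(emis[1, ])
      a <- exp(emis[1, ] - c1) / G
      sa <- sum(a)
      ll <- c1 + log(sa)
      a <- a / sa
      for (k in seq_len(K - 1)) {
        b <- as.vector(a %*% trans[[k]])
        ck <- max(emis[k + 1, ])
        y <- b * exp(emis[k + 1, ] - ck)
        sy <- sum(y)
        if (sy == 0 || !is.finite(sy)) {
          ll <- -Inf
          break
        }
        ll <- ll + ck + log(sy)
        a <- y / sy
      }
      L[i, j] <- ll
    }
  }
  L
}
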