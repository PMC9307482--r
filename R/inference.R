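#' Joint posterior of clone fitness and stem-cell pool size
#'
#' For each clone of the given structure, computes the marginal posterior of
#' its fitness `s` on the configuration's grid, jointly with the shared
#' wild-type pool size `N_w` (log-uniform prior). The likelihood at each
#' grid cell comes from a forward pass over latent clone sizes: a flat
#' belief over the latent VAF grid is updated by the binomial read emission
#' at the first age, propagated between ages with the negative-binomial
#' birth-death transition, and multiplied by the emission at each later age.
#' No acquisition time is estimated; conditioning on the first observation
#' makes the dynamics independent of it.
#'
#' @param data One participant's cohort rows (fit variants only); every
#'   clone needs observations at two or more ages.
#' @param structure A `cf_structure`; defaults to all-singletons.
#' @param config An [inference_config()].
#' @return A `cf_fitness` object with a `clones` tibble (per clone:
#'   `map_s`, `ci_lo`, `ci_hi` for the narrowest 90 percent credible interval and
#'   the full `s_density` over `s_grid`), the pool-size posterior, and the
#'   total log evidence. Use [generics::tidy()] / [generics::glance()] to
#'   extract tidy summaries.
#' @export
infer_posterior <- function(data, structure = NULL,
                            config = inference_config()) {
  data <- tibble::as_tibble(data)
  pid <- unique(data$participant_id)
  if (length(pid) != 1) abort("`data` must contain a single participant.")
  if (is.null(structure)) {
    ids <- sort(unique(data$variant_id))
    structure <- clonal_structure(pid, as.list(ids))
  }
  sg <- structure_grid(data, structure, config)
  C <- length(sg$L_list)

  # per-N_w fitness-marginalised log likelihood of each clone
  clone_nw <- lapply(sg$L_list, function(L) {
    apply(L + config$log_prior_s, 2, logsumexp)
  })
  lp_nw <- sg$lp_nw - logsumexp(sg$lp_nw)

  clones <- purrr::map_dfr(seq_len(C), function(ci) {
    others <- if (C == 1) 0 else {
      Reduce(`+`, clone_nw[-ci])
    }
    lp_s <- apply(sg$L_list[[ci]] + config$log_prior_s, 1, function(row) {
      logsumexp(row + config$log_prior_n_w + others)
    })
    dens <- exp(lp_s - logsumexp(lp_s))
    ci90 <- credible_interval(dens, config$s_grid, 0.90)
    tibble::tibble(
      clone_id = ci,
      variants = list(structure$clones[[ci]]),
      n_variants = length(structure$clones[[ci]]),
      map_s = config$s_grid[which.max(dens)],
      ci_lo = ci90[1],
      ci_hi = ci90[2],
      s_density = list(dens))
  })

  nw_dens <- exp(lp_nw)
  out <- list(participant_id = pid,
              structure = structure,
              clones = clones,
              s_grid = config$s_grid,
              n_w_grid = config$n_w_grid,
              n_w_density = nw_dens,
              map_n_w = config$n_w_grid[which.max(nw_dens)],
              log_evidence = sg$log_evidence,
              config = config)
  class(out) <- "cf_fitness"
  out
}

#' @export
print.cf_fitness <- function(x, ...) {
  cat(sprintf("<cf_fitness> participant %s, %d clone(s), MAP N_w = %.3g\n",
              x$participant_id, nrow(x$clones), x$map_n_w))
  for (i in seq_len(nrow(x$clones))) {
    cat(sprintf("  clone %d [%s]: MAP s = %.3f (90%% CI %.3f-%.3f)\n",
                i, paste(x$clones$variants[[i]], collapse = ","),
                x$clones$map_s[i], x$clones$ci_lo[i], x$clones$ci_hi[i]))
  }
  invisible(x)
}

#' Narrowest credible interval on a grid
#'
#' Finds the shortest contiguous run of grid cells whose probability mass
#' reaches `mass`; among equally short runs, the one containing the mode is
#' returned (the first such run if several contain it).
#'
#' @param density Probabilities over the grid (normalised to sum to 1).
#' @param grid Grid values (same length); defaults to cell indices.
#' @param mass Target coverage in (0, 1), default 0.90.
#' @return `c(lo, hi)` in grid units.
#' @export
credible_interval <- function(density, grid = seq_along(density),
                              mass = 0.90) {
  if (mass <= 0 || mass >= 1) abort("`mass` must lie strictly in (0, 1).")
  G <- length(density)
  density <- density / sum(density)
  cs <- c(0, cumsum(density))
  mode_i <- which.max(density)
  for (len in seq_len(G)) {
    starts <- seq_len(G - len + 1)
    cover <- cs[starts + len] - cs[starts]
    ok <- which(cover >= mass - 1e-12)
    if (length(ok) > 0) {
      with_mode <- ok[ok <= mode_i & ok + len - 1 >= mode_i]
      i <- if (length(with_mode) > 0) with_mode[1] else ok[1]
      return(c(grid[i], grid[i + len - 1]))
    }
  }
  c(grid[1], grid[G])
}
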