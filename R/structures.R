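#' Construct a clonal structure
#'
#' A clonal structure partitions an individual's fit variants into clones:
#' variants in the same block are carried by the same cells and share one
#' latent size trajectory.
#'
#' @param participant_id Participant identifier.
#' @param clones A list of non-overlapping character vectors of variant ids.
#' @param kappa Prior odds penalty per co-occurrence merge (see
#'   [enumerate_structures()]).
#' @return A `cf_structure` list with fields `participant_id`, `clones`,
#'   `n_variants`, `merges`, `prior_log_weight`.
#' @export
clonal_structure <- function(participant_id, clones, kappa = 0.5) {
  ids <- unlist(clones)
  if (anyDuplicated(ids) > 0) {
    abort("Clones must be disjoint.", class = "cf_validation_error")
  }
  merges <- length(ids) - length(clones)
  structure(list(participant_id = participant_id,
                 clones = lapply(clones, sort),
                 n_variants = length(ids),
                 merges = merges,
                 prior_log_weight = if (merges == 0) 0 else
                   merges * log(kappa)),
            class = "cf_structure")
}

#' @export
print.cf_structure <- function(x, ...) {
  blocks <- vapply(x$clones, function(v) paste0("{", paste(v, collapse = ","),
                                                "}"), character(1))
  cat(sprintf("<cf_structure> %s: %s (merges = %d)\n",
              x$participant_id, paste(blocks, collapse = " "), x$merges))
  invisible(x)
}

#' Enumerate all clonal structures of a variant set
#'
#' Generates every set partition of the variants (a Bell-number count).
#' Each partition carries a prior log weight of `log(kappa)` per merge
#' (i.e. per unit reduction in clone count relative to all-singletons),
#' expressing that clones carrying several driver mutations are rarer.
#'
#' @param variant_ids Character vector of variant ids.
#' @param participant_id Identifier attached to each structure.
#' @param kappa Per-merge prior odds in `[0, 1]`; `kappa = 0` forbids
#'   merges outright.
#' @param max_variants Hard cap on the enumeration (default 8; Bell(8) =
#'   4140 partitions). Raise the cap or pre-group variants for larger sets.
#' @return A list of `cf_structure` objects.
#' @export
enumerate_structures <- function(variant_ids, participant_id = NA_character_,
                                 kappa = 0.5, max_variants = 8) {
  n <- length(variant_ids)
  if (n == 0) abort("Need at least one variant.")
  if (n > max_variants) {
    abort(sprintf(
      "%d variants exceeds max_variants = %d; raise the cap or pre-cluster.",
      n, max_variants))
  }
  parts <- set_partitions(variant_ids)
  lapply(parts, clonal_structure, participant_id = participant_id,
         kappa = kappa)
}

# All set partitions, by inserting each element into every block of every
# partition of the remaining elements (or as a new block).
set_partitions <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  sub <- set_partitions(x[-1])
  out <- vector("list", 0)
  for (p in sub) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(x[1]), p)
  }
  out
}

# Per-clone observation tables and shared-pool plug-in sizes for one
# participant's data under a given structure. The pool correction for clone c
# at each of its observation ages counts the cells of the other clones,
# estimated by jointly inverting the VAF map at the clones' observed mean
# VAFs (interpolated in age where a clone lacks an observation).
structure_grid <- function(data, structure, config) {
  data <- tibble::as_tibble(data)
  if (!"vaf" %in% names(data)) {
    data$vaf <- ifelse(data$depth > 0, data$alt_reads / data$depth, NA_real_)
  }
  ids <- sort(unique(data$variant_id))
  if (!setequal(unlist(structure$clones), ids)) {
    abort("Structure is not a partition of the participant's variants.",
          class = "cf_validation_error")
  }
  clones <- structure$clones
  C <- length(clones)

  clone_obs <- lapply(clones, function(vs) {
    rows <- data[data$variant_id %in% vs, ]
    tibble::tibble(age = rows$age_years, alt = rows$alt_reads,
                   depth = rows$depth)
  })
  # mean observed VAF per clone as a function of age
  vbar_fun <- lapply(clones, function(vs) {
    rows <- data[data$variant_id %in% vs, ]
    agg <- dplyr::summarise(dplyr::group_by(rows, .data$age_years),
                            v = mean(.data$vaf), .groups = "drop")
    if (nrow(agg) == 1) {
      function(a) rep(agg$v, length(a))
    } else {
      function(a) approx(agg$age_years, agg$v, xout = a, rule = 2)$y
    }
  })

  L_list <- vector("list", C)
  for (ci in seq_len(C)) {
    ages_c <- sort(unique(clone_obs[[ci]]$age))
    pool_fun <- if (C == 1) NULL else {
      vball <- vapply(vbar_fun, function(f) f(ages_c),
                      numeric(length(ages_c)))
      vball <- matrix(vball, nrow = length(ages_c))
      tot <- pmin(rowSums(vball), 0.49)
      force(ci)
      function(n_w) {
        n_hat <- 2 * vball * n_w / (1 - 2 * tot)
        rowSums(n_hat[, -ci, drop = FALSE])
      }
    }
    L_list[[ci]] <- clone_loglik_grid(clone_obs[[ci]], config, pool_fun)
  }
  lp_nw <- config$log_prior_n_w +
    Reduce(`+`, lapply(L_list, function(L) {
      apply(L + config$log_prior_s, 2, logsumexp)
    }))
  list(L_list = L_list, lp_nw = lp_nw, log_evidence = logsumexp(lp_nw))
}

#' Marginal likelihood of one clonal structure
#'
#' Marginalises each clone's fitness (uniform prior on the fitness grid),
#' the shared wild-type pool size (log-uniform) and the latent clone-size
#' paths via the forward pass.
#'
#' @param data One participant's cohort rows (the fit variants only).
#' @param structure A `cf_structure` partitioning those variants.
#' @param config An [inference_config()].
#' @return Log evidence (a scalar). The structure's prior weight is not
#'   included; see [select_structure()].
#' @export
structure_log_evidence <- function(data, structure, config = inference_config()) {
  structure_grid(data, structure, config)$log_evidence
}

#' Select the best-supported clonal structure
#'
#' Scores every set partition of a participant's fit variants by
#' `log evidence + prior log weight` and returns the maximiser; ties are
#' broken towards more clones (fewer merges).
#'
#' @inheritParams structure_log_evidence
#' @param kappa Per-merge prior odds (default 0.5); `kappa = 0` always
#'   selects all-singletons.
#' @param max_variants Enumeration cap (see [enumerate_structures()]).
#' @return A `cf_structure_selection` with the chosen `best` structure, a
#'   `candidates` tibble (one row per partition with `log_evidence`,
#'   `prior_log_weight`, `score`) and `log_evidence_vs_independent`, the
#'   evidence of the best structure relative to all-singletons.
#' @export
select_structure <- function(data, config = inference_config(), kappa = 0.5,
                             max_variants = 8) {
  data <- tibble::as_tibble(data)
  pid <- unique(data$participant_id)
  if (length(pid) != 1) abort("`data` must contain a single participant.")
  ids <- sort(unique(data$variant_id))
  structures <- enumerate_structures(ids, pid, kappa, max_variants)

  ev <- vapply(structures, function(st) {
    structure_log_evidence(data, st, config)
  }, numeric(1))
  lw <- vapply(structures, `[[`, numeric(1), "prior_log_weight")
  n_clones <- vapply(structures, function(st) length(st$clones), integer(1))
  score <- ev + lw

  best_score <- max(score)
  cand <- which(score >= best_score - 1e-9)
  best_i <- cand[which.max(n_clones[cand])]
  singleton_i <- which(n_clones == length(ids))

  out <- list(
    best = structures[[best_i]],
    candidates = tibble::tibble(
      structure = structures,
      n_clones = n_clones,
      merges = length(ids) - n_clones,
      log_evidence = ev,
      prior_log_weight = lw,
      score = score,
      is_best = seq_along(structures) == best_i),
    log_evidence_vs_independent = ev[best_i] - ev[singleton_i])
  class(out) <- "cf_structure_selection"
  out
}

#' @export
print.cf_structure_selection <- function(x, ...) {
  cat(sprintf(
    "<cf_structure_selection> %d candidate partitions; best vs independent: %.3f\n",
    nrow(x$candidates), x$log_evidence_vs_independent))
  print(x$best)
  invisible(x)
}
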