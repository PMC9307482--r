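#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitness fit into one row per clone
#'
#' @param x A `cf_fitness` from [infer_posterior()].
#' @param ... Unused.
#' @return A tibble: `participant_id`, `clone_id`, `variants` (list-column),
#'   `n_variants`, `map_s`, `ci_lo`, `ci_hi`.
#' @export
tidy.cf_fitness <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$clones, -"s_density"),
    participant_id = x$participant_id, .before = 1)
}

#' One-line summary of a fitness fit
#'
#' @param x A `cf_fitness`.
#' @param ... Unused.
#' @return A one-row tibble: `participant_id`, `n_clones`, `n_variants`,
#'   `map_n_w`, `log_evidence`.
#' @export
glance.cf_fitness <- function(x, ...) {
  tibble::tibble(participant_id = x$participant_id,
                 n_clones = nrow(x$clones),
                 n_variants = sum(x$clones$n_variants),
                 map_n_w = x$map_n_w,
                 log_evidence = x$log_evidence)
}

# per-variant expansion of a fit (pipeline helper)
tidy_fitness_variants <- function(x) {
  td <- tidy(x)
  tidyr::unnest(dplyr::rename(td, variant_id = "variants"),
                "variant_id")
}

#' Tidy a structure selection into one row per candidate partition
#'
#' @param x A `cf_structure_selection` from [select_structure()].
#' @param ... Unused.
#' @return The candidates tibble with a readable `partition` label.
#' @export
tidy.cf_structure_selection <- function(x, ...) {
  dplyr::mutate(
    x$candidates,
    partition = vapply(x$candidates$structure, function(st) {
      paste(vapply(st$clones, function(v) {
        paste0("{", paste(v, collapse = ","), "}")
      }, character(1)), collapse = " ")
    }, character(1)),
    .before = 1)
}

#' @export
glance.cf_structure_selection <- function(x, ...) {
  tibble::tibble(
    participant_id = x$best$participant_id,
    n_candidates = nrow(x$candidates),
    best_n_clones = length(x$best$clones),
    log_evidence_vs_independent = x$log_evidence_vs_independent)
}
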