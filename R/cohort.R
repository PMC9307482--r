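required_cols <- c("participant_id", "variant_id", "gene", "protein_change",
                   "consequence", "age_years", "depth", "alt_reads")
optional_cols <- c("unique_alt_reads", "gnomad_p", "gene_category", "cosmic")

#' Build a longitudinal variant cohort from a data frame
#'
#' A cohort is a tibble with one row per participant x variant x timepoint.
#' The constructor validates read counts, recomputes VAF from counts (input
#' VAF columns are ignored), drops zero-depth timepoints with a warning,
#' sorts each trajectory by age and flags variants recurring in more than
#' one participant.
#'
#' @param df A data frame with columns `participant_id`, `variant_id`,
#'   `gene`, `protein_change`, `consequence`, `age_years`, `depth`,
#'   `alt_reads`, and optionally `unique_alt_reads`, `gnomad_p`,
#'   `gene_category`, `cosmic`.
#' @param provenance Free-text metadata stored as an attribute.
#' @return A `cf_cohort` tibble with derived columns `vaf` and `recurrent`.
#' @export
as_cohort <- function(df, provenance = NULL) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "cf_schema_error")
  }
  df$age_years <- as.numeric(df$age_years)
  df$depth <- as.numeric(df$depth)
  df$alt_reads <- as.numeric(df$alt_reads)

  bad <- which(df$alt_reads > df$depth | df$alt_reads < 0)
  if (length(bad) > 0) {
    abort(paste0("alt_reads exceeds depth (or is negative) at row(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "cf_validation_error")
  }
  zero <- df$depth == 0
  if (any(zero)) {
    warn(sprintf("Dropping %d timepoint(s) with zero depth.", sum(zero)))
    df <- df[!zero, ]
  }
  dup <- duplicated(df[c("participant_id", "variant_id", "age_years")])
  if (any(dup)) {
    abort(paste0("Duplicate (participant, variant, age) row(s): ",
                 paste(head(which(dup), 5), collapse = ", ")),
          class = "cf_validation_error")
  }

  df <- dplyr::arrange(df, .data$participant_id, .data$variant_id,
                       .data$age_years)
  df$vaf <- ifelse(df$depth > 0, df$alt_reads / df$depth, NA_real_)
  carriers <- dplyr::summarise(
    dplyr::group_by(df, .data$variant_id),
    n_participants = dplyr::n_distinct(.data$participant_id))
  df <- dplyr::left_join(df, carriers, by = "variant_id")
  df$recurrent <- df$n_participants > 1
  df$n_participants <- NULL
  new_cohort(df, provenance)
}

new_cohort <- function(df, provenance = NULL) {
  attr(df, "provenance") <- provenance
  class(df) <- unique(c("cf_cohort", class(tibble::tibble())))
  df
}

#' Read a cohort from a tab-delimited file
#'
#' @param path Path to a TSV file with the schema described in
#'   [as_cohort()].
#' @param provenance Optional free-text metadata; defaults to the path.
#' @return A `cf_cohort` tibble.
#' @export
read_cohort <- function(path, provenance = path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_cohort(df, provenance = provenance)
}

#' Write a cohort back to a tab-delimited file
#'
#' Writes the schema columns only (derived columns such as `vaf` and
#' `recurrent` are recomputed on read), so `read_cohort(write_cohort(x))`
#' round-trips.
#'
#' @param cohort A `cf_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  keep <- intersect(c(required_cols, optional_cols), names(cohort))
  readr::write_tsv(as.data.frame(cohort)[keep], path, progress = FALSE)
  invisible(path)
}

#' Split a cohort into trajectories
#'
#' @param cohort A `cf_cohort`.
#' @return A tibble with one row per (participant, variant) and a `data`
#'   list-column of per-timepoint observations.
#' @export
cohort_trajectories <- function(cohort) {
  tidyr::nest(tibble::as_tibble(cohort),
              data = -dplyr::all_of(c("participant_id", "variant_id")))
}

#' Quality-control filtering of trajectories
#'
#' Applies trajectory-level quality rules: (1) coverage - at least one
#' timepoint must reach `min_ao` variant-supporting reads and, when the
#' `unique_alt_reads` column is present, `min_uao` unique supporting reads
#' at the same timepoint; (2) gnomAD - variants must be significantly
#' underrepresented in population databases (`gnomad_p <= gnomad_alpha`);
#' (3) germline - trajectories whose VAF sits in a band around 0.5 or at
#' `>= 1 - germline_halfwidth` at every timepoint look like germline
#' variants and are removed. Rules whose input columns are absent are
#' skipped with a warning rather than failed.
#'
#' @param cohort A `cf_cohort`.
#' @param min_ao Minimum alt-supporting reads at some timepoint (default 5).
#' @param min_uao Minimum unique alt-supporting reads at that timepoint
#'   (default 3).
#' @param gnomad_alpha Significance level for population underrepresentation
#'   (default 0.05). Missing p-values are not penalised.
#' @param germline_halfwidth Half-width of the heterozygous germline band
#'   around VAF 0.5 (default 0.05); the homozygous band is
#'   `[1 - germline_halfwidth, 1]`.
#' @return The filtered `cf_cohort`; rejected trajectories and the rule each
#'   one hit are recorded in the `"qc_log"` attribute (see [qc_log()]).
#' @export
qc_filter <- function(cohort, min_ao = 5, min_uao = 3, gnomad_alpha = 0.05,
                      germline_halfwidth = 0.05) {
  has_uao <- "unique_alt_reads" %in% names(cohort)
  has_gnomad <- "gnomad_p" %in% names(cohort)
  if (!has_uao) {
    warn("Column `unique_alt_reads` absent; unique-read rule skipped.")
  }
  if (!has_gnomad) {
    warn("Column `gnomad_p` absent; gnomAD rule skipped.")
  }
  per <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), .data$participant_id,
                    .data$variant_id),
    pass_cov = any(.data$alt_reads >= min_ao &
                     (if (has_uao) {
                        is.na(.data$unique_alt_reads) |
                          .data$unique_alt_reads >= min_uao
                      } else TRUE)),
    pass_gnomad = if (has_gnomad) {
      all(is.na(.data$gnomad_p)) || any(.data$gnomad_p <= gnomad_alpha,
                                        na.rm = TRUE)
    } else TRUE,
    germline_like = all(abs(.data$vaf - 0.5) <= germline_halfwidth |
                          .data$vaf >= 1 - germline_halfwidth),
    .groups = "drop")
  per$rule <- dplyr::case_when(
    !per$pass_cov ~ "coverage",
    !per$pass_gnomad ~ "gnomad",
    per$germline_like ~ "germline",
    TRUE ~ NA_character_)
  log <- dplyr::select(dplyr::filter(per, !is.na(.data$rule)),
                       "participant_id", "variant_id", "rule")
  keep <- dplyr::filter(per, is.na(.data$rule))
  out <- dplyr::semi_join(tibble::as_tibble(cohort), keep,
                          by = c("participant_id", "variant_id"))
  out <- new_cohort(out, attr(cohort, "provenance"))
  attr(out, "qc_log") <- log
  out
}

#' Retrieve the rejection log from a QC-filtered cohort
#' @param cohort A cohort returned by [qc_filter()].
#' @return A tibble with columns `participant_id`, `variant_id`, `rule`.
#' @export
qc_log <- function(cohort) {
  attr(cohort, "qc_log") %||%
    tibble::tibble(participant_id = character(), variant_id = character(),
                   rule = character())
}

#' Threshold-based CHIP variant selection
#'
#' The conventional definition of a CHIP variant: at least `min_timepoints`
#' observations and a VAF reaching `vaf_threshold` at some timepoint.
#'
#' @param cohort A `cf_cohort`.
#' @param vaf_threshold VAF threshold in (0, 1); default 0.02.
#' @param min_timepoints Minimum number of timepoints (default 2).
#' @return The subset `cf_cohort` of qualifying trajectories.
#' @export
chip_threshold_filter <- function(cohort, vaf_threshold = 0.02,
                                  min_timepoints = 2) {
  if (vaf_threshold <= 0 || vaf_threshold >= 1) {
    abort("`vaf_threshold` must lie strictly between 0 and 1.")
  }
  per <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), .data$participant_id,
                    .data$variant_id),
    n_tp = dplyr::n(), max_vaf = max(.data$vaf), .groups = "drop")
  keep <- dplyr::filter(per, .data$n_tp >= min_timepoints,
                        .data$max_vaf >= vaf_threshold)
  out <- dplyr::semi_join(tibble::as_tibble(cohort), keep,
                          by = c("participant_id", "variant_id"))
  new_cohort(out, attr(cohort, "provenance"))
}

#' First-to-last VAF gradient of a trajectory
#'
#' @param ages Observation ages (years), at least two, increasing.
#' @param vafs VAFs at those ages.
#' @return `(v_last - v_first) / (t_last - t_first)` per year; positive for
#'   growing trajectories.
#' @export
vaf_gradient <- function(ages, vafs) {
  if (length(ages) < 2) {
    abort("At least two timepoints are needed to compute a gradient.",
          class = "cf_insufficient_data")
  }
  k <- order(ages)
  ages <- ages[k]
  vafs <- vafs[k]
  n <- length(ages)
  (vafs[n] - vafs[1]) / (ages[n] - ages[1])
}

#' Per-trajectory VAF gradients for a cohort
#'
#' @param cohort A `cf_cohort`. Trajectories with fewer than two timepoints
#'   are omitted.
#' @return A tibble with one row per trajectory: first/last age and VAF,
#'   `gradient` (per year) and the logical `growing` (`gradient > 0`).
#' @export
vaf_gradients <- function(cohort) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), .data$participant_id,
                    .data$variant_id, .data$gene),
    age_first = min(.data$age_years), age_last = max(.data$age_years),
    vaf_first = .data$vaf[which.min(.data$age_years)],
    vaf_last = .data$vaf[which.max(.data$age_years)],
    n_tp = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_tp >= 2) |>
    dplyr::mutate(
      gradient = (.data$vaf_last - .data$vaf_first) /
        (.data$age_last - .data$age_first),
      growing = .data$gradient > 0)
}
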