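#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]: QC rules, the two
#' variant filters (VAF threshold and LiFT), the clonal-structure penalty,
#' the inference grids and the gene-level comparison. Fully serialisable so
#' that a run manifest reproduces the run.
#'
#' @param input Path to a cohort TSV (see [read_cohort()]).
#' @param out_dir Output directory; `NULL` (default) writes nothing.
#' @param qc List of [qc_filter()] arguments.
#' @param vaf_threshold,min_timepoints Threshold-filter settings.
#' @param lift_threshold,min_vaf LiFT settings (Bayes factor and candidate
#'   pre-filter).
#' @param kappa Structure-selection penalty per merge.
#' @param max_structure_variants Enumeration cap; participants with more fit
#'   variants fall back to all-singletons with a warning.
#' @param inference List of [inference_config()] arguments.
#' @param min_gene_fitness Exclusion threshold for gene comparisons.
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `cf_pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir = NULL,
                            qc = list(),
                            vaf_threshold = 0.02, min_timepoints = 2,
                            lift_threshold = 4, min_vaf = 0.01,
                            kappa = 0.5, max_structure_variants = 8,
                            inference = list(),
                            min_gene_fitness = 0.02,
                            seed = 1L) {
  structure(list(input = input, out_dir = out_dir, qc = qc,
                 vaf_threshold = vaf_threshold,
                 min_timepoints = min_timepoints,
                 lift_threshold = lift_threshold, min_vaf = min_vaf,
                 kappa = kappa,
                 max_structure_variants = max_structure_variants,
                 inference = inference,
                 min_gene_fitness = min_gene_fitness,
                 seed = seed),
            class = "cf_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path A YAML file whose keys match [pipeline_config()] arguments.
#' @return A `cf_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Orchestrates: validate/read -> QC -> both variant filters (the classical
#' 2 percent VAF threshold and LiFT) -> clonal-structure selection per participant
#' on the LiFT-fit variants -> fitness inference -> gene-level summaries.
#' Outputs are pure functions of (input, config); a manifest with the full
#' configuration is written alongside results when `out_dir` is set
#' (`lift.tsv`, `structures.json`, `fitness.json`, `genes.tsv`,
#' `manifest.json`).
#'
#' @param config A [pipeline_config()], or a path to a YAML file for
#'   [read_pipeline_config()].
#' @param cohort Optionally, an already-loaded `cf_cohort` (skips reading
#'   `config$input`).
#' @return A `cf_report` list: the QC'd cohort, both filter results, the
#'   structure selections, the fitness fits, the tidy per-variant fitness
#'   table, gene summaries and comparison, and summary `counts`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "cf_pipeline_config"))
  set.seed(config$seed)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", what, "` failed: ",
                   conditionMessage(e)), parent = e)
    })
  }

  cohort <- stage("read", cohort %||% read_cohort(config$input))
  qcd <- stage("qc", do.call(qc_filter, c(list(cohort), config$qc)))
  icfg <- do.call(inference_config, config$inference)

  thresholded <- stage("threshold", chip_threshold_filter(
    qcd, config$vaf_threshold, config$min_timepoints))
  lift <- stage("lift", lift_classify(
    qcd, threshold = config$lift_threshold,
    min_timepoints = config$min_timepoints, min_vaf = config$min_vaf,
    config = icfg))

  fit_calls <- dplyr::filter(tibble::as_tibble(lift), .data$call == "fit")
  fit_rows <- dplyr::semi_join(tibble::as_tibble(qcd), fit_calls,
                               by = c("participant_id", "variant_id"))

  structures <- list()
  fits <- list()
  for (pid in unique(fit_rows$participant_id)) {
    dat <- fit_rows[fit_rows$participant_id == pid, ]
    ids <- unique(dat$variant_id)
    sel <- NULL
    if (length(ids) <= config$max_structure_variants) {
      sel <- stage("structure", select_structure(dat, icfg, config$kappa,
                                                 config$max_structure_variants))
      st <- sel$best
    } else {
      warn(sprintf(
        "Participant %s has %d fit variants (> %d); using all-singletons.",
        pid, length(ids), config$max_structure_variants))
      st <- clonal_structure(pid, as.list(sort(ids)), config$kappa)
    }
    structures[[pid]] <- sel
    fits[[pid]] <- stage("infer", infer_posterior(dat, st, icfg))
  }

  fitness_tbl <- if (length(fits) > 0) {
    purrr::map_dfr(fits, tidy_fitness_variants)
  } else {
    tibble::tibble(participant_id = character(), variant_id = character(),
                   gene = character(), clone_id = integer(),
                   map_s = numeric(), ci_lo = numeric(), ci_hi = numeric())
  }
  if (nrow(fitness_tbl) > 0) {
    genes <- dplyr::distinct(tibble::as_tibble(qcd), .data$variant_id,
                             .data$gene)
    fitness_tbl <- dplyr::left_join(
      dplyr::select(fitness_tbl, -dplyr::any_of("gene")), genes,
      by = "variant_id")
  }
  gene_table <- stage("genes", gene_fitness_table(fitness_tbl))
  gene_tests <- stage("genes", compare_gene_fitness(
    fitness_tbl, config$min_gene_fitness))

  lift_gr <- tibble::as_tibble(lift)
  thr_gr <- vaf_gradients(thresholded)
  report <- list(
    config = config,
    cohort = qcd,
    qc_log = qc_log(qcd),
    thresholded = thresholded,
    lift = lift,
    structures = structures,
    fits = fits,
    fitness = fitness_tbl,
    gene_table = gene_table,
    gene_tests = gene_tests,
    counts = list(
      trajectories = nrow(dplyr::distinct(tibble::as_tibble(cohort),
                                          .data$participant_id,
                                          .data$variant_id)),
      qc_rejected = nrow(qc_log(qcd)),
      thresholded = nrow(dplyr::distinct(tibble::as_tibble(thresholded),
                                         .data$participant_id,
                                         .data$variant_id)),
      candidates = nrow(lift_gr),
      fit = sum(lift_gr$call == "fit"),
      filtered = sum(lift_gr$call == "filtered"),
      growing_fraction_fit = if (any(lift_gr$call == "fit")) {
        mean(lift_gr$gradient[lift_gr$call == "fit"] > 0)
      } else NA_real_,
      growing_fraction_thresholded = if (nrow(thr_gr) > 0) {
        mean(thr_gr$growing)
      } else NA_real_))
  class(report) <- "cf_report"

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.cf_report <- function(x, ...) {
  c <- x$counts
  cat("<cf_report>\n")
  cat(sprintf("  trajectories: %d (QC rejected %d)\n",
              c$trajectories, c$qc_rejected))
  cat(sprintf("  2%%-VAF threshold: %d variants, %.0f%% growing\n",
              c$thresholded, 100 * c$growing_fraction_thresholded))
  cat(sprintf("  LiFT: %d candidates, %d fit (%.0f%% growing), %d filtered\n",
              c$candidates, c$fit, 100 * c$growing_fraction_fit,
              c$filtered))
  cat(sprintf("  genes summarised: %d\n", nrow(x$gene_table)))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(report$lift, file.path(out_dir, "lift.tsv"), "tsv")
  write_results(report$fitness, file.path(out_dir, "fitness.tsv"), "tsv")
  write_results(report$fits, file.path(out_dir, "fitness.json"), "json")
  write_results(purrr::compact(report$structures),
                file.path(out_dir, "structures.json"), "json")
  write_results(report$gene_table, file.path(out_dir, "genes.tsv"), "tsv")
  manifest <- list(
    package = "clonefit",
    version = as.character(utils::packageVersion("clonefit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass_config(report$config),
    counts = report$counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$out_dir <- NULL
  out
}

#' Write pipeline products to disk
#'
#' Tabular results are written as TSV; structured objects (fitness fits,
#' structure selections, or any list) as JSON. Numbers are written at full
#' precision so that reading back preserves them.
#'
#' @param results A tibble/data frame, a `cf_fitness`, a
#'   `cf_structure_selection`, or a list of such objects.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(results)) {
      abort("TSV output requires a data frame; use format = \"json\".")
    }
    df <- tibble::as_tibble(results)
    df <- df[!vapply(df, is.list, logical(1))]
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    jsonlite::write_json(serialize_result(results), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

serialize_result <- function(x) {
  if (inherits(x, "cf_fitness")) {
    list(participant_id = x$participant_id,
         clones = lapply(seq_len(nrow(x$clones)), function(i) {
           list(clone_id = x$clones$clone_id[i],
                variants = x$clones$variants[[i]],
                map_s = x$clones$map_s[i],
                ci90 = c(x$clones$ci_lo[i], x$clones$ci_hi[i]),
                s_grid = x$s_grid,
                s_density = x$clones$s_density[[i]])
         }),
         n_w_grid = x$n_w_grid, n_w_density = x$n_w_density,
         map_n_w = x$map_n_w, log_evidence = x$log_evidence)
  } else if (inherits(x, "cf_structure_selection")) {
    list(best = serialize_result(x$best),
         log_evidence_vs_independent = x$log_evidence_vs_independent,
         candidates = lapply(seq_len(nrow(x$candidates)), function(i) {
           list(clones = x$candidates$structure[[i]]$clones,
                log_evidence = x$candidates$log_evidence[i],
                prior_log_weight = x$candidates$prior_log_weight[i],
                is_best = x$candidates$is_best[i])
         }))
  } else if (inherits(x, "cf_structure")) {
    list(participant_id = x$participant_id, clones = x$clones,
         prior_log_weight = x$prior_log_weight)
  } else if (is.data.frame(x)) {
    x
  } else if (is.list(x)) {
    lapply(x, serialize_result)
  } else {
    x
  }
}
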