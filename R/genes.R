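#' Gene-level summary of MAP fitness estimates
#'
#' Groups per-variant MAP fitness estimates by gene and reports, per gene,
#' the number of variants, the median MAP fitness and the exclusive-method
#' interquartile range (quantile type 6), ranked by median fitness
#' descending. The IQR is omitted (`NA`) for single-variant genes.
#'
#' @param fitness A tibble with columns `gene` and `map_s` (e.g. the row-
#'   bound [generics::tidy()] output of [infer_posterior()] fits joined to
#'   gene annotations).
#' @return A tibble: `gene`, `n_variants`, `median_s`, `q1`, `q3`, `iqr`.
#' @export
gene_fitness_table <- function(fitness) {
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(fitness), .data$gene),
    n_variants = dplyr::n(),
    median_s = median(.data$map_s),
    q1 = if (dplyr::n() >= 2) {
      unname(quantile(.data$map_s, 0.25, type = 6))
    } else NA_real_,
    q3 = if (dplyr::n() >= 2) {
      unname(quantile(.data$map_s, 0.75, type = 6))
    } else NA_real_,
    .groups = "drop")
  out$iqr <- out$q3 - out$q1
  dplyr::arrange(out, dplyr::desc(.data$median_s))
}

#' Pairwise nonparametric comparison of gene fitness distributions
#'
#' Runs a Kruskal-Wallis test for every pair of genes on the MAP fitness
#' estimates of their variants, after excluding variants below
#' `min_fitness` (such variants are predicted to confer no meaningful
#' advantage). The effect size reported is epsilon squared,
#' `H / ((n^2 - 1) / (n + 1))` with `n` the combined sample size.
#'
#' @param fitness A tibble with columns `gene` and `map_s`.
#' @param min_fitness Exclude variants with `map_s` below this (default
#'   0.02).
#' @param min_variants Genes with fewer retained variants are reported as
#'   untestable (default 2).
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @return A tibble with one row per gene pair: sample sizes, the
#'   Kruskal-Wallis `H`, `p_value`, `epsilon_sq` and `significant`.
#'   Untestable genes are listed in the `"untestable"` attribute.
#' @export
compare_gene_fitness <- function(fitness, min_fitness = 0.02,
                                 min_variants = 2, alpha = 0.05) {
  df <- dplyr::filter(tibble::as_tibble(fitness),
                      .data$map_s >= min_fitness)
  counts <- dplyr::count(df, .data$gene)
  testable <- counts$gene[counts$n >= min_variants]
  untestable <- setdiff(unique(fitness$gene), testable)
  if (length(testable) < 2) {
    out <- tibble::tibble(gene_a = character(), gene_b = character(),
                          n_a = integer(), n_b = integer(), H = numeric(),
                          p_value = numeric(), epsilon_sq = numeric(),
                          significant = logical())
    attr(out, "untestable") <- untestable
    return(out)
  }
  pairs <- utils::combn(sort(testable), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]
    gb <- pairs[2, k]
    xa <- df$map_s[df$gene == ga]
    xb <- df$map_s[df$gene == gb]
    kw <- kruskal.test(list(xa, xb))
    n <- length(xa) + length(xb)
    H <- unname(kw$statistic)
    tibble::tibble(gene_a = ga, gene_b = gb,
                   n_a = length(xa), n_b = length(xb),
                   H = H, p_value = kw$p.value,
                   epsilon_sq = H / ((n^2 - 1) / (n + 1)),
                   significant = kw$p.value < alpha)
  })
  attr(out, "untestable") <- untestable
  out
}
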