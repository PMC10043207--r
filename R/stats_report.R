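#' Paired Wilcoxon signed-rank comparison
#'
#' Compares a per-disk interpretability metric between two attribution
#' methods. Pairs with missing values are deleted pairwise and zero
#' differences are dropped (the signed-rank convention); the exact
#' distribution is used for n <= 25 when there are no ties, the normal
#' approximation otherwise.
#'
#' @param values_a,values_b equal-length numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (a vs b).
#' @param alpha_corrected significance level after multiplicity
#'   correction (see [bonferroni_alpha()]).
#' @return A `comparison_result`: statistic, p_value, alpha_corrected,
#'   significant, n_pairs.
#' @export
wilcoxon_signed_rank <- function(values_a, values_b,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 alpha_corrected = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(length(values_a) == length(values_b))
  ok <- complete.cases(values_a, values_b)
  d <- values_a[ok] - values_b[ok]
  d <- d[d != 0]
  if (length(d) < 6)
    stop("insufficient-data: fewer than 6 non-zero-difference pairs")
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  wt <- stats::wilcox.test(d, alternative = alternative, exact = exact,
                           correct = !exact)
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 alpha_corrected = alpha_corrected,
                 significant = wt$p.value < alpha_corrected,
                 n_pairs = length(d), alternative = alternative),
            class = "comparison_result")
}

#' Bonferroni-corrected significance level
#'
#' @param family_alpha family-wise level (e.g. 0.05).
#' @param m number of comparisons in the family.
#' @return `family_alpha / m` (0.05 over 3 comparisons gives 0.0167,
#'   conventionally printed as 0.017).
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  stopifnot(m >= 1)
  family_alpha / m
}

#' One-sided two-sample t-test on per-fold AUCs
#'
#' Tests whether the AUCs in `aucs_a` are greater than those in `aucs_b`
#' (Welch two-sample t-test, alternative "a > b"); used to compare
#' training with augmented data against training on base data only.
#'
#' @param aucs_a,aucs_b numeric vectors (>= 2 values each).
#' @param alpha significance level.
#' @return A `comparison_result`.
#' @export
one_sided_t_test <- function(aucs_a, aucs_b, alpha = 0.05) {
  stopifnot(length(aucs_a) >= 2, length(aucs_b) >= 2)
  if (stats::var(aucs_a) == 0 && stats::var(aucs_b) == 0)
    stop("degenerate: zero variance in both samples")
  tt <- stats::t.test(aucs_a, aucs_b, alternative = "greater")
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 alpha_corrected = alpha,
                 significant = tt$p.value < alpha,
                 alternative = "greater"),
            class = "comparison_result")
}

#' Pairwise method comparisons for every strategy and metric
#'
#' Runs the Wilcoxon signed-rank test for each pair of attribution
#' methods, per strategy and metric, at the Bonferroni-corrected level
#' (family = the method pairs within one strategy/metric).
#'
#' @param metrics_table long-format tibble from
#'   [run_interpretability_study()], filtered to one threshold factor.
#' @param family_alpha family-wise level.
#' @return Tibble of comparisons with p-values and significance flags.
#' @export
compare_methods <- function(metrics_table, family_alpha = 0.05) {
  methods <- unique(metrics_table$method)
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  alpha_c <- bonferroni_alpha(family_alpha, length(pairs))
  rows <- list()
  for (strat in unique(metrics_table$strategy))
    for (metric in c("iou", "lesion_pct", "nat_pct"))
      for (pr in pairs) {
        a <- metrics_table[metrics_table$strategy == strat &
                             metrics_table$method == pr[1], ]
        b <- metrics_table[metrics_table$strategy == strat &
                             metrics_table$method == pr[2], ]
        a <- a[order(a$disk), ]; b <- b[order(b$disk), ]
        res <- tryCatch(
          wilcoxon_signed_rank(a[[metric]], b[[metric]],
                               alpha_corrected = alpha_c),
          error = function(e) NULL)
        rows[[length(rows) + 1]] <- tibble::tibble(
          strategy = strat, metric = metric,
          method_a = pr[1], method_b = pr[2],
          p_value = if (is.null(res)) NA_real_ else res$p_value,
          alpha_corrected = alpha_c,
          significant = if (is.null(res)) NA else res$significant)
      }
  do.call(rbind, rows)
}

#' Assemble the study report
#'
#' Writes the study outputs as plain CSV files (and, when ggplot2 is
#' available, boxplot/average-map PNG figures): per-class model metrics,
#' interpretability summaries (mean +/- sd per method, strategy and
#' threshold factor), the method comparisons, and the
#' correct-vs-incorrect classification means. Aggregates are recomputed
#' from the long table at write time, so regeneration is idempotent.
#'
#' @param eval_summary per-class model metric tibble (see
#'   [cross_validate()] `$summary`).
#' @param metrics_table long-format interpretability table.
#' @param comparisons tibble from [compare_methods()].
#' @param out_dir output directory (created if needed).
#' @param figures also render PNG figures.
#' @return Invisibly, the list of written file paths.
#' @export
build_report <- function(eval_summary, metrics_table, comparisons, out_dir,
                         figures = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(eval_summary, "model_metrics.csv")
  wr(metrics_table, "interpretability_long.csv")
  wr(summarise_interp(metrics_table), "interpretability_summary.csv")
  wr(comparisons, "method_comparisons.csv")
  cvsi <- summarise_interp(metrics_table, by_correct = TRUE)
  wr(cvsi, "correct_vs_incorrect.csv")
  if (figures && requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot(
      metrics_table[metrics_table$factor == 1.0, ],
      ggplot2::aes(x = method, y = iou, fill = method)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~strategy) +
      ggplot2::theme_minimal()
    p <- file.path(out_dir, "iou_boxplot.png")
    ggplot2::ggsave(p, gg, width = 8, height = 4, dpi = 120)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Mean +/- sd summary of the interpretability table
#'
#' @param metrics_table long-format table.
#' @param by_correct also split by the correct-classification flag.
#' @return Aggregated tibble.
#' @export
summarise_interp <- function(metrics_table, by_correct = FALSE) {
  keys <- c("method", "strategy", "factor",
            if (by_correct) "correct")
  grp <- interaction(metrics_table[keys], drop = TRUE)
  rows <- lapply(split(metrics_table, grp), function(d) {
    out <- d[1, keys]
    for (metric in c("iou", "lesion_pct", "nat_pct")) {
      out[[paste0(metric, "_mean")]] <- mean(d[[metric]], na.rm = TRUE)
      out[[paste0(metric, "_sd")]] <- sd(d[[metric]], na.rm = TRUE)
    }
    out$n <- nrow(d)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
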