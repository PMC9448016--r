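# Agreement analysis between two index score sets on the same subjects:
# Bland-Altman bias and 95% limits of agreement, Pearson correlation on
# totals, Spearman rank correlation per component, and distributional
# summaries.

#' Pair two cohort score tables by subject
#'
#' @param scores_a,scores_b Data frames from [score_cohort()] (or with at
#'   least `subject_id` and `total`); A is the reference index, differences
#'   are A - B.
#' @return A list of class `paired_scores` with aligned data frames `a`,
#'   `b` and `n`.
#' @export
paired_scores <- function(scores_a, scores_b) {
  common <- intersect(scores_a$subject_id, scores_b$subject_id)
  unmatched <- union(setdiff(scores_a$subject_id, common),
                     setdiff(scores_b$subject_id, common))
  if (length(unmatched) > 0) {
    mhei_abort(
      paste0("subjects present in only one score set: ",
             paste(sort(unmatched), collapse = ", ")),
      "mhei_pairing_error"
    )
  }
  a <- scores_a[match(common, scores_a$subject_id), , drop = FALSE]
  b <- scores_b[match(common, scores_b$subject_id), , drop = FALSE]
  structure(list(a = a, b = b, n = length(common)), class = "paired_scores")
}

#' Bland-Altman agreement of paired totals
#'
#' Computes the mean difference (bias) of A - B and the 95% limits of
#' agreement, bias +/- 1.96 x SD of the differences (sample SD, n-1
#' denominator) — the literal 1.96, not a t quantile. Normal-theory
#' confidence intervals: for the bias, +/- t x SD/sqrt(n); for each limit,
#' +/- t x SD x sqrt(3/n), with t the 97.5% quantile on n-1 degrees of
#' freedom (reported when n >= 3).
#'
#' @param paired A `paired_scores` object, or a numeric vector of A totals
#'   (with `b` the matching B totals).
#' @param b Numeric vector of B totals when `paired` is a vector.
#' @return A list of class `agreement_result`: `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, and CI vectors `bias_ci`, `loa_low_ci`,
#'   `loa_high_ci`.
#' @examples
#' bland_altman(c(1, 2, 3), c(3, 2, 1))  # differences -2, 0, 2
#' @export
bland_altman <- function(paired, b = NULL) {
  if (inherits(paired, "paired_scores")) {
    a <- paired$a$total
    b <- paired$b$total
  } else {
    a <- paired
  }
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  n <- length(a)
  if (n < 2) {
    mhei_abort("Bland-Altman needs at least 2 paired observations",
               "mhei_insufficient_data_error")
  }
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  bias_ci <- c(NA_real_, NA_real_)
  loa_low_ci <- c(NA_real_, NA_real_)
  loa_high_ci <- c(NA_real_, NA_real_)
  tq <- stats::qt(0.975, df = n - 1)
  half_bias <- tq * sd_diff / sqrt(n)
  bias_ci <- c(bias - half_bias, bias + half_bias)
  if (n >= 3) {
    half_loa <- tq * sd_diff * sqrt(3 / n)
    loa_low_ci <- c(loa_low - half_loa, loa_low + half_loa)
    loa_high_ci <- c(loa_high - half_loa, loa_high + half_loa)
  }
  structure(
    list(n = n, bias = bias, sd_diff = sd_diff,
         loa_low = loa_low, loa_high = loa_high,
         bias_ci = bias_ci, loa_low_ci = loa_low_ci,
         loa_high_ci = loa_high_ci),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d\n", x$n))
  cat(sprintf("  bias %.3f [%.3f; %.3f]\n", x$bias, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  LOA  %.3f [%.3f; %.3f] to %.3f [%.3f; %.3f]\n",
              x$loa_low, x$loa_low_ci[1], x$loa_low_ci[2],
              x$loa_high, x$loa_high_ci[1], x$loa_high_ci[2]))
  invisible(x)
}

#' Correlations between two score sets
#'
#' Pearson's r between the total scores, and Spearman's rho (average-rank
#' ties) for each component that both tables carry — rank correlation is
#' used for components because their score distributions are far from
#' normal.
#'
#' @param paired A `paired_scores` object.
#' @return A list with `pearson_total` and named vector `spearman`. A
#'   zero-variance vector yields `NA` with a `zero_variance` attribute
#'   listing the affected components, not an error.
#' @export
score_correlations <- function(paired) {
  stopifnot(inherits(paired, "paired_scores"))
  a <- paired$a
  b <- paired$b
  safe_cor <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  pearson_total <- safe_cor(a$total, b$total, "pearson")
  comps <- intersect(mhei_component_names(), intersect(names(a), names(b)))
  spearman <- vapply(comps, function(comp) {
    safe_cor(a[[comp]], b[[comp]], "spearman")
  }, numeric(1))
  flagged <- comps[is.na(spearman)]
  if (is.na(pearson_total)) flagged <- c("total", flagged)
  out <- list(pearson_total = pearson_total, spearman = spearman)
  attr(out, "zero_variance") <- flagged
  out
}

#' Distributional summary of a score table
#'
#' Mean, sample SD (n-1), median and IQR (linear-interpolation, type-7
#' quantiles) for every component column and the total.
#'
#' @param scores Data frame from [score_cohort()].
#' @return Data frame with one row per component plus `total`.
#' @export
summarize_scores <- function(scores) {
  cols <- c(intersect(mhei_component_names(), names(scores)), "total")
  rows <- lapply(cols, function(col) {
    x <- scores[[col]]
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(
      component = col, n = length(x), mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0,
      median = stats::median(x), iqr = q[2] - q[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman plot
#'
#' Mean-versus-difference scatter with horizontal lines at the bias and
#' both limits of agreement, plus marginal histograms of the means and the
#' differences rendered as top/right rugs of binned counts. Also writes a
#' CSV of the plotted values. Purely presentational: all numbers come from
#' [bland_altman()].
#'
#' @param paired A `paired_scores` object.
#' @param result Optional precomputed `agreement_result`.
#' @param path Image output path (`.png`, `.svg` or `.pdf`); the CSV is
#'   written next to it with extension `.csv`.
#' @return The `ggplot` object, invisibly.
#' @export
bland_altman_plot <- function(paired, result = NULL, path = NULL) {
  stopifnot(inherits(paired, "paired_scores"))
  if (paired$n < 2) {
    mhei_abort("not enough paired observations to plot",
               "mhei_insufficient_data_error")
  }
  if (is.null(result)) result <- bland_altman(paired)
  df <- data.frame(
    subject_id = paired$a$subject_id,
    mean = (paired$a$total + paired$b$total) / 2,
    difference = paired$a$total - paired$b$total
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = result$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = result$loa_high, colour = "darkgreen",
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = result$loa_low, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_rug(sides = "tr", alpha = 0.25) +
    ggplot2::labs(
      x = "Mean of the two total scores",
      y = "Difference of total scores (A - B)",
      title = sprintf("Bias %.2f, 95%% LOA [%.2f; %.2f]",
                      result$bias, result$loa_low, result$loa_high)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
    csv_path <- paste0(tools::file_path_sans_ext(path), ".csv")
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(p)
}
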