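#' Paired-sample summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), and standard error
#' of the mean — one side of a paired-samples summary table.
#'
#' @param values Numeric vector with at least 2 values.
#' @return A one-row tibble: `mean`, `sd`, `sem`, `n`.
#' @examples
#' paired_summary(c(1, 2, 3))
#' @export
paired_summary <- function(values) {
  if (length(values) < 2L || anyNA(values)) {
    abort("need at least 2 non-missing values")
  }
  n <- length(values)
  s <- sd(values)
  tibble(mean = mean(values), sd = s, sem = s / sqrt(n), n = n)
}

#' Per-dataset paired differences of a tree metric
#'
#' Each dataset is the same subject observed under two conditions — a tree
#' built on original data and one built on protected data — so differences
#' are taken row-wise, original minus protected, preserving row order.
#'
#' @param rows A paired-metrics tibble with columns `size_orig`,
#'   `leaves_orig`, `accuracy_orig` and the `_prot` counterparts (as
#'   produced by [compare_run()] or [table1_fixture()]).
#' @param metric One of `"size"`, `"leaves"`, `"accuracy"`.
#' @return Numeric vector of differences.
#' @export
paired_differences <- function(rows, metric = c("size", "leaves", "accuracy")) {
  metric <- match.arg(metric)
  rows <- as_tibble(rows)
  if (nrow(rows) == 0L) abort("no metric rows")
  rows[[paste0(metric, "_orig")]] - rows[[paste0(metric, "_prot")]]
}

#' Bootstrapped paired test for a zero mean difference
#'
#' Resamples the n paired differences with replacement B times and uses the
#' distribution of replicate means: the statistic is the sample mean
#' difference, bias the bootstrap mean minus it, the standard error the SD
#' of replicate means, the 95% CI the percentile interval, and the
#' two-sided achieved significance level
#' `2 * min(P(replicate >= 0), P(replicate <= 0))` clipped to `[1/B, 1]`.
#' No distributional assumption is made, which matters here because tree
#' sizes across datasets are heavily outlier-prone. Degenerate all-equal
#' differences give `se = 0` and `p = 1`.
#'
#' @param diffs Numeric vector of paired differences (n >= 2).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; results are reproducible given
#'   `(diffs, B, seed)`.
#' @return An object of class `paired_boot`.
#' @examples
#' res <- bootstrap_paired(c(-1, 0, 2), B = 1000, seed = 1)
#' glance(res)
#' @export
bootstrap_paired <- function(diffs, B = 1000L, seed = 1L) {
  if (length(diffs) < 2L || anyNA(diffs)) {
    abort("need at least 2 non-missing differences")
  }
  if (B < 1L) abort("B must be >= 1")
  n <- length(diffs)
  stat <- mean(diffs)

  if (all(diffs == diffs[[1]])) {
    # resampling a constant vector is a no-op; report no significance
    means <- rep(stat, B)
  } else {
    means <- with_preserved_rng(seed, {
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
      rowMeans(matrix(diffs[idx], nrow = B))
    })
  }
  ge <- mean(means >= 0)
  le <- mean(means <= 0)
  p <- if (all(means == 0)) 1 else min(1, max(1 / B, 2 * min(ge, le)))
  ci <- unname(stats::quantile(means, c(0.025, 0.975), type = 7))
  structure(
    list(
      stat = stat, bias = mean(means) - stat,
      se = if (all(means == means[[1]])) 0 else sd(means),
      ci95 = ci, p = p, B = as.integer(B), seed = as.integer(seed),
      n = n, replicates = means
    ),
    class = "paired_boot"
  )
}

#' @export
print.paired_boot <- function(x, ...) {
  cat(sprintf(
    "<paired_boot> mean difference %.4g (bias %.4g, SE %.4g), 95%% CI [%.4g, %.4g], two-sided p = %.3g (B = %d, n = %d)\n",
    x$stat, x$bias, x$se, x$ci95[[1]], x$ci95[[2]], x$p, x$B, x$n
  ))
  invisible(x)
}

#' @rdname bootstrap_paired
#' @param x A `paired_boot` object.
#' @param ... Unused.
#' @return For `tidy()`/`glance()`: a one-row tibble with `estimate`,
#'   `bias`, `std.error`, `conf.low`, `conf.high`, `p.value` (plus `B`,
#'   `n`, `seed` in `glance()`).
#' @method tidy paired_boot
#' @export
tidy.paired_boot <- function(x, ...) {
  tibble(
    estimate = x$stat, bias = x$bias, std.error = x$se,
    conf.low = x$ci95[[1]], conf.high = x$ci95[[2]], p.value = x$p
  )
}

#' @rdname bootstrap_paired
#' @method glance paired_boot
#' @export
glance.paired_boot <- function(x, ...) {
  dplyr::mutate(tidy(x), B = x$B, n = x$n, seed = x$seed)
}

#' @rdname bootstrap_paired
#' @param object A `paired_boot` object.
#' @method autoplot paired_boot
#' @export
autoplot.paired_boot <- function(object, ...) {
  df <- tibble(mean = object$replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$ci95, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$stat, colour = "red") +
    ggplot2::geom_vline(xintercept = 0, colour = "blue") +
    ggplot2::labs(
      x = "bootstrap replicate mean difference", y = "count",
      title = sprintf(
        "Paired bootstrap (B = %d): mean %.3g, p = %.3g",
        object$B, object$stat, object$p
      )
    ) +
    ggplot2::theme_minimal()
}

#' Paired summaries and bootstrap tests for a metrics table
#'
#' Produces the two report tables of the original-versus-protected
#' comparison: per-metric paired summary statistics for both conditions
#' (means and SDs of tree size, leaf count, and accuracy as a proportion),
#' and the bootstrapped paired test of a zero mean difference for each
#' metric whose differences are not all zero. Sizes and leaves are
#' reported to 1 decimal, proportions to 3.
#'
#' @param rows A paired-metrics tibble (see [paired_differences()]).
#' @param B,seed Passed to [bootstrap_paired()].
#' @return A list with tibbles `summary` and `tests`, class
#'   `paired_report`.
#' @export
compare_report <- function(rows, B = 1000L, seed = 1L) {
  rows <- as_tibble(rows)
  metrics <- c("size", "leaves", "accuracy")
  summary_tbl <- purrr::map_dfr(metrics, function(m) {
    scale <- if (m == "accuracy") 0.01 else 1 # percent -> proportion
    dplyr::bind_rows(
      dplyr::mutate(
        paired_summary(rows[[paste0(m, "_orig")]] * scale),
        metric = m, condition = "original", .before = 1
      ),
      dplyr::mutate(
        paired_summary(rows[[paste0(m, "_prot")]] * scale),
        metric = m, condition = "protected", .before = 1
      )
    )
  })
  tests_tbl <- purrr::map_dfr(metrics, function(m) {
    scale <- if (m == "accuracy") 0.01 else 1
    diffs <- paired_differences(rows, m) * scale
    res <- bootstrap_paired(diffs, B = B, seed = seed)
    dplyr::mutate(tidy(res),
      metric = m, degenerate = all(diffs == 0), .before = 1
    )
  })
  structure(
    list(summary = summary_tbl, tests = tests_tbl, B = as.integer(B)),
    class = "paired_report"
  )
}

#' @export
print.paired_report <- function(x, ...) {
  cat("Paired samples statistics\n")
  s <- x$summary
  dp <- ifelse(s$metric == "accuracy", 3L, 1L)
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-9s %-9s mean %-9s sd %-9s sem %s\n",
      s$metric[[i]], s$condition[[i]],
      formatC(s$mean[[i]], format = "f", digits = dp[[i]]),
      formatC(s$sd[[i]], format = "f", digits = dp[[i]]),
      formatC(s$sem[[i]], format = "f", digits = dp[[i]])
    ))
  }
  cat(sprintf("\nBootstrapped paired tests (B = %d)\n", x$B))
  t <- x$tests
  for (i in seq_len(nrow(t))) {
    if (t$degenerate[[i]]) {
      cat(sprintf(
        "  %-9s all differences zero; no test performed\n", t$metric[[i]]
      ))
    } else {
      cat(sprintf(
        "  %-9s mean %-8s bias %-8s se %-8s 95%% CI [%s, %s]  p %s\n",
        t$metric[[i]],
        formatC(t$estimate[[i]], format = "f", digits = 1),
        formatC(t$bias[[i]], format = "f", digits = 1),
        formatC(t$std.error[[i]], format = "f", digits = 1),
        formatC(t$conf.low[[i]], format = "f", digits = 1),
        formatC(t$conf.high[[i]], format = "f", digits = 1),
        formatC(t$p.value[[i]], format = "f", digits = 2)
      ))
    }
  }
  invisible(x)
}

#' Scatter of original versus protected tree metrics
#'
#' @param rows A paired-metrics tibble (see [paired_differences()]).
#' @return A ggplot object, one facet per metric, identity line overlaid;
#'   points off the line are datasets whose protected tree differed.
#' @export
plot_paired_metrics <- function(rows) {
  rows <- as_tibble(rows)
  long <- tidyr::pivot_longer(
    rows,
    cols = dplyr::matches("_(orig|prot)$"),
    names_to = c("metric", "condition"), names_sep = "_"
  )
  wide <- tidyr::pivot_wider(long, names_from = "condition")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$orig, y = .data$prot)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      x = "tree induced on original data",
      y = "tree induced on protected data"
    ) +
    ggplot2::theme_minimal()
}
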