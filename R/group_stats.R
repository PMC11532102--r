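# One-way ANOVA with Tukey-Kramer post hoc comparisons across treatment groups.

.check_samples <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) stop("need >= 2 groups")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  ns <- vapply(samples, length, 0L)
  if (any(ns < 2L)) stop("every group needs >= 2 observations")
  all_x <- unlist(samples, use.names = FALSE)
  if (!all(is.finite(all_x))) stop("non-finite observations")
  if (stats::var(all_x) == 0) stop("degenerate input: all values identical")
  samples
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square ratio with the p-value from the F
#' distribution on (k - 1, N - k) degrees of freedom.
#'
#' @param samples named list of numeric vectors, one per group.
#' @return List of class `anova_oneway`: `F`, `p_anova`, `df`, `ms_within`,
#'   `means`, `n`.
#' @export
anova_oneway <- function(samples) {
  samples <- .check_samples(samples)
  k <- length(samples)
  ns <- vapply(samples, length, 0L)
  N <- sum(ns)
  means <- vapply(samples, mean, 0)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(samples, function(x) sum((x - mean(x))^2), 0))
  df1 <- k - 1L
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  F <- if (msw == 0) Inf else msb / msw
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  structure(list(F = F, p_anova = p, df = c(df1 = df1, df2 = df2),
                 ms_within = msw, means = means, n = ns),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_anova))
  invisible(x)
}

#' Tukey-Kramer post hoc pairwise comparisons
#'
#' For each pair of groups the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MSW * (1/n_i + 1/n_j) / 2)` is referred to
#' the studentized range distribution with `k` means and `N - k` degrees of
#' freedom. The Kramer standard error handles unequal group sizes; for a
#' balanced design it reduces to `sqrt(MSW / n)`.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param alpha family-wise level for the confidence limits.
#' @return Data frame of class `tukey_kramer`: one row per pair with the mean
#'   difference, confidence limits, and Tukey-adjusted p-value.
#' @export
tukey_kramer <- function(samples, alpha = 0.05) {
  samples <- .check_samples(samples)
  a <- anova_oneway(samples)
  k <- length(samples)
  df2 <- a$df[["df2"]]
  pairs <- utils::combn(names(samples), 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    gi <- pairs[1L, j]; gj <- pairs[2L, j]
    se <- sqrt(a$ms_within / 2 * (1 / a$n[[gi]] + 1 / a$n[[gj]]))
    diff <- a$means[[gj]] - a$means[[gi]]
    q <- if (se == 0) Inf else abs(diff) / se
    p <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    crit <- stats::qtukey(1 - alpha, nmeans = k, df = df2)
    data.frame(group_a = gi, group_b = gj, diff = diff,
               lwr = diff - crit * se, upr = diff + crit * se,
               p_adj = p, stringsAsFactors = FALSE)
  }))
  attr(out, "alpha") <- alpha
  attr(out, "df") <- df2
  class(out) <- c("tukey_kramer", "data.frame")
  out
}

# asterisk tiers used in printed reports
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Compare biomarkers across treatment groups
#'
#' Runs one-way ANOVA plus Tukey-Kramer post hoc tests for each biomarker
#' column of a per-image results table (rows are the experimental units).
#'
#' @param results data frame with a group column and biomarker columns (as
#'   produced by stacking [compute_biomarkers()] rows).
#' @param biomarkers character vector of column names to test; defaults to the
#'   numeric biomarker columns present.
#' @param group_col name of the group label column.
#' @return Named list of class `group_comparison`; each element holds the
#'   `anova_oneway` fit and the `tukey_kramer` table for one biomarker.
#' @export
compare_groups <- function(results,
                           biomarkers = NULL,
                           group_col = "group") {
  if (!group_col %in% names(results)) stop("no '", group_col, "' column")
  groups <- unique(results[[group_col]])
  if (length(groups) < 2L) stop(">= 2 groups required for any group comparison")
  if (is.null(biomarkers)) {
    cand <- c("median_tortuosity", "n_segments_per_mm2",
              "median_segment_distance_um", "sd_orientation_rad",
              "iqr_orientation_rad")
    biomarkers <- intersect(cand, names(results))
  }
  out <- lapply(biomarkers, function(b) {
    samples <- split(results[[b]], results[[group_col]])
    samples <- lapply(samples, function(x) x[is.finite(x)])
    list(biomarker = b,
         anova = anova_oneway(samples),
         tukey = tukey_kramer(samples),
         n_per_group = vapply(samples, length, 0L))
  })
  names(out) <- biomarkers
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  for (b in names(x)) {
    cmp <- x[[b]]
    cat("==", b, "==\n")
    print(cmp$anova)
    tk <- cmp$tukey
    for (i in seq_len(nrow(tk))) {
      cat(sprintf("  %s vs %s: diff = %.4g, p_adj = %.4g %s\n",
                  tk$group_a[i], tk$group_b[i], tk$diff[i], tk$p_adj[i],
                  as.character(significance_stars(tk$p_adj[i]))))
    }
  }
  invisible(x)
}
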