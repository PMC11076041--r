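#' Grubbs outlier screen
#'
#' Iteratively applies Grubbs's single-outlier test: compute
#' `G = max |x_i - mean(x)| / sd(x)` and remove the extreme point while `G`
#' exceeds the critical value
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)` (two-sided). At most `max_removals` points
#' are removed (one per iteration). Zero-variance or too-small samples are
#' returned unchanged.
#'
#' @param x Numeric sample (n >= 3 for any removal to occur).
#' @param alpha Significance level (default 0.05).
#' @param max_removals Maximum number of removals (default 2).
#' @return List with `values` (cleaned sample) and `removed` (indices into the
#'   original `x`, possibly empty).
#' @export
grubbs_screen <- function(x, alpha = 0.05, max_removals = 2) {
  stopifnot(is.numeric(x), alpha > 0, alpha < 1)
  removed <- integer(0)
  idx <- seq_along(x)
  cur <- x
  while (length(removed) < max_removals && length(cur) >= 3) {
    s <- stats::sd(cur)
    if (!is.finite(s) || s == 0) break
    dev <- abs(cur - mean(cur))
    g <- max(dev) / s
    n <- length(cur)
    tq <- stats::qt(1 - alpha / (2 * n), n - 2)
    g_crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (g <= g_crit) break
    drop <- which.max(dev)
    removed <- c(removed, idx[drop])
    cur <- cur[-drop]
    idx <- idx[-drop]
  }
  list(values = cur, removed = removed)
}

#' Dunn's posthoc test after Kruskal-Wallis
#'
#' Pairwise z-statistics on mean ranks of the pooled sample with tie
#' correction:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups. Two-sided p-values are adjusted
#' for multiple comparisons (Bonferroni by default, Dunn's original
#' correction).
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (same length).
#' @param p_adjust Adjustment method for [stats::p.adjust()] (default
#'   `"bonferroni"`).
#' @return Tibble with `group1`, `group2`, `z`, `p_value`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (mean_r[[p[1]]] - mean_r[[p[2]]]) /
      sqrt(v0 * (1 / n_g[[p[1]]] + 1 / n_g[[p[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                 p_value = p, p_adj = stats::p.adjust(p, p_adjust))
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Normality-gated group comparison
#'
#' Implements the decision procedure used throughout the analyses this package
#' supports: optionally screen each group for outliers (Grubbs), test each
#' group's normality (Shapiro-Wilk at alpha 0.05), then
#'
#' * two groups, all normal: two-sided pooled-variance Student's t-test;
#' * two groups, otherwise: Mann-Whitney U test;
#' * more than two groups, all normal: one-way ANOVA with Tukey's posthoc;
#' * more than two groups, otherwise: Kruskal-Wallis with Dunn's posthoc.
#'
#' The gate is all-or-none: a single non-normal group selects the
#' nonparametric branch. Significance stars follow the 0.05 / 0.01 / 0.001
#' convention. Inputs are experiment-level summary values (one per
#' experiment), not individual ROIs or profiles.
#'
#' @param data Tibble with a value column and a group column.
#' @param value,group Column names (tidyselect-style strings; defaults
#'   `"value"`, `"group"`).
#' @param alpha Significance level for the normality gate (default 0.05).
#' @param grubbs Screen each group with [grubbs_screen()] first (default
#'   `TRUE`).
#' @return An object of class `group_comparison`: `chosen_test`, `p_value`,
#'   `statistic`, `stars`, `normality` (per-group Shapiro-Wilk p), `posthoc`
#'   (tibble or `NULL`), `outliers_removed`, `groups` (cleaned data). Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           alpha = 0.05, grubbs = TRUE) {
  stopifnot(value %in% names(data), group %in% names(data))
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 3)) {
    stop("every group needs n >= 3 (got: ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), ")",
         call. = FALSE)
  }
  outliers <- list()
  if (grubbs) {
    keep <- rep(TRUE, length(v))
    for (lev in levels(g)) {
      sel <- which(g == lev)
      scr <- grubbs_screen(v[sel], alpha = alpha)
      if (length(scr$removed)) {
        keep[sel[scr$removed]] <- FALSE
        outliers[[lev]] <- v[sel[scr$removed]]
      }
    }
    v <- v[keep]; g <- droplevels(g[keep])
  }
  normality <- vapply(levels(g), function(lev) {
    xx <- v[g == lev]
    if (length(unique(xx)) < 3) return(0)   # degenerate: treat as non-normal
    stats::shapiro.test(xx)$p.value
  }, numeric(1))
  all_normal <- all(normality > alpha)
  posthoc <- NULL
  if (nlevels(g) == 2) {
    if (all_normal) {
      ht <- stats::t.test(v ~ g, var.equal = TRUE)
      chosen <- "two-sided Student's t-test"
    } else {
      ht <- stats::wilcox.test(v ~ g, exact = FALSE)
      chosen <- "Mann-Whitney U test"
    }
    p <- ht$p.value; stat <- unname(ht$statistic)
  } else {
    if (all_normal) {
      fit <- stats::aov(v ~ g)
      sm <- summary(fit)[[1]]
      p <- sm[["Pr(>F)"]][1]; stat <- sm[["F value"]][1]
      chosen <- "one-way ANOVA + Tukey"
      tk <- stats::TukeyHSD(fit)$g
      posthoc <- tibble::tibble(
        comparison = rownames(tk),
        diff = tk[, "diff"], p_adj = tk[, "p adj"],
        stars = significance_stars(tk[, "p adj"])
      )
    } else {
      ht <- stats::kruskal.test(v ~ g)
      p <- ht$p.value; stat <- unname(ht$statistic)
      chosen <- "Kruskal-Wallis + Dunn"
      dn <- dunn_test(v, g)
      dn$stars <- significance_stars(dn$p_adj)
      posthoc <- dn
    }
  }
  structure(
    list(chosen_test = chosen, p_value = p, statistic = stat,
         stars = significance_stars(p), alpha = alpha,
         normality = normality, all_normal = all_normal,
         posthoc = posthoc, outliers_removed = outliers,
         groups = tibble::tibble(value = v, group = g)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat(sprintf("  %s: p = %.4g %s\n", x$chosen_test, x$p_value, x$stars))
  cat(sprintf("  normality (Shapiro-Wilk p): %s -> %s branch\n",
              paste(sprintf("%s %.3g", names(x$normality), x$normality),
                    collapse = ", "),
              if (x$all_normal) "parametric" else "nonparametric"))
  n_out <- sum(lengths(x$outliers_removed))
  if (n_out) cat(sprintf("  Grubbs screen removed %d value(s)\n", n_out))
  if (!is.null(x$posthoc)) {
    cat("  posthoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}
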