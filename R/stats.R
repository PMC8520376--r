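#' Group summaries from raw samples
#'
#' Collapses a grouped cohort data frame to per-group `(label, n, mean, sd)`
#' triples — the form in which clinical tables print their results, and the
#' input accepted by every summary-statistics test in this package.
#'
#' @param data Data frame with a grouping column and a numeric value column.
#' @param group,value Column names (strings) for group labels and values.
#' @return Tibble with columns `label`, `n`, `mean`, `sd`.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 4), y = c(1:4, 3:6))
#' group_summary(df, "g", "y")
#' @export
group_summary <- function(data, group = "group", value = "value") {
  stopifnot(is.data.frame(data))
  if (!all(c(group, value) %in% names(data))) {
    stop(sprintf("columns `%s` and `%s` must exist", group, value),
         call. = FALSE)
  }
  data |>
    dplyr::group_by(label = .data[[group]]) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[value]]),
                     sd = stats::sd(.data[[value]]),
                     .groups = "drop")
}

# Accept either raw numeric samples or a (n, mean, sd) summary row.
as_group_summary <- function(x, label = "group") {
  if (is.numeric(x)) {
    if (length(x) < 2L) stop("each group needs n >= 2", call. = FALSE)
    return(tibble::tibble(label = label, n = length(x), mean = mean(x),
                          sd = stats::sd(x)))
  }
  if (is.data.frame(x) || is.list(x)) {
    x <- as.list(x)
    need <- c("n", "mean", "sd")
    if (!all(need %in% names(x))) {
      stop("a group summary needs fields `n`, `mean`, `sd`", call. = FALSE)
    }
    if (x$n < 2L) stop("each group needs n >= 2", call. = FALSE)
    if (x$sd < 0) stop("`sd` must be nonnegative", call. = FALSE)
    return(tibble::tibble(label = as.character(x$label %||% label),
                          n = as.integer(x$n), mean = as.numeric(x$mean),
                          sd = as.numeric(x$sd)))
  }
  stop("group must be a numeric vector or an (n, mean, sd) summary",
       call. = FALSE)
}

new_echo_test <- function(method, statistic, df, p_value, estimate = NA_real_,
                          ...) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, estimate = estimate, ...),
            class = "echo_test")
}

#' @export
print.echo_test <- function(x, ...) {
  cat(sprintf("%s\n", x$method))
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("  statistic = %.6g, df = %s, p = %.4g\n",
              x$statistic, dfs, x$p_value))
  if (!is.na(x$estimate)) cat(sprintf("  estimate = %.6g\n", x$estimate))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an echometrics test result
#'
#' @param x An `echo_test`.
#' @param ... Unused.
#' @return One-row tibble with `method`, `statistic`, `df` (and `df2` for
#'   F-type tests), `p.value`, `estimate`.
#' @method tidy echo_test
#' @export
tidy.echo_test <- function(x, ...) {
  out <- tibble::tibble(method = x$method, statistic = x$statistic,
                        df = x$df[1L], p.value = x$p_value,
                        estimate = x$estimate)
  if (length(x$df) > 1L) {
    out <- dplyr::mutate(out, df2 = x$df[2L], .after = "df")
  }
  out
}

#' @rdname tidy.echo_test
#' @method glance echo_test
#' @export
glance.echo_test <- function(x, ...) tidy(x, ...)

#' Two-sample t-test from raw samples or printed summaries
#'
#' Student (pooled-variance) by default, matching the clinical-statistics
#' convention; Welch available. Both groups may be given either as numeric
#' sample vectors or as `(n, mean, sd)` summaries, and the two paths agree
#' exactly when the summaries are computed from the samples.
#'
#' When both group variances are zero the test is degenerate: equal means
#' give `statistic = 0, p = 1` by convention; unequal means are flagged with
#' a warning and `p = 0`.
#'
#' @param group_a,group_b Numeric vectors, or lists/one-row data frames with
#'   `n`, `mean`, `sd` (optionally `label`).
#' @param variant `"student"` (default) or `"welch"`.
#' @return An `echo_test` (see [tidy.echo_test()]).
#' @examples
#' t_test(c(10, 12, 14, 16), c(11, 13, 15, 17))
#' t_test(list(n = 20, mean = 55.3, sd = 9.8),
#'        list(n = 19, mean = 55.9, sd = 10.4))
#' @export
t_test <- function(group_a, group_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as_group_summary(group_a, "a")
  b <- as_group_summary(group_b, "b")
  diff_means <- a$mean - b$mean
  if (a$sd == 0 && b$sd == 0) {
    if (diff_means == 0) {
      return(new_echo_test(sprintf("Two-sample t-test (%s)", variant),
                           statistic = 0,
                           df = a$n + b$n - 2, p_value = 1,
                           estimate = 0))
    }
    warning("zero variance in both groups with unequal means: p = 0",
            call. = FALSE)
    return(new_echo_test(sprintf("Two-sample t-test (%s)", variant),
                         statistic = sign(diff_means) * Inf,
                         df = a$n + b$n - 2, p_value = 0,
                         estimate = diff_means))
  }
  if (variant == "student") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  stat <- diff_means / se
  new_echo_test(sprintf("Two-sample t-test (%s)", variant),
                statistic = stat, df = df,
                p_value = 2 * stats::pt(-abs(stat), df),
                estimate = diff_means)
}

# Normalize a list of groups (samples or summaries) to a summary tibble.
groups_to_summary <- function(groups) {
  if (is.data.frame(groups)) {
    need <- c("n", "mean", "sd")
    if (all(need %in% names(groups))) {
      if (!"label" %in% names(groups)) {
        groups$label <- paste0("group", seq_len(nrow(groups)))
      }
      return(purrr::map_dfr(seq_len(nrow(groups)),
                            function(i) as_group_summary(groups[i, ])))
    }
    stop("a summary data frame needs columns `n`, `mean`, `sd`",
         call. = FALSE)
  }
  stopifnot(is.list(groups))
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  labels[labels == ""] <- paste0("group", which(labels == ""))
  purrr::map2_dfr(groups, labels, as_group_summary)
}

anova_components <- function(summ) {
  k <- nrow(summ)
  N <- sum(summ$n)
  grand <- sum(summ$n * summ$mean) / N
  ss_between <- sum(summ$n * (summ$mean - grand)^2)
  ss_within <- sum((summ$n - 1) * summ$sd^2)
  list(k = k, N = N, grand = grand, ss_between = ss_between,
       ss_within = ss_within,
       ms_between = ss_between / (k - 1),
       ms_within = ss_within / (N - k))
}

#' One-way analysis of variance (raw samples or printed summaries)
#'
#' \eqn{F = \mathrm{MS}_{between} / \mathrm{MS}_{within}} with
#' \eqn{SS_{between} = \sum_i n_i(\bar x_i - \bar x)^2} and
#' \eqn{SS_{within} = \sum_i (n_i - 1) s_i^2}; the summary-statistics path
#' reproduces the raw-sample ANOVA exactly because these are sufficient
#' statistics.
#'
#' @param groups Either a named list whose elements are numeric sample
#'   vectors or `(n, mean, sd)` summaries, or a summary data frame with
#'   columns `label`, `n`, `mean`, `sd` (as from [group_summary()]).
#' @return An `echo_anova`; see [tidy.echo_anova()].
#' @examples
#' one_way_anova(data.frame(label = c("CG", "MIG", "APG"),
#'                          n = c(20, 19, 21),
#'                          mean = c(55.3, 55.9, 53.6),
#'                          sd = c(9.8, 10.4, 8.5)))
#' @export
one_way_anova <- function(groups) {
  summ <- groups_to_summary(groups)
  if (nrow(summ) < 2L) stop("need at least 2 groups", call. = FALSE)
  cmp <- anova_components(summ)
  if (cmp$ms_within == 0) {
    if (cmp$ss_between == 0) {
      warning("all groups are identical constants: F is undefined (0/0)",
              call. = FALSE)
      f <- NaN; p <- NA_real_
    } else {
      warning("zero within-group variance: F is infinite", call. = FALSE)
      f <- Inf; p <- 0
    }
  } else {
    f <- cmp$ms_between / cmp$ms_within
    p <- stats::pf(f, cmp$k - 1, cmp$N - cmp$k, lower.tail = FALSE)
  }
  structure(list(summary = summ, f = f, df1 = cmp$k - 1, df2 = cmp$N - cmp$k,
                 p_value = p, ss_between = cmp$ss_between,
                 ss_within = cmp$ss_within, ms_within = cmp$ms_within),
            class = "echo_anova")
}

#' @export
print.echo_anova <- function(x, ...) {
  cat("One-way ANOVA\n")
  cat(sprintf("  F(%d, %d) = %.6g, p = %.4g\n", x$df1, x$df2, x$f,
              x$p_value))
  invisible(x)
}

#' Tidy a one-way ANOVA
#'
#' @param x An `echo_anova`.
#' @param ... Unused.
#' @return `tidy()`: the between/within decomposition, one term per row.
#'   `glance()`: one row with `statistic`, `df`, `df2`, `p.value`.
#' @method tidy echo_anova
#' @export
tidy.echo_anova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df1, x$df2),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df1, x$ss_within / x$df2),
    statistic = c(x$f, NA_real_),
    p.value = c(x$p_value, NA_real_)
  )
}

#' @rdname tidy.echo_anova
#' @method glance echo_anova
#' @export
glance.echo_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f, df = x$df1, df2 = x$df2,
                 p.value = x$p_value)
}

#' LSD pairwise comparisons after a one-way ANOVA
#'
#' Fisher's least-significant-difference procedure: unadjusted pairwise
#' t-tests using the ANOVA's pooled within-group mean square,
#' \eqn{t_{ij} = (\bar x_i - \bar x_j) /
#'   \sqrt{\mathrm{MS}_{within}(1/n_i + 1/n_j)}} on `N - k` degrees of
#' freedom. No multiplicity adjustment, by design.
#'
#' @inheritParams one_way_anova
#' @return Tibble with one row per unordered pair: `group1`, `group2`,
#'   `estimate` (mean difference), `statistic`, `df`, `p.value`.
#' @examples
#' lsd_pairwise(list(a = rnorm(10), b = rnorm(10), c = rnorm(10, 5)))
#' @export
lsd_pairwise <- function(groups) {
  fit <- one_way_anova(groups)
  summ <- fit$summary
  pairs <- utils::combn(nrow(summ), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    est <- summ$mean[i] - summ$mean[j]
    se <- sqrt(fit$ms_within * (1 / summ$n[i] + 1 / summ$n[j]))
    stat <- if (se == 0) {
      if (est == 0) 0 else sign(est) * Inf
    } else est / se
    pv <- if (se == 0) {
      if (est == 0) 1 else 0
    } else 2 * stats::pt(-abs(stat), fit$df2)
    tibble::tibble(group1 = summ$label[i], group2 = summ$label[j],
                   estimate = est, statistic = stat, df = fit$df2,
                   p.value = pv)
  })
}

#' Pearson chi-square test of independence
#'
#' \eqn{X^2 = \sum (O - E)^2 / E} with expected counts from the row and
#' column marginals; `df = (r - 1)(c - 1)`; no continuity correction.
#'
#' @param table Matrix (or data frame) of nonnegative counts, at least 2x2,
#'   with all row and column totals positive.
#' @return An `echo_test`.
#' @examples
#' chi_square_independence(rbind(male = c(10, 10, 11),
#'                               female = c(10, 9, 10)))
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || any(m < 0)) {
    stop("`table` must be a matrix of nonnegative counts", call. = FALSE)
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("`table` must be at least 2x2", call. = FALSE)
  }
  rt <- rowSums(m); ct <- colSums(m); N <- sum(m)
  if (any(rt == 0) || any(ct == 0)) {
    stop("all row and column marginal totals must be positive",
         call. = FALSE)
  }
  expected <- outer(rt, ct) / N
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  new_echo_test("Pearson chi-square test of independence",
                statistic = stat, df = df,
                p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Pearson correlation with t-based p-value
#'
#' \eqn{r = \mathrm{cov}(x, y) / (s_x s_y)}; the two-sided p-value comes
#' from \eqn{t = r \sqrt{(n - 2) / (1 - r^2)}} on `n - 2` degrees of
#' freedom.
#'
#' @param data Data frame containing the two variables (pass column names in
#'   `x` and `y`), or `NULL` to pass numeric vectors directly.
#' @param x,y Column names (when `data` is given) or numeric vectors.
#' @return An `echo_test` with `estimate = r`.
#' @examples
#' pearson_correlation(data.frame(a = 1:5, b = c(2, 1, 4, 3, 5)), "a", "b")
#' @export
pearson_correlation <- function(data = NULL, x, y) {
  if (!is.null(data)) {
    stopifnot(is.data.frame(data))
    x <- data[[x]]; y <- data[[y]]
  }
  if (length(x) != length(y)) stop("`x` and `y` lengths differ",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
  r <- min(1, max(-1, r))
  df <- n - 2
  p <- if (abs(r) == 1) 0 else {
    stat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(stat), df)
  }
  new_echo_test("Pearson product-moment correlation",
                statistic = if (abs(r) == 1) sign(r) * Inf else
                  r * sqrt(df / (1 - r^2)),
                df = df, p_value = p, estimate = r)
}
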