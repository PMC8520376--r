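test_that("student t-test matches base R and the hand-pooled formula", {
  a <- c(10, 12, 14, 16); b <- c(11, 13, 15, 17)
  got <- t_test(a, b)
  want <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  expect_equal(got$df, 6)
  expect_equal(got$statistic, -1 / sqrt((20 / 3) * 0.5))

  w <- t_test(a, b, variant = "welch")
  ww <- stats::t.test(a, b)
  expect_equal(w$statistic, unname(ww$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ww$parameter), tolerance = 1e-12)
  expect_equal(w$p_value, ww$p.value, tolerance = 1e-12)
})

test_that("summary-statistics and raw-sample t-test paths agree", {
  set.seed(10)
  for (i in 1:5) {
    a <- rnorm(7 + i, 50, 8); b <- rnorm(9, 53, 6)
    raw <- t_test(a, b)
    summ <- t_test(list(n = length(a), mean = mean(a), sd = sd(a)),
                   list(n = length(b), mean = mean(b), sd = sd(b)))
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  }
})

test_that("identical groups give t = 0, p = 1", {
  got <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  degenerate <- t_test(list(n = 5, mean = 3, sd = 0),
                       list(n = 5, mean = 3, sd = 0))
  expect_equal(degenerate$p_value, 1)
  expect_warning(bad <- t_test(list(n = 5, mean = 3, sd = 0),
                               list(n = 5, mean = 4, sd = 0)),
                 "zero variance")
  expect_equal(bad$p_value, 0)
})

test_that("one-way anova from summaries reproduces aov on raw samples", {
  set.seed(2)
  g <- list(a = rnorm(8, 10, 2), b = rnorm(12, 11, 2), c = rnorm(9, 9, 3))
  fit <- one_way_anova(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  ref <- summary(stats::aov(y ~ grp, df))[[1]]
  expect_equal(fit$f, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(fit$p_value, ref$`Pr(>F)`[1], tolerance = 1e-9)
  # summary path identical to raw path (sufficient statistics)
  summ <- group_summary(df, "grp", "y")
  fit2 <- one_way_anova(summ)
  expect_equal(fit2$f, fit$f, tolerance = 1e-12)
  expect_equal(fit2$p_value, fit$p_value, tolerance = 1e-12)
})

test_that("equal group means give F = 0 and p = 1", {
  fit <- one_way_anova(data.frame(label = c("a", "b", "c"),
                                  n = c(10, 10, 10),
                                  mean = c(5, 5, 5), sd = c(2, 2, 2)))
  expect_equal(fit$f, 0)
  expect_equal(fit$p_value, 1)
})

test_that("two-group anova satisfies the F = t^2 identity", {
  set.seed(6)
  a <- rnorm(10, 0, 1); b <- rnorm(14, 0.8, 1.3)
  f <- one_way_anova(list(a = a, b = b))$f
  t <- t_test(a, b)$statistic
  expect_equal(f, t^2, tolerance = 1e-9)
})

test_that("lsd pairwise uses the pooled MS within and stays unadjusted", {
  groups <- data.frame(label = c("g1", "g2", "g3"),
                       n = c(10, 10, 10),
                       mean = c(0, 0, 10), sd = c(1, 1, 1))
  out <- lsd_pairwise(groups)
  expect_equal(nrow(out), 3)
  near <- out[out$group1 == "g1" & out$group2 == "g2", ]
  expect_gt(near$p.value, 0.9)
  far <- out[out$group2 == "g3", ]
  expect_true(all(far$p.value < 1e-6))
  expect_true(all(out$df == 27))
  # symmetric in the pair order: swapping labels flips the sign only
  groups_swapped <- groups[c(2, 1, 3), ]
  out2 <- lsd_pairwise(groups_swapped)
  pair2 <- out2[out2$group1 == "g2" & out2$group2 == "g1", ]
  expect_equal(pair2$p.value, near$p.value, tolerance = 1e-12)
  expect_equal(pair2$estimate, -near$estimate)
})

test_that("lsd of identical groups gives p = 1 everywhere", {
  out <- lsd_pairwise(data.frame(label = c("a", "b", "c"),
                                 n = c(8, 8, 8), mean = c(3, 3, 3),
                                 sd = c(1.5, 1.5, 1.5)))
  expect_true(all(out$p.value == 1))
})

test_that("chi-square independence matches base R without correction", {
  m <- rbind(c(10, 10, 11), c(10, 9, 10))
  got <- chi_square_independence(m)
  want <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  expect_equal(got$df, 2)
  # uniform table
  u <- chi_square_independence(matrix(5, 2, 2))
  expect_equal(u$statistic, 0)
  expect_equal(u$p_value, 1)
  # row-swap invariance
  expect_equal(chi_square_independence(m[2:1, ])$statistic, got$statistic)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("pearson correlation matches hand computation and cor.test", {
  got <- pearson_correlation(data.frame(x = 1:5, y = c(2, 1, 4, 3, 5)),
                             "x", "y")
  expect_equal(got$estimate, 0.8)
  want <- stats::cor.test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(got$p_value, want$p.value, tolerance = 1e-12)

  x <- c(1.2, 3.4, 2.2, 5.5, 4.1)
  expect_equal(pearson_correlation(x = x, y = 2 * x + 3)$estimate, 1.0)
  expect_equal(pearson_correlation(x = x, y = -x)$estimate, -1.0)
  expect_error(pearson_correlation(x = c(1, 1, 1), y = c(1, 2, 3)),
               "zero variance")
})

test_that("correlation is affine invariant and sign-flips under negation", {
  set.seed(12)
  x <- rnorm(20); y <- x + rnorm(20, 0, 0.5)
  r0 <- pearson_correlation(x = x, y = y)$estimate
  expect_equal(pearson_correlation(x = 3 * x + 7, y = 0.1 * y - 2)$estimate,
               r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(x = -x, y = y)$estimate, -r0,
               tolerance = 1e-12)
})

test_that("p-values stay in [0, 1] and shrink as the mean offset grows", {
  set.seed(3)
  base <- rnorm(15, 0, 1)
  ps <- vapply(c(0, 0.5, 1, 2, 4), function(delta) {
    p <- t_test(list(n = 15, mean = 0, sd = 1),
                list(n = 15, mean = delta, sd = 1))$p_value
    expect_gte(p, 0); expect_lte(p, 1)
    p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("tidy and glance return broom-shaped tibbles", {
  td <- tidy(t_test(c(1, 2, 3, 4), c(2, 3, 4, 6)))
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("statistic", "p.value", "estimate") %in% names(td)))
  fit <- one_way_anova(list(a = rnorm(5), b = rnorm(5)))
  expect_equal(nrow(tidy(fit)), 2)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("statistic", "df", "df2", "p.value") %in% names(gl)))
})
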