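test_that("group comparison matches hand-computed one-way ANOVA", {
  df <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6),
                       g = rep(c("a", "b"), each = 3))
  out <- compare_groups(df, v, g)
  # hand arithmetic: SSB = 13.5, MSW = 1 -> F = 13.5
  expect_equal(out$f_statistic, 13.5, tolerance = 1e-12)
  # hand Kruskal-Wallis on ranks 1..6: H = 12/42 * (36/3 + 225/3) - 21
  expect_equal(out$kw_statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-10)
  expect_true(out$f_p >= 0 && out$f_p <= 1)
  gs <- attr(out, "group_summary")
  expect_equal(gs$n, c(3, 3))
  expect_equal(gs$mean, c(2, 5))
})

test_that("all-equal values give zero statistics, not NaN", {
  df <- tibble::tibble(v = rep(5, 9), g = rep(c("a", "b", "c"), each = 3))
  out <- compare_groups(df, v, g)
  expect_equal(out$f_statistic, 0)
  expect_equal(out$f_p, 1)
  expect_equal(out$kw_statistic, 0)
})

test_that("with two groups the ANOVA F equals the pooled t squared", {
  set.seed(13)
  df <- tibble::tibble(v = rnorm(30), g = rep(c("a", "b"), 15))
  out <- compare_groups(df, v, g)
  tt <- t.test(v ~ g, data = df, var.equal = TRUE)
  expect_equal(out$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$f_p, tt$p.value, tolerance = 1e-10)
})

test_that("under the null the ANOVA p-value is approximately uniform", {
  set.seed(29)
  v <- rnorm(24)
  ps <- vapply(1:400, function(r) {
    g <- sample(rep(c("a", "b", "c"), 8))
    compare_groups(tibble::tibble(v = v, g = g), v, g)$f_p
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("small groups are excluded with a warning", {
  df <- tibble::tibble(v = c(1, 2, 3, 4, 9),
                       g = c("a", "a", "b", "b", "c"))
  expect_warning(out <- compare_groups(df, v, g), "excluding")
  expect_equal(out$n_groups, 2)
})

test_that("paired halves test handles regular and degenerate inputs", {
  # first = second: delta 0, t = 0, p = 1
  out0 <- paired_halves_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out0$t_statistic, 0)
  expect_equal(out0$t_p, 1)
  expect_true(is.na(out0$wilcoxon_p))
  # constant positive shift: unbounded t, flagged
  out5 <- paired_halves_test(c(1, 2, 3), c(6, 7, 8))
  expect_true(is.infinite(out5$t_statistic) && out5$t_statistic > 0)
  expect_equal(out5$t_p, 0)
  expect_true(out5$degenerate)
  expect_match(out5$note, "all-positive")
  expect_equal(out5$direction, "progressivity")
  # seeded Gaussian pairs vs the textbook t formula
  set.seed(17)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  out <- paired_halves_test(a, b)
  d <- b - a
  t_oracle <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(out$t_statistic, t_oracle, tolerance = 1e-10)
  expect_equal(out$t_p, 2 * pt(-abs(t_oracle), 9), tolerance = 1e-10)
  expect_error(paired_halves_test(1:2, 1:3), "equal length")
  expect_error(paired_halves_test(1:2, 2:3), "at least 3")
})

test_that("identical groups give a Pillai trace of zero", {
  z <- random_compositions(10, 3, seed = 3) |> ilr_transform()
  y <- rbind(z, z)
  g <- rep(c("a", "b"), each = 10)
  out <- manova_compositions(y, g)
  expect_equal(out$pillai, 0, tolerance = 1e-12)
})

test_that("one-coordinate MANOVA reduces exactly to one-way ANOVA", {
  set.seed(21)
  y <- matrix(rnorm(30), ncol = 1)
  g <- rep(c("a", "b", "c"), 10)
  out <- manova_compositions(y, g)
  a <- anova(lm(y[, 1] ~ factor(g)))
  expect_equal(out$f_statistic, a$`F value`[1], tolerance = 1e-12)
  expect_equal(out$p, a$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("Pillai trace matches the H/E eigen-decomposition oracle", {
  set.seed(23)
  x <- random_compositions(40, 3, seed = 23)
  z <- ilr_transform(x)
  g <- factor(rep(c("a", "b"), 20))
  out <- manova_compositions(z, g)
  # oracle: between (H) and within (E) scatter matrices directly
  grand <- colMeans(z)
  h_mat <- matrix(0, 2, 2)
  e_mat <- matrix(0, 2, 2)
  for (lev in levels(g)) {
    zi <- z[g == lev, , drop = FALSE]
    mi <- colMeans(zi)
    h_mat <- h_mat + nrow(zi) * tcrossprod(mi - grand)
    e_mat <- e_mat + crossprod(sweep(zi, 2, mi))
  }
  pillai_oracle <- sum(diag(h_mat %*% solve(h_mat + e_mat)))
  expect_equal(out$pillai, pillai_oracle, tolerance = 1e-10)
})

test_that("Pillai trace is invariant to the ilr basis choice", {
  x <- random_compositions(30, 4, seed = 27)
  g <- rep(c("a", "b", "c"), 10)
  v1 <- ilr_basis(4)
  rot <- random_rotation(3, seed = 5)
  v2 <- v1 %*% rot # another orthonormal log-contrast basis
  p1 <- manova_compositions(ilr_transform(x, basis = v1), g)$pillai
  p2 <- manova_compositions(ilr_transform(x, basis = v2), g)$pillai
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("singular within-group covariance is reported by coordinate", {
  y <- cbind(ilr1 = rnorm(10), ilr2 = rep(c(1, 2), each = 5))
  g <- rep(c("a", "b"), each = 5)
  expect_error(manova_compositions(y, g), "ilr2")
  expect_error(
    manova_compositions(matrix(rnorm(4), 2, 2), c("a", "b")),
    "more observations"
  )
})

test_that("load peaks are found at constructed peak weeks", {
  wk <- 25:1
  val <- 50 + 20 * exp(-(wk - 21)^2 / 4) + 25 * exp(-(wk - 5)^2 / 4)
  traj <- tibble::tibble(week_before_bp = wk, mean_ttl = val)
  peaks <- find_load_peaks(traj)
  expect_equal(peaks, c(21, 5))
  # a flat line yields no peaks
  flat <- tibble::tibble(week_before_bp = wk, mean_ttl = rep(60, 25))
  expect_length(find_load_peaks(flat), 0)
  # minimum separation: twin peaks 2 weeks apart collapse to the higher one
  val2 <- 50 + 20 * exp(-(wk - 10)^2 / 1) + 18 * exp(-(wk - 8)^2 / 1)
  traj2 <- tibble::tibble(week_before_bp = wk, mean_ttl = val2)
  peaks2 <- find_load_peaks(traj2, smooth_window = 1)
  expect_equal(peaks2, 10)
})

test_that("profile summaries are consistent with the assignment oracle", {
  coh <- simulate_cohort(sim_config(n_seasons = 40, seed = 61))
  ttl <- compute_ttl(coh$training)
  fit <- fit_lcmm(ttl, lcmm_spec(n_classes = 2, n_interior_knots = 3),
                  n_starts = 2, seed = 2)
  prof <- summarize_profiles(fit, ttl, coh$seasons, coh$training)
  expect_equal(nrow(prof), 2)
  expect_equal(sum(prof$share), 1, tolerance = 1e-12)
  oracle_shares <- tabulate(apply(fit$posterior, 1, which.max), 2) / 40
  expect_equal(prof$share, oracle_shares)
  expect_equal(prof$n, tabulate(fit$modal_class, 2))
  expect_true(all(prof$p_mhi > 0.8 & prof$p_mhi < 0.95))
  expect_true(all(prof$progressivity %in% c("progressivity", "degressivity")))
  # single-class cohort: one row, share 1
  fit1 <- fit_lcmm(ttl, lcmm_spec(n_classes = 1, n_interior_knots = 3),
                   n_starts = 1, seed = 1)
  prof1 <- summarize_profiles(fit1, ttl, coh$seasons, coh$training)
  expect_equal(nrow(prof1), 1)
  expect_equal(prof1$share, 1)
})

test_that("covariate cross-tabs report chi-square tests per covariate", {
  coh <- simulate_cohort(sim_config(n_seasons = 60, seed = 71))
  ttl <- compute_ttl(coh$training)
  fit <- fit_lcmm(ttl, lcmm_spec(n_classes = 2, n_interior_knots = 2),
                  n_starts = 2, seed = 3)
  ct <- suppressWarnings(covariate_crosstabs(coh$seasons, fit))
  expect_equal(nrow(ct), 3)
  expect_true(all(ct$p >= 0 & ct$p <= 1))
})

test_that("the variance-homogeneity gate equals Levene's median-centered
           test", {
  skip_if_not_installed("car")
  set.seed(37)
  df <- tibble::tibble(v = c(rnorm(12), rnorm(12, 0, 4)),
                       g = rep(c("a", "b"), each = 12))
  out <- compare_groups(df, v, g)
  lev_p <- car::leveneTest(df$v, factor(df$g), center = median)$`Pr(>F)`[1]
  expect_equal(out$variance_ok, lev_p > 0.05)
})
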