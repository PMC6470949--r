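test_that("spline basis has the right dimension and degenerates to a line", {
  b0 <- spline_basis(1:25, 0)
  expect_equal(ncol(b0), 2)
  # 0 interior knots: natural spline space is {1, t}
  fit <- lm.fit(b0, 3 + 2 * (1:25))
  expect_lt(max(abs(fit$residuals)), 1e-10)
  b3 <- spline_basis(1:25, 3)
  expect_equal(ncol(b3), 5)
  # exact reproduction of a line by least squares on any basis size
  fit3 <- lm.fit(b3, 3 + 2 * (1:25))
  expect_lt(max(abs(fit3$residuals)), 1e-8)
  expect_error(spline_basis(1:3, 5), "distinct times")
})

test_that("spline basis is C2: continuous value and derivatives at knots", {
  tgrid <- seq(1, 25, by = 1e-3)
  b <- spline_basis(1:25, 4, at = tgrid)
  kn <- attr(spline_basis(1:25, 4), "knots")
  for (j in seq_len(ncol(b))) {
    f <- b[, j]
    d1 <- diff(f) / 1e-3
    d2 <- diff(d1) / 1e-3
    for (k in kn) {
      i <- which.min(abs(tgrid - k))
      # value, first and second finite-difference derivative continuous
      expect_lt(abs(f[i + 1] - f[i - 1]), 1e-2)
      expect_lt(abs(d1[i + 1] - d1[i - 1]), 1e-1)
      expect_lt(abs(d2[i + 2] - d2[i - 2]), 2)
    }
  }
})

test_that("marginal loglik collapses to iid Gaussian when K=1, B=0", {
  ttl <- random_ttl(4, weeks = 1:5, seed = 2)
  spec <- lcmm_spec(n_classes = 1, n_interior_knots = 1)
  beta <- matrix(c(48, 2, 1), 3, 1)
  params <- list(pi = 1, beta = beta, B = matrix(0, 1, 1), w = 1, sigma = 7)
  ll <- lcmm_marginal_loglik(ttl, spec, params)
  basis <- spline_basis(sort(rep(1:5, 4)), 1)
  df <- ttl |> dplyr::arrange(swimmer_id, week_before_bp)
  basis <- spline_basis(df$week_before_bp, 1)
  mu <- as.vector(basis %*% beta)
  expect_equal(ll, sum(dnorm(df$ttl, mu, 7, log = TRUE)), tolerance = 1e-10)
})

test_that("marginal loglik is invariant to permuting class labels", {
  ttl <- random_ttl(5, weeks = 1:4, seed = 3)
  spec <- lcmm_spec(n_classes = 2, n_interior_knots = 1)
  params <- list(
    pi = c(0.3, 0.7),
    beta = cbind(c(40, 1, 0.5), c(60, -1, 0)),
    B = matrix(16, 1, 1), w = c(1, 1), sigma = 5
  )
  swapped <- list(
    pi = params$pi[2:1], beta = params$beta[, 2:1],
    B = params$B, w = params$w, sigma = params$sigma
  )
  expect_equal(lcmm_marginal_loglik(ttl, spec, params),
               lcmm_marginal_loglik(ttl, spec, swapped), tolerance = 1e-12)
})

test_that("marginal loglik agrees with adaptive quadrature on tiny instances", {
  set.seed(42)
  for (r in 1:5) {
    k <- sample(1:2, 1)
    n_sub <- sample(2:4, 1)
    weeks <- seq_len(sample(3:5, 1))
    ttl <- random_ttl(n_sub, weeks = weeks, seed = 100 + r)
    spec <- lcmm_spec(n_classes = k, n_interior_knots = 1)
    p <- 3
    params <- list(
      pi = { v <- runif(k, 0.3, 1); v / sum(v) },
      beta = matrix(rnorm(p * k, c(50, 0, 0), 3), p, k),
      B = matrix(runif(1, 1, 25), 1, 1),
      w = rep(1, k), sigma = runif(1, 2, 6)
    )
    expect_equal(
      lcmm_marginal_loglik(ttl, spec, params),
      quadrature_loglik(ttl, spec, params),
      tolerance = 1e-6
    )
  }
})

test_that("posterior probabilities match the direct density-ratio oracle", {
  ttl <- random_ttl(6, weeks = 1:5, seed = 4)
  coh <- simulate_cohort(sim_config(n_seasons = 12, seed = 5))
  data <- compute_ttl(coh$training)
  fit <- fit_lcmm(data, lcmm_spec(n_classes = 2, n_interior_knots = 2),
                  n_starts = 2, seed = 1)
  post <- posterior_probs(fit, data)
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-10)
  # oracle: per-subject class densities via quadrature, then Bayes' rule
  spec <- fit$spec
  params <- fit$params
  df <- data |>
    dplyr::mutate(.id = paste(swimmer_id, season_label, sep = ":"))
  id1 <- rownames(post)[1]
  sub <- df |> dplyr::filter(.id == id1)
  dens <- vapply(1:2, function(g) {
    one_class <- list(pi = 1, beta = params$beta[, g, drop = FALSE],
                      B = params$B, w = 1, sigma = params$sigma)
    exp(quadrature_loglik(sub, lcmm_spec(1, spec$n_interior_knots),
                          one_class))
  }, numeric(1))
  oracle <- params$pi * dens / sum(params$pi * dens)
  expect_equal(unname(post[1, ]), oracle, tolerance = 1e-6)
  # K = 1: all posteriors are 1
  fit1 <- fit_lcmm(data, lcmm_spec(n_classes = 1, n_interior_knots = 2),
                   n_starts = 1, seed = 1)
  expect_true(all(fit1$posterior == 1))
})

test_that("K=1 fit matches the lme4 maximum-likelihood oracle", {
  skip_if_not_installed("lme4")
  coh <- simulate_cohort(sim_config(
    n_seasons = 25, class_proportions = 1, class_curves = "long",
    performance_means = 6, performance_sds = 3, seed = 9
  ))
  data <- compute_ttl(coh$training)
  fit <- fit_lcmm(data, lcmm_spec(n_classes = 1, n_interior_knots = 3),
                  n_starts = 1, seed = 1)
  df <- data |> dplyr::arrange(swimmer_id, week_before_bp)
  d <- data.frame(ttl = df$ttl, swimmer_id = df$swimmer_id)
  d$x <- spline_basis(df$week_before_bp, 3)
  lmerfit <- lme4::lmer(ttl ~ 0 + x + (1 | swimmer_id), data = d,
                        REML = FALSE)
  expect_equal(as.vector(fit$params$beta),
               unname(lme4::fixef(lmerfit)), tolerance = 1e-4)
  expect_equal(fit$params$sigma, sigma(lmerfit), tolerance = 1e-4)
})

test_that("noise-free well-separated classes are classified exactly", {
  cfg <- sim_config(
    n_seasons = 16, class_proportions = c(0.5, 0.5),
    class_curves = list(40, 70), random_effect_sd = 0, residual_sd = 0,
    performance_means = c(6, 7), performance_sds = c(3, 3), seed = 12
  )
  coh <- simulate_cohort(cfg)
  data <- compute_ttl(coh$training)
  fit <- fit_lcmm(data, lcmm_spec(n_classes = 2, n_interior_knots = 1),
                  n_starts = 2, seed = 2)
  acc <- aligned_accuracy(fit$modal_class, coh$truth$true_class, 2)
  expect_equal(acc, 1)
  truth_share <- mean(coh$truth$true_class ==
                        which.max(tabulate(coh$truth$true_class)))
  expect_equal(sort(fit$params$pi), sort(tabulate(coh$truth$true_class) / 16),
               tolerance = 0.02)
})

test_that("EM iterations never decrease the marginal log-likelihood", {
  coh <- simulate_cohort(sim_config(n_seasons = 40, seed = 15))
  data <- compute_ttl(coh$training)
  for (k in 1:3) {
    fit <- fit_lcmm(data, lcmm_spec(n_classes = k, n_interior_knots = 3),
                    n_starts = 2, seed = k)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
    expect_equal(unname(rowSums(fit$posterior)), rep(1, fit$n_subjects),
                 tolerance = 1e-10)
  }
})

test_that("the K-class maximum loglik is >= the (K-1)-class one", {
  coh <- simulate_cohort(sim_config(n_seasons = 30, seed = 19))
  data <- compute_ttl(coh$training)
  lls <- vapply(1:3, function(k) {
    fit_lcmm(data, lcmm_spec(n_classes = k, n_interior_knots = 2),
             n_starts = 3, seed = 7)$loglik
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("information criteria recompute from loglik and n_params", {
  coh <- simulate_cohort(sim_config(n_seasons = 20, seed = 23))
  data <- compute_ttl(coh$training)
  fit <- fit_lcmm(data, lcmm_spec(n_classes = 2, n_interior_knots = 2,
                                  re_class_structure = "proportional"),
                  n_starts = 2, seed = 3)
  expect_equal(fit$AIC, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$BIC, -2 * fit$loglik + fit$n_params * log(fit$n_subjects))
  # parameter count: (K-1) logits + K*p betas + q cov + (K-1) scalars + sigma
  expect_equal(fit$n_params, 1 + 2 * 4 + 1 + 1 + 1)
  expect_true(all(fit$params$w > 0))
  expect_equal(fit$params$w[2], 1)
})

test_that("parameters are recovered on well-separated two-class cohorts", {
  pi_err <- sig_err <- curve_rmse <- numeric(0)
  for (s in 1:3) {
    cfg <- sim_config(
      n_seasons = 250, class_proportions = c(0.6, 0.4),
      class_curves = c("long", "stable_flat"),
      performance_means = c(6, 7.4), performance_sds = c(3.1, 2.9),
      seed = 300 + s
    )
    coh <- simulate_cohort(cfg)
    data <- compute_ttl(coh$training)
    fit <- fit_lcmm(data, lcmm_spec(n_classes = 2, n_interior_knots = 5),
                    n_starts = 2, seed = s)
    perm <- best_alignment(fit$modal_class, coh$truth$true_class, 2)
    emp <- tabulate(coh$truth$true_class, 2) / 250
    pi_hat <- fit$params$pi
    pi_err <- c(pi_err, max(abs(pi_hat[order(perm)] - emp)))
    sig_err <- c(sig_err, abs(fit$params$sigma - cfg$residual_sd) /
                   cfg$residual_sd)
    mu <- swimperiod:::class_mean_matrix(cfg)
    pred <- predict_class_means(fit, weeks = 1:25)
    for (g in 1:2) {
      fitted_g <- pred$mean_ttl[pred$class == g]
      true_g <- mu[, perm[g]]
      curve_rmse <- c(curve_rmse,
                      sqrt(mean((fitted_g - true_g)^2)) / mean(true_g))
    }
  }
  expect_lt(mean(pi_err), 0.03)
  expect_lt(mean(sig_err), 0.10)
  expect_lt(mean(curve_rmse), 0.02)
})

test_that("modal assignment, tie-breaking and summaries match brute force", {
  post <- matrix(c(0.9, 0.1, 0.9, 0.1, 0.9, 0.1), 3, 2, byrow = TRUE)
  asg <- assign_and_summarize(post)
  expect_equal(asg$modal_class, c(1, 1, 1))
  expect_equal(asg$mean_posterior_by_class, c(0.9, NA))
  expect_equal(asg$class_shares, c(1, 0))
  tie <- assign_and_summarize(rbind(c(0.5, 0.5), c(0.2, 0.8)))
  expect_equal(tie$modal_class, c(1, 2)) # tie goes to the lowest index
  expect_equal(tie$n_ties, 1)
  set.seed(6)
  r <- matrix(runif(40), 10, 4)
  r <- r / rowSums(r)
  asg2 <- assign_and_summarize(r)
  oracle_modal <- apply(r, 1, which.max)
  expect_equal(asg2$modal_class, oracle_modal)
  for (g in 1:4) {
    members <- oracle_modal == g
    if (any(members)) {
      expect_equal(asg2$mean_posterior_by_class[g], mean(r[members, g]))
    }
  }
  expect_equal(asg2$class_shares, tabulate(oracle_modal, 4) / 10)
})

test_that("weighted class means reduce to group means and grand means", {
  ttl <- random_ttl(6, weeks = 1:4, seed = 31)
  ids <- ttl |>
    dplyr::distinct(swimmer_id, season_label) |>
    dplyr::mutate(.id = paste(swimmer_id, season_label, sep = ":"))
  hard <- cbind(rep(c(1, 0), 3), rep(c(0, 1), 3))
  rownames(hard) <- ids$.id
  wm <- weighted_class_means(ttl, hard)
  grp1 <- ttl |>
    dplyr::filter(swimmer_id %in% ids$swimmer_id[c(1, 3, 5)]) |>
    dplyr::group_by(week_before_bp) |>
    dplyr::summarise(m = mean(ttl))
  expect_equal(wm$mean_ttl[wm$class == 1], grp1$m, tolerance = 1e-12)
  unif <- matrix(0.5, 6, 2)
  rownames(unif) <- ids$.id
  wm_u <- weighted_class_means(ttl, unif)
  grand <- ttl |>
    dplyr::group_by(week_before_bp) |>
    dplyr::summarise(m = mean(ttl))
  expect_equal(wm_u$mean_ttl[wm_u$class == 1], grand$m, tolerance = 1e-12)
  expect_equal(wm_u$mean_ttl[wm_u$class == 2], grand$m, tolerance = 1e-12)
  # random weights vs direct oracle
  set.seed(7)
  w <- matrix(runif(12), 6, 2)
  w <- w / rowSums(w)
  rownames(w) <- ids$.id
  wm_r <- weighted_class_means(ttl, w)
  df <- ttl |> dplyr::mutate(.id = paste(swimmer_id, season_label, sep = ":"))
  for (g in 1:2) {
    for (t in 1:4) {
      sub <- df |> dplyr::filter(week_before_bp == t)
      wt <- w[match(sub$.id, ids$.id), g]
      expect_equal(
        wm_r$mean_ttl[wm_r$class == g & wm_r$week_before_bp == t],
        sum(wt * sub$ttl) / sum(wt), tolerance = 1e-12
      )
    }
  }
})

test_that("a single-cell model search returns that fit", {
  coh <- simulate_cohort(sim_config(n_seasons = 15, seed = 41))
  data <- compute_ttl(coh$training)
  sr <- model_search(data, k_range = 2, knot_range = 3, n_starts = 2,
                     seed = 1)
  expect_equal(nrow(sr$table), 1)
  expect_equal(sr$selected_k, 2)
  expect_s3_class(sr$fit, "lcmm_fit")
  # AIC/BIC columns recompute exactly from loglik and n_params
  expect_equal(sr$table$AIC, -2 * sr$table$logLik + 2 * sr$table$n_params)
  expect_equal(sr$table$BIC,
               -2 * sr$table$logLik + sr$table$n_params * log(15))
})

test_that("tidiers return well-formed tibbles", {
  coh <- simulate_cohort(sim_config(n_seasons = 12, seed = 51))
  data <- compute_ttl(coh$training)
  fit <- fit_lcmm(data, lcmm_spec(n_classes = 2, n_interior_knots = 2),
                  n_starts = 1, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("term", "class", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_classes, 2)
  au <- augment(fit)
  expect_equal(nrow(au), 12)
  expect_true(all(au$modal_class %in% 1:2))
  p <- autoplot(fit, data = data)
  expect_s3_class(p, "ggplot")
})
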