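#' Natural cubic spline basis for trajectory mean curves
#'
#' Builds the design matrix used for the class-specific mean TTL curves: an
#' intercept column plus a natural cubic spline in `week_before_bp` with the
#' requested number of interior knots placed at equally spaced quantiles of
#' the observation times. Natural splines are linear beyond the boundary
#' knots, so evaluation outside the observed range extrapolates linearly.
#' With 0 interior knots the basis degenerates to `{1, t}`.
#'
#' @param times Numeric vector of observation times used to place the knots.
#' @param n_interior_knots Number of interior knots (0--15).
#' @param at Times at which to evaluate the basis (default `times`).
#' @return A matrix with `n_interior_knots + 2` columns (intercept included),
#'   with attributes `knots` and `boundary`.
#' @examples
#' b <- spline_basis(1:25, 3)
#' dim(b) # 25 x 5
#' @export
spline_basis <- function(times, n_interior_knots, at = NULL) {
  ut <- sort(unique(times))
  if (length(ut) < n_interior_knots + 2) {
    abort("need at least n_interior_knots + 2 distinct times")
  }
  at <- at %||% times
  bk <- range(ut)
  kn <- if (n_interior_knots > 0) {
    as.numeric(quantile(times, probs = seq_len(n_interior_knots) /
                          (n_interior_knots + 1), names = FALSE))
  } else {
    numeric(0)
  }
  ns_part <- splines::ns(at, knots = kn, Boundary.knots = bk)
  x <- cbind(1, ns_part)
  colnames(x) <- c("(Intercept)", paste0("ns", seq_len(ncol(ns_part))))
  attr(x, "knots") <- kn
  attr(x, "boundary") <- bk
  x
}

#' Specification of a latent-class linear mixed model
#'
#' A finite mixture of K Gaussian linear mixed models for longitudinal TTL
#' series: class-specific natural-spline mean curves over `week_before_bp`,
#' subject-level random effects with covariance `B` (shared across classes,
#' or scaled per class as `w_g^2 * B` under the proportional structure), iid
#' residual noise, and intercept-only multinomial class-membership
#' probabilities.
#'
#' @param n_classes Number of latent classes K (1--5).
#' @param n_interior_knots Interior knots of the spline mean curves (0--15).
#' @param random_effects `"intercept"` (default) or `"intercept_slope"`
#'   (adds a subject-level linear slope in centered time).
#' @param re_covariance `"diagonal"` or `"unstructured"` random-effect
#'   covariance (identical when there is a single random effect).
#' @param re_class_structure `"common"` (one `B` for all classes) or
#'   `"proportional"` (`B_g = w_g^2 B`, `w_K = 1`).
#' @return An `lcmm_spec` object.
#' @export
lcmm_spec <- function(n_classes = 1,
                      n_interior_knots = 3,
                      random_effects = c("intercept", "intercept_slope"),
                      re_covariance = c("diagonal", "unstructured"),
                      re_class_structure = c("common", "proportional")) {
  random_effects <- match.arg(random_effects)
  re_covariance <- match.arg(re_covariance)
  re_class_structure <- match.arg(re_class_structure)
  if (n_classes < 1 || n_classes > 5) abort("n_classes must be in 1..5")
  if (n_interior_knots < 0 || n_interior_knots > 15) {
    abort("n_interior_knots must be in 0..15")
  }
  structure(
    list(
      n_classes = as.integer(n_classes),
      n_interior_knots = as.integer(n_interior_knots),
      random_effects = random_effects,
      re_covariance = re_covariance,
      re_class_structure = re_class_structure
    ),
    class = "lcmm_spec"
  )
}

# ---- internal data container ----------------------------------------------

# Convert a TTL tibble (swimmer_id, season_label, week_before_bp, ttl) into
# per-subject response vectors, design matrices and shared time-pattern
# groups (subjects observed at identical times share the marginal covariance
# and its Cholesky factor).
build_lcmm_data <- function(ttl, spec) {
  need <- c("swimmer_id", "season_label", "week_before_bp", "ttl")
  if (!all(need %in% names(ttl))) {
    abort(paste("`data` needs columns", paste(need, collapse = ", ")))
  }
  ttl <- ttl |>
    dplyr::mutate(.id = season_key(.data$swimmer_id, .data$season_label)) |>
    dplyr::arrange(.data$.id, .data$week_before_bp)
  ids <- unique(ttl$.id)
  all_times <- ttl$week_before_bp
  q <- if (spec$random_effects == "intercept") 1L else 2L
  t_center <- mean(range(all_times))
  basis_all <- spline_basis(all_times, spec$n_interior_knots)
  split_idx <- split(seq_len(nrow(ttl)), factor(ttl$.id, levels = ids))
  subjects <- lapply(split_idx, function(idx) {
    ti <- ttl$week_before_bp[idx]
    if (length(ti) < 2) abort("every subject needs at least 2 observations")
    z <- if (q == 1) matrix(1, length(ti), 1) else cbind(1, ti - t_center)
    list(
      y = ttl$ttl[idx],
      x = basis_all[idx, , drop = FALSE],
      z = z,
      times = ti,
      pattern = paste(ti, collapse = ",")
    )
  })
  patterns <- unique(vapply(subjects, `[[`, "", "pattern"))
  pat_of <- match(vapply(subjects, `[[`, "", "pattern"), patterns)
  pat_z <- lapply(patterns, function(p) {
    subjects[[which(pat_of == match(p, patterns))[1]]]$z
  })
  list(
    ids = ids, subjects = subjects, n = length(ids), q = q,
    p = ncol(basis_all), pat_of = pat_of, pat_z = pat_z,
    n_patterns = length(patterns),
    knots = attr(basis_all, "knots"), boundary = attr(basis_all, "boundary"),
    t_center = t_center,
    n_obs = nrow(ttl)
  )
}

# Per-pattern response matrix (columns = subjects of that pattern) for
# vectorized density evaluation.
pattern_blocks <- function(dat) {
  lapply(seq_len(dat$n_patterns), function(k) {
    idx <- which(dat$pat_of == k)
    list(
      idx = idx,
      y = do.call(cbind, lapply(dat$subjects[idx], `[[`, "y")),
      x = dat$subjects[[idx[1]]]$x,
      z = dat$pat_z[[k]]
    )
  })
}

log_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

b_class <- function(params, g) params$w[g]^2 * params$B

# ---- marginal likelihood ---------------------------------------------------

#' Marginal log-likelihood of a latent-class mixed model
#'
#' Computes `sum_i log sum_g pi_g * N(y_i; X_i beta_g, Z_i B_g Z_i' +
#' sigma^2 I)` with `B_g = w_g^2 B`, stabilized with log-sum-exp. The random
#' effects are integrated out analytically (the marginal covariance of a
#' Gaussian linear mixed model is available in closed form), so this is exact
#' up to floating point.
#'
#' @param data A TTL tibble with columns `swimmer_id`, `season_label`,
#'   `week_before_bp`, `ttl`.
#' @param spec An [lcmm_spec()].
#' @param params A list with elements `pi` (length K), `beta` (p x K matrix),
#'   `B` (q x q PSD matrix), `w` (length K positive, `w[K] = 1` under the
#'   proportional structure, all 1 under common), `sigma` (> 0).
#' @return The marginal log-likelihood (scalar).
#' @export
lcmm_marginal_loglik <- function(data, spec, params) {
  dat <- build_lcmm_data(data, spec)
  validate_params(params, dat, spec)
  sum(log_sum_exp(class_logdens(dat, params) +
                    rep(log(params$pi), each = dat$n)))
}

validate_params <- function(params, dat, spec) {
  k <- spec$n_classes
  if (length(params$pi) != k || abs(sum(params$pi) - 1) > 1e-8 ||
      any(params$pi <= 0)) {
    abort("params$pi must be positive and sum to 1")
  }
  if (!all(dim(as.matrix(params$beta)) == c(dat$p, k))) {
    abort(paste0("params$beta must be ", dat$p, " x ", k))
  }
  ev <- eigen(as.matrix(params$B), symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10)) abort("params$B must be positive semi-definite")
  if (params$sigma <= 0) abort("params$sigma must be positive")
  if (any(params$w <= 0)) abort("params$w must be positive")
  invisible(params)
}

# n x K matrix of per-subject per-class Gaussian log-densities.
class_logdens <- function(dat, params, blocks = NULL) {
  blocks <- blocks %||% pattern_blocks(dat)
  k <- length(params$pi)
  ld <- matrix(NA_real_, dat$n, k)
  for (g in seq_len(k)) {
    bg <- b_class(params, g)
    mu_g <- as.matrix(params$beta)[, g]
    for (blk in blocks) {
      nt <- nrow(blk$z)
      v <- blk$z %*% bg %*% t(blk$z) + diag(params$sigma^2, nt)
      r <- chol(v)
      resid <- blk$y - as.vector(blk$x %*% mu_g)
      qf <- colSums(backsolve(r, resid, transpose = TRUE)^2)
      ld[blk$idx, g] <- -0.5 * nt * log(2 * pi) - sum(log(diag(r))) - 0.5 * qf
    }
  }
  ld
}

# ---- EM --------------------------------------------------------------------

# One E-step: returns loglik, posteriors, and the conditional random-effect
# moments needed by the closed-form M-step.
e_step <- function(dat, params, blocks) {
  k <- length(params$pi)
  ld <- matrix(NA_real_, dat$n, k)
  cond <- vector("list", k) # per class: list over patterns of (W, M)
  for (g in seq_len(k)) {
    bg <- b_class(params, g)
    mu_g <- as.matrix(params$beta)[, g]
    cond[[g]] <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      nt <- nrow(blk$z)
      v <- blk$z %*% bg %*% t(blk$z) + diag(params$sigma^2, nt)
      r <- chol(v)
      resid <- blk$y - as.vector(blk$x %*% mu_g)
      qf <- colSums(backsolve(r, resid, transpose = TRUE)^2)
      ld[blk$idx, g] <- -0.5 * nt * log(2 * pi) - sum(log(diag(r))) - 0.5 * qf
      # conditional moments of b | y, class: W = (Z'Z/s2 + Bg^-1)^-1
      ztz <- crossprod(blk$z)
      bg_reg <- bg + diag(1e-10, nrow(bg))
      w_mat <- solve(ztz / params$sigma^2 + solve(bg_reg))
      m_mat <- w_mat %*% crossprod(blk$z, resid) / params$sigma^2
      cond[[g]][[bi]] <- list(W = w_mat, M = m_mat, ztz = ztz)
    }
  }
  lp <- ld + rep(log(params$pi), each = dat$n)
  li <- log_sum_exp(lp)
  list(loglik = sum(li), post = exp(lp - li), cond = cond, ld = ld)
}

# Closed-form M-step given posteriors and conditional moments.
m_step <- function(dat, spec, blocks, est) {
  k <- ncol(est$post)
  q <- dat$q
  p <- dat$p
  n_obs <- dat$n_obs
  pi_new <- pmax(colMeans(est$post), 1e-12)
  pi_new <- pi_new / sum(pi_new)
  beta_new <- matrix(0, p, k)
  s_list <- vector("list", k)
  n_g <- colSums(est$post)
  rss_tr <- 0
  for (g in seq_len(k)) {
    xtx <- matrix(0, p, p)
    xty <- numeric(p)
    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      pg <- est$post[blk$idx, g]
      zm <- blk$z %*% est$cond[[g]][[bi]]$M
      xtx <- xtx + sum(pg) * crossprod(blk$x)
      xty <- xty + crossprod(blk$x, (blk$y - zm) %*% pg)
    }
    beta_new[, g] <- solve(xtx, xty)
    s_g <- matrix(0, q, q)
    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      pg <- est$post[blk$idx, g]
      cnd <- est$cond[[g]][[bi]]
      e_mat <- blk$y - as.vector(blk$x %*% beta_new[, g]) - blk$z %*% cnd$M
      rss_tr <- rss_tr +
        sum(pg * colSums(e_mat^2)) +
        sum(pg) * sum(cnd$ztz * cnd$W)
      s_g <- s_g + cnd$M %*% (pg * t(cnd$M)) + sum(pg) * cnd$W
    }
    s_list[[g]] <- s_g / max(n_g[g], 1e-12)
  }
  sigma_new <- max(sqrt(rss_tr / n_obs), 1e-4)
  # random-effect covariance update
  w_new <- rep(1, k)
  if (spec$re_class_structure == "common" || k == 1) {
    b_new <- Reduce(`+`, Map(function(s, ng) ng * s, s_list, n_g)) / dat$n
    if (spec$re_covariance == "diagonal") b_new <- diag(diag(b_new), q)
  } else {
    # B_g = w_g^2 B with w_K = 1: alternate exact conditional updates
    b_new <- s_list[[k]]
    w_new <- rep(1, k)
    for (it in seq_len(15)) {
      b_new <- Reduce(`+`, Map(function(s, ng, wg) ng * s / wg^2,
                               s_list, n_g, w_new)) / dat$n
      if (spec$re_covariance == "diagonal") b_new <- diag(diag(b_new), q)
      b_reg <- b_new + diag(1e-12, q)
      for (g in seq_len(k - 1)) {
        w_new[g] <- sqrt(max(sum(diag(solve(b_reg, s_list[[g]]))) / q, 1e-12))
      }
    }
  }
  b_new <- (b_new + t(b_new)) / 2
  list(pi = pi_new, beta = beta_new, B = b_new, w = w_new, sigma = sigma_new)
}

params_to_vec <- function(params) {
  c(params$pi, as.vector(params$beta), as.vector(params$B), params$w,
    params$sigma)
}

run_em <- function(dat, spec, blocks, params, tol, max_iter) {
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    est <- e_step(dat, params, blocks)
    trace <- c(trace, est$loglik)
    if (it > 1) {
      rel <- abs(est$loglik - trace[it - 1]) /
        (abs(trace[it - 1]) + .Machine$double.eps)
      par_change <- max(abs(params_to_vec(params) - params_to_vec(old)))
      if (rel < tol && par_change < 1e-5) {
        converged <- TRUE
        break
      }
    }
    old <- params
    params <- m_step(dat, spec, blocks, est)
  }
  list(params = params, loglik = trace[length(trace)], trace = trace,
       converged = converged, post = est$post)
}

# ---- parameter packing for quasi-Newton polish -----------------------------

pack_params <- function(params, spec, q) {
  k <- spec$n_classes
  xi <- if (k > 1) log(params$pi[-k] / params$pi[k]) else numeric(0)
  covp <- if (spec$re_covariance == "diagonal" || q == 1) {
    0.5 * log(pmax(diag(as.matrix(params$B)), 1e-12))
  } else {
    l <- t(chol(as.matrix(params$B) + diag(1e-10, q)))
    c(log(diag(l)), l[lower.tri(l)])
  }
  wv <- if (spec$re_class_structure == "proportional" && k > 1) {
    log(params$w[-k])
  } else {
    numeric(0)
  }
  c(xi, as.vector(params$beta), covp, wv, log(params$sigma))
}

unpack_params <- function(theta, spec, p, q) {
  k <- spec$n_classes
  i <- 0
  xi <- theta[seq_len(k - 1) + i]; i <- i + (k - 1)
  e <- exp(c(xi, 0))
  pi_v <- e / sum(e)
  beta <- matrix(theta[seq_len(p * k) + i], p, k); i <- i + p * k
  if (spec$re_covariance == "diagonal" || q == 1) {
    b_mat <- diag(exp(2 * theta[seq_len(q) + i]), q); i <- i + q
  } else {
    nl <- q * (q + 1) / 2
    v <- theta[seq_len(nl) + i]; i <- i + nl
    l <- diag(exp(v[seq_len(q)]), q)
    l[lower.tri(l)] <- v[-seq_len(q)]
    b_mat <- l %*% t(l)
  }
  w <- rep(1, k)
  if (spec$re_class_structure == "proportional" && k > 1) {
    w[seq_len(k - 1)] <- exp(theta[seq_len(k - 1) + i]); i <- i + (k - 1)
  }
  sigma <- max(exp(theta[i + 1]), 1e-4)
  list(pi = pi_v, beta = beta, B = b_mat, w = w, sigma = sigma)
}

count_params <- function(spec, p, q) {
  covp <- if (spec$re_covariance == "diagonal" || q == 1) q else q * (q + 1) / 2
  k <- spec$n_classes
  (k - 1) + k * p + covp +
    (if (spec$re_class_structure == "proportional") k - 1 else 0) + 1
}

# ---- initialization --------------------------------------------------------

init_params <- function(dat, spec, blocks, start, seed) {
  k <- spec$n_classes
  p <- dat$p
  q <- dat$q
  coefs <- t(vapply(dat$subjects, function(s) {
    qr.coef(qr(s$x), s$y)
  }, numeric(p)))
  coefs[is.na(coefs)] <- 0
  cl <- if (k == 1) {
    rep(1L, dat$n)
  } else {
    km <- kmeans(scale(coefs), centers = k, nstart = 5)
    km$cluster
  }
  beta0 <- vapply(seq_len(k), function(g) {
    if (sum(cl == g) >= 1) colMeans(coefs[cl == g, , drop = FALSE]) else
      colMeans(coefs)
  }, numeric(p))
  fitted_res <- unlist(lapply(seq_along(dat$subjects), function(i) {
    s <- dat$subjects[[i]]
    s$y - as.vector(s$x %*% beta0[, cl[i]])
  }))
  subj_means <- vapply(seq_along(dat$subjects), function(i) {
    s <- dat$subjects[[i]]
    mean(s$y - as.vector(s$x %*% beta0[, cl[i]]))
  }, numeric(1))
  tau2 <- max(var(subj_means), 1e-4)
  sig2 <- max(var(fitted_res) - tau2, 1e-4)
  b0 <- if (q == 1) matrix(tau2, 1, 1) else diag(c(tau2, tau2 / 100), 2)
  pi0 <- pmax(tabulate(cl, k) / dat$n, 0.05)
  pi0 <- pi0 / sum(pi0)
  params <- list(pi = pi0, beta = beta0, B = b0, w = rep(1, k),
                 sigma = sqrt(sig2))
  if (start > 1) {
    set.seed(seed + 1000L * start)
    params$beta <- params$beta * (1 + 0.2 * runif(length(params$beta), -1, 1))
    params$sigma <- params$sigma * (1 + 0.2 * runif(1, -1, 1))
    params$B <- params$B * (1 + 0.2 * runif(1, -1, 1))
  }
  params
}

# ---- main fit --------------------------------------------------------------

#' Fit a latent-class linear mixed model to TTL trajectories
#'
#' Maximum-likelihood estimation by EM with (class membership, random effect)
#' as missing data -- closed-form M-steps for the mean-curve coefficients,
#' residual variance and random-effect covariance -- followed by quasi-Newton
#' (BFGS) polishing of the full marginal likelihood under a log/Cholesky
#' parameterization. Multiple starts perturb a K-means initialization on
#' per-subject least-squares curve coefficients; the best-likelihood start is
#' returned. After fitting, classes are relabeled in order of decreasing mean
#' fitted trajectory level (the likelihood is invariant to this).
#'
#' @param data TTL tibble (`swimmer_id`, `season_label`, `week_before_bp`,
#'   `ttl`), e.g. from [compute_ttl()].
#' @param spec An [lcmm_spec()].
#' @param n_starts Number of EM starts (default 10).
#' @param seed Integer seed controlling initialization jitter.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8);
#'   convergence also requires maximum absolute parameter change < 1e-5.
#' @param max_iter EM iteration cap per start (default 500).
#' @param polish Run BFGS refinement on the best start (default TRUE).
#' @return An `lcmm_fit` object with elements `spec`, `params` (`pi`, `beta`,
#'   `B`, `w`, `sigma`), `loglik`, `loglik_trace`, `n_params`, `AIC`, `BIC`
#'   (using the number of subjects as N), `posterior`, `modal_class`,
#'   `mean_posterior_by_class`, `class_shares`, `converged`, `n_starts_used`,
#'   and the spline/basis metadata needed for prediction.
#' @examples
#' coh <- simulate_cohort(sim_config(n_seasons = 30, seed = 7))
#' ttl <- compute_ttl(coh$training)
#' fit <- fit_lcmm(ttl, lcmm_spec(n_classes = 2, n_interior_knots = 2),
#'                 n_starts = 2, seed = 1)
#' glance(fit)
#' @export
fit_lcmm <- function(data, spec, n_starts = 10, seed = 1, tol = 1e-8,
                     max_iter = 500, polish = TRUE) {
  stopifnot(inherits(spec, "lcmm_spec"))
  dat <- build_lcmm_data(data, spec)
  if (spec$n_classes > dat$n) abort("more classes than subjects")
  blocks <- pattern_blocks(dat)
  best <- NULL
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    params0 <- init_params(dat, spec, blocks, s, seed)
    res <- tryCatch(
      run_em(dat, spec, blocks, params0, tol, max_iter),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) abort("all EM starts failed")
  params <- best$params
  loglik <- best$loglik
  if (polish) {
    theta0 <- pack_params(params, spec, dat$q)
    negll <- function(th) {
      p_try <- unpack_params(th, spec, dat$p, dat$q)
      ll <- tryCatch(
        sum(log_sum_exp(class_logdens(dat, p_try, blocks) +
                          rep(log(p_try$pi), each = dat$n))),
        error = function(e) -Inf
      )
      if (!is.finite(ll)) 1e10 else -ll
    }
    opt <- tryCatch(
      optim(theta0, negll, method = "BFGS",
            control = list(maxit = 100, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(opt) && -opt$value > loglik) {
      params <- unpack_params(opt$par, spec, dat$p, dat$q)
      loglik <- -opt$value
    }
    # a stationary point found by the quasi-Newton polish also counts as
    # convergence (EM can stall short of its parameter-change criterion on
    # flat likelihood ridges, e.g. when a class is redundant)
    if (!is.null(opt) && opt$convergence == 0) best$converged <- TRUE
  }
  params <- canonicalize_labels(params, dat, spec)
  finalize_fit(dat, spec, blocks, params, loglik, best, n_starts)
}

# Reorder classes by descending mean fitted trajectory level; under the
# proportional structure re-anchor w so the new last class has w = 1.
canonicalize_labels <- function(params, dat, spec) {
  k <- spec$n_classes
  if (k == 1) return(params)
  xall <- do.call(rbind, lapply(dat$subjects, `[[`, "x"))
  level <- colMeans(xall %*% as.matrix(params$beta))
  ord <- order(level, decreasing = TRUE)
  params$pi <- params$pi[ord]
  params$beta <- as.matrix(params$beta)[, ord, drop = FALSE]
  w <- params$w[ord]
  params$B <- w[k]^2 * params$B
  params$w <- w / w[k]
  params
}

finalize_fit <- function(dat, spec, blocks, params, loglik, best, n_starts) {
  ld <- class_logdens(dat, params, blocks)
  lp <- ld + rep(log(params$pi), each = dat$n)
  li <- log_sum_exp(lp)
  post <- exp(lp - li)
  rownames(post) <- dat$ids
  colnames(post) <- paste0("class", seq_len(spec$n_classes))
  asg <- assign_and_summarize(post)
  npar <- count_params(spec, dat$p, dat$q)
  structure(
    list(
      spec = spec,
      params = params,
      loglik = sum(li),
      loglik_trace = best$trace,
      n_params = npar,
      AIC = -2 * sum(li) + 2 * npar,
      BIC = -2 * sum(li) + npar * log(dat$n),
      posterior = post,
      modal_class = asg$modal_class,
      mean_posterior_by_class = asg$mean_posterior_by_class,
      class_shares = asg$class_shares,
      n_ties = asg$n_ties,
      degenerate_class = any(colSums(post) < 1),
      converged = best$converged,
      n_starts_used = n_starts,
      n_subjects = dat$n,
      n_obs = dat$n_obs,
      knots = dat$knots,
      boundary = dat$boundary,
      t_center = dat$t_center
    ),
    class = "lcmm_fit"
  )
}

#' Posterior class-membership probabilities
#'
#' Row i, class g is `pi_g * phi_ig / sum_l pi_l * phi_il` where `phi_ig` is
#' the marginal Gaussian density of subject i's trajectory under class g.
#' Rows sum to 1.
#'
#' @param fit An `lcmm_fit`.
#' @param data Optional TTL tibble to score; defaults to the training data's
#'   stored posterior.
#' @return An n x K matrix of posterior probabilities.
#' @export
posterior_probs <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "lcmm_fit"))
  if (is.null(data)) return(fit$posterior)
  dat <- build_lcmm_data(data, fit$spec)
  ld <- class_logdens(dat, fit$params)
  lp <- ld + rep(log(fit$params$pi), each = dat$n)
  post <- exp(lp - log_sum_exp(lp))
  rownames(post) <- dat$ids
  colnames(post) <- paste0("class", seq_len(fit$spec$n_classes))
  post
}

#' Modal class assignment and per-class posterior summary
#'
#' Assigns each subject to its highest-posterior class (ties broken toward
#' the lowest class index and counted), and summarizes the classification:
#' the mean posterior probability of the assigned class among its members
#' (the paper-style "mean probability of belonging to the assigned group")
#' and the share of subjects per class.
#'
#' @param posterior An n x K matrix of posterior probabilities (rows sum
#'   to 1).
#' @return A list with `modal_class` (integer per subject),
#'   `mean_posterior_by_class` (length K, `NA` for empty classes),
#'   `class_shares` (length K, sums to 1) and `n_ties`.
#' @export
assign_and_summarize <- function(posterior) {
  posterior <- as.matrix(posterior)
  if (any(abs(rowSums(posterior) - 1) > 1e-6)) {
    abort("posterior rows must sum to 1")
  }
  k <- ncol(posterior)
  modal <- max.col(posterior, ties.method = "first")
  row_max <- posterior[cbind(seq_len(nrow(posterior)), modal)]
  n_ties <- sum(rowSums(posterior == row_max) > 1)
  shares <- tabulate(modal, k) / nrow(posterior)
  mean_post <- vapply(seq_len(k), function(g) {
    if (any(modal == g)) mean(posterior[modal == g, g]) else NA_real_
  }, numeric(1))
  list(modal_class = modal, mean_posterior_by_class = mean_post,
       class_shares = shares, n_ties = n_ties)
}

#' Observed class-specific mean trajectories weighted by membership
#'
#' For each class and week, the weighted mean of the observed TTL values with
#' the posterior class-membership probabilities as weights:
#' `mean_g(t) = sum_i p_ig y_it / sum_i p_ig` over subjects observed at week
#' t. With hard (0/1) posteriors this reduces to ordinary per-group means.
#'
#' @param data TTL tibble.
#' @param posterior Posterior matrix with rownames `swimmer_id:season_label`
#'   (as produced by [fit_lcmm()]).
#' @return A tibble with `class`, `week_before_bp`, `mean_ttl`,
#'   `n_effective` (sum of weights; weeks with zero total weight are `NA`).
#' @export
weighted_class_means <- function(data, posterior) {
  posterior <- as.matrix(posterior)
  ids <- rownames(posterior)
  if (is.null(ids)) abort("posterior needs rownames identifying the seasons")
  df <- data |>
    dplyr::mutate(.id = season_key(.data$swimmer_id, .data$season_label))
  if (!all(df$.id %in% ids)) abort("data contains seasons not in posterior")
  k <- ncol(posterior)
  purrr::map_dfr(seq_len(k), function(g) {
    df |>
      dplyr::mutate(.w = posterior[match(.data$.id, ids), g]) |>
      dplyr::group_by(week_before_bp = .data$week_before_bp) |>
      dplyr::summarise(
        mean_ttl = ifelse(sum(.data$.w) > 0,
                          sum(.data$.w * .data$ttl) / sum(.data$.w),
                          NA_real_),
        n_effective = sum(.data$.w),
        .groups = "drop"
      ) |>
      dplyr::mutate(class = g, .before = 1)
  })
}
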