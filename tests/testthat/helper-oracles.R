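# Shared helpers: independent oracles and small fixture builders.

# All permutations of 1..k (k small).
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v)) {
      for (p in rec(v[-i])) res[[length(res) + 1]] <- c(v[i], p)
    }
    res
  }
  rec(seq_len(k))
}

# Best classification agreement over label permutations.
aligned_accuracy <- function(modal, truth, k) {
  best <- 0
  for (p in all_perms(k)) best <- max(best, mean(p[modal] == truth))
  best
}

# Best-aligned permutation (mapping fitted label -> true label).
best_alignment <- function(modal, truth, k) {
  best <- NULL
  best_acc <- -1
  for (p in all_perms(k)) {
    acc <- mean(p[modal] == truth)
    if (acc > best_acc) {
      best_acc <- acc
      best <- p
    }
  }
  best
}

# Random TTL tibble: n subjects at the given weeks, values iid around a line.
random_ttl <- function(n_subjects, weeks = 1:5, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(
    swimmer_id = sprintf("s%03d", seq_len(n_subjects)),
    season_label = "a",
    week_before_bp = weeks
  ) |>
    dplyr::mutate(ttl = 50 + 0.5 * week_before_bp +
                    rnorm(dplyr::n(), 0, 8))
}

# Brute-force mixture log-likelihood for a random-intercept model by
# adaptive quadrature over the random effect, one subject at a time.
quadrature_loglik <- function(ttl, spec, params) {
  df <- ttl |>
    dplyr::mutate(.id = paste(swimmer_id, season_label, sep = ":")) |>
    dplyr::arrange(.id, week_before_bp)
  basis <- swimperiod::spline_basis(df$week_before_bp, spec$n_interior_knots)
  k <- length(params$pi)
  total <- 0
  for (id in unique(df$.id)) {
    rows <- which(df$.id == id)
    y <- df$ttl[rows]
    x <- basis[rows, , drop = FALSE]
    li <- 0
    for (g in seq_len(k)) {
      tau <- params$w[g] * sqrt(params$B[1, 1])
      mu <- as.vector(x %*% as.matrix(params$beta)[, g])
      if (tau < 1e-12) {
        dens <- prod(dnorm(y, mu, params$sigma))
      } else {
        f <- function(b) {
          vapply(b, function(bb) {
            prod(dnorm(y, mu + bb, params$sigma)) * dnorm(bb, 0, tau)
          }, numeric(1))
        }
        dens <- integrate(f, -10 * tau, 10 * tau, rel.tol = 1e-12,
                          abs.tol = 0)$value
      }
      li <- li + params$pi[g] * dens
    }
    total <- total + log(li)
  }
  total
}

# Small training table for one season, constant weeks.
constant_season <- function(i1 = 20000, i2 = 10000, i3 = 2000, i4 = 800,
                            i5 = 200, gc = 100, st = 50, n_weeks = 25,
                            swimmer_id = "s1", season_label = "a") {
  tibble::tibble(
    swimmer_id = swimmer_id, season_label = season_label,
    week_before_bp = seq_len(n_weeks),
    i1_m = i1, i2_m = i2, i3_m = i3, i4_m = i4, i5_m = i5,
    gc_min = gc, st_min = st
  )
}

# Random nonnegative training table (several seasons).
random_training <- function(n_seasons = 3, n_weeks = 25, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_seasons), function(i) {
    tibble::tibble(
      swimmer_id = sprintf("s%03d", i), season_label = "a",
      week_before_bp = seq_len(n_weeks),
      i1_m = runif(n_weeks, 0, 30000),
      i2_m = runif(n_weeks, 0, 20000),
      i3_m = runif(n_weeks, 0, 5000),
      i4_m = runif(n_weeks, 0, 2000),
      i5_m = runif(n_weeks, 0, 500),
      gc_min = runif(n_weeks, 0, 200),
      st_min = runif(n_weeks, 0, 100)
    )
  })
}

# Random compositions (rows sum to 1, strictly positive).
random_compositions <- function(n, d, seed = 1) {
  set.seed(seed)
  x <- matrix(rgamma(n * d, shape = 2), n, d)
  x / rowSums(x)
}

# Random orthogonal (D-1)x(D-1) matrix (for ilr basis rotation).
random_rotation <- function(m, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(m * m), m, m)))
}
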