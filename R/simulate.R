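#' Archetype TTL mean curves
#'
#' Smooth 25-week mean Total Training Load curves for the three canonical
#' sprint periodization profiles, as natural cubic spline interpolants through
#' hand-chosen control points (these are qualitative fixtures, not measured
#' data):
#' * `"long"` -- two macrocycles with load peaks about 21 and 5 weeks before
#'   the season-best performance and a progressive load increase into the
#'   second macrocycle;
#' * `"balanced"` -- two balanced macrocycles peaking about 19 and 10 weeks
#'   out, with a load decrease toward the competition (degressivity) and high
#'   week-to-week swing;
#' * `"stable_flat"` -- a single flat macrocycle near 60% TTL with one mild
#'   peak about 8 weeks out and low variability.
#'
#' @param name One of `"long"`, `"balanced"`, `"stable_flat"`.
#' @param weeks Integer vector of `week_before_bp` values at which to evaluate
#'   (1 = final week before the performance). For horizons other than 25
#'   weeks the control points are rescaled proportionally.
#' @param n_weeks Length of the horizon the weeks refer to (default 25).
#' @return Numeric vector of mean TTL values (percent) at `weeks`.
#' @examples
#' archetype_curve("long", 25:1)
#' @export
archetype_curve <- function(name, weeks, n_weeks = 25) {
  ctrl <- switch(name,
    long = list(
      x = c(25, 23, 21, 18, 15, 13, 10, 8, 5, 3, 1),
      y = c(45, 60, 72, 60, 48, 50, 62, 70, 78, 60, 40)
    ),
    balanced = list(
      x = c(25, 22, 19, 16, 13, 10, 8, 5, 3, 1),
      y = c(48, 66, 76, 56, 42, 68, 56, 48, 42, 32)
    ),
    stable_flat = list(
      x = c(25, 20, 15, 12, 8, 5, 3, 1),
      y = c(58, 60, 59, 60, 64, 60, 56, 50)
    ),
    abort(paste0("unknown archetype '", name, "'"))
  )
  x <- 1 + (ctrl$x - 1) * (n_weeks - 1) / 24
  stats::spline(x, ctrl$y, xout = weeks, method = "natural")$y
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model of [simulate_cohort()]: K latent classes with
#' smooth class-specific mean TTL curves, a subject-level random intercept
#' (optionally a random linear slope), Gaussian residual noise,
#' class-dependent relative-performance distributions and target intensity
#' compositions. Defaults reproduce the sprint study conditions: three
#' classes (long / balanced / stable-flat) with proportions 0.53 / 0.24 /
#' 0.23, relative performance means 6.0 / 6.8 / 7.4% (SDs 3.1 / 3.5 / 2.9%),
#' and an in-water intensity split of 88% / 8% / 4% (MHI / SI / EI).
#'
#' @param n_seasons Number of swimmer-seasons to generate.
#' @param n_weeks Weeks per season (>= 4; default 25).
#' @param class_proportions Probability vector of length K (sums to 1).
#' @param class_curves Length-K list (or character vector) of class mean
#'   curves: an archetype name (see [archetype_curve()]), a single number
#'   (flat curve), a numeric vector of length `n_weeks` (values at
#'   `week_before_bp` = 1..n_weeks), or a function of `week_before_bp`.
#' @param random_effect_sd SD of the subject-level random intercept (TTL %).
#' @param random_slope_sd SD of an optional subject-level linear slope per
#'   week (default 0 = intercept-only).
#' @param residual_sd SD of the week-level Gaussian noise (TTL %).
#' @param composition_targets List with `in_water` (MHI, SI, EI; sums to 1)
#'   and `dryland` (GC, ST; sums to 1) mean proportion targets.
#' @param performance_means,performance_sds Per-class mean and SD of relative
#'   performance Pr (%).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_seasons = 105,
                       n_weeks = 25,
                       class_proportions = c(0.53, 0.24, 0.23),
                       class_curves = c("long", "balanced", "stable_flat"),
                       random_effect_sd = 6,
                       random_slope_sd = 0,
                       residual_sd = 4,
                       composition_targets = list(
                         in_water = c(mhi = 0.88, si = 0.08, ei = 0.04),
                         dryland = c(gc = 0.65, st = 0.35)
                       ),
                       performance_means = c(6.0, 6.8, 7.4),
                       performance_sds = c(3.1, 3.5, 2.9),
                       seed = 1) {
  k <- length(class_proportions)
  if (abs(sum(class_proportions) - 1) > 1e-12 || any(class_proportions <= 0)) {
    abort("class_proportions must be strictly positive and sum to 1")
  }
  if (n_weeks < 4) abort("n_weeks must be at least 4")
  if (length(class_curves) != k) {
    abort("class_curves must have one entry per class")
  }
  if (abs(sum(composition_targets$in_water) - 1) > 1e-12) {
    abort("in-water composition targets must sum to 1")
  }
  if (abs(sum(composition_targets$dryland) - 1) > 1e-12) {
    abort("dryland composition targets must sum to 1")
  }
  if (length(performance_means) != k || length(performance_sds) != k) {
    abort("performance_means and performance_sds must have one entry per class")
  }
  if (random_effect_sd < 0 || residual_sd < 0 || random_slope_sd < 0) {
    abort("SDs must be nonnegative")
  }
  structure(
    list(
      n_seasons = as.integer(n_seasons), n_weeks = as.integer(n_weeks),
      class_proportions = class_proportions,
      class_curves = as.list(class_curves),
      random_effect_sd = random_effect_sd,
      random_slope_sd = random_slope_sd,
      residual_sd = residual_sd,
      composition_targets = composition_targets,
      performance_means = performance_means,
      performance_sds = performance_sds,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Evaluate the class mean curves at week_before_bp = 1..n_weeks.
class_mean_matrix <- function(config) {
  weeks <- seq_len(config$n_weeks)
  vapply(config$class_curves, function(cc) {
    if (is.character(cc)) {
      archetype_curve(cc, weeks, config$n_weeks)
    } else if (is.function(cc)) {
      vapply(weeks, cc, numeric(1))
    } else if (is.numeric(cc) && length(cc) == 1) {
      rep(cc, config$n_weeks)
    } else if (is.numeric(cc) && length(cc) == config$n_weeks) {
      as.numeric(cc)
    } else {
      abort("class curve must be a name, number, vector or function")
    }
  }, numeric(config$n_weeks))
}

# Class-specific maximum weekly volumes (meters or minutes) implied by the
# composition targets; the in-water total max is 50 km/week, dryland 200 min.
component_maxima <- function(config) {
  c(config$composition_targets$in_water * 50000,
    config$composition_targets$dryland * 200)
}

#' Simulate a cohort of swimmer-seasons with known latent classes
#'
#' Draws each season's latent class from `class_proportions`, builds the
#' latent weekly TTL as the class mean curve plus a subject random intercept
#' (and optional random slope) plus Gaussian noise, truncates it to
#' \[0, 100\] by clipping, and back-computes weekly volumes per component so
#' that re-running [compute_ttl()] on the generated training log reproduces
#' the latent TTL exactly (up to clipping): each component's normalized
#' series is anchored at exactly 100% in one of the five highest-load weeks,
#' with the remaining components compensated in that week so the weekly mean
#' is unchanged. Relative performance is drawn per class.
#'
#' @param config A [sim_config()].
#' @return An object of class `swim_cohort`: a list with
#' \describe{
#'   \item{training}{weekly training log tibble (the [aggregate_intensities()]
#'     input schema).}
#'   \item{seasons}{per-season covariates, `performance_s`, `m10wp_s`, `pr`.}
#'   \item{truth}{tibble `swimmer_id`, `season_label`, `true_class`.}
#'   \item{latent}{tibble of the latent weekly TTL before back-computation.}
#'   \item{config}{the generating configuration.}
#'   \item{n_clipped}{count of latent values clipped to \[0, 100\], plus
#'     component values clipped during back-computation.}
#' }
#' @examples
#' coh <- simulate_cohort(sim_config(n_seasons = 5, seed = 42))
#' dplyr::count(coh$truth, true_class)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$class_proportions)
  mu <- class_mean_matrix(config)
  maxima <- component_maxima(config)
  nw <- config$n_weeks
  weeks <- seq_len(nw)

  withr_seed(config$seed, {
    true_class <- sample.int(k, config$n_seasons, replace = TRUE,
                             prob = config$class_proportions)
    b <- rnorm(config$n_seasons, 0, config$random_effect_sd)
    u <- rnorm(config$n_seasons, 0, config$random_slope_sd)
    n_clipped <- 0L
    training <- vector("list", config$n_seasons)
    latent <- vector("list", config$n_seasons)
    for (i in seq_len(config$n_seasons)) {
      g <- true_class[i]
      eps <- rnorm(nw, 0, config$residual_sd)
      lat <- mu[, g] + b[i] + u[i] * (weeks - (nw + 1) / 2) + eps
      n_clipped <- n_clipped + sum(lat < 0 | lat > 100)
      lat <- pmin(100, pmax(0, lat))
      comp <- back_compute_components(lat)
      n_clipped <- n_clipped + comp$n_clipped
      cn <- comp$norm # n_weeks x 5, columns MHI SI EI GC ST (percent)
      raw <- sweep(cn / 100, 2, maxima, `*`)
      sid <- sprintf("sw%04d", i)
      training[[i]] <- tibble::tibble(
        swimmer_id = sid, season_label = "s1", week_before_bp = weeks,
        i1_m = raw[, 1] * 0.47, i2_m = raw[, 1] * 0.53,
        i3_m = raw[, 2],
        i4_m = raw[, 3] * 0.8, i5_m = raw[, 3] * 0.2,
        gc_min = raw[, 4], st_min = raw[, 5]
      )
      latent[[i]] <- tibble::tibble(
        swimmer_id = sid, season_label = "s1", week_before_bp = weeks,
        ttl_latent = lat
      )
    }
    pr <- rnorm(config$n_seasons,
                config$performance_means[true_class],
                config$performance_sds[true_class])
    m10wp <- 48.0
    seasons <- tibble::tibble(
      swimmer_id = sprintf("sw%04d", seq_len(config$n_seasons)),
      season_label = "s1",
      sex = sample(c("F", "M"), config$n_seasons, replace = TRUE),
      age = round(rnorm(config$n_seasons, 20.5, 3), 1),
      stroke = sample(c("freestyle", "breaststroke", "butterfly", "backstroke"),
                      config$n_seasons, replace = TRUE,
                      prob = c(0.43, 0.26, 0.17, 0.14)),
      distance_class = "sprint",
      quarter = sample(c("2nd", "3rd"), config$n_seasons, replace = TRUE),
      season_in_study = sample(1:4, config$n_seasons, replace = TRUE),
      season_in_quadrennial = sample(
        c("post_olympic", "world_championship", "pre_olympic", "olympic"),
        config$n_seasons, replace = TRUE),
      quadrennial = sample(
        c("1992-1996", "1996-2000", "2000-2004", "2004-2008", "2008-2012"),
        config$n_seasons, replace = TRUE),
      pr = pr,
      m10wp_s = m10wp,
      performance_s = m10wp * (1 + pr / 100)
    )
  })

  structure(
    list(
      training = dplyr::bind_rows(training),
      seasons = seasons,
      truth = tibble::tibble(
        swimmer_id = sprintf("sw%04d", seq_len(config$n_seasons)),
        season_label = "s1",
        true_class = true_class
      ),
      latent = dplyr::bind_rows(latent),
      config = config,
      n_clipped = n_clipped
    ),
    class = "swim_cohort"
  )
}

# Decompose a latent weekly TTL series into 5 normalized component series
# (columns MHI, SI, EI, GC, ST in percent) whose weekly mean equals the
# latent TTL and whose per-component maximum is exactly 100, so that
# max-normalization reproduces the latent TTL. Each component is anchored at
# 100 in one of the five highest-TTL weeks; the other four components are
# compensated in that week. Small mean-zero jitter differentiates the
# components elsewhere.
back_compute_components <- function(lat, jitter_sd = 2) {
  nw <- length(lat)
  anchors <- order(lat, decreasing = TRUE)[seq_len(min(5, nw))]
  jit <- matrix(rnorm(nw * 5, 0, jitter_sd), nw, 5)
  jit <- jit - rowMeans(jit)
  cn <- matrix(lat, nw, 5) + jit
  for (j in seq_along(anchors)) {
    t_j <- anchors[j]
    cn[t_j, ] <- (5 * lat[t_j] - 100) / 4
    cn[t_j, j] <- 100
  }
  n_clipped <- sum(cn < 0 | cn > 100)
  cn <- pmin(pmax(cn, 0), 100)
  # guard: the anchor must remain the maximum of its column
  for (j in seq_along(anchors)) cn[anchors[j], j] <- 100
  colnames(cn) <- c("mhi", "si", "ei", "gc", "st")
  list(norm = cn, n_clipped = n_clipped)
}

#' @export
print.swim_cohort <- function(x, ...) {
  cat("Synthetic swim cohort: ", x$config$n_seasons, " seasons x ",
      x$config$n_weeks, " weeks, K = ",
      length(x$config$class_proportions), " classes\n", sep = "")
  print(dplyr::count(x$truth, .data$true_class))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Writes the training log, the season-level table and the ground-truth class
#' labels in the same CSV dialects consumed by [read_training_csv()] and
#' friends.
#'
#' @param cohort A `swim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "swim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    training = file.path(dir, "training.csv"),
    seasons = file.path(dir, "seasons.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(cohort$training, paths["training"])
  readr::write_csv(cohort$seasons, paths["seasons"])
  readr::write_csv(cohort$truth, paths["truth"])
  invisible(paths)
}
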