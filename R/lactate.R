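#' Fit a lactate-speed profile from an incremental swim test
#'
#' Each season's intensity zones are anchored on an incremental test
#' (typically 6 x 200 m at increasing speeds, blood lactate sampled after each
#' stage). The lactate-speed relationship is modeled as piecewise log-linear:
#' log(lactate) is interpolated linearly in speed between consecutive stages,
#' which is monotone wherever the data are, assumption-light and exact at the
#' observed stages. The zone threshold speeds `v2`, `v4`, `v6` are where the
#' interpolant crosses 2, 4 and 6 mmol/L. Crossings outside the observed
#' speed range use log-linear extrapolation of the terminal segment, flagged;
#' upward extrapolation is capped at twice the last segment's speed range,
#' beyond which the threshold is reported missing (`NA`).
#'
#' @param stages A data frame with columns `speed_ms` (strictly increasing)
#'   and `lactate_mmol` (> 0), one row per test stage; at least 3 stages.
#' @return An object of class `lactate_profile`: a list with `stages`, the
#'   threshold speeds `v2`, `v4`, `v6` (m/s, `NA` when unreachable), and
#'   `extrapolated`, a logical vector flagging thresholds obtained outside
#'   the observed range.
#' @examples
#' st <- tibble::tibble(speed_ms = c(1.3, 1.4, 1.45), lactate_mmol = c(2, 4, 6))
#' fit_lactate_profile(st)
#' @export
fit_lactate_profile <- function(stages) {
  if (!all(c("speed_ms", "lactate_mmol") %in% names(stages))) {
    abort("`stages` needs columns speed_ms and lactate_mmol")
  }
  s <- stages$speed_ms
  la <- stages$lactate_mmol
  if (length(s) < 3) abort("at least 3 test stages are required")
  if (any(diff(s) <= 0)) abort("stage speeds must be strictly increasing")
  if (any(la <= 0)) abort("lactate values must be positive")
  th <- vapply(c(2, 4, 6), function(L) threshold_speed(s, la, L),
               c(speed = 0, extrapolated = 0))
  structure(
    list(
      stages = tibble::as_tibble(stages[c("speed_ms", "lactate_mmol")]),
      v2 = unname(th["speed", 1]), v4 = unname(th["speed", 2]),
      v6 = unname(th["speed", 3]),
      extrapolated = setNames(th["extrapolated", ] > 0, c("v2", "v4", "v6"))
    ),
    class = "lactate_profile"
  )
}

# First upward crossing of lactate level L by the piecewise log-linear
# interpolant; log-linear extrapolation from the terminal segments outside
# the observed range, capped above at 2x the last segment's speed range.
threshold_speed <- function(s, la, L) {
  n <- length(s)
  lla <- log(la)
  lL <- log(L)
  hit <- which(la == L)
  if (length(hit) > 0) return(c(speed = s[hit[1]], extrapolated = 0))
  for (i in seq_len(n - 1)) {
    if ((la[i] - L) * (la[i + 1] - L) < 0 && la[i] != la[i + 1]) {
      v <- s[i] + (s[i + 1] - s[i]) * (lL - lla[i]) / (lla[i + 1] - lla[i])
      return(c(speed = v, extrapolated = 0))
    }
  }
  if (L < min(la)) {
    slope <- (lla[2] - lla[1]) / (s[2] - s[1])
    if (slope <= 0) return(c(speed = NA_real_, extrapolated = 1))
    return(c(speed = s[1] + (lL - lla[1]) / slope, extrapolated = 1))
  }
  slope <- (lla[n] - lla[n - 1]) / (s[n] - s[n - 1])
  if (slope <= 0) return(c(speed = NA_real_, extrapolated = 1))
  v <- s[n] + (lL - lla[n]) / slope
  if (v > s[n] + 2 * (s[n] - s[n - 1])) {
    return(c(speed = NA_real_, extrapolated = 1))
  }
  c(speed = v, extrapolated = 1)
}

#' @export
print.lactate_profile <- function(x, ...) {
  cat("Lactate-speed profile (", nrow(x$stages), " stages)\n", sep = "")
  cat(sprintf("  v2 = %.4f  v4 = %.4f  v6 = %.4f m/s\n", x$v2, x$v4, x$v6))
  if (any(x$extrapolated, na.rm = TRUE)) {
    cat("  extrapolated:", paste(names(which(x$extrapolated)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Classify a swimming speed into an intensity level
#'
#' Assigns I1..I5 from the zone threshold speeds of a [fit_lactate_profile()]
#' fit: I1 below `v2` (blood lactate < 2 mmol/L), I2 from `v2` up to and
#' including `v4` (2 to 4 mmol/L), I3 above `v4` up to and including `v6`
#' (>4--6 mmol/L), I4 above `v6` (>6 mmol/L), and I5 for maximal sprint
#' efforts regardless of speed. Zone boundaries are closed on the upper end
#' of I2 and I3 (a speed exactly at `v4` is I2, exactly at `v6` is I3).
#'
#' An optional correction table shifts the measured speed for the set's
#' distance and rest interval before classification (longer rests and shorter
#' distances permit faster speeds at the same metabolic intensity); by
#' default no correction is applied.
#'
#' @param speed Swimming speed(s), m/s.
#' @param profile A `lactate_profile`.
#' @param is_max_sprint Logical (recycled): maximal sprint effort, always I5.
#' @param correction Optional data frame with columns `distance_m`, `rest_s`,
#'   `delta_speed` (m/s, subtracted from `speed`), matched exactly on
#'   `distance_m` and `rest_s`; or a function `f(distance_m, rest_s)`
#'   returning the offset.
#' @param distance_m,rest_s Set distance and rest interval, used only when
#'   `correction` is supplied.
#' @return Character vector of levels `"I1"`..`"I5"`.
#' @export
classify_speed <- function(speed, profile, is_max_sprint = FALSE,
                           correction = NULL, distance_m = NULL,
                           rest_s = NULL) {
  stopifnot(inherits(profile, "lactate_profile"))
  if (any(is.na(c(profile$v2, profile$v4, profile$v6)))) {
    abort("profile has missing thresholds; cannot classify")
  }
  if (!(profile$v2 <= profile$v4 && profile$v4 <= profile$v6)) {
    abort("profile thresholds must satisfy v2 <= v4 <= v6")
  }
  if (!is.null(correction)) {
    if (is.function(correction)) {
      speed <- speed - correction(distance_m, rest_s)
    } else {
      idx <- match(
        paste(distance_m, rest_s),
        paste(correction$distance_m, correction$rest_s)
      )
      if (anyNA(idx)) abort("no correction entry for given distance/rest")
      speed <- speed - correction$delta_speed[idx]
    }
  }
  n <- max(length(speed), length(is_max_sprint))
  speed <- rep_len(speed, n)
  is_max_sprint <- rep_len(is_max_sprint, n)
  out <- dplyr::case_when(
    is_max_sprint ~ "I5",
    speed < profile$v2 ~ "I1",
    speed <= profile$v4 ~ "I2",
    speed <= profile$v6 ~ "I3",
    TRUE ~ "I4"
  )
  out
}

#' Simulate an incremental lactate test
#'
#' Generates stage (speed, lactate) pairs from a monotone piecewise
#' exponential lactate-speed curve passing exactly through the three zone
#' thresholds (2, 4, 6 mmol/L at the given speeds), with log-linear
#' extrapolation beyond them. Stage speeds always include the three threshold
#' speeds; extra stages are placed below `v2` (warm-up stages) and one above
#' `v6` (the maximal effort). Seeded Gaussian noise is added to the lactate
#' readings and floored at 0.5 mmol/L.
#'
#' @param true_thresholds Numeric length-3 vector: speeds (m/s) at 2, 4 and
#'   6 mmol/L, strictly increasing.
#' @param n_stages Number of stages (>= 3), default 6.
#' @param noise_sd SD of measurement noise on lactate, mmol/L.
#' @param seed Integer seed.
#' @return A tibble with columns `stage`, `speed_ms`, `lactate_mmol`.
#' @examples
#' st <- simulate_lactate_test(c(1.30, 1.40, 1.45), noise_sd = 0, seed = 1)
#' fit_lactate_profile(st) # recovers the thresholds
#' @export
simulate_lactate_test <- function(true_thresholds, n_stages = 6,
                                  noise_sd = 0, seed = 1) {
  v <- as.numeric(true_thresholds)
  if (length(v) != 3 || any(diff(v) <= 0)) {
    abort("true_thresholds must be 3 strictly increasing speeds")
  }
  if (n_stages < 3) abort("n_stages must be at least 3")
  n_below <- max(0L, n_stages - 4L)
  n_above <- if (n_stages >= 4) 1L else 0L
  d1 <- v[2] - v[1]
  speeds <- c(
    if (n_below > 0) v[1] - d1 * rev(seq_len(n_below)) / 2,
    v,
    if (n_above > 0) v[3] + 0.5 * (v[3] - v[2])
  )
  lla <- ifelse(
    speeds <= v[2],
    log(2) + (speeds - v[1]) * (log(4) - log(2)) / (v[2] - v[1]),
    log(4) + (speeds - v[2]) * (log(6) - log(4)) / (v[3] - v[2])
  )
  lactate <- exp(lla)
  if (noise_sd > 0) {
    withr_seed(seed, {
      lactate <- pmax(0.5, lactate + rnorm(length(lactate), 0, noise_sd))
    })
  }
  tibble::tibble(
    stage = seq_along(speeds),
    speed_ms = speeds,
    lactate_mmol = lactate
  )
}

# Evaluate an expression with a temporary RNG seed, restoring prior state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
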