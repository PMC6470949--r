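#' Aggregate weekly intensity-zone volumes into the five training components
#'
#' Collapses the five in-water intensity zones I1--I5 into the three
#' lactate-anchored categories used throughout the analysis -- moderate-to-heavy
#' intensity (MHI = I1 + I2, blood lactate <= 4 mmol/L), severe intensity
#' (SI = I3, >4--6 mmol/L) and extreme intensity (EI = I4 + I5, >6 mmol/L plus
#' maximal sprinting) -- and carries the two dryland components through
#' (general conditioning GC and maximal strength training ST, minutes/week).
#'
#' @param training A data frame of weekly training logs with columns
#'   `swimmer_id`, `season_label`, `week_before_bp`, `i1_m` .. `i5_m`
#'   (meters/week), `gc_min`, `st_min` (minutes/week).
#' @return A tibble with one row per swimmer-season-week and columns
#'   `swimmer_id`, `season_label`, `week_before_bp`, `mhi_m`, `si_m`, `ei_m`,
#'   `gc_min`, `st_min`.
#' @examples
#' wk <- tibble::tibble(
#'   swimmer_id = "s1", season_label = "2010", week_before_bp = 1,
#'   i1_m = 20000, i2_m = 10000, i3_m = 2000, i4_m = 800, i5_m = 200,
#'   gc_min = 100, st_min = 50
#' )
#' aggregate_intensities(wk)
#' @export
aggregate_intensities <- function(training) {
  validate_training(training)
  training |>
    dplyr::transmute(
      .data$swimmer_id, .data$season_label, .data$week_before_bp,
      mhi_m = .data$i1_m + .data$i2_m,
      si_m = .data$i3_m,
      ei_m = .data$i4_m + .data$i5_m,
      gc_min = .data$gc_min,
      st_min = .data$st_min
    ) |>
    tibble::as_tibble()
}

training_cols <- c(
  "swimmer_id", "season_label", "week_before_bp",
  "i1_m", "i2_m", "i3_m", "i4_m", "i5_m", "gc_min", "st_min"
)

validate_training <- function(training) {
  missing_cols <- setdiff(training_cols, names(training))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`training` is missing required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  vol <- c("i1_m", "i2_m", "i3_m", "i4_m", "i5_m", "gc_min", "st_min")
  for (v in vol) {
    bad <- which(training[[v]] < 0)
    if (length(bad) > 0) {
      abort(paste0("negative volume in column ", v, " at row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  dup <- training |>
    dplyr::count(.data$swimmer_id, .data$season_label, .data$week_before_bp) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated week_before_bp within season(s): ",
                 paste(season_key(dup$swimmer_id, dup$season_label),
                       collapse = ", ")))
  }
  invisible(training)
}

#' Relative performance with respect to the world's best
#'
#' Expresses a season-best time as its percentage gap to the mean of the 10
#' best world performance times (M10WP) for the same year, sex, stroke and
#' distance: `Pr = 100 * (P - M10WP) / M10WP`. Lower is better; 0 means the
#' swimmer matched the world's-best mean. This normalization absorbs
#' year-to-year changes in competition conditions (e.g. swimsuit eras).
#'
#' @param performance_s Season-best performance time(s) in seconds.
#' @param m10wp_s Mean of the 10 best world performance times in seconds.
#' @return Numeric vector of relative performances, in percent.
#' @examples
#' relative_performance(52.5, 50) # 5
#' relative_performance(49, 50)   # -2
#' @export
relative_performance <- function(performance_s, m10wp_s) {
  if (any(performance_s <= 0) || any(m10wp_s <= 0)) {
    abort("performance_s and m10wp_s must be strictly positive")
  }
  100 * (performance_s - m10wp_s) / m10wp_s
}

#' Normalize weekly training components to each season's maximum
#'
#' For each swimmer-season and each training component, weekly volumes are
#' rescaled to a percentage of the maximum weekly volume of that component
#' within the season, so every non-zero component reaches exactly 100% in at
#' least one week. This puts loads of different units (meters, minutes) and of
#' swimmers of different capacities on a common 0--100% scale.
#'
#' @param training Weekly training logs (see [aggregate_intensities()]).
#' @param mode `"five_category"` (default) normalizes the MHI/SI/EI/GC/ST
#'   aggregates; `"seven_component"` normalizes I1..I5 and GC/ST separately.
#' @return A long tibble with columns `swimmer_id`, `season_label`,
#'   `week_before_bp`, `component`, `raw`, `norm` (0--100). Components whose
#'   season maximum is 0 get `norm = 0` everywhere and are listed in the
#'   `"zero_components"` attribute.
#' @seealso [compute_ttl()]
#' @export
normalize_components <- function(training,
                                 mode = c("five_category", "seven_component")) {
  mode <- match.arg(mode)
  if (nrow(training) == 0) abort("empty training table")
  comp <- if (mode == "five_category") {
    aggregate_intensities(training) |>
      tidyr::pivot_longer(
        cols = c("mhi_m", "si_m", "ei_m", "gc_min", "st_min"),
        names_to = "component", values_to = "raw"
      )
  } else {
    validate_training(training)
    training |>
      tidyr::pivot_longer(
        cols = c("i1_m", "i2_m", "i3_m", "i4_m", "i5_m", "gc_min", "st_min"),
        names_to = "component", values_to = "raw"
      )
  }
  out <- comp |>
    dplyr::group_by(.data$swimmer_id, .data$season_label, .data$component) |>
    dplyr::mutate(
      season_max = max(.data$raw),
      norm = ifelse(.data$season_max > 0, 100 * .data$raw / .data$season_max, 0)
    ) |>
    dplyr::ungroup()
  zero <- out |>
    dplyr::filter(.data$season_max == 0) |>
    dplyr::distinct(.data$swimmer_id, .data$season_label, .data$component)
  out <- out |> dplyr::select(-"season_max")
  attr(out, "zero_components") <- zero
  out
}

#' Weekly Total Training Load (TTL)
#'
#' The weekly TTL is the arithmetic mean of the season-max-normalized training
#' components ([normalize_components()]), expressed in percent (0--100). It
#' summarizes each week's combined in-water and dryland load relative to the
#' swimmer's own season maxima, and is the outcome clustered by
#' [fit_lcmm()].
#'
#' @inheritParams normalize_components
#' @param absent How to handle a component that is zero for the whole season:
#'   `"drop"` (default) averages over the components actually present;
#'   `"fixed"` always divides by the full component count.
#' @return A tibble with one row per swimmer-season-week: `swimmer_id`,
#'   `season_label`, `week_before_bp`, `ttl` (percent), `n_components`.
#'   Seasons with dropped components are listed in the `"zero_components"`
#'   attribute.
#' @examples
#' tr <- simulate_cohort(sim_config(n_seasons = 2, seed = 1))$training
#' compute_ttl(tr)
#' @export
compute_ttl <- function(training,
                        mode = c("five_category", "seven_component"),
                        absent = c("drop", "fixed")) {
  mode <- match.arg(mode)
  absent <- match.arg(absent)
  norm <- normalize_components(training, mode = mode)
  zero <- attr(norm, "zero_components")
  n_total <- if (mode == "five_category") 5L else 7L
  if (absent == "drop" && nrow(zero) > 0) {
    norm <- norm |>
      dplyr::anti_join(zero,
        by = c("swimmer_id", "season_label", "component"))
  }
  out <- norm |>
    dplyr::group_by(.data$swimmer_id, .data$season_label,
                    .data$week_before_bp) |>
    dplyr::summarise(
      ttl = mean(.data$norm),
      n_components = dplyr::n(),
      .groups = "drop"
    )
  if (absent == "fixed") {
    out$ttl <- out$ttl * out$n_components / n_total
    out$n_components <- n_total
  }
  attr(out, "zero_components") <- zero
  out
}

#' Week-to-week variation in TTL
#'
#' Mean absolute difference in TTL between consecutive weeks, per
#' swimmer-season -- the variability measure used to contrast periodization
#' profiles (e.g. a stable-flat profile shows low variation, a balanced
#' two-macrocycle profile high variation).
#'
#' @param ttl A tibble as returned by [compute_ttl()] (needs `swimmer_id`,
#'   `season_label`, `week_before_bp`, `ttl`).
#' @return A tibble with one row per swimmer-season: `swimmer_id`,
#'   `season_label`, `variation` (mean absolute consecutive-week change, %).
#' @export
weekly_variation <- function(ttl) {
  counts <- ttl |> dplyr::count(.data$swimmer_id, .data$season_label)
  if (any(counts$n < 2)) abort("every season needs at least 2 weeks")
  ttl |>
    dplyr::group_by(.data$swimmer_id, .data$season_label) |>
    dplyr::arrange(.data$week_before_bp, .by_group = TRUE) |>
    dplyr::summarise(
      variation = mean(abs(diff(.data$ttl))),
      .groups = "drop"
    )
}

#' Progressivity of training load across the two halves of the preparation
#'
#' Compares each swimmer-season's mean of a variable over the first half of
#' the 25-week preparation (weeks 25..13 before the season-best performance,
#' 13 weeks, chronologically earlier) against the second half (weeks 12..1,
#' 12 weeks). A positive delta (second minus first) indicates progressivity
#' -- the load grows toward the competition; a negative delta, degressivity.
#'
#' @param data A tibble with `swimmer_id`, `season_label`, `week_before_bp`
#'   and the value column.
#' @param value Column to average (tidy-eval), e.g. `ttl` or `mhi_m`.
#' @param first_weeks,second_weeks Integer vectors of `week_before_bp` values
#'   defining the two halves. Defaults follow the 25-week split.
#' @return A tibble per swimmer-season with `mean_first`, `mean_second`,
#'   `delta`.
#' @export
progressivity <- function(data, value = "ttl",
                          first_weeks = 25:13, second_weeks = 12:1) {
  value <- col_sym(rlang::enquo(value))
  if (length(intersect(first_weeks, second_weeks)) > 0) {
    abort("first_weeks and second_weeks must be disjoint")
  }
  need <- sort(c(first_weeks, second_weeks))
  miss <- data |>
    dplyr::group_by(.data$swimmer_id, .data$season_label) |>
    dplyr::summarise(
      ok = all(need %in% .data$week_before_bp), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(miss) > 0) {
    abort(paste0("season(s) missing required weeks: ",
                 paste(season_key(miss$swimmer_id, miss$season_label),
                       collapse = ", ")))
  }
  data |>
    dplyr::group_by(.data$swimmer_id, .data$season_label) |>
    dplyr::summarise(
      mean_first = mean((!!value)[.data$week_before_bp %in% first_weeks]),
      mean_second = mean((!!value)[.data$week_before_bp %in% second_weeks]),
      .groups = "drop"
    ) |>
    dplyr::mutate(delta = .data$mean_second - .data$mean_first)
}

#' Mean intensity distribution of a swimmer-season as compositional data
#'
#' The in-water block is the season-mean MHI, SI and EI volumes divided by the
#' season-mean total in-water volume; the dryland block is the season-mean GC
#' and ST minutes divided by their total. Each block is a composition summing
#' to 1, suitable for [ilr_transform()] (after zero replacement).
#'
#' @inheritParams aggregate_intensities
#' @return A tibble per swimmer-season with `p_mhi`, `p_si`, `p_ei`
#'   (in-water) and `p_gc`, `p_st` (dryland). A block whose season-mean total
#'   is zero is returned as `NA` and flagged in the `"zero_blocks"` attribute.
#' @export
intensity_composition <- function(training) {
  agg <- aggregate_intensities(training)
  out <- agg |>
    dplyr::group_by(.data$swimmer_id, .data$season_label) |>
    dplyr::summarise(
      dplyr::across(c("mhi_m", "si_m", "ei_m", "gc_min", "st_min"), mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      water_total = .data$mhi_m + .data$si_m + .data$ei_m,
      dry_total = .data$gc_min + .data$st_min,
      p_mhi = ifelse(.data$water_total > 0, .data$mhi_m / .data$water_total, NA_real_),
      p_si = ifelse(.data$water_total > 0, .data$si_m / .data$water_total, NA_real_),
      p_ei = ifelse(.data$water_total > 0, .data$ei_m / .data$water_total, NA_real_),
      p_gc = ifelse(.data$dry_total > 0, .data$gc_min / .data$dry_total, NA_real_),
      p_st = ifelse(.data$dry_total > 0, .data$st_min / .data$dry_total, NA_real_)
    )
  zero <- out |>
    dplyr::filter(.data$water_total == 0 | .data$dry_total == 0) |>
    dplyr::transmute(.data$swimmer_id, .data$season_label,
                     water_zero = .data$water_total == 0,
                     dry_zero = .data$dry_total == 0)
  out <- out |>
    dplyr::select("swimmer_id", "season_label",
                  "p_mhi", "p_si", "p_ei", "p_gc", "p_st")
  attr(out, "zero_blocks") <- zero
  out
}
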