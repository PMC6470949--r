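#' Between-group comparison of a season-level variable
#'
#' Computes both a one-way ANOVA (F) and a Kruskal-Wallis rank-sum test (H)
#' of a numeric variable across profile groups, together with the assumption
#' checks that decide which is marked primary: Shapiro-Wilk normality per
#' group and a Brown-Forsythe test of variance homogeneity (one-way ANOVA of
#' absolute deviations from group medians), both at alpha = 0.05. Both test
#' results are always reported so the choice is transparent. Groups with
#' fewer than 2 observations are excluded with a warning.
#'
#' @param data A data frame.
#' @param value Numeric column to compare (tidy-eval or string).
#' @param group Grouping column (tidy-eval or string).
#' @return A one-row tibble with `variable`, `n_total`, `n_groups`,
#'   `f_statistic`, `f_p`, `kw_statistic`, `kw_p`, `normality_ok`,
#'   `variance_ok`, `primary` (`"anova"` or `"kruskal"`). Per-group n, mean
#'   and SD are in the `"group_summary"` attribute.
#' @export
compare_groups <- function(data, value, group) {
  value <- col_sym(rlang::enquo(value))
  group <- col_sym(rlang::enquo(group))
  df <- tibble::tibble(
    value = dplyr::pull(data, !!value),
    group = as.character(dplyr::pull(data, !!group))
  ) |>
    dplyr::filter(!is.na(.data$value), !is.na(.data$group))
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste("excluding group(s) with < 2 observations:",
               paste(small, collapse = ", ")))
    df <- df |> dplyr::filter(!.data$group %in% small)
  }
  if (length(unique(df$group)) < 2) abort("need at least 2 usable groups")
  g <- factor(df$group)
  x <- df$value
  grand <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  if (ssb < .Machine$double.eps * sum(x^2 + 1)) {
    f_stat <- 0; f_p <- 1
  } else {
    a <- anova(lm(x ~ g))
    f_stat <- a$`F value`[1]; f_p <- a$`Pr(>F)`[1]
  }
  if (length(unique(x)) == 1) {
    kw_stat <- 0; kw_p <- 1
  } else {
    kw <- kruskal.test(x, g)
    kw_stat <- unname(kw$statistic); kw_p <- kw$p.value
  }
  normality_ok <- all(vapply(split(x, g), function(v) {
    if (length(v) < 3 || length(unique(v)) == 1) return(FALSE)
    tryCatch(shapiro.test(v)$p.value > 0.05, error = function(e) FALSE)
  }, logical(1)))
  variance_ok <- tryCatch({
    dev <- abs(x - tapply(x, g, median)[g])
    if (all(dev == dev[1])) TRUE else
      anova(lm(dev ~ g))$`Pr(>F)`[1] > 0.05
  }, error = function(e) FALSE)
  out <- tibble::tibble(
    variable = rlang::as_string(value),
    n_total = nrow(df),
    n_groups = nlevels(g),
    f_statistic = f_stat, f_p = f_p,
    kw_statistic = kw_stat, kw_p = kw_p,
    normality_ok = normality_ok, variance_ok = variance_ok,
    primary = if (normality_ok && variance_ok) "anova" else "kruskal"
  )
  attr(out, "group_summary") <- df |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = sd(.data$value), .groups = "drop")
  out
}

#' Paired first-half / second-half test
#'
#' Tests whether a training variable changed between the first and second
#' halves of the preparation within swimmer-seasons: paired t-test and
#' Wilcoxon signed-rank test on the paired differences, with Shapiro-Wilk on
#' the differences deciding which is primary. Degenerate inputs are handled
#' explicitly: all differences zero gives t = 0, p = 1 and an undefined
#' Wilcoxon (reported missing); constant non-zero differences give an
#' unbounded t statistic, reported as `Inf` with p = 0 and flagged.
#'
#' @param first_half_means,second_half_means Equal-length paired numeric
#'   vectors (n >= 3), e.g. the `mean_first` / `mean_second` columns of
#'   [progressivity()].
#' @return A one-row tibble: `n`, `mean_diff` (second minus first),
#'   `direction` (`"progressivity"`, `"degressivity"`, `"none"`),
#'   `t_statistic`, `t_p`, `wilcoxon_v`, `wilcoxon_p`, `degenerate`,
#'   `primary`, `note`.
#' @export
paired_halves_test <- function(first_half_means, second_half_means) {
  if (length(first_half_means) != length(second_half_means)) {
    abort("paired vectors must have equal length")
  }
  n <- length(first_half_means)
  if (n < 3) abort("need at least 3 pairs")
  d <- second_half_means - first_half_means
  md <- mean(d)
  direction <- if (md > 0) "progressivity" else if (md < 0) "degressivity"
    else "none"
  degenerate <- sd(d) == 0
  note <- NA_character_
  if (degenerate && md == 0) {
    t_stat <- 0; t_p <- 1
    w_v <- NA_real_; w_p <- NA_real_
    note <- "all differences zero; Wilcoxon undefined"
  } else if (degenerate) {
    t_stat <- sign(md) * Inf; t_p <- 0
    w_v <- NA_real_; w_p <- NA_real_
    note <- paste0("all differences identical (",
                   if (md > 0) "all-positive" else "all-negative",
                   "); p below machine floor")
  } else {
    tt <- t.test(second_half_means, first_half_means, paired = TRUE)
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
    wt <- suppressWarnings(
      wilcox.test(second_half_means, first_half_means, paired = TRUE,
                  exact = FALSE)
    )
    w_v <- unname(wt$statistic); w_p <- wt$p.value
  }
  normal_ok <- !degenerate && n >= 3 &&
    tryCatch(shapiro.test(d)$p.value > 0.05, error = function(e) FALSE)
  tibble::tibble(
    n = n, mean_diff = md, direction = direction,
    t_statistic = t_stat, t_p = t_p,
    wilcoxon_v = w_v, wilcoxon_p = w_p,
    degenerate = degenerate,
    primary = if (normal_ok) "t" else "wilcoxon",
    note = note
  )
}

#' MANOVA on ilr-transformed compositions across groups
#'
#' One-way MANOVA of isometric log-ratio coordinates on profile group,
#' reporting Pillai's trace with its standard F approximation. Because the
#' ilr map is an isometry, the Pillai trace is invariant to the particular
#' orthonormal log-ratio basis used. With a single coordinate this reduces
#' exactly to one-way ANOVA (Pillai = SSB / SST).
#'
#' @param ilr Matrix or data frame of ilr coordinates (seasons x D-1).
#' @param groups Group labels, one per row.
#' @return A one-row tibble: `pillai`, `f_statistic`, `df1`, `df2`, `p`.
#' @export
manova_compositions <- function(ilr, groups) {
  y <- as.matrix(ilr)
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) <= ncol(y))) {
    abort("each group needs more observations than ilr coordinates")
  }
  res <- stats::residuals(lm(y ~ g))
  wvar <- apply(as.matrix(res), 2, var)
  if (any(wvar < .Machine$double.eps)) {
    bad <- colnames(y)[which(wvar < .Machine$double.eps)[1]] %||%
      which(wvar < .Machine$double.eps)[1]
    abort(paste0("singular within-group covariance: coordinate ", bad,
                 " has zero within-group variance"))
  }
  if (ncol(y) == 1) {
    a <- anova(lm(y[, 1] ~ g))
    ssb <- a$`Sum Sq`[1]
    sse <- a$`Sum Sq`[2]
    return(tibble::tibble(
      pillai = ssb / (ssb + sse),
      f_statistic = a$`F value`[1],
      df1 = a$Df[1], df2 = a$Df[2],
      p = a$`Pr(>F)`[1]
    ))
  }
  fit <- manova(y ~ g)
  sm <- summary(fit, test = "Pillai")$stats
  tibble::tibble(
    pillai = sm[1, "Pillai"],
    f_statistic = sm[1, "approx F"],
    df1 = sm[1, "num Df"], df2 = sm[1, "den Df"],
    p = sm[1, "Pr(>F)"]
  )
}

#' Locate load peaks in a class mean trajectory
#'
#' Local maxima of the trajectory after 3-point moving-average smoothing,
#' filtered by prominence and minimum separation, keeping the top peaks by
#' height. The defaults (prominence >= 2 TTL points, separation >= 3 weeks,
#' 2 peaks) suit 25-week mean TTL curves with one load peak per macrocycle.
#'
#' @param trajectory Data frame with `week_before_bp` and a value column
#'   (default `mean_ttl`).
#' @param value Value column (tidy-eval or string).
#' @param smooth_window Moving-average window (odd; 1 disables smoothing).
#' @param min_prominence Minimum peak prominence, in value units.
#' @param min_separation Minimum distance between retained peaks, in weeks.
#' @param n_peaks Maximum number of peaks returned.
#' @return Integer vector of `week_before_bp` values of the retained peaks,
#'   in chronological order (largest week first).
#' @export
find_load_peaks <- function(trajectory, value = "mean_ttl",
                            smooth_window = 3, min_prominence = 2,
                            min_separation = 3, n_peaks = 2) {
  value <- col_sym(rlang::enquo(value))
  df <- trajectory |>
    dplyr::arrange(dplyr::desc(.data$week_before_bp))
  x <- dplyr::pull(df, !!value)
  wk <- df$week_before_bp
  if (smooth_window > 1) {
    half <- smooth_window %/% 2
    x <- vapply(seq_along(x), function(i) {
      mean(x[max(1, i - half):min(length(x), i + half)])
    }, numeric(1))
  }
  n <- length(x)
  cand <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1) x[i - 1] else Inf
    right <- if (i < n) x[i + 1] else Inf
    x[i] > left && x[i] > right
  }, logical(1)))
  if (length(cand) == 0) return(integer(0))
  prominence <- vapply(cand, function(i) {
    h <- x[i]
    side_min <- function(idx) {
      cur_min <- Inf
      for (j in idx) {
        if (x[j] > h) return(cur_min)
        cur_min <- min(cur_min, x[j])
      }
      cur_min
    }
    left_idx <- rev(seq_len(i - 1))
    right_idx <- if (i < n) (i + 1):n else integer(0)
    h - max(side_min(left_idx), side_min(right_idx))
  }, numeric(1))
  keep <- cand[prominence >= min_prominence]
  if (length(keep) == 0) return(integer(0))
  keep <- keep[order(x[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in keep) {
    if (all(abs(wk[i] - wk[chosen]) >= min_separation)) {
      chosen <- c(chosen, i)
    }
    if (length(chosen) >= n_peaks) break
  }
  sort(wk[chosen], decreasing = TRUE)
}

#' Summarize periodization profiles
#'
#' Builds the per-class profile summary table: share of seasons, week-to-week
#' TTL variation (mean and SD), relative performance Pr (mean and SD),
#' progressivity label (sign of the mean first-to-second-half TTL delta),
#' load-peak weeks of the weighted observed class mean trajectory, and mean
#' intensity compositions.
#'
#' @param fit An `lcmm_fit`.
#' @param ttl TTL tibble used for the fit.
#' @param seasons Season-level tibble with `pr` (or `performance_s` and
#'   `m10wp_s`) and covariates.
#' @param training Weekly training log (for compositions).
#' @param ... Passed to [find_load_peaks()].
#' @return A tibble with one row per class.
#' @export
summarize_profiles <- function(fit, ttl, seasons, training, ...) {
  stopifnot(inherits(fit, "lcmm_fit"))
  assignments <- augment(fit) |>
    dplyr::select("swimmer_id", "season_label", "modal_class")
  if (!"pr" %in% names(seasons)) {
    seasons <- seasons |>
      dplyr::mutate(pr = relative_performance(.data$performance_s,
                                              .data$m10wp_s))
  }
  variation <- weekly_variation(ttl) |>
    dplyr::left_join(assignments, by = c("swimmer_id", "season_label"))
  prog <- progressivity(ttl,
                        first_weeks = max(ttl$week_before_bp):
                          (min(ttl$week_before_bp) +
                             floor(diff(range(ttl$week_before_bp)) / 2)),
                        second_weeks = (min(ttl$week_before_bp) +
                                          floor(diff(range(ttl$week_before_bp)) / 2) - 1):
                          min(ttl$week_before_bp)) |>
    dplyr::left_join(assignments, by = c("swimmer_id", "season_label"))
  comp <- intensity_composition(training) |>
    dplyr::left_join(assignments, by = c("swimmer_id", "season_label"))
  perf <- seasons |>
    dplyr::left_join(assignments, by = c("swimmer_id", "season_label"))
  wcm <- weighted_class_means(ttl, fit$posterior)
  k <- fit$spec$n_classes
  purrr::map_dfr(seq_len(k), function(g) {
    vg <- variation |> dplyr::filter(.data$modal_class == g)
    pg <- perf |> dplyr::filter(.data$modal_class == g)
    prg <- prog |> dplyr::filter(.data$modal_class == g)
    cg <- comp |> dplyr::filter(.data$modal_class == g)
    peaks <- find_load_peaks(wcm |> dplyr::filter(.data$class == g), ...)
    tibble::tibble(
      class = g,
      n = nrow(pg),
      share = fit$class_shares[g],
      mean_posterior = fit$mean_posterior_by_class[g],
      variation_mean = mean(vg$variation),
      variation_sd = sd(vg$variation),
      pr_mean = mean(pg$pr),
      pr_sd = sd(pg$pr),
      progressivity_delta = mean(prg$delta),
      progressivity = ifelse(mean(prg$delta) > 0, "progressivity",
                             "degressivity"),
      peak_weeks = paste(peaks, collapse = ", "),
      p_mhi = mean(cg$p_mhi, na.rm = TRUE),
      p_si = mean(cg$p_si, na.rm = TRUE),
      p_ei = mean(cg$p_ei, na.rm = TRUE),
      p_gc = mean(cg$p_gc, na.rm = TRUE),
      p_st = mean(cg$p_st, na.rm = TRUE)
    )
  })
}

#' Cross-tabulate covariates against profile groups
#'
#' Chi-square tests of association between each categorical covariate and the
#' modal profile class, mirroring the demographic characterization tables.
#' Cells with expected counts below 5 are flagged.
#'
#' @param seasons Season-level tibble.
#' @param modal_class Integer class per season (aligned with `seasons` rows),
#'   or an `lcmm_fit` whose assignments are matched by season key.
#' @param covariates Character vector of covariate columns to test.
#' @return A tibble: `covariate`, `chi_sq`, `df`, `p`, `low_expected`.
#' @export
covariate_crosstabs <- function(seasons, modal_class,
                                covariates = c("sex", "quadrennial",
                                               "season_in_quadrennial")) {
  if (inherits(modal_class, "lcmm_fit")) {
    asg <- augment(modal_class)
    idx <- match(
      season_key(seasons$swimmer_id, seasons$season_label),
      season_key(asg$swimmer_id, asg$season_label)
    )
    modal_class <- asg$modal_class[idx]
  }
  purrr::map_dfr(covariates, function(v) {
    tab <- table(as.character(seasons[[v]]), modal_class)
    ct <- suppressWarnings(chisq.test(tab))
    low <- any(ct$expected < 5)
    if (low) {
      warn(paste0("cross-tab for ", v, " has expected counts below 5"))
    }
    tibble::tibble(
      covariate = v,
      chi_sq = unname(ct$statistic),
      df = unname(ct$parameter),
      p = ct$p.value,
      low_expected = low
    )
  })
}
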