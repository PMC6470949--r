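#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a simulation
#' configuration or input CSV paths, the TTL component mode, the model-search
#' grid, fitting controls and the output directory. All randomness flows from
#' the single `seed`, split into named per-stage substreams, so stages are
#' individually reproducible.
#'
#' @param simulate A [sim_config()] to generate a synthetic cohort, or `NULL`
#'   to read `training_csv` / `seasons_csv`.
#' @param training_csv,seasons_csv Input paths (ignored when simulating).
#' @param distance_class Filter: `"sprint"`, `"middle_distance"` or `"all"`.
#' @param n_weeks Expected weeks per season (validation).
#' @param ttl_mode `"five_category"` or `"seven_component"` (see
#'   [compute_ttl()]).
#' @param k_range,knot_range,re_covariance,re_class_structure Model-search
#'   grid (see [model_search()]).
#' @param n_starts EM starts per grid cell.
#' @param seed Root seed.
#' @param out_dir Output directory for artifacts.
#' @param peak_min_separation,peak_prominence Peak-detection thresholds (see
#'   [find_load_peaks()]).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(simulate = NULL,
                            training_csv = NULL, seasons_csv = NULL,
                            distance_class = "all",
                            n_weeks = 25,
                            ttl_mode = "five_category",
                            k_range = 1:3,
                            knot_range = c(2, 3, 5),
                            re_covariance = "diagonal",
                            re_class_structure = "common",
                            n_starts = 5,
                            seed = 1,
                            out_dir = tempfile("swimperiod_run_"),
                            peak_min_separation = 3,
                            peak_prominence = 2) {
  if (is.null(simulate) && (is.null(training_csv) || is.null(seasons_csv))) {
    abort("either a simulation config or both input CSV paths are required")
  }
  if (any(k_range < 1 | k_range > 5)) abort("k_range must lie in 1..5")
  if (any(knot_range < 0 | knot_range > 15)) {
    abort("knot_range must lie in 0..15")
  }
  structure(
    list(
      simulate = simulate, training_csv = training_csv,
      seasons_csv = seasons_csv, distance_class = distance_class,
      n_weeks = as.integer(n_weeks), ttl_mode = ttl_mode,
      k_range = k_range, knot_range = knot_range,
      re_covariance = re_covariance,
      re_class_structure = re_class_structure,
      n_starts = as.integer(n_starts), seed = as.integer(seed),
      out_dir = out_dir,
      peak_min_separation = peak_min_separation,
      peak_prominence = peak_prominence
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys mirror the
#'   arguments of [pipeline_config()]; a `simulate:` block is passed to
#'   [sim_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(lst$simulate)) {
    lst$simulate <- do.call(sim_config, lst$simulate)
  }
  do.call(pipeline_config, lst)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate -> quantify -> latent-class
#' model search -> characterize, writing every artifact as CSV/JSON to the
#' configured output directory: a sample description, the TTL table (one row
#' per season, one column per week), season-level metrics (Pr, variability,
#' progressivity, compositions), the model-search table, the selected fit
#' (JSON), the posterior matrix, weighted class-mean trajectories, the
#' profile summary, group-comparison tests, covariate cross-tabs, and a
#' manifest recording inputs, configuration hash, seed and versions.
#' Identical configuration and seed reproduce every artifact byte for byte.
#'
#' @param config A [pipeline_config()] or a path readable by
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the fitted search object, the tables, and
#'   the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  # -- acquire ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    simc <- config$simulate
    simc$seed <- stage_seed(config$seed, "simulate")
    cohort <- simulate_cohort(simc)
    training <- cohort$training
    seasons <- cohort$seasons
    readr::write_csv(cohort$truth, file.path(out, "truth.csv"))
  } else {
    cohort <- NULL
    training <- read_training_csv(config$training_csv)
    seasons <- read_seasons_csv(config$seasons_csv)
  }
  if (config$distance_class != "all" && "distance_class" %in% names(seasons)) {
    keep <- seasons$distance_class == config$distance_class
    seasons <- seasons[keep, , drop = FALSE]
    training <- training |>
      dplyr::semi_join(seasons, by = c("swimmer_id", "season_label"))
  }

  # -- validate --------------------------------------------------------------
  week_check <- training |>
    dplyr::group_by(.data$swimmer_id, .data$season_label) |>
    dplyr::summarise(
      ok = dplyr::n() == config$n_weeks &&
        all(sort(.data$week_before_bp) == seq_len(config$n_weeks)),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(week_check) > 0) {
    abort(paste0(
      "season(s) without a complete 1..", config$n_weeks,
      " week ladder: ",
      paste(season_key(week_check$swimmer_id, week_check$season_label),
            collapse = ", ")
    ))
  }

  # -- quantify --------------------------------------------------------------
  if (!"pr" %in% names(seasons)) {
    seasons$pr <- relative_performance(seasons$performance_s, seasons$m10wp_s)
  }
  ttl <- compute_ttl(training, mode = config$ttl_mode)
  ttl_wide <- ttl |>
    dplyr::select("swimmer_id", "season_label", "week_before_bp", "ttl") |>
    tidyr::pivot_wider(names_from = "week_before_bp", values_from = "ttl",
                       names_prefix = "week_")
  metrics <- weekly_variation(ttl) |>
    dplyr::left_join(progressivity(ttl), by = c("swimmer_id", "season_label")) |>
    dplyr::left_join(intensity_composition(training),
                     by = c("swimmer_id", "season_label")) |>
    dplyr::left_join(
      seasons |> dplyr::select("swimmer_id", "season_label", "pr"),
      by = c("swimmer_id", "season_label")
    )
  sample_desc <- seasons |>
    dplyr::count(.data$sex, .data$distance_class, .data$season_in_quadrennial)
  readr::write_csv(sample_desc, file.path(out, "sample_description.csv"))
  readr::write_csv(ttl_wide, file.path(out, "ttl.csv"))
  readr::write_csv(metrics, file.path(out, "metrics.csv"))

  # -- fit -------------------------------------------------------------------
  search <- model_search(
    ttl,
    k_range = config$k_range, knot_range = config$knot_range,
    re_covariance = config$re_covariance,
    re_class_structure = config$re_class_structure,
    n_starts = config$n_starts,
    seed = stage_seed(config$seed, "fit")
  )
  fit <- search$fit
  readr::write_csv(search$table, file.path(out, "search_table.csv"))
  post_tbl <- augment(fit)
  readr::write_csv(post_tbl, file.path(out, "posterior.csv"))
  class_means <- weighted_class_means(ttl, fit$posterior)
  readr::write_csv(class_means, file.path(out, "class_means.csv"))
  fit_json <- list(
    spec = unclass(fit$spec),
    params = list(
      pi = fit$params$pi, beta = fit$params$beta, B = fit$params$B,
      w = fit$params$w, sigma = fit$params$sigma
    ),
    loglik = fit$loglik, n_params = fit$n_params,
    AIC = fit$AIC, BIC = fit$BIC, converged = fit$converged,
    class_shares = fit$class_shares,
    mean_posterior_by_class = fit$mean_posterior_by_class
  )
  jsonlite::write_json(fit_json, file.path(out, "selected_fit.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "columnmajor")

  # -- characterize ----------------------------------------------------------
  profile <- summarize_profiles(
    fit, ttl, seasons, training,
    min_prominence = config$peak_prominence,
    min_separation = config$peak_min_separation
  )
  readr::write_csv(profile, file.path(out, "profile_summary.csv"))
  asg <- augment(fit) |>
    dplyr::select("swimmer_id", "season_label", "modal_class")
  metrics_cls <- metrics |>
    dplyr::left_join(asg, by = c("swimmer_id", "season_label"))
  tests <- dplyr::bind_rows(
    compare_groups(metrics_cls, "variation", "modal_class"),
    compare_groups(metrics_cls, "pr", "modal_class"),
    compare_groups(metrics_cls, "delta", "modal_class")
  )
  comp_mat <- zero_replace(as.matrix(
    metrics_cls[, c("p_mhi", "p_si", "p_ei")]
  ))
  man_water <- manova_compositions(ilr_transform(comp_mat),
                                   metrics_cls$modal_class)
  dry_mat <- zero_replace(as.matrix(metrics_cls[, c("p_gc", "p_st")]))
  man_dry <- manova_compositions(ilr_transform(dry_mat),
                                 metrics_cls$modal_class)
  manova_tbl <- dplyr::bind_rows(
    dplyr::mutate(man_water, block = "in_water", .before = 1),
    dplyr::mutate(man_dry, block = "dryland", .before = 1)
  )
  readr::write_csv(tests, file.path(out, "tests.csv"))
  readr::write_csv(manova_tbl, file.path(out, "manova.csv"))
  crosstabs <- tryCatch(
    suppressWarnings(covariate_crosstabs(seasons, fit)),
    error = function(e) tibble::tibble()
  )
  readr::write_csv(crosstabs, file.path(out, "crosstabs.csv"))

  # -- manifest --------------------------------------------------------------
  artifacts <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("swimperiod")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      "out_dir")]),
    inputs = if (is.null(config$simulate)) {
      list(training_csv = config$training_csv,
           seasons_csv = config$seasons_csv)
    } else {
      list(simulated = TRUE, n_seasons = config$simulate$n_seasons)
    },
    selected_k = search$selected_k,
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    search = search, ttl = ttl, metrics = metrics, profile = profile,
    tests = tests, manova = manova_tbl, manifest = manifest,
    cohort = cohort, out_dir = out
  ))
}
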