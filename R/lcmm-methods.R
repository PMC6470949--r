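#' @export
print.lcmm_fit <- function(x, ...) {
  cat("Latent-class linear mixed model fit\n")
  cat(sprintf("  K = %d classes, %d interior knots, %s random effects (%s, %s)\n",
              x$spec$n_classes, x$spec$n_interior_knots,
              x$spec$random_effects, x$spec$re_covariance,
              x$spec$re_class_structure))
  cat(sprintf("  %d subjects, %d observations\n", x$n_subjects, x$n_obs))
  cat(sprintf("  logLik %.3f  AIC %.1f  BIC %.1f  (%d parameters)%s\n",
              x$loglik, x$AIC, x$BIC, x$n_params,
              if (x$converged) "" else "  [not converged]"))
  cat("  class shares:",
      paste(sprintf("%.2f", x$class_shares), collapse = " / "), "\n")
  cat("  mean posterior of assigned class:",
      paste(sprintf("%.2f", x$mean_posterior_by_class), collapse = " / "),
      "\n")
  invisible(x)
}

#' Evaluate the fitted class mean curves
#'
#' @param fit An `lcmm_fit`.
#' @param weeks `week_before_bp` values at which to evaluate (default 25..1
#'   within the fitted range).
#' @return A tibble with `class`, `week_before_bp`, `mean_ttl`.
#' @export
predict_class_means <- function(fit, weeks = NULL) {
  stopifnot(inherits(fit, "lcmm_fit"))
  weeks <- weeks %||% seq(fit$boundary[2], fit$boundary[1])
  ns_part <- splines::ns(weeks, knots = fit$knots,
                         Boundary.knots = fit$boundary)
  x <- cbind(1, ns_part)
  mu <- x %*% as.matrix(fit$params$beta)
  tibble::tibble(
    class = rep(seq_len(fit$spec$n_classes), each = length(weeks)),
    week_before_bp = rep(weeks, fit$spec$n_classes),
    mean_ttl = as.vector(mu)
  )
}

#' @rdname fit_lcmm
#' @param x,object An `lcmm_fit`.
#' @param ... Unused.
#' @method tidy lcmm_fit
#' @export
tidy.lcmm_fit <- function(x, ...) {
  k <- x$spec$n_classes
  p <- nrow(as.matrix(x$params$beta))
  beta_tbl <- tibble::tibble(
    term = rep(paste0("beta", seq_len(p)), k),
    class = rep(seq_len(k), each = p),
    estimate = as.vector(as.matrix(x$params$beta))
  )
  extra <- tibble::tibble(
    term = c(paste0("pi", seq_len(k)),
             paste0("w", seq_len(k)),
             paste0("B", seq_len(length(x$params$B))),
             "sigma"),
    class = NA_integer_,
    estimate = c(x$params$pi, x$params$w, as.vector(x$params$B),
                 x$params$sigma)
  )
  dplyr::bind_rows(beta_tbl, extra)
}

#' @rdname fit_lcmm
#' @method glance lcmm_fit
#' @export
glance.lcmm_fit <- function(x, ...) {
  tibble::tibble(
    n_classes = x$spec$n_classes,
    n_interior_knots = x$spec$n_interior_knots,
    re_covariance = x$spec$re_covariance,
    re_class_structure = x$spec$re_class_structure,
    logLik = x$loglik,
    n_params = x$n_params,
    AIC = x$AIC,
    BIC = x$BIC,
    sigma = x$params$sigma,
    converged = x$converged,
    n_subjects = x$n_subjects,
    n_obs = x$n_obs
  )
}

#' @rdname fit_lcmm
#' @method augment lcmm_fit
#' @export
augment.lcmm_fit <- function(x, ...) {
  post <- x$posterior
  ids <- rownames(post)
  parts <- strsplit(ids, ":", fixed = TRUE)
  tibble::tibble(
    swimmer_id = vapply(parts, `[[`, "", 1),
    season_label = vapply(parts, function(z) {
      paste(z[-1], collapse = ":")
    }, ""),
    modal_class = x$modal_class,
    max_posterior = post[cbind(seq_len(nrow(post)), x$modal_class)]
  ) |>
    dplyr::bind_cols(tibble::as_tibble(post))
}

#' Plot fitted or observed class-mean TTL trajectories
#'
#' Without `data`, draws the fitted spline mean curve of each class. With a
#' TTL tibble, overlays the observed class-specific mean evolutions weighted
#' by the posterior class-membership probabilities (points), the style used
#' to display latent trajectory classes. The time axis runs from 25 weeks
#' before the season-best performance down to the final week.
#'
#' @param object An `lcmm_fit`.
#' @param data Optional TTL tibble used to compute weighted observed means.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcmm_fit
#' @export
autoplot.lcmm_fit <- function(object, data = NULL, ...) {
  curves <- predict_class_means(object) |>
    dplyr::mutate(class = factor(.data$class))
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$week_before_bp,
                                    y = .data$mean_ttl,
                                    colour = .data$class)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Weeks before best performance", y = "TTL (%)",
                  colour = "Class") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    obs <- weighted_class_means(data, object$posterior) |>
      dplyr::mutate(class = factor(.data$class))
    p <- p + ggplot2::geom_point(
      data = obs,
      ggplot2::aes(y = .data$mean_ttl), size = 1.6, alpha = 0.7
    )
  }
  p
}

#' Plot weekly TTL series of individual seasons
#'
#' @param ttl TTL tibble from [compute_ttl()].
#' @param highlight Optional vector of `swimmer_id` values to emphasize.
#' @return A ggplot object.
#' @export
plot_ttl_series <- function(ttl, highlight = NULL) {
  df <- ttl |>
    dplyr::mutate(.id = season_key(.data$swimmer_id, .data$season_label))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$week_before_bp,
                                        y = .data$ttl, group = .data$.id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Weeks before best performance", y = "TTL (%)") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_line(
      data = dplyr::filter(df, .data$swimmer_id %in% highlight),
      colour = "firebrick", linewidth = 0.8
    )
  }
  p
}

#' AIC/BIC model search over the latent-class grid
#'
#' Mirrors the two-stage selection protocol: for each candidate number of
#' classes K, every combination of spline knot count, random-effect
#' covariance shape and class structure is fitted and the AIC-minimal
#' converged model is retained; across K, the BIC of each K-best model is
#' compared and the BIC-minimal K selected. The full search table is
#' returned so the final "interpretation" judgement stays with the analyst.
#' Non-converged fits are kept in the table, flagged, and excluded from
#' selection. With a single random intercept the diagonal and unstructured
#' covariances coincide, so duplicates are dropped from the grid.
#'
#' @inheritParams fit_lcmm
#' @param k_range Candidate numbers of classes (subset of 1..5).
#' @param knot_range Candidate interior knot counts (subset of 0..15).
#' @param re_covariance,re_class_structure Character vectors of structures to
#'   cross.
#' @param random_effects Random-effects design (fixed across the grid).
#' @return An `lcmm_search` list: `fit` (the selected `lcmm_fit`), `table`
#'   (one row per fitted cell), `by_k` (the AIC-winner per K), `selected_k`.
#' @export
model_search <- function(data, k_range = 1:3, knot_range = c(2, 3, 5),
                         re_covariance = "diagonal",
                         re_class_structure = "common",
                         random_effects = "intercept",
                         n_starts = 5, seed = 1, tol = 1e-8, max_iter = 500,
                         polish = TRUE) {
  q <- if (random_effects == "intercept") 1L else 2L
  if (q == 1) re_covariance <- unique(sub("unstructured", "diagonal",
                                          re_covariance))
  grid <- expand.grid(
    k = k_range, knots = knot_range, cov = unique(re_covariance),
    struct = unique(re_class_structure), stringsAsFactors = FALSE
  )
  # proportional scaling is vacuous with a single class
  grid$struct[grid$k == 1] <- "common"
  grid <- unique(grid)
  if (nrow(grid) == 0) abort("empty model grid")
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    spec <- lcmm_spec(
      n_classes = g$k, n_interior_knots = g$knots,
      random_effects = random_effects,
      re_covariance = g$cov, re_class_structure = g$struct
    )
    fit <- tryCatch(
      fit_lcmm(data, spec, n_starts = n_starts, seed = seed + i, tol = tol,
               max_iter = max_iter, polish = polish),
      error = function(e) NULL
    )
    fits[[i]] <- fit
    rows[[i]] <- tibble::tibble(
      n_classes = g$k, n_interior_knots = g$knots,
      re_covariance = g$cov, re_class_structure = g$struct,
      logLik = if (is.null(fit)) NA_real_ else fit$loglik,
      n_params = if (is.null(fit)) NA_integer_ else fit$n_params,
      AIC = if (is.null(fit)) NA_real_ else fit$AIC,
      BIC = if (is.null(fit)) NA_real_ else fit$BIC,
      converged = if (is.null(fit)) FALSE else fit$converged
    )
  }
  table <- dplyr::bind_rows(rows)
  ok <- which(table$converged)
  if (length(ok) == 0) abort("no converged fit in the search grid")
  by_k_idx <- vapply(sort(unique(table$n_classes[ok])), function(k) {
    cand <- ok[table$n_classes[ok] == k]
    cand[which.min(table$AIC[cand])]
  }, integer(1))
  by_k <- table[by_k_idx, ]
  sel_idx <- by_k_idx[which.min(table$BIC[by_k_idx])]
  structure(
    list(
      fit = fits[[sel_idx]],
      table = table,
      by_k = by_k,
      selected_k = table$n_classes[sel_idx]
    ),
    class = "lcmm_search"
  )
}

#' @export
print.lcmm_search <- function(x, ...) {
  cat("LCMM model search (", nrow(x$table), " cells)\n", sep = "")
  cat("AIC winner per K (BIC decides across K):\n")
  print(as.data.frame(x$by_k), row.names = FALSE)
  cat("Selected K =", x$selected_k, "\n")
  invisible(x)
}
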