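training_schema <- c(
  swimmer_id = "c", season_label = "c", week_before_bp = "d",
  i1_m = "d", i2_m = "d", i3_m = "d", i4_m = "d", i5_m = "d",
  gc_min = "d", st_min = "d"
)

seasons_schema <- c(
  swimmer_id = "c", season_label = "c", performance_s = "d", m10wp_s = "d",
  sex = "c", age = "d", stroke = "c", distance_class = "c", quarter = "c",
  season_in_study = "d", season_in_quadrennial = "c", quadrennial = "c",
  pr = "d"
)

lactate_schema <- c(
  swimmer_id = "c", test_date = "c", stage = "d", speed_ms = "d",
  lactate_mmol = "d"
)

read_checked_csv <- function(path, schema, required = names(schema)) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  unknown <- setdiff(header, names(schema))
  if (length(unknown) > 0) {
    abort(paste0(path, ": unknown column(s): ",
                 paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  types <- paste(unname(schema[header]), collapse = "")
  df <- readr::read_csv(path, col_types = types, show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0(path, ": malformed value at row ", probs$row[1],
                 ", column ", probs$col[1], " (expected ", probs$expected[1],
                 ")"))
  }
  if (nrow(df) == 0) warn(paste0(path, ": no data rows"))
  df
}

#' Read and write the package's CSV interchange formats
#'
#' Strictly validated readers for the three input tables (weekly training
#' logs, season-level performance/covariates, lactate-test stages) and their
#' writer counterparts. Unknown columns, missing columns, malformed values
#' (with file/row/column in the message) and negative volumes are errors;
#' write-then-read round-trips are identity.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_training_csv <- function(path) {
  df <- read_checked_csv(path, training_schema)
  if (nrow(df) > 0) validate_training(df)
  df
}

#' @rdname read_training_csv
#' @export
read_seasons_csv <- function(path) {
  df <- read_checked_csv(
    path, seasons_schema,
    required = c("swimmer_id", "season_label", "performance_s", "m10wp_s")
  )
  if (nrow(df) > 0 && (any(df$performance_s <= 0) || any(df$m10wp_s <= 0))) {
    bad <- which(df$performance_s <= 0 | df$m10wp_s <= 0)
    abort(paste0(path, ": nonpositive performance time at row ",
                 bad[1]))
  }
  df
}

#' @rdname read_training_csv
#' @export
read_lactate_csv <- function(path) {
  read_checked_csv(path, lactate_schema)
}

#' @rdname read_training_csv
#' @param data Tibble to write.
#' @export
write_training_csv <- function(data, path) {
  validate_training(data)
  readr::write_csv(data[training_cols], path)
  invisible(path)
}
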