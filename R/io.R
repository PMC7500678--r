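# CSV input/output for environment schedules, rate datasets and trajectory
# observations. Numerics are written with 17 significant digits so that
# write -> read round trips are lossless.

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  .check(length(missing) == 0, "file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
}

.parse_numeric <- function(df, cols, path) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    .check(length(bad) == 0, "file ", path, ": non-numeric value in column ",
           col, " at data line ", if (length(bad)) bad[1] else "")
    df[[col]] <- v
  }
  df
}

#' Write / read an environment schedule as CSV
#'
#' Columns: `time_h, T_med_C, B_feed_g_d, W_med_pct, A_air_l_min`.
#'
#' @param schedule an [environment_schedule()] (or [env_state()]).
#' @param path CSV file path.
#' @return `write_schedule`: `path` invisibly; `read_schedule`: an
#'   [environment_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  schedule <- as_schedule(schedule)
  .write_csv17(schedule$data, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  .check(file.exists(path), "schedule file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- c("time_h", "T_med_C", "B_feed_g_d", "W_med_pct", "A_air_l_min")
  .require_columns(df, cols, path)
  df <- .parse_numeric(df, cols, path)
  .check(nrow(df) >= 1, "file ", path, ": schedule is empty")
  .check(nrow(df) == 1 || all(diff(df$time_h) > 0),
         "file ", path, ": time stamps must be strictly increasing")
  environment_schedule(df$time_h, df$T_med_C, df$B_feed_g_d, df$W_med_pct,
                       df$A_air_l_min)
}

#' Write / read a rate dataset as CSV
#'
#' Columns: `factor, response, source_id, unit_factor, unit_response`. The
#' factor kind is inferred from the factor unit on reading (`degC` ->
#' temperature, `g d-1` -> feed density, `kg kg-1` -> moisture, `l min-1` ->
#' airflow, `h`/`d` -> time) unless given explicitly.
#'
#' @param ds a [rate_dataset()].
#' @param path CSV file path.
#' @param factor_kind optional explicit factor kind for `read_dataset`.
#' @param id dataset label for `read_dataset` (default: file name).
#' @return `write_dataset`: `path` invisibly; `read_dataset`: a
#'   [rate_dataset()].
#' @export
write_dataset <- function(ds, path) {
  .check(inherits(ds, "rate_dataset"), "ds must be a rate_dataset")
  .write_csv17(as.data.frame(ds), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, factor_kind = NULL, id = NULL) {
  .check(file.exists(path), "dataset file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("factor", "response", "source_id", "unit_factor",
                         "unit_response"), path)
  df <- .parse_numeric(df, c("factor", "response"), path)
  unit_f <- df$unit_factor[1]
  if (is.null(factor_kind)) {
    kind_map <- c(`degC` = "temperature", `g d-1` = "feed_density",
                  `kg kg-1` = "moisture", `l min-1` = "airflow",
                  h = "time", d = "time")
    factor_kind <- kind_map[[unit_f]]
    .check(!is.null(factor_kind), "file ", path,
           ": cannot infer factor kind from unit '", unit_f,
           "'; pass factor_kind explicitly")
  }
  rate_dataset(df$factor, df$response, factor_kind,
               id = id %||% sub("\\.csv$", "", basename(path)),
               source_id = df$source_id, unit_factor = unit_f,
               unit_response = df$unit_response[1],
               normalized = all(df$unit_response == "normalized"))
}

#' Read trajectory observations (time vs dry mass) from CSV
#'
#' Columns: `time_h, B_dry_g, source_id`.
#'
#' @param path CSV file path.
#' @return Data frame `time_h`, `B_dry_g`, `source_id`, time-ordered.
#' @export
read_trajectory_obs <- function(path) {
  .check(file.exists(path), "trajectory file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("time_h", "B_dry_g", "source_id"), path)
  df <- .parse_numeric(df, c("time_h", "B_dry_g"), path)
  df[order(df$time_h), ]
}
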