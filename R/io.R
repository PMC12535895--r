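trajectory_csv_cols <- c("time_s", "roll_dps", "pitch_dps", "yaw_dps")

#' Read and write trajectory CSV files
#'
#' The trajectory dialect has a mandatory header row with columns `time_s`,
#' `roll_dps`, `pitch_dps`, `yaw_dps` and one row per sample.
#'
#' @param trajectory A `vs_trajectory` (or `vs_trace`).
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a `vs_trajectory`.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  if (!inherits(trajectory, c("vs_trajectory", "vs_trace"))) {
    stop_invalid("`trajectory` must be a vs_trajectory or vs_trace")
  }
  df <- as.data.frame(trajectory)[, trajectory_csv_cols]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) {
    stop_invalid_input(sprintf("trajectory file not found: %s", path))
  }
  df <- read.csv(path, check.names = TRUE)
  missing <- setdiff(trajectory_csv_cols, names(df))
  if (length(missing) > 0L) {
    stop_invalid_input(sprintf(
      "malformed trajectory CSV %s: expected columns %s; missing %s",
      path, paste(trajectory_csv_cols, collapse = ", "),
      paste(missing, collapse = ", ")))
  }
  new_trajectory(as.numeric(df$time_s),
                 cbind(roll = as.numeric(df$roll_dps),
                       pitch = as.numeric(df$pitch_dps),
                       yaw = as.numeric(df$yaw_dps)))
}

model_to_list <- function(model) {
  stopifnot(inherits(model, "vs_model"))
  tc <- model$time_constants
  list(tau_roll_s = tc$tau_roll, tau_pitch_s = tc$tau_pitch,
       tau_yaw_s = tc$tau_yaw,
       h_yr_per_s = model$coupling$h_yr, h_yp_per_s = model$coupling$h_yp,
       yaw_gain = model$yaw_gain)
}

model_from_list <- function(x) {
  known <- c("tau_roll_s", "tau_pitch_s", "tau_yaw_s", "h_yr_per_s",
             "h_yp_per_s", "yaw_gain")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    stop_invalid(sprintf("unknown model field(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  defaults <- list(tau_roll_s = 5, tau_pitch_s = 5, tau_yaw_s = 18,
                   h_yr_per_s = 0, h_yp_per_s = 0, yaw_gain = 1)
  x <- modifyList(defaults, x[!vapply(x, is.null, logical(1))])
  vs_model(time_constants(x$tau_roll_s, x$tau_pitch_s, x$tau_yaw_s),
           coupling_terms(x$h_yr_per_s, x$h_yp_per_s),
           yaw_gain = x$yaw_gain)
}

#' Serialize a model to and from flat JSON
#'
#' The schema is a flat object
#' `{tau_roll_s, tau_pitch_s, tau_yaw_s, h_yr_per_s, h_yp_per_s, yaw_gain}`.
#' Values are written at full double precision so a write/read round trip
#' reproduces the model exactly.
#'
#' @param model A `vs_model`.
#' @param path File path (for `model_from_json()`, an existing file).
#' @return `model_to_json()` returns `path` invisibly; `model_from_json()`
#'   returns a `vs_model`.
#' @export
model_to_json <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  if (!file.exists(path)) {
    stop_invalid_input(sprintf("model file not found: %s", path))
  }
  model_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
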