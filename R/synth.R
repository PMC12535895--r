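#' Generate a figure-style sampled OKAN trace
#'
#' Samples the closed-form zero-input response on a regular grid (default 4
#' samples per second, the convention of plotted OKAN dot displays) and
#' injects independent zero-mean Gaussian noise on every component of every
#' sample.  The noise emulates the jitter used to visualize spatio-temporal
#' progression in such plots; its distribution is a modelling choice, with
#' the SD left to the caller.  Generation is fully deterministic given
#' `seed` and never touches the session's global random state.
#'
#' @param model A `vs_model`.
#' @param x0 Initial state `(roll, pitch, yaw)` in deg/s; default
#'   `c(0, 0, 20)` (idealized OKAN after yaw optokinetic stimulation).
#' @param duration_s Trace duration in seconds (> 0), default 120.
#' @param noise_sd Noise standard deviation in deg/s (>= 0); 0 reproduces
#'   the closed form exactly on the sample grid.
#' @param seed Integer seed; required so every trace is reproducible.
#' @param sample_rate Samples per second, default 4.
#' @return An object of class `vs_trace` (also a `vs_trajectory`): fields
#'   `times`, `states` (noisy), `clean_states`, `noise_sd`, `seed`,
#'   `sample_rate`, plus the generating `model` and `x0` for provenance.
#' @seealso [write_trace_bundle()] to persist the trace with its
#'   ground-truth sidecar, [fit_model()] to recover the parameters.
#' @examples
#' tcs <- time_constants(5, 5, 18)
#' m <- build_pull(tcs, coupling_from_tilt(15, "roll-yaw", tcs))
#' tr <- generate_trace(m, noise_sd = 0.5, seed = 42)
#' tr
#' @export
generate_trace <- function(model, x0 = c(0, 0, 20), duration_s = 120,
                           noise_sd = 0.5, seed, sample_rate = 4) {
  stopifnot(inherits(model, "vs_model"))
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    stop_invalid("`noise_sd` must be >= 0 (deg/s)")
  }
  if (missing(seed) || !is_scalar_number(seed)) {
    stop_invalid("`seed` must be supplied as a single integer")
  }
  times <- default_time_grid(duration_s, sample_rate)
  clean <- zero_input_response(model, x0, times)
  n <- length(times)
  noise <- if (noise_sd > 0) {
    withr::with_seed(as.integer(seed),
                     matrix(rnorm(3L * n, sd = noise_sd), nrow = n, ncol = 3L))
  } else {
    matrix(0, nrow = n, ncol = 3L)
  }
  states <- clean$states + noise
  colnames(states) <- vs_axes
  structure(
    list(times = times, states = states, clean_states = clean$states,
         gain_applied = TRUE, noise_sd = as.numeric(noise_sd),
         seed = as.integer(seed), sample_rate = as.numeric(sample_rate),
         model = model, x0 = validate_x0(x0)),
    class = c("vs_trace", "vs_trajectory")
  )
}

#' @export
print.vs_trace <- function(x, ...) {
  cat(sprintf(
    "sampled OKAN trace: %d samples at %g Hz, noise SD %g deg/s, seed %d\n",
    length(x$times), x$sample_rate, x$noise_sd, x$seed))
  invisible(x)
}

#' Persist a synthetic trace with its ground-truth sidecar
#'
#' Writes the trace in the trajectory CSV dialect plus a sidecar JSON
#' (`<csv path with .json extension>`) recording the generating model,
#' initial state, noise SD, seed and sample rate — the bundle the fitting
#' tests consume.
#'
#' @param trace A `vs_trace` from [generate_trace()].
#' @param csv_path Path for the CSV; the sidecar path is derived from it.
#' @return Invisibly, `c(csv = ..., json = ...)`.
#' @export
write_trace_bundle <- function(trace, csv_path) {
  if (!inherits(trace, "vs_trace")) {
    stop_invalid("`trace` must come from generate_trace()")
  }
  write_trajectory_csv(trace, csv_path)
  json_path <- sub("\\.csv$", ".json", csv_path)
  if (identical(json_path, csv_path)) json_path <- paste0(csv_path, ".json")
  sidecar <- list(model = model_to_list(trace$model),
                  x0_dps = trace$x0, noise_sd_dps = trace$noise_sd,
                  seed = trace$seed, sample_rate_hz = trace$sample_rate)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
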