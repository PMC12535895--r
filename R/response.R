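#' Default figure-style time grid
#'
#' 0 to 120 s sampled at 4 Hz, mirroring the sampling convention used for
#' plotted OKAN traces (one dot per 0.25 s).
#'
#' @param duration_s Duration in seconds (> 0).
#' @param rate_hz Samples per second (> 0).
#' @return Numeric vector of times starting at 0 (length
#'   `duration_s * rate_hz + 1`).
#' @export
default_time_grid <- function(duration_s = 120, rate_hz = 4) {
  if (!is_scalar_number(duration_s) || duration_s <= 0) {
    stop_invalid("`duration_s` must be > 0")
  }
  if (!is_scalar_number(rate_hz) || rate_hz <= 0) {
    stop_invalid("`rate_hz` must be > 0")
  }
  seq(0, duration_s, by = 1 / rate_hz)
}

validate_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0L || anyNA(times) ||
      any(!is.finite(times))) {
    stop_invalid("`times` must be a non-empty finite numeric vector")
  }
  if (times[1] != 0) {
    stop_invalid("`times` must start at t = 0 (trajectory convention)")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_invalid("`times` must be strictly increasing")
  }
  as.numeric(times)
}

validate_x0 <- function(x0) {
  if (!is.numeric(x0) || length(x0) != 3L || any(!is.finite(x0))) {
    stop_invalid("`x0` must be a finite numeric vector (roll, pitch, yaw) in deg/s")
  }
  as.numeric(x0)
}

new_trajectory <- function(times, states, gain_applied = TRUE) {
  colnames(states) <- vs_axes
  structure(list(times = times, states = states,
                 gain_applied = gain_applied),
            class = "vs_trajectory")
}

#' @export
print.vs_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("velocity trajectory: %d samples over [0, %.4g] s%s\n",
              n, x$times[n],
              if (isTRUE(x$gain_applied)) " (yaw gain applied)" else ""))
  invisible(x)
}

#' @export
as.data.frame.vs_trajectory <- function(x, ...) {
  data.frame(time_s = x$times,
             roll_dps = x$states[, "roll"],
             pitch_dps = x$states[, "pitch"],
             yaw_dps = x$states[, "yaw"])
}

# One cross-coupled term of the closed form.  At coincident decay rates the
# generic form 0/0s; the analytic limit x_y0 * h * t * exp(h t) keeps the
# response continuous in the parameters.
cross_term <- function(h_ya, h_aa, h_yy, x_yaw0, t) {
  if (h_ya == 0 || x_yaw0 == 0) return(numeric(length(t)))
  if (abs(h_yy - h_aa) < DEGENERACY_TOL) {
    x_yaw0 * h_ya * t * exp(h_yy * t)
  } else {
    x_yaw0 * (h_ya / (h_yy - h_aa)) * (exp(h_yy * t) - exp(h_aa * t))
  }
}

#' Closed-form zero-input response (idealized OKAN)
#'
#' Evaluates the response of \eqn{\dot{x} = Hx} to an initial condition with
#' no further input — the slow-phase velocity profile of idealized
#' optokinetic after-nystagmus.  Componentwise:
#' \deqn{x_{roll}(t) = x_{roll}(0)e^{h_{rr}t} +
#'   x_{yaw}(0)\frac{h_{yr}}{h_{yy}-h_{rr}}(e^{h_{yy}t}-e^{h_{rr}t}),}
#' pitch analogously with \eqn{h_{yp}, h_{pp}}, and
#' \eqn{x_{yaw}(t) = k\,x_{yaw}(0)e^{h_{yy}t}} — the yaw output gain k
#' scales only the reported yaw component, never the internal dynamics.
#' When a decay-rate pair coincides the cross term switches to its analytic
#' limit \eqn{x_{yaw}(0)\,h\,t\,e^{ht}}.
#'
#' @param model A `vs_model`.
#' @param x0 Initial state `(roll, pitch, yaw)` in deg/s.  The canonical
#'   OKAN-after-yaw-OKS condition is `c(0, 0, x_yaw0)`.
#' @param times Sample times in seconds: strictly increasing, starting at 0.
#' @return A `vs_trajectory` with a `times` vector and an n-by-3 `states`
#'   matrix (deg/s); the state at t = 0 is the k-scaled initial condition.
#' @seealso [numeric_response_oracle()] for an independent numerical check.
#' @examples
#' m <- build_normal(time_constants(5, 5, 18))
#' tr <- zero_input_response(m, c(0, 0, 20), default_time_grid(60))
#' head(as.data.frame(tr))
#' @export
zero_input_response <- function(model, x0 = c(0, 0, 20),
                                times = default_time_grid()) {
  stopifnot(inherits(model, "vs_model"))
  x0 <- validate_x0(x0)
  times <- validate_times(times)
  h <- decay_rates(model)
  cp <- model$coupling
  k <- model$yaw_gain
  roll <- x0[1] * exp(h[["roll"]] * times) +
    cross_term(cp$h_yr, h[["roll"]], h[["yaw"]], x0[3], times)
  pitch <- x0[2] * exp(h[["pitch"]] * times) +
    cross_term(cp$h_yp, h[["pitch"]], h[["yaw"]], x0[3], times)
  yaw <- k * x0[3] * exp(h[["yaw"]] * times)
  new_trajectory(times, cbind(roll, pitch, yaw))
}

#' Fixed-step Runge-Kutta reference response
#'
#' Integrates \eqn{\dot{x} = Hx} with the classical 4th-order Runge-Kutta
#' scheme at a fixed step and applies the yaw output gain after integration.
#' For a linear system the classical RK4 update is exactly the linear map
#' \eqn{T = I + hH + (hH)^2/2! + (hH)^3/3! + (hH)^4/4!} applied once per
#' step, which is how it is computed here; the result is independent of the
#' eigen-decomposition closed form and serves as its verification oracle in
#' tests and cross-checks.
#'
#' @param model A `vs_model`.
#' @param x0 Initial state `(roll, pitch, yaw)` in deg/s.
#' @param t_end Integration horizon in seconds (> 0).
#' @param dt Fixed step in seconds (> 0).
#' @param sample_every Record every `sample_every`-th step (plus t = 0);
#'   the integration itself always proceeds at `dt`.
#' @return A `vs_trajectory` on the recorded grid.
#' @export
numeric_response_oracle <- function(model, x0, t_end, dt,
                                    sample_every = 1L) {
  stopifnot(inherits(model, "vs_model"))
  x0 <- validate_x0(x0)
  if (!is_scalar_number(t_end) || t_end <= 0) stop_invalid("`t_end` must be > 0")
  if (!is_scalar_number(dt) || dt <= 0) stop_invalid("`dt` must be > 0")
  sample_every <- as.integer(sample_every)
  if (is.na(sample_every) || sample_every < 1L) {
    stop_invalid("`sample_every` must be a positive integer")
  }
  H <- system_matrix(model)
  hH <- dt * H
  T1 <- diag(3) + hH + hH %*% hH / 2 + hH %*% hH %*% hH / 6 +
    hH %*% hH %*% hH %*% hH / 24
  # stride propagator: advance sample_every RK4 steps at once
  Ts <- T1
  if (sample_every > 1L) {
    for (i in seq_len(sample_every - 1L)) Ts <- Ts %*% T1
  }
  n_steps <- floor(t_end / dt + 1e-9)
  n_out <- n_steps %/% sample_every
  states <- matrix(0, nrow = n_out + 1L, ncol = 3L)
  x <- x0
  states[1L, ] <- x
  for (i in seq_len(n_out)) {
    x <- as.numeric(Ts %*% x)
    states[i + 1L, ] <- x
  }
  times <- (0:n_out) * (dt * sample_every)
  states[, 3L] <- model$yaw_gain * states[, 3L]
  new_trajectory(times, states)
}

#' Peak time of a cross-coupled response component
#'
#' The cross-coupled roll (or pitch) term of the zero-input response rises
#' from zero and peaks at \eqn{t = \ln(h_{aa}/h_{yy}) / (h_{yy} - h_{aa})}
#' before declining.  At coincident rates the analytic limit is the shared
#' time constant \eqn{\tau = -1/h}.
#'
#' @param model A `vs_model`.
#' @param plane `"roll-yaw"` or `"pitch-yaw"`.
#' @return Peak time in seconds.
#' @export
cross_coupled_peak_time <- function(model, plane = c("roll-yaw", "pitch-yaw")) {
  plane <- match.arg(plane)
  h <- decay_rates(model)
  h_yy <- h[["yaw"]]
  h_aa <- if (plane == "roll-yaw") h[["roll"]] else h[["pitch"]]
  if (abs(h_yy - h_aa) < DEGENERACY_TOL) {
    -1 / h_yy
  } else {
    log(h_aa / h_yy) / (h_yy - h_aa)
  }
}

#' Asymptotic direction of the decaying response
#'
#' With the yaw time constant longest and `x_yaw(0) != 0`, the ratios
#' `x_roll(t)/x_yaw(t)` and `x_pitch(t)/x_yaw(t)` approach
#' `h_yr/(h_yy-h_rr)` and `h_yp/(h_yy-h_pp)`: the trajectory tail lines up
#' with the (gain-scaled) yaw eigenvector.  This is therefore identical to
#' [subjective_up()]; it is exposed under its dynamical reading.
#'
#' @param model A non-degenerate `vs_model`.
#' @return A `vs_orientation` vector.
#' @export
asymptote_direction <- function(model) {
  subjective_up(model)
}
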