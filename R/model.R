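#' Velocity storage decay time constants
#'
#' Bundle the per-axis decay time constants of the velocity storage
#' integrator.  Each constant is the time for the corresponding velocity
#' component to decay to 1/e; it maps to the system matrix diagonal as
#' \eqn{h_{aa} = -1/\tau_a}.
#'
#' @param tau_roll,tau_pitch,tau_yaw Strictly positive, finite time
#'   constants in seconds.  Physiologically the roll and pitch constants are
#'   several-fold shorter than the yaw constant when upright; that regime is
#'   not enforced here but can be checked with [is_canonical_regime()].
#'
#' @return An object of class `vs_time_constants`.
#' @seealso [vs_model()], [build_normal()]
#' @examples
#' tcs <- time_constants(5, 5, 18)
#' is_canonical_regime(tcs)
#' @export
time_constants <- function(tau_roll, tau_pitch, tau_yaw) {
  for (nm in c("tau_roll", "tau_pitch", "tau_yaw")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) {
      stop_invalid(sprintf("`%s` must be a single finite value > 0 (seconds), got %s",
                           nm, deparse(v)))
    }
  }
  structure(
    list(tau_roll = as.numeric(tau_roll),
         tau_pitch = as.numeric(tau_pitch),
         tau_yaw = as.numeric(tau_yaw)),
    class = "vs_time_constants"
  )
}

#' @rdname time_constants
#' @param tcs A `vs_time_constants` object.
#' @details `is_canonical_regime()` tests the stipulation under which the
#'   tail of OKAN approaches the yaw eigenvector: the yaw time constant
#'   strictly exceeds both the roll and the pitch time constants.
#' @export
is_canonical_regime <- function(tcs) {
  stopifnot(inherits(tcs, "vs_time_constants"))
  tcs$tau_yaw > tcs$tau_roll && tcs$tau_yaw > tcs$tau_pitch
}

#' Yaw-to-roll and yaw-to-pitch coupling terms
#'
#' Off-diagonal elements of the pull-type system matrix, in 1/s.  `h_yr`
#' couples yaw velocity into roll (forward/backward pull, sign selects the
#' polarity); `h_yp` couples yaw into pitch (laterally directed pull).
#' Either or both may be zero.
#'
#' @param h_yr,h_yp Finite coupling coefficients in 1/s.
#' @return An object of class `vs_coupling`.
#' @export
coupling_terms <- function(h_yr = 0, h_yp = 0) {
  if (!is_scalar_number(h_yr) || !is_scalar_number(h_yp)) {
    stop_invalid("coupling terms must be single finite numbers (1/s)")
  }
  structure(list(h_yr = as.numeric(h_yr), h_yp = as.numeric(h_yp)),
            class = "vs_coupling")
}

#' Construct a velocity storage model
#'
#' A `vs_model` is the structured 3x3 system matrix of the velocity storage
#' integrator plus a yaw output gain.  The implied matrix \eqn{H} has
#' diagonal \eqn{(-1/\tau_{roll}, -1/\tau_{pitch}, -1/\tau_{yaw})}; the only
#' permitted off-diagonal entries sit in the yaw column: \eqn{h_{yr}} in the
#' roll row and \eqn{h_{yp}} in the pitch row.  The gain `yaw_gain` (k)
#' scales the yaw component at the output stage only — the internal dynamics
#' \eqn{\dot{x} = Hx} are unaffected; `k = 1` is the identity case and
#' values above 1 (amplification) are rejected as outside the habituation
#' framing.
#'
#' @param time_constants A [time_constants()] object.
#' @param coupling A [coupling_terms()] object; defaults to no coupling.
#' @param yaw_gain Output gain k in (0, 1].
#' @return An object of class `vs_model`.
#' @seealso [build_normal()], [build_pull()], [system_matrix()],
#'   [misalignment_angle()]
#' @examples
#' m <- vs_model(time_constants(5, 5, 18), coupling_terms(h_yr = 0.0387))
#' system_matrix(m)
#' misalignment_angle(m)
#' @export
vs_model <- function(time_constants, coupling = coupling_terms(),
                     yaw_gain = 1) {
  if (!inherits(time_constants, "vs_time_constants")) {
    stop_invalid("`time_constants` must be created with time_constants()")
  }
  if (!inherits(coupling, "vs_coupling")) {
    stop_invalid("`coupling` must be created with coupling_terms()")
  }
  if (!is_scalar_number(yaw_gain) || yaw_gain <= 0 || yaw_gain > 1) {
    stop_invalid("`yaw_gain` must be in (0, 1]")
  }
  structure(
    list(time_constants = time_constants, coupling = coupling,
         yaw_gain = as.numeric(yaw_gain)),
    class = "vs_model"
  )
}

#' @rdname vs_model
#' @details `build_normal()` is the normal-upright construction: a diagonal
#'   system matrix (zero coupling) with unit yaw gain, whose eigenvectors
#'   align with the head-fixed roll, pitch and yaw axes.
#' @param tcs A [time_constants()] object.
#' @export
build_normal <- function(tcs) {
  vs_model(tcs, coupling_terms(0, 0), yaw_gain = 1)
}

#' @rdname vs_model
#' @details `build_pull()` is the gravitational-pull construction: the same
#'   diagonal plus yaw-column cross-coupling, unit yaw gain.
#' @export
build_pull <- function(tcs, coupling) {
  vs_model(tcs, coupling, yaw_gain = 1)
}

#' Diagonal decay rates of a model
#'
#' @param model A `vs_model`.
#' @return Named numeric vector `c(roll=, pitch=, yaw=)` of the diagonal
#'   entries \eqn{h_{aa} = -1/\tau_a}, in 1/s.
#' @export
decay_rates <- function(model) {
  stopifnot(inherits(model, "vs_model"))
  tc <- model$time_constants
  c(roll = -1 / tc$tau_roll, pitch = -1 / tc$tau_pitch,
    yaw = -1 / tc$tau_yaw)
}

#' Realize the 3x3 system matrix H
#'
#' @param model A `vs_model`.
#' @return A 3x3 numeric matrix with `roll`/`pitch`/`yaw` dimnames.  The yaw
#'   output gain is not part of H (it acts on the output, not the dynamics).
#' @export
system_matrix <- function(model) {
  h <- decay_rates(model)
  H <- diag(h)
  dimnames(H) <- list(vs_axes, vs_axes)
  H["roll", "yaw"] <- model$coupling$h_yr
  H["pitch", "yaw"] <- model$coupling$h_yp
  H
}

#' @export
print.vs_model <- function(x, ...) {
  tc <- x$time_constants
  cat("Velocity storage model\n")
  cat(sprintf("  time constants (s): roll %.4g, pitch %.4g, yaw %.4g\n",
              tc$tau_roll, tc$tau_pitch, tc$tau_yaw))
  cat(sprintf("  coupling (1/s):     h_yr %.6g, h_yp %.6g\n",
              x$coupling$h_yr, x$coupling$h_yp))
  cat(sprintf("  yaw output gain k:  %.4g\n", x$yaw_gain))
  g <- tryCatch(misalignment_angle(x), error = function(e) NA_real_)
  if (!is.na(g)) cat(sprintf("  misalignment angle: %.4g deg\n", g))
  invisible(x)
}

orientation_vector <- function(roll, pitch, yaw) {
  structure(c(roll = roll, pitch = pitch, yaw = yaw),
            class = c("vs_orientation", "numeric"))
}

#' @export
print.vs_orientation <- function(x, ...) {
  cat(sprintf("orientation vector (roll, pitch, yaw): (%.6g, %.6g, %.6g)\n",
              x[["roll"]], x[["pitch"]], x[["yaw"]]))
  invisible(x)
}

# Degeneracy check: the eigenbasis closed form divides by h_yy - h_aa; a
# coincident pair of decay rates with nonzero coupling in that plane has no
# such eigenvector.
check_nondegenerate <- function(model) {
  h <- decay_rates(model)
  cp <- model$coupling
  if (cp$h_yr != 0 && abs(h[["yaw"]] - h[["roll"]]) < DEGENERACY_TOL) {
    stop_degenerate(
      "degenerate eigenstructure: h_yy == h_rr with nonzero yaw-to-roll coupling")
  }
  if (cp$h_yp != 0 && abs(h[["yaw"]] - h[["pitch"]]) < DEGENERACY_TOL) {
    stop_degenerate(
      "degenerate eigenstructure: h_yy == h_pp with nonzero yaw-to-pitch coupling")
  }
  invisible(model)
}

#' Subjective estimate of the up direction
#'
#' The yaw eigenvector of H, gain-scaled at the output:
#' \eqn{v_{yaw} = (h_{yr}/(h_{yy}-h_{rr}),\; h_{yp}/(h_{yy}-h_{pp}),\; k)}.
#' For a diagonal (normal) model this is `(0, 0, k)`, i.e. the head
#' vertical; cross-coupling tilts it away.
#'
#' @param model A non-degenerate `vs_model`.
#' @return A `vs_orientation` vector (dimensionless, head-fixed frame).
#' @seealso [eigenbasis()] for the unscaled eigenvectors,
#'   [misalignment_angle()] for the tilt it implies.
#' @export
subjective_up <- function(model) {
  stopifnot(inherits(model, "vs_model"))
  check_nondegenerate(model)
  h <- decay_rates(model)
  cp <- model$coupling
  rc <- if (cp$h_yr == 0) 0 else cp$h_yr / (h[["yaw"]] - h[["roll"]])
  pc <- if (cp$h_yp == 0) 0 else cp$h_yp / (h[["yaw"]] - h[["pitch"]])
  orientation_vector(rc, pc, model$yaw_gain)
}

#' Closed-form eigenbasis of the system matrix
#'
#' Returns the eigenvectors of H (yaw gain NOT applied): `u_roll = (1,0,0)`
#' and `u_pitch = (0,1,0)` always align with the head roll and pitch axes;
#' `u_yaw = (h_yr/(h_yy-h_rr), h_yp/(h_yy-h_pp), 1)` is the internal
#' estimate of the up direction.  The associated eigenvalues are the
#' diagonal decay rates.
#'
#' @param model A non-degenerate `vs_model`.
#' @return Named list `u_roll`, `u_pitch`, `u_yaw` of `vs_orientation`
#'   vectors, satisfying `H %*% u == lambda * u` for
#'   `lambda = h_rr, h_pp, h_yy` respectively.
#' @export
eigenbasis <- function(model) {
  stopifnot(inherits(model, "vs_model"))
  check_nondegenerate(model)
  h <- decay_rates(model)
  cp <- model$coupling
  rc <- if (cp$h_yr == 0) 0 else cp$h_yr / (h[["yaw"]] - h[["roll"]])
  pc <- if (cp$h_yp == 0) 0 else cp$h_yp / (h[["yaw"]] - h[["pitch"]])
  list(u_roll = orientation_vector(1, 0, 0),
       u_pitch = orientation_vector(0, 1, 0),
       u_yaw = orientation_vector(rc, pc, 1))
}

#' Misalignment angle between subjective up and the head vertical
#'
#' The angle gamma between the gain-scaled yaw eigenvector and the yaw
#' (head-vertical) axis, from its yaw-direction cosine
#' \deqn{\cos\gamma = k \big/ \sqrt{(h_{yr}/(h_{yy}-h_{rr}))^2 +
#'   (h_{yp}/(h_{yy}-h_{pp}))^2 + k^2},}
#' which reduces to the unit-gain form when k = 1.  Gamma is the model's
#' proxy for the strength of the gravitational-pull sensation.
#'
#' @param model A non-degenerate `vs_model`.
#' @return Angle in degrees, in `[0, 90)`.
#' @examples
#' tcs <- time_constants(5, 5, 18)
#' cp <- coupling_from_tilt(15, "roll-yaw", tcs)
#' misalignment_angle(build_pull(tcs, cp))  # 15 by construction
#' @export
misalignment_angle <- function(model) {
  u <- subjective_up(model)
  transverse <- sqrt(u[["roll"]]^2 + u[["pitch"]]^2)
  rad2deg(atan2(transverse, u[["yaw"]]))
}

#' Solve for the coupling that produces a designed tilt
#'
#' Inverts the misalignment-cosine relation: for a single-plane pull the
#' subjective-up component in that plane equals `tan(tilt)`, so
#' \eqn{h = \tan(\gamma)\,(h_{yy} - h_{aa})} where \eqn{h_{aa}} is the decay
#' rate of the chosen plane's other axis.  The returned coupling satisfies
#' `misalignment_angle(build_pull(tcs, result)) == tilt` to high precision;
#' the coupling in the other plane is zero.  In the canonical regime
#' (yaw time constant longest) a positive tilt yields positive coupling,
#' i.e. subjective up tilted toward +roll (backward pull) for the roll-yaw
#' plane.
#'
#' @param tilt Designed misalignment in degrees, `0 <= tilt < 90`.
#' @param plane `"roll-yaw"` (sets `h_yr`) or `"pitch-yaw"` (sets `h_yp`).
#' @param tcs A [time_constants()] object with distinct decay rates in the
#'   chosen plane.
#' @return A [coupling_terms()] object.
#' @export
coupling_from_tilt <- function(tilt, plane = c("roll-yaw", "pitch-yaw"),
                               tcs) {
  plane <- match.arg(plane)
  if (!is_scalar_number(tilt) || tilt < 0 || tilt >= 90) {
    stop_invalid("`tilt` must be in [0, 90) degrees")
  }
  stopifnot(inherits(tcs, "vs_time_constants"))
  if (tilt == 0) return(coupling_terms(0, 0))
  h_yy <- -1 / tcs$tau_yaw
  h_aa <- if (plane == "roll-yaw") -1 / tcs$tau_roll else -1 / tcs$tau_pitch
  if (abs(h_yy - h_aa) < DEGENERACY_TOL) {
    stop_degenerate("coincident decay rates in the requested plane: tilt unreachable")
  }
  h <- tan(deg2rad(tilt)) * (h_yy - h_aa)
  if (plane == "roll-yaw") coupling_terms(h_yr = h) else coupling_terms(h_yp = h)
}

#' Percent increase in the false sensation of tilt
#'
#' Compares the misalignment of two models on the tangent scale:
#' `100 * (tan(gamma_after) / tan(gamma_before) - 1)`.  The tangent of the
#' misalignment angle is the transverse-to-vertical component ratio of the
#' subjective-up vector, so for a pure yaw-gain change from 1 to k the
#' increase is exactly `100 * (1/k - 1)` regardless of the baseline tilt.
#' An angle-ratio variant (`100 * (gamma_after/gamma_before - 1)`) is
#' available via `scale = "angle"`.
#'
#' @param before,after Non-degenerate `vs_model`s; `before` must have
#'   nonzero misalignment.
#' @param scale `"tangent"` (default) or `"angle"`.
#' @return Percent change (positive = exaggerated tilt).
#' @export
tilt_increase_pct <- function(before, after, scale = c("tangent", "angle")) {
  scale <- match.arg(scale)
  g_before <- misalignment_angle(before)
  g_after <- misalignment_angle(after)
  if (g_before <= 0) {
    stop_undefined_ratio("baseline model has zero misalignment: percent increase undefined")
  }
  if (scale == "tangent") {
    100 * (tan(deg2rad(g_after)) / tan(deg2rad(g_before)) - 1)
  } else {
    100 * (g_after / g_before - 1)
  }
}
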