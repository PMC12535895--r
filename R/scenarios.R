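#' Velocity storage attenuation interventions
#'
#' An intervention modifies exactly one aspect of a model:
#' * `set_yaw_time_constant` — replace the yaw time constant (value in
#'   seconds, > 0), i.e. change only \eqn{h_{yy}};
#' * `set_yaw_gain` — replace the yaw output gain k (value in (0, 1]);
#' * `scale_coupling` — multiply both `h_yr` and `h_yp` by a factor in
#'   `[0, 1]`; factor 0 is the idealized full optokinetic-stimulation
#'   remedy, which removes the pull entirely.
#'
#' The first two are absolute setters, not multipliers: applying the same
#' setter twice is idempotent.
#'
#' @param kind One of `"set_yaw_time_constant"`, `"set_yaw_gain"`,
#'   `"scale_coupling"`.
#' @param value Numeric value in the domain of its kind (see above).
#' @return An object of class `vs_intervention`.
#' @export
intervention <- function(kind = c("set_yaw_time_constant", "set_yaw_gain",
                                  "scale_coupling"),
                         value) {
  kind <- match.arg(kind)
  ok <- switch(kind,
    set_yaw_time_constant = is_scalar_number(value) && value > 0,
    set_yaw_gain = is_scalar_number(value) && value > 0 && value <= 1,
    scale_coupling = is_scalar_number(value) && value >= 0 && value <= 1
  )
  if (!ok) {
    stop_invalid(sprintf("value %s is outside the domain of intervention '%s'",
                         deparse(value), kind))
  }
  structure(list(kind = kind, value = as.numeric(value)),
            class = "vs_intervention")
}

#' Apply an intervention to a model
#'
#' Returns a new model with exactly one aspect changed; every other
#' parameter is untouched.
#'
#' @param model A `vs_model`.
#' @param iv A [intervention()] object.
#' @return A modified `vs_model`.
#' @examples
#' base <- build_pull(time_constants(5, 5, 18),
#'                    coupling_from_tilt(15, "roll-yaw", time_constants(5, 5, 18)))
#' apply_intervention(base, intervention("set_yaw_time_constant", 12))
#' @export
apply_intervention <- function(model, iv) {
  stopifnot(inherits(model, "vs_model"))
  if (!inherits(iv, "vs_intervention")) {
    stop_invalid("`iv` must be created with intervention()")
  }
  tc <- model$time_constants
  cp <- model$coupling
  switch(iv$kind,
    set_yaw_time_constant = vs_model(
      time_constants(tc$tau_roll, tc$tau_pitch, iv$value), cp,
      model$yaw_gain),
    set_yaw_gain = vs_model(tc, cp, iv$value),
    scale_coupling = vs_model(
      tc, coupling_terms(cp$h_yr * iv$value, cp$h_yp * iv$value),
      model$yaw_gain)
  )
}

#' Run an attenuation scenario
#'
#' Applies an intervention to a baseline model and gathers the quantities a
#' treatment-effect exploration needs: misalignment angle before and after,
#' the tangent-scale percent change, and the paired zero-input responses on
#' a shared time grid.
#'
#' @param baseline A non-degenerate `vs_model`.
#' @param iv A [intervention()] object.
#' @param grid Shared sample times (seconds, from 0); defaults to the
#'   figure-style 0-120 s at 4 Hz.
#' @param x0 Initial state for the paired trajectories, default
#'   `c(0, 0, 20)` deg/s (OKAN after yaw optokinetic stimulation).
#' @return An object of class `vs_scenario` with fields `baseline_model`,
#'   `modified_model`, `intervention`, `gamma_before`, `gamma_after`
#'   (degrees), `increase_pct` (tangent scale; `NA` when the baseline has
#'   no misalignment), and `trajectories` (list `baseline`, `modified`).
#' @examples
#' tcs <- time_constants(5, 5, 18)
#' base <- build_pull(tcs, coupling_from_tilt(15, "roll-yaw", tcs))
#' sc <- run_scenario(base, intervention("set_yaw_gain", 0.8))
#' sc$gamma_after      # 18.5 degrees to one decimal
#' sc$increase_pct     # 25 percent
#' @export
run_scenario <- function(baseline, iv, grid = default_time_grid(),
                         x0 = c(0, 0, 20)) {
  stopifnot(inherits(baseline, "vs_model"))
  modified <- apply_intervention(baseline, iv)
  gamma_before <- misalignment_angle(baseline)
  gamma_after <- misalignment_angle(modified)
  increase <- if (gamma_before > 0) {
    tilt_increase_pct(baseline, modified)
  } else {
    NA_real_
  }
  structure(
    list(baseline_model = baseline, modified_model = modified,
         intervention = iv,
         gamma_before = gamma_before, gamma_after = gamma_after,
         increase_pct = increase,
         trajectories = list(
           baseline = zero_input_response(baseline, x0, grid),
           modified = zero_input_response(modified, x0, grid))),
    class = "vs_scenario"
  )
}

#' @export
print.vs_scenario <- function(x, ...) {
  cat("Velocity storage attenuation scenario\n")
  cat(sprintf("  intervention: %s = %.4g\n", x$intervention$kind,
              x$intervention$value))
  cat(sprintf("  misalignment: %.4g deg -> %.4g deg\n",
              x$gamma_before, x$gamma_after))
  if (!is.na(x$increase_pct)) {
    cat(sprintf("  tilt increase (tangent scale): %.4g%%\n", x$increase_pct))
  }
  invisible(x)
}

#' Serialize a scenario to a JSON report plus trajectory CSVs
#'
#' Writes `<stem>.json` with the baseline model, the intervention, both
#' misalignment angles and the percent increase on both scales, plus
#' `<stem>_baseline.csv` / `<stem>_modified.csv` in the trajectory CSV
#' dialect.  Every number in the report is recomputable from the two
#' embedded models.
#'
#' @param scenario A `vs_scenario`.
#' @param stem Output path stem (directory must exist).
#' @return Invisibly, the three paths written.
#' @export
write_scenario_report <- function(scenario, stem) {
  stopifnot(inherits(scenario, "vs_scenario"))
  increase_angle <- if (scenario$gamma_before > 0) {
    tilt_increase_pct(scenario$baseline_model, scenario$modified_model,
                      scale = "angle")
  } else {
    NA_real_
  }
  report <- list(
    baseline = model_to_list(scenario$baseline_model),
    intervention = list(kind = scenario$intervention$kind,
                        value = scenario$intervention$value),
    gamma_before_deg = scenario$gamma_before,
    gamma_after_deg = scenario$gamma_after,
    increase_pct_tangent = scenario$increase_pct,
    increase_pct_angle = increase_angle
  )
  json_path <- paste0(stem, ".json")
  csv_base <- paste0(stem, "_baseline.csv")
  csv_mod <- paste0(stem, "_modified.csv")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  write_trajectory_csv(scenario$trajectories$baseline, csv_base)
  write_trajectory_csv(scenario$trajectories$modified, csv_mod)
  invisible(c(json = json_path, baseline_csv = csv_base,
              modified_csv = csv_mod))
}
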