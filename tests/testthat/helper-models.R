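# Shared fixtures: the canonical worked-example models and a generator of
# random valid models for property-style tests.

canonical_tcs <- function() time_constants(5, 5, 18)

# baseline backward-pull model: 15 degree designed tilt in the roll-yaw plane
baseline_pull_model <- function(tilt = 15) {
  tcs <- canonical_tcs()
  build_pull(tcs, coupling_from_tilt(tilt, "roll-yaw", tcs))
}

# random valid model in the canonical regime (yaw time constant longest);
# callers wrap in withr::with_seed for reproducibility
random_model <- function(with_gain = TRUE) {
  tr_ <- runif(1, 2, 10)
  tp_ <- runif(1, 2, 10)
  ty_ <- runif(1, max(tr_, tp_) + 1, 30)
  k <- if (with_gain) runif(1, 0.5, 1) else 1
  vs_model(time_constants(tr_, tp_, ty_),
           coupling_terms(runif(1, -0.1, 0.1), runif(1, -0.1, 0.1)),
           yaw_gain = k)
}

expect_orientation_equal <- function(u, expected, tol = 1e-12) {
  expect_equal(unname(as.numeric(u)), expected, tolerance = tol)
}
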