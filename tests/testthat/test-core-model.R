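test_that("normal construction gives a diagonal matrix of reciprocal rates", {
  H <- system_matrix(build_normal(time_constants(5, 5, 18)))
  expect_equal(unname(diag(H)), c(-0.2, -0.2, -1 / 18))
  expect_equal(round(diag(H)[["yaw"]], 4), -0.0556)
  expect_true(all(H[upper.tri(H)] == 0) && all(H[lower.tri(H)] == 0))

  expect_equal(unname(diag(system_matrix(build_normal(time_constants(1, 1, 1))))),
               c(-1, -1, -1))
  expect_equal(round(-1 / 12, 4), -0.0833)  # yaw rate after tau_yaw -> 12 s
})

test_that("time constants are validated and the canonical regime is detectable", {
  expect_error(time_constants(-5, 5, 18), class = "vstorage_invalid_parameter")
  expect_error(time_constants(5, 0, 18), class = "vstorage_invalid_parameter")
  expect_error(time_constants(5, 5, Inf), class = "vstorage_invalid_parameter")
  expect_true(is_canonical_regime(time_constants(5, 5, 18)))
  expect_false(is_canonical_regime(time_constants(5, 20, 18)))
  expect_error(vs_model(time_constants(5, 5, 18), coupling_terms(), yaw_gain = 1.2),
               class = "vstorage_invalid_parameter")
  expect_error(vs_model(time_constants(5, 5, 18), coupling_terms(), yaw_gain = 0),
               class = "vstorage_invalid_parameter")
})

test_that("pull construction places coupling only in the yaw column", {
  tcs <- time_constants(5, 5, 18)
  H1 <- system_matrix(build_pull(tcs, coupling_terms(h_yr = 0.04)))
  expect_equal(H1["roll", "yaw"], 0.04)
  expect_equal(H1["pitch", "yaw"], 0)
  off <- H1; diag(off) <- 0; off["roll", "yaw"] <- 0
  expect_true(all(off == 0))

  H2 <- system_matrix(build_pull(tcs, coupling_terms(h_yp = 0.04)))
  expect_equal(H2["pitch", "yaw"], 0.04)
  expect_equal(H2["roll", "yaw"], 0)

  expect_identical(build_pull(tcs, coupling_terms(0, 0)), build_normal(tcs))
})

test_that("subjective up follows the closed-form yaw eigenvector, gain-scaled", {
  tcs <- time_constants(5, 5, 18)
  expect_orientation_equal(subjective_up(vs_model(tcs, yaw_gain = 0.7)),
                           c(0, 0, 0.7))
  cp <- coupling_from_tilt(15, "roll-yaw", tcs)
  up <- subjective_up(build_pull(tcs, cp))
  expect_equal(unname(as.numeric(up)), c(tan(15 * pi / 180), 0, 1),
               tolerance = 1e-12)
  up_k <- subjective_up(vs_model(tcs, cp, yaw_gain = 0.8))
  expect_equal(unname(as.numeric(up_k)), c(tan(15 * pi / 180), 0, 0.8),
               tolerance = 1e-12)
})

test_that("eigenbasis satisfies the eigen-equation for random models", {
  m <- baseline_pull_model()
  basis <- eigenbasis(m)
  expect_orientation_equal(basis$u_roll, c(1, 0, 0))
  expect_orientation_equal(basis$u_pitch, c(0, 1, 0))
  expect_equal(basis$u_yaw[["yaw"]], 1)  # gain not applied here

  withr::with_seed(1203, {
    worst <- 0
    for (i in 1:1000) {
      mod <- random_model()
      H <- system_matrix(mod)
      h <- decay_rates(mod)
      b <- eigenbasis(mod)
      for (ax in c("roll", "pitch", "yaw")) {
        u <- as.numeric(b[[paste0("u_", ax)]])
        worst <- max(worst, max(abs(H %*% u - h[[ax]] * u)))
      }
    }
    expect_lt(worst, 1e-10)
  })
})

test_that("degenerate eigenstructure raises a classed error", {
  tcs <- time_constants(5, 5, 5)  # coincident rates
  m <- build_pull(tcs, coupling_terms(h_yr = 0.04))
  expect_error(subjective_up(m), class = "vstorage_degenerate_error")
  expect_error(eigenbasis(m), class = "vstorage_degenerate_error")
  expect_error(misalignment_angle(m), class = "vstorage_degenerate_error")
  # coincident rates with zero coupling are fine (diagonal system)
  expect_equal(misalignment_angle(build_normal(tcs)), 0)
})

test_that("misalignment angle reproduces the worked-example chain", {
  tcs <- time_constants(5, 5, 18)
  cp <- coupling_from_tilt(15, "roll-yaw", tcs)

  # zero coupling is neutral for any gain
  expect_equal(misalignment_angle(vs_model(tcs, yaw_gain = 0.6)), 0)

  # yaw time-constant reduction 18 s -> 12 s: 15 deg -> 18.4 deg
  faster <- vs_model(time_constants(5, 5, 12), cp, 1)
  expect_equal(round(misalignment_angle(faster), 1), 18.4)

  # yaw gain reduction k = 0.8: 15 deg -> 18.5 deg
  lowgain <- vs_model(tcs, cp, yaw_gain = 0.8)
  expect_equal(round(misalignment_angle(lowgain), 1), 18.5)
})

test_that("coupling_from_tilt inverts the misalignment angle", {
  tcs <- time_constants(5, 5, 18)
  expect_identical(coupling_from_tilt(0, "roll-yaw", tcs),
                   coupling_terms(0, 0))
  cp <- coupling_from_tilt(15, "roll-yaw", tcs)
  expect_equal(cp$h_yr, tan(15 * pi / 180) * (-1 / 18 + 1 / 5),
               tolerance = 1e-12)  # about 0.0387 per-second
  expect_equal(round(cp$h_yr, 4), 0.0387)
  expect_equal(cp$h_yp, 0)
  expect_error(coupling_from_tilt(90, "roll-yaw", tcs),
               class = "vstorage_invalid_parameter")

  # round trip across the tilt grid and both planes
  for (g in c(1, 5, 15, 30, 45, 60)) {
    for (pl in c("roll-yaw", "pitch-yaw")) {
      m <- build_pull(tcs, coupling_from_tilt(g, pl, tcs))
      expect_lt(abs(misalignment_angle(m) - g), 1e-9)
    }
  }
  # and across yaw time constants
  for (ty in seq(8, 30, by = 2)) {
    tc2 <- time_constants(5, 5, ty)
    m <- build_pull(tc2, coupling_from_tilt(20, "roll-yaw", tc2))
    expect_lt(abs(misalignment_angle(m) - 20), 1e-9)
  }
})

test_that("tilt increase is measured on the tangent scale", {
  base <- baseline_pull_model(15)
  after_tc <- apply_intervention(base, intervention("set_yaw_time_constant", 12))
  after_k <- apply_intervention(base, intervention("set_yaw_gain", 0.8))

  expect_equal(round(tilt_increase_pct(base, after_tc)), 24)
  expect_equal(round(tilt_increase_pct(base, after_k)), 25)
  # pure gain change: exactly 100 * (1/k - 1), independent of baseline
  expect_equal(tilt_increase_pct(base, after_k), 100 * (1 / 0.8 - 1),
               tolerance = 1e-10)
  small <- baseline_pull_model(3)
  expect_equal(round(tilt_increase_pct(
    small, apply_intervention(small, intervention("set_yaw_gain", 0.8)))), 25)

  # angle-scale variant is exposed and differs
  expect_lt(tilt_increase_pct(base, after_tc, scale = "angle"),
            tilt_increase_pct(base, after_tc))

  expect_error(tilt_increase_pct(build_normal(canonical_tcs()), after_k),
               class = "vstorage_undefined_ratio")
})

test_that("gain-change tangent ratio is exactly 1/k for random pull models", {
  withr::with_seed(77, {
    for (i in 1:50) {
      m <- random_model(with_gain = FALSE)
      if (misalignment_angle(m) == 0) next
      k <- runif(1, 0.2, 0.99)
      mk <- apply_intervention(m, intervention("set_yaw_gain", k))
      ratio <- tan(misalignment_angle(mk) * pi / 180) /
        tan(misalignment_angle(m) * pi / 180)
      expect_equal(ratio, 1 / k, tolerance = 1e-10)
    }
  })
})

test_that("misalignment grows as tau_yaw shrinks toward tau_roll and as k drops", {
  tcs <- time_constants(5, 5, 18)
  cp <- coupling_from_tilt(10, "roll-yaw", tcs)
  gammas_tc <- vapply(seq(18, 6, by = -2), function(ty) {
    misalignment_angle(vs_model(time_constants(5, 5, ty), cp, 1))
  }, numeric(1))
  expect_true(all(diff(gammas_tc) > 0))

  gammas_k <- vapply(seq(1, 0.2, by = -0.1), function(k) {
    misalignment_angle(vs_model(tcs, cp, yaw_gain = k))
  }, numeric(1))
  expect_true(all(diff(gammas_k) > 0))
})

test_that("model JSON serialization round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- vs_model(time_constants(5.3, 4.7, 17.9),
                coupling_terms(0.03870377224005106, -0.011),
                yaw_gain = 0.85)
  model_to_json(m, path)
  m2 <- model_from_json(path)
  expect_equal(m2, m)
  # unknown fields are rejected
  writeLines('{"tau_roll_s": 5, "bogus": 1}', path)
  expect_error(model_from_json(path), class = "vstorage_invalid_parameter")
})
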