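test_that("Fourier phase extraction matches a least-squares cosine fit", {
  cfg <- sweep_config()
  phis <- c(-2.9, -1.3, 0, 0.4, 1.7, 3.0)
  for (k in c(2, 3)) {
    for (phi0 in phis) {
      x <- synth_cosine(phi0, k, n = 1000)
      got <- extract_phase(x, cfg)
      oracle <- fit_cosine_phase(x, k)
      expect_lt(abs(wrap_pi(got$phase - oracle)), 1e-9)
      expect_lt(abs(wrap_pi(got$phase - phi0)), 1e-9)
      expect_equal(got$bin, k)
    }
  }
})

test_that("phase extraction is 2*pi periodic and flags flat traces", {
  cfg <- sweep_config()
  x1 <- synth_cosine(0.8, 2)
  x2 <- synth_cosine(0.8 + 2 * pi, 2)  # shifted by exactly one FSR
  expect_equal(extract_phase(x1, cfg)$phase, extract_phase(x2, cfg)$phase,
               tolerance = 1e-12)
  flat <- extract_phase(rep(0.6, 1000), cfg)
  expect_true(flat$low_contrast)
  expect_error(extract_phase(rep(0.5, 8)), "16 samples")
  expect_error(extract_phase(c(rep(0.5, 999), NA), cfg), "non-finite")
})

test_that("static zero-noise stream tracks a flat zero sensorgram", {
  o <- config_objects(default_config())
  raw <- simulate_cycles(o$layout, NULL, o$sweep, noise_budget(0, 0, 0),
                         n_cycles = 50, seed = 1)
  sg <- track_sensorgram(raw, c(0, 5))
  expect_true(all(abs(sg$shift_pm) < 1e-9))
  expect_false(any(sg$unwrap_suspect))
})

test_that("a 2-FSR opd ramp unwraps to 2 FSR of wavelength shift", {
  o <- config_objects(default_config())
  dur <- 60
  st <- state_with_trajectory(function(t) 3000 * t / dur, dur)
  raw <- simulate_cycles(o$layout, st, o$sweep, noise_budget(0, 0, 0),
                         n_cycles = 600, seed = 1)
  sg <- track_sensorgram(raw, baseline_window = NULL)
  total <- unname(sg$shift_pm[600, 1] - sg$shift_pm[1, 1])
  expected <- 3000 * raw$time_s[600] / dur
  # wrapped per-cycle phases cross pi repeatedly; unwrapping restores the ramp
  expect_gt(diff(range(sg$phase_rad[, 1])), 3.5 * pi)
  expect_equal(total, expected, tolerance = 5e-4)
})

test_that("an imposed 100 pm step is recovered within the noise", {
  o <- config_objects(default_config())
  st <- state_with_trajectory(function(t) ifelse(t >= 30, 100, 0), 60)
  raw <- simulate_cycles(o$layout, st, o$sweep, noise_budget(),
                         n_cycles = 600, seed = 4)
  sg <- track_sensorgram(raw, c(0, 25))
  before <- mean(sg$shift_pm[raw$time_s < 29, 1])
  after <- mean(sg$shift_pm[raw$time_s > 31, 1])
  expect_equal(after - before, 100, tolerance = 0.01)
})

test_that("differential referencing cancels common mode and keeps the specific term", {
  o <- config_objects(default_config())
  st <- run_assay_program(
    list(flow_step("b", 10),
         flow_step("bulk+bind", 50, bulk_index_delta_riu = 1e-4)),
    dt_s = 0.1, transport_delay_s = 2, mixing_tau_s = 2)
  binding <- 40 * pmax(st$time_s - 10, 0) / 50
  st$surface_shift_pm[, 1] <- binding  # specific binding on channel 1 only
  raw <- simulate_cycles(o$layout, st, o$sweep, noise_budget(0, 0, 0),
                         n_cycles = 600, seed = 1)
  sg <- track_sensorgram(raw, c(0, 5))
  # identical channels difference to zero
  d22 <- differential_signal(sg, 2, 2)
  expect_true(all(abs(d22$shift_pm) < 1e-9))
  # the ~500 pm common bulk excursion cancels, leaving the binding ramp
  d12 <- differential_signal(sg, 1, 2)
  expect_gt(max(abs(sg$shift_pm[, 2])), 400)
  imposed <- approx(st$time_s, binding, raw$time_s)$y
  expect_equal(as.vector(d12$shift_pm), imposed, tolerance = 0.01)
  expect_equal(d12$referencing, list(signal = "ch1", reference = "ch2"))
  expect_error(differential_signal(sg, 1, 12), "not present")
})

test_that("resolution estimation guards its baseline window", {
  o <- config_objects(default_config())
  raw <- simulate_cycles(o$layout, NULL, o$sweep, noise_budget(0, 0, 0),
                         n_cycles = 100, seed = 1)
  sg <- track_sensorgram(raw, NULL)
  expect_equal(unname(estimate_resolution(sg, c(0, 10))), rep(0, 8),
               tolerance = 1e-9)
  expect_error(estimate_resolution(sg, c(0, 2)), "30 cycles")
  prog <- list(flow_step("a", 5), flow_step("b", 5))
  expect_error(estimate_resolution(sg, c(0, 10), program = prog),
               "liquid change")
})

test_that("known injected jitter is recovered as 3 sigma and scales the LoD linearly", {
  o <- config_objects(default_config())
  raw1 <- simulate_cycles(o$layout, NULL, o$sweep, noise_budget(0, 0.25, 0),
                          n_cycles = 300, seed = 9)
  sg1 <- track_sensorgram(raw1, NULL)
  r1 <- estimate_resolution(sg1, c(0, 30))[[1]]
  expect_equal(r1, 0.75, tolerance = 0.12)
  # doubling every component doubles the estimated LoD (same seed)
  raw2 <- simulate_cycles(o$layout, NULL, o$sweep, noise_budget(0, 0.5, 0),
                          n_cycles = 300, seed = 9)
  sg2 <- track_sensorgram(raw2, NULL)
  lod1 <- estimate_lod(sg1, c(0, 30), 5000)
  lod2 <- estimate_lod(sg2, c(0, 30), 5000)
  expect_equal(lod2 / lod1, 2, tolerance = 0.02)
})

test_that("step analysis finds plateaus, levels and response delays", {
  # synthetic sensorgram: two clean steps with first-order edges
  t <- seq(0, 150, by = 0.1)
  tau <- 2
  y <- ifelse(t < 50, 0, 200 * (1 - exp(-(t - 50) / tau)))
  y <- ifelse(t < 100, y, 200 * exp(-(t - 100) / tau))
  sg <- structure(list(time_s = t,
                       shift_pm = matrix(y, ncol = 1,
                                         dimnames = list(NULL, "ch1")),
                       phase_rad = matrix(0, length(t), 1),
                       fsr_pm = 1500, units = "pm", roles = "sensing",
                       baseline_window = NULL, referencing = NULL,
                       low_contrast_frac = 0, unwrap_suspect = FALSE),
                  class = "sensorgram")
  prog <- list(flow_step("A", 50), flow_step("B", 50), flow_step("C", 50))
  thr <- 20
  sa <- analyze_steps(sg, prog, channel = 1, min_threshold_pm = thr)
  expect_equal(sa$plateau_pm, c(0, 200, 0), tolerance = 1e-3)
  expect_equal(sa$level_diff_pm[2:3], c(200, -200), tolerance = 1e-3)
  expect_true(all(sa$settled))
  # analytic threshold crossing of the exponential edge:
  # delay = tau * log(amp / (amp - thr)), quantized up to the sample grid
  delay_true <- tau * log(200 / (200 - thr))
  expect_gte(sa$response_delay_s[2], delay_true - 1e-9)
  expect_lte(sa$response_delay_s[2], delay_true + 0.11)
  # slower edges are detected later
  y_slow <- ifelse(t < 50, 0, 200 * (1 - exp(-(t - 50) / (5 * tau))))
  sg$shift_pm[, 1] <- ifelse(t < 100, y_slow,
                             y_slow[max(which(t < 100))] *
                               exp(-(t - 100) / (5 * tau)))
  sa_slow <- analyze_steps(sg, prog, channel = 1, min_threshold_pm = thr)
  expect_gt(sa_slow$response_delay_s[2], sa$response_delay_s[2])
  # zero-amplitude steps: no detections
  sg$shift_pm[, 1] <- 0
  sa0 <- analyze_steps(sg, prog, channel = 1)
  expect_true(all(is.na(sa0$detect_time_s[2:3])))
})

test_that("QC flags fire only when the quiet channels move", {
  o <- config_objects(default_config())
  raw <- simulate_cycles(o$layout, NULL, o$sweep, noise_budget(),
                         n_cycles = 100, seed = 2)
  sg <- track_sensorgram(raw, c(0, 10))
  expect_false(any(qc_check(sg, bound_pm = 25)))
  sg$shift_pm[, 8] <- sg$shift_pm[, 8] + 100
  expect_true(qc_check(sg, bound_pm = 25)[["ch8"]])
})
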