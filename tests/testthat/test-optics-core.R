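test_that("transfer function is the two-beam interference law", {
  expect_equal(transfer_phase(0), 1.0)
  expect_equal(transfer_phase(pi), 0.0, tolerance = 1e-12)
  expect_equal(transfer_phase(pi / 2), 0.5)
  expect_error(transfer_phase(NaN), "finite")
  # bounded and 2*pi-periodic over random phases
  set.seed(42)
  phis <- stats::runif(200, -50, 50)
  tt <- transfer_phase(phis)
  expect_true(all(tt >= 0 & tt <= 1))
  expect_equal(tt, transfer_phase(phis + 2 * pi), tolerance = 1e-9)
})

test_that("wavelength-domain transfer matches the phase-domain form", {
  expect_equal(transfer_wavelength(850, 0), 1.0)
  expect_equal(transfer_wavelength(850, 425), 0.0, tolerance = 1e-12)
  expect_equal(transfer_wavelength(850, 212.5), 0.5, tolerance = 1e-12)
  expect_error(transfer_wavelength(-1, 100), "positive")
  set.seed(7)
  lam <- stats::runif(50, 800, 900)
  opd <- stats::runif(50, 0, 1e6)
  expect_identical(transfer_wavelength(lam, opd),
                   transfer_phase(2 * pi * opd / lam))
})

test_that("group index corrects the effective index for dispersion", {
  expect_equal(group_index(mode_dispersion(1.55, 0, 850)), 1.55)
  expect_equal(group_index(mode_dispersion(1.55, -5e-4, 850)), 1.975)
  expect_equal(group_index(mode_dispersion(2.0, 1e-3, 850)), 1.15)
  expect_error(mode_dispersion(n_eff = 0.9), "> 1")
})

test_that("free spectral range follows lambda0^2 / (n_g L)", {
  expect_equal(free_spectral_range(850, 2.0, 0.2408), 1500, tolerance = 1e-3)
  f1 <- free_spectral_range(850, 2.0, 0.2)
  expect_equal(free_spectral_range(850, 2.0, 0.4), f1 / 2)
  expect_equal(free_spectral_range(1700, 2.0, 0.2), 4 * f1)
  expect_error(free_spectral_range(850, -1, 0.2), "positive")
  expect_error(free_spectral_range(0, 2, 0.2), "positive")
})

test_that("sensitivity follows L * FSR / lambda_res", {
  expect_equal(amzi_sensitivity(12.5, 1500, 850), 22058.8235294, tolerance = 1e-9)
  expect_equal(amzi_sensitivity(0.85, 1000, 850), 1000)
  s <- amzi_sensitivity(10, 1000, 850)
  expect_equal(amzi_sensitivity(10, 500, 850), s / 2)
  expect_equal(amzi_sensitivity(20, 1000, 850), 2 * s)
  expect_error(amzi_sensitivity(0, 1000, 850), "positive")
})

test_that("FSR and sensitivity chain scales linearly in L, inversely in ng*Lasym", {
  set.seed(11)
  for (i in 1:20) {
    L <- stats::runif(1, 1, 30)
    ng <- stats::runif(1, 1.5, 2.5)
    La <- stats::runif(1, 0.05, 1)
    s <- amzi_sensitivity(L, free_spectral_range(850, ng, La), 850)
    expect_equal(amzi_sensitivity(2 * L, free_spectral_range(850, ng, La), 850),
                 2 * s, tolerance = 1e-12)
    expect_equal(amzi_sensitivity(L, free_spectral_range(850, 2 * ng, La), 850),
                 s / 2, tolerance = 1e-12)
    expect_equal(amzi_sensitivity(L, free_spectral_range(850, ng, 2 * La), 850),
                 s / 2, tolerance = 1e-12)
  }
})

test_that("noise components compose by root-sum-square", {
  expect_equal(measurement_noise_3sigma(noise_budget(0.5, 0, 0)), 1.5)
  expect_equal(measurement_noise_3sigma(noise_budget(0.1, 0.2, 0.2)), 0.9)
  expect_equal(measurement_noise_3sigma(noise_budget(0, 0, 0)), 0)
  # composed 3-sigma dominates each individual 3*component
  set.seed(5)
  for (i in 1:20) {
    b <- noise_budget(stats::runif(1), stats::runif(1), stats::runif(1))
    tot <- measurement_noise_3sigma(b)
    expect_gte(tot, 3 * b$sigma_ampl_pm)
    expect_gte(tot, 3 * b$sigma_spect_pm)
    expect_gte(tot, 3 * b$sigma_temp_pm)
  }
})

test_that("limit of detection is R/S and monotone in every noise component", {
  expect_equal(limit_of_detection(0.8, 5000), 1.6e-7)
  expect_equal(limit_of_detection(1.6, 5000), 3.2e-7)
  expect_equal(limit_of_detection(1.0, 10000), 1.0e-7)
  expect_error(limit_of_detection(0.8, 0), "positive")
  b0 <- noise_budget(0.1, 0.2, 0.15)
  lod0 <- limit_of_detection(measurement_noise_3sigma(b0), 5000)
  for (comp in 1:3) {
    args <- list(0.1, 0.2, 0.15)
    args[[comp]] <- args[[comp]] + 0.05
    b1 <- do.call(noise_budget, args)
    expect_gt(limit_of_detection(measurement_noise_3sigma(b1), 5000), lod0)
  }
})

test_that("phase and wavelength-shift conversions round-trip", {
  expect_equal(phase_to_wavelength_shift(2 * pi, 1500), 1500)
  expect_equal(phase_to_wavelength_shift(0, 1500), 0)
  expect_equal(phase_to_wavelength_shift(pi, 1500), 750)
  set.seed(3)
  phi <- stats::runif(100, -10, 10)
  back <- wavelength_shift_to_phase(phase_to_wavelength_shift(phi, 1500), 1500)
  expect_equal(back, phi, tolerance = 1e-12)
})

test_that("default design reproduces the device figures", {
  d <- amzi_design()
  expect_equal(d$fsr_pm, 1500, tolerance = 1e-9)
  expect_equal(d$sensitivity_nm_riu, 5000)  # pinned bulk sensitivity
  expect_equal(d$sensitivity_intrinsic_nm_riu, 22058.82, tolerance = 1e-6)
  pf <- performance_figure(d, noise_budget())
  expect_equal(pf$resolution_pm, 0.8, tolerance = 1e-12)
  expect_equal(pf$lod_riu, pf$resolution_pm / 1000 / pf$sensitivity_nm_riu)
  expect_error(amzi_design(arm_length_mm = -1), "positive")
})
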