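test_that("Langmuir occupancy has the correct limits and stays in [0,1]", {
  m <- binding_model(k_on = 1e5, k_off = 1e-4)
  # no analyte, clean surface: nothing binds
  expect_equal(langmuir_occupancy(0, m, c(0, 10, 1e5)), rep(0, 3))
  # equilibrium isotherm c / (c + KD)
  kd <- m$k_off / m$k_on
  for (c_m in c(1e-10, 1e-9, 1e-8)) {
    expect_equal(langmuir_occupancy(c_m, m, 1e9), c_m / (c_m + kd),
                 tolerance = 1e-9)
  }
  # irreversible binding saturates at full occupancy
  m_irr <- binding_model(k_on = 1e5, k_off = 0)
  expect_equal(langmuir_occupancy(1e-9, m_irr, 1e9), 1, tolerance = 1e-9)
  expect_error(langmuir_occupancy(-1e-9, m, 1), "non-negative")
  # bounded for random inputs
  set.seed(8)
  for (i in 1:50) {
    th <- langmuir_occupancy(stats::runif(1, 0, 1e-6),
                             binding_model(k_on = 10^stats::runif(1, 3, 7),
                                           k_off = 10^stats::runif(1, -6, -2)),
                             stats::runif(1, 0, 1e4),
                             theta0 = stats::runif(1))
    expect_true(th >= 0 && th <= 1)
  }
})

test_that("equilibrium isotherm is monotone increasing and saturating", {
  m <- binding_model()
  conc <- 10^seq(-12, -5, length.out = 30)
  theta_eq <- vapply(conc, function(c_m) langmuir_occupancy(c_m, m, 1e9),
                     numeric(1))
  expect_true(all(diff(theta_eq) > 0))
  expect_lt(theta_eq[30], 1)
  expect_gt(theta_eq[30], 0.99)
})

test_that("buffer-only programs produce zero surface signal and tracked bulk", {
  prog <- list(flow_step("PBS", 30),
               flow_step("PBS-lowNaCl", 60, bulk_index_delta_riu = -4e-4),
               flow_step("PBS", 60))
  st <- run_assay_program(prog, dt_s = 0.1, transport_delay_s = 5,
                          mixing_tau_s = 2)
  expect_true(all(st$surface_shift_pm == 0))
  # bulk approaches each target as a first-order response
  i_end2 <- max(which(st$time_s <= 90))
  expect_equal(st$bulk_index_riu[i_end2], -4e-4, tolerance = 1e-2)
  expect_equal(st$bulk_index_riu[length(st$time_s)], 0, tolerance = 4e-6)
  # edges are monotone after the transport delay
  seg <- st$bulk_index_riu[st$time_s > 35 & st$time_s < 90]
  expect_true(all(diff(seg) <= 1e-12))
})

test_that("a cognate analyte step produces a rising, capacity-bounded sensorgram", {
  models <- default_binding_models()
  prog <- list(flow_step("buffer", 30),
               flow_step("sample", 600,
                         analyte_concentrations_ng_ml = c(TGFBI = 1000)))
  st <- run_assay_program(prog, dt_s = 0.1)
  y <- st$surface_shift_pm[, 1]  # anti-TGFBI channel
  expect_true(all(diff(y[st$time_s >= 30]) >= -1e-9))
  expect_lt(max(y), models$TGFBI$surface_capacity_shift_pm)
  expect_gt(y[length(y)], 100)
  # non-cognate antibody channels see nothing: the nonspecific term is
  # common to both balanced arms and cancels
  expect_true(all(abs(st$surface_shift_pm[, c(5, 6)]) < 1e-9))
  # unspotted controls accumulate only the signed drift while protein flows
  expect_true(all(st$surface_shift_pm[, c(2, 4)] <= 0))
})

test_that("POSTN cross-reactivity switches on above 1 ug/mL", {
  below <- run_assay_program(
    list(flow_step("s", 300, analyte_concentrations_ng_ml = c(POSTN = 800))),
    dt_s = 0.5)
  above <- run_assay_program(
    list(flow_step("s", 300, analyte_concentrations_ng_ml = c(POSTN = 2000))),
    dt_s = 0.5)
  # anti-TGFBI channel 1: clean below threshold, nonzero above
  expect_lt(max(abs(below$surface_shift_pm[, 1])), 1e-9)
  expect_gt(above$surface_shift_pm[nrow(above$surface_shift_pm), 1], 1)
})

test_that("program validation enforces bookkeeping and instrument limits", {
  prog <- list(flow_step("a", 75, flow_rate_ul_min = 48))
  v <- validate_program(prog)
  expect_equal(v$volume_ul, 60)  # 75 s at 48 uL/min
  bad <- list(flow_step("a", 60, flow_rate_ul_min = 300))
  expect_silent(validate_program(bad))
  expect_error(validate_program(bad, instrument_mode = TRUE), "4-200")
  expect_error(validate_program(list()), "empty")
  expect_error(flow_step("a", -5), "positive")
  expect_error(flow_step("a", 10, analyte_concentrations_ng_ml = c(X = -1)),
               ">= 0")
  expect_error(run_assay_program(
    list(flow_step("s", 10, analyte_concentrations_ng_ml = c(UNKNOWN = 5)))),
    "unknown analyte")
  expect_error(run_assay_program(list(flow_step("s", 10)), dt_s = 3),
               "divide")
})

test_that("serum exposure gives positive spotted and negative control traces", {
  st <- serum_sample_state(serum_fraction_pct = 10, dt_s = 0.5)
  fin <- st$surface_shift_pm[nrow(st$surface_shift_pm), ]
  expect_true(all(fin[c(1, 3, 5, 6)] > 0))   # antibody-spotted
  expect_true(all(fin[c(2, 4)] < 0))         # unspotted BSA controls
  # control trace is monotone negative during the sample step
  ctrl <- st$surface_shift_pm[st$time_s > 120, 2]
  expect_true(all(diff(ctrl) <= 1e-12))
  # zero serum and zero analyte reduces to a plain buffer run: no signal
  st0 <- serum_sample_state(serum_fraction_pct = 0, dt_s = 0.5,
                            analyte_concentrations_ng_ml =
                              c(TGFBI = 0, POSTN = 0))
  expect_true(all(st0$surface_shift_pm == 0))
  expect_error(serum_sample_state(serum_fraction_pct = 150), "\\[0, 100\\]")
})
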