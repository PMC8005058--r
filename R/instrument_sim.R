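# Swept-source acquisition chain: a current-tuned VCSEL driven by a 10 Hz
# sawtooth sweeps the wavelength across the aMZI fringes once per cycle; the
# eight photodiode channels record sine-like interferograms at 1000 samples
# per cycle (10 kHz per photodiode). Noise enters as per-sample intensity
# noise (amplitude), per-cycle common-mode wavelength jitter (spectral) and a
# slow common-mode drift of the fringe position (temperature).

#' Wavelength-sweep configuration
#'
#' @param sweep_rate_hz Sawtooth repetition rate, Hz.
#' @param samples_per_cycle Samples recorded per photodiode per cycle (>= 16).
#' @param sweep_span_pm Wavelength span covered by one ramp, pm. The default,
#'   two free spectral ranges of the standard design, puts two full fringes in
#'   every record for robust Fourier phase extraction.
#' @param center_wavelength_nm Sweep center wavelength, nm.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(sweep_rate_hz = 10,
                         samples_per_cycle = 1000,
                         sweep_span_pm = 3000,
                         center_wavelength_nm = 850) {
  .check_positive(sweep_rate_hz, "sweep_rate_hz")
  .check_positive(sweep_span_pm, "sweep_span_pm")
  .check_positive(center_wavelength_nm, "center_wavelength_nm")
  if (samples_per_cycle < 16) {
    stop("'samples_per_cycle' must be >= 16", call. = FALSE)
  }
  structure(list(sweep_rate_hz = sweep_rate_hz,
                 samples_per_cycle = as.integer(samples_per_cycle),
                 sweep_span_pm = sweep_span_pm,
                 center_wavelength_nm = center_wavelength_nm),
            class = "sweep_config")
}

#' Per-photodiode sampling rate
#'
#' `sweep_rate * samples_per_cycle`; the default 10 Hz x 1000 samples gives
#' 10 kHz per photodiode.
#'
#' @param cfg A [sweep_config()].
#' @return Sampling rate in Hz.
#' @export
sample_rate_hz <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  cfg$sweep_rate_hz * cfg$samples_per_cycle
}

#' Wavelength ramp of one sweep cycle
#'
#' Linear ramp from `center - span/2` to `center + span/2`, strictly
#' increasing; the middle of the ramp sits exactly at the center wavelength.
#'
#' @param cfg A [sweep_config()].
#' @return Numeric vector of wavelengths (nm), length `samples_per_cycle`.
#' @export
wavelength_ramp <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  n <- cfg$samples_per_cycle
  span_nm <- cfg$sweep_span_pm / PM_PER_NM
  cfg$center_wavelength_nm + span_nm * (seq_len(n) - 1) / (n - 1) - span_nm / 2
}

#' Eight-channel chip layout
#'
#' One input split on-chip into 8 outputs, each feeding one aMZI: six sensing
#' interferometers, one low-sensitivity bulk-index monitor and one sealed
#' internal reference. Each channel carries its own [amzi_design()]; the bulk
#' monitor gets a reduced pinned sensitivity and the internal reference does
#' not see the sample at all.
#'
#' @param sensing_design [amzi_design()] used for the six sensing channels.
#' @param bulk_sensitivity_nm_riu Pinned sensitivity of the bulk monitor.
#' @return An object of class `chip_layout` with `n_outputs = 8`, per-channel
#'   `roles` and `designs`, and `bulk_response_nm_riu` (per-channel response
#'   to a bulk-index change).
#' @export
chip_layout <- function(sensing_design = amzi_design(),
                        bulk_sensitivity_nm_riu = 500) {
  stopifnot(inherits(sensing_design, "amzi_design"))
  .check_positive(bulk_sensitivity_nm_riu, "bulk_sensitivity_nm_riu")
  roles <- c(rep("sensing", 6), "bulk_low_sensitivity", "internal_reference")
  bulk_design <- amzi_design(
    arm_length_mm = sensing_design$arm_length_mm,
    asym_length_mm = sensing_design$asym_length_mm,
    lambda_res_nm = sensing_design$lambda_res_nm,
    mode = sensing_design$mode,
    sensitivity_override_nm_riu = bulk_sensitivity_nm_riu)
  designs <- c(rep(list(sensing_design), 6), list(bulk_design),
               list(sensing_design))
  structure(list(n_outputs = 8L,
                 roles = roles,
                 designs = designs,
                 bulk_response_nm_riu = c(
                   rep(sensing_design$sensitivity_nm_riu, 6),
                   bulk_sensitivity_nm_riu, 0)),
            class = "chip_layout")
}

#' @export
print.chip_layout <- function(x, ...) {
  cat("Photonic chip layout: 1 input -> 8 outputs\n")
  for (i in seq_len(x$n_outputs)) {
    cat(sprintf("  ch%-2d %-22s FSR %.4g pm, S %.4g nm/RIU\n",
                i, x$roles[i], x$designs[[i]]$fsr_pm,
                if (i <= 6 || x$roles[i] == "bulk_low_sensitivity")
                  x$bulk_response_nm_riu[i] else 0))
  }
  invisible(x)
}

# Wavelength-shift trajectory (pm) of every chip output at given times,
# interpolated from an assay state. Sensing channels see their net surface
# signal plus the full bulk response; the bulk monitor sees only bulk; the
# sealed reference sees nothing.
channel_shift_pm <- function(layout, state, t_s) {
  stopifnot(inherits(layout, "chip_layout"))
  shifts <- matrix(0, length(t_s), layout$n_outputs)
  if (is.null(state)) return(shifts)
  stopifnot(inherits(state, "analyte_state"))
  bulk <- stats::approx(state$time_s, state$bulk_index_riu, t_s, rule = 2)$y
  for (ch in seq_len(layout$n_outputs)) {
    s <- bulk * layout$bulk_response_nm_riu[ch] * PM_PER_NM
    if (layout$roles[ch] == "sensing") {
      s <- s + stats::approx(state$time_s, state$surface_shift_pm[, ch],
                             t_s, rule = 2)$y
    }
    shifts[, ch] <- s
  }
  shifts
}

# Intensity sd that makes additive white detector noise demodulate to a
# fringe-position sd of sigma_pm: sigma_I = sigma_phi * a * sqrt(N/2), with
# a the fringe amplitude and N the samples per cycle (first-order inverse of
# the DFT phase-error variance for a sinusoid in white noise).
amplitude_noise_intensity_sd <- function(sigma_pm, fsr_pm, fringe_amplitude,
                                         samples_per_cycle) {
  sigma_phi <- wavelength_shift_to_phase(sigma_pm, fsr_pm)
  sigma_phi * fringe_amplitude * sqrt(samples_per_cycle / 2)
}

#' Simulate raw interferogram sweep cycles
#'
#' Produces the per-cycle, per-photodiode interferograms of the acquisition
#' chain. For each cycle the wavelength ramps linearly across the sweep span;
#' each channel's detected intensity is
#' `offset + gain * T(lambda, opd(channel, t))` plus amplitude noise, where
#' the channel's optical path difference combines its design asymmetry with
#' the assay state's wavelength-shift trajectory. Spectral noise is injected
#' as per-cycle common-mode wavelength jitter; temperature noise as a slow
#' (AR(1)) common-mode fringe-position drift. The stream is reproducible:
#' a single top-level seed deterministically derives independent sub-streams
#' for the common-mode terms and for each channel's amplitude noise.
#'
#' @param layout A [chip_layout()].
#' @param state An `analyte_state` from [run_assay_program()], or `NULL` for
#'   a static (baseline) chip.
#' @param cfg A [sweep_config()].
#' @param noise A [noise_budget()].
#' @param n_cycles Number of sweep cycles to simulate (> 0).
#' @param seed Integer seed; mandatory for any noisy run.
#' @param gain,offset Detector gain and offset, arbitrary intensity units.
#' @param temp_tau_cycles Correlation time of the temperature drift, in
#'   cycles (AR(1); stationary sd equals the budget's `sigma_temp_pm`).
#' @param t0_s Time of the first cycle, s.
#' @return An object of class `raw_sweeps`: list with `intensity` (array
#'   cycles x samples x channels), `time_s`, `cycle_index`, `cfg`, `layout`.
#' @export
simulate_cycles <- function(layout, state, cfg, noise = noise_budget(),
                            n_cycles = 100, seed = 1,
                            gain = 1.0, offset = 0.1,
                            temp_tau_cycles = 5, t0_s = 0) {
  stopifnot(inherits(layout, "chip_layout"), inherits(cfg, "sweep_config"),
            inherits(noise, "noise_budget"))
  if (!is.numeric(n_cycles) || n_cycles <= 0) {
    stop("'n_cycles' must be positive", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  n <- cfg$samples_per_cycle
  nch <- layout$n_outputs
  t_cycle <- t0_s + (seq_len(n_cycles) - 1) / cfg$sweep_rate_hz
  ramp <- wavelength_ramp(cfg)
  lam0 <- cfg$center_wavelength_nm

  # deterministic sub-streams from the top-level seed
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, nch + 2L)

  # spectral: per-cycle common-mode wavelength jitter (pm)
  set.seed(sub_seeds[1L])
  eps_spect <- stats::rnorm(n_cycles, 0, noise$sigma_spect_pm)
  # temperature: AR(1) common-mode fringe-position drift (pm)
  set.seed(sub_seeds[2L])
  if (noise$sigma_temp_pm > 0) {
    rho <- if (temp_tau_cycles > 0) exp(-1 / temp_tau_cycles) else 0
    innov <- stats::rnorm(n_cycles, 0, noise$sigma_temp_pm * sqrt(1 - rho^2))
    eps_temp <- numeric(n_cycles)
    eps_temp[1] <- stats::rnorm(1, 0, noise$sigma_temp_pm)
    if (n_cycles > 1) {
      for (i in 2:n_cycles) eps_temp[i] <- rho * eps_temp[i - 1] + innov[i]
    }
  } else {
    eps_temp <- numeric(n_cycles)
  }

  shifts <- channel_shift_pm(layout, state, t_cycle)  # cycles x channels
  intensity <- array(NA_real_, c(n_cycles, n, nch))
  for (ch in seq_len(nch)) {
    fsr <- layout$designs[[ch]]$fsr_pm
    opd0 <- lam0^2 / (fsr / PM_PER_NM)  # nm
    shift_nm <- (shifts[, ch] + eps_temp) / PM_PER_NM
    opd <- opd0 + shift_nm * opd0 / lam0  # cycles
    lam <- outer(eps_spect / PM_PER_NM, ramp, `+`)  # cycles x samples
    clean <- offset + gain * 0.5 * (1 + cos(2 * pi * opd / lam))
    if (noise$sigma_ampl_pm > 0) {
      set.seed(sub_seeds[2L + ch])
      sd_i <- amplitude_noise_intensity_sd(noise$sigma_ampl_pm, fsr,
                                           gain / 2, n)
      clean <- clean + matrix(stats::rnorm(n_cycles * n, 0, sd_i),
                              n_cycles, n)
    }
    intensity[, , ch] <- clean
  }

  structure(list(intensity = intensity,
                 time_s = t_cycle,
                 cycle_index = seq_len(n_cycles),
                 cfg = cfg,
                 layout = layout,
                 gain = gain,
                 offset = offset,
                 seed = as.integer(seed)),
            class = "raw_sweeps")
}

#' Extract one raw sweep record
#'
#' @param raw A `raw_sweeps` object from [simulate_cycles()].
#' @param cycle Cycle index.
#' @return List with `cycle_index`, `timestamp_s` and `intensity` (matrix,
#'   samples x channels).
#' @export
get_record <- function(raw, cycle) {
  stopifnot(inherits(raw, "raw_sweeps"))
  if (cycle < 1 || cycle > length(raw$cycle_index)) {
    stop("cycle index out of range", call. = FALSE)
  }
  list(cycle_index = raw$cycle_index[cycle],
       timestamp_s = raw$time_s[cycle],
       intensity = raw$intensity[cycle, , , drop = TRUE])
}

#' @export
print.raw_sweeps <- function(x, ...) {
  cat("Raw sweep records\n")
  cat(sprintf("  cycles   : %d (%.4g s at %.4g Hz)\n",
              length(x$cycle_index), diff(range(x$time_s)) +
                1 / x$cfg$sweep_rate_hz, x$cfg$sweep_rate_hz))
  cat(sprintf("  channels : %d, %d samples/cycle (%.4g kHz per photodiode)\n",
              dim(x$intensity)[3], x$cfg$samples_per_cycle,
              sample_rate_hz(x$cfg) / 1000))
  cat(sprintf("  sweep    : %.4g pm span around %.4g nm\n",
              x$cfg$sweep_span_pm, x$cfg$center_wavelength_nm))
  invisible(x)
}

#' @export
as.data.frame.raw_sweeps <- function(x, ..., cycles = x$cycle_index) {
  n <- x$cfg$samples_per_cycle
  nch <- dim(x$intensity)[3]
  out <- vector("list", length(cycles))
  for (k in seq_along(cycles)) {
    c_i <- cycles[k]
    out[[k]] <- data.frame(
      cycle = c_i,
      channel = rep(seq_len(nch), each = n),
      sample_index = rep(seq_len(n), nch),
      intensity = as.vector(x$intensity[c_i, , ]))
  }
  do.call(rbind, out)
}
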