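# Fourier phase demodulation of the sine-like per-cycle interferograms,
# phase unwrapping into sensorgrams, differential referencing, resolution /
# limit-of-detection estimation and bulk-step quantification.

.wrap_phase <- function(x) atan2(sin(x), cos(x))

# DFT phase of the dominant fringe for one cycle's samples x channels matrix.
# Returns phase referenced to the sweep-centre sample so that the pm
# conversion via the centre-wavelength FSR round-trips opd changes without
# first-order bias. Sign convention: an optical-path-difference increase
# (index increase in the sensing window) increases the returned phase.
.dft_phase <- function(mat, contrast_floor) {
  n <- nrow(mat)
  nch <- ncol(mat)
  X <- stats::mvfft(mat)
  dc <- Re(X[1, ]) / n
  kmax <- floor(n / 2)
  mags <- Mod(X[2:(kmax + 1), , drop = FALSE])
  # largest non-DC bin; which.max ties break toward lower frequency
  bins <- apply(mags, 2, which.max)
  idx <- cbind(bins + 1L, seq_len(nch))
  amp <- 2 * Mod(X[idx]) / n
  contrast <- amp / pmax(dc, .Machine$double.eps)
  i_c <- (n - 1) / 2
  phase <- .wrap_phase(-Arg(X[idx]) - 2 * pi * bins * i_c / n)
  list(phase = phase, amplitude = amp, contrast = contrast,
       bin = bins, low_contrast = contrast < contrast_floor)
}

#' Fourier phase extraction from one sweep record
#'
#' Computes the discrete Fourier transform of each channel's per-cycle
#' interferogram, selects the dominant non-DC bin (ties broken toward the
#' lower frequency) and returns its argument, referenced to the sweep-centre
#' sample, in (-pi, pi]. No window function is applied: with the default
#' sweep span of an integer number of free spectral ranges the fringe falls
#' on (very nearly) an integer bin. A trace whose fringe contrast falls below
#' `contrast_floor` is flagged low-contrast rather than raising an error.
#'
#' @param intensity Numeric matrix (samples x channels) or vector of one
#'   cycle's detected intensities; at least 16 samples.
#' @param cfg A [sweep_config()] (used for validation of the record length).
#' @param contrast_floor Fringe amplitude / DC level below which the result
#'   is flagged low-contrast.
#' @return A data.frame with one row per channel: `phase` (radians),
#'   `amplitude`, `contrast`, `bin` (fringe count over the sweep span) and
#'   `low_contrast`.
#' @export
extract_phase <- function(intensity, cfg = NULL, contrast_floor = 0.01) {
  if (is.list(intensity) && !is.null(intensity$intensity)) {
    intensity <- intensity$intensity
  }
  mat <- if (is.matrix(intensity)) intensity else matrix(intensity, ncol = 1)
  if (nrow(mat) < 16) {
    stop("record must contain at least 16 samples", call. = FALSE)
  }
  if (!is.null(cfg)) {
    stopifnot(inherits(cfg, "sweep_config"))
    if (nrow(mat) != cfg$samples_per_cycle) {
      stop("record length does not match 'samples_per_cycle'", call. = FALSE)
    }
  }
  if (any(!is.finite(mat))) stop("non-finite intensity sample", call. = FALSE)
  res <- .dft_phase(mat, contrast_floor)
  data.frame(channel = seq_len(ncol(mat)), phase = res$phase,
             amplitude = res$amplitude, contrast = res$contrast,
             bin = res$bin, low_contrast = res$low_contrast)
}

#' Track a sensorgram from a stream of sweep records
#'
#' Extracts the dominant-fringe phase of every cycle and channel, unwraps it
#' across cycles (nearest multiple of 2*pi; assumes the fringe moves by less
#' than half a free spectral range between consecutive cycles), converts to a
#' wavelength shift in pm via each channel's FSR, and zeroes the baseline on
#' a configurable reference window.
#'
#' @param raw A `raw_sweeps` object from [simulate_cycles()].
#' @param baseline_window Length-2 numeric, time window (s) whose mean shift
#'   is subtracted per channel. `NULL` zeroes on the first cycle.
#' @param contrast_floor Passed to the phase extractor.
#' @return An object of class `sensorgram`: `time_s`, `shift_pm` (matrix,
#'   cycles x channels), `phase_rad` (unwrapped), `fsr_pm`, QC metadata
#'   (`low_contrast_frac`, `unwrap_suspect` per channel) and referencing
#'   metadata.
#' @export
track_sensorgram <- function(raw, baseline_window = c(0, 10),
                             contrast_floor = 0.01) {
  stopifnot(inherits(raw, "raw_sweeps"))
  n_cycles <- length(raw$cycle_index)
  nch <- dim(raw$intensity)[3]
  phase <- matrix(NA_real_, n_cycles, nch)
  lowc <- matrix(FALSE, n_cycles, nch)
  for (ch in seq_len(nch)) {
    res <- .dft_phase(t(raw$intensity[, , ch, drop = TRUE]), contrast_floor)
    phase[, ch] <- res$phase
    lowc[, ch] <- res$low_contrast
  }
  unwrapped <- apply(phase, 2, signal::unwrap)
  unwrapped <- matrix(unwrapped, n_cycles, nch)
  # jumps approaching pi per cycle are ambiguous under nearest-2*pi unwrapping
  suspect <- apply(unwrapped, 2, function(p) {
    n_cycles > 1 && max(abs(diff(p))) > 0.9 * pi
  })
  fsr <- vapply(raw$layout$designs, `[[`, numeric(1), "fsr_pm")
  shift <- sweep(unwrapped, 2, 2 * pi / fsr, `/`)
  if (is.null(baseline_window)) {
    base_idx <- 1L
  } else {
    base_idx <- which(raw$time_s >= baseline_window[1] &
                        raw$time_s <= baseline_window[2])
    if (!length(base_idx)) base_idx <- 1L
  }
  shift <- sweep(shift, 2, colMeans(shift[base_idx, , drop = FALSE]), `-`)
  structure(list(time_s = raw$time_s,
                 shift_pm = `colnames<-`(shift, paste0("ch", seq_len(nch))),
                 phase_rad = unwrapped,
                 fsr_pm = fsr,
                 units = "pm",
                 roles = raw$layout$roles,
                 baseline_window = baseline_window,
                 referencing = NULL,
                 low_contrast_frac = colMeans(lowc),
                 unwrap_suspect = suspect),
            class = "sensorgram")
}

#' Differential referencing of two channels
#'
#' The differential wavelength shift: the signal on an antibody-spotted aMZI
#' minus the signal on its (nearest) control aMZI, cancelling common-mode
#' bulk and background effects. The pairing is recorded in the result's
#' `referencing` metadata.
#'
#' @param sg A `sensorgram`.
#' @param signal_channel,reference_channel Column indices or names in `sg`.
#' @return A `sensorgram` with a single differential channel.
#' @export
differential_signal <- function(sg, signal_channel, reference_channel) {
  stopifnot(inherits(sg, "sensorgram"))
  cn <- colnames(sg$shift_pm)
  pick <- function(x) if (is.character(x)) match(x, cn) else as.integer(x)
  si <- pick(signal_channel); ri <- pick(reference_channel)
  if (is.na(si) || is.na(ri) || si < 1 || ri < 1 ||
      si > ncol(sg$shift_pm) || ri > ncol(sg$shift_pm)) {
    stop("signal/reference channel not present in sensorgram", call. = FALSE)
  }
  d <- sg$shift_pm[, si] - sg$shift_pm[, ri]
  out <- sg
  out$shift_pm <- matrix(d, ncol = 1,
                         dimnames = list(NULL, paste0(cn[si], "-", cn[ri])))
  out$phase_rad <- matrix(sg$phase_rad[, si] - sg$phase_rad[, ri], ncol = 1)
  out$fsr_pm <- sg$fsr_pm[si]
  out$roles <- "differential"
  out$referencing <- list(signal = cn[si], reference = cn[ri])
  out
}

.window_index <- function(sg, window) {
  idx <- which(sg$time_s >= window[1] & sg$time_s <= window[2])
  if (length(idx) < 30) {
    stop("baseline window must contain at least 30 cycles", call. = FALSE)
  }
  idx
}

#' Estimate the resolution from a baseline window
#'
#' The resolution is the 3-sigma standard deviation of the measured fringe
#' position: here, 3 x the sample SD of the sensorgram shift within a quiet
#' baseline window. If the fluidic program is supplied, a window containing a
#' programmed liquid change is rejected.
#'
#' @param sg A `sensorgram`.
#' @param baseline_window Length-2 time window, s; must span >= 30 cycles.
#' @param program Optional list of [flow_step()] defining programmed
#'   transitions (assumed to start at time 0).
#' @return Named vector, 3-sigma resolution in pm per channel.
#' @export
estimate_resolution <- function(sg, baseline_window, program = NULL) {
  stopifnot(inherits(sg, "sensorgram"))
  if (!is.null(program)) {
    durs <- vapply(program, `[[`, numeric(1), "duration_s")
    transitions <- cumsum(durs)[-length(durs)]
    inside <- transitions > baseline_window[1] &
      transitions < baseline_window[2]
    if (any(inside)) {
      stop("baseline window spans a programmed liquid change", call. = FALSE)
    }
  }
  idx <- .window_index(sg, baseline_window)
  3 * apply(sg$shift_pm[idx, , drop = FALSE], 2, stats::sd)
}

#' Estimate the limit of detection from a baseline window
#'
#' [estimate_resolution()] divided by the sensitivity, `LoD = R / S`.
#'
#' @inheritParams estimate_resolution
#' @param sensitivity_nm_riu Sensitivity used for the conversion, nm/RIU.
#' @param channel Channel to report (index or name).
#' @return Estimated limit of detection, RIU.
#' @export
estimate_lod <- function(sg, baseline_window, sensitivity_nm_riu,
                         channel = 1, program = NULL) {
  r <- estimate_resolution(sg, baseline_window, program = program)
  r_ch <- if (is.character(channel)) r[[channel]] else r[[as.integer(channel)]]
  limit_of_detection(r_ch, sensitivity_nm_riu)
}

#' Analyze programmed bulk/liquid steps in a sensorgram
#'
#' For each step of the fluidic program: the plateau level (mean over the
#' final `settle_fraction` of the step), its SD, the level difference from the
#' previous plateau, and the response delay — the time after the liquid change
#' at which the signal first exceeds `detect_k` x the previous plateau's SD
#' (with an absolute noise floor) away from the previous plateau. Steps
#' shorter than `settling_guard_s` are flagged unsettled.
#'
#' @param sg A `sensorgram`.
#' @param program List of [flow_step()] time-aligned with the sensorgram
#'   (program start at `t0_s`).
#' @param channel Channel to analyze (index or name).
#' @param settle_fraction Final fraction of each step treated as plateau.
#' @param detect_k Detection threshold in units of plateau SD.
#' @param min_threshold_pm Absolute floor on the detection threshold, pm.
#' @param settling_guard_s Minimum step duration regarded as settleable, s.
#' @param t0_s Program start time, s.
#' @return An object of class `step_analysis` (a data.frame with one row per
#'   step: label, t_start_s, t_end_s, plateau_pm, plateau_sd_pm,
#'   level_diff_pm, detect_time_s, response_delay_s, settled).
#' @export
analyze_steps <- function(sg, program, channel = 1,
                          settle_fraction = 0.4, detect_k = 5,
                          min_threshold_pm = 0.5,
                          settling_guard_s = 20, t0_s = 0) {
  stopifnot(inherits(sg, "sensorgram"))
  validate_program(program)
  y <- if (is.character(channel)) {
    sg$shift_pm[, channel]
  } else {
    sg$shift_pm[, as.integer(channel)]
  }
  t <- sg$time_s
  durs <- vapply(program, `[[`, numeric(1), "duration_s")
  starts <- t0_s + cumsum(c(0, durs[-length(durs)]))
  ends <- starts + durs
  m <- length(program)
  plateau <- plateau_sd <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    sel <- t >= ends[j] - settle_fraction * durs[j] & t < ends[j]
    if (sum(sel) >= 2) {
      plateau[j] <- mean(y[sel])
      plateau_sd[j] <- stats::sd(y[sel])
    }
  }
  detect <- delay <- rep(NA_real_, m)
  level_diff <- c(NA_real_, diff(plateau))
  for (j in 2:max(2, m)) {
    if (j > m || is.na(plateau[j - 1])) next
    thr <- max(detect_k * plateau_sd[j - 1], min_threshold_pm, na.rm = TRUE)
    sel <- which(t >= starts[j] & t < ends[j])
    hit <- sel[abs(y[sel] - plateau[j - 1]) > thr]
    if (length(hit)) {
      detect[j] <- t[hit[1]]
      delay[j] <- detect[j] - starts[j]
    }
  }
  out <- data.frame(
    step = seq_len(m),
    label = vapply(program, `[[`, character(1), "label"),
    t_start_s = starts, t_end_s = ends,
    plateau_pm = plateau, plateau_sd_pm = plateau_sd,
    level_diff_pm = level_diff,
    detect_time_s = detect, response_delay_s = delay,
    settled = durs >= settling_guard_s & !is.na(plateau))
  class(out) <- c("step_analysis", "data.frame")
  out
}

#' @export
print.step_analysis <- function(x, ...) {
  cat("Step analysis\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Run-validity check on the bulk and internal-reference channels
#'
#' The low-sensitivity bulk monitor and the sealed internal-reference aMZI
#' should stay quiet during a biological run; observing no signal there
#' indicates a functional photonic chip. Raises a QC flag per channel whose
#' peak-to-baseline excursion exceeds `bound_pm`.
#'
#' @param sg A `sensorgram` with the full 8-channel layout.
#' @param bound_pm Allowed excursion, pm.
#' @param channels Channels to check (defaults to the bulk and reference
#'   roles recorded in the sensorgram).
#' @return Named logical vector; `TRUE` means the channel violated the bound.
#' @export
qc_check <- function(sg, bound_pm = 25,
                     channels = which(sg$roles %in%
                                        c("bulk_low_sensitivity",
                                          "internal_reference"))) {
  stopifnot(inherits(sg, "sensorgram"))
  flags <- vapply(channels, function(ch) {
    max(abs(sg$shift_pm[, ch])) > bound_pm
  }, logical(1))
  names(flags) <- colnames(sg$shift_pm)[channels]
  flags
}

#' @export
print.sensorgram <- function(x, ...) {
  cat("Sensorgram\n")
  cat(sprintf("  %d cycles over %.4g s, %d channel(s), units: %s\n",
              nrow(x$shift_pm), diff(range(x$time_s)), ncol(x$shift_pm),
              x$units))
  if (!is.null(x$referencing)) {
    cat(sprintf("  differential: %s minus %s\n",
                x$referencing$signal, x$referencing$reference))
  }
  rng <- range(x$shift_pm)
  cat(sprintf("  shift range : [%.4g, %.4g] pm\n", rng[1], rng[2]))
  if (any(x$low_contrast_frac > 0)) {
    cat("  low-contrast cycles present\n")
  }
  if (any(x$unwrap_suspect)) {
    cat("  warning: inter-cycle phase jumps approaching pi (unwrap ambiguity)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.sensorgram <- function(x, ...) {
  n <- nrow(x$shift_pm)
  nch <- ncol(x$shift_pm)
  data.frame(
    time_s = rep(x$time_s, nch),
    channel = rep(colnames(x$shift_pm), each = n),
    shift_pm = as.vector(x$shift_pm))
}

#' @export
plot.sensorgram <- function(x, channels = seq_len(ncol(x$shift_pm)), ...) {
  graphics::matplot(x$time_s, x$shift_pm[, channels, drop = FALSE],
                    type = "l", lty = 1,
                    xlab = "time (s)", ylab = "wavelength shift (pm)", ...)
  graphics::legend("topleft", colnames(x$shift_pm)[channels],
                   col = seq_along(channels), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
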