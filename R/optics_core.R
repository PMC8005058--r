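# Interferometer physics and refractometric performance figures for an
# asymmetric Mach-Zehnder interferometer (aMZI) evanescent-field sensor.
#
# Unit discipline (applied throughout the package):
#   wavelengths in nm, wavelength shifts in pm, lengths in mm,
#   refractive-index changes in RIU (dimensionless). Conversions are
#   centralized here.

PM_PER_NM <- 1000
NM_PER_MM <- 1e6

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Guided-mode dispersion description
#'
#' Holds the effective index of the guided mode at a reference wavelength and
#' its first-order wavelength dispersion. The pair determines the group index
#' that sets the free spectral range of an asymmetric interferometer.
#'
#' @param n_eff Effective index of the guided mode (dimensionless, > 1).
#' @param dneff_dlambda_per_nm Derivative of the effective index with respect
#'   to wavelength, per nm (typically negative for dielectric waveguides).
#' @param lambda0_nm Reference wavelength in nm.
#' @return An object of class `mode_dispersion`.
#' @examples
#' m <- mode_dispersion(1.55, -5e-4, 850)
#' group_index(m)
#' @export
mode_dispersion <- function(n_eff = 1.55,
                            dneff_dlambda_per_nm = -(0.45 / 850),
                            lambda0_nm = 850) {
  .check_positive(lambda0_nm, "lambda0_nm")
  if (!is.numeric(n_eff) || length(n_eff) != 1L || !is.finite(n_eff) ||
      n_eff <= 1) {
    stop("'n_eff' must be a single finite number > 1", call. = FALSE)
  }
  if (!is.numeric(dneff_dlambda_per_nm) || !is.finite(dneff_dlambda_per_nm)) {
    stop("'dneff_dlambda_per_nm' must be finite", call. = FALSE)
  }
  structure(list(n_eff = n_eff,
                 dneff_dlambda_per_nm = dneff_dlambda_per_nm,
                 lambda0_nm = lambda0_nm),
            class = "mode_dispersion")
}

#' Group index of the guided mode
#'
#' `n_g = n_eff - lambda0 * dn_eff/dlambda`: the effective index corrected for
#' first-order dispersion. The group index, not the phase index, sets the
#' fringe spacing (free spectral range) of the interferometer.
#'
#' @param mode A [mode_dispersion()] object.
#' @return The dimensionless group index.
#' @export
group_index <- function(mode) {
  stopifnot(inherits(mode, "mode_dispersion"))
  mode$n_eff - mode$lambda0_nm * mode$dneff_dlambda_per_nm
}

#' aMZI interferometer design
#'
#' Geometry of one asymmetric Mach-Zehnder interferometer: the physical length
#' of each (spiral) arm, the effective optical asymmetry length that sets the
#' free spectral range, and the resonance operating wavelength. The intrinsic
#' effective-index sensitivity follows from `L * FSR / lambda_res`
#' (see [amzi_sensitivity()]); because the bulk-cladding response additionally
#' involves the mode's confinement in the cladding, a design may pin its
#' working sensitivity with `sensitivity_override_nm_riu`, and shipped default
#' designs pin 5000 nm/RIU, the device's stated bulk figure.
#'
#' @param arm_length_mm Physical pathlength of each arm, mm.
#' @param asym_length_mm Effective optical asymmetry length used in the FSR
#'   relation, mm.
#' @param lambda_res_nm Resonance operating wavelength, nm.
#' @param mode A [mode_dispersion()] object for the guided mode.
#' @param sensitivity_override_nm_riu Optional sensitivity in nm/RIU that
#'   supersedes the intrinsic `L * FSR / lambda_res` value.
#' @return An object of class `amzi_design` with derived `fsr_pm` and
#'   `sensitivity_nm_riu`.
#' @examples
#' d <- amzi_design()
#' d$fsr_pm
#' d$sensitivity_nm_riu
#' @export
amzi_design <- function(arm_length_mm = 12.5,
                        asym_length_mm = 722500 / (2 * 1500) * 1e-3,
                        lambda_res_nm = 850,
                        mode = mode_dispersion(),
                        sensitivity_override_nm_riu = 5000) {
  .check_positive(arm_length_mm, "arm_length_mm")
  .check_positive(asym_length_mm, "asym_length_mm")
  .check_positive(lambda_res_nm, "lambda_res_nm")
  if (!is.null(sensitivity_override_nm_riu)) {
    .check_positive(sensitivity_override_nm_riu, "sensitivity_override_nm_riu")
  }
  n_g <- group_index(mode)
  fsr <- free_spectral_range(lambda_res_nm, n_g, asym_length_mm)
  s_intrinsic <- amzi_sensitivity(arm_length_mm, fsr, lambda_res_nm)
  structure(list(arm_length_mm = arm_length_mm,
                 asym_length_mm = asym_length_mm,
                 lambda_res_nm = lambda_res_nm,
                 mode = mode,
                 fsr_pm = fsr,
                 sensitivity_intrinsic_nm_riu = s_intrinsic,
                 sensitivity_override_nm_riu = sensitivity_override_nm_riu,
                 sensitivity_nm_riu = if (is.null(sensitivity_override_nm_riu))
                   s_intrinsic else sensitivity_override_nm_riu),
            class = "amzi_design")
}

#' @export
print.amzi_design <- function(x, ...) {
  cat("aMZI design\n")
  cat(sprintf("  arm length        : %.4g mm\n", x$arm_length_mm))
  cat(sprintf("  asymmetry length  : %.4g mm\n", x$asym_length_mm))
  cat(sprintf("  operating lambda  : %.4g nm\n", x$lambda_res_nm))
  cat(sprintf("  group index       : %.4f\n", group_index(x$mode)))
  cat(sprintf("  FSR               : %.4g pm\n", x$fsr_pm))
  cat(sprintf("  sensitivity (eff.): %.5g nm/RIU\n",
              x$sensitivity_intrinsic_nm_riu))
  if (!is.null(x$sensitivity_override_nm_riu)) {
    cat(sprintf("  sensitivity (pinned bulk): %.5g nm/RIU\n",
                x$sensitivity_override_nm_riu))
  }
  invisible(x)
}

#' Three-component measurement noise budget
#'
#' Wavelength-equivalent standard deviations of the three independent noise
#' contributions to the measured fringe position: amplitude (detector/source
#' intensity) noise, spectral (laser wavelength) noise and temperature drift.
#'
#' @param sigma_ampl_pm,sigma_spect_pm,sigma_temp_pm Component standard
#'   deviations, pm (wavelength equivalent), each >= 0. The defaults split a
#'   total 3-sigma of 0.8 pm equally over the three components.
#' @return An object of class `noise_budget`.
#' @examples
#' b <- noise_budget()
#' measurement_noise_3sigma(b)  # 0.8 pm
#' @export
noise_budget <- function(sigma_ampl_pm = (0.8 / 3) / sqrt(3),
                         sigma_spect_pm = (0.8 / 3) / sqrt(3),
                         sigma_temp_pm = (0.8 / 3) / sqrt(3)) {
  .check_nonneg(sigma_ampl_pm, "sigma_ampl_pm")
  .check_nonneg(sigma_spect_pm, "sigma_spect_pm")
  .check_nonneg(sigma_temp_pm, "sigma_temp_pm")
  structure(list(sigma_ampl_pm = sigma_ampl_pm,
                 sigma_spect_pm = sigma_spect_pm,
                 sigma_temp_pm = sigma_temp_pm),
            class = "noise_budget")
}

#' aMZI transfer function versus phase
#'
#' Two-beam interference transmission `T(phi) = (1 + cos(phi)) / 2`; periodic
#' with period 2*pi, 1 at constructive interference (multiples of 2*pi) and 0
#' at destructive interference.
#'
#' @param delta_phi Phase difference between the two arms, radians (vectorized).
#' @return Transmission fraction(s) in \[0, 1\].
#' @export
transfer_phase <- function(delta_phi) {
  if (!is.numeric(delta_phi) || any(!is.finite(delta_phi))) {
    stop("'delta_phi' must be finite", call. = FALSE)
  }
  0.5 * (1 + cos(delta_phi))
}

#' aMZI transfer function versus wavelength
#'
#' `T(lambda) = (1 + cos(2*pi*opd/lambda)) / 2` where `opd` is the optical
#' path-length difference between the two arms. The opd combines the geometric
#' asymmetry contribution `n_eff * delta_L` and any sensing-window
#' effective-index change `delta_n_eff * L`.
#'
#' @param lambda_nm Wavelength, nm (> 0, vectorized).
#' @param opd_nm Optical path-length difference, nm.
#' @return Transmission fraction(s) in \[0, 1\].
#' @export
transfer_wavelength <- function(lambda_nm, opd_nm) {
  if (!is.numeric(lambda_nm) || any(!is.finite(lambda_nm)) ||
      any(lambda_nm <= 0)) {
    stop("'lambda_nm' must be positive and finite", call. = FALSE)
  }
  transfer_phase(2 * pi * opd_nm / lambda_nm)
}

#' Free spectral range of an asymmetric interferometer
#'
#' `FSR = lambda0^2 / (n_g * L_asym)`: the wavelength spacing between
#' successive interference maxima near `lambda0`.
#'
#' @param lambda0_nm Operating wavelength, nm.
#' @param n_g Group index of the guided mode (dimensionless).
#' @param asym_length_mm Optical asymmetry length between the arms, mm.
#' @return Free spectral range in pm.
#' @examples
#' free_spectral_range(850, 2.0, 0.2408333)  # ~1500 pm
#' @export
free_spectral_range <- function(lambda0_nm, n_g, asym_length_mm) {
  .check_positive(lambda0_nm, "lambda0_nm")
  .check_positive(n_g, "n_g")
  .check_positive(asym_length_mm, "asym_length_mm")
  fsr_nm <- lambda0_nm^2 / (n_g * asym_length_mm * NM_PER_MM)
  fsr_nm * PM_PER_NM
}

#' Effective-index sensitivity of an aMZI
#'
#' `S = delta_lambda / delta_n_eff = L * FSR / lambda_res`: the fringe
#' wavelength shift per unit change of the effective index in the sensing
#' window. Note this is the effective-index scale; the response to a
#' bulk-cladding index change is smaller by the mode's cladding confinement
#' factor, which is why device configurations may pin a measured bulk
#' sensitivity instead (see [amzi_design()]).
#'
#' @param arm_length_mm Sensing-arm length, mm.
#' @param fsr_pm Free spectral range, pm.
#' @param lambda_res_nm Resonance operating wavelength, nm.
#' @return Sensitivity in nm/RIU.
#' @examples
#' amzi_sensitivity(12.5, 1500, 850)  # ~22059 nm/RIU
#' @export
amzi_sensitivity <- function(arm_length_mm, fsr_pm, lambda_res_nm) {
  .check_positive(arm_length_mm, "arm_length_mm")
  .check_positive(fsr_pm, "fsr_pm")
  .check_positive(lambda_res_nm, "lambda_res_nm")
  (arm_length_mm * NM_PER_MM) * (fsr_pm / PM_PER_NM) / lambda_res_nm
}

#' Composed 3-sigma measurement noise
#'
#' Root-sum-square composition of the independent amplitude, spectral and
#' temperature contributions:
#' `3*sigma_meas = 3 * sqrt(sigma_ampl^2 + sigma_spect^2 + sigma_temp^2)`.
#'
#' @param budget A [noise_budget()] object.
#' @return The 3-sigma total measurement noise, pm.
#' @export
measurement_noise_3sigma <- function(budget) {
  stopifnot(inherits(budget, "noise_budget"))
  3 * sqrt(budget$sigma_ampl_pm^2 + budget$sigma_spect_pm^2 +
             budget$sigma_temp_pm^2)
}

#' Limit of detection
#'
#' `LoD = R / S`: the smallest refractive-index change resolvable above the
#' noise floor, with the resolution `R` taken as the 3-sigma of the measured
#' fringe position.
#'
#' @param resolution_pm Resolution (3-sigma fringe-position noise), pm.
#' @param sensitivity_nm_riu Sensitivity, nm/RIU.
#' @return Limit of detection in RIU.
#' @examples
#' limit_of_detection(0.8, 5000)  # 1.6e-7 RIU
#' @export
limit_of_detection <- function(resolution_pm, sensitivity_nm_riu) {
  .check_nonneg(resolution_pm, "resolution_pm")
  .check_positive(sensitivity_nm_riu, "sensitivity_nm_riu")
  (resolution_pm / PM_PER_NM) / sensitivity_nm_riu
}

#' Convert interferometer phase to fringe wavelength shift
#'
#' One full 2*pi fringe of phase corresponds to one free spectral range of
#' wavelength shift: `delta_lambda = delta_phi * FSR / (2*pi)`.
#'
#' @param delta_phi Phase change, radians (vectorized).
#' @param fsr_pm Free spectral range, pm.
#' @return Wavelength shift in pm.
#' @seealso [wavelength_shift_to_phase()] for the exact inverse.
#' @export
phase_to_wavelength_shift <- function(delta_phi, fsr_pm) {
  .check_positive(fsr_pm, "fsr_pm")
  delta_phi * fsr_pm / (2 * pi)
}

#' Convert fringe wavelength shift to interferometer phase
#'
#' Inverse of [phase_to_wavelength_shift()].
#'
#' @param shift_pm Wavelength shift, pm (vectorized).
#' @param fsr_pm Free spectral range, pm.
#' @return Phase change in radians.
#' @export
wavelength_shift_to_phase <- function(shift_pm, fsr_pm) {
  .check_positive(fsr_pm, "fsr_pm")
  shift_pm * 2 * pi / fsr_pm
}

#' Performance figures of an aMZI design under a noise budget
#'
#' Combines the design's free spectral range and sensitivity with the
#' composed 3-sigma measurement noise into the standard figure set:
#' sensitivity S (nm/RIU), resolution R (pm, = 3-sigma noise) and the limit
#' of detection LoD = R/S (RIU).
#'
#' @param design An [amzi_design()].
#' @param budget A [noise_budget()].
#' @return An object of class `performance_figure` with fields
#'   `fsr_pm`, `sensitivity_nm_riu`, `resolution_pm`, `lod_riu`.
#' @examples
#' performance_figure(amzi_design(), noise_budget())
#' @export
performance_figure <- function(design = amzi_design(),
                               budget = noise_budget()) {
  stopifnot(inherits(design, "amzi_design"))
  r <- measurement_noise_3sigma(budget)
  s <- design$sensitivity_nm_riu
  structure(list(fsr_pm = design$fsr_pm,
                 sensitivity_nm_riu = s,
                 resolution_pm = r,
                 lod_riu = limit_of_detection(r, s)),
            class = "performance_figure")
}

#' @export
print.performance_figure <- function(x, ...) {
  cat("aMZI performance figures\n")
  cat(sprintf("  FSR         : %.5g pm\n", x$fsr_pm))
  cat(sprintf("  sensitivity : %.5g nm/RIU\n", x$sensitivity_nm_riu))
  cat(sprintf("  resolution  : %.3g pm (3-sigma)\n", x$resolution_pm))
  cat(sprintf("  LoD         : %.3g RIU\n", x$lod_riu))
  invisible(x)
}
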