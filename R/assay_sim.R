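# Assay-level simulation: timed fluidic programs, 1:1 Langmuir surface
# binding on functionalized aMZI arms, nonspecific background, control-channel
# drift and bulk refractive-index transients. Produces per-channel
# refractive-index / wavelength-shift trajectories that the instrument
# simulator converts into raw interferograms.

#' One step of a fluidic program
#'
#' @param label Step label, e.g. "sample", "wash-water", "buffer-BSA", "PBS",
#'   "PBS-lowNaCl".
#' @param duration_s Step duration, s (> 0).
#' @param flow_rate_ul_min Flow rate, uL/min.
#' @param bulk_index_delta_riu Bulk refractive-index offset of this liquid
#'   relative to the running buffer, RIU.
#' @param analyte_concentrations_ng_ml Named numeric vector of analyte
#'   concentrations, ng/mL (all >= 0). Empty for plain buffers.
#' @param serum_fraction_pct Percentage of serum in the liquid (0-100);
#'   drives nonspecific background and control drift.
#' @return An object of class `flow_step`.
#' @export
flow_step <- function(label,
                      duration_s,
                      flow_rate_ul_min = 60,
                      bulk_index_delta_riu = 0,
                      analyte_concentrations_ng_ml = numeric(0),
                      serum_fraction_pct = 0) {
  .check_positive(duration_s, "duration_s")
  .check_positive(flow_rate_ul_min, "flow_rate_ul_min")
  if (length(analyte_concentrations_ng_ml) &&
      (is.null(names(analyte_concentrations_ng_ml)) ||
       any(!nzchar(names(analyte_concentrations_ng_ml))))) {
    stop("'analyte_concentrations_ng_ml' must be a named vector", call. = FALSE)
  }
  if (any(analyte_concentrations_ng_ml < 0)) {
    stop("analyte concentrations must be >= 0", call. = FALSE)
  }
  if (serum_fraction_pct < 0 || serum_fraction_pct > 100) {
    stop("'serum_fraction_pct' must be in [0, 100]", call. = FALSE)
  }
  structure(list(label = as.character(label),
                 duration_s = duration_s,
                 flow_rate_ul_min = flow_rate_ul_min,
                 bulk_index_delta_riu = bulk_index_delta_riu,
                 analyte_concentrations_ng_ml = analyte_concentrations_ng_ml,
                 serum_fraction_pct = serum_fraction_pct),
            class = "flow_step")
}

#' Validate a fluidic program
#'
#' Checks volume bookkeeping (duration x flow rate = dispensed volume) and,
#' when `instrument_mode = TRUE`, that every flow rate lies within the
#' instrument's syringe-drive range of 4 to 200 uL/min.
#'
#' @param steps List of [flow_step()] objects.
#' @param instrument_mode Enforce the instrument flow-rate range.
#' @return Invisibly, a data.frame with one row per step: label, duration_s,
#'   flow_rate_ul_min and dispensed volume_ul.
#' @export
validate_program <- function(steps, instrument_mode = FALSE) {
  if (!length(steps)) stop("empty fluidic program", call. = FALSE)
  if (!all(vapply(steps, inherits, logical(1), "flow_step"))) {
    stop("'steps' must be a list of flow_step objects", call. = FALSE)
  }
  rates <- vapply(steps, `[[`, numeric(1), "flow_rate_ul_min")
  if (instrument_mode && (any(rates < 4) || any(rates > 200))) {
    stop("flow rate outside the instrument range of 4-200 uL/min",
         call. = FALSE)
  }
  durs <- vapply(steps, `[[`, numeric(1), "duration_s")
  invisible(data.frame(
    label = vapply(steps, `[[`, character(1), "label"),
    duration_s = durs,
    flow_rate_ul_min = rates,
    volume_ul = durs * rates / 60))
}

#' 1:1 binding model for one analyte
#'
#' Kinetic and signal-transduction parameters for a single analyte binding to
#' its immobilized antibody: Langmuir association/dissociation constants, the
#' wavelength-equivalent shift at full surface occupancy, the molar mass used
#' to convert ng/mL to molarity, plus phenomenological nonspecific-adsorption
#' and cross-reactivity terms. The device's own data cards print no kinetic
#' constants, so these are free parameters with defaults giving
#' nanomolar-affinity antibody behavior.
#'
#' @param k_on Association rate constant, 1/(M*s).
#' @param k_off Dissociation rate constant, 1/s.
#' @param surface_capacity_shift_pm Wavelength shift at full occupancy, pm.
#' @param molar_mass_g_mol Analyte molar mass, g/mol.
#' @param nonspecific_rate_pm_s_per_ng_ml Background adsorption rate on
#'   non-cognate surfaces, pm/s per ng/mL of this analyte.
#' @param crossreact_threshold_ng_ml Concentration above which an extra
#'   cross-reactive adsorption onto antibody-spotted (non-cognate) surfaces
#'   switches on, ng/mL.
#' @param crossreact_rate_pm_s_per_ng_ml Slope of that thresholded term,
#'   pm/s per ng/mL above threshold.
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(k_on = 1e5,
                          k_off = 1e-4,
                          surface_capacity_shift_pm = 2000,
                          molar_mass_g_mol = 7e4,
                          nonspecific_rate_pm_s_per_ng_ml = 2e-5,
                          crossreact_threshold_ng_ml = Inf,
                          crossreact_rate_pm_s_per_ng_ml = 0) {
  .check_nonneg(k_on, "k_on")
  .check_nonneg(k_off, "k_off")
  .check_nonneg(surface_capacity_shift_pm, "surface_capacity_shift_pm")
  .check_positive(molar_mass_g_mol, "molar_mass_g_mol")
  .check_nonneg(nonspecific_rate_pm_s_per_ng_ml,
                "nonspecific_rate_pm_s_per_ng_ml")
  .check_nonneg(crossreact_rate_pm_s_per_ng_ml,
                "crossreact_rate_pm_s_per_ng_ml")
  structure(list(k_on = k_on, k_off = k_off,
                 surface_capacity_shift_pm = surface_capacity_shift_pm,
                 molar_mass_g_mol = molar_mass_g_mol,
                 nonspecific_rate_pm_s_per_ng_ml =
                   nonspecific_rate_pm_s_per_ng_ml,
                 crossreact_threshold_ng_ml = crossreact_threshold_ng_ml,
                 crossreact_rate_pm_s_per_ng_ml =
                   crossreact_rate_pm_s_per_ng_ml),
            class = "binding_model")
}

#' Default binding models for the two biomarkers
#'
#' TGFBI (transforming growth factor beta-induced protein, ~68 kDa) and POSTN
#' (periostin, ~90 kDa), both with nanomolar-affinity monoclonal antibodies.
#' POSTN carries a cross-reactive adsorption term that switches on at
#' 1000 ng/mL, reproducing the nonspecific binding observed at POSTN
#' concentrations of 1 ug/mL and above.
#'
#' @return Named list of [binding_model()] objects.
#' @export
default_binding_models <- function() {
  list(
    TGFBI = binding_model(molar_mass_g_mol = 68000),
    POSTN = binding_model(molar_mass_g_mol = 90000,
                          crossreact_threshold_ng_ml = 1000,
                          crossreact_rate_pm_s_per_ng_ml = 2e-4)
  )
}

#' Analyte concentration in molar units
#'
#' @param c_ng_ml Concentration, ng/mL.
#' @param molar_mass_g_mol Molar mass, g/mol.
#' @return Molar concentration, mol/L.
#' @export
ng_ml_to_molar <- function(c_ng_ml, molar_mass_g_mol) {
  .check_positive(molar_mass_g_mol, "molar_mass_g_mol")
  c_ng_ml * 1e-6 / molar_mass_g_mol
}

#' Closed-form 1:1 Langmuir occupancy
#'
#' Fractional occupancy of the surface under constant analyte concentration:
#' `theta(t) = theta_eq + (theta0 - theta_eq) * exp(-(k_on*c + k_off)*t)` with
#' `theta_eq = k_on*c / (k_on*c + k_off)`.
#'
#' @param c_molar Analyte concentration, mol/L (>= 0).
#' @param model A [binding_model()].
#' @param t_s Time(s) since the start of the exposure, s (vectorized).
#' @param theta0 Initial occupancy fraction in \[0, 1\].
#' @return Occupancy fraction(s) in \[0, 1\].
#' @export
langmuir_occupancy <- function(c_molar, model, t_s, theta0 = 0) {
  stopifnot(inherits(model, "binding_model"))
  if (!is.numeric(c_molar) || length(c_molar) != 1L || !is.finite(c_molar) ||
      c_molar < 0) {
    stop("'c_molar' must be a single non-negative concentration", call. = FALSE)
  }
  if (theta0 < 0 || theta0 > 1) {
    stop("'theta0' must be in [0, 1]", call. = FALSE)
  }
  rate <- model$k_on * c_molar + model$k_off
  if (rate == 0) return(rep(theta0, length(t_s)))
  theta_eq <- model$k_on * c_molar / rate
  theta_eq + (theta0 - theta_eq) * exp(-rate * t_s)
}

# Probe vocabulary: which analyte each surface probe captures specifically.
.probe_cognate <- c("anti-TGFBI" = "TGFBI", "anti-POSTN" = "POSTN")
.probe_levels <- c("anti-TGFBI", "anti-POSTN", "mIgG", "none")

#' Per-channel assay configuration
#'
#' Surface functionalization of one sensing aMZI: the probe printed on the
#' exposed sensing-arm window and the probe on the reference-arm window. The
#' balanced two-arm design means the channel's net surface signal is the
#' sensing-arm shift minus the reference-arm shift.
#'
#' @param amzi_index Sensing channel index, 1-6.
#' @param sensing_arm_probe,reference_arm_probe One of "anti-TGFBI",
#'   "anti-POSTN", "mIgG", "none" ("none" = unspotted, BSA-blocked).
#' @return An object of class `channel_assay_config`.
#' @export
channel_assay_config <- function(amzi_index, sensing_arm_probe,
                                 reference_arm_probe = "mIgG") {
  if (!amzi_index %in% 1:6) stop("'amzi_index' must be 1-6", call. = FALSE)
  sensing_arm_probe <- match.arg(sensing_arm_probe, .probe_levels)
  reference_arm_probe <- match.arg(reference_arm_probe, .probe_levels)
  structure(list(amzi_index = as.integer(amzi_index),
                 sensing_arm_probe = sensing_arm_probe,
                 reference_arm_probe = reference_arm_probe),
            class = "channel_assay_config")
}

#' Default six-channel assay layout
#'
#' aMZIs 1 and 3 spotted with anti-TGFBI, 5 and 6 with anti-POSTN, 2 and 4
#' left unspotted (BSA-blocked negative controls); every reference arm carries
#' polyclonal mouse IgG.
#'
#' @return List of six [channel_assay_config()] objects.
#' @export
default_assay_channels <- function() {
  probes <- c("anti-TGFBI", "none", "anti-TGFBI", "none",
              "anti-POSTN", "anti-POSTN")
  lapply(1:6, function(i) channel_assay_config(i, probes[i], "mIgG"))
}

.check_channels <- function(channels) {
  if (length(channels) != 6L ||
      !all(vapply(channels, inherits, logical(1), "channel_assay_config"))) {
    stop("'channels' must be a list of exactly six channel_assay_config",
         call. = FALSE)
  }
  idx <- vapply(channels, `[[`, integer(1), "amzi_index")
  if (!identical(sort(idx), 1:6)) {
    stop("channel amzi_index values must be a permutation of 1-6",
         call. = FALSE)
  }
  channels[order(idx)]
}

# Surface shift accumulated on one arm over the program time grid.
# Specific Langmuir binding for the cognate analyte carries occupancy over
# step boundaries; nonspecific and thresholded cross-reactive adsorption
# accumulate linearly while the triggering liquid is present.
.arm_shift_trajectory <- function(probe, steps, models, time_s, step_id,
                                  step_start) {
  n <- length(time_s)
  shift <- numeric(n)
  cognate <- if (probe %in% names(.probe_cognate))
    .probe_cognate[[probe]] else NA_character_
  antibody_arm <- probe %in% names(.probe_cognate)

  # specific binding (closed-form Langmuir, piecewise per step)
  if (!is.na(cognate) && cognate %in% names(models)) {
    model <- models[[cognate]]
    theta <- numeric(n)
    theta_at_step_start <- 0
    for (j in seq_along(steps)) {
      sel <- step_id == j
      if (!any(sel)) next
      conc <- steps[[j]]$analyte_concentrations_ng_ml
      c_m <- if (cognate %in% names(conc))
        ng_ml_to_molar(conc[[cognate]], model$molar_mass_g_mol) else 0
      tt <- time_s[sel] - step_start[j]
      theta[sel] <- langmuir_occupancy(c_m, model, tt, theta_at_step_start)
      theta_at_step_start <- langmuir_occupancy(
        c_m, model, steps[[j]]$duration_s, theta_at_step_start)
    }
    shift <- shift + theta * model$surface_capacity_shift_pm
  }

  # nonspecific + cross-reactive accumulation rates per step
  rate_per_step <- vapply(seq_along(steps), function(j) {
    conc <- steps[[j]]$analyte_concentrations_ng_ml
    r <- 0
    for (a in names(conc)) {
      if (!a %in% names(models)) {
        stop(sprintf("unknown analyte '%s' in step '%s'", a, steps[[j]]$label),
             call. = FALSE)
      }
      m <- models[[a]]
      if (is.na(cognate) || a != cognate) {
        r <- r + m$nonspecific_rate_pm_s_per_ng_ml * conc[[a]]
        if (antibody_arm && conc[[a]] > m$crossreact_threshold_ng_ml) {
          r <- r + m$crossreact_rate_pm_s_per_ng_ml *
            (conc[[a]] - m$crossreact_threshold_ng_ml)
        }
      }
    }
    r
  }, numeric(1))
  if (any(rate_per_step > 0)) {
    dt <- c(diff(time_s), 0)
    shift <- shift + cumsum(rate_per_step[step_id] * dt) -
      rate_per_step[step_id] * dt  # left-rectangle accumulation
  }
  shift
}

#' Run a timed fluidic/assay program
#'
#' Integrates the surface and bulk refractive-index state of all six sensing
#' channels over a fluidic program. Each channel's net surface signal is the
#' sensing-arm shift minus the reference-arm shift (balanced aMZI arms);
#' unspotted control channels additionally accrue a signed drift while
#' protein-containing liquid flows, emulating the opposite-sign control
#' behavior seen with complex samples. The global bulk index follows each
#' step's `bulk_index_delta_riu` through a transport delay and a first-order
#' mixing transient.
#'
#' @param steps List of [flow_step()] objects (the program).
#' @param channels List of six [channel_assay_config()]; default
#'   [default_assay_channels()].
#' @param models Named list of [binding_model()] per analyte; default
#'   [default_binding_models()].
#' @param dt_s Time-grid resolution, s.
#' @param mixing_tau_s First-order time constant of bulk-liquid exchange in
#'   the flow cell, s.
#' @param transport_delay_s Dead time between a pump switch and liquid
#'   arriving at the sensor, s.
#' @param control_drift_rate_pm_s Signed drift rate of unspotted control
#'   channels while protein/serum flows, pm/s.
#' @param serum_background_rate_pm_s_per_pct Net background accumulation on
#'   antibody-spotted channels, pm/s per percent serum.
#' @param instrument_mode Passed to [validate_program()].
#' @return An object of class `analyte_state`: list with `time_s`,
#'   `surface_shift_pm` (matrix, time x 6 channels), `bulk_index_riu`,
#'   `channels`, `steps`.
#' @export
run_assay_program <- function(steps,
                              channels = default_assay_channels(),
                              models = default_binding_models(),
                              dt_s = 0.1,
                              mixing_tau_s = 5,
                              transport_delay_s = 15,
                              control_drift_rate_pm_s = -1.0,
                              serum_background_rate_pm_s_per_pct = 0.03,
                              instrument_mode = FALSE) {
  validate_program(steps, instrument_mode = instrument_mode)
  channels <- .check_channels(channels)
  .check_positive(dt_s, "dt_s")
  durs <- vapply(steps, `[[`, numeric(1), "duration_s")
  if (any(abs(durs / dt_s - round(durs / dt_s)) > 1e-8)) {
    stop("'dt_s' must divide every step duration", call. = FALSE)
  }
  total <- sum(durs)
  time_s <- seq(0, total, by = dt_s)
  step_start <- cumsum(c(0, durs[-length(durs)]))
  step_id <- pmin(findInterval(time_s, step_start), length(steps))
  n <- length(time_s)

  # bulk index: delayed step targets through a first-order mixing filter
  targets <- vapply(steps, `[[`, numeric(1), "bulk_index_delta_riu")
  delayed_id <- pmin(findInterval(pmax(time_s - transport_delay_s, 0),
                                  step_start), length(steps))
  target_t <- targets[delayed_id]
  bulk <- numeric(n)
  alpha <- 1 - exp(-dt_s / mixing_tau_s)
  for (i in seq_len(n - 1)) {
    bulk[i + 1] <- bulk[i] + alpha * (target_t[i] - bulk[i])
  }

  # per-arm surface shifts, net per channel
  arm_cache <- new.env(parent = emptyenv())
  arm_shift <- function(probe) {
    if (is.null(arm_cache[[probe]])) {
      arm_cache[[probe]] <- .arm_shift_trajectory(probe, steps, models,
                                                  time_s, step_id, step_start)
    }
    arm_cache[[probe]]
  }
  protein_present <- vapply(steps, function(s) {
    sum(s$analyte_concentrations_ng_ml) > 0 || s$serum_fraction_pct > 0
  }, logical(1))
  serum_pct <- vapply(steps, `[[`, numeric(1), "serum_fraction_pct")
  dt_grid <- c(diff(time_s), 0)

  surface <- matrix(0, n, 6,
                    dimnames = list(NULL, paste0("amzi", 1:6)))
  for (ch in channels) {
    net <- arm_shift(ch$sensing_arm_probe) - arm_shift(ch$reference_arm_probe)
    if (ch$sensing_arm_probe == "none") {
      rate <- ifelse(protein_present[step_id], control_drift_rate_pm_s, 0)
      net <- net + cumsum(rate * dt_grid) - rate * dt_grid
    }
    if (ch$sensing_arm_probe %in% names(.probe_cognate)) {
      rate <- serum_pct[step_id] * serum_background_rate_pm_s_per_pct
      net <- net + cumsum(rate * dt_grid) - rate * dt_grid
    }
    surface[, ch$amzi_index] <- net
  }

  structure(list(time_s = time_s,
                 surface_shift_pm = surface,
                 bulk_index_riu = bulk,
                 channels = channels,
                 steps = steps),
            class = "analyte_state")
}

#' Simulate a diluted-serum sample exposure
#'
#' Convenience wrapper around [run_assay_program()] that builds the canonical
#' serum protocol — running buffer, water wash, BSA-containing buffer, then
#' the diluted serum sample — and runs it. Serum adds a nonspecific background
#' on antibody-spotted channels and the signed opposite drift on unspotted
#' controls, scaled by the serum fraction.
#'
#' @param serum_fraction_pct Serum content of the sample, percent (0-100).
#' @param analyte_concentrations_ng_ml Named analyte concentrations in the
#'   sample, ng/mL.
#' @param channels,models,dt_s,... Passed to [run_assay_program()].
#' @param sample_duration_s Duration of the serum exposure step, s.
#' @return An `analyte_state` object.
#' @export
serum_sample_state <- function(serum_fraction_pct = 10,
                               analyte_concentrations_ng_ml =
                                 c(TGFBI = 500, POSTN = 500),
                               channels = default_assay_channels(),
                               models = default_binding_models(),
                               dt_s = 0.1,
                               sample_duration_s = 600,
                               ...) {
  if (serum_fraction_pct < 0 || serum_fraction_pct > 100) {
    stop("'serum_fraction_pct' must be in [0, 100]", call. = FALSE)
  }
  steps <- list(
    flow_step("buffer", 60),
    flow_step("wash-water", 30),
    flow_step("buffer-BSA", 30),
    flow_step("sample", sample_duration_s,
              analyte_concentrations_ng_ml = analyte_concentrations_ng_ml,
              serum_fraction_pct = serum_fraction_pct)
  )
  run_assay_program(steps, channels = channels, models = models, dt_s = dt_s,
                    ...)
}

#' @export
print.analyte_state <- function(x, ...) {
  cat("Assay state\n")
  cat(sprintf("  duration : %.1f s (%d samples, dt = %.3g s)\n",
              max(x$time_s), length(x$time_s), x$time_s[2] - x$time_s[1]))
  cat(sprintf("  steps    : %s\n",
              paste(vapply(x$steps, `[[`, character(1), "label"),
                    collapse = " > ")))
  fin <- round(x$surface_shift_pm[nrow(x$surface_shift_pm), ], 1)
  cat("  final net surface shift (pm):\n")
  print(fin)
  invisible(x)
}

#' @export
as.data.frame.analyte_state <- function(x, ...) {
  n <- length(x$time_s)
  data.frame(
    time_s = rep(x$time_s, 6),
    channel = rep(colnames(x$surface_shift_pm), each = n),
    surface_shift_pm = as.vector(x$surface_shift_pm),
    bulk_index_riu = rep(x$bulk_index_riu, 6)
  )
}

#' @export
plot.analyte_state <- function(x, ...) {
  graphics::matplot(x$time_s, x$surface_shift_pm, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "net surface shift (pm)", ...)
  graphics::legend("topleft", colnames(x$surface_shift_pm),
                   col = 1:6, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
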