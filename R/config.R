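# Run configuration: a single nested list, serializable to YAML, validated
# against the package's schema (the structure of `default_config()`), with
# unknown keys rejected so that typos fail loudly rather than silently
# falling back to defaults.

#' Default run configuration
#'
#' The full configuration of a run: chip design (geometry, dispersion,
#' pinned sensitivity), sweep parameters (10 Hz sawtooth, 1000 samples/cycle,
#' a two-FSR span around 850 nm), the three-component noise budget (composing
#' to a 3-sigma of 0.8 pm), assay kinetics and channel layout, analysis
#' thresholds, and the mandatory seed.
#'
#' @return A named nested list of class `run_config`.
#' @export
default_config <- function() {
  models <- default_binding_models()
  structure(list(
    seed = 1L,
    chip = list(
      n_outputs = 8L,
      arm_length_mm = 12.5,
      asym_length_mm = 722500 / (2 * 1500) * 1e-3,
      lambda_res_nm = 850,
      n_eff = 1.55,
      dneff_dlambda_per_nm = -(0.45 / 850),
      sensitivity_override_nm_riu = 5000,
      bulk_sensitivity_nm_riu = 500
    ),
    sweep = list(
      sweep_rate_hz = 10,
      samples_per_cycle = 1000L,
      sweep_span_pm = 3000,
      center_wavelength_nm = 850
    ),
    noise = list(
      sigma_ampl_pm = (0.8 / 3) / sqrt(3),
      sigma_spect_pm = (0.8 / 3) / sqrt(3),
      sigma_temp_pm = (0.8 / 3) / sqrt(3)
    ),
    instrument = list(
      gain = 1.0,
      offset = 0.1,
      temp_tau_cycles = 5,
      instrument_mode = FALSE
    ),
    assay = list(
      dt_s = 0.1,
      mixing_tau_s = 5,
      transport_delay_s = 15,
      control_drift_rate_pm_s = -1.0,
      serum_background_rate_pm_s_per_pct = 0.03,
      channels = lapply(default_assay_channels(), unclass),
      models = lapply(models, unclass),
      program = list()
    ),
    analysis = list(
      baseline_window_s = c(0, 10),
      contrast_floor = 0.01,
      settle_fraction = 0.4,
      detect_k = 5,
      min_threshold_pm = 0.5,
      settling_guard_s = 20,
      qc_bound_pm = 25,
      lod_channel = 1L
    )
  ), class = "run_config")
}

# recursive merge of user values onto defaults, rejecting unknown keys.
# 'free' marks subtrees whose key sets are user-defined (programs, models,
# concentration maps).
.free_keys <- c("program", "models", "analyte_concentrations_ng_ml",
                "channels")

.merge_config <- function(default, user, path = "") {
  if (!is.list(user) || !is.list(default)) return(user)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    if (k %in% .free_keys) {
      default[[k]] <- user[[k]]
    } else {
      default[[k]] <- .merge_config(default[[k]], user[[k]],
                                    paste0(path, k, "$"))
    }
  }
  default
}

.step_from_list <- function(x) {
  known <- c("label", "duration_s", "flow_rate_ul_min",
             "bulk_index_delta_riu", "analyte_concentrations_ng_ml",
             "serum_fraction_pct")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop(sprintf("unknown flow-step key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  conc <- x$analyte_concentrations_ng_ml
  do.call(flow_step, c(
    list(label = x$label, duration_s = x$duration_s),
    x[setdiff(names(x), c("label", "duration_s",
                          "analyte_concentrations_ng_ml"))],
    list(analyte_concentrations_ng_ml = unlist(conc %||% numeric(0)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialize configuration objects
#'
#' Builds the typed objects (chip layout, sweep config, noise budget,
#' channel configs, binding models, fluidic program) from a validated
#' [default_config()]-shaped list, enforcing every type invariant on the way.
#'
#' @param cfg A `run_config` list.
#' @return List with `layout`, `sweep`, `noise`, `channels`, `models`,
#'   `program`, `design`.
#' @export
config_objects <- function(cfg) {
  if (cfg$chip$n_outputs != 8L) {
    stop("'chip$n_outputs' must be 8 (6 sensing + bulk + reference)",
         call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("'seed' is mandatory", call. = FALSE)
  mode <- mode_dispersion(cfg$chip$n_eff, cfg$chip$dneff_dlambda_per_nm,
                          cfg$chip$lambda_res_nm)
  design <- amzi_design(cfg$chip$arm_length_mm, cfg$chip$asym_length_mm,
                        cfg$chip$lambda_res_nm, mode,
                        cfg$chip$sensitivity_override_nm_riu)
  layout <- chip_layout(design, cfg$chip$bulk_sensitivity_nm_riu)
  sweep <- sweep_config(cfg$sweep$sweep_rate_hz, cfg$sweep$samples_per_cycle,
                        cfg$sweep$sweep_span_pm,
                        cfg$sweep$center_wavelength_nm)
  noise <- noise_budget(cfg$noise$sigma_ampl_pm, cfg$noise$sigma_spect_pm,
                        cfg$noise$sigma_temp_pm)
  channels <- lapply(cfg$assay$channels, function(ch) {
    channel_assay_config(ch$amzi_index, ch$sensing_arm_probe,
                         ch$reference_arm_probe %||% "mIgG")
  })
  models <- lapply(cfg$assay$models, function(m) do.call(binding_model, m))
  program <- lapply(cfg$assay$program, function(s) {
    if (inherits(s, "flow_step")) s else .step_from_list(s)
  })
  if (length(program)) {
    validate_program(program,
                     instrument_mode = isTRUE(cfg$instrument$instrument_mode))
  }
  list(layout = layout, sweep = sweep, noise = noise, channels = channels,
       models = models, program = program, design = design)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration file, applies
#' package defaults for absent keys, rejects unknown keys, and validates all
#' type invariants by materializing the configuration objects.
#'
#' @param path Path to the configuration file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file '%s' not found", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(unclass(default_config()), user)
  class(cfg) <- "run_config"
  config_objects(cfg)  # validation side effect
  cfg
}

#' Save a run configuration to YAML
#'
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  o <- config_objects(x)
  cat("aMZI twin run configuration\n")
  cat(sprintf("  seed: %d\n", as.integer(x$seed)))
  print(o$design)
  cat(sprintf("  sweep: %.4g Hz x %d samples (%.4g kHz/photodiode), span %.4g pm\n",
              o$sweep$sweep_rate_hz, o$sweep$samples_per_cycle,
              sample_rate_hz(o$sweep) / 1000, o$sweep$sweep_span_pm))
  cat(sprintf("  noise 3-sigma: %.3g pm\n", measurement_noise_3sigma(o$noise)))
  cat(sprintf("  program: %d step(s)\n", length(o$program)))
  invisible(x)
}
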