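# End-to-end pipeline: configuration -> assay state -> raw sweeps ->
# sensorgram -> performance report; plus the canonical desk-scale fixtures
# emulating the device's validation experiments.

#' Run the full simulation and analysis pipeline
#'
#' Executes the whole chain for a configuration: integrates the fluidic/assay
#' program into refractive-index trajectories, simulates the swept-wavelength
#' acquisition with the configured noise budget, demodulates every cycle with
#' the Fourier phase extractor, tracks and baselines the sensorgram, and
#' derives the performance figures (FSR, sensitivity, estimated resolution
#' and LoD) plus QC flags. Deterministic for a fixed configuration and seed.
#'
#' If the program contains no steps, a quiet baseline run of
#' `baseline_duration_s` is simulated instead.
#'
#' @param cfg A `run_config` (see [default_config()], [load_config()]).
#' @param out_dir Optional output directory; when given, writes
#'   `sensorgram.csv`, `assay_state.csv` (if a program ran), `report.json`
#'   and optionally `raw.csv`.
#' @param write_raw Write the (large) raw interferogram CSV.
#' @param baseline_duration_s Duration of the quiet run used when the
#'   program is empty, s.
#' @return Invisibly, a list with `state`, `raw`, `sensorgram`, `steps`
#'   (step analysis or NULL) and `report`.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = NULL,
                         write_raw = FALSE, baseline_duration_s = 60) {
  o <- config_objects(cfg)
  a <- cfg$assay
  an <- cfg$analysis

  state <- NULL
  if (length(o$program)) {
    state <- run_assay_program(
      o$program, channels = o$channels, models = o$models, dt_s = a$dt_s,
      mixing_tau_s = a$mixing_tau_s, transport_delay_s = a$transport_delay_s,
      control_drift_rate_pm_s = a$control_drift_rate_pm_s,
      serum_background_rate_pm_s_per_pct = a$serum_background_rate_pm_s_per_pct,
      instrument_mode = isTRUE(cfg$instrument$instrument_mode))
    duration <- max(state$time_s)
  } else {
    duration <- baseline_duration_s
  }
  n_cycles <- max(2L, floor(duration * o$sweep$sweep_rate_hz))

  raw <- simulate_cycles(o$layout, state, o$sweep, o$noise,
                         n_cycles = n_cycles, seed = cfg$seed,
                         gain = cfg$instrument$gain,
                         offset = cfg$instrument$offset,
                         temp_tau_cycles = cfg$instrument$temp_tau_cycles)
  sg <- track_sensorgram(raw, baseline_window = an$baseline_window_s,
                         contrast_floor = an$contrast_floor)

  resolution <- tryCatch(
    estimate_resolution(sg, an$baseline_window_s, program = o$program),
    error = function(e) rep(NA_real_, ncol(sg$shift_pm)))
  s_pinned <- o$design$sensitivity_nm_riu
  lod_ch <- an$lod_channel
  lod <- if (all(is.na(resolution))) NA_real_ else
    limit_of_detection(resolution[[lod_ch]], s_pinned)

  # QC: the sealed reference must always stay quiet; the bulk monitor only
  # when the program does not intentionally step the bulk index.
  qc_channels <- which(sg$roles == "internal_reference")
  bulk_stepped <- length(o$program) &&
    any(vapply(o$program, `[[`, numeric(1), "bulk_index_delta_riu") != 0)
  if (!bulk_stepped) {
    qc_channels <- c(which(sg$roles == "bulk_low_sensitivity"), qc_channels)
  }
  qc <- qc_check(sg, bound_pm = an$qc_bound_pm, channels = qc_channels)

  steps <- NULL
  if (length(o$program) > 1) {
    steps <- analyze_steps(sg, o$program, channel = lod_ch,
                           settle_fraction = an$settle_fraction,
                           detect_k = an$detect_k,
                           min_threshold_pm = an$min_threshold_pm,
                           settling_guard_s = an$settling_guard_s)
  }

  report <- list(
    seed = as.integer(cfg$seed),
    n_cycles = n_cycles,
    sample_rate_hz = sample_rate_hz(o$sweep),
    fsr_pm = o$design$fsr_pm,
    sensitivity_nm_riu = s_pinned,
    sensitivity_intrinsic_nm_riu = o$design$sensitivity_intrinsic_nm_riu,
    resolution_pm = unname(resolution[[lod_ch]]),
    lod_riu = lod,
    qc_flags = as.list(qc),
    qc_pass = !any(qc),
    low_contrast_frac = as.list(sg$low_contrast_frac)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(sg),
                     file.path(out_dir, "sensorgram.csv"), row.names = FALSE)
    if (!is.null(state)) {
      utils::write.csv(as.data.frame(state),
                       file.path(out_dir, "assay_state.csv"),
                       row.names = FALSE)
    }
    if (!is.null(steps)) {
      utils::write.csv(as.data.frame(steps),
                       file.path(out_dir, "step_analysis.csv"),
                       row.names = FALSE)
    }
    if (write_raw) {
      utils::write.csv(as.data.frame(raw), file.path(out_dir, "raw.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(state = state, raw = raw, sensorgram = sg, steps = steps,
                 report = report))
}

# refractive-index increment of NaCl in water, RIU per mol/L
NACL_DNDC_RIU_PER_M <- 0.0101

#' Build a named desk-scale fixture configuration
#'
#' Self-contained configurations reproducing the qualitative structure of the
#' device's three validation experiments:
#'
#' * `"titration"` — spiked-buffer multiplex titration: increasing TGFBI then
#'   POSTN concentrations from 100 to 2500 ng/mL with buffer washes, on a
#'   chip with anti-TGFBI on aMZIs 1 and 3, anti-POSTN on 5 and 6 and mouse
#'   IgG on 2 and 4.
#' * `"serum"` — a 10% diluted serum sample on the default layout (unspotted
#'   BSA-blocked controls on aMZIs 2 and 4), with nonspecific serum
#'   background on spotted channels and opposite-signed control drift.
#' * `"salt_steps"` — the bulk-refractive-index validation: alternating PBS
#'   and PBS with NaCl reduced by 40 mM, 60 uL per step at 48 uL/min (75 s
#'   per step), run in instrument mode.
#'
#' @param name One of `"titration"`, `"serum"`, `"salt_steps"`.
#' @param seed Seed stored in the configuration.
#' @return List with `config` (a `run_config`) and `expected` (shape
#'   metadata: what the fixture should qualitatively produce).
#' @export
make_fixture <- function(name = c("titration", "serum", "salt_steps"),
                         seed = 1L) {
  name <- match.arg(name)
  cfg <- default_config()
  cfg$seed <- as.integer(seed)

  if (name == "titration") {
    conc <- c(100, 500, 1000, 2500)
    steps <- list(list(label = "buffer", duration_s = 60,
                       flow_rate_ul_min = 60))
    for (analyte in c("TGFBI", "POSTN")) {
      for (c_i in conc) {
        steps <- c(steps, list(
          list(label = sprintf("%s-%g", analyte, c_i), duration_s = 120,
               flow_rate_ul_min = 60,
               analyte_concentrations_ng_ml = stats::setNames(list(c_i),
                                                              analyte)),
          list(label = "wash", duration_s = 30, flow_rate_ul_min = 60)))
      }
    }
    cfg$assay$program <- steps
    probes <- c("anti-TGFBI", "mIgG", "anti-TGFBI", "mIgG",
                "anti-POSTN", "anti-POSTN")
    cfg$assay$channels <- lapply(1:6, function(i) {
      list(amzi_index = i, sensing_arm_probe = probes[i],
           reference_arm_probe = "mIgG")
    })
    expected <- list(
      analyte_order = c("TGFBI", "POSTN"),
      concentrations_ng_ml = conc,
      cognate_channels = list(TGFBI = c(1, 3), POSTN = c(5, 6)),
      control_channels = c(2, 4),
      crossreact_analyte = "POSTN",
      crossreact_threshold_ng_ml = 1000)
  } else if (name == "serum") {
    cfg$assay$program <- list(
      list(label = "buffer", duration_s = 60, flow_rate_ul_min = 60),
      list(label = "wash-water", duration_s = 30, flow_rate_ul_min = 60),
      list(label = "buffer-BSA", duration_s = 30, flow_rate_ul_min = 60),
      list(label = "sample", duration_s = 600, flow_rate_ul_min = 60,
           serum_fraction_pct = 10,
           analyte_concentrations_ng_ml = list(TGFBI = 500, POSTN = 500)))
    expected <- list(
      serum_fraction_pct = 10,
      spotted_channels = c(1, 3, 5, 6),
      control_channels = c(2, 4),
      spotted_sign = 1, control_sign = -1)
  } else { # salt_steps
    delta_n <- -0.040 * NACL_DNDC_RIU_PER_M
    mk <- function(label, dn) {
      list(label = label, duration_s = 75, flow_rate_ul_min = 48,
           bulk_index_delta_riu = dn)
    }
    cfg$assay$program <- c(
      list(mk("PBS-prime", 0)),
      rep(list(mk("PBS-lowNaCl", delta_n), mk("PBS", 0)), 3))
    cfg$instrument$instrument_mode <- TRUE
    expected <- list(
      step_volume_ul = 60,
      flow_rate_ul_min = 48,
      step_duration_s = 75,
      bulk_delta_riu = delta_n,
      expected_step_amplitude_pm =
        abs(delta_n) * cfg$chip$sensitivity_override_nm_riu * 1000)
  }
  list(config = cfg, expected = expected)
}
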