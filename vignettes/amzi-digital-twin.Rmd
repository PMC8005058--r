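---
title: "Modelling a multiplexed aMZI biosensor: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a multiplexed aMZI biosensor: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amzitwin)
```

## The sensing principle

An asymmetric Mach–Zehnder interferometer (aMZI) splits guided light over
two waveguide arms of unequal optical path and recombines them. The
transmitted power follows the two-beam interference law

$$T(\Delta\varphi) = \tfrac{1}{2}\left(1 + \cos\Delta\varphi\right),
\qquad \Delta\varphi = \frac{2\pi}{\lambda}\,\mathrm{OPD},$$

so the transmission is a sinusoid in wavelength with period equal to the
free spectral range, $\mathrm{FSR} = \lambda_0^2/(n_g L_\mathrm{asym})$,
where $n_g = n_\mathrm{eff} - \lambda_0\,dn_\mathrm{eff}/d\lambda$ is the
group index. One arm of each sensing aMZI has its oxide cladding opened so
the evanescent field samples the liquid: molecules binding inside that
window raise the local refractive index, raise $n_\mathrm{eff}$, and shift
the fringe pattern to the red. Tracking the fringe position over time is a
sensorgram, the same readout logic as surface plasmon resonance but with a
wavelength-swept single-frequency laser and on-chip interferometers.

The twin models the optical path difference as the sum of two terms,
$\mathrm{OPD} = n_\mathrm{eff}\,\Delta L_\mathrm{geo} +
\Delta n_\mathrm{eff}\,L$: the geometric asymmetry sets the FSR while the
sensing-window index change moves the fringes. Only their sum is
observable per cycle, but both are needed for an interferometer that is
simultaneously asymmetric and analyte-sensitive. An index increase is
defined to produce a positive (red) shift.

### Two sensitivity scales

The effective-index sensitivity of a design follows
$S = L\,\mathrm{FSR}/\lambda_\mathrm{res}$; with the default 12.5 mm arms,
1500 pm FSR and 850 nm operation this evaluates to about 22 000 nm/RIU.
The response to a *bulk cladding* index change is smaller by the mode's
cladding confinement factor, which depends on the layer stack and is not
computed here (no mode solver is in scope). Device-level work quotes bulk
sensitivities up to 5000 nm/RIU for this geometry, so the shipped designs
*pin* their working sensitivity at 5000 nm/RIU through
`sensitivity_override_nm_riu`, and every bulk-index response in the
simulator uses the pinned value. Both numbers are exposed on the design
object; the confinement factor itself is deliberately not guessed.

### Performance figures

Resolution is the 3-sigma scatter of the measured fringe position. Three
independent contributions are budgeted in wavelength-equivalent picometres
— amplitude (intensity) noise, spectral (laser wavelength) noise and
temperature drift — and compose by root-sum-square:
$3\sigma_\mathrm{meas} = 3\sqrt{\sigma_a^2+\sigma_s^2+\sigma_t^2}$. The
limit of detection is $\mathrm{LoD} = R/S$. The default budget splits
0.8 pm (3-sigma) equally over the three components, giving
$\mathrm{LoD} = 1.6\times10^{-7}$ RIU at the pinned sensitivity:

```{r}
performance_figure(amzi_design(), noise_budget())
```

## The assay model

The chip carries eight outputs: six sensing aMZIs, one low-sensitivity
bulk monitor and one sealed internal reference. Each sensing aMZI is
balanced — a functionalized sensing-arm window and a reference-arm window
exposed to the same liquid — so its net surface signal is the difference of
the two arm shifts, which cancels adsorption common to both chemistries.

Specific capture follows closed-form 1:1 Langmuir kinetics,
$\theta(t) = \theta_{eq} + (\theta_0-\theta_{eq})
e^{-(k_{on}c + k_{off})t}$, integrated piecewise across fluidic steps with
occupancy carried over step boundaries. No kinetic constants are published
for these antibody clones, so the defaults are a deliberate one-time
choice of ordinary nanomolar-affinity monoclonal behaviour:
$k_{on} = 10^5\ \mathrm{M^{-1}s^{-1}}$, $k_{off} = 10^{-4}\ \mathrm{s^{-1}}$
($K_D = 1$ nM), full-occupancy shifts of 2000 pm, molar masses 68 kDa
(TGFBI) and 90 kDa (periostin). Under these defaults a 10 ng/mL sample
produces tens of picometres within a half-hour incubation — comfortably
above the 0.8 pm noise floor, matching the detectability the device
demonstrates at that concentration.

Three phenomenological terms complete the model, all free parameters with
documented defaults:

* **Nonspecific adsorption** accumulates linearly with concentration on
  every surface; being common to both balanced arms, it cancels in the net
  channel signal.
* **Cross-reactivity**: periostin above 1 µg/mL adds a thresholded
  adsorption term on antibody-coated (non-cognate) surfaces only, so it
  survives differential referencing — reproducing the nonspecific response
  observed at high periostin concentrations.
* **Control drift**: unspotted, BSA-blocked channels drift with a signed
  rate (default −1 pm/s) while protein-containing liquid flows. The
  opposite-sign control shift is consistently observed with complex
  samples and its mechanism is debated (surface rearrangement, reversible
  adsorption); the twin models the phenomenon, not a mechanism, and the
  serum background on spotted channels (default 0.03 pm/s per % serum) is
  equally phenomenological.

Bulk refractive-index changes follow each step's target through a
transport dead time (default 15 s, matching the observed delay between a
pump switch and the optical response) and a first-order mixing transient
(default 5 s). The −40 mM NaCl step uses the standard refractive-index
increment 0.0101 RIU per mol/L, i.e. −4.04×10⁻⁴ RIU; no published RIU
value exists for this step, so the increment is the defensible choice.

## The instrument model

A sawtooth current sweeps the VCSEL at 10 Hz; the twin parameterizes the
sweep directly in wavelength (linear ramp, centre 850 nm) because no
current-tuning coefficient is published and demodulation is per-cycle.
Each photodiode records 1000 samples per cycle (10 kHz). The sweep span
defaults to 3000 pm = 2 FSR so every record holds two full fringes — an
integer fringe count keeps the Fourier estimate leakage-free.

Noise enters exactly where the budget says it lives:

* **Amplitude noise** is white intensity noise per sample. Its standard
  deviation is calibrated as $\sigma_I = \sigma_\varphi\, a\sqrt{N/2}$
  (fringe amplitude $a$, $N$ samples/cycle), the first-order inverse of
  the DFT phase-error variance for a sinusoid in white noise, so that a
  budget entry of $\sigma$ pm demodulates back to $\sigma$ pm.
* **Spectral noise** is a per-cycle wavelength jitter of the whole ramp,
  common to all channels (one shared laser).
* **Temperature noise** is a slow common-mode fringe drift, modelled AR(1)
  with a 5-cycle correlation time and stationary SD equal to the budget
  entry.

A single top-level seed deterministically derives independent sub-streams
for the two common-mode terms and for each channel's amplitude noise, so
runs are bit-reproducible and channels are statistically independent.

## Demodulation

Each cycle's interferogram is demodulated by discrete Fourier transform:
the largest non-DC bin is selected (ties toward lower frequency), and its
argument — re-referenced to the sweep-centre sample — is the fringe phase.
Referencing the centre rather than the first sample matters: the phase
sensitivity to an OPD change is then $2\pi/\lambda_0$ exactly, so the
conversion to picometres through the centre-wavelength FSR round-trips
programmed shifts without the $O(\mathrm{span}/\lambda)$ bias a
start-referenced phase would carry. No window function is applied by
default because the default span is an integer number of FSRs; with
non-integer fringe counts the conjugate-bin leakage limits accuracy to
roughly the 10⁻³–10⁻² rad level and a window becomes worthwhile. On
noiseless integer-fringe records the extractor agrees with a nonlinear
least-squares cosine fit to better than 10⁻⁹ rad (the test suite carries
that oracle).

Phases are unwrapped cycle-to-cycle by nearest multiple of 2π, which
assumes the fringe moves less than FSR/2 between cycles (75 pm per 100 ms
at the default settings) — channels approaching that limit are flagged.
Sensorgrams are baseline-zeroed on the first 10 s by default. A flat
record (fringe contrast below 1%) yields a low-contrast flag rather than
an error, so a dead channel cannot abort a run.

Analysis thresholds, all configurable: resolution windows must hold at
least 30 cycles and contain no programmed liquid change; step plateaus are
the final 40% of each step; step detection triggers at 5× the previous
plateau's SD (with a 0.5 pm absolute floor, since a noiseless plateau has
zero SD); steps shorter than 20 s are flagged unsettled. The bulk monitor
and the sealed reference act as run-validity checks: excursions beyond
25 pm raise QC flags (the bulk monitor is exempted when the program
intentionally steps the bulk index).

## Fixtures, and what passing them shows

`make_fixture()` builds three desk-scale experiments: the spiked-buffer
titration (100→2500 ng/mL of each biomarker, mouse-IgG control channels),
the 10% serum exposure (unspotted BSA controls on channels 2 and 4), and
the alternating PBS / low-NaCl bulk validation (60 µL per step at
48 µL/min, hence 75 s steps, run under the 4–200 µL/min instrument flow
limits). Desk scale means minutes of simulated time, not the multi-hour
laboratory protocols: the suite verifies structure — specificity,
cross-reactivity thresholds, sign and ordering of serum responses, settled
plateaus and volume bookkeeping — not absolute biological magnitudes.
Serum shift magnitudes in particular depend on real patient material and
are emulated qualitatively only.

The test and acceptance problem sizes are the package's own choice of
desk scale: 400-cycle (40 s) baselines for noise/LoD recovery, repeated
over ten seeds; 510 s (5100-cycle) salt-step runs; assay trajectories at
0.1–0.5 s resolution. At these sizes the whole suite runs in well under a
minute on one core.

## Known limitations

* No electromagnetic mode solving: $n_\mathrm{eff}$, its dispersion and
  the confinement factor are inputs, not outputs.
* No mass-transport or depletion modelling; binding sees the bulk
  concentration directly after the transport delay.
* The VCSEL ramp is ideal (linear in wavelength, no tuning nonlinearity,
  no intra-cycle dynamics) and the detector chain is gain + offset +
  white noise — no TIA shaping or ADC quantization.
* Kinetic and background parameters are plausible defaults, not fitted
  constants; quantitative concentration calibration (pm → ng/mL) is out
  of scope, as is any processing of real instrument files.
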