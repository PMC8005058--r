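# amzitwin

A digital twin of a multiplexed **asymmetric Mach–Zehnder interferometer
(aMZI) photonic biosensor** for blood-borne protein biomarkers. The package
simulates the complete signal chain — analyte binding on functionalized
waveguide surfaces, effective-index changes, swept-wavelength interferogram
acquisition with a realistic noise budget, Fourier phase demodulation into
sensorgrams, differential referencing — and computes the standard
refractometric performance figures. It is aimed at people developing or
evaluating label-free optical immunosensors who need a faithful, fully
controllable software replica of the instrument: for testing demodulation
and referencing algorithms against known ground truth, budgeting noise, or
designing assay protocols before touching hardware.

## The model

An aMZI transmits
$T(\Delta\varphi) = \tfrac12(1+\cos\Delta\varphi)$ with
$\Delta\varphi = 2\pi\,\mathrm{OPD}/\lambda$, so its transmission is
periodic in wavelength with free spectral range
$\mathrm{FSR} = \lambda_0^2/(n_g L_\mathrm{asym})$, where
$n_g = n_\mathrm{eff}-\lambda_0\,dn_\mathrm{eff}/d\lambda$. Binding in the
exposed sensing window raises $n_\mathrm{eff}$ and red-shifts the fringes;
the effective-index sensitivity is
$S = L\,\mathrm{FSR}/\lambda_\mathrm{res}$ (bulk-cladding configurations
pin a measured bulk sensitivity instead — 5000 nm/RIU by default).
Resolution is the 3σ fringe-position noise, composed from amplitude,
spectral and temperature terms,
$3\sigma = 3\sqrt{\sigma_a^2+\sigma_s^2+\sigma_t^2}$, and the limit of
detection is $\mathrm{LoD} = R/S$.

The simulated instrument is an 8-output chip (6 sensing aMZIs, one
low-sensitivity bulk monitor, one sealed reference) read by a 10 Hz
sawtooth-swept VCSEL at 1000 samples per cycle per photodiode (10 kHz).
Surface binding follows closed-form 1:1 Langmuir kinetics per fluidic step;
demodulation takes the argument of the dominant DFT bin of each sine-like
interferogram, unwraps it across cycles and converts it to picometres via
the FSR. See the methods vignette (`vignettes/amzi-digital-twin.Rmd`) for
every modelling decision and default.

## Worked example

Design figures, then a full simulate–demodulate–analyze run of the
bulk-index validation experiment (alternating PBS and PBS with NaCl reduced
by 40 mM, 60 µL per step at 48 µL/min):

```r
library(amzitwin)
performance_figure(amzi_design(), noise_budget())
#> aMZI performance figures
#>   FSR         : 1500 pm
#>   sensitivity : 5000 nm/RIU
#>   resolution  : 0.8 pm (3-sigma)
#>   LoD         : 1.6e-07 RIU

fx <- make_fixture("salt_steps", seed = 7)
res <- run_pipeline(fx$config)
res$steps
#> Step analysis
#>  step       label t_start_s t_end_s plateau_pm plateau_sd_pm level_diff_pm
#>     1   PBS-prime         0      75  3.892e-02        0.2707            NA
#>     2 PBS-lowNaCl        75     150 -2.019e+03        1.2290         -2019
#>     3         PBS       150     225 -8.231e-01        1.2592          2018
#>     4 PBS-lowNaCl       225     300 -2.019e+03        1.2174         -2018
#>     ...
#>  detect_time_s response_delay_s settled
#>             NA               NA    TRUE
#>           90.1             15.1    TRUE
#>          165.1             15.1    TRUE
```

Each −40 mM NaCl step is −4.04×10⁻⁴ RIU; at the pinned 5000 nm/RIU it
produces the ~2020 pm plateau-to-plateau swing recovered above. The 15.1 s
response delay is the liquid transport dead time; `settled` confirms each
plateau stabilizes before the next liquid change. The same run reports an
estimated baseline resolution of 0.833 pm and LoD of 1.67×10⁻⁷ RIU —
scattered, as expected, around the 0.8 pm / 1.6×10⁻⁷ RIU budget values.

Other entry points: `run_assay_program()` / `serum_sample_state()` for
binding trajectories, `simulate_cycles()` for raw interferograms,
`track_sensorgram()`, `differential_signal()`, `estimate_lod()`,
`analyze_steps()` for the analysis half, and `load_config()` /
`save_config()` for YAML run configurations (examples in `inst/extdata/`).
A thin command-line wrapper lives at `inst/cli/amzi_twin.R`:

```sh
Rscript inst/cli/amzi_twin.R describe
Rscript inst/cli/amzi_twin.R run --config inst/extdata/salt_steps.yaml --seed 1 --out out/
```

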