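# fwavetilt

Quantifying autonomic effects on atrial fibrillatory waves during tilt
testing.

During atrial fibrillation (AF) the ECG shows no P waves; instead the atria
produce continuous fibrillatory waves (f-waves) whose repetition rate — the
atrial fibrillatory rate, typically 4–12 Hz — reflects atrial refractoriness
and hence autonomic (sympathetic/parasympathetic) tone. Head-down and head-up
tilt provoke controlled autonomic shifts, so tracking the f-wave frequency
and its respiration-linked modulation across tilt phases probes how the
autonomic nervous system shapes AF. `fwavetilt` implements the complete
analysis chain for this experiment, plus a ground-truth synthetic generator
used to validate every stage. It is aimed at cardiac electrophysiology signal
processing: people analysing multi-lead AF ECGs from tilt or other autonomic
protocols, and people post-processing simulated atrial activation maps.

## What it computes

For each of the six protocol phases (B1, B2, HDT1, HDT2, HUT1, HUT2 — the
first 2 and last 3 minutes of baseline, −30° head-down and +60° head-up
tilt):

* **f-wave frequency trend `f(m)`** — the ECG is QRST-cancelled on lead V1
  (average beat subtraction with per-beat least-squares scaling; ectopic
  beats are detected against a normal template and their windows excluded),
  resampled to 50 Hz, and the analytic signal is fitted on sliding 0.5-s
  windows with the two-harmonic model

  `s(n; θ) = Σ_{p=1,2} A_p exp(j(2π p f n / f_s + φ_p))`,

  maximizing the likelihood over `f` in `[f0 − 1.5, f0 + 1.5]` Hz (grid
  search refined by golden section), where `f0` is the Welch-periodogram peak
  in [4, 12] Hz. A signal-quality index `S = 1 − σ_ê/σ_xa` gates 5-s blocks
  at `S > 0.3`; recordings with more than 10% failing blocks are excluded.
  **Ff** is the per-phase median of `f(m)`.
* **FHR** — mean heart rate from RR intervals not adjacent to ectopic beats.
* **ECG-derived respiration** — per-lead QRS slope-range series (max − min
  derivative around R) combined by periodic component analysis (πCA) into a
  joint-lead respiration signal `r(m)` and rate **FRR**.
* **Respiratory f-wave modulation** — the detrended trend is projected onto
  the subspace spanned by delayed copies of `r(m)`
  (`f_r = V(VᵀV)⁻¹Vᵀ f̃`); **ΔFf = √(2 f_rᵀf_r/(M−q))** is the average peak
  amplitude of the respiration-linked frequency variation and
  **Pr = 100·f_rᵀf_r/f̃ᵀf̃** its relative power.
* **Simulated activation analysis** — from per-point activation times (as
  extracted from atrial simulations), per-point instantaneous frequency at
  10 Hz, spectral peak-conditioned point selection, the mean trend `f_s(m)`,
  its median **Ffs**, and **ΔFfs** against a fixed 0.14 Hz reference
  sinusoid.
* **Phase statistics** — Lilliefors normality screening (Monte-Carlo null),
  exact Wilcoxon signed-rank tests, Bonferroni correction over the nine
  protocol comparisons, and increase/decrease/minimal response coding.

## Worked example

```r
library(fwavetilt)

scenario <- tiltScenario(seed = 101)       # calibrated six-phase study
gen <- generateTiltRecording(scenario)     # two-lead 900-s ECG + truth
res <- runEcgPipeline(gen$record, patient = "s101")
res$table[, c("phase", "ff_hz", "fhr_bpm", "frr_hz", "delta_ff_hz")]
```

```
  phase ff_hz fhr_bpm frr_hz delta_ff_hz
1    B1 6.771   94.53 0.1299     0.07114
2    B2 6.672   90.58 0.1299     0.06757
3  HDT1 6.495   91.84 0.1502     0.08549
4  HDT2 6.535   95.23 0.1603     0.05674
5  HUT1 6.763   98.17 0.1199     0.07460
6  HUT2 6.715   97.12 0.1502     0.06897
```

The scenario injects, per phase, a known fundamental (6.74, 6.69, 6.49,
6.55, 6.77, 6.72 Hz), heart rate, respiration rate and modulation amplitude
(0.077, 0.070, 0.090, 0.063, 0.081, 0.079 Hz); the table above is the
pipeline's blind recovery of those values from the raw synthetic ECG —
fundamentals within a few hundredths of a Hz, respiration rates on the scan
grid, modulation amplitudes within a few thousandths of a Hz. The
characteristic tilt signature (f-wave frequency drop into head-down tilt,
rise into head-up tilt; modulation enhancement in the head-down transient)
is preserved. `summarizeMetrics()` and `comparePhases()` then produce the
cohort table and the Bonferroni-corrected paired comparisons.

For simulation post-processing:

```r
act <- generateActivationSeries(nPoints = 223, duration = 60,
                                fracUnpeaked = 0.3)
runActivationPipeline(list(act$set),
                      defaultAnalysisConfig(activationWindowSeconds = NULL))$table
```

A thin command-line wrapper is installed under `inst/cli/fwavetilt`
(subcommands `simulate`, `analyze`, `activation`, `stats`).

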