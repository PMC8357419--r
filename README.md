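# spindev

Analysis of spindle-band (8–25 Hz) oscillations in developing cortex —
spindle bursts and delta brushes in the immature brain, sleep spindles
after maturation — and of the developmental trajectories of their
properties. The package targets neonatal rodent LFP (int16 binary +
channel-map sidecar) and infant scalp EEG (EDF), and bundles a
ground-truthed synthetic-data module so the whole pipeline can be
validated without restricted clinical or animal data.

## What it computes

* **State scoring** from the EMG envelope: wake (high tone ≥ 1.5 s),
  twitches (< 1.5 s bursts on atonia), atonia (≥ 2 s below threshold),
  quiet sleep (twitch-free atonia ≥ 10 s) and active sleep.
* **Spindle-band events** via the power-asymmetry ratio

  `PAR = (Pspi − (Plow + Phigh)) / (Pspi + Plow + Phigh)`

  computed from Gabor-wavelet band powers (Pspi: 8–25 Hz, Plow: 1–5 Hz —
  2–6 Hz for infants under 40 post-gestational weeks, Phigh: 30–80 Hz).
  Events are PAR > −0.1 runs of 0.3–5 s with a positive PAR peak and
  spindle power above a MAD-scaled threshold inside sleep.
* **Event characterization**: median Hilbert-envelope power, spatial
  extent (fraction of channels with a co-occurring event: overlap
  > 300 ms, midpoint separation ≤ 50 ms), and waveform asymmetry (ESR —
  peak vs trough sharpness at ±8 ms, extrema located between
  zero-crossings of the 5–30 Hz trace).
* **Cross-frequency coupling**: event-locked amplitude–amplitude
  comodulograms, the spindle-band coupling curve, retained peaks
  (prominence > 0.75, width rule) with coupling index
  `value × prominence / width`, and band AUC.
* **Spiking**: multi-unit detection at 4× the MAD noise floor with
  artifact and duplicate removal, ISI, autocorrelograms with
  hollow-kernel 95% confidence bands, baseline-normalized event-triggered
  rates, and spindle-phase locking (von Mises kappa + Rayleigh/Kuiper
  test; significant iff kappa > 0.1 and p < 0.05).
* **Trajectories**: polynomial fits of feature vs age selected by
  per-animal LOOCV, bootstrap localization of the first interior
  extremum (the developmental nadir) against an across-age null, a
  combinatorial maturation metric of asymmetry/extent/power, and a
  coarse decision-tree maturity classifier.

## Worked example

```r
library(spindev)

# synthesise a 2-minute recording with 20 known spindle-band events
spec <- synth_lfp_spec(n_channels = 1, duration = 120, n_events = 20)
g <- generate_lfp(spec, seed = 42)

# detect events with the PAR statistic
pr <- compute_par(g$recording$signal[1, ], g$recording$fs)
ev <- detect_spindle_events(pr, data.frame(start_s = 0, end_s = 120))
nrow(ev)            # 20  (all 20 injected events recovered)
round(ev$peak_par[1:3], 2)   # 0.92 0.90 0.97

# characterize the first event
event_power(g$recording$signal[1, ], g$recording$fs,
            ev$start_s[1], ev$end_s[1])    # 121.2 uV (125 uV injected, 25 uV background)
waveform_asymmetry(g$recording$signal[1, ], g$recording$fs,
                   ev$start_s[1], ev$end_s[1])$esr   # 1.04 (symmetric events)

# a developmental cohort with a programmed nadir at age 8.5
co  <- generate_cohort(cohort_spec(), seed = 1)   # 7 animals/day, P5-P14
fit <- fit_trajectory(co)                         # LOOCV picks degree 2
nad <- bootstrap_nadir(co, fit$best$degree, n_boot = 2000, seed = 1)
nad$mode_age      # 8.5 — the bootstrap mode lands on the true vertex
nad$exceedance    # 6.5 — within-age mass at the mode vs the across-age null
```

Numbers shown are what the calls print under these seeds: the detector
recovers all 20 events, the events' ESR sits at 1 because the generator
injected symmetric waveforms, and the bootstrap localizes the programmed
nadir in the 8–9 age bin with several-fold exceedance over the null.

A full multi-stage run (simulation → scoring → detection →
characterization → coupling → spikes → trajectory) with CSV/JSON outputs:

```r
cfg <- pipeline_config(out_dir = "out", seed = 1,
                       lfp = list(duration = 60, n_events = 10))
run_pipeline(cfg)
```

or from a shell via the bundled CLI:

```sh
Rscript inst/cli/spindev run-all --out out --seed 1
```

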