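# tsaprv

Pulse rate variability (PRV) and atrial fibrillation (AF) detection from
single-channel radial-artery pulse wave recordings, by an improved time
synchronous averaging (TSA) procedure.

## The problem and the idea

Wearable pulse-wave devices detect AF almost exclusively through
inter-beat-interval (IBI) series, which makes them fragile: every beat must
be located accurately before any rhythm statistic exists.  TSA is the
opposite kind of tool — a noise-suppression method that *averages over*
beats — but classic single-period TSA discards all rhythm information.

`tsaprv` averages windows spanning **two adjacent pulse periods**, aligned
at the maximum of the first derivative (the systolic upstroke, the
pulse-wave analogue of the ECG R peak):

```
X_a = (1/N) * sum_i X_i
```

where each `X_i` is a detected period expanded by 50% on both sides and
zero-filled to the common frame.  Beat-to-beat irregularity leaves the
first period of `X_a` sharp but smears the second.  The distance between
the first and second ascending limbs `X_f`, `X_s` (equal length `n`)
quantifies PRV without any IBI series:

```
D_e = sqrt(sum (x_fi - x_si)^2)        Euclidean
D_m = sum |x_fi - x_si|                Manhattan
D_c = sum(x_fi x_si) / (|X_f| |X_s|)   cosine
```

AF — irregularly irregular cycle durations — is called when `D_e` strictly
exceeds a threshold (default 2.1, in device-native amplitude units).  The
package also ships the seeded simulator used to screen the three candidate
indexes on a 1000-sample synthetic training cohort (50 individuals x 20
base cycle durations, 60 cycles per recording, duration jitter
U(-0.09, 0.09) s for the arrhythmia group vs U(-0.07, 0.07) s for
control), plus ROC/AUC and Kruskal-Wallis evaluation utilities.

See `vignettes/tsaprv-methods.Rmd` for the model, assumptions, parameter
choices, and limitations.

## Worked example

```r
library(tsaprv)

sr <- simulate_rhythm("SR", n_beats = 60, fs = 500, seed = 7)  # sinus rhythm
af <- simulate_rhythm("AF", n_beats = 60, fs = 500, seed = 8)  # fibrillation
measure_prv(sr)
#> <prv_result 'sim-SR'>
#>   d_e = 0.9314  d_m = 8.1204  d_c = 0.99626  (n = 115)
#>   N averaged = 58, fs = 500 Hz, segmentation threshold 0.1
#>   decision: non-AF (d_e <= 2.10)
measure_prv(af)
#> <prv_result 'sim-AF'>
#>   d_e = 2.4111  d_m = 17.7694  d_c = 0.99245  (n = 115)
#>   N averaged = 57, fs = 500 Hz, segmentation threshold 0.2
#>   decision: AF (d_e > 2.10)
```

Both recordings are 60 beats at 500 Hz from the same pulse template; they
differ only in cycle-duration jitter (±0.02 s vs ±0.15 s).  The pipeline
segmented each recording into ~58 usable periods, averaged the expanded
windows, and compared the two ascending limbs of the average (115 samples
each).  The irregular rhythm smears the second limb, raising the Euclidean
limb distance from 0.93 to 2.41, across the 2.1 decision threshold, while
the cosine index barely moves — the reason the Euclidean form is the
selected index.

For file-based use, `read_pulse_series()` reads a single-column CSV with
an `fs=<Hz>` header, and `inst/cli/tsaprv` exposes `segment`, `detect`,
`average`, `simulate-train` and `evaluate` subcommands.

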