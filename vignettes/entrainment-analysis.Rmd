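---
title: "Deciding entrainment from fly activity records: methods and design"
author: "entrainR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding entrainment from fly activity records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainR)
```

## The problem

Drosophila Activity Monitors record one number per minute per fly: the
count of infrared beam crossings. From such records, three questions
recur in circadian work:

1. **Is this fly entrained** to the light cycle it lives under, or is its
   clock free-running through it?
2. **What is its free-running period** (τ) under constant darkness (DD) or
   constant light (LL), and how does light intensity change it?
3. **Where is its activity peak** (phase, in Zeitgeber Time), and does the
   phase on the first day after release into constant conditions match the
   entrained phase (*phase control*, the touchstone of true entrainment)?

entrainR implements the full chain from raw monitor files to these
answers, together with a ground-truth simulator used to validate every
stage.

## The analysis chain

### Smoothing (Savitzky–Golay)

Discrete light transitions evoke *startle* bursts — activity spikes
recurring at exactly 24 h intervals that dominate any periodogram even
when the underlying clock free-runs. `savitzkyGolay()` fits a local
least-squares polynomial in a sliding window; three presets are used:

| preset | order | frame | cadence | used for |
|---|---|---|---|---|
| `entrainment_gate` | 2 | 251 samples | 1 min | period values for the entrainment gate |
| `peak_finding` | 2 | 81 samples | 1 min | evening-peak phases |
| `ramp_peaks` | 1 | 41 samples | 15 min | peak phases under ramped cycles |

Frame lengths are counted in samples of the series' current bin width, so
"251" means 251 minutes on 1-min data. At the series ends, where the
window would overhang, the first and last half-window of outputs are taken
from the least-squares polynomial of the first/last full window. This
choice (over reflection or zero padding) is what makes the filter
reproduce polynomials of degree ≤ order *exactly over the whole series*,
and it leaves no edge transient to corrupt first/last-day phase
estimates. The boundary region still carries more variance than the
interior, which is why per-cycle statistics (below) exclude the final
cycle when nothing is recorded after it.

### Period estimation (χ² periodogram)

`chiSquarePeriodogram()` implements the Sokolove–Bushell statistic: for a
trial period of K bins the series is folded into K columns and

$$Q_p \;=\; N\,\frac{\sum_h n_h\,(M_h-\bar M)^2}{\sum_i (x_i-\bar M)^2},$$

which under the null of exchangeable bins is approximately
χ² with K−1 degrees of freedom. The default bin width is **20 min**, so
the tested grid contains 23.67 h, 24.00 h and 24.33 h exactly — the two
grid neighbours of 24 h define the entrainment window below. Defaults:
period range 16–32 h, α = 0.05 **Bonferroni-corrected across the grid**
(the uncorrected variant is an argument). *Rhythmic power* is the peak Qp
minus the significance line at the peak — 0 when nothing is significant.

A consequence that shapes the classifier: the χ² null presumes
uncorrelated bins. The SG-smoothed series is strongly autocorrelated, and
feeding it to the periodogram inflates long-period tails enormously (we
measured a ~70% spurious "significant peak" rate on flat-waveform Poisson
flies, against 2–4% for raw counts). The gates therefore use **two
strands**: *significance and rhythmic power* come from the raw binned
counts, where the null is calibrated; the *period value* is read from the
smoothed periodogram's peak, where startle cannot drag it.

### Period tracking (Morlet wavelet)

`morletWaveletSpectrum()` is an FFT-based continuous wavelet transform
with the analytic Morlet mother (ω₀ = 6), period grid 16–32 h at 50
voices per octave, power normalized by series variance. The cone of
influence (e-folding time √2·s) marks edge-affected cells.
`dailyPeriods()` reports, per 24 h cycle, the period of maximal
time-averaged power — a period competes only where it is edge-safe for at
least half of the cycle's samples, so edge cycles return `NA` rather than
a short-period artifact. The wavelet's time resolution at 24 h is about
three cycles; period excursions shorter than that are averaged away.

### Classification

`classifySkeleton()` (≥ 6 days): rhythmic flies with a (smoothed-)peak
period in **[23.67, 24.33] h** are *entrained*; rhythmic flies outside the
window are *free-running*; flies with no significant raw peak are
*arrhythmic*.

`classifyRamp()` (≥ 9 cycles) adds two strands of evidence and a fourth
category, with the first matching rule winning:

1. *arrhythmic*: no significant periodogram peak and no detectable
   wavelet ridge (cycle-median ridge power below 2 variance units; white
   noise sits near 1);
2. *entrained*: daily wavelet periods from cycle 6 onward all within
   **[23.5, 24.5] h** (a deliberately wider band than the periodogram
   window — the wavelet wobbles more), phase drift ≤ **20 min/cycle**,
   and periodogram peak in the entrainment window;
3. *free-running*: monotone phase drift beyond the threshold **and** an
   out-of-window periodogram peak;
4. *relative coordination*: everything else — unstable daily periods,
   multiple peaks, drift that reverses or stalls.

The drift is measured on the circular centre of gravity of the smoothed
per-cycle waveform rather than on the per-cycle argmax: on flat-topped
smoothed waveforms the argmax jitters by more than an hour per cycle at
realistic count rates, which would swamp a 20 min/cycle criterion. (The
per-cycle peak phases are still computed and attached as evidence.) The
20 min/cycle threshold itself is a package decision — no numeric value
exists in the field for "stabilized by visual inspection" — and it is
deliberately consistent with the periodogram window: a clock at the window
edge (23.67 or 24.33 h) drifts 20 min per cycle.

### Phases and phase control

`eveningPeakPhase()` takes, per day, the highest smoothed peak inside a
configurable evening window (default ZT06–ZT15), skipping bins within
30 min after any discrete light transition (startle guard), and combines
the last five days by circular mean. `releaseDayPhase()` finds the
dominant peak on the first full cycle after release, on 15-min binned,
SG(1,41)-smoothed data — smoothing the *whole* series first, so the
release day carries no filter edge.

`assessPhaseControl()` sets the hypothesized direction μ₀ to the circular
median of the entrained phases and applies the **V-test** (modified
Rayleigh; u = V√(2n), one-sided normal p) to the release-day phases. μ₀
is never estimated from the sample being tested. The circular median
minimizes mean circular absolute deviation, ties broken toward the
circular mean; phases map to angles as 24 h = 360°.

### Group statistics

Phases across light regimes are compared with Kruskal–Wallis plus
pairwise rank-sum tests at Bonferroni-corrected α and a compact letter
display (groups sharing a letter do not differ significantly). DD vs LL
periods use the Wilcoxon rank-sum test (exact for the smaller sample
≤ 25 without ties). The intensity dose–response of the free-running
period is fit with the four-parameter logistic
$y = \alpha_L + \delta/(1+e^{-\eta(x-\phi_m)})$ by Levenberg–Marquardt
from a deterministic 50-point start grid; the fit is canonicalized to
η ≥ 0 (the curve is invariant under jointly flipping the signs of δ and
η). `anovaVsFlat()` tests it against a flat line with
F = ((RSS₀−RSS₁)/3)/(RSS₁/(n−4)) on F(3, n−4). The dose axis is raw
intensity in µW cm⁻² (no log transform by default). One design note: the
F reference distribution is only meaningful when the model cannot
saturate the dose means — with exactly 3 distinct doses a 4-parameter
curve interpolates them, so calibration work uses ≥ 15 distinct doses.

## The simulator

`simulateFly()` is a phase-only oscillator observed through an
inhomogeneous Poisson emission process, at 1-min steps:

* **Parametric light action**: dφ = dt·(24/τ)·(1 + ε·g(φ)·I), with
  g(φ) = sin(2π(φ−12)/24) — light in the subjective morning accelerates
  the clock, light in the subjective evening decelerates it. Two
  consequences emerge rather than being programmed: under LL the
  oscillator dwells where light slows it, so the realized period exceeds
  τ and grows with intensity (the classic period-lengthening under
  constant light); and under ramped cycles entrainment is reached only
  over several cycles of transients.
* **Non-parametric action**: at discrete light transitions the phase jumps
  by prcAmp·prc(φ), where prc has a dead zone through the subjective day
  and a delay→advance half-sine over the subjective night. The dead zone
  matters: without it, the dawn and dusk pulses of a skeleton photoperiod
  cancel and discrete entrainment cannot lock. Lights-off transitions act
  at half amplitude.
* **Emission**: rate = base·w(φ)·exp(−κ·I) + startle, with w a two-bump
  von Mises mixture (morning and dominant evening component, normalized
  to mean 1), κ the light-masking coefficient, and a startle transient
  (default 6 counts/min, 12 min decay, active ≤ 60 min) after each
  discrete transition. Counts are Poisson draws per minute; every fly has
  one explicit seed recorded in its truth record.
* **Intensity normalization**: I is normalized by the regime's cycle
  maximum, or by an explicit `iRef` when cohorts at different absolute
  intensities must share one scale (dose–response work uses iRef = 50
  µW cm⁻², the top of the intensity series).

Default condition sizes follow the experimental design the package
targets: ~32 flies per cohort, 1-min cadence, 8–10 days for skeleton/LL
experiments, 9 ramp cycles with release into constant nadir light
(~10 µW cm⁻²) afterwards; skeleton pulses 30 min at 400–500 lux; ramps
linear from 10 to 40–50 µW cm⁻² and never dark (the "gradual" profile is
modelled as the simplest monotone interpolant; a step-quantized variant
is not provided). Intensity units are labels — a display-only constant
(1 lux ≈ 0.57 µW cm⁻² for the broad-spectrum source, from the
400–500 lux ≈ 228–285 µW cm⁻² correspondence) is exported but never
applied to data.

What the generator does **not** emulate: non-stationary activity levels
(ageing, death), bout structure and sleep architecture beyond the mean
waveform, inter-fly correlation, monitor artifacts other than flagged
rows, and internal desynchronization with more than one concurrent
period. Classifier accuracies measured on it therefore bound what clean,
stationary data allow; they do not certify performance on pathological
recordings.

Two behaviours of the simulator deserve flagging because they are
faithful to the biology and easily mistaken for bugs. First, an
*arrhythmic* fly with normal startle responses under a pulsed regime
produces genuine 24 h periodicity (driven by the light, not a clock) and
is classified entrained — exactly the masking confound the ramped
paradigm was designed to remove; classification-fidelity checks
therefore run under DD. Second, a *relative-coordination* fly (gain just
below what locking needs, default τ = 24.45, ε = 0.3) drifts with a
one-directional beat and is frequently called free-running; the
relative-coordination verdict is exercised instead with flies whose
period alternates in blocks of ≥ 3 days, which the wavelet can resolve.

## Numerical and interface choices

* Counts stay integers from file to smoothing; binning conserves totals
  exactly; a write→read monitor-file round trip is bit-exact.
* Flagged DAM rows (status ≠ 1) are zeroed with a warning and their
  indices kept on the object; they are never silently dropped.
* ZT alignment is metadata (`zt0Offset`, minutes from recording start to
  the first ZT00) supplied by the caller, never inferred from light data.
* Degenerate inputs: constant series give all-zero periodograms and no
  peak; flat series give no peaks in `findPeaks()`; an all-cone wavelet
  cycle gives `NA`, not a guess.
* All reports embed their configuration and seed; re-running a
  configuration reproduces every CSV byte for byte.
* Problem sizes in the shipped tests (cohorts of 6–32 flies, 8–11 days,
  500-replicate calibrations) were chosen to exercise each claim at the
  scale of the targeted experimental design.

## Known limitations

* The χ² periodogram's grid resolution at 20-min bins is ±20 min around
  24 h; finer discrimination needs longer records or a different
  estimator.
* The V-test p-value uses the normal approximation of u; for n < 8 it is
  rough (the package requires n ≥ 2 but the tests it ships use n ≥ 8).
* The 4PL fit with three dose levels cannot test curve shape, only
  monotone change; the flat-line ANOVA is then approximate.
* `classifyRamp()` needs at least 9 cycles and judges drift on cycles
  6–8; a fly entraining later than cycle 6 is reported as relative
  coordination, matching the conservative reading of transients.
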