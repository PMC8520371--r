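---
title: "Methods: Doppler fetal heart rate detection and twin sFGR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Doppler fetal heart rate detection and twin sFGR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhrdoppler)
```

## The problem

A fetal heart rate (FHR) monitor insonates the fetal heart with continuous
ultrasound and listens to the echo. Because the heart wall moves, the echo
is frequency-shifted; demodulated to audio, it is a noisy, amplitude- and
frequency-modulated signal whose *envelope* pulses once per heart beat. The
clinically useful quantity is the beat rate: a normal fetus beats at
120–160 bpm, and rates outside that band indicate fetal distress.

This package implements the full chain for that measurement on synthetic
signals with known ground truth: a Doppler-audio simulator, envelope
demodulation, a windowed autocorrelation rate estimator driven by a
precomputed heart-rate/lag lookup table, an AMDF (average magnitude
difference function) alternative, umbilical-artery waveform typing for
selective fetal growth restriction (sFGR) in monochorionic twins, and the
summary-statistics machinery used for twin-cohort comparison tables.

## Signal model

The simulator drives the reflected-wave Doppler relation

$$f_D = \frac{2\,v\,f_0 \cos\theta}{c}$$

with a parametric cardiac velocity waveform: one raised-cosine systolic
pulse per beat, pulse width 30% of the cycle, zero velocity in diastole.
The synthetic audio is a tone whose instantaneous frequency is the
per-sample Doppler shift of that waveform and whose amplitude follows the
normalised velocity magnitude, plus white Gaussian noise at a configured
SNR. Defaults — carrier $f_0 = 2$ MHz, $c = 1540$ m/s, beam angle
$\theta = 0$, audio rate $f_s = 4000$ Hz, peak wall velocity 0.3 m/s — are
typical fetal-Doppler values chosen as implementation defaults; with them
the peak Doppler shift is about 780 Hz, comfortably inside the audio band.

Two choices deserve comment:

* **Beat waveform.** A raised cosine is band-limited and gives an
  unambiguous envelope period. It does *not* emulate valve clicks, fetal
  movement, maternal vessel interference, or probe repositioning — so
  passing recovery tests here demonstrates correctness of the estimator on
  its signal model, not robustness to every clinical artefact.
* **Noise.** Additive white Gaussian noise, power set against the clean
  signal power. Real Doppler noise is burstier and non-stationary; AWGN is
  the neutral default when no noise spectrum is specified.

## Rate estimation

The echo is full-wave rectified and low-pass filtered (4th-order
Butterworth at 10 Hz, applied forward–backward for zero phase; the
rectified signal is reflected at both ends so the filter transient decays
in the padding), then resampled to a reduced envelope rate. On each
analysis window of $N$ envelope samples the biased, mean-removed
autocorrelation

$$R(m) = \frac{1}{N}\sum_{n=0}^{N-1-m} x(n)\,x(n+m)$$

is evaluated. The $1/N$ normalisation guarantees $R(0) \ge R(m)$, so
$R(m)/R(0)$ is a well-behaved confidence in $[0,1]$, and it damps peaks at
period multiples, which keeps the maximum at the fundamental.

Rather than searching every lag, a **lookup table** maps each candidate
heart rate $R_f$ on a 1-bpm grid to its lag serial number

$$S_n = \operatorname{round}(60 f_s / R_f),$$

and the autocorrelation is only read at those lags; the estimate is the
grid rate whose lag carries the maximum. Duplicate serial numbers keep the
lowest-rate entry, and ties in the maximum go to the lower rate
(fundamental over harmonic).

### Numerical choices

* **Envelope rate 500 Hz.** The lag grid quantises rate as
  $\Delta \approx R_f^2/(60 f_s)$ per lag: at 240 bpm and 200 Hz this is
  4.8 bpm, too coarse for ±1 bpm accuracy at the top of the 50–240 bpm
  search band; at 500 Hz it is 1.9 bpm, which the 1-bpm grid then absorbs.
  500 Hz is still an 8-fold reduction from the audio rate, and the table
  tops out at $S_n = 600$ lags.
* **Window 4 s, hop 1 s.** Four seconds hold ≥3 beat periods even at the
  50 bpm search floor; 1 s hop gives a responsive trace.
* **Harmonic guard.** A detector can lock onto half the beat period
  (doubling the rate). The guard switches to the doubled lag only when the
  bias-corrected autocorrelation $R(m)/(1 - m/N)$ at twice the winning lag
  *strictly exceeds* the winner's corrected value by 5%. A near-equality
  rule would be wrong: for a periodic envelope the biased $R$ at twice the
  period is only a factor $(N-2P)/(N-P)$ below the peak, so near-equality
  triggers systematically on genuinely fast rates and would halve them.
* **AMDF fundamental selection.** $D(m)$ nearly vanishes at the true
  period *and* its multiples, and the $1/(N-m)$ normalisation can put the
  global minimum on a subharmonic. Among lags whose $D$ is within 3% of
  the observed range of the minimum, the smallest lag wins.
* **No-signal rule.** Windows whose normalised peak falls below 0.3 (or
  whose envelope has zero energy) report `no_signal` rather than a
  spurious rate, and are excluded from the 3-point median smoother applied
  to the rate series.
* **Degenerate inputs.** All-zero envelopes give $R \equiv 0$ and
  `no_signal`; windows shorter than the largest table lag raise an
  insufficient-data error rather than silently truncating the search.

## Umbilical-artery sFGR typing

sFGR is screened by the small-for-gestational-age rule — estimated fetal
weight strictly below the 10th percentile for the gestational week, with
linear interpolation between tabulated weeks. The shipped reference table
is a synthetic demonstration (smooth, strictly increasing); it is not a
published growth standard, and real analyses should supply their own.

The Doppler subtype is read from per-cycle end-diastolic velocity (EDV):
the minimum velocity over the final 20% of each cardiac cycle. All cycles
positive → Type I; all absent/reversed → Type II; a mixture → Type III.
Since measured velocities are never exactly zero, "absent" is
operationalised as EDV at or below a 0.5 cm/s dead-band (configurable). At
least three cycles are required to call a type — a floor, not a clinical
recommendation; "intermittent" patterns are more convincingly established
on longer strips.

## Cohort statistics

The group comparisons in twin-cohort tables are reproduced from printed
summaries:

* `t_from_summary()` — two-sample t from $(\bar x, s, n)$ triples,
  pooled-variance by default (Welch by flag). On the example cohort's sFGR
  birth weights, $(2119 \pm 454)$ vs $(1444 \pm 350)$ g with $n = 23$, it
  gives $t = 5.65$ on 44 df. Recomputation from rounded printed summaries
  carries that rounding with it, and it cannot recover design details the
  summaries do not encode — if the original comparison was paired within
  twin pairs, an unpaired recomputation will differ; the control-group
  birth weights are a case where a summary-based t does not match a
  printed one, which is a known limitation of this kind of reproduction.
* `proportion_pct()` — count/total as a percentage rounded half-up to one
  decimal, matching how printed tables round (71.875 → 71.9).
* `rank_sum_z()` — Mann–Whitney U standardised by the exact permutation
  mean and tie-corrected variance, with no continuity correction, so Z
  matches full enumeration of group assignments exactly; the p-value is
  the two-sided normal approximation.
* `fisher_exact_or_chisq()` — Fisher's exact test when any expected cell
  is below 5 (the cohort's condition tables contain cells of 0 and 1),
  otherwise chi-square with continuity correction; the rule is
  overridable because the choice is a convention, not a theorem.

## Problem sizes used in the checks

The packaged tests and the acceptance script work at sizes chosen to
exercise every code path at full fidelity: 8-second signals, the full
50–240 bpm search band, 20 noisy seeds per rate in the recovery study
(10 in the acceptance script), 200 noiseless pulse-train fixtures for the
lookup-vs-exhaustive-search equivalence, 100 random vectors against the
literal double-loop autocorrelation oracle, and exhaustive enumeration for
the rank-sum and Fisher oracles (all 2×2 tables with the cohort's 23/32
group sizes as margins). The simulator's defaults are the study
conditions; none of them are tuned per run.

## Known limitations

* The simulator's beat waveform and AWGN noise are idealised; see above.
* The detector reports one rate per window: no beat-to-beat variability,
  accelerations/decelerations, or CTG scoring.
* Printed-summary statistics inherit the rounding and the unstated design
  choices of the original tables.
* The sFGR typing operates on a supplied velocity trace; extracting such
  traces from real spectral-Doppler clips is out of scope.
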