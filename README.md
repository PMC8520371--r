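# fhrdoppler

Ultrasound-Doppler **fetal heart rate (FHR) detection** and
monochorionic-twin **selective fetal growth restriction (sFGR)** analysis
in R.

A continuous-wave fetal Doppler probe returns an echo frequency-shifted by
the moving heart wall,

$$f_D = \frac{2\,v\,f_0\cos\theta}{c},$$

which, demodulated to audio, pulses once per beat. The package estimates
the beat rate by the classic windowed-autocorrelation method: on each
window the biased, mean-removed autocorrelation

$$R(m) = \frac{1}{N}\sum_{n=0}^{N-1-m} x(n)\,x(n+m)$$

of the envelope is read **only at precomputed lag "serial numbers"**
$S_n = \mathrm{round}(60 f_s / R_f)$, one per candidate heart rate $R_f$
on a 1-bpm grid, and the rate carrying the maximum wins. An AMDF (average
magnitude difference function) minimum-search alternative is included.
Estimated rates are classified against the 120–160 bpm normal band.

Around the detector the package provides:

* a **signal simulator** with known ground-truth heart rate, configurable
  SNR and seeded reproducibility (`doppler_config()`,
  `synthesize_doppler()`);
* **umbilical-artery waveform typing** for sFGR: per-cycle end-diastolic
  velocities, Types I/II/III (normal / continuously absent-or-reversed /
  intermittent end-diastolic flow), and the small-for-gestational-age
  10th-percentile screen (`end_diastolic_velocities()`,
  `classify_sfgr_type()`, `is_sga()`);
* **cohort statistics** for twin comparison tables from printed summaries:
  two-sample t from (mean, SD, n), count(percent) cells, tie-corrected
  Mann–Whitney Z, Fisher/chi-square for 2×2 counts (`t_from_summary()`,
  `proportion_pct()`, `rank_sum_z()`, `fisher_exact_or_chisq()`);
* WAV/CSV signal I/O, a fixture battery generator, `tidy()`/`glance()`
  methods and `autoplot()` figures, and a `fhrdop` command-line front end
  (`simulate | detect | classify-ua | sga | stats | fixtures`).

## Worked example

```r
library(fhrdoppler)

sig <- synthesize_doppler(doppler_config(heart_rate_bpm = 140,
                                         duration_s = 8, snr_db = 10,
                                         seed = 1))
trk <- track(sig)
tidy(trk)
#> # A tibble: 5 × 5
#>   window_start_s   bpm bpm_raw confidence status
#>            <dbl> <dbl>   <dbl>      <dbl> <chr>
#> 1              0   140     140      0.898 normal
#> 2              1   140     140      0.889 normal
#> 3              2   140     140      0.891 normal
#> 4              3   140     140      0.896 normal
#> 5              4   140     140      0.884 normal
```

Five one-second-spaced 4-s windows each recover the true 140 bpm exactly
at 10 dB SNR; the normalised autocorrelation peak (~0.89) is the
confidence, and 140 bpm falls inside the 120–160 bpm normal band.
`autoplot(trk)` draws the track against that band.

Cohort statistics from printed summaries — birth weights of the larger vs
smaller twin in an sFGR group, (2119 ± 454) vs (1444 ± 350) g, n = 23
each:

```r
t_from_summary(2119, 454, 23, 1444, 350, 23)
#> # A tibble: 1 × 5
#>   statistic    df    p.value estimate method
#>       <dbl> <dbl>      <dbl>    <dbl> <chr>
#> 1      5.65    44 0.00000111      675 Two-sample t (pooled) from summary stati…

proportion_pct(19, 23)   # 82.6
classify_sfgr_type(tibble::tibble(edv_cmps = c(5, 0, 4, -1)))$type  # "III"
```

The same operations are available from a shell:

```sh
fhrdop simulate --hr 140 --snr 10 --duration 8 --seed 1 -o sig.wav
fhrdop detect sig.wav --window 4 --hop 1 -o fhr.csv
fhrdop stats t --mean1 2119 --sd1 454 --n1 23 --mean2 1444 --sd2 350 --n2 23
```

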