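# rcdpe

Ordinal-pattern complexity analysis for uniformly sampled physiological
signals, built around the permutation-entropy (PE) estimator family and
aimed at the kind of question that arises in surface-electromyography (sEMG)
fatigue studies: *at which time scale, and with which multiscale estimator,
does a complexity measure best separate physiological states?*

## The estimators

For a signal $x$ embedded with dimension $d$ and delay $\tau$, permutation
entropy is the Shannon entropy of the empirical distribution of ordinal
patterns (the permutations sorting each embedded window), normalized by
$\ln d!$:

$$\bar H = -\frac{1}{\ln d!}\sum_{i=1}^{d!} \hat p_i \ln \hat p_i \in [0, 1].$$

The package implements the seven-member family that extends PE across time
scales $m$:

| route | plain | composite | refined composite |
|---|---|---|---|
| coarse-graining (block means of $m$) | `mpe()` | `cmpe()` | `rcmpe()` |
| decimation (every $\tau$-th sample) | `dpe()` | `cdpe()` | `rcdpe()` |

Composite variants average the entropies of the $m$ (or $\tau$)
phase-shifted scaled sequences; refined composite variants average the
per-phase *pattern distributions* first and take one entropy, which by
Jensen's inequality can only raise the value and — for decimation, whose
phases are disjoint — sharply lowers the estimator variance.  rcDPE (refined
composite downsampling PE) is the estimator of interest: on i.i.d. noise its
sampling dispersion is an order of magnitude below MPE's at the same scale.

Supporting tools: spectral utilities that tie the analysis scale to
bandwidth (`effective_rate()`, `nyquist_after()`, `ma_filter_cutoff()`,
`welch_psd()`, `band_power_ratio_db()`), a surrogate sEMG fatigue-cohort
generator (`gen_fatigue_cohort()`), a windowed fatigue-discrimination
pipeline with repeated-measures ANOVA (`fatigue_study()`), and WAV/CSV
signal I/O.  A command-line front end is installed as `exec/rcdpe`
(subcommands `simulate`, `pe`, `profile`, `fatigue-study`).

## Worked example

Simulate a small fatigue cohort (four subjects, four chronological windows
whose spectral content compresses 500 → 400 → 320 → 250 Hz as fatigue
progresses) and run the full discrimination pipeline:

```r
library(rcdpe)
co <- gen_fatigue_cohort(cohort_spec(n_subjects = 4, duration_s = 8, seed = 7))
st <- fatigue_study(co, scales = 1:30, dims = 3:4, anova_on = "windows")
st
#> <fatigue_study> 4 subjects, 4 windows, scales 1..30
#>   selected scale: 8
#>   mean entropy by window (last method, scan d):  W1=0.9568  W2=0.8749  W3=0.8047  W4=0.7236
#> <rm_anova_report> 4 subjects, factors: step, method, d (alpha = 0.05)
#>   step                 F(3,9) = 1767.985  p = 8.761e-13  *
#>   method               F(2,6) =  286.532  p = 1.112e-06  *
#>   d                    F(1,3) = 10273.047  p = 2.117e-06  *
#>   ...
```

Reading the output: the scan over scales finds the pairwise window deltas
largest at scale 8 — consistent with the arithmetic that a scale-10
reduction of a 10 kHz record analyses exactly the 0–500 Hz sEMG band —
and mean rcDPE at that scale falls monotonically across the four windows
(0.957 → 0.724), the entropy signature of fatigue.  The repeated-measures
ANOVA confirms the fatigue-step effect (and, on this synthetic cohort, the
method and dimension effects).

The spectral diagnostics that justify decimation without prefiltering:

```r
s <- co$subjects[[1]]$signal
band_power_ratio_db(welch_psd(s), c(0, 500), c(500, 5000))
#> 30.3          # dB: out-of-band power is negligible
ma_filter_cutoff(10, 10000)
#> 444.8703      # Hz: the -3 dB point of the scale-10 coarse-graining filter
effective_rate(10000, 10);  nyquist_after(10000, 10)
#> 1000          # Hz
#> 500           # Hz
```

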