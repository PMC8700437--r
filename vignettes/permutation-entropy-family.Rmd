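---
title: "Multiscale and downsampling permutation entropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale and downsampling permutation entropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcdpe)
```

## The ordinal-pattern framework

Permutation entropy (PE) quantifies the complexity of a uniformly sampled
signal $x = [x_0, \dots, x_{N-1}]$ through the distribution of its *ordinal
patterns*: each delay-embedded window
$(x_n, x_{n+\tau}, \dots, x_{n+(d-1)\tau})$ is reduced to the permutation
that sorts it ascending.  With embedding dimension $d$ there are $d!$
possible patterns; counting them over the $N - (d-1)\tau$ windows gives an
empirical probability mass function $\hat p$, and

$$\hat H = -\sum_{i=1}^{d!} \hat p_i \ln \hat p_i, \qquad
  \bar H = \hat H / \ln(d!)$$

is the (normalized) permutation entropy.  The normalized form lies in
$[0, 1]$: 0 for a monotone ramp (a single pattern), 1 for i.i.d. noise
(uniform patterns).  Because only order relations enter, PE is invariant
under strictly increasing transformations and robust to amplitude outliers.

`encode_pattern()` indexes patterns by the lexicographic Lehmer code of the
sorting permutation — an arbitrary but documented bijection that the tests
verify against an explicit sort-the-pairs oracle.  Unobserved patterns
contribute $0 \ln 0 := 0$.  Windows shorter than recommended trigger a
warning (we warn below $5\,d!$ usable windows, the middle of the published
length recommendations) but never an error: the user may knowingly trade
precision for resolution.

**Ties.**  Sampled, quantized data contain equal values, and the embedding
must rank them.  The default (`tie_policy = "stable"`) gives the earlier
sample the lower rank — the convention that makes the encoder deterministic
and matches the usual implementation of the Bandt–Pompe symbolization.  A
seeded `"random"` policy is provided so the sensitivity of a result to tie
handling can be measured rather than assumed; on heavily quantized signals
at high scales the two can differ, and reporting both is cheap insurance.

## Two routes to multiple scales

Physiological signals are routinely oversampled relative to the bandwidth of
the process of interest, and single-scale PE then mostly measures the
sampling grid, not the physiology.  Two scaling constructions are
implemented.

**Coarse-graining (MPE).**  `coarse_grain()` replaces non-overlapping blocks
of $m$ samples by their mean.  This is exactly an $m$-tap constant-coefficient
FIR filter followed by decimation by $m$ (a property the tests check against
`stats::filter`), so MPE at scale $m$ analyses a low-passed signal at
effective rate $f_s/m$.  Trailing samples that do not fill a block are
discarded — real record lengths are never exact multiples of $m$.

**Decimation (DPE).**  `composite_downsample()` keeps every $\tau$-th sample.
The $\tau$ phase-shifted decimated sequences are *disjoint*: they partition
the raw samples, so no averaging filter is applied and no information is
shared between phases.  The cost is aliasing — content above $f_s/(2\tau)$
folds down — which is why the package pairs the estimators with spectral
diagnostics (below).  An optional moving-average prefilter
(`prefilter = TRUE`) is available for studying the aliasing contribution,
but the default keeps the plain decimation definition.

On the definition of DPE itself: "PE with delay $\tau$" computed over *all*
start indices pools windows from all $\tau$ decimation phases, which is not
the same estimator as PE of a single decimated sequence.  `dpe()` is defined
as PE (delay 1) of the first phase — the single-decimated-signal reading —
so that the composite and refined variants below add phases explicitly and
the estimator hierarchy is clean.  The all-start-indices variant remains
available as `permutation_entropy(x, tau = ...)`; it coincides with
count-weighted refined pooling.

**Composite and refined composite variants.**  For either scaling route, the
$m$ (or $\tau$) phase-shifted scaled sequences can be combined in two ways:

* *composite* (`cmpe()`, `cdpe()`): average the per-phase entropies
  $\tfrac1m \sum_k H(\hat p_k)$;
* *refined composite* (`rcmpe()`, `rcdpe()`): average the per-phase pattern
  distributions first, $\bar p = \tfrac1m \sum_k \hat p_k$, and take a single
  entropy $H(\bar p)$.

Concavity of Shannon entropy gives $H(\bar p) \ge \tfrac1m \sum_k H(\hat
p_k)$ pointwise — a Jensen inequality the test suite asserts on every signal
in its battery.  At scale 1 all seven estimators collapse to PE exactly.

Phase pmfs are pooled with *equal* weights even though phase lengths can
differ by one when $\tau \nmid N$; the refined average is defined as an
unweighted mean of distributions.  A `weights = "length"` option (equivalent
to pooling raw counts) is provided for comparison; at the record lengths
this package targets the difference is far below estimator noise.

**Why rcDPE.**  Coarse-grained phases share raw samples through their
overlapping block contents, so their pattern distributions are artificially
cross-correlated and the averaging in cMPE/rcMPE removes less variance than
the phase count suggests.  Decimated phases are disjoint, so rcDPE pools
$\tau$ genuinely independent looks at the process.  Empirically (and in the
acceptance suite): over 200 replicates of i.i.d. noise with $N = 20{,}000$,
$d = 3$, scale 10, the standard deviation of rcDPE is an order of magnitude
below that of MPE and of single-phase DPE.

## The scale–bandwidth link

The estimators are interpretable only together with simple spectral
arithmetic, implemented in the `spectral` functions:

* `effective_rate(fs, scale)` and `nyquist_after(fs, scale)`: scaling by
  $m$ reduces a 10 kHz record to $f_s = 1$ kHz at $m = 10$, which sees only
  0–500 Hz — precisely the physiological surface-EMG band.  Choosing the
  scale is choosing the band.
* `ma_filter_cutoff(m, fs)`: the −3 dB point of the coarse-graining filter,
  found by root finding on
  $|\sin(\pi m f/f_s)/(m \sin(\pi f/f_s))| = 1/\sqrt 2$.  For
  $m = 10$, $f_s = 10$ kHz this gives 444.87 Hz (the common $0.443 f_s/m$
  approximation gives 442.9).  We solve numerically rather than use the
  approximation so small-$m$ cases ($m = 2$: exactly $f_s/4$) are exact.
* `welch_psd()` and `band_power_ratio_db()`: an averaged-periodogram PSD
  (Hann window, 1-s segments, 50 % overlap by default — conventional
  choices, all configurable) normalized to unit integral, and integrated
  band ratios in dB.  The in-band/out-of-band ratio is the diagnostic that
  justifies ignoring aliasing when decimating: if the band above the
  post-scaling Nyquist holds 30 dB less power than the band below it, the
  folded contribution is negligible.

## The synthetic fatigue cohort

No public recordings accompany the muscle-fatigue application this package
is aimed at, so every pipeline stage is validated on surrogates built by
`gen_semg_surrogate()` / `gen_fatigue_cohort()`:

* the surrogate is Gaussian noise band-pass filtered to 20–500 Hz (the
  physiological sEMG band) with a linear-phase FIR filter applied forward
  and backward — zero phase, so the filter itself injects no asymmetric
  ordinal patterns.  The two passes are carried out in the frequency domain
  (multiplying the spectrum by $|B(\omega)|^2$), which is the same operation
  at $O(N \log N)$ cost.  A white floor is added at −30 dB relative to the
  in-band power, reproducing the ≈ 30 dB in-band/noise-band ratio of
  high-quality laboratory sEMG; the calibration is itself a test.
* *fatigue* is modelled as progressive spectral compression: across the four
  chronological windows the upper band edge falls 500 → 400 → 320 → 250 Hz.
  Physiologically, fatigue widens motor-unit action potentials and
  synchronizes firing, which biases ordinal patterns toward monotone runs
  and lowers entropy; spectral compression is the second-order signature of
  that mechanism and is sufficient to exercise every estimator.  An explicit
  action-potential-train generator would add realism (spikes, heavy tails,
  nonstationarity within windows) and is left as an extension hook.
* the default cohort is 10 subjects × 27.4 s at 10 kHz (274,000 samples,
  four windows of 68,500), with per-subject, per-window seeds derived
  deterministically from the cohort seed, so the whole study is reproducible
  from one integer.

What passing tests on this cohort do *not* show: robustness to electrode
artifacts, movement noise, within-window nonstationarity, or inter-subject
spectral diversity — the surrogate shares only the second-order statistics
of real sEMG.  Conclusions about real recordings need real recordings.

## The fatigue-discrimination pipeline

`fatigue_study()` chains the full analysis: split each record into four
equal windows (`segment_windows()`, floor rule, remainder dropped);
compute entropy-versus-scale profiles (`entropy_profile()`, scales 1–100,
with the `tau = m` coupling so downsampling and coarse-graining methods are
compared at matched effective rates); form the five pairwise window deltas
W1−W2, W1−W3, W1−W4, W2−W3, W3−W4 (`pairwise_deltas()`); select the scale
maximizing the mean absolute delta (`select_scale()`, ties to the smallest
scale — the explicit operationalization of what is usually done by eye on
delta curves); then evaluate all methods and dimensions at that scale and
compare them with a three-way repeated-measures ANOVA
(`run_statistics()`: within-subject factors fatigue step or delta pair,
method, and embedding dimension; Bonferroni-adjusted paired post-hoc
comparisons at $\alpha = 0.05$).  Whether deltas or raw window entropies
enter the ANOVA is a genuine modelling choice, so both entry points are
exposed (`anova_on`).

Normality (Lilliefors) and variance-homogeneity (Levene) screening is
attached to every report but never gates execution: with 10 subjects the
screens are weakly powered, and an analysis that silently switches tests on
their outcome is harder to reproduce than one that reports them.

By default the scale scan runs all comparison methods at a single scan
dimension ($d = 4$) and the full method × dimension grid only at the
selected scale.  Scanning the full grid at all 100 scales would multiply
runtime several-fold without changing the selection, whose criterion
averages over subjects and pairs at fixed method and dimension.  On the
default cohort the selected scale lands at 8 — inside the 8–15 range that
the designed band compression maps onto ($f_s/(2 \cdot 10) = 500$ Hz, the
fresh-window band edge) — and mean rcDPE at $d = 4$, $\tau = 10$ falls
strictly from W1 to W4.

Problem sizes used by the validation suite (its own choices, balancing
Monte-Carlo resolution against desk-scale runtimes): oracle-equivalence
checks on 64 seeded 240-sample signals across $d \in \{2..5\}$ and scales
$\{1, 2, 3, 10\}$; noise asymptotes at $N = 10^5$; variance ordering over
200 replicates at $N = 20{,}000$; the full synthetic study at the default
cohort size above.

## Numerical and degenerate-input choices

* Embedding ranks are computed by vectorized pairwise comparison; the
  rank-vector → Lehmer-index map is a cached $d!$ lookup table, practical to
  $d = 8$ (beyond which pattern statistics are hopeless at realistic $N$
  anyway, and the constructor refuses).
* Composite coarse-grained phases are computed from one cumulative sum per
  scale, so building all $m$ phases costs $O(N)$, not $O(Nm)$.
* `ma_filter_cutoff()` brackets its root in $(0, f_s/m)$, where the
  magnitude response falls monotonically from 1 through $1/\sqrt 2$ before
  its first null; `m = 1` short-circuits to $f_s/2$.
* Degenerate inputs: constant signals give a single pattern and entropy 0;
  signals too short for $(d, \tau)$ raise a length error; a sinusoid
  incommensurate with $\tau$ exercises unequal phase alignments and must
  (and does) give identical rcDPE on recomputation, since nothing in the
  default path is randomized.
* `welch_psd()` integrals use the trapezoidal rule on the one-sided grid;
  band-power integrals interpolate the density linearly at interior band
  edges so adjacent bands tile the spectrum exactly and
  `band_power_ratio_db(a, b) = -band_power_ratio_db(b, a)` holds to machine
  precision.

## Known limitations

* Ordinal methods discard amplitude information entirely; amplitude-aware
  PE variants are out of scope.
* The surrogate cohort validates estimator behaviour, not physiological
  claims; the ANOVA F-statistics it produces are far larger than anything
  real inter-subject variability would allow.
* Decimation without prefiltering is only defensible when the out-of-band
  power is demonstrably negligible — use `band_power_ratio_db()` before
  trusting rcDPE at scales that alias.
* WAV support covers mono PCM-16 and float-32 only; biosignal container
  formats (EDF/BDF) are extension hooks.
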