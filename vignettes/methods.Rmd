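---
title: "Methods: multi-domain feature analysis of finger motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-domain feature analysis of finger motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fingereeg` analyses six-class finger motor-imagery EEG — five imagined
finger movements plus a no-mental-task (NoMT) baseline — recorded from the
19 channels of the 10–20 montage as 1 s epochs at 1000 Hz. This vignette is
the package's own account of the models and conventions it implements:
every constant a user might wonder about is listed here with its rationale.

## 1. The epoch model and feature inventory

An `eeg_segment` is a 19 × 1000 real matrix (microvolt scale), a class
label in 1..6, and subject metadata. Each segment expands into 1102
features over four domains, identified by strings `"<domain>:<code>:ch<k>"`
and ordered channel-major (channel 1's full code list, then channel 2, …)
so that per-channel blocks are contiguous — the natural layout for the
channel maps of section 4.

### Time domain (24 × 19 = 456)

No complete published enumeration of the 24 temporal descriptors exists
for this analysis family, so the catalog is a fixed package convention
(`td_catalog()`), drawn from the standard EMG/EEG repertoire: mean, MAV,
median, RMS, SD, variance, integrated signal Σ|x|, simple square integral,
log detector, waveform length, average amplitude change, DASDV, max, min,
peak-to-peak, skewness, kurtosis, zero crossings, the three Hjorth
parameters, Willison amplitude, myopulse percentage rate, and slope-sign
changes. Codes TD10–TD12 and TD24 are pinned to waveform length, AAC,
DASDV and slope-sign change: in subject-independent channel maps of this
analysis family those four form a visibly distinct all-or-nothing block,
which identifies them; all other code assignments are arbitrary and
documented only here.

Conventions: SD/variance use the sample (N−1) denominator; skewness and
kurtosis use population moments (kurtosis is the raw Pearson ratio, 3 for
a Gaussian), both 0 for a flat channel; zero crossings count strict sign
changes with an optional amplitude deadband (default 0); Willison
amplitude and myopulse rate use a 10 µV threshold by default (configurable
— the scale matches the generator's ~10 µV background); the log detector
`exp(mean(log|x|))` collapses to 0 if any sample is exactly 0, which only
occurs on degenerate inputs.

### Frequency domain (15 × 19 = 285)

The five canonical bands are δ 0.5–4, θ 4–8, α 8–13, β 13–30, γ 30–100 Hz,
half-open `[f_lo, f_hi)` so no bin is double-counted. A 1000-sample FFT at
1000 Hz gives a 1 Hz grid; DC is excluded, so δ keeps bins {1, 2, 3} Hz
(0.5 Hz is not on the grid). No window or detrending is applied by default
(a `demean` switch exists). Per band, on the one-sided magnitudes:

* energy `Σ|y_i|²` (FD1–FD5),
* sample variance of the magnitudes, denominator M−1 (FD6–FD10),
* normalized spectral entropy `−Σ p_i log p_i / log M`, with
  `p_i = |y_i|²/Σ|y_j|²` and `0·log 0 = 0` (FD11–FD15).

Here M is the count of retained bins — the only reading under which the
variance's M−1 and the entropy's log M normalization both make sense. The
entropy is implemented as genuine (nonnegative, in [0, 1]) Shannon entropy
of within-band power: uniform power gives 1, a single active bin 0, an
all-zero band 0 by convention. The energy/variance/entropy × band code
layout is itself a convention and is configurable in the sense that the
ids carry it explicitly.

### Time–frequency domain (15 × 19 = 285)

A full 9-level Haar wavelet-packet tree tiles [0, 500) Hz into 512
terminal nodes of width 500/512 ≈ 0.977 Hz. Three non-obvious choices:

* **Padding.** 1000 samples is not a power of two. The default is zero
  padding to 1024: appended zeros carry zero energy, so the orthonormal
  transform's total coefficient energy equals the *original* signal energy
  exactly (verified to 1e−6 relative tolerance in the tests). Symmetric
  reflection is available (`padding = "symmetric"`) but shifts the energy
  reference to the padded signal.
* **Sequency ordering.** The natural (Paley) tree order does not increase
  with frequency: the high-pass branch mirrors the spectrum at every
  level. The classic Gray-code correction is applied — children of a node
  at an even frequency position keep (low, high), at an odd position they
  swap — so node index equals frequency order. The tests pin this down by
  localizing pure tones at 5–77 Hz to the correct node.
* **Band assignment.** Each node goes to at most one band by its center
  frequency against the half-open band edges, giving 3/4/5/18/71 nodes for
  δ/θ/α/β/γ; the 0–0.5 Hz node and everything above 100 Hz stay
  unassigned. The assignment is a partition by construction.

Per band, on the concatenated node coefficients: energy `Σd²`, sample
variance, and the *log-energy* entropy `Σ d² log(d²)` with `0·log 0 = 0` —
deliberately implemented without a minus sign, exactly in its printed
historical form, so values can be negative and are not normalized. This is
flagged in the function documentation; `shannon = TRUE` flips the sign for
users who want a conventional orientation. Haar's 2-tap filters have poor
stop-band behaviour: for a pure 10 Hz tone only ≈ 40 % of the energy lands
in the α nodes (independently confirmed against a from-scratch oracle
implementation). Band statistics remain monotone in band power, which is
what the downstream selection uses; after Parseval rescaling (dividing the
FFT band energy by N) the two routes agree within 25 % on a pure tone.

### Nonlinear domain (4 × 19 = 76)

Poincaré plot measures at the conventional lag 1. The published forms of
the SD1/SD2 equations in this analysis family are typographically
corrupted; the package implements the standard, internally consistent
identities

* `SD1 = sd((x_{i+lag} − x_i)/√2)`, equivalently `SD1² = SDSD²/2`,
* `SD2 = sd((x_{i+lag} + x_i)/√2)`, equivalently `SD2² = 2·SD² − SDSD²/2`,

with sample (N−1) standard deviations, plus the product SD1·SD2 and ratio
SD1/SD2 (defined 0 when SD2 = 0 — the degenerate case of a strictly
alternating signal). ND codes: ND1 = SD1, ND2 = SD2, ND3 = product,
ND4 = ratio. A lag hook exists for lags 2–10 but only lag 1 is exercised
beyond smoke tests.

## 2. The synthetic generator: a stated world

`generate_segment` builds each channel as

```
gain_subject × [ 1/f^e background (sd 10 µV)
                 + Σ_bands band-limited noise × scale_b × √multiplier ]
```

* **Background**: Gaussian noise with power spectrum ∝ 1/f (exponent 1 by
  default), the canonical broadband EEG floor. Components are drawn
  directly in the frequency domain (the DFT of white Gaussian noise is
  complex Gaussian), which is distributionally identical to filtering
  white noise and halves the FFT count.
* **Oscillations**: five independent band-limited Gaussian components with
  standard deviations δ 6, θ 4, α 5, β 3, γ 1.5 µV — a realistic resting
  hierarchy (slow rhythms strong, gamma weak) chosen once and not tuned.
* **Class effects**: a 6 × 5 multiplier matrix acts on band *power*
  (amplitude × √multiplier) on an affected-channel subset, default
  channels 8–10 (T3/C3/Cz in the package's montage order — a
  central-region stand-in for ERD/ERS-style sensorimotor modulation). The
  default world gives each finger class a distinct α/β pattern
  (e.g. class 1: α × 1.8; class 5: β × 1.9); NoMT is pinned to all-ones by
  an invariant.
* **Subject heterogeneity**: one log-normal gain per subject
  (sdlog 0.2), making subject-dependent and subject-independent analyses
  genuinely different.
* **Determinism**: every generator output is a pure function of
  (parameters, seed); the RNG state is sandboxed so library calls never
  perturb user code.

What the generator does *not* emulate: volume conduction and inter-channel
correlation (channels are independent), non-stationarity within an epoch,
ocular/muscular artifacts, and acquisition filtering (the real recordings
are distributed already filtered). A green test on this world therefore
establishes the pipeline's statistical and numerical correctness — not
that real finger imagery is decodable at any particular accuracy.

## 3. ANOVA selection

Each feature column gets a classical one-way fixed-effects ANOVA F-test
across the six class labels; `significant ⇔ p < α` with α = 0.05 and *no*
multiple-testing correction, matching the analysis convention this package
implements (Benjamini–Hochberg is available but off by default).
Zero-variance columns are defined to p = 1 (never selected); perfect
separation gives p = 0. The implementation is vectorized sums-of-squares
and is tested to 1e−15 agreement against `stats::oneway.test`.

Two scopes, chosen because published maps of this analysis family come in
a binary and a 0–8 count form: **subject-independent** selection pools all
subjects into one test per feature (binary maps); **subject-dependent**
selection runs per-subject tests and counts, per cell, how many subjects
selected it (count maps). Pooling, rather than intersecting per-subject
results, is the default SI rule; the per-subject machinery doubles as the
alternative.

A calibration subtlety worth stating explicitly: with two or more subjects
of different gain, the pooled design is *blocked* — every class contains
the same per-subject proportions, so between-subject variance enters the
within-class mean square but cancels from the between-class one, and the
raw F-test becomes conservative for amplitude-sensitive features (observed
type-I fraction ≈ 0.02 at α = 0.05 under gain sdlog 0.2). The acceptance
calibration therefore uses the fully exchangeable global null (all
multipliers 1 *and* zero gain dispersion), where the empirical type-I rate
is ≈ 0.05 and p-values are uniform; a companion test documents that the
heterogeneous null errs only on the conservative side. Similarly, the
uniformity check uses one feature per channel per replicate: channels are
independent in the generator but features within a channel are not, and a
KS test on dependent draws would reject for reasons unrelated to
calibration.

## 4. Distribution maps

A `distribution_map` is the feature-type × 19-channel grid with row,
column and grand totals. Binary mode: cell = 1 iff the pooled test
selected that (type, channel). Count mode: cell = number of subjects
(0..n) whose per-subject test selected it. Grand totals equal mask counts
by construction and are asserted as conservation laws in the tests. Maps
serialize to JSON (schema-versioned) and to a CSV grid with a Total
row/column mirroring the published table layout.

## 5. Classification benchmark

`crossval` uses stratified k-fold CV (default k = 5, per-class round-robin
after a seeded shuffle, so fold class counts differ by at most 1).
Features are z-scored with training-fold statistics only, and only for
scale-sensitive families (SVM, kNN, neural nets, kernel approximation) —
trees, discriminant analysis and naive Bayes are scale-equivariant by
construction. Accuracy is trace/total of the confusion matrix, which for
two classes reduces to the familiar (TP + TN)/(TP + FN + TN + FP).

The offline environment ships no tree/SVM/NN packages, so the eight
catalogued families are implemented in-package (MASS backs the
discriminant family): CART-style gini trees with max-split caps 100/20/4
(fine/medium/coarse); Gaussian and kernel-density naive Bayes; SVMs as
one-vs-rest least-squares kernel machines (linear, polynomial degree 2/3,
and RBF with kernel scale √p/4, √p, 4√p for fine/medium/coarse, ridge
λ = 1); kNN with k = 10 under Minkowski-3 ("cubic") and cosine distances;
ensembles — SAMME-boosted shallow trees (weighted resampling
approximation), bagged trees with √p feature subsampling, random-subspace
LDA and 1-NN (half the features per member, 30 members, majority vote with
deterministic ties), and RUSBoost (per-round random undersampling to the
minority count, identical to boosting on balanced data); ReLU MLPs with
hidden layouts 10 / 25 / 100 / 10-10 / 10-10-10 trained full-batch with
Adam (200 epochs, lr 0.01, L2 1e-4); and random-Fourier-feature kernel
approximation (256 features, scale √p) with least-squares and softmax
heads. These presets approximate common GUI defaults; since the reference
analysis states none of its hyperparameters, *numeric* reproduction of its
accuracy tables is explicitly not a target, and all presets are fixed in
one place (`.variant_presets`).

`run_grid` crosses feature sets × specs × {full, ANOVA-reduced}, derives a
deterministic seed per cell, records failed fits (e.g. QDA on p ≫ n
tables) and empty reduced tables as NA rows rather than aborting, and
`summarize_grid` reports the best variant per family — the convention used
when one number per family is quoted; the all-variants table is always
retained.

## 6. Numerical and degenerate-input decisions

* Feature extraction is fully vectorized across channels; the
  multi-channel wavelet path is asserted equal to the scalar
  `wpd_decompose` route.
* Degenerate conventions, all tested: flat signal → Hjorth (0,0,0),
  skewness/kurtosis 0, Poincaré (0,0,0,0); all-zero band → entropy 0;
  zero-variance feature → p = 1; SD2 = 0 → ratio 0.
* `with_seed` gives every stochastic entry point private RNG state;
  re-running any generator, CV, or pipeline call with the same seed is
  bit-identical (asserted down to written CSV bytes).
* Serialized signals are rounded to 1e−6 µV in the CSV container — far
  below any feature's sensitivity but not bit-exact; round-trip tests use
  a 1e−5 tolerance on signals and exact equality on metadata.

## 7. Known limitations

* Channel independence in the generator means spatial filters (CSP,
  Laplacian) have nothing to exploit; they are out of scope.
* Haar's spectral leakage makes TF band features crude band-power proxies;
  other mother wavelets are deliberately not implemented.
* The kernel naive Bayes and exact-scan tree learners are O(n·p)-heavy in
  pure R; they are intended for the benchmark's table sizes (hundreds of
  rows), not for large-scale use.
* `read_source_container` cannot parse MATLAB containers in this offline
  build; it reads the package's CSV layout and raises a format error
  otherwise.
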