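---
title: "Wavelet phase coherence networks from fNIRS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet phase coherence networks from fNIRS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpconet)
```

## The problem

Resting-state functional connectivity (rsFC) asks whether slow hemodynamic
oscillations recorded over different cortical sites keep a stable phase
relation. `wpconet` implements that analysis for multichannel fNIRS
oxyhemoglobin (ΔHbO) recordings on a 22-channel prefrontal montage sampled
at 13.33 Hz: signal conditioning, complex Morlet decomposition, pairwise
wavelet phase coherence (WPCO) with an amplitude-adjusted Fourier-transform
(AAFT) surrogate significance test, aggregation of channel pairs into a
10-region brain network, and the group statistics that relate connectivity
to behavioral performance. Because no public recording set accompanies this
montage, the package also ships a synthetic-cohort generator whose planted
structure makes every stage testable against ground truth.

## Signal model and procedure

### Preprocessing

Two conditioning steps are applied per channel:

* **HRF low-pass.** Convolution with the canonical double-gamma hemodynamic
  response kernel (gamma pdfs of shape 6 and 16, rate 1, undershoot ratio
  1/6, 32 s support), sampled at the recording rate and normalized to unit
  sum, so the DC level is untouched. The convolution is a single causal pass
  with reflection pre-padding of one kernel length: there is no startup
  transient, and a unit impulse maps exactly onto the kernel. The kernel's
  ~5 s hemodynamic delay is common to every channel, and WPCO depends only
  on *between-channel phase differences*, so the filter's phase response
  cancels out of the analysis. Whether resting-state segments should be HRF
  smoothed at all is a modeling choice; the step is on by default and
  switchable (`preprocess(..., hrf = FALSE)`).
* **DCT high-pass.** The discrete-cosine-transform detrend conventional in
  fMRI/fNIRS: basis function *k* on an *n*-sample segment has period
  `2 * duration / k`; every basis function with period above the cutoff
  (default 128 s, the conventional value; the constant term always) is
  projected out. The removed basis is orthogonal, so the operator is an
  idempotent linear projection — applying it twice changes nothing beyond
  floating-point noise — and the output is zero-mean per channel. A cutoff
  longer than the segment degenerates to mean removal, with a warning.

### Morlet decomposition

Each channel is decomposed with the complex Morlet wavelet
`psi(t) = (pi*fb)^(-1/2) exp(2i*pi*fc*t) exp(-t^2/fb)`, bandwidth `fb = 2`
and center frequency `fc = 0.5` — the empirical shape established for fNIRS
slow oscillations; analysis frequency `f` maps to scale `fc / f`. Three
numerical choices matter:

* **L1 normalization.** The filter response peaks at 1 (times a factor 2,
  below) at every scale, so time-averaged moduli are comparable across
  frequencies — required when amplitudes are averaged over a band.
* **Analytic filter.** This Morlet is broad: at `fb*fc^2 = 0.5` the raw
  Gaussian frequency response leaks ~1.5 % through DC and into negative
  frequencies. That leakage corrupts instantaneous phase precisely where the
  modulus fades, which is fatal for a phase-coherence statistic. The bank is
  therefore made exactly analytic (response zeroed at `f <= 0`), the
  standard construction for instantaneous-phase work. The factor 2 restores
  unit modulus for a unit-amplitude sinusoid.
* **Padding.** By default the FFT convolution zero-pads to the next power of
  two past twice the length so the segment's end cannot wrap onto its start
  (`pad = "zero"`). For signals that are *periodic by construction* — every
  band-limited component the synthetic generator emits is built on the DFT
  grid of its own segment — `pad = "none"` convolves circularly and has no
  edge transient at all; with the analytic bank, a planted constant phase
  lag is then recovered exactly, to machine precision. Real recordings are
  not periodic, so the default remains `"zero"`.

The instantaneous phase is the four-quadrant angle of each coefficient
(zero-modulus cells are flagged `NA`); the wavelet amplitude at each
frequency is the time-averaged modulus `(1/T) * sum_n |x(w_k, t_n)|` — the
mean instantaneous amplitude, not the mean energy (the two differ for
fluctuating signals; mean-of-modulus is what the amplitude feature below
uses, and is documented as such). Samples inside the cone of influence are
retained by default, since the amplitude average is defined over the whole
series; `coi_mask()` supports excluding them.

The default grid is log-spaced at 12 voices per octave over 0.005–2 Hz,
covering all six physiological intervals (cardiac 0.6–2 Hz, respiration
0.145–0.6, myogenic 0.052–0.145, neurogenic 0.021–0.052, endothelial
metabolic 0.0095–0.021, endothelial 0.0005–0.0095); connectivity is
evaluated on the 0.01–0.1 Hz analysis band, where 8 voices per octave
(27 grid points) is the default resolution.

### Phase coherence and surrogate validity

For channels *i*, *j* the per-frequency coherence is the modulus of the
time-averaged unit phasor of the phase difference,

```
WPCO(w_k) = sqrt( mean_n cos(dphi_k_n)^2 + mean_n sin(dphi_k_n)^2 ),
```

which is 1 for a constant phase difference and tends to 0 for unrelated
phases. Raw WPCO is *biased upward at low frequencies*: a 10-minute segment
holds only six cycles of 0.01 Hz, so the phase difference barely has room to
decorrelate and even independent channels score highly. The surrogate test
controls this: each channel is replaced by AAFT surrogates — value multiset
preserved exactly, modulus spectrum approximately, cross-channel phase
relations destroyed — and the pair's band-averaged WPCO must exceed the
surrogate ensemble's mean plus twice its sample SD (strict inequality) to
be accepted. Invalid coherence *is zero* downstream.

Design points decided here:

* **Both channels are surrogated** per realization (the symmetric null);
  `surrogate_mode = "one"` keeps one channel original. Either destroys the
  phase relation; the symmetric default is the stricter, assumption-free
  choice.
* **Ensembles are built per channel**, m surrogates each, and realization
  *k* of channel *i* is compared with realization *k* of channel *j*. This
  yields the full `C(22,2) * m` surrogate comparisons from `22 * m` AAFT
  transforms and keeps the whole ensemble reproducible from one seed via
  named substreams, independent of evaluation order.
* **Validity is decided on the band average** (one decision per pair, the
  granularity at which networks are reported), while per-frequency coherence
  and validity masks are stored as attributes for inspection. Deciding per
  frequency and then aggregating is the plausible alternative; band-level is
  what the network layer consumes.
* **m = 100 surrogates** by default; the sample (n−1) SD is used.

### ROI networks

The montage maps to 10 prefrontal regions (left/right FOA, OFA, PTBA,
DLPFC, IPFG); two midline channels belong to both hemispheric instances of
their region (CH04 in LFOA and RFOA, CH19 in LOFA and ROFA). The edge
between regions A and B is the mean over their cross-region channel pairs
of (band WPCO if valid, else 0). Pairs lying entirely inside either region
are excluded from cross-region edges (they are within-region coherence,
exported separately by `intra_roi_coherence()`, not placed on the diagonal),
and each unordered pair counts once even when shared channels offer two
routes to it. Whether invalid pairs should enter the mean as zeros or be
dropped cannot be settled from the reporting conventions in the field; the
package implements both (`mode = "zero"`, the default and stricter reading
of "invalid coherence is 0", and `mode = "valid-only"`) and records the
choice in every output manifest.

### Group statistics

The inferential layer mirrors standard practice for edge-wise screens:

* **Condition contrasts** (near- vs far-transfer) by two-sided paired t per
  ROI edge or per-ROI amplitude, `df = n_pairs - 1` computed from the data
  actually present.
* **Prior-level contrast** by the 27 % extreme-group design: top and bottom
  `ceiling(0.27 n)` subjects by prior score (9 of 31; ceiling is the only
  rounding consistent with that group size). The two ends are taken from one
  ranking by (score, subject order), so tied scores still give disjoint,
  deterministic groups. The groups are then *rank-matched and compared by a
  paired t with df = group size − 1* — the matched-extremes design used in
  the source analyses; an independent-samples t would be the textbook
  alternative, and the rank-matched pairing is deliberately reproduced here
  as the field-fidelity choice.
* **Performance correlations** by Pearson r with the usual
  `t = r * sqrt((n-2)/(1-r^2))` two-sided p.
* p-values are reported uncorrected (the convention these edge-wise screens
  use) with Benjamini–Hochberg q-values alongside.

`paired_t()` and `pearson_cor()` delegate to `stats::t.test()` and
`stats::cor.test()`; the test suite checks both against independent
textbook-formula loop oracles at 1e-10, and checks the whole contrast
machinery by Monte-Carlo: a planted paired effect of d = 1.2 at one edge
(n = 31) must be detected at p < 0.05 in at least 90 % of runs, and under a
global null the pooled edge-wise rejection rate must stay inside the
binomial band around 0.05.

## The synthetic cohort

`cohort_config()` defaults encode the study conditions the pipeline
targets: 31 subjects, 22 channels at 13.33 Hz, 600 s resting segments per
condition (prior / near / far).

* **Oscillators** are white noise spectrally confined to
  `center*(1±0.3)` — realistic irregular rhythms, not tones — one per
  physiological interval that the montage plausibly carries (cardiac 1.1 Hz,
  respiration 0.30, myogenic 0.09, neurogenic 0.035, endothelial metabolic
  0.014 Hz), with amplitudes (0.3/0.3/0.5/1.0/0.5 signal units) chosen so
  the slow bands dominate, as they do in ΔHbO. Spectral masking makes each
  component exactly band-limited (an IIR band-pass at normalized frequencies
  of 10^-3 is numerically fragile) and periodic on its segment.
* **Coupling.** A planted pair shares a common in-band source with amplitude
  weight `sqrt(kappa)` against independent sources at `sqrt(1-kappa)`, the
  second channel receiving the shared source at a constant phase lag
  (implemented by rotating its positive-frequency components). The shared
  fraction of in-band variance therefore equals kappa exactly and total
  power does not depend on kappa, giving a clean monotone map from kappa to
  expected WPCO: kappa = 0 is independence, kappa = 1 a constant in-band
  phase difference. (Weighting amplitudes by kappa and 1−kappa instead
  would make the variance share `kappa^2/(kappa^2+(1-kappa)^2)` — nearly
  flat below kappa = 0.5 and power-confounded; the square-root mixing is
  the same idea done on the variance scale.)
* **Subject heterogeneity and behavior.** Each subject draws one kappa scale
  (truncated normal, default mean 0.6, sd 0.15) that multiplies every
  planted coupling; performance under each condition is
  `intercept + slope * kappa + N(0, residual_sd)`, so the planted population
  correlation is `slope * sd(kappa) / sqrt(slope^2 var(kappa) +
  residual_sd^2)` (defaults give ≈ 0.5; slope 40 with sd 8 plants 0.6).
  Ground-truth tests that need the planted coupling verbatim set the subject
  scale to exactly 1 (`subject_kappa = list(mean = 1, sd = 0)`).
* **Drift and noise.** A half-cosine drift (period twice the segment, so it
  lives below any cutoff and exercises the DCT detrend) plus white Gaussian
  noise (sd 0.5).
* **Reproducibility.** Every draw flows from the root seed through named
  substreams keyed by (purpose, subject, condition, channel, realization),
  via a multiplicative hash into a 31-bit seed, so any recording can be
  regenerated bit-identically in isolation and generation order is
  irrelevant.

What the generator does **not** emulate: optode physics and scalp coupling,
motion artifacts, heterogeneous per-channel SNR, non-stationary coupling,
and any task structure. Passing recovery tests therefore demonstrates the
*algorithmic* correctness of the pipeline on signals with the assumed
statistical structure, not robustness to the full messiness of real fNIRS
data.

## Calibration experiments and problem sizes

The test suite runs four Monte-Carlo experiments whose sizes are the
package's own desk-scale choices:

* **Null calibration**: 22 independent white-noise channels, 240 s segments,
  m = 100 surrogates, 50 seeds; the mean fraction of validated pairs must
  stay below 10 %. (Measured around 2–3 %: the mean + 2 SD rule is
  conservative on a band average.)
* **Coupling recovery**: planted kappa in {0, 0.25, 0.5, 0.75, 1}, 600 s
  two-channel recordings, 20 replicates per level; mean band WPCO must be
  nondecreasing in kappa.
* **Behavioral recovery**: 200 cohorts of 31 subjects planted at population
  r = 0.6; the mean recovered Pearson r must land within ±0.05 (behavioral
  generation only — recordings are irrelevant to this statistic).
* **Contrast calibration**: the power and size runs described above
  (100 and 500 feature-level simulations).

Connectivity computations in these experiments decimate recordings by 8
(13.33 → 1.67 Hz) before the transform. The decimator is a zero-phase
spectral brick-wall low-pass at 0.4 of the target rate followed by
subsampling: for a 0.01–0.1 Hz analysis far below the new Nyquist this is
transparent to in-band phase (a causal IIR decimator would not be — phase
is the analyte), and it cuts transform cost by the decimation factor.

## Known limitations

* WPCO validity depends on the AAFT null; heavy nonstationarity (drifting
  variance, transient artifacts) violates the surrogate model and can
  inflate validity rates. Preprocess first; the pipeline assumes detrended,
  roughly stationary channels.
* The band-level validity decision can hide a narrow in-band coherence
  peak; per-frequency masks are stored so users can look.
* The rank-matched extreme-group t-test inherits the statistical quirks of
  its source design (it treats independent groups as pairs); it is provided
  for fidelity, with the machinery to run conventional alternatives.
* Eq.-level amplitude averaging uses mean modulus; analyses that averaged
  energy instead will differ by a Jensen-gap factor on fluctuating signals.
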