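---
title: "Mapping neurophysiological dynamics onto cortical micro-architecture: methods"
author: "dynmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping neurophysiological dynamics onto cortical micro-architecture: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`dynmap` implements a complete analysis chain for asking how the *temporal*
organization of regional brain activity relates to the *structural and
molecular* organization of the cortex:

1. **Phenotype** each region's resting-state time-series (MEG-like, ~500 Hz)
   with a broad catalog of time-series features.
2. **Extract the dominant spatial gradient** of those features with PCA.
3. **Relate dynamics to micro-architecture** (myelin-, thickness-,
   receptor-, expression-like maps) with partial least squares (PLS),
   assessed by spatial-autocorrelation-preserving permutation ("spin")
   tests, bootstrap confidence intervals, and distance-dependent
   cross-validation.
4. **Check confounds**: signal-to-noise geometry and empty-room
   (participant-free) recordings.
5. **Process expression data** in the style of post-mortem microarray
   atlases: probe filtering, differential-stability probe selection,
   robust-sigmoid normalization, sample-to-parcel assignment, cell-class
   mean maps.

Every stage is exercised end-to-end on synthetic data with known ground
truth; nothing in the package requires external downloads.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is verified.

**Geometry.** `gen_parcellation(n)` places `n` centroids per hemisphere on
the unit sphere with a Fibonacci lattice (left hemisphere at `x < 0`), the
right hemisphere being the exact mirror through the `x = 0` plane. Mirrored
geometry is what makes the one-hemisphere-rotation-then-mirror spin null
well defined.

**Spatial structure.** `gen_smooth_map()` draws from a Gaussian process on
the sphere with squared-exponential covariance in great-circle distance.
The default lengthscale of 0.5 rad gives maps whose autocorrelation range
is a substantial fraction of a hemisphere — comparable to the smoothness of
real cortical maps at a 100-parcel resolution. The kernel is not guaranteed
positive definite with geodesic distance, so a Cholesky with escalating
diagonal jitter is used; failure after eight escalations is a hard error.

**Regional time-series.** `gen_regional_timeseries()` shapes white Gaussian
noise in the frequency domain so that the one-sided spectral density
follows, exactly in expectation,

$$\log_{10} \mathrm{PSD}(f) = b - \log_{10}(k + f^{\chi}) +
  \textstyle\sum_p a_p \exp\left(-\tfrac{(f - c_p)^2}{2 w_p^2}\right),$$

i.e. a 1/f-with-knee aperiodic background plus Gaussian (in log-power)
oscillatory peaks. This is the same parametric family the spectral module
fits, which closes the generator–analyzer loop: recovery failures indicate
implementation defects, not model mismatch. `graded_profiles()` varies the
knee frequency (default 3–12 Hz), an alpha-band peak frequency (8–12 Hz)
and peak height (0.2–0.8 log10-power) linearly along a latent map — a
caricature of the sensory-to-association hierarchy of spectra. Defaults:
100 parcels, 509 Hz sampling, 110 s per recording (30 s discarded before
feature extraction, 80 s retained), 6 participants for the demo
configuration. Inter-participant spectral variability is not characterized
by the emulated studies, so `participant_jitter` (log-normal jitter on knee
and peak height) defaults to 0 and makes no fidelity claim.

**Coupled feature sets.** `gen_coupled_feature_sets()` builds the rank-1
latent model `X = c\,z w_x^\top + \sigma E` used for PLS parameter
recovery, returning the ground-truth latent map and unit-norm weights. One
subtlety worth knowing: because PLS z-scores columns, a *noiseless* rank-1
`X` collapses to sign information about `w_x` — every standardized column
equals `±ẑ`. Exact recovery at zero noise therefore holds for the score
maps and the weight signs; recovery of weight *magnitudes* is only a
meaningful claim in the presence of noise, where it is tested (median
`|r| > 0.9` at coupling 0.9, noise SD 0.5).

**Donor expression.** `gen_donor_expression()` mixes a shared per-probe
regional profile with donor noise, `x_d = \rho\,g + (1-\rho)\,\varepsilon_d`,
so differential stability rises monotonically with the reliability `ρ`;
a fifth of probes get high below-background rates so the intensity filter
has work to do.

All generators are pure functions of an integer seed; sub-streams are
derived with a counter/key hashing scheme (`split_seed`) so each component
can be regenerated independently and bit-identically.

# Spectral analysis

`welch_psd()` uses Hann-tapered overlapping windows (4 s, 50% overlap) and
a one-sided density normalization, checked by a Parseval test (integral of
the PSD equals the signal variance). No installed R package provides a
Welch estimator, so it is implemented here; the taper is not dictated by
the emulated protocol, and any standard taper satisfying the Parseval
property would do.

`fit_spectral_model()` is the package's spectral parameterization: in
log10-power space over 1–60 Hz it (1) fits the aperiodic knee model by
bounded nonlinear least squares with analytic gradients and a multi-start
over the exponent (χ ∈ {0.5, 1.5, 2.5}) — the knee model has genuine local
minima; (2) refits robustly after excluding points lying above the initial
fit (candidate oscillatory mass); (3) extracts Gaussian peaks
largest-first from the flattened spectrum until 6 peaks are reached or no
residual exceeds 2 residual-SDs and 0.1 log10-power, discarding guesses
within one SD of the fit-range edge and resolving overlapping guesses by
height, then jointly refits all peaks with width SDs bounded in
[0.5, 3] Hz; (4) refits the aperiodic component on the peak-removed
spectrum and reports the R² of the full model. These settings (range,
width limits, peak cap, height and threshold parameters) are the published
defaults of the procedure being emulated and are exposed as arguments.

The knee parameter yields the knee frequency `f_k = k^{1/χ}` and intrinsic
timescale `τ = 1/(2π f_k)`. Fits with `k ≤ 0` or `χ ≤ 0` are flagged
undefined rather than clamped.

**Accuracy.** On noiseless model spectra, `(k, χ)` are recovered to well
under 2%. On realized 80-s recordings, a *single-participant* τ estimate
carries ~7% median relative error across 100 regions — dominated by
periodogram variance interacting with data-driven peak removal, not by
bias (signed median error ≈ −2%). The analysis chain never consumes
single-recording τ maps: like the emulated protocol it averages
per-participant estimates into a group map, and at the demo scale of 6
participants the group-level median error is ~3.9%. The round-trip test
asserts the 5% tolerance at that group level.

**Oscillation scores.** Per band (delta 2–4, theta 5–7, alpha 8–14, beta
15–30 Hz; gamma excluded because consistent gamma peaks are not detectable
by this class of algorithm), the score multiplies a max-normalized
group-average peak-power map by a detection-probability map. The average
in step (b) runs over participants *with* a detection: the probability
factor already penalizes non-detection, and counting zeros would conflate
the two maps. Total-power band maps additionally cover lo-gamma 30–59 and
hi-gamma 60–90 Hz. Band edges are integers as printed in the emulated
protocol; at 0.25 Hz resolution the gaps between bands (e.g. 12–15 Hz)
are intentional and no tie-breaking is needed.

# The feature catalog

`feature_catalog()` lists ~105 deterministic features across seven
families — distribution, autocorrelation, forecasting, fluctuation
(detrended fluctuation analysis and variants), wavelet (Haar
multiresolution energies), entropy (histogram, ordinal-pattern,
word-richness), and spectral. This is a curated analogue of
massive-feature-extraction toolboxes, not a census: the claims the package
tests concern families and specific highlighted features (`t_c`, the first
zero-crossing of the ACF; `ac₄₈`, autocorrelation at 48 ms ≈ 24 samples at
509 Hz; the DFA exponent α), all of which are present by name. Lags are
specified in seconds and converted with half-up rounding, which makes the
"24 steps" and "48 ms" conventions agree at ~500 Hz. The sample ACF uses
the biased 1/N normalization (a valid correlation sequence, the common
toolbox convention). Features that error or return non-finite values are
flagged invalid, never raised.

DFA detrends the cumulative-sum profile in non-overlapping windows
(default ~18 log-spaced scales, 16–2048 samples) and reports the log-log
slope; rms and mean-absolute fluctuation formulations and detrending
orders 1–2 are separate catalog entries. Note a degenerate-input subtlety:
a straight-line *signal* integrates to a quadratic profile, so it is
order-2 detrending that removes it exactly; zero fluctuation (up to
machine precision relative to the profile scale) is flagged invalid.

**Normalization.** Per feature across parcels, the outlier-robust sigmoid
`1/(1+\exp(-(x-\mathrm{med})/(\mathrm{IQR}/1.35)))` followed by min-max
rescaling to [0, 1]. The 1.35 divisor makes the sigmoid slope consistent
with a unit-SD Gaussian (the feature-extraction-toolbox convention); the
expression module deliberately uses the bare IQR, as its source procedure
prints it. Both conventions are exposed as arguments. Aggregation drops
any feature invalid in any participant, then averages — matching the
stated pruning rule.

**Stability analysis.** `stability_curve()` correlates feature vectors of
consecutive nested-from-start segments (5–125 s in 5 s steps, reduced
fast catalog). Whether consecutive segments share samples was not stated
in the emulated protocol; nested segments are used and documented here.

# Spin nulls and FDR

`make_spin_ensemble()` draws uniform rotations via normalized quaternions
(exact uniformity on SO(3)), rotates the left hemisphere, applies the
x-mirror-conjugated rotation to the right, and reassigns each rotated
centroid the nearest original same-hemisphere centroid. Reassignment is
not a bijection — duplicated and dropped parcels are intended behavior of
the "closest resulting parcel" scheme. The left hemisphere carries the
primary rotation; by the mirror symmetry of the construction the choice is
exchangeable. p-values are two-sided by absolute value with the plus-one
convention `(1 + \#\{|r_{null}| \ge |r|\})/(1 + n_{perm})`, hence never
zero. Type-I error at α = 0.05 on independent smooth-map pairs is
verified to lie in [0.03, 0.08]. FDR control is Benjamini–Hochberg via
`stats::p.adjust`, tested against a hand-written step-up oracle.

# Gradients and PLS

`fit_pca()` z-scores feature columns (features are on heterogeneous scales
even after unit-interval normalization) and fixes each component's sign by
nonnegative Spearman correlation with a reference map (default: the first
feature column) — PCA signs are otherwise arbitrary. Only PC1 is analyzed
by default; higher components are retained behind `n_components`.

`pls_fit()` computes `R = X^\top Y/(n-1)` on z-scored columns, so entries
of `R` are exactly Pearson correlations — the cross-correlation is only
defined up to a scalar, which rescales singular values but leaves singular
vectors, effect sizes `η_i = s_i^2/\sum_j s_j^2`, and permutation
p-values unchanged (unit-tested). Brain scores are `XU` and `YV`;
loadings are Pearson correlations of input columns with own-side scores.

The permutation test spins the rows of `X` only (spinning one side
suffices to break the pairing while preserving each side's spatial
autocorrelation) and compares same-rank singular values without Procrustes
realignment of permuted LVs, matching a null distribution of singular
values. Bootstrap resampling draws parcels jointly for `X` and `Y`,
aligns LV signs to the original fit by scalar product before recomputing
loadings, and reports percentile 2.5/97.5 intervals; degenerate resamples
(fewer than 3 distinct parcels, or a constant column) are redrawn. At 100
parcels the percentile interval's empirical coverage of a known loading
of ≈0.81 is ~94–95%.

Distance-dependent cross-validation draws seed parcels without
replacement (99 splits is the maximum at 100 parcels), trains on the 75%
of parcels nearest the seed in Euclidean centroid distance, standardizes
test rows with training statistics (no leakage), projects them onto
training singular vectors, and records train/test Spearman correlations
of the LV1 score maps. Out-of-sample evaluation uses LV1; other LVs are
available via the `lv` argument.

# Confound analyses

`snr_db()` implements the decibel sensor-model SNR
`10\log_{10}\!\big(\tfrac{a^2}{N}\sum_k b_k^2/s_k^2\big)` with a 10 nAm
default dipole amplitude. `snr_feature_filter()` removes features whose
spin-tested correlation with the SNR map has `p < 0.05` *uncorrected* —
deliberately conservative for feature removal, since correcting would
remove fewer features; FDR-based filtering is available behind a flag.
`regress_covariate()` residualizes features on the SNR map (residuals
exactly orthogonal to the centered covariate). The empty-room pathway
reuses the full catalog on noise recordings, Procrustes-aligns the noise
PCA weights to the rest weights, and spin-tests the correlation of the
aligned first-component score maps. Because data-level sign flips move the
score map itself (not the weights), this comparison is only defined up to
sign; magnitude and two-sided significance carry the meaning. With
centroid-level synthetic data the SNR map is directly per-parcel — the
vertex-level parcellation step of the emulated protocol has no analogue
here, a deliberate simplification.

# Expression processing

Probes below background in ≥ 50% of samples pooled across donors are
discarded (the boundary case is discarded, as stated in the emulated
procedure). Differential stability is the mean pairwise Spearman
correlation of a probe's regional profile across donors; the most stable
probe represents each gene. Normalization applies the robust sigmoid +
unit rescale across genes within each sample, then across samples within
each gene — the two stages do not commute, and the order-dependence is
tested rather than hidden. Samples (and their x-mirrored copies) are
assigned to the nearest centroid within a configurable angular radius
(the synthetic analogue of a 2 mm rule); empty parcels are filled by
inverse-distance-weighted averages over the donor's assigned samples — a
centroid-level analogue of dense volumetric interpolation that preserves
the statistical role (no empty parcels) without a volumetric space.
Cell-class maps are unweighted means over gene sets; the seven canonical
class names (astro, endo, micro, neuron-ex, neuron-in, oligo, opc) are
taken as given input, their derivation being out of scope.

# Problem sizes and determinism

The demo configuration (`pipeline_config()` defaults) is 100 parcels,
6 participants, 110 s at 509 Hz, 45 micro-architecture maps, 1000 spin
permutations, 500 bootstrap resamples, 99 CV splits; it completes in a
few minutes on one CPU and recovers the generating latent gradient with
`|r_s| > 0.99`. Calibration experiments use 500 map pairs at 1000
permutations (spin type-I), 200 replicates at 500 permutations (PLS null
uniformity), and 400 replicates at 500 bootstraps (CI coverage) — sizes
chosen so each estimate's Monte-Carlo error is small relative to the band
being asserted. Every stochastic step consumes a seed derived from one
master seed, and rerunning a configuration reproduces results
bit-for-bit.

# What passing tests do and do not show

The generator produces stationary Gaussian signals with exactly the
fitted spectral family, smooth latent structure, and exchangeable
participants. Real MEG is nonstationary, non-Gaussian, volume-conducted,
and its micro-architectural maps are compiled across datasets and
individuals. Passing tests therefore demonstrate that the *procedures*
are implemented correctly and are statistically calibrated under known
conditions — not that the scientific conclusions of any particular
dataset would replicate. Headline empirical quantities (variance
fractions, covariance percentages, score-map correlations) are
data-bound: the synthetic demo prints its own values, which are not
comparable to values computed on empirical recordings.

# Known limitations

- The spectral generator and analyzer share one parametric family;
  recovery tests cannot detect model misspecification, only
  implementation error.
- The feature catalog is representative, not a replica of any toolbox
  census; features requiring embedding-dimension searches or O(n²)
  kernels are out of scope.
- Spin nulls operate on centroids, not vertices; variogram-matching and
  parameterized surrogate nulls are not implemented.
- The expression module's coordinate space is the unit sphere; ontology-
  constrained sample matching and probe re-annotation have no synthetic
  analogue and are not emulated.
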