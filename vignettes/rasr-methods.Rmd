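---
title: "Artifact subspace reconstruction on the SPD manifold: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact subspace reconstruction on the SPD manifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasr)
```

This vignette is the package's account of the science it implements: the
statistical model behind artifact subspace reconstruction (ASR) and its
Riemannian variant (rASR), the parameters that matter and why they default
to what they do, what the synthetic-data generator emulates (and what it
does not), and the numerical and design decisions taken where the method
leaves room.

## 1. The model

EEG artifacts such as eye-blinks are high-variance, spatially stereotyped
events superimposed on comparatively low-variance brain activity. ASR
treats them as statistical anomalies in component space. The method has
two phases.

**Calibration.** From an artifact-poor stretch (one minute of resting EEG
is the practical recommendation) the pipeline learns:

1. a robust covariance $U$: windowed sample covariances of spectrally
   shaped calibration data are combined by the Euclidean geometric
   (L1) median, $U = \arg\min_U \sum_i \lVert C_i - U\rVert_F$, computed
   with a damped Weiszfeld iteration. The median, unlike the mean, is not
   dragged by residual artifacts in the calibration data;
2. the mixing matrix $M = U^{1/2}$ (unique symmetric root, $MM^\top=U$),
   which maps whitened component space to sensor space;
3. an orthonormal component basis $V$: the eigenvectors of $M$
   (Euclidean mode) or a basis derived from principal geodesic analysis
   of the windowed covariances at base $U$ (Riemannian mode, §4);
4. per-component amplitude statistics of the shaped calibration signal:
   windowed RMS values per component, summarized by a robust location
   $\mu_j$ (median) and scale $\sigma_j$ (1.4826·MAD, consistent with the
   SD under normality). These become the threshold operator
   $T = \mathrm{diag}(\mu + k\sigma)\,V^\top$.

**Processing.** The stream is consumed in analysis windows of
$\mathrm{range} = \mathrm{round}(\mathrm{srate}\cdot\mathrm{window})$
samples. For each detection step the (smoothed) covariance is
eigendecomposed, $U(s) = V_{new} D_{new} V_{new}^\top$ with ascending
eigenvalues, and component $j$ is flagged when

$$D_{new}[j] > \textstyle\sum_i (T\,V_{new})^2_{ij},$$

i.e. when its variance exceeds the squared projection of the calibration
thresholds onto its direction. At most `maxdims` components (the largest
offenders) may be flagged; if every component exceeds its threshold the
previous reconstruction operator is held (degenerate-window policy).
Flagged components are removed and the window is reprojected through the
calibration mixing matrix,

$$X_{clean} = M\,(V_{clean}^\top M)^{+}\,V^\top X,$$

which re-expresses the lost variance inside the retained subspace — the
output keeps all channels and full rank. Successive reconstruction
operators are cross-faded with a raised-cosine ramp over one stepsize so
the output has no switching discontinuities.

The two engines differ only in covariance handling:

* **Euclidean (ASR):** one covariance per stepsize chunk, combined as a
  uniform weighted average over the trailing analysis window (a sliding
  one-window covariance), decomposed at every chunk.
* **Riemannian (rASR):** one unbiased estimator $U = XX^\top/(t-1)$ per
  analysis segment, averaged with the previous segment's estimator by a
  two-point Karcher mean, decomposed **once per segment**. The smaller
  published stepsize only controls the reconstruction/cross-fade cadence.

This is where the efficiency difference comes from: per analysis window
the Euclidean engine performs $\lceil \mathrm{range}/\mathrm{stepsize}
\rceil$ eigendecompositions, the Riemannian engine exactly one. The
package instruments this count (`decomposition_counter()`), which is the
hardware-independent content of the runtime comparison between the two
methods.

## 2. Riemannian geometry of covariance matrices

Covariance matrices are symmetric positive-definite (SPD) and form a
negatively curved manifold, not a vector space. The package implements
the affine-invariant metric — the standard choice in the EEG/BCI
literature — in `R/spd.R`:

* geodesic distance
  $d(A,B) = \lVert \log(A^{-1/2} B A^{-1/2}) \rVert_F$, invariant under
  congruence $A \mapsto WAW^\top$ (e.g. re-referencing or linear sensor
  transformations);
* exp/log maps
  $\mathrm{Exp}_B(V) = B^{1/2}\exp(B^{-1/2} V B^{-1/2})B^{1/2}$ and its
  inverse;
* the weighted Karcher mean
  $\arg\min_U \sum_i w_i\, d(C_i, U)^2$. Two-point means use the closed
  geodesic form $A \#_t B = A^{1/2}(A^{-1/2}BA^{-1/2})^t A^{1/2}$ (the
  fixed-point iteration can stall on the ill-conditioned covariances of
  strongly spatially correlated EEG); larger sets use the standard
  fixed-point iteration (tolerance $10^{-8}$ on the metric gradient norm,
  at most 50 iterations, initialized at the weighted Euclidean mean);
* principal geodesic analysis (PGA), realized as tangent-space PCA at the
  base point: whitened matrix logarithms are vectorized with off-diagonal
  entries scaled by $\sqrt2$ (preserving the Frobenius inner product) and
  eigendecomposed. Variances are squared geodesic distances from the
  base, so they sum to the mean squared distance of the inputs.

The determinant of the geodesic midpoint is the geometric mean
$\sqrt{\det A \det B}$, whereas the Euclidean average always has a
determinant at least that large (the *swelling effect*, strict for
non-commuting pairs) — the quantitative reason for geometry-aware
averaging, and a property-tested invariant of the package.

## 3. Parameters

`asr_params()` resolves the published per-method values; every field can
be overridden.

| field | rASR | ASR | meaning |
|---|---|---|---|
| `cutoff` (k) | 1 | 5 | threshold multiplier in $\mu + k\sigma$ (unitless) |
| `window` | 0.3 s | 0.5 s | analysis-window length; `range = round(srate*window)` |
| `stepsize` | 16 | 32 | samples between covariance/reconstruction updates |
| `maxdims` | 1.0 | 0.66 | reconstructable fraction of dimensions (count if > 1) |
| `flatline` | 1 s | 5 s | flat-run duration that marks a dead channel |
| `hp_band` | (0.25, 0.95) Hz | (0.25, 0.95) Hz | drift high-pass transition band |

Two published values need interpretation. `maxdims = 1` is read as the
*fraction* 1.0 (all dimensions reconstructable), consistent with 0.66
being a fraction — not as "one dimension". A legacy `burst` entry is
accepted as an alias for `cutoff`, with an explicit `cutoff` taking
precedence; the relationship between the two wrapper-level names is not
settled by their source, and the alias rule is the package's reading.
`window` is converted to samples by round-half-away-from-zero.

The rASR values are deliberately aggressive (small cutoff, short window):
its covariance model updates once per segment instead of once per chunk,
so detection must be more sensitive to compensate. The practical
consequences of `cutoff = 1` are analyzed in §7.

## 4. Design choices in open territory

**Covariance smoothing and lookahead.** The smoothing function is only
loosely constrained by the method's description ("a weighted average with
the previous data segment"). The package uses the sliding one-window
average (Euclidean) and the equal-weight two-point Karcher mean of the
current and previous segment estimators (Riemannian). Both estimators are
*centred*: the reconstruction operator derived from a covariance spanning
$W$ samples is applied, through a short internal delay queue, to the
chunk of samples at the centre of that span — a delay of
$(W-\mathrm{chunk})/2$ samples (46 samples for ASR, 37 for rASR at
250 Hz). An exponential-forgetting smoother was evaluated and rejected:
its centre-of-mass lag exceeds one analysis window at the published
stepsizes, so the correction operator activates after the artifact has
passed and blink suppression collapses (~32% instead of >99%). No output
sample depends on data beyond the end of its own analysis window, so the
processing remains causal with a fixed, sub-window latency — exactly the
regime the online variant targets.

**Calibration shaping filter.** Detection statistics are calibrated on
spectrally shaped data approximating an inverse typical-EEG spectrum
(low frequencies and >80 Hz boosted ×3, 3–13 Hz attenuated to 0.33–0.75,
16–40 Hz unchanged). The filter is realized as a causal *minimum-phase*
FIR (cepstral construction, length = one second of taps): a linear-phase
design of useful length would delay the detection statistics by hundreds
of milliseconds relative to the samples being reconstructed. The filter
can be bypassed (`use_shaping_filter = FALSE`). The same shaped signal is
used in calibration and processing, so thresholds and detection
statistics stay commensurable.

**PGA-derived basis in Riemannian calibration.** PGA yields principal
*tangent directions* (symmetric matrices), not a channel basis. The
bridge chosen here: from the whitened directions $G_k$ and variances
$\lambda_k$, form the channel-space spread operator
$A = U^{1/2}\big(\sum_k \lambda_k G_k^2\big)U^{1/2}$ — equal to the
second moment $\sum_i w_i \,\mathrm{Log}\,(C_i)^2$ of the tangent cloud —
and take its eigenvectors, ordered ascending. This gives an orthonormal
basis whose directions are ranked by how much manifold variation they
carry, coinciding with the PCA basis when the windowed covariances
fluctuate isotropically around $U$. It is switchable
(`riemannian_calibration = FALSE` falls back to PCA of $M$).

**Robust component statistics.** Median and scaled MAD of windowed RMS
(non-overlapping windows of `window` seconds), with a classical mean/SD
variant via `robust_stats = FALSE`. Robust statistics keep residual
calibration artifacts from inflating the thresholds.

**Blink-evaluation windows.** Blink epochs span −400…400 ms around the
peak with baseline −400…−300 ms — entirely outside the ~[−250, 450] ms
blink waveform support, so the baseline cannot subtract part of the
artifact itself. Both scalp maps entering the topography similarity are
taken at the *single* blink-peak latency of the uncorrected average;
searching the corrected map for its own extremum would select the worst
residual latency and bias the similarity upward. N1 is the signed
minimum of the O1/O2 mean in 120–250 ms; P1 is searched in 70–150 ms;
SNR is $10\log_{10}(|\mathrm{peak}|/\mathrm{SD}_{baseline})$ with the
baseline SD taken over the 200 ms pre-stimulus interval.

**Blink detection.** A robust threshold detector (median + 3·scaled-MAD
on the smoothed mean of Fp1/Fp2, peak-aligned, 500 ms refractory)
replaces template-learning blink detectors: synthetic sessions carry
ground-truth blink times, so a learned template adds nothing, and the
detector is validated against that ground truth (recall and precision
≥ 95% at ±40 ms).

## 5. The synthetic-data generator

`generate_session()` emulates the recording situation the method is meant
for: a 24-channel, 250 Hz mobile cap, one minute of clean resting
calibration, and a task stretch with frontal eye-blinks and occipital
visual-evoked potentials. All pieces are pure functions of
(config, seed), and the task data equal background + blink component +
VEP component *exactly*, so signal and artifact can be separated when
scoring.

* **Background:** independent $1/f^\alpha$ latent sources (default
  $\alpha = 1.5$, a typical broadband EEG slope) under each electrode,
  mixed through a fixed Gaussian spatial kernel over the 10/20 layout
  (width 0.5 head radii — neighbouring channels correlate ≈ 0.6),
  scaled to 10 µV RMS per channel. Each source and each channel's 1 µV
  white sensor noise is amplitude-modulated by a slow log-normal
  envelope (CV 0.4, ~2 s timescale): mobile EEG is strongly
  nonstationary (rhythm waxing/waning, gait and electrode-contact
  fluctuations), and a stationary Gaussian background would make the
  calibration scale estimates unrealistically tight. The 1 µV noise
  floor keeps channel covariances full rank, as real amplifiers do.
* **Blinks:** a biphasic ~300 ms bump (generalized-Gaussian main lobe,
  mild negative rebound), frontally focal (exponential fall-off from the
  frontopolar midpoint; occipital weight < 6% of frontal), peak
  calibrated to 254.92 µV at Fp1/Fp2 — the blink amplitude scale of
  indoor mobile recordings. Timing is a renewal process (default
  40/min) with a hard 500 ms refractory gap.
* **VEPs:** a positive P1 (default +5 µV, 100 ms) and negative N1
  (−10 µV, 170 ms) with an occipitally focal topography, at ~2 s
  stimulus intervals.

What the generator does **not** emulate: gait/movement artifacts,
saccades and non-stereotypical eye activity, electrode pops, line noise,
and genuine neural nonstationarity beyond amplitude modulation. Passing
tests therefore demonstrate that the engines remove large, spatially
stereotyped transients while preserving small evoked signals under
realistic amplitude statistics — not that they handle every artifact
class of field recordings.

## 6. Numerical choices

* SPD validation symmetrizes and, for rank-deficient estimates, adds a
  relative ridge $10^{-10}\,\mathrm{tr}(U)/c$ before any matrix log or
  inverse square root.
* Eigendecompositions use ascending eigenvalue order throughout.
* The Weiszfeld iteration uses the Vardi–Zhang rule when an iterate
  coincides with a data point (tolerance $10^{-8}$, 100 iterations).
* Pseudoinverses are SVD-based with tolerance
  $\max(\mathrm{dim})\cdot\varepsilon\cdot\sigma_{max}$.
* Component scales are floored at $10^{-12}(\mu+1)$ so exactly periodic
  calibration components (zero MAD) cannot produce zero thresholds.
* Fisher z of a topography correlation clips $|r|$ at $1-10^{-12}$.
* FIR filtering is FFT-based; offline filters are linear-phase applied
  zero-phase (reflection padding, group-delay compensation), the online
  shaping path is causal minimum-phase with streaming carry, so chunked
  and offline runs are bit-identical.
* Problem sizes in the test suite: module tests use 60 s sessions; the
  end-to-end score card uses a 300 s task (~200 blinks, ~148 VEPs),
  enough for the blink-locked background noise to sit below 1 µV.

## 7. Known limitations

* **`cutoff = 1` flags constantly on matched data.** The rASR threshold
  $\mu + 1\sigma$ sits near the 84th percentile of the very statistic
  that fluctuates during processing, so on data statistically identical
  to the calibration the Riemannian engine flags a large fraction of
  windows (measured ~48%, with channel correlation ~0.87 after
  correction) — with `cutoff ≥ 3` the same engine passes clean data
  essentially untouched. This mirrors the published observation that the
  rASR parameter set is "substantially more aggressive": the method
  buys blink suppression and SNR at the price of touching clean data.
  The VEP itself survives (N1 retained within 10% in the score card).
* **Karcher smoothing shrinks artifact spikes.** The geodesic mean of a
  blink-loaded and a clean covariance has the blink eigenvalue reduced
  toward the geometric mean $\sqrt{\lambda_{blink}\lambda_{bg}}$ — far
  more shrinkage than Euclidean averaging. The decomposed eigenvector
  therefore tilts slightly away from the true blink direction
  ($|\cos|\approx 0.9986$ vs ≈ 0.9995 for the Euclidean engine's
  sliding window), leaving a spatially structured blink-locked residual
  of a few tenths of a µV. Once suppression reaches ~99.9%, the
  blink-topography similarity $R^2$ compares two near-noise maps and
  fluctuates strongly between sessions (observed 0.0–0.67 across seeds,
  rASR above ASR) — the similarity criterion is only meaningful while
  the residual clearly exceeds the blink-locked background noise.
* **Flat eigen-spectra inflate sample eigenvalues.** In near-isotropic
  subspaces (e.g. a pure white-noise montage at c/t ≈ 0.2) the top
  sample eigenvalue is biased up by ~$(1+\sqrt{c/t})^2$, eroding the
  detection margin; realistic spatially correlated EEG has a decaying
  spectrum and is unaffected, but detection thresholds should not be
  trusted for high channel counts at very short windows.
* **I/O formats.** Recordings are exchanged as plain-text containers
  (header + TSV, 15 significant digits) plus TSV event sidecars;
  EDF/BDF readers are not bundled. Calibration models serialize to JSON
  bit-exactly.
* The evaluation module reports descriptive scores; inferential group
  statistics are out of scope.
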