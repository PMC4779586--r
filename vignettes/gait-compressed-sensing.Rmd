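---
title: "Methods: compressed sensing of gait accelerometry with gaitcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compressed sensing of gait accelerometry with gaitcs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcs)
```

## The problem

A hip-worn accelerometer samples tri-axial acceleration at 100 Hz. Sending
the raw stream to a remote terminal is the dominant energy cost of the
device, so the stream is compressed on-device by a linear sketch
$Y = \Phi X$ with $\Phi \in \mathbb{R}^{M \times N}$, $M < N$, and
reconstructed at the terminal. Two obstacles shape the design. First, the
device has almost no compute: the measurement operator must be
implementable with a handful of integer additions. Second, acceleration
during gait is quasi-periodic but *not* exactly sparse in any fixed basis,
so reconstruction methods that rely on exact sparsity degrade.

`gaitcs` addresses both: a sparse binary $\Phi$ with a minimal column
weight for the device side, and block sparse Bayesian learning for the
terminal side, with the classic sparsity-based algorithms as baselines and
a downstream feature/classification chain to quantify whether the
reconstruction preserves what matters for activity recognition.

## Measurement matrices

`make_sparse_binary(M, N, d, seed)` places exactly `d` ones uniformly at
random (without replacement) in each column. Entries are the literal value
1; an optional flag rescales by $1/\sqrt{d}$ for unit-norm columns, but the
default keeps the integer structure that makes the device-side product a
count of `d` additions per input sample. Two deliberate choices:

* **Zero-row rejection.** A row of zeros is a measurement that ignores the
  signal entirely. After drawing all columns, any draw containing an
  all-zero row is rejected and redrawn (up to 100 attempts, then an
  error). The redraw continues the same seeded RNG stream, so the
  construction remains a pure function of `(M, N, d, seed)`.
* **Descriptor regeneration.** The matrix never needs to be transmitted:
  `matrix_descriptor()` captures `{kind, M, N, d, seed, normalized}` and
  `matrix_from_descriptor()` regenerates the matrix bit-exactly.

Dense Gaussian ($N(0, 1/M)$ entries) and Bernoulli ($\pm 1/\sqrt{M}$)
matrices serve as the conventional comparison points; the $1/\sqrt{M}$
scaling gives unit expected column norms, the common convention.

## The BSBL model and the BSBL-BO updates

A length-$N$ frame (or its DCT coefficient vector) is partitioned into $l$
contiguous blocks of sizes $h_1, \dots, h_l$ (default: equal blocks of 20
samples; `block_partition()` exposes arbitrary sizes). Each block is
zero-mean Gaussian with covariance $\lambda_j B_j$: $\lambda_j \ge 0$ is
the block scale — $\lambda_j = 0$ switches the block off, which is how
block sparsity enters — and $B_j$ is a positive-definite matrix describing
correlation *within* the block. Measurements carry white Gaussian noise of
variance $\rho$. Conditional on the hyperparameters, the posterior of the
frame is Gaussian with

$$\mu = \Sigma_0 \Phi^T (\rho I + \Phi \Sigma_0 \Phi^T)^{-1} Y,
\qquad
\Sigma = \Sigma_0 - \Sigma_0 \Phi^T (\rho I + \Phi \Sigma_0 \Phi^T)^{-1}
\Phi \Sigma_0,$$

with $\Sigma_0 = \mathrm{blkdiag}(\lambda_j B_j)$. `posterior_moments()`
implements exactly this $M \times M$ form, which stays valid when blocks
have been pruned ($\Sigma_0$ singular). The reconstruction is
$\hat X = \mu$ at the learned hyperparameters.

Hyperparameters are learned by iterating, with
$H = \rho I + \Phi \Sigma_0 \Phi^T$ and $v_j = \Phi_j^T H^{-1} Y$:

* **Block scales** (bound-optimization fixed point):
  $\lambda_j \leftarrow \lambda_j \sqrt{v_j^T B_j v_j \big/
  \mathrm{tr}(\Phi_j^T H^{-1} \Phi_j B_j)}.$
  The multiplicative form drives irrelevant blocks to zero geometrically,
  which is what makes pruning effective; an additive EM-style update
  shrinks them only harmonically and stalls above any practical pruning
  threshold.
* **Noise variance** (exact EM):
  $\rho \leftarrow \big(\|Y - \Phi\mu\|^2 +
  \mathrm{tr}(\Phi \Sigma \Phi^T)\big)/M$, with
  $\mathrm{tr}(\Phi \Sigma \Phi^T) = \mathrm{tr}(S) -
  \mathrm{tr}(S H^{-1} S)$, $S = \Phi\Sigma_0\Phi^T$, computed from cached
  $M \times M$ quantities. The posterior covariance has cross-block terms;
  summing per-block traces instead of using the full expression
  systematically overestimates $\rho$ (by roughly a factor of three in our
  parameter-recovery tests), so the exact form matters.
* **Intra-block correlation.** The per-block empirical second moments
  $(\Sigma_{jj} + \mu_j\mu_j^T)/\lambda_j$ are pooled across blocks and
  collapsed to a single AR(1) parameter
  $r = \overline{\text{first subdiagonal}} / \overline{\text{diagonal}}$,
  clipped to $|r| \le 0.99$, giving $B_j = \mathrm{Toeplitz}(1, r, r^2,
  \dots)$ (`estimate_intra_block_correlation()`). One shared parameter is
  all the data can support when each block contributes a handful of
  samples; with `learn_correlation = FALSE` the $B_j$ stay identity.

### Scaling, pruning, convergence

* Measurements are internally rescaled to unit RMS and the estimate scaled
  back, so thresholds on $\lambda$ are meaningful regardless of units
  (accelerations in g, in m/s², or DCT coefficients). The returned state
  reports hyperparameters on the rescaled model plus the factor.
* **Pruning** removes blocks with $\lambda_j$ below `prune_threshold`
  (default $10^{-3}$; $10^{-5}$ in noiseless mode). Pruning is deferred
  for the first `prune_burnin = 8` sweeps: early in the fit the scale of a
  weak-but-real block can transiently undershoot while a dominant block
  absorbs the signal, and pruning on that transient is irreversible. A
  final hard prune guarantees the invariant users rely on: every block
  whose final scale is below the threshold is *exactly* zero in the
  output.
* **Convergence** is declared when $\max_j |\Delta\lambda_j| <$ `tol`
  (default $10^{-8}$) or after `max_iter = 500` sweeps; non-convergence is
  reported in the returned status, with the best iterate.
* **Degeneracies.** $Y = 0$ returns the zero signal immediately. If every
  block is pruned, the zero signal is returned with a warning status. A
  single block spanning the frame reduces the model to ridge-type
  estimation and is supported. If $H$ is numerically singular (typical
  once most blocks are pruned in near-noiseless fits), an escalating
  diagonal jitter of $10^{-10} \cdot \mathrm{tr}(H)/M$ is added before
  factorization.
* **Noiseless mode** fixes $\rho = 10^{-10}$ for exact-recovery settings
  where $Y = \Phi X$ holds to machine precision.

### Time domain or DCT domain

`bsbl_bo()` operates on any effective matrix, so the block model can be
placed on the time-domain frame directly or, via
`reconstruct_in_basis()`, on the coefficients of an orthonormal basis
(`dct_basis()`). For quasi-periodic gait frames the DCT concentrates the
harmonic structure into a few low-frequency coefficient blocks and is the
default for all reconstruction workflows here; in our measurements the
time-domain placement was substantially worse for this signal class
(blocks of 20 samples of a gait cycle are neither sparse nor accurately
AR(1)). Time-domain mode remains available because the model itself does
not require sparsity of the frame.

## Baselines

All baselines estimate DCT coefficients $\alpha$ from $Y = (\Phi\Psi)
\alpha$ and are standard: OMP (greedy selection, least-squares refit per
step), subspace pursuit (candidate merge, refit, prune to $k$), SL0
(smoothed-$\ell_0$ descent over the affine constraint set with a geometric
$\sigma$ schedule: from $2\max|\Psi^T\Phi^+Y|$ by factor 0.7 down to
$10^{-4}$, 3 projected-gradient steps per $\sigma$), and basis pursuit.
Basis pursuit is solved by ADMM — alternating projection onto
$\{A\alpha = Y\}$ (cached Cholesky of $AA^T$) with entrywise soft
thresholding — run to residual tolerance $10^{-9}$, which attains the
$\ell_1$ optimum to a gap around $10^{-7}$ on unit-scale problems; the
tests cross-check it against an LP solver on small instances. Group-aware
algorithms (e.g. group lasso, structured OMP) are not implemented but can
be attached through `register_reconstructor()`, which is also how the
command-line `--algo` flag resolves names.

`omp()` defaults to $k = \lfloor M/4 \rfloor$ atoms when neither a
sparsity level nor a residual tolerance is given; subspace pursuit uses
the same default through the registry. These defaults are deliberately
generous for signals whose energy concentrates in few DCT coefficients.

## Evaluation criteria and conventions

NMSE $= \|X - \hat X\|^2 / \|X\|^2$, SNR $= -10\log_{10}$ NMSE (dB;
`Inf` for a perfect reconstruction — consumers clip as needed), and the
Pearson correlation between frame and reconstruction.

**Compression ratio.** The package defines CR $= (N - M)/N \times 100\%$:
higher CR means fewer measurements and a harder problem, which is the
orientation in which all trends here are stated (error grows as CR grows).
The quotient form $N/M \times 100\%$ appears in parts of the CS literature
and is provided as `compression_ratio_literal()`, but it is inconsistent
with percentages below 100 for $M \le N$ and is not used anywhere else in
the package.

**Rounding.** All metrics are returned at full precision; reported
percentages are rounded half-up (`round_half_up()`) only at the reporting
layer.

## The comparison protocol

`compare_reconstructors()` draws synthetic gait frames, compresses each
with a fresh `d = 8` sparse binary matrix at the requested $M$, runs every
algorithm on the same measurements, and records NMSE/SNR/correlation per
trial. One protocol decision deserves emphasis: the measurements in this
protocol are *exact* — the generator's sensor noise is part of the frame
being reconstructed, not of the channel — and the greedy/$\ell_1$
baselines all solve equality-constrained problems. BSBL-BO therefore runs
in its noiseless measurement mode here (its noisy mode would model part of
the frame itself as channel noise and answer a different question).
Function-level defaults are unchanged: `bsbl_bo()` alone still learns
$\rho$, because telemonitoring channels generally are noisy. Within the
protocol BP is capped at 5000 ADMM iterations, past its quality plateau on
frames of this size.

## Windowing, features, classification

Recordings are segmented into 512-sample windows with 50% overlap
(half-open `[start, start + L)`, 0-based starts; trailing partial windows
are dropped). Each window maps to exactly 12 features: per-axis standard
deviation, skewness and kurtosis, plus the three inter-axis Pearson
correlations. Four statistics on three axes would naively give that count
per axis, but correlation is a pairwise quantity; the three inter-axis
pairs are the composition consistent with a 12-dimensional vector, and the
one this package uses.

The moment formulas use the population ($1/L$) standard deviation inside
skewness and kurtosis by default, with the textbook bias-correction
prefactors applied on top; `sd_type = "sample"` switches to the $(L-1)$
form under which those prefactors reduce to the conventional adjusted
statistics (kurtosis of `1:5` is then $-1.2$ rather than $2.625$). The
default preserves the formulas as stated; the switch exists because the
prefactors normally assume the sample form.

`crossval_protocol()` provides class-stratified k-fold assignment
(reproducible by seed) and leave-one-subject-out splits; subject-level
hold-out is the meaningful generalization test for wearables, since
windows from one subject are strongly dependent. `classify_features()`
runs both. Classifier backends are pluggable; shipped configurations are
an MLP (600 epochs — learning rate 0.3 and momentum 0.5 are recorded for
backends that accept them; the bundled `nnet` backend uses its own BFGS
optimizer) and a polynomial-kernel SVM (degree 2, cost 1). The SVM uses
the inhomogeneous kernel ($\mathrm{coef}_0 = 1$): the homogeneous
degree-2 kernel is invariant to sign flips of the feature vector and
generalized poorly across held-out subjects in our tests. A KStar-style
learner has no R implementation here and would be supplied as a plug-in.

## Synthetic data: what it does and does not emulate

`gen_block_sparse()` produces exactly block-sparse vectors (uniformly
chosen active blocks, stationary AR(1) interiors with unit marginal
variance, optional white noise calibrated to a target SNR). This matches
the BSBL prior by construction and is used to validate recovery and
hyperparameter learning — it is deliberately the model's home turf.

`gen_gait_signal()` produces harmonic sums per axis (amplitude decay
$1/h$, random phases) warped by per-cycle duration jitter, a gravity
offset on the vertical axis, and white sensor noise of SD 0.03 g (0.008 g
for sitting) — values typical of MEMS accelerometers worn at the hip.
Class presets (walking variants near 1 Hz, stairs near 0.8 Hz with
enhanced vertical amplitude, running at 2.5 Hz, near-DC sitting) are tuned
for *class separability*, not biomechanical fidelity. What this generator
does not emulate: impact transients at heel strike, amplitude modulation
across strides, long-range correlation, non-stationarity, sensor
saturation, or gyroscope channels. Consequently, passing tests show the
pipeline is correct and that the qualitative orderings hold on compressible
quasi-periodic signals; absolute SNR levels on real recordings will differ,
because real acceleration carries broadband structure these caricatures
lack.

Every generator is a pure function of its seed; all test fixtures are
generated in code at run time.

## Problem sizes used by the test suite

The suite exercises the full operating point where it matters and smaller
instances elsewhere: exact recovery at $N = 500$, $M = 250$, 25 blocks of
20, 3 active, over 20 seeded trials; the algorithm comparison at $N = 512$,
$M = 256$, $d = 8$, 20 frames; the compression-ratio trend over
$\{30, 50, 80\}\%$ with 7 frames per point; and the measurement-count
trend over $M \in \{100, 150, \dots, 400\}$ with 9 noisy frames per point.
These sizes were chosen to make the medians stable while keeping the suite
quick to run.

## Known limitations

* The AR(1) collapse of $B_j$ is shared across blocks; signals whose
  blocks have genuinely different correlation structure are mis-modeled.
* Pruned blocks never revive; with pathological initializations this can
  lock out signal (mitigated by the burn-in).
* The MAT container reader supports little-endian level-5 files with
  numeric and character arrays (plain or zlib-compressed) — the layout of
  public hip-sensor activity datasets — and fails with a descriptive error
  on cells, structs, v4, or HDF5-based v7.3 files.
* Basis pursuit via ADMM is first-order: tightening the optimality gap
  much beyond $10^{-7}$ is slow; an interior-point plug-in would be the
  right tool for certified high-accuracy solutions.
* The classification chain evaluates *protocols*, not classifiers: backend
  internals are out of scope and delegated.
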