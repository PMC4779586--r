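# gaitcs — compressed sensing of wearable accelerometer data for gait telemonitoring

Body-worn gait telemonitoring systems acquire tri-axial acceleration at
around 100 Hz and ship it wirelessly to a remote terminal, where the signal
is analyzed and activities are classified. Radio transmission of the raw
stream dominates the device's energy budget, and acceleration is *not*
sparse — neither in time nor, exactly, in any fixed transform — so classic
compressed-sensing recovery degrades. `gaitcs` implements a scheme built
for that setting, for researchers and engineers working on wearable
inertial sensing:

1. **Sparse binary measurement matrices.** The on-device compression is
   `Y = Φ X` with `Φ ∈ {0,1}^{M×N}` holding exactly `d` ones per column
   (`d = 8` at the default operating point). A frame of `N` samples costs
   only `d` additions per sample to compress — no random-number hardware,
   no multiplications — and both ends can regenerate `Φ` bit-exactly from a
   tiny JSON descriptor `{kind, M, N, d, seed}`. Dense Gaussian and
   Bernoulli matrices are provided as references.
2. **Block sparse Bayesian learning (BSBL-BO) reconstruction.** The frame
   (or its DCT coefficient vector) is modeled as a concatenation of blocks
   `x_j ~ N(0, λ_j B_j)` with per-block scales `λ_j ≥ 0` capturing block
   sparsity, AR(1) Toeplitz matrices `B_j` capturing intra-block
   correlation, and measurement noise `N(0, ρI)`. Hyperparameters are
   learned by bound-optimization fixed-point updates and the reconstruction
   is the posterior mean
   `μ = Σ₀Φᵀ(ρI + ΦΣ₀Φᵀ)⁻¹Y`, `Σ₀ = blkdiag(λ_j B_j)`.
3. **Classic baselines** — orthogonal matching pursuit, subspace pursuit,
   smoothed-ℓ0, and basis pursuit (`min ‖α‖₁ s.t. Y = ΦΨα`) — in an
   orthonormal DCT basis, plus a plug-in registry for additional
   reconstructors.
4. **Evaluation chain**: compression ratio `(N−M)/N·100%`, NMSE,
   `SNR = −10·log₁₀(NMSE)`, Pearson correlation; 512-sample windows with
   50% overlap; the 12-dimensional gait feature vector (per-axis SD,
   skewness, kurtosis + the three inter-axis correlations); stratified
   k-fold and leave-one-subject-out protocols; binary and multiclass
   confusion metrics.
5. **Synthetic generators** for exactly block-sparse vectors with AR(1)
   intra-block correlation and for quasi-periodic gait-like tri-axial
   signals (walking, stairs, running, sitting presets), so the entire
   pipeline runs and is tested without any data download.

## Worked example

Compress one 512-sample frame of gait-like vertical acceleration to
M = 256 measurements (50% compression) with a `d = 8` sparse binary matrix
and reconstruct it by BSBL-BO in the DCT basis:

```r
library(gaitcs)
x   <- gait_test_frame(N = 512, class = "walk_forward", seed = 1)
Phi <- make_sparse_binary(M = 256, N = 512, d = 8, seed = 2)
y   <- compress(Phi, x)
fit <- reconstruct_in_basis(y, Phi, dct_basis(512),
                            partition = block_partition(512, 20),
                            noiseless = TRUE)
fit
#> <bsbl_fit> N=512, 3/26 blocks active, rho=1e-10, 28 iterations (converged)
reconstruction_report(x, fit$x, M = 256, algorithm = "bsbl-bo")
#> <reconstruction_report> bsbl-bo N=512 M=256 CR=50.0%  NMSE=0.00086  SNR=30.66 dB  r=0.9978
```

The fit keeps 3 of 26 coefficient blocks — the harmonic structure of gait
concentrates in a few low-frequency DCT blocks — and reconstructs the frame
at 30.7 dB SNR with correlation 0.998 to the original.

Classification metrics from the bundled seven-pattern confusion table
(walk forward/left/right, upstairs, downstairs, run, sit; 140 test windows
per class):

```r
m <- multiclass_metrics(example_confusion_table())
round_half_up(m$overall_accuracy)    #> 92
round_half_up(m$precision[["sit"]])  #> 99
round_half_up(m$recall[["sit"]])     #> 99
```

A command-line interface wraps the same functions
(`inst/cli/gaitcs simulate | compress | reconstruct | evaluate | sweep-d |
sweep-cr | features | classify-eval`); every command writes CSV results and
a JSON manifest so runs with a fixed `--seed` are byte-identical.

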