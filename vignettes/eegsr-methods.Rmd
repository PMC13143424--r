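---
title: "EEG super-resolution with a bidirectional selective state-space diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG super-resolution with a bidirectional selective state-space diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Scalp EEG trades spatial for temporal resolution: a standard montage has
8–64 electrodes, so the spatial sampling of the cortical field is coarse,
while the temporal sampling is excellent. *Spatio-temporal super-resolution*
asks for the inverse of a deliberate degradation: given a low-density
montage (spatial task) or a decimated sampling rate (temporal task),
reconstruct the dense, fast recording. The problem is ill-posed — many
high-resolution (HR) fields are consistent with one low-resolution (LR)
observation — which motivates a *conditional generative* treatment: model
`p(X_HR | X_LR, electrode positions, class label)` rather than a single
point estimate.

`eegsr` implements that treatment end to end in R: the data model and
synthetic generator, the degradation and classical-interpolation operators,
a bidirectional selective state-space (Mamba) sequence backbone, a
denoising-diffusion reconstruction model with deterministic one-step
sampling, a deterministic regression variant of the same trunk, and the
fidelity metric suite used to compare them. The neural networks, including
all reverse-mode gradients, are written in plain R; every result in the
package is reproducible from a seed on one CPU.

## The selective state-space backbone

The temporal workhorse is the selective SSM recurrence

$$h_t = e^{\Delta_t A} \odot h_{t-1} + (\Delta_t B_t)\, u_t, \qquad
  y_t = C_t \cdot h_t + D \odot u_t,$$

a linear recurrence whose step size $\Delta_t$ and mixing vectors
$B_t, C_t$ are functions of the input at each step (that input dependence
is what distinguishes Mamba from classical linear state-space layers). One
left-to-right pass costs $O(L)$; `selectiveScan()` implements it and the
test suite pins it against a brute-force per-step loop. Discretization is
the canonical choice: zero-order hold on the decay ($e^{\Delta A}$) and an
Euler step on the input path ($\Delta \cdot B$); $\Delta$ is the softplus
of a learned projection with the bias initialized so that
$\Delta \in [10^{-3}, 0.1]$ at the start, the standard stable range.

A *Mamba block* wraps the scan with an input projection (expansion factor
2), a depthwise causal convolution of width 3, SiLU gating, and an output
projection. Version 1 learns a full `dInner x dState` decay matrix
(initialized row-wise at $-1, -2, \dots$); version 2 is the multi-head
variant with one scalar decay per head and a layer normalization between
the scan and the gate. The hardware-oriented duality kernels of the
original Mamba-2 are deliberately not reproduced — the sequential scan is
the reference semantics, and correctness beats speed at this scale.

EEG is non-causal: the field at time $t$ is as constrained by the future
as by the past. The *bidirectional layer* therefore runs `M` stacked Mamba
blocks (each with an internal residual) plus a depthwise k=3 convolution
forward in time, the same structure (separate parameters) on the
time-reversed sequence, and fuses the two streams by element-wise
addition, preserving width. Layers stack with a convolutional residual
path, `x <- layer(x) + conv_k3(x)`. With the test-only `tieDirections`
flag the layer provably commutes with time reversal, which the suite uses
as an equivariance oracle; with separate weights the suite instead checks
that mid-sequence outputs respond to perturbations on both sides.

## The reconstruction models

Both models share one trunk: a depth-2 strided-convolution encoder (width
doubling per stage, SiLU), a bottleneck, and a mirrored decoder built from
zero-stuffing (fractionally strided) convolutions, with a k=3 output head.
The bottleneck is either the bidirectional Mamba stack above or, as an
ablation variant, a plain Conv1d/BatchNorm/LeakyReLU/Dropout stack
(dropout 0.1). Swapping bottlenecks changes no encoder/decoder parameters,
which keeps ablations clean.

Conditioning enters three ways, all optional flags:

* **LR signal** — the degraded input, brought to HR shape first
  (zero-padding missing channels in the spatial task, per-channel linear
  interpolation in the temporal task). The regression model takes it as
  its input; the diffusion denoiser gets it channel-concatenated with the
  noisy signal. In both cases a *global residual connection* adds the
  upsampled LR back to the trunk output, so the network learns a
  correction field rather than the identity — standard super-resolution
  practice, and the reason an untrained model already scores at the
  zero-padding level.
* **Electrode positions** — a learned per-rank table plus a learned linear
  map of the unit-sphere coordinates, collapsed to one scalar bias per HR
  channel and added at the input. This keeps channel identity information
  available without tying the trunk to a fixed montage.
* **Class label** — a learned table (with a reserved null id for
  unconditional use) added to the first encoder stage, broadcast over
  time.

The diffusion denoiser additionally receives a sinusoidal timestep
embedding, passed through a small learned map and added at every encoder
stage.

## Diffusion, the schedule, and one-step sampling

The forward process is the standard variance-preserving DDPM marginal
$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon$ over
$T = 1000$ steps. Training draws a uniform timestep per batch element and
regresses the denoiser output on the clean signal (prediction type
`"sample"`, the default; `"epsilon"` is available since the loss can
equivalently be written in the noise) with MSE. An optional high-t-biased
timestep mode exposes the model more often to the maximum-noise regime;
it is off by default.

Two schedule shapes are provided. The default interpolates
$\beta_t$ *linearly in t* from $10^{-4}$ to $0.015$; it hits both
endpoints exactly and leaves $\bar\alpha_{T-1} \approx 5\times10^{-4}$,
i.e. the terminal state is essentially pure noise, which is what one-step
sampling from $t = T-1$ requires. The alternative `shape = "cosine"`
computes the squared-cosine $\bar\alpha$ curve (offset 0.008, per-step
$\beta$ capped at 0.999) and affinely rescales its $\beta$ range to the
same endpoints; because that curve concentrates its largest steps in the
final few timesteps, the rescaled variant retains $\bar\alpha_{T-1}
\approx 0.74$ — most of the signal survives to the end, and a sampler
started there is not starting from noise. We keep it for comparison but
do not recommend it; the linear default is the shape under which every
schedule invariant in the test suite holds.

Inference is deterministic one-step sampling: initialize at
$\sigma \epsilon$ (optionally plus the upsampled LR signal, aligning the
inference distribution with the residual-guided training), present
$t = T-1$, and return the clean-sample prediction from exactly one
denoiser call — the call counter is instrumented and the contract
enforced. Reference DDPM (ancestral) and DDIM ($\eta = 0$) samplers over
strided timestep subsequences are included for comparison; with an oracle
denoiser all of them return the clean signal exactly, which the tests use
as a recursion oracle.

## Preprocessing

Recording-level cleaning follows fixed, testable rules: a channel is a
*flatline* when its variance is below $10^{-10}$ and a *saturation* when
all consecutive differences stay below $10^{-8}$; windows with more than
30% bad channels are rejected outright, and remaining bad channels are
re-interpolated by spherical splines. Note the two thresholds interact:
within a 2-s window a sub-$10^{-8}$-step signal cannot accumulate
$10^{-10}$ of variance, so the saturation rule effectively fires on long
recordings, which is where saturation artifacts live.

Spherical-spline interpolation uses the classical Legendre-series kernel
on the unit sphere (order m = 4, 50 series terms, ridge $\lambda =
10^{-5}$), solved through the standard bordered system so constants are
reproduced exactly; the solve is linear in the data, so one transfer
matrix handles a whole window. Filtering is a zero-phase windowed-sinc
FIR chain (Hamming, order $3 \cdot \mathrm{rate}/f_{lo}$ rounded even):
mains notch first, then the band-pass; probe-tone tests assert at least
26 dB of notch attenuation and <1 dB passband ripple. Normalization is
per-channel z-scoring with a $10^{-8}$ stabilizer and population sigma
(an optional common-average reference runs first). Windows are 2 s,
non-overlapping, shuffled with a seed and split 80/10/10.

Degradation is exact and idempotent under
degrade–upsample–degrade: spatial masking keeps a coverage-maximizing
electrode subset, temporal decimation keeps every factor-th sample
starting at sample 0 (anti-aliasing is delegated to the preceding
band-pass). The retained subset is chosen by greedy farthest-point
sampling on the sphere, seeded at the vertex electrode with ties broken
by canonical rank — a deterministic, montage-agnostic stand-in for a
practical low-density cap layout; the tests verify its minimum pairwise
distance beats 100 random subsets of the same size.

## The synthetic generator — and what it does not emulate

All tests and the acceptance script run on generated data: band-limited
oscillatory sources (delta–gamma, realized as FFT-masked Gaussian noise)
placed on the upper hemisphere, mixed onto electrodes through a Gaussian
distance-decay gain ($e^{-d^2/\sigma_{lf}^2}$ in great-circle distance,
$\sigma_{lf} = 0.8$ rad), plus $1/f$ background noise at a configured
SNR, then per-channel z-scored. Class labels switch which source subset
is active, so label conditioning has real signal to exploit. One root
seed fixes source geometry; window w uses the derived stream seed
`seed + 1000 + w`.

Default conditions, chosen once as a realistic desk-scale regime and not
revisited: 16 channels at 32 Hz, 2-s windows (64 samples), six sources
across delta/theta/alpha (all below the 16 Hz Nyquist), 10 dB SNR, 200
training windows, 2 classes. What the generator does *not* emulate:
volume-conduction physics beyond smooth distance decay (no BEM/FEM
leadfields), eye-blink/EMG artifacts, non-stationarity across windows,
inter-subject variability, and real electrode noise. Passing tests
therefore demonstrate the machinery — degradation, learning, sampling,
metrics — under a controlled model of EEG structure, not performance on
clinical recordings.

One consequence of per-channel z-scoring is worth knowing: it equalizes
total power across channels, so a channel far from all sources is
noise-dominated *at full variance*. Classical spline interpolation then
has little to work with on such channels, and with a single compact
source the spline baseline can even lose to zero-padding. The baseline
comparisons in the tests use either the multi-source default (where most
channel variance is coherent) or a smooth single-source fixture
($\sigma_{lf} = 1.5$, 25 dB SNR) that represents the regime splines are
designed for.

## Metrics

The suite reports NMSE (energy-normalized error), mean per-channel
Pearson correlation, a 1-D adaptation of SSIM (Gaussian window 11,
$\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, dynamic range taken from the
reference), PSNR with MAX = 1 (exact matches reported as `Inf`), SNR
(tied to NMSE by $\mathrm{SNR} = -10\log_{10}\mathrm{NMSE}$, asserted as
a cross-metric identity), topographic smoothness (mean squared
k-nearest-neighbour Laplacian residual, k = 4 with tie-inclusive
neighbourhoods so the metric is permutation-invariant), per-band
log-band-power MAE (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–50 Hz, clipped to the passband), mean absolute imaginary coherence
(insensitive to zero-lag volume conduction), and a Frechet distance
between Gaussian fits of window features. Spectral estimates use fixed
Welch conventions (Hann, segment length `min(L, 256)`, 50% overlap),
stated in the report metadata. The feature extractor behind the Frechet
metric is a fixed-seed random convolutional encoder — a deterministic
stand-in, clearly documented as such, with the extractor pluggable for
anyone who has a trained one.

## Training protocol and problem sizes

Optimization is AdamW (lr $10^{-3}$ cosine-decayed to $10^{-5}$ by
default, weight decay $10^{-4}$, global gradient-norm clip 1.0), batch
32, early stopping on validation NMSE with patience 10; reference epoch
counts are 30 (regression) and 50 (diffusion). The package's desk-scale
experiments — used in the test suite and the acceptance script — use the
8-to-16-channel spatial task with 64-sample windows, 200 training
windows, and a deliberately small trunk (base width 24, backbone
`dModel` 32, `dState` 4, one bidirectional layer of one block per
direction), trained for 10 epochs with batch 8 at lr $3\times10^{-3}$.
Each training run takes roughly 20 s on one CPU thread, so the whole
experiment grid stays in the low minutes.

Under those conditions the trained regressor reaches test NMSE ≈ 0.17
against ≈ 0.25–0.32 for the spherical-spline baseline and exactly 0.50
for zero-padding (half the channels are missing), and the LR-conditioned
diffusion model clearly beats its unconditioned twin (≈ 0.23 vs ≈ 0.73
NMSE) — the orderings the method's design claims predict. Two caveats
belong here rather than in fine print. First, training-loss *ratios* are
floor-limited: with the global LR residual the untrained model starts at
MSE 0.5, and the unpredictable per-channel noise puts the ideal
(Bayes-optimal) training loss near 0.045, so even perfect inference
caps the achievable drop near one order of magnitude; the observed ratio
is 3–4x. Second, desk-scale numbers are not comparable to benchmark
results on real recordings in any direction — the point of the synthetic
conditions is falsifiable orderings, not absolute scores.

## Numerical and design notes

* Decimation phase is fixed at sample 0; linear interpolation holds the
  last LR sample so the HR length is exactly `factor x L_LR`.
* Population (not sample) sigma in z-scoring, with the $10^{-8}$ guard;
  a constant channel maps to zeros.
* The spline solve raises an informative error if the bordered system is
  singular (advice: increase lambda); at $\lambda = 0$ it interpolates
  data sites to machine precision.
* Batch normalization keeps running statistics in a per-model state
  environment; evaluation mode uses them, training mode uses batch
  statistics.
* The output head is initialized near zero so both models start at their
  residual baseline rather than at noise.
* All randomness flows through R's RNG, seeded at entry points
  (generator, training loop, samplers); two runs with the same seed are
  bit-identical on a single thread, which the suite asserts.
* Backward passes are hand-derived; the suite contains finite-difference
  gradient checks for every parameter tensor of a small model of each
  bottleneck type. Instrumentation counters verify the O(L) scan budget
  and the one-call sampling contract.

## Limitations

No real-data readers beyond delimited text are bundled (EDF/FIF import
belongs to dedicated readers; datasets serialize to RDS/CSV), training is
single-threaded CPU R and sized accordingly, the 2048-dimensional
pretrained feature extractor behind a published EEG Frechet score is out
of scope (the distance and the extractor interface are in), and
benchmark-scale model sizes (≈2 M parameters) are configurable but not
the tested default.
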