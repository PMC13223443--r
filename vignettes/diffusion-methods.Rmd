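---
title: "Methods: denoising diffusion for small grayscale medical images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: denoising diffusion for small grayscale medical images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`minidiffusion` implements a denoising diffusion probabilistic model (DDPM)
for stacks of small grayscale medical images, at the scale of the 28×28
chest X-ray collections distributed in MedMNIST layout. The generative
model has two halves.

The **forward process** is a fixed Markov chain that corrupts a clean image
$x_0 \in [-1, 1]^{28 \times 28}$ with Gaussian noise over $T$ steps
according to a variance schedule $\beta_t$. Its marginal at step $t$ has
the closed form used throughout the package:

$$x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1 - \bar\alpha_t}\, \varepsilon,
\qquad \varepsilon \sim \mathcal N(0, I),$$

with $\alpha_t = 1 - \beta_t$ and $\bar\alpha_t = \prod_{s \le t}
\alpha_s$. The schedule is linear: `make_linear_schedule(300, 1e-4, 0.02)`
spaces $\beta_t$ evenly from $10^{-4}$ to $0.02$ inclusive; $\bar\alpha_T
\approx 0.048$, so the terminal state is almost pure noise.

The **reverse process** is learned. A network $\varepsilon_\theta(x_t, t)$
is trained to predict the injected noise by minimizing

$$\mathcal L(\theta) = \mathbb E_{x_0,\, t \sim \mathcal U\{1..T\},\,
\varepsilon} \; \rho\!\left(\varepsilon_\theta(x_t, t) -
\varepsilon\right),$$

where $\rho$ is the L1, L2 or Huber penalty, averaged over every element
(`noise_prediction_loss()`). Generation runs the ancestral sampler from
pure noise, for $t = T, \dots, 1$:

$$x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
\frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\,\varepsilon_\theta(x_t, t)\right)
+ \sigma_t z, \qquad z \sim \mathcal N(0, I),$$

with the noise term suppressed at $t = 1$ (`p_sample_step()`,
`sample_images()`).

Assumptions worth stating: images are treated as continuous once mapped
from `[0, 255]` to `[-1, 1]`; training is unconditional (labels in the
archives are read but never consumed); and the sampler is the plain
ancestral one — no accelerated (DDIM-style) sampling, guidance, or learned
variances.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `timesteps` (T) | 300 | diffusion steps; also the reverse-chain length |
| `beta_start`, `beta_end` | 1e-4, 0.02 | linear schedule endpoints (per-step noise variance) |
| `sigma_variant` | `"beta"` | reverse noise scale $\sigma_t^2 = \beta_t$; `"posterior"` uses $\beta_t(1-\bar\alpha_{t-1})/(1-\bar\alpha_t)$ |
| `epochs`, `steps_per_epoch` | 40, 300 | optimizer updates per run = epochs × steps |
| `batch_size` | 32 | images per update, incomplete batches dropped |
| `learning_rate` | 1e-3 | Adam step size |
| `loss_kind`, `huber_delta` | `"huber"`, 1.0 | training penalty and its branch point |
| FID dims | 64, 2048 | feature widths of the evaluation embedding |
| `n_generate` | 20,480 | generated-sample count for full-scale FID runs |

Choices made where the protocol left room, adopted once and documented
here rather than revisited:

* **T = 300.** The protocol's staged-denoising figures count up to 299
  completed updates and its training epochs contain 300 steps; a 300-step
  chain is the only consistent reading.
* **Batch size 32 with drop-last.** A 78,468-image corpus split into 2,453
  batches gives 78,468 / 2,453 ≈ 31.99; batch 32 with the last incomplete
  batch dropped is the unique consistent reading of that pair of numbers.
* **"300 steps per epoch"** is read as 300 optimizer updates per epoch
  (not a full pass over all batches); both readings are available through
  `steps_per_epoch`.
* **Huber δ = 1** (the smooth-L1 convention); no δ is stated anywhere in
  the protocol.
* **Loss scalings.** L2 is the plain mean square without a ½ factor; the
  Huber quadratic branch carries the ½, so Huber → ½·L2 as δ → ∞ and
  `0 ≤ huber(δ=1) ≤ l2/2` pointwise. Loss curves across kinds are only
  comparable with these scalings in mind.
* **σ-variant `"beta"`** is the default; both options satisfy
  $\sigma_t^2 \le \beta_t$.
* **Adam** at 1e-3: no optimizer is named in the protocol; this is the
  community default for this model family.
* **Fixed epoch budget.** "Train until converged" has no stopping rule
  specified; the fixed `epochs` budget is what is implemented.

## The denoiser

`denoiser_spec()` describes a compact U-Net: a stem convolution; for each
resolution level (28 → 14 → 7 with multipliers 1, 2, 4) two
time-conditioned residual blocks — group norm, SiLU, 3×3 convolution, a
per-channel additive time projection, group norm, SiLU, convolution, plus
a 1×1 shortcut when widths change — followed by optional multi-head
self-attention and a strided-convolution downsample; a middle section of
two residual blocks around an attention module; a mirrored decoder with
transposed-convolution upsampling and encoder skips concatenated on the
channel axis; and a normalized output convolution back to one channel.
The timestep enters as a sinusoidal embedding (`sinusoidal_time_embedding()`)
passed through a two-layer MLP.

Since no R deep-learning framework is involved, the forward *and* backward
passes are written directly in this package: each layer is a pure
function pair, the 3×3 convolutions run as per-image patch gathers feeding
BLAS `dgemm` (compiled code under `src/`), and gradient correctness is
pinned by finite-difference tests over every layer type. Adam maintains
first/second-moment trees parallel to the parameter tree.

Architecture decisions: attention is available at every level (the
protocol places an attention module in each stage) with
`attention_levels` configurable, since full-resolution attention at 28×28
costs 784² scores per image; group-norm uses the largest group count ≤ 8
that divides the channel width (8 for widths 8/16/32/56/112, 7 for 28 —
the default width 28 is not divisible by 8, so a fixed count of 8 cannot
be universal); downsampling is a stride-2 convolution and upsampling a
2×2 transposed convolution; the output convolution is initialized near
zero so an untrained model predicts small noise. The `tiny_denoiser_spec()`
preset (base 8, attention only at the 7×7 level, 2 heads, ~180k
parameters) is the desk-scale configuration used in tests and examples.

## FID evaluation

Generation quality is the Fréchet distance between Gaussian fits of
feature embeddings of real and generated sets:

$$d^2 = \lVert \mu_a - \mu_b \rVert^2 +
\operatorname{Tr}\!\left(\Sigma_a + \Sigma_b -
2 (\Sigma_a \Sigma_b)^{1/2}\right).$$

Covariances use the $n-1$ denominator (this matters at small $n$; it
matches the dominant FID implementation convention). The square-root
trace is evaluated through the algebraically identical symmetric form
$\operatorname{Tr}\big((\Sigma_a^{1/2} \Sigma_b
\Sigma_a^{1/2})^{1/2}\big)$ using symmetric eigendecompositions: tiny
negative eigenvalues from rounding are clipped to zero (and logged), a
failed decomposition is retried once with $10^{-6} I$ jitter on both
covariances, and a slightly negative final value is clipped to zero and
logged. A direct principal square root of the non-symmetric product
serves as an independent oracle in the test suite.

The default extractor is download-free and deterministic: pixels are
scaled to the canonical $[0,1]$ range (so FID magnitudes do not depend on
the storage domain), flattened, and mapped through a fixed-seed random
orthogonal projection —
orthonormal rows for `dim` ≤ 784, orthonormal columns (an isometric
embedding) for `dim` = 2048. The dimensions 64/2048 mirror the pooling
widths of the Inception-v3 evaluators customarily used for this metric;
with no network weights available offline, absolute FID values from this
extractor are *not* comparable to Inception-based numbers, but
identities (FID(x, x) ≈ 0), orderings and scale relations are preserved
and are what the tests assert.

## The phantom generator

`generate_phantoms()` renders seeded 28×28 chest phantoms: a bright
elliptical thorax on a dark background, two darker elliptical lung
fields, faint sinusoidal rib bands, and mild Gaussian pixel noise. Each
image draws five factors from configurable ranges that emulate the
variability axes seen across chest radiographs — body scale (body
shape/BMI proxy, default 0.9–1.1), rotation (posture, ±8°), combined
lung-area fraction of the thorax (lung volume, 0.25–0.40), brightness
(gray value, 0.85–1.15) and integer center jitter (field of view, ±1 px).
Defaults were chosen once as visually plausible mild variability for a
low-entropy training distribution; the generator is the package's stand-in
for real radiographs wherever a download-free dataset is needed.

What the phantoms are *not*: radiologically plausible images. They have
no pathology, no soft-tissue texture, no acquisition artifacts, and far
lower entropy than real chest X-rays. A pipeline that learns phantoms
demonstrates that the mathematics, gradients, sampler and evaluator work
end to end; it does not demonstrate clinical image quality, and results
on phantoms say nothing about FID values attainable on real data.

## Numerical choices

* Timesteps are 1-based in every public interface; internal storage is
  0-based arrays with the +1 mapping applied at the boundary.
* A 1-step schedule keeps only `beta_start` (inclusive-endpoint
  convention with a single sample).
* Schedule constants are precomputed once at construction and never
  recomputed per step.
* The reverse trajectory is never clamped mid-chain; only emitted images
  (snapshots and the final batch) are clamped to $[-1,1]$ and quantized
  to uint8, with rounding half away from zero so the uint8 → normalized →
  uint8 round trip is exact.
* Snapshots count *completed reverse updates* (so `snapshot_after = 299`
  with T = 300 is the state one update before the final image), matching
  0-based step-count captions on staged-denoising figures.
* One master seed drives everything through
  `derive_seed(master, purpose)` sub-streams, so e.g. changing the number
  of generated images cannot perturb training reproducibility.
* Group-norm uses $\epsilon = 10^{-5}$; attention scales scores by
  $1/\sqrt{d_{head}}$ with a row-max shift before softmax.

## Desk-scale problem sizes

The test suite and the acceptance script run a scaled-down study chosen
to exercise every component on a single CPU: 512 training phantoms and
256 held-out phantoms, the `tiny_denoiser_spec()` network, a T = 100
schedule, 5 epochs × 50 steps at batch 32 for each loss, 64 generated
images, and FID at dimension 64 (plus one dimension-2048 evaluation).
Under these conditions the tests assert qualitative properties — the
final epoch improves on the first for each loss, generated images score
closer to held-out phantoms than pure noise does, seeded runs replay
bitwise — rather than any absolute loss or FID level.

## Limitations

* Full-protocol runs (78k images, 40 × 300 steps, 20,480 samples) are
  supported by the same code paths but are long on a single CPU; the
  package targets method-level correctness and desk-scale studies.
* The projection extractor makes FID values internally consistent but not
  comparable to Inception-based literature numbers.
* Only linear schedules are provided (no cosine or learned schedules), and
  only the ancestral sampler (no DDIM), matching the implemented
  protocol's scope.
* NPZ support covers the MedMNIST layout (uncompressed or stored members,
  common numeric dtypes), not arbitrary NumPy archives.
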