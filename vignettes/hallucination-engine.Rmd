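---
title: "Simulated hallucinations: the dream engine, temporal coherence, and the experiment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated hallucinations: the dream engine, temporal coherence, and the experiment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepdreamr)
```

## The model

Deep Dream turns a trained convolutional network into an image generator
by inverting the direction of optimization: the network's weights are
frozen and the *input image* is updated by gradient ascent so that the
activation of one chosen ("clamped") layer grows. Because shallow layers
of such networks detect local geometry and deep layers detect object-like
structure, clamping a shallow layer paints geometric textures over the
image while clamping a deep layer imposes complex, object-like content —
a parameterizable analogue of simple versus complex visual
hallucinations.

The ascent objective implemented here is half the sum of squared
activations of the clamped layer,

$$ L(x) = \tfrac{1}{2} \sum_k a_k(x)^2, $$

whose gradient with respect to the activations is the activation tensor
itself; backpropagating it through the frozen network yields the pixel
gradient. This is the standard "amplify what is already detected" form:
the content that emerges is whatever the layer already responds to most
strongly in the current image, which also realizes automatic category
selection — no explicit target class is chosen. A guided variant
restricting $L$ to a single channel is available via the `channel`
argument of `dream_config()`.

Each ascent step draws a cyclic jitter shift uniform on
$[-j, j]^2$, shifts the image, adds

$$ x \leftarrow x + \eta \, \frac{g}{\operatorname{mean}\lvert g \rvert}, $$

undoes the shift, and clamps to the working intensity range. The
mean-absolute normalization makes the step size $\eta$ comparable across
layers of very different activation scale. Jitter suppresses grid
artifacts tied to pixel alignment; with the bundled *periodic* toy
network it is exactly neutralized by shift-equivariance (a property the
test suite exploits as an oracle), but it matters for any network with
boundary effects, including the zero-padding toy variant and external
networks.

The octave loop runs the ascent coarse-to-fine over a resolution pyramid.
Sizes follow `round(base / scale^k)` with round-half-away-from-zero (the
rounding rule is pinned so size sequences are exactly reproducible), and
a *detail buffer* — the difference between the dreamed and the plain
image at the previous octave — is upsampled and added before each new
octave, so structure invented at coarse scales survives refinement.

Defaults follow the parameter set used for the published high-level
hallucination footage: `octaves = 3`, `octave_scale = 1.8`,
`iterations = 32`, `jitter = 32`, `zoom = 1`, `step_size = 1.5`, with
`dream_preset_layer()` mapping `"higher"`, `"middle"` and `"lower"` onto
the deepest, middle and shallowest rectifier of the model in use.

## The toy network

Full-scale use clamps a large pretrained classification network through
the `model_activations()` / `input_gradient()` generics. For testing and
desk-scale experimentation the package bundles a deterministic toy
network: three convolution + rectifier blocks (3 → 8 → 16 → 16 channels,
3×3 kernels, stride 1), weights uniform on
$[-0.5, 0.5]\cdot \mathrm{fan}_{in}^{-1/2}$, zero biases, and a seed that
fixes every weight bit-exactly. Circular (periodic) padding is the
default because it pairs with equirectangular wrap and gives exact
shift-equivariance, which in turn gives strong test oracles; zero padding
is available. 2×2 max-pool layers are supported for custom
architectures; gradients route to the first position attaining each
window maximum (ties are measure-zero under random weights).

A random network has no semantics — its dreams are textures, not dogs —
so tests built on it demonstrate the *mechanics* (ascent, octaves,
equivariance, determinism), never perceptual content. That is the main
respect in which passing tests understate behaviour on real footage with
a trained network.

## Temporal coherence for video

Dreaming frames independently makes hallucinatory content flicker.
The video stage therefore lets each frame inherit the previous frame's
hallucinations, transported along the scene's motion:

1. estimate dense optical flow from raw frame $t-1$ to raw frame $t$;
2. warp the previous *dreamed* frame backwards along that flow;
3. blend it convexly into the current raw frame,
   $x_t^{in} = \rho \cdot \mathrm{warp}(d_{t-1}) + (1-\rho)\, x_t$;
4. dream the blended frame.

The blend weight $\rho$ is two-valued: 0.9 where the flow magnitude
exceeds a threshold (moving foreground) and 0.1 in static areas — the
high ratio keeps hallucinations attached to moving objects, while the low
background ratio prevents static regions from saturating under repeated
inheritance. The threshold (1.0 px) separates the regimes; it has no
published value and is exposed as a parameter. Carrying the full
previous dreamed frame (rather than a dreamed-minus-raw residual) is the
default because it matches the video implementations this design
extends; `coherence_config(mode = "residual")` switches to residual
carrying.

Flow estimation is coarse-to-fine Lucas–Kanade: a Gaussian image pyramid,
and at each level an iterated warp-and-solve of the locally
Gaussian-windowed structure-tensor system. It is deterministic,
dependency-free, and recovers the synthetic fixtures' integer
translations to well under half a pixel, which is all the blending stage
needs; it does not attempt occlusion reasoning or learned flow.
Warping uses backward mapping with bilinear sampling, edge-clamped, or
horizontally wrapped in equirectangular mode.

## Panoramic (equirectangular) handling

Equirectangular frames are physically continuous across the left/right
edge. Before dreaming, `equirect_pad()` copies `wrap_pad` columns
cyclically onto each side so the ascent sees the seam as interior;
`equirect_unpad()` crops back, and flow warping wraps horizontally.
Vertical edges are poles and are never wrapped. The test suite measures
that padding reduces the dreamed seam discontinuity. Frame rate (16 fps)
and source resolution (4096 × 2048) are carried as manifest metadata;
processing itself is resolution-agnostic, and frames are dreamed whole
(tiling very large frames is future work).

Each frame dreams under `frame_seed(seed, t)`, a deterministic 31-bit
mix, so randomness is indexed by frame, not by execution order; the run
manifest (config, per-frame seeds, objectives, timings) is sufficient to
re-run a job bit-identically, which the tests assert.

## Synthetic data: what it emulates, and what it does not

* `generate_synthetic_video()` — a static smoothed-noise background with
  a textured patch translating by integer $(dx, dy)$ per frame, so
  ground-truth flow is known exactly. It emulates moving footage for
  flow/blend/pipeline testing; it has no parallax, occlusion boundaries
  beyond the patch edge, lighting change, or camera motion.
* `generate_synthetic_ratings()` — two-condition ratings on a
  $[0, 100]$ visual-analogue scale for the 17 questionnaire dimensions,
  with subject intercepts (SD 8), within-subject noise (SD 10) around a
  baseline of 45, and a condition shift of $\delta \sqrt{2} \sigma$ so
  that $\delta$ *is* the standardized paired effect. The published
  instrument's response bounds are not stated anywhere; $[0, 100]$ is a
  conventional VAS assumption, and clipping to it very slightly
  attenuates extreme effects.
* `generate_synthetic_timing()` — tone-cued interval production at
  1/2/4 s targets under scalar timing: produced
  $\sim \mathcal{N}(t(1+b),\ (w t)^2)$ with Weber fraction $w = 0.15$
  and bias $b = 0.1$ as moderate, empirically typical defaults; 12
  blocks alternating video type with a handful of productions per target
  per block mirrors the published session structure. Tone frequencies
  and durations are carried as metadata only.

Effect-recovery tests compare the mean recovered Cohen's d against
$\delta$ times the analytic small-sample expectation factor of the
$t$-based estimator ($\sqrt{\nu/2}\,\Gamma((\nu-1)/2)/\Gamma(\nu/2)$,
about 1.075 at $n = 12$) — at these sample sizes the estimator's bias
exceeds Monte-Carlo error, so naive comparison against $\delta$ would
reject a correct generator.

## The experiment statistics

The published analyses are reproducible from printed summaries, and the
package implements them directly:

* **JZS default Bayes factor.** `jzs_bf10(t, df, n_eff)` computes
  $\mathrm{BF}_{10}$ for a $t$ statistic under a Cauchy(0, 0.707) prior
  on the standardized effect, via the normal-scale-mixture form: the
  marginal likelihood under the alternative is an integral over an
  inverse-gamma(1/2, 1/2) mixing variable, evaluated in log space by
  adaptive quadrature (relative tolerance $10^{-8}$) after mapping
  $(0,\infty)$ to the unit interval with $g = u/(1-u)$. A Monte-Carlo
  integration over Cauchy draws serves as the independent oracle in the
  tests. Paired designs use $n_\mathrm{eff} = n$; independent designs
  $n_\mathrm{eff} = n_1 n_2/(n_1+n_2)$ with pooled-variance
  $df = n_1 + n_2 - 2$ (the published independent comparisons print
  $t(25)$ for groups of 12 and 15, confirming pooled rather than Welch).
* **Effect sizes.** $d = t/\sqrt{n}$ (paired),
  $d = t\sqrt{1/n_1 + 1/n_2}$ (independent).
* **Bonferroni.** Multiplication by $m$ (default: the 17 dimensions),
  capped at 1 by default; an uncapped mode exists because published
  tables sometimes print raw products. Published corrected $p$ values
  are not consistent with any single integer multiplier and are not
  treated as recomputation targets.
* **Interpretation.** $\mathrm{BF}_{10} > 3$ supports a difference,
  $< 1/3$ supports no difference, otherwise the data are insensitive.
* **Repeated-measures ANOVA.** `rm_anova_2way()` computes the classical
  fully-within-subject decomposition on cell means, testing each effect
  against its own subject-by-effect stratum. Effect sizes are partial
  $\eta^2$ (the convention of the software the published values came
  from), with classical $\eta^2$ alongside. Degenerate zero-noise data
  use the convention $F = 0$ when the effect's SS is zero and
  $F = \infty,\ p = 0$ when a positive effect sits over a zero error
  stratum. `stats::aov` with `Error()` strata is the cross-check in the
  tests, and a brute-force mean-decomposition oracle verifies every sum
  of squares to $10^{-10}$ relative.
* **Screening.** `practice_criterion()` (Pearson $r \ge 0.5$ between
  target and produced intervals) and `inversion_exclusion()` (exclude
  unless per-target means increase strictly; a tie counts as inverted,
  the conservative reading).

`bf_from_summary()` applies the Bayes-factor and effect-size machinery
to a table of printed $(t, n)$ pairs — the route by which the published
questionnaire tables are reproduced without raw data, since the raw
ratings were never deposited. Three printed effect sizes (paired
"vivid", independent "intensity" and "float") are internally
inconsistent with their own printed $t$ at the third decimal; the
package reports the $t$-derived values.

## Numerical choices and problem sizes

Images are `H × W × 3` double arrays on $[0, 255]$, clamped after every
ascent step; resampling is bilinear with half-pixel-centre sampling
everywhere (resize, zoom, warp), which makes same-size resizing an exact
identity. Octave rounding is half-away-from-zero. The Lucas–Kanade
solver regularizes the structure-tensor determinant with $10^{-4}$ and
limits per-iteration updates to ±2 px per level.

The test and acceptance workloads run on desk-scale problems chosen to
exercise every code path with comfortable margins: 16×16 inputs for
finite-difference gradient checks, 32–64 px frames for dream properties,
8-frame 64×64 synthetic videos for the end-to-end pipeline, and 120–200
replicate simulations for the statistical generators.

## Known limitations

* The toy network is untrained; perceptual claims about hallucination
  *content* require an external pretrained network behind the
  `model_activations()` contract.
* The flow estimator assumes mostly-translational local motion and has
  no occlusion model; fast rotation or large displacements beyond the
  pyramid's reach will blur inherited content.
* Whether the original pipeline blended warped content or blended before
  warping is under-specified in its description; warp-then-blend is the
  default here, and both the residual mode and the blend parameters are
  switchable.
* Bayesian model-averaged repeated-measures ANOVA (the source of
  published model-comparison BFs for the timing experiment) requires raw
  data and a model-prior framework and is out of scope; the classical
  ANOVA and the $t$-based Bayes factors are in scope and reproduced.
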