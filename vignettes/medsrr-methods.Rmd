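---
title: "medsrr: methods and numerical policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medsrr: methods and numerical policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsrr)
```

## Model

`medsrr` performs single-image ×4 super-resolution of grayscale images with
a hybrid network whose first layer is not learned at all: it is the exact
bicubic interpolation operator, expressed as 16 integer convolution
stencils. The remaining layers learn only the residual mapping from the
bicubic estimate to the high-resolution target.

### The frozen template layer

Separable cubic convolution interpolation with the `a = -1` kernel

$$S(\omega)=\begin{cases}1-2\omega^2+\omega^3 & 0\le\omega<1\\
4-8\omega+5\omega^2-\omega^3 & 1\le\omega<2\\ 0 & \omega\ge 2\end{cases}$$

evaluates, at fractional offset $t$, the weight vector
$\big(S(1{+}t),\,S(t),\,S(1{-}t),\,S(2{-}t)\big)$ on four consecutive
samples. A ×4 upscale needs the 16 subcell midpoints
$u,v\in\{1/8,3/8,5/8,7/8\}$; at eighth arguments every weight is a rational
over 512, so each 4×4 template (the outer product of the row and column
weight vectors) is an integer matrix over $2^{18}$. `cubic_kernel()`
evaluates $S$ in exact integer arithmetic (all intermediates are far below
$2^{53}$, hence exact in doubles), `derive_template()` forms the outer
products, and `build_template_bank()` enumerates the 16 offsets v-major.

Three structural identities hold exactly and are enforced by tests:
each template sums to $2^{18}$ (partition of unity); swapping $u$ and $v$
transposes the stencil; and the point reflection
$(u,v)\mapsto(1{-}u,1{-}v)$ rotates it by 180°.

`printed_template_table()` transcribes the historically published table
verbatim; `verify_against_printed()` reports the two cells (templates 7 and
11) where that table prints 2205 for a derived 2025 — preserved as data so
the discrepancy is documented rather than silently corrected.

One point worth stating precisely: the $a=-1$ kernel is a partition of
unity but does **not** interpolate linear functions at the nominal offset —
the weight vector at offset $v$ has first moment $m_1(v)\ne v$ (e.g.
$m_1(1/8)=106/512\approx0.207$). An affine ramp therefore comes back
exactly as an affine function of each template's *effective* sample
position $i_0-1+m_1(v)$; the test suite checks that identity bit-for-bit
rather than the (false) pointwise reproduction at the midpoints.

### Integer arithmetic policy

For integer input, `upscale4()` performs the entire contraction in integer
arithmetic: 16 integer multiplications, 15 additions, and one final
division by $2^{18}$ per output pixel (`count_ops()` verifies the counts by
instrumentation). Two output modes exist:

* `rounding = "integer"`: divide, round half away from zero, clamp to the
  bit-depth range — the deployable path;
* `rounding = "none"`: return the exact dyadic quotient. Because the
  numerators are integers and the denominator is $2^{18}$, these quotients
  are *exact* in double precision; the equivalence test against
  `bicubic_reference()` (an independent dense evaluation sharing no code
  with the shifted-accumulation implementation) is therefore bit-for-bit.

Border handling replicates the edge pixel by default (`"reflect"` mirrors
about it); both policies agree on all outputs whose 4×4 neighbourhood lies
inside the image.

### Trainable layers and initialization

On top of the frozen layer sit three convolutions: patch extraction
(`f2 × f2`, `n2` filters, ReLU), nonlinear mapping (1×1, `n3`, ReLU) and a
linear `f3 × f3` reconstruction. They are trained by seeded mini-batch SGD
(optional classical momentum) on the mean squared error, with analytic
backpropagation (verified against central finite differences to ~1e-10;
the check fixture biases the ReLUs off their kinks since a central
difference across a kink does not estimate the one-sided gradient).

Two initializations are provided. `"gaussian"` is the plain zero-bias,
small-Gaussian scheme. The default `"identity"` additionally seeds a unit
pass-through on one channel path (centre taps of layers 2 and 4, the
matching 1×1 tap of layer 3), so the untrained network reproduces the
template-layer output exactly and training starts from bicubic quality.
This is a deliberate design deviation from the plain scheme: with a frozen
interpolation layer already producing a good estimate, small training
budgets should be spent improving on that estimate, not re-learning the
identity. With small inputs bounded away from zero the equality is exact
(both ReLUs stay active on the pass-through channel).

Default problem sizes in the pipeline (`f2 = 5, n2 = 16, n3 = 8, f3 = 3`,
HR patches of 32, 200 epochs for the acceptance experiment) are this
package's own choices, sized so the full experiment suite runs in minutes
on one CPU; the layer sizes are free parameters, and SRCNN-scale settings
(9/64/32/5, 128-pixel patches) remain available for full-scale training.
The default learning rate 0.1 was chosen by a small sweep: 0.5 diverges on
these problem sizes, 0.1 converges stably.

### Transfer-learning selection

Given SIFT feature sets of a candidate subregion $S$ ($m$ descriptors) and
a reference image $T$ ($n$ descriptors),

$$D(S,T)=\frac1m\sum_{i=1}^m\min_{1\le j\le n}\lVert s_i-t_j\rVert,$$

and $\eta = N_m/N_t$, where $N_t$ is the number of features in the
*candidate* set and $N_m$ the number of them matched in $T$ under the
nearest-neighbour rule with Lowe's 0.8 ratio test. A candidate is admitted
iff $\eta \ge D$, with $D$ aggregated as the minimum and $\eta$ as the
maximum over the reference images. These normalization choices (candidate
count in the denominator; min/max aggregation; unit-length descriptors so
$D$ and $\eta$ live on comparable O(1) scales) resolve the ambiguity in the
published formulation and are fixed here once. Candidates with no features
are flagged and rejected rather than scored.

The implemented SIFT is the classical construction — Gaussian scale space
($s+3$ levels per octave, base $\sigma_0$, factor $2^{1/s}$), DoG, strict
26-neighbour extrema with a contrast threshold, 36-bin orientation
assignment, 4×4×8 descriptor with unit normalization and the 0.2
clamp-and-renormalize — *without* subpixel refinement or Hessian edge
rejection. Keypoints whose descriptor window leaves the image are dropped;
this matters on small crops, which is why the pipeline uses 64-pixel
candidate crops with $\sigma_0 = 1.2$ and one octave.

A practical property of the $\eta \ge D$ rule worth knowing: Lowe's ratio
test passes only when the candidate feature has a genuinely closer match in
the reference than the background descriptor distribution, so $\eta$ is
essentially zero between *independent* textures even of the same kind.
Selection admits candidates that share content with a reference (crops of
the reference scene: $\eta \to 1$, $D \to 0$) and rejects unrelated or flat
ones. The default pipeline therefore uses the first `n_refs` pool images
themselves as the target-domain references, and selection recovers exactly
the pool subregions related to them.

## Synthetic fixtures: realism and limits

All experiments run on seeded generators (`generate_fixture()`): smoothed
band-limited noise, separated Gaussian blobs, checkerboards, sinusoids,
steps, ramps and constants. Smoothed noise stands in for the band-limited
texture of medical images and is the training/evaluation workhorse; blobs
give isolated scale-space extrema; ramps/constants give analytic ground
truths. None of these reproduce the global anatomy, noise statistics or
acquisition physics of real medical images, so the held-out PSNR gains
(~+0.7 to +1.0 dB over bicubic) demonstrate that the training mechanism
works, not clinical performance. Published full-corpus results additionally
require real image corpora and far larger training budgets, both out of
scope here.

## Numerical policies (summary)

* Template derivation: exact integer arithmetic end to end; no floats.
* `rounding = "none"` quotients are exact dyadic doubles; oracle
  comparisons are `identical`-level, not tolerance-level.
* Integer output rounds half away from zero, then clamps to the bit range.
* PSNR uses the $(2^n-1)$ peak; unit-interval inputs are mapped to the
  integer scale first; identical images report `Inf` dB.
* All stochastic steps (fixtures, crops, initialization, shuffling) consume
  seeded, save/restored RNG state and never perturb the caller's RNG.
* Descriptor distances zap squared distances below 1e-10 to zero so
  $D(S,S)=0$ holds exactly despite BLAS round-off.
* Model and template serialization uses JSON at full precision
  (`digits = NA`); weights round-trip to ~15 significant digits.

## Limitations

* SIFT omits subpixel refinement and edge rejection; keypoint counts on
  small or weakly textured crops are low, and 48-pixel crops generally
  yield no descriptors at the default scales.
* The training engine is plain SGD on CPU, intended for the package's
  experiment sizes, not for large corpora.
* Grayscale single-channel only; color inputs are converted to luminance
  at I/O time.
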