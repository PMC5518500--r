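# medsrr

Single-image ×4 super-resolution for grayscale (medical) images, built
around a **frozen, exactly derived interpolation layer**: the 16 bicubic
convolution templates — 4×4 integer stencils over the common denominator
2¹⁸ — are computed in exact integer arithmetic from the `a = −1` cubic
convolution kernel and applied as the first layer of a small hybrid
convolutional network. Only the layers *after* the interpolation are
trained (by mini-batch SGD on a mean-squared-error loss), so the network
starts from a strong, fully deterministic bicubic estimate and learns the
residual detail. A SIFT-feature transfer-learning selector grows a small
domain-specific training corpus from a generic image pool.

## The science in one page

**Templates.** Separable cubic convolution interpolation at fractional
offset `(v, u)` inside a pixel cell combines a 4×4 input neighbourhood with
the kernel weight vector `(S(1+t), S(t), S(1−t), S(2−t))` per axis, where

```
S(ω) = 1 − 2ω² + ω³          0 ≤ ω < 1
S(ω) = 4 − 8ω + 5ω² − ω³     1 ≤ ω < 2
S(ω) = 0                     ω ≥ 2
```

At the 16 quarter-cell midpoints `u, v ∈ {1/8, 3/8, 5/8, 7/8}` every weight
is a rational with denominator 512, so each 4×4 outer-product stencil is an
**integer matrix over 2¹⁸**. `build_template_bank()` derives all 16 without
any floating-point arithmetic; each stencil's entries sum to exactly
2¹⁸ = 262144 (partition of unity), and the bank closes under transposition
(`u ↔ v`) and 180° rotation (`u → 1−u, v → 1−v`).

Applying one template costs **16 integer multiplications, 15 integer
additions and 1 integer division** per output pixel (`count_ops()` verifies
this by instrumentation) — no floating point until the final division.

**Network.** `hybrid_network()` stacks the frozen template layer with three
trainable convolutions: patch extraction (`f2×f2`, `n2` filters, ReLU),
nonlinear mapping (1×1, `n3` filters, ReLU), and a linear `f3×f3`
reconstruction. `train_network()` runs seeded mini-batch SGD with
backpropagation; the template bank is asserted unchanged after training.
The default *identity* initialization seeds a pass-through channel so the
untrained network already reproduces the bicubic upscale — training then
only has to improve on it.

**Transfer selection.** For a candidate subregion `S` and reference set `T`,
`sift_distance()` computes the mean-minimum descriptor distance
`D(S,T) = (1/m) Σᵢ minⱼ ‖sᵢ − tⱼ‖`, and `match_ratio()` the fraction `η` of
candidate features matched under Lowe's 0.8 nearest-neighbour ratio test.
`select_candidates()` admits a candidate iff `η ≥ D` (η maximized and D
minimized over the reference images). Candidates with no SIFT features are
flagged and never admitted.

## Worked example

```r
library(medsrr)

bank <- build_template_bank()
bank$templates[[1]]$numerators[1, 1]   # 2401  (= 49²; 49/512 × 49/512 × 2^18)
sum(bank$templates[[6]]$numerators)    # 262144 (partition of unity)
verify_against_printed(bank)           # the two documented table typos:
#>   template row col derived printed
#> 1        7   4   1    2025    2205
#> 2       11   1   1    2025    2205

img <- generate_fixture(fixture_spec("smooth_noise", 32, 32, seed = 1))
up  <- upscale4(img, bank)             # 128 x 128, integer arithmetic
count_ops(img[1:4, 1:4], bank)
#> <op_count> per output pixel: 16 int mul, 15 int add, 1 int div,
#>            0 float add, 0 float mul (256 pixels)

# train a small network on synthetic pairs and compare against bicubic
pairs <- make_pairs(lapply(1:50, function(i)
  generate_fixture(fixture_spec("smooth_noise", 32, 32, seed = i))))
net <- hybrid_network(f2 = 5, n2 = 16, n3 = 8, f3 = 3, seed = 1, bank = bank)
net <- train_network(net, pairs, epochs = 200, learning_rate = 0.1, seed = 1)

held <- generate_fixture(fixture_spec("smooth_noise", 64, 64, seed = 999))
evaluate_sr(held, function(lr) super_resolve(net, lr))$psnr_db          # ~22.3 dB
evaluate_sr(held, function(lr)
  pmin(pmax(upscale4(lr, bank, rounding = "none"), 0), 1))$psnr_db      # ~21.6 dB
```

The full flow (fixtures → SIFT selection → pairs → training → evaluation)
is wrapped in `run_pipeline()` and in the CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "srr.R", package = "medsrr"))') \
  run-pipeline --seed 1 --out runs/demo
```

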