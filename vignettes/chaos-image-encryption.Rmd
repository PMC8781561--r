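---
title: "Chaos-based image encryption: model, design choices, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaos-based image encryption: model, design choices, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Medical images move between acquisition devices, archives and diagnostic
pipelines, and an 8-bit grayscale radiograph is highly redundant: adjacent
pixels correlate at 0.9 or higher, and the intensity histogram is far from
flat. A cipher for such images must destroy both forms of structure — the
ciphertext should look like i.i.d. uniform bytes — while remaining exactly
invertible and cheap enough to run per image. `chaoscrypt` implements a
permutation–substitution cipher keyed by a 64-bit key, with a chaotic
pseudo-random generator as its keystream source, plus the statistical
evaluation suite used to judge it.

## Chaotic maps

Four one-dimensional maps on the open unit interval are used, each with a
control parameter restricted to its chaotic regime:

* **Logistic** `T -> G·T·(1−T)`, `G ∈ [3.58, 4]`.
* **PWLCM** (piecewise linear chaotic map): `T/G` for `T < G`,
  `(T−G)/(0.5−G)` for `G ≤ T < 0.5`, mirrored via `F(1−T)` for `T ≥ 0.5`;
  `G ∈ (0, 0.5)`.
* **LTS** (logistic–tent system): `(G·T·(1−T) + (4−G)·T/2) mod 1` for
  `T < 0.5`, with `T` replaced by `1−T` in the tent term otherwise;
  `G ∈ (0, 4)`. The two branches are identical up to the `T ↔ 1−T` swap;
  we apply the second branch for `T ≥ 0.5` and take `mod 1` over the whole
  expression. The endpoints of the control range are excluded because both
  degenerate (at `G = 0` the map is a pure tent scaled by 2; at `G = 4` the
  tent term vanishes identically).
* **Cubic** `T -> λ·T·(1−T²)` at the fixed chaotic value `λ = 2.59`, used
  only to expand the key into generator parameters. λ is capped at
  `3·√3/2 ≈ 2.598`, above which the map can leave the unit interval.

Every step is passed through a sanitizer that clamps the result into
`[2⁻³², 1−2⁻³²]`. Both 0 and 1 map to the absorbing fixed point 0 under all
four maps, so a trajectory that lands exactly on a boundary (e.g. the
logistic map at `T = 0.5, G = 4`) would otherwise die. The clamp width 2⁻³²
is far below the 1/256 resolution at which any stream is quantized, so it is
statistically invisible.

## The keystream generator

The generator is organized as a four-layer feed-forward network — widths 1,
`nhl`, `nhl`, 4 — in which every neuron's transfer function is a chaotic map.
A 64-bit key splits into two 32-bit halves; each half `h` maps to
`(h + 0.5)/2³²`, which is strictly inside (0, 1) for every possible value
(plain `h/2³²` would make the all-zero key seed the absorbing state).

**Initialization.** The second half seeds the cubic map, which is iterated 50
times with outputs discarded so the transient has died out. The following
outputs fill, in fixed row-major order, the weight matrices `W0 (1×1)`,
`W1 (nhl×1)`, `W2 (nhl×nhl)`, `W3 (4×nhl)`, then the biases `B0–B3` and the
control-parameter matrices `P0–P3` (shapes 1, nhl, nhl, 4). A raw unit value
destined for a `P` matrix is rescaled affinely into the control range of that
layer's map, so every neuron operates in its chaotic regime by construction.
The first key half initializes the neuron states.

**Forward pass.** The network topology fixes only the wiring, so the neuron
semantics are a design choice of this package: each neuron computes the
pre-activation `a = (Σ wᵢxᵢ + b) mod 1` — keeping every intermediate in the
maps' domain — and then applies its layer's map `r` times with its own
control parameter. The four output values are the streams OP4w (pixel
scrambling), OP4x (substitution), OP4y (bit scrambling) and OP4z. The input
neuron is recurrent: its next input is its own previous output, so the
generator never re-reads the key after initialization.

**Iteration-count feedback.** OP4z sets the per-neuron iteration count of the
next pass as `r = r_min + floor(OP4z·(r_max − r_min + 1))`, defaults
`r_min = 4`, `r_max = 16`. The floor matters: the pre-activation of an output
neuron has a fixed, slightly lumpy distribution determined by the frozen
weights, and the output map needs a few applications to mix that density down
to its uniform invariant measure. With only one or two applications the
emitted bytes of those passes carry measurable bias (a 256-bin chi-square
statistic an order of magnitude above its null expectation); from three
applications on, the bias is below statistical resolution at 2¹⁶ draws.
`r_min = 4` keeps one application of margin.

**Layer–map assignment.** The maps alternate across layers; the default is
logistic → PWLCM → LTS → **PWLCM**. The output layer's map is the one choice
that matters statistically: the PWLCM's four branches are linear and each
maps onto the full unit interval, and the inverse-slope moduli sum to
`G + (0.5−G) + (0.5−G) + G = 1`, so the map preserves Lebesgue measure
exactly — uniform in, uniform out, and mixing pushes any smooth density
toward uniform geometrically. The logistic map, by contrast, has an
arcsine-shaped invariant density concentrated at the interval ends, and for
`G < 4` its iterates are confined to `[G²(4−G)/16, G/4]` — bytes quantized
from it could never reach the full 0–255 range. A logistic output layer is
therefore structurally unable to produce a near-8-bit-entropy keystream; the
assignment is configurable per layer for experimentation.

**Quantization.** Byte streams use `b = min(floor(u·256), 255)`; permutation
indices use `floor(u·N·M)` on the raw unit values rather than a byte taken
`mod N·M`, avoiding modulo bias.

## The cipher

**P-box.** One permutation step per pixel: at step `t` (scan order,
row-major) the pixel at position `t` is swapped with position
`floor(u_t·N·M)` drawn from the raw OP4w stream. A sequence of
transpositions is bijective by construction, and replaying the swaps in
reverse order is its exact inverse — the properties that any reading of a
keystream-indexed permutation must guarantee. The P-box only moves pixels,
so it conserves the intensity histogram exactly.

**SP-box.** Each pixel is then substituted and bit-permuted using one byte
from each of streams x and y: `c = p XOR kx`, then `c` is encoded as four
DNA bases (2 bits per base, MSB first) under coding rule `ky mod 8`, each
base is replaced by its Watson–Crick complement, the base string is rotated
left by `(ky >> 3) mod 4` positions, and decoded under the same rule. The
inverse applies the exact reverse. The stage is total and bijective on bytes
for every key byte, verified exhaustively over all `p × kx × ky`
combinations.

Two deliberate design notes. First, the eight canonical DNA rules all assign
complementary bases complementary 2-bit codes, so the composite
encode–complement–rotate–decode collapses to "complement the byte, rotate by
`2·rot` bits" regardless of the rule; the rule machinery is implemented and
tested as specified, and this algebraic collapse is itself a tested
property. Second, substitution is stateless XOR with no ciphertext chaining.
Consequently the cipher does **not** provide plaintext-sensitivity
(NPCR/UACI-style avalanche between plaintexts differing in one pixel), and
the package makes no such claim; what the stateless design buys is exact
noise localization (below).

## Security evaluation

The suite computes, for a (plaintext, ciphertext) pair: MSE and PSNR between
the two; Shannon entropy of the ciphertext histogram (ideal: 8 bits);
Pearson correlation of adjacent ciphertext pixels in the horizontal, vertical
and diagonal directions (ideal: 0); and the energy `ΣP²` and contrast
`Σ(i−j)²P` of the normalized gray-level co-occurrence matrix. GLCM defaults
are 8 quantization levels with a one-pixel horizontal offset, unsymmetric:
at that resolution an ideal uniform ciphertext has energy `1/64 ≈ 0.0156`
and contrast `2·Var(U{0..7}) = 10.5`, which are the right magnitudes to
compare against published cipher-image texture tables; at 256 levels energy
would collapse to ~1.5·10⁻⁵ and the statistic would lose its discriminating
power at image-sized samples. Execution time is recorded in the report but
never asserted — it is hardware-dependent.

**Noise attack.** The trial encrypts, corrupts the ciphertext with
salt-and-pepper noise of density `d` (each pixel independently set to 0 or
255 with equal odds), and decrypts with the correct key. Because the cipher
is a position permutation plus a stateless per-pixel SP-box, each corrupted
ciphertext pixel damages exactly one plaintext pixel: the damaged fraction
concentrates at `d·255/256` (a corrupted pixel decrypts back to the original
value with probability 1/256), and the recovered image stays recognizable
(PSNR well above 15 dB at `d = 0.05`). This error-localization property is
the quantitative form of "the content survives a noisy channel".

## Ensemble voting

Two committee rules for two-class model ensembles, independent of any
specific classifier. Hard voting takes the modal predicted label; soft
voting averages the members' class-A probabilities and reports both class
percentages rounded to one decimal (the worked five-member committee
`(0.84, 0.90, 0.65, 0.89, 0.54)` scores class A at 76.4% and class B at its
complement 23.6%). Ties break toward the class that sorts first; percentages
always complement to 100 within rounding. These rules are exercised on the
packaged 60-patient symptom table, which ships verbatim (13 symptom columns
coded 0/1/2, including one unlabeled column preserved from the printed
layout, 30 Normal / 30 Pneumonia).

## Synthetic test images

The clinical radiographs the cipher targets are not redistributable, so
tests run on a seeded synthetic stand-in: a low-frequency Gaussian random
field (coarse grid at ~1/32 of the image scale, bilinearly upsampled), two
bright elliptical regions placed where lung fields sit, and mild pixel noise
(σ = 0.02 of the field scale), rescaled into 20–235. The construction is
low-pass, so horizontally adjacent pixels correlate above 0.9 — the regime
in which encryption-induced decorrelation is a meaningful measurement — and
the histogram is smooth and mid-gray. What the stand-in does *not* emulate:
radiographic noise physics, anatomy, detector artifacts, or any
diagnostically meaningful content. Passing tests therefore demonstrate the
cipher's statistical behaviour on smooth, highly correlated 8-bit fields,
not clinical validity on real radiographs.

## Numerical choices

* All map arithmetic is double precision; the compiled generator is built
  with floating-point contraction disabled so that its trajectories are
  bit-identical to a plain-R replay of the same operations. Under chaotic
  dynamics two implementations that differ by one ulp diverge completely
  within a single pass, so reproducibility across the compiled path and the
  reference path is all-or-nothing; the test suite asserts bit-identity.
* Sanitation clamp `2⁻³²`; key-half mapping `(h + 0.5)/2³²`; both chosen to
  exclude exact 0 and 1.
* `mod 1` is computed as `x − floor(x)` in both implementations.
* Degenerate inputs: a constant image has undefined adjacent-pixel
  correlation (reported as `NA` with a warning); identical images have
  infinite PSNR (reported as `Inf`, serialized as the string `"Inf"`);
  a 1×1 image is a legal cipher input whose P-box is the identity.
* Problem sizes: the statistical checks use 2¹⁶ keystream draws
  (chi-square, entropy, key sensitivity) and 1024×1024 images for the
  headline ciphertext statistics; structural properties (round trip, SP-box
  inversion) are checked exhaustively where the space is finite and on
  randomized non-square shapes otherwise.

## Known limitations

* No chosen/known-plaintext resistance is claimed: the keystream depends
  only on the key, so two images encrypted under the same key share their
  keystreams (use per-image keys in practice).
* The uniformity evidence is a chi-square and entropy check, not a full
  randomness battery.
* 8-bit grayscale only; 16-bit imagery and DICOM metadata are out of scope.
* PNG and TIFF I/O only; lossy formats are refused by design, and BMP is not
  supported.
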