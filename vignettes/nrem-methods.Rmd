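---
title: "Reconstruction-based no-reference scoring of edge maps: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-based no-reference scoring of edge maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrem)
```

## The problem and the model

A binary edge map $e$ of a grayscale image $i$ is useful to the extent that
it marks the structure of $i$ — object boundaries, tissue interfaces — with
as few pixels as possible. When no ground-truth edge map exists (the normal
situation for medical images), quality must be judged from $i$ and $e$
alone. The score implemented here operationalizes one idea: *an edge map is
good if the image can be reconstructed from the intensities along its
edges*. Concretely:

1. $e$ is dilated with a square structuring element and multiplied with
   $i$, giving a *grayscale edge map*: original intensities on the dilated
   mask, zero elsewhere, with $N_e$ mask pixels.
2. Every off-mask pixel is interpolated from the first mask pixel
   encountered in each of the 8 compass directions (intensity $t_k$,
   Euclidean distance $d_k$; axial steps count 1, diagonal steps
   $\sqrt{2}$).
3. The reconstruction $r$ is compared with $i$ by MGSSIM, the mean over
   nonoverlapping windows of a gradient-domain structural similarity.
4. The score is $\mathrm{NREM}(i, e) = \mathrm{MGSSIM}(i, r)^{\alpha}
   f_p^{\beta}$ with density penalty $f_p = 1/(1 + N_e/MN)$.

The two factors pull in opposite directions by design. MGSSIM alone is
maximized by the densest possible map — every extra edge pixel hands the
reconstruction another sample of the original — so it cannot rank edge maps
by itself; the penalty makes density costly, and the exponent $\beta$ sets
the exchange rate between fidelity and parsimony.

## Interpolators

Four interpolators are provided (`reconstruction_config()`):

* **Weighted mean** $r = \sum_k t_k/d_k \,/\, \sum_k 1/d_k$ — uses all
  directions, smooth, but sensitive to noise in the anchor intensities.
* **Weighted median** and **central weighted median** — the median of the
  sequence in which $t_k$ is replicated $w_k = \mathrm{round}(100/d_k)$
  times; an even-length middle pair is averaged. Robust, but in low-gradient
  regions the winner-takes-most behavior can paint spurious uniform patches.
  Under the shared $\times 100$ integerization and the pair-averaging tie
  rule the two formulations coincide; both names are exported so either can
  be requested explicitly.
* **Alpha-trimmed weighted mean** (default) — sort the weighted values
  $x_k = t_k/d_k$, discard the $T_\alpha = \lceil \alpha K \rceil$ smallest
  and largest, average the survivors. The default $\alpha = 0.125$ discards
  exactly the extremes when all $K = 8$ directions respond, interpolating
  between the mean's smoothness and the median's robustness. When
  $K - 2T_\alpha < 1$ the untrimmed weighted mean is used.

Two numerical choices deserve note. First, the trimmed *raw* values $x_k$
have the physical units of intensity/distance, so their plain average is not
an intensity whenever the distances differ; the default therefore
renormalizes the surviving terms by their weights,
$\sum' t_k/d_k / \sum' 1/d_k$, which is a convex combination of the
surviving $t_k$ and hence a valid intensity. The literal unnormalized form
remains available (`renormalize = FALSE`) for fidelity experiments. Second,
distances use the Euclidean convention (diagonal step $\sqrt 2$) so axial
and diagonal anchors are weighted comparably.

Degenerate inputs are kept total rather than fatal: a pixel whose eight rays
all exit the image before meeting the mask falls back to the mean on-mask
intensity; an entirely empty edge map reconstructs (with a warning) as a
constant at the image's global mean — such maps score poorly anyway, which
is the correct verdict. Outputs are clipped to $[0, L]$.

## Similarity

SSIM-family statistics are computed on **8 × 8 nonoverlapping tiles**
(partial border tiles dropped; `n_windows` is reported). The window means,
population standard deviations and covariance give the standard two-factor
SSIM; GSSIM keeps the luminance factor on intensities and computes the
contrast and structure factors on Sobel gradient magnitudes
(unnormalized 3 × 3 stencils, edge-mirrored padding):

$$\mathrm{GSSIM}(x, y) = [l(x, y)]^{\alpha_g} [c(x', y')]^{\beta_g}
  [s(x', y')]^{\gamma_g}, \qquad \alpha_g = \beta_g = \gamma_g = 1 .$$

Stabilizing constants follow the conventional choice $C_1 = (0.01L)^2$,
$C_2 = (0.03L)^2$, $C_3 = C_2/2$, defined on the intensity dynamic range
(gradient magnitudes are not rescaled). The window size, constants and
exponents are all configurable because none of them is canonical; the
defaults are the classic SSIM block size and constants. The structure
factor's sign is preserved under non-integer exponents by the odd extension
$\mathrm{sign}(v)\,|v|^p$, so anticorrelated windows keep a real,
negative contribution.

## Score defaults and selection tasks

The exponents default to $\alpha = 1$, $\beta = 3$ — the experimentally
chosen operating point for the measure; both are configurable
(`nrem_config()`). The dilation element defaults to the 3 × 3 square
(radius 1), the smallest element that turns an 8-connected edge chain into
a continuous band; the original source for the measure does not specify the
element, so the radius is exposed as a parameter.

`rank_candidates()` orders candidate maps by score, breaking exact ties
toward the sparser map and then input order. `sweep_threshold()` runs a
detector over a strictly increasing threshold grid and reports the winning
grid point. Built-in detectors (`detector_spec()`): thresholded-gradient
Sobel/Prewitt/Roberts, a zero-crossing LoG, and a Canny
(Gaussian smoothing, nonmaximum suppression, hysteresis). Gradient
magnitudes are computed on intensities scaled to $[0, 1]$ with kernels
normalized so a full-contrast step responds with 0.5 — the convention under
which the customary sweep grids (e.g. 0.01–0.08) are meaningful at any bit
depth.

## Consensus baseline

The comparison method estimates a ground truth from the candidates
themselves: level-$i$ *potential ground truths* mark pixels voted edge by at
least $i$ of $N$ maps (nested across levels); averaged TPR/FPR per level
trace the correspondence-threshold ROC; the level nearest the ideal corner
$(0, 1)$ is taken as the estimated ground truth; the candidate with the best
F1 against it wins. Two points where the original recipe underdetermines
the algorithm were resolved as follows: the "diagnosis line" is realized as
the nearest-to-$(0,1)$ rule (the chi-square alternative is defined only in
earlier work and is not reimplemented here — a deliberate fidelity caveat),
and "best match" is realized as maximum F1. Per-level rates are averaged
over maps, not pooled over pixels. Degenerate confusion denominators
(empty-reference levels) report flagged zeros rather than erroring, so
sweeps never abort. Note that along levels both FPR and TPR are
nondecreasing — level 1 is the union of the maps (no false positives are
possible against it) and level $N$ the intersection (contained in every
map) — so the ROC runs from the conservative corner toward $(1, 1)$ as the
consensus tightens. F1 ties between distinct masks are broken by mask
content, not input position, so the selected *mask* is invariant to
candidate order.

## Phantoms: what they emulate, and what they do not

`make_phantom()` renders piecewise-constant scenes (axis-aligned rectangles
and circles) plus additive Gaussian noise, with the ground-truth edge mask
extracted *before* noise is added: an edge pixel is an object pixel with a
4-neighbor of different rendered intensity, giving 1-pixel closed contours
on the object side of each boundary — the same localization a thresholded
gradient detector targets. The canonical scene
(`shapes_phantom_spec()`, 64 × 64, background 100) contains a rectangle at
180, a circle at 220, and a low-contrast rectangle at 130. The low-contrast
object is deliberate: its normalized step response ($30/255 \times 0.5
\approx 0.059$) sits inside the usual sweep grid, so low thresholds admit
noise while high thresholds destroy real structure and the optimal
threshold is interior — the tradeoff the score exists to resolve. With
noise $\sigma = 10$ the noise-alone Sobel response crosses the same grid
from the other side, which makes the 64 × 64 scene an honest miniature of a
low-contrast radiograph *for this purpose*.

What the phantoms do **not** emulate: textured tissue, intensity gradients
inside objects, correlated or signal-dependent noise (Poisson, speckle),
partial-volume blur at boundaries, and anatomically curved low-contrast
interfaces. Passing the phantom experiments therefore shows that the
measure's mechanics behave as designed (penalty beats density bias,
degradation is detected, interior optima are found); it does not certify
performance on clinical data, where detector idiosyncrasies and noise
structure can shift the operating point.

All experiment sizes in the test suite and the acceptance script — 64 × 64
phantoms, 10-seed replicate families, 16 × 16 oracle instances — were
chosen as the smallest scales at which the tested effects are comfortably
away from their decision boundaries.

## Known limitations

* The directional search uses ray casting on the dilated mask; an edge
  pixel diagonally adjacent to a ray can be missed by that ray, which is
  inherent to the 8-direction formulation, not a defect of the scan.
* MGSSIM can be negative (anticorrelated gradient structure); the score's
  sign-preserving powers keep it real, but strongly negative values should
  be read simply as "very poor", not on a linear scale.
* The density penalty counts pixels *after* dilation, so the dilation
  radius affects both fidelity and penalty; comparisons are only meaningful
  at a fixed radius.
* The consensus baseline inherits the known bias of consensus methods: if
  most candidates miss a feature, the estimated ground truth misses it too.
  This is the motivating weakness the reconstruction-based score addresses,
  and the baseline is included for exactly that comparison.
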