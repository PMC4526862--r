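---
title: "Boundary reconstruction by normal-ray resampling: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary reconstruction by normal-ray resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 5)
library(raycontour)
```

## The problem and the model

A micron-resolution microscopy stack of a whole mouse brain holds thousands
of coronal slices; the brain's outer shell appears on each slice as one
closed boundary between a bright interior and a dark exterior. Two
properties of such data defeat the classic global approaches: the sheer data
volume (level sets and snakes touch every voxel) and strong low-frequency
intensity inhomogeneity along the boundary (threshold-like criteria fail
where the signal fades).

`raycontour` implements a local alternative. Given an initial closed
contour — traced manually for the first slice, inherited from the previous
slice thereafter — each boundary element may move only along its exterior
normal. For element $i$ the candidate positions form a *ray*
$\mathbf{r}_{0i} + m\,\mathbf{n}_i$, $m \in [-M, M]$, and the only image
data the solver ever reads are the intensity samples on these rays. The
offsets $r(s_i)$ minimise

$$E(r) \;=\; \sum_i \Big[\, \tfrac{\alpha}{2}\,\big(r(s_{i+1}) - r(s_i)\big)^2
\;-\; \beta_i \, E_\mathrm{ext}\!\big(s_i, r(s_i)\big) \Big],$$

with
$E_\mathrm{ext}(s, r) = \sum_m g(p_m, s)\, e^{-(p_m - r)^2 / 2\sigma^2}$.
The smoothness term encodes the assumption that the true boundary is smooth,
so the offset function changes slowly along the contour; the external term
pulls each element toward the kernel-smoothed peak of its ray's *valid
gradient* $g$ — the evidence for an intensity drop, i.e. a boundary
crossing. Two assumptions are load-bearing and should be checked on new
data: the interior is brighter than the exterior at every boundary point,
and the shape is a single connected domain (the model cannot split or merge
contours).

## From raw samples to the valid gradient

Each ray sample $v(p_m)$ is the mean of the 5×5 pixel window centred on the
pixel containing the position (windows clipped at image borders). Three
conditioning stages follow:

1. **Clamping.** $L_2$ = mean of the interior samples ($m < 0$), $L_1$ =
   mean of the exterior samples ($m > 0$); every sample is clamped into
   $[\min(L_1, L_2), \max(L_1, L_2)]$. With a bright interior this caps
   bright interference outside the boundary at the interior level, removing
   spurious gradient peaks while leaving the true transition intact. The
   bounds are computed once per ray when the resampling dataset is built and
   are fixed from then on (clamping with the fixed bounds is idempotent;
   recomputing bounds from a clamped profile would shrink them further).
   Computing $L_1, L_2$ per ray rather than pooled over the slice is
   deliberate: per-ray bounds are what make the conditioning robust to
   inhomogeneous boundary contrast.
2. **Smoothing.** Ten passes of the 3-point mean. Endpoints use edge
   replication (a virtual sample equal to the end value), which preserves
   constant profiles; the smoothing is a max-norm contraction.
3. **Valid gradient.** Forward differences are negated and thresholded at
   zero: $g_m = \max(0, v(p_m) - v(p_{m+1}))$. Rising stretches carry no
   boundary evidence for a bright-inside object and are zeroed; the sum of
   $g$ equals the total negative variation of the conditioned profile.
   Gradient sample $m$ lives at the half-integer offset $m + 1/2$.

"Mean of the 5×5 window" deserves one note: we read the 25-pixel window as
including the containing pixel once (mean over 25 values). Positions are
assigned to pixels by nearest-integer rounding with ties toward $+\infty$,
with pixel centres at integer 0-based coordinates; this fixed convention
makes ray sampling bit-reproducible under integer translation of image and
contour together.

## The iteration

Minimisation follows the standard gradient-flow route: introduce time, drive
$r$ by the negative functional gradient, stop at stationarity. Per
iteration:

$$(1 + 2\Delta t)\, r_i^{k+1} - \Delta t\, r_{i+1}^{k+1} - \Delta t\, r_{i-1}^{k+1}
\;=\; r_i^k + \Delta t\, \tfrac{\beta_i}{\alpha} F_i(r_i^k),$$

where $F_i$ is $\partial E_\mathrm{ext} / \partial r$ and the element
spacing over $\alpha$ is fixed to one. The smoothness term is treated
semi-implicitly — the cyclic tridiagonal solve above — because the explicit
update is unstable at the published $\Delta t = 1$; the semi-implicit form
is the standard unconditionally stable discretisation and has the same fixed
points. The system matrix is constant, so its inverse is computed once and
each iteration is a matrix–vector product.

The explicit external step can still overshoot when the kernel is narrow
(the descent condition requires roughly
$\Delta t/\alpha \le \sigma^2 / (\beta_i \sum_m g_m)$, which fails at
$\sigma = 0.5$ for typical edges). We therefore backtrack: if an update
would increase the discrete objective, the time step is halved for that
iteration (solver matrices are cached per step size). This guarantees the
objective is non-increasing at every fixed $\sigma$ — a property the test
suite asserts to $10^{-9}$ on randomized phantoms — without changing where
the flow converges. If even a tiny step cannot decrease the energy the
element set is at a constrained stationary point and the iterate is kept.

Offsets are clipped to $[-M+1, M-1]$ so the force is never evaluated outside
the sampled gradient range. Convergence is declared when
$\max_i |\Delta r_i| < 10^{-3}$ px (well below evaluation resolution), with
at most 500 iterations per stage; a stage that exhausts its budget returns
`converged = FALSE` with a warning rather than an error.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.8 | — | smoothness weight; larger flattens the offset function |
| `beta0` | 0.2 | — | external weight base; $\beta_i = \beta_0/(10^{-6} + \max_m g)$ normalises pull per ray |
| `sigma` | 0.5 | px | final kernel width: localisation sharpness of the edge evidence |
| `sigma_schedule` | 3, 1.5, 0.5 | px | annealing; see below |
| `dt` | 1 | — | time step (backtracked per iteration when needed) |
| `M` | 30 | px | ray half-width; must cover the largest expected inter-slice displacement plus the edge transition |
| `n_points` | 540 | — | contour discretisation; the method is insensitive over 360–720 |
| `smoothing_passes` | 10 | — | profile conditioning |

At $\sigma = 0.5$ the Gaussian's capture radius is sub-pixel: an element
initialised more than a pixel or two from the edge feels almost no force.
That is adequate when the initial contour comes from the neighbouring slice
(differences are subtle), but fragile for a hand-drawn first contour a few
pixels off. The schedule anneals $\sigma$ from 3 px down, each stage
warm-starting the next, extending capture to the several-pixel regime while
the final stage matches the published width exactly. A strict single-stage
run is available via `sigma_schedule = 0.5`.

## What the phantom emulates — and what it does not

`generate_phantom()` renders a star-convex shape
$\rho(\theta) = R\,(1 + \sum_j a_j \cos(j\theta + \varphi_j))$, drifting in
scale by `z_drift` per slice, with: bright interior over dark exterior; a
low-frequency multiplicative field $1 + A\sin(\theta + 0.25\,z)$ on the
interior (the inhomogeneity that defeats thresholds); optional bright arc
blobs just outside the boundary (the interference the clamping stage must
suppress); additive Gaussian noise; and rounding to integer counts, as a
detector produces — which also makes 16-bit TIFF round trips bit-exact. The
standard phantom (`standard_phantom_spec()`) is 220×220×20, base radius 60,
harmonics (3, 0.12, 0) and (5, 0.05, 1.0), drift 1.003, intensities 120/20,
30% inhomogeneity, one blob (centre π/4, 20° wide, 5 px out, intensity 110,
slices 9–13, 4 px thick), noise sd 6, seed 0. Its problem size keeps the
whole pipeline run in the ten-second range on one core while preserving the
regime of the real data: a ~0.2 px/slice drift (subtle inter-slice change),
edge contrast varying ±30% along the boundary, and noise an order of
magnitude below the edge step.

Star-convex truth shapes cover non-convexity (concave reaches) while
guaranteeing simple polygons; the phantom does **not** emulate brain
texture, vasculature, optical point-spread, montaging seams, or
multi-domain topology. Passing tests on the phantom therefore demonstrate
correctness of the machinery and robustness to inhomogeneity, interference
and noise — not performance on artifacts the phantom lacks.

## Numerical choices and degenerate inputs

* Arc-length resampling snaps interpolation targets within $10^{-9}$ of the
  perimeter onto existing vertices, so resampling an already-uniform contour
  is an exact identity; a constant image is then an exact fixed point of
  slice reconstruction (zero gradient → zero offsets → unchanged contour).
* Orientation is canonicalised by shoelace sign (counter-clockwise);
  normals are perpendicular to the chord $\mathbf{r}_{0,i-1} \to
  \mathbf{r}_{0,i+1}$, the discrete stand-in for the tangent. Coincident
  chord endpoints raise a degenerate-geometry error naming the element.
* Rays whose 5×5 window centre would leave the image raise an error naming
  the element; in stack runs such a slice is flagged `failed` and inherits
  the previous contour, so one bad slice cannot end a long run.
* A refined contour that self-intersects is repaired by one arc-length
  resampling; if it still self-intersects the slice is reported failed
  rather than silently continuing.
* Rasterization uses pixel-centre-in-polygon with the even-odd rule
  (scanline crossings); recall and precision are pixel counts at image
  resolution, matching how reconstructions are compared against manual
  delineations.
* Exact stationarity on a stack of identical slices is *not* attainable:
  re-refining a refined contour shifts the ray sampling phase, and at
  $\sigma = 0.5$ the kernel sum over unit-spaced gradient samples has
  sub-pixel ripples, so consecutive reconstructions wobble by a few tenths
  of a pixel. The pipeline is held to sub-pixel stationarity instead; the
  wobble is far below the evaluation scale (a 0.3 px radial wobble moves
  overlap scores by well under one point on the standard phantom).

## Design decisions that were genuinely open

* **Propagation direction.** The published procedure runs from the seeded
  slice forward; `reconstruct_stack()` adds `backward` and `both` so a seed
  in mid-stack can cover the whole volume.
* **Interference rejection vs. capture.** The clamp bounds and the
  $\beta$-normalisation already suppress most interference; the annealed
  schedule re-introduces long-range capture, which in principle could reach
  a strong spurious peak. On the standard phantom the blob costs under 0.1
  overlap points; for data with heavier interference a shorter schedule
  (or the strict single-$\sigma$ mode) trades capture for caution.
* **Integer-count images.** The generator rounds to integer intensities and
  stack I/O is 16-bit TIFF; this mirrors real detectors and makes every
  file round trip exact, at a quantisation cost three orders of magnitude
  below the noise floor.

## Known limitations

Single connected domain only (no topology change); rays live strictly in
the slice plane (no 3D regularisation across slices); the first contour
must be supplied and must lie within $M$ pixels of the true boundary
everywhere; evaluation is pixel-count overlap, not surface distance.
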