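---
title: "Johnson-SB mixture thresholding of liver CT slices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Johnson-SB mixture thresholding of liver CT slices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsbseg)
```

## The problem

A liver CT slice is an 8-bit grayscale image in which the liver parenchyma
occupies a fairly narrow band of gray levels, flanked by darker soft tissue
and brighter bone. Threshold segmentation therefore reduces to estimating
the `[low, high]` gray interval occupied by the liver. The classical tool —
a Gaussian mixture fitted to the gray-level histogram, with thresholds read
off component intersections — struggles because liver histogram peaks are
visibly *skewed*, and a symmetric component either misplaces the
intersection or forces extra components whose positions drift with the
chosen cluster number.

`jsbseg` replaces the Gaussian component with the bounded Johnson-SB
distribution, whose two shape parameters give each component a flexible
asymmetric shape, and pairs it with a *divided-histogram* strategy that
splits the histogram at the liver peak so each half presents a one-sided,
strongly skewed profile — exactly the shape Johnson-SB fits well.

## The Johnson-SB distribution

A variable $x$ on the open interval $(\xi, \xi + \lambda)$ follows a
Johnson-SB distribution when

$$ z \;=\; \gamma + \delta \,\ln \frac{x - \xi}{\lambda + \xi - x} $$

is standard normal, with shape parameters $\delta > 0$ and
$\gamma \in (-\infty, \infty)$. The density is

$$ p(x) \;=\; \frac{\delta}{\sqrt{2\pi}}\,
   \frac{\lambda}{(x-\xi)(\lambda+\xi-x)}\,
   \exp\!\Big[-\tfrac12\big(\gamma + \delta f(x)\big)^2\Big],
   \qquad f(x) = \ln\frac{x-\xi}{\lambda+\xi-x}. $$

$\gamma = 0$ gives a density symmetric about $\xi + \lambda/2$; $\delta$
controls concentration; the median is available in closed form,
$\xi + \lambda\,\mathrm{logis}(-\gamma/\delta)$. Sampling inverts the
transform on standard normal draws, the CDF is
$\Phi(\gamma + \delta f(x))$, and the density is defined as zero outside
the open support so mixtures can be evaluated over the whole 0–255 grid.

One caveat on vocabulary: the field's convention of labelling $\gamma > 0$
"negatively skewed" and $\gamma < 0$ "positively skewed" (implemented in
`jsb_skew_direction()`) refers to the displacement of the density peak, and
is *opposite in sign* to the third-moment skewness: a $\gamma < 0$
component has its median above the support midpoint and a long left tail,
i.e. negative moment skewness. Tests that assert skewness therefore compare
against moments computed by quadrature from the generating density, not
against the label.

### Support convention

The support is not estimated: it is anchored to the image's gray axis,
$\xi = \min(x)$, $\lambda = \max(x) - \min(x)$, padded by half a gray level
on each side ($\xi - 0.5$, width $+1$). The padding keeps every observed
integer level — including 0 and 255 — strictly inside the open support
where $f$ is finite. `init_model()` takes the axis from the histogram's
level range (a CT slice always spans black background to bright bone), so
a whole-slice fit uses $(-0.5, 255.5)$ and a histogram part uses its own
level range padded the same way.

## The mixture and its EM fit

A $K$-component mixture $p(x) = \sum_k \Phi_k\, p_k(x \mid \gamma_k,
\delta_k)$ shares one support across components; only the weights and shape
pairs are optimized. Fitting operates on the 256-bin histogram with counts
as multiplicities,

$$ L(\Theta) = \sum_i c_i \ln \sum_k \Phi_k\, p_k(x_i), $$

which is identical to per-pixel likelihood but costs $O(256K)$ per
iteration instead of $O(512^2 K)$.

**E-step.** Posterior responsibilities
$w_{ik} = \Phi_k p_k(x_i) / \sum_j \Phi_j p_j(x_i)$, computed in log space
with a log-sum-exp guard.

**M-step.** With $f_i = f(x_i)$, $N_k = \sum_i c_i w_{ik}$, and $m_k, v_k$
the responsibility-weighted mean and variance of $f$, the stationary point
of the weighted likelihood is closed-form:

$$ \Phi_k = \frac{N_k}{\sum_i c_i}, \qquad
   \delta_k = \frac{1}{\sqrt{v_k}}, \qquad
   \gamma_k = -\delta_k\, m_k. $$

These updates are verified in the test suite against a direct numerical
maximizer (BFGS on $(\gamma, \log\delta)$) on randomized histograms; the
two agree to well below $10^{-4}$.

### Degeneracy and the quantization floor

The likelihood above is unbounded: a component that concentrates on a
single populated level drives $v_k \to 0$ and $\delta_k \to \infty$. This
is not hypothetical — the divided-histogram split deliberately places the
liver peak at a part's support edge, where one bin sits half a level from
the boundary and the transform $f$ stretches bins apart, so EM reliably
tries to collapse a component onto it.

Since the data are integer-quantized, a component narrower than one gray
level is unidentifiable, and the minimal regularization is to floor each
component's $f$-variance at the in-bin quantization variance
$\overline{f'(x)^2}/12$ (the image of a unit-width gray bin under $f$,
responsibility-averaged; $1/12$ for the Gaussian family). The floor is a
`max`, so it only binds for near-degenerate components; everywhere else the
update equals the exact closed form. To preserve EM's ascent property while
the floor binds, the driver ratchets it: the floor passed at each iteration
never exceeds a component's current variance, so the constrained M-step
always (weakly) increases the objective and the log-likelihood trace is
non-decreasing — a property asserted on every fit in the test suite.
`m_step(var_floor = "none")` exposes the unregularized update, which raises
a collapse error naming the offending component.

### Initialization and convergence

Component locations are evenly spaced over the populated gray range,
$c_k = lo + \frac{k}{K+1}(hi - lo)$, placed strictly in the interior;
each Johnson-SB component is built so $c_k$ is exactly its median
($\delta_k = 2$, $\gamma_k = -2 f(c_k)$), and weights start at $1/K$. The
fit stops when the relative log-likelihood change drops below $10^{-6}$
(or 500 iterations). Everything is deterministic given the histogram, so
repeated runs are bit-identical.

## From fitted curves to thresholds

The per-slice pipeline (`segment_slice()`) runs:

1. **LV_A** — on the sequence's reference slice (one third into the stack,
   where the liver section is largest: `select_reference_slice()`), take a
   10-pixel-tall horizontal band one quarter of the way down the body's
   bounding box and return its modal gray value, excluding the black zone
   (levels < 10) and white zone (levels > 245).
2. **LV_M** — on each slice's histogram (5-level moving average, strict
   local maxima with prominence ≥ 1% of the maximum), the peak nearest
   LV_A; ties break toward the larger count, then the lower level.
3. **Split and fit** — divide the histogram at LV_M, the LV_M bin shared
   by both parts so the liver peak sits at each part's edge, and fit a
   K-component mixture (default K = 13) to each part. The pure-black
   level 0 is dropped first: background air is a delta spike that a
   continuous density cannot represent and carries no liver information.
4. **Thresholds** — on the left part, the candidate low threshold is the
   crossing of the weighted curves of the two components with the largest
   medians; on the right part, the two with the smallest medians. If
   another component's density peaks strictly between that crossing and
   LV_M, the peak's gray value is used instead (*peak override*). The
   final range is clamped so `low ≤ LV_M ≤ high`.
5. **Binarize and clean** — pixels in the closed interval `[low, high]`,
   then hole filling, a radius-3 disc opening, and retention of the
   largest 8-connected component; the boundary is traced as the contour.

Three selection details deserve justification, since a fitted mixture at
K = 13 is messier than an idealized three-curve sketch:

* **Edge fragments.** Because the liver peak sits at the part's support
  edge, EM often dedicates a small component to the boundary bin itself.
  Such a curve describes the liver peak — not a neighboring structure — so
  it can neither carry a separating intersection nor count as an
  interposed peak. Components whose mode lies within 1.5 gray levels of
  LV_M are excluded from the selection (waived if fewer than two would
  remain). Without this, the "two rightmost curves" are the liver curve
  and its own edge fragment, and the threshold degenerates to LV_M.
* **Boundary crossings.** Two bounded densities both vanish toward the
  support ends, where their difference can change sign spuriously. The
  separating point of two unimodal curves lies between their peaks, so
  crossings are restricted to that interval when it contains any; among
  several candidates the one nearest LV_M is taken, since the threshold
  bounds the liver mode.
* **Weight floor.** Components with weight ≤ 1e-4 are ignored; at K = 13
  EM routinely parks near-empty components.

The whole-histogram variant (`twh_threshold()`) fits one mixture to the
undivided histogram and takes the adjacent-component crossings nearest
LV_M on either side; it is the convention used for the Gaussian baseline
and is retained for comparison, not as the headline mode. Both threshold
modes accept either component family.

## The phantom generator

`make_phantom()` renders a 512×512 abdominal-CT-like slice: black
background (gray 0), an elliptical body with a bright bone-like rim
(support 235–257, clipped at 255), a broad soft-tissue interior (median
95), one large elliptical liver (default median 150), and three smaller
confounding organs at medians −15, +15 and +25 relative to the liver. All
regions draw from known Johnson-SB distributions, so the generating
mixture, the liver mask, and every geometric fraction are exact ground
truth. The liver's `gamma = -0.8` makes its histogram peak visibly skewed
— the regime where the Johnson-SB component has an advantage — and the
confounder offsets of 15–25 gray levels make the threshold placement
nontrivial without being adversarial. The liver ellipse is placed to
dominate the quarter-height sampling band, mimicking a mid-liver slice, so
`estimate_lva()` lands within a few levels of the liver median. One seeded
generator drives all sampling; a `(spec, seed)` pair reproduces the image
bit for bit.

What the phantom does *not* emulate: spatial noise correlation and
texture, partial-volume blur at organ boundaries, anatomical shape
variability, contrast-agent gradients, and any slice-to-slice drift beyond
what independent seeds produce. Passing the phantom suite therefore shows
that the estimator chain — peak location, split, fit, intersection rules,
morphology — is internally consistent on data from its own model family;
it does not certify accuracy on patient data, where windowing and
anatomy-dependent overlap dominate.

## Numerical choices

| Quantity | Value | Where |
|---|---|---|
| EM convergence | relative change < 1e-6, max 500 iterations | `em_config()` |
| Initial delta | 2.0 | `em_config()` |
| Variance floor | in-bin quantization variance, ratcheted | `m_step()` |
| Crossing search | 0.1-level grid + bisection to 1e-3 | `component_intersections()` |
| Mode search | 1024-point grid + golden-section refinement | `jsb_mode()` |
| Weight floor | 1e-4 | `threshold_from_part()` |
| Edge-fragment margin | 1.5 gray levels around LV_M | `threshold_from_part()` |
| LV_M smoothing / prominence | 5-level window, 1% of max | `find_lvm()` |
| Black / white cutoffs | < 10, > 245 | `estimate_lva()` |
| Morphology | radius-3 disc opening, 8-connectivity | `morphology_clean()` |
| HU window | center 60 HU, width 400 HU | `window_hu()` |

Test and acceptance problem sizes are chosen to keep the full suite fast
while leaving no estimator untested: density/normalization checks use
quadrature; M-step oracle checks use 20 randomized 3k-sample histograms;
parameter recovery uses 100k-sample histograms; the segmentation suite
uses ten 512×512 phantoms at K = 13 plus a K = 12–15 stability sweep.

## Known limitations

* PNG input only. No DICOM reader is bundled; `window_hu()` implements the
  standard center/width windowing so CT slices can be converted externally.
* Thresholds are global per slice; no spatial regularization beyond the
  morphological cleanup, and the largest connected component stands in for
  anatomical liver selection.
* Model order is fixed by the user (default K = 13, where the
  divided-histogram thresholds are empirically stable); there is no
  AIC/BIC selection.
* The skew-direction labels follow the field's peak-displacement
  convention, not moment skewness (see above).
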