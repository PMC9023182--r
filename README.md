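# jsbseg

Threshold segmentation of liver CT slices with Johnson-SB mixture models.

## The problem

Gray-level histograms of liver CT slices carry a liver peak that is
visibly skewed, so the classical route — fit a Gaussian mixture model
(GMM) to the histogram and read segmentation thresholds off component
intersections — places thresholds that wander as the number of mixture
components changes. `jsbseg` is for image-analysis researchers and
pipeline builders who want a deterministic, auditable, histogram-based
liver segmenter: it replaces the Gaussian component with the bounded,
skew-flexible Johnson-SB distribution and stabilizes the thresholds with a
divided-histogram strategy.

## The model

A gray value $x \in (\xi, \xi + \lambda)$ is Johnson-SB distributed when
$z = \gamma + \delta \ln\frac{x-\xi}{\lambda+\xi-x}$ is standard normal
($\delta > 0$ controls concentration, $\gamma$ skewness). The slice
histogram is modeled as a $K$-component mixture
$p(x) = \sum_k \Phi_k\, p_k(x \mid \gamma_k, \delta_k)$ with one shared
support, fitted by EM on the discrete likelihood
$L = \sum_i c_i \ln \sum_k \Phi_k p_k(x_i)$ (histogram counts $c_i$ as
multiplicities). The M-step is closed form:
$\Phi_k = N_k/\sum c_i$, $\delta_k = v_k^{-1/2}$,
$\gamma_k = -\delta_k m_k$, with $m_k, v_k$ the responsibility-weighted
mean and variance of the transform $f(x_i)$.

Segmentation then follows the divided-histogram (TDH) recipe: locate the
approximate liver gray value LV_A on the sequence's reference slice, find
the histogram peak LV_M nearest it on each slice, split the histogram at
LV_M, fit a K = 13 mixture to each half, and take as thresholds the
intersections of the two rightmost (left part) / leftmost (right part)
weighted component curves — unless another component's peak interposes
between the intersection and LV_M, in which case the peak wins. The
`[low, high]` band is binarized and cleaned up morphologically (fill,
open, largest component). A GMM baseline, whole-histogram (TWH) mode,
Jaccard/Dice evaluation, and a seeded synthetic phantom generator with
exact ground truth are included.

## Worked example

```r
library(jsbseg)

ph <- make_phantom(seed = 1)         # synthetic abdominal slice + truth
ph
#> phantom 512x512 (seed 1): liver 29815 px, background 47.6%

res <- segment_slice(ph$image, config = em_config(K = 13))
res
#> segmentation (tdh): LV_A 148, LV_M 151, thresholds [142.1, 155.9], mask 29155 px

jaccard(res$mask, ph$liver_mask)     # overlap with generator ground truth
#> [1] 0.9779
dice(res$mask, ph$liver_mask)
#> [1] 0.9888
```

The phantom's liver draws from Johnson-SB(gamma = -0.8, delta = 2.5) with
median 150; the pipeline estimates the approximate liver value LV_A = 148
from the quarter-height sampling band, snaps to the histogram peak
LV_M = 151, and the divided-histogram fit brackets the liver at
[142.1, 155.9]. After hole filling and opening, the mask covers 29155
pixels against 29815 true liver pixels, for a Jaccard index of 0.978. `res$thresholds` keeps
the per-part fits, the rule that produced each threshold
(`intersection` or `peak_override`), and the component counts, for audit.

A sequence is segmented with `segment_sequence(slices, em_config(K = 13))`
(LV_A estimated once on the reference slice, one third into the stack);
`thresholds_table()` exports per-slice thresholds as a data frame. A thin
command-line wrapper lives in `inst/cli/jsbseg.R`:

```sh
Rscript inst/cli/jsbseg.R phantom --out data --seed 1 --n 3
Rscript inst/cli/jsbseg.R segment --input data --clusters 13 --out seg
Rscript inst/cli/jsbseg.R eval    --pred seg --truth data --out eval.csv
```

Input is 8-bit grayscale PNG; window DICOM slices to PNG first (the
standard center/width mapping is provided as `window_hu()`).

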