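---
title: "Quantifying ER puncta: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ER puncta: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpuncta)
```

## The measurement problem

Misfolded secretory proteins such as mutant proinsulin concentrate into
discrete fluorescent puncta in the endoplasmic reticulum. Whether those
puncta stay small (confined to ER tubules, accessible to the tubular
ER-phagy machinery) or enlarge (in sheet-like ER, escaping degradation) is
read out from confocal images through a small set of quantities: puncta
areas and size classes, object-overlap colocalization between a cargo and a
marker channel, background-subtracted intensities at sites of interest,
puncta velocities from time-lapse movies, and exchange kinetics from
fluorescence recovery after photobleaching (FRAP). `erpuncta` implements
that measurement chain as composable R functions and pairs it with a
ground-truthed synthetic-microscopy generator, so every stage can be
validated by parameter recovery rather than by eye.

## Segmentation

Puncta are detected per cropped cell by automatic thresholding with Yen's
maximum-correlation criterion on a 256-bin histogram spanning the image's
intensity range, independent of bit depth. For a normalized histogram
$p_i$ with cumulative sums $P_1(t)=\sum_{i\le t}p_i$,
$P_2(t)=\sum_{i\le t}p_i^2$ and $P_2^c(t)=\sum_{i>t}p_i^2$, the criterion

$$C(t) = -\ln\!\big(P_2(t)\,P_2^c(t)\big) + 2\ln\!\big(P_1(t)(1-P_1(t))\big)$$

is maximized over all levels; ties within numerical tolerance
($10^{-10}$) break toward the lower level so the result is deterministic.
Pixels strictly above the threshold are foreground. This thresholding
style captures isolated spots as well as punctate accentuations on
tubules, which is what makes it suitable for spot-on-network images.

Particle analysis labels 8-connected components, measures the calibrated
area (pixel count $\times$ pixel size$^2$, exact by construction), the
physical centroid (pixel-centre convention: index $+\,0.5$ pixels), and
circularity $\min(1,\,4\pi A/P^2)$ with the perimeter estimated as the
polygon length of the traced outer boundary (axial steps count 1, diagonal
steps $\sqrt 2$; single-pixel objects are assigned circularity 1; holes
are not filled). The default filters retain circularity 0.5–1; both
filters are inclusive at their bounds. Size classes are
$[0, 0.12)$, $[0.12, 0.24]$ and $(0.24, \infty)$ µm² — the middle bin is
closed on both sides, reading "0.12–0.24" literally — and the independent
"large punctum" flag is area $\ge 0.5$ µm². Boundary cases are measure
zero in practice; the conventions matter only for reproducibility.

## Colocalization

Colocalization is object-based, not intensity-correlative. The binary
masks of the two channels are intersected pixelwise (Boolean AND) and

$$\%\,\text{coloc of A with B} \;=\; \frac{\#\,\text{components of }A\wedge B}{\#\,\text{components of }A}\times 100.$$

Implemented literally, one elongated A object crossed by several B objects
can produce more intersection components than A objects; the result is
flagged (`over_100`) rather than capped. A second published variant —
the count of A objects that touch B at least once over the A count
(`mode = "object_hit"`) — is bounded by 100 and is also provided. Both
modes exist because both formulations appear in this workflow's
literature; `and_count` is the default. Size-stratified colocalization
restricts mask A to the objects of one size bin at a time, with per-bin
denominators (an empty bin yields an undefined percent, never 0).
Lysosomal delivery is the area-overlap fraction $|A\wedge B|/|A|$.

## Intensity measurements

Site intensity is the mean of the target channel over a thresholded site
mask minus the mean over a hand-drawn extracellular background region.
Which channel defines the sites is an explicit argument, never inferred.
Negative corrected values are retained with a flag — clipping them would
bias condition means. Relative intensities divide each condition's mean by
the control condition's mean (the control maps to exactly 1.0), and fold
overexpression divides each transfected cell's mean by the mean over all
non-transfected cells.

## Tracking and velocity

Detections are linked frame to frame by greedy nearest-neighbour
assignment: candidate pairs sorted by distance, assigned one-to-one,
rejected beyond `max_disp_um`; unmatched detections start or end tracks and
gaps are never bridged. This replaces an interactive tracker with a
reproducible rule; at the puncta densities of these experiments the greedy
and globally optimal assignments coincide almost always. Velocity is the
calibrated *total* path length divided by the elapsed recording time — a
punctum that loops back to its start has positive velocity, and total-path
velocity is never smaller than net-displacement velocity (`method =
"net"` exists for comparison). The frame interval is a required input; it
is not recoverable from the data and is never guessed.

## FRAP

Raw traces carry the bleach-ROI mean $B(t)$, the whole-cell mean $W(t)$
and a background mean $bg(t)$, with the bleach at $t=0$ (the first
post-bleach frame sits half a frame interval later). Double normalization

$$N(t) = \frac{W_{pre}}{W(t)-bg(t)}\cdot\frac{B(t)-bg(t)}{B_{pre}}$$

cancels monitor bleaching and global gain; single normalization is
available when no whole-cell channel exists. Recovery is fitted for
$t \ge 0$ to the minimal single-exponential model

$$N(t) = b_0 + (\text{plateau}-b_0)\,(1-e^{-kt}),$$

initialized from the data ($b_0$ from the first post-bleach point, the
plateau from the final 10% of samples, $k$ from the time to the recovery
midpoint) and solved by Levenberg–Marquardt least squares with positivity
bounds. The mobile fraction is $(\text{plateau}-b_0)/(1-b_0)$, the
half-time $\ln 2 / k$, and the recovery percentage $100\times$ plateau
relative to the pre-bleach level of 1 — the scale on which "~60% versus
~90% recovery" contrasts are quoted. A perfectly flat post-bleach trace
returns mobile fraction 0 with an undefined-half-time flag rather than an
arbitrary rate. The default acquisition schedule is six pre-bleach frames
at two frames per second, continuous post-bleach acquisition for 30 s,
then 2 s intervals out to 150 s.

## Experiment-level statistics

The unit of replication is the independent experiment, not the cell:
per-cell values are averaged within experiment first, and means, SEM
($s/\sqrt{n}$ over experiment means) and tests operate on those. The test
is the classical equal-variance Student's unpaired t-test (two-sided, with
$n_A+n_B-2$ degrees of freedom; Welch available as an option), with
significance stars NS/*/**/*** at 0.05/0.01/0.001. Zero-variance
degenerate inputs follow the conventions p = 1 for equal means and p = 0
(flagged) otherwise. Blind two-observer scores are combined by
element-wise averaging. A per-cell pooling mode exists but is not the
default and is labelled as such.

## The synthetic-data generator

Because the quantities above are validated by recovery, the generator must
produce scenes whose ground truth is exact. Each scene is an elliptical
cell containing a tubule skeleton (random nodes joined to their 2–3
nearest neighbours, rasterized and dilated to ~2 px) and filled elliptical
sheet patches; structure intensities default to 3–4 ADU against a puncta
amplitude of 150 ADU, so puncta are the dominant bright class — the
regime in which spot-on-network thresholding is meaningful. Small puncta
(< 0.25 µm²) are placed on the skeleton and larger ones on sheets,
mirroring the geography these experiments report. Noise is Poisson on the
signal plus Gaussian read noise (SD 2 ADU), rounded to integer camera
ADU; the default peak SNR is ≈ 12.

Puncta are rendered as top-hat disks convolved with the Gaussian PSF
(σ = 0.7 px). A pure Gaussian profile cannot guarantee the footprint
contract — the area above a threshold $t$ of a Gaussian spot scales as
$\ln(\mathrm{amp}/t)$, so small threshold shifts rescale every area — whereas
a blurred disk has a steep, erf-shaped rim whose thresholded area is
insensitive to the exact level. The disk radius is calibrated per spot by
bisection so that the blurred spot's area above a fixed reference level
(0.17 × amplitude, corrected for the local structure pedestal) equals the
requested pixel count; the last ±1–2 pixels of rasterization residual are
resolved by nudging individual rim pixels fully below or well above the
reference level. The requested area is therefore met exactly, and truth
tables record both the requested and the rendered footprint area.

Requested areas are drawn per size class from ranges that stay clear of
the bin edges (B1 0.04–0.085, B2 0.15–0.215, B3 0.28–0.42, large 0.6–1.0
µm²), so that one-pixel segmentation noise cannot flip a bin — a property
the validation suite checks (≥ 95% of rendered puncta recover their
requested bin at SNR ≥ 10; measured ≈ 99% at the defaults). A programmed
fraction *f* of channel-1 puncta receives a channel-2 partner co-centred
within 1 px; all other cross-channel placements keep a minimum edge gap so
accidental overlaps are rare. One global seed drives per-object derived
seeds, so adding a punctum does not perturb earlier objects, and repeated
calls are bit-identical.

Time-lapse movies move puncta with per-frame displacement `speed ×
interval`, either along a fixed random direction or with a fresh direction
each step (so the programmed speed is the total-path speed in both
modes); trajectories that would leave the usable field are clamped and
flagged. FRAP traces are generated by the forward model above with
optional monitor-bleach decay and fractional Gaussian noise.

What the generator does **not** emulate: 3D optical sectioning,
out-of-focus haze, spectral bleed-through, uneven illumination, motion
blur, condensate fission/fusion, or biophysically realistic ER dynamics.
Passing recovery tests on these scenes demonstrates that the measurement
chain is correct and unbiased under its stated assumptions; it does not
certify performance on real images that violate them.

## Numerical choices and degenerate inputs

* Histograms: 256 bins regardless of bit depth; constant images raise an
  error (no threshold exists).
* Coordinates: (row, column) pixel indices with physical centroids at
  (index − 0.5) × pixel size in R's 1-based indexing; all arithmetic in
  double precision; images written as 16-bit integer TIFF round-trip
  exactly.
* Thresholding is per cropped cell by default (a per-field call is one
  argument away), matching the workflow's unit of analysis; cell masks are
  required inputs, and the generator always emits them.
* Empty denominators (no A objects, empty size bin, zero puncta) yield
  `NA` with an explicit flag, never silent zeros.
* The FRAP fit bounds $k \in [10^{-6}, 100]$ s⁻¹ and restarts are not
  needed in practice; non-convergence raises an error rather than
  returning a junk fit.
* Problem sizes in the validation suite — 256² px scenes, 60 puncta per
  channel and 10 seeds per colocalization fraction, 100 Monte-Carlo FRAP
  traces per recovery check, 3 × 30 cells × 20 seeds for the end-to-end
  contrast, 10⁴ null replicates for t-test calibration — were chosen as
  the smallest sizes at which binomial/Monte-Carlo error is comfortably
  inside each tolerance.

## Known limitations

Touching puncta are not split (no watershed), matching the source
workflow; at high densities counts are biased low. The literal AND-count
colocalization can exceed 100% by construction (flagged, per the printed
formula). Greedy linking can swap identities when two puncta approach
within one step length. The single-exponential FRAP model is
phenomenological: it summarizes recovery by half-time and plateau and
deliberately does not distinguish diffusion- from binding-limited
recovery.
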