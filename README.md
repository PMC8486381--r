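# erpuncta

Quantification of misfolded-protein puncta in endoplasmic-reticulum (ER)
fluorescence microscopy.

Misfolded secretory cargoes (mutant proinsulin and related prohormones)
concentrate into fluorescent puncta in the ER. Small puncta reside in ER
tubules, where the ER-phagy machinery can capture them; when degradation is
blocked or the ER shifts toward sheets, puncta enlarge. Testing that model
requires a reproducible measurement chain over confocal images, and this
package implements it end to end:

* **Segmentation** — Yen entropy auto-thresholding (256-bin histogram,
  deterministic tie-breaking), 8-connected particle analysis with calibrated
  areas, contour-traced perimeters, circularity filtering (0.5–1), and size
  classification into `<0.12`, `0.12–0.24`, `>0.24` µm² bins with an
  independent *large* flag at `≥0.5` µm².
* **Object-overlap colocalization** —
  `% coloc of A with B = #components(A AND B) / #components(A) × 100`,
  plus the bounded `object_hit` variant, size-stratified percents, and the
  area-overlap fraction `|A∧B|/|A|` used for lysosomal-delivery estimates.
* **Intensity** — background-subtracted site intensities, control-normalized
  relative intensities (control ≡ 1.0), fold overexpression.
* **Velocimetry** — nearest-neighbour linking of time-lapse detections and
  the total-path velocity `Σ step lengths / elapsed time` (not net
  displacement over time).
* **FRAP** — double (Phair–Misteli-style) normalization
  `N(t) = [W_pre/(W−bg)]·[(B−bg)/B_pre]` and single-exponential recovery
  fitting `N(t) = b₀ + (plateau − b₀)(1 − e^{−kt})`, reporting mobile
  fraction, half-time `ln2/k`, and the recovery percentage.
* **Statistics** — experiment-level aggregation (mean ± SEM over experiment
  means), Student's unpaired equal-variance t-test with significance stars,
  two-observer averaging.
* **Synthetic microscopy** — a ground-truthed scene/movie/trace generator
  (ER-like tubule network and sheets, calibrated-footprint puncta, Poisson +
  Gaussian read noise) used to validate every stage by parameter recovery,
  since raw images for such studies are typically not deposited.

## Worked example

Simulate a two-channel scene with a programmed 50% object colocalization,
segment both channels, and recover the fraction:

```r
library(erpuncta)

sc <- make_scene(scene_spec(seed = 7, channels = c("cargo", "receptor"),
                            n_puncta = 40, coloc_fraction = 0.5))
segA <- classify_size(segment_puncta(sc$images$cargo, sc$cell_mask,
                                     size_range_um2 = c(0.02, Inf)))
segB <- segment_puncta(sc$images$receptor, sc$cell_mask,
                       size_range_um2 = c(0.02, Inf))
segA
#> PunctaSet: 40 objects (21 discarded by filters), 0.08 um/px

percent_colocalization(puncta_mask(segA), puncta_mask(segB))
#> ColocResult [and_count]: A=40 B=40 AND=20 -> 50.0%
```

The 20 intersection objects over 40 cargo puncta recover the programmed
fraction exactly; the 21 discarded objects are sub-0.02 µm² noise specks
removed by the size filter, as in any particle-analysis workflow.

Fit FRAP kinetics from a noisy synthetic trace generated with a 13 s
half-time and 0.9 mobile fraction:

```r
fit_frap(normalize_frap(make_frap_trace(0.9, 13, noise_sd_frac = 0.02,
                                        seed = 3)))
#> FrapFit: mobile fraction 0.910, half-time 12.86 s, plateau 0.918 (recovery 91.8%)
```

Run the end-to-end demonstration — control cells form a large (≥0.5 µm²)
punctum with probability 0.15, knockout-like cells with probability 0.76;
three simulated experiments of 30 cells per condition are rendered,
segmented, and compared:

```r
demo_experiment(seed = 1)$summary
#>   condition percent_large      sem n_experiments
#> 1   control      18.88889 4.444444             3
#> 2        ko      78.88889 4.006168             3
# t = -10.03, p = 0.00056 (***)
```

The percentages estimate the generating probabilities (15% and 76%) within
binomial error, and the difference is detected at p < 0.001 with the
experiment as the unit of replication.

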