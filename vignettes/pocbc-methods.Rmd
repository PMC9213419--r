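---
title: "Models and methods behind pocbc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pocbc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pocbc` models an image-based point-of-care complete blood count (CBC)
workflow end to end: a hemocytometer chamber is imaged, cells are detected
and classified, counts become concentrations through the dilution and the
counted volume, hemoglobin is read colorimetrically from a reagent strip,
and the whole pipeline is judged with the statistics battery used in
clinical method validation. Because no public image data exist for this
class of device, the package's first-class component is a synthetic-data
generator with known ground truth; every downstream stage is exercised
against that truth.

## The counting model

A hemocytometer counts cells in a known volume of diluted blood. With an
evaluation area of 1 mm^2 and the conventional improved-Neubauer depth of
0.1 mm, the counted volume is 0.1 mm^3 (0.1 uL). The kit dilutes whole
blood 179-fold for the erythrocyte/platelet chamber (chamber 2) and 9-fold
for the leukocyte chamber (chamber 1, where red cells are lysed), so

    concentration = count x dilution / (area x depth).

A normal red-cell concentration of 4.5 x 10^6 per mm^3 therefore yields
about 2514 red cells in the counted field, a leukocyte concentration of
7 x 10^3 per mm^3 about 78 leukocytes, and a platelet concentration of
250 x 10^3 per mm^3 about 140 platelets. These expected counts matter
because counting statistics bound the attainable precision: the CV of a
Poisson count is 1/sqrt(N). At 0.1 uL this floor is about 2% for red
cells but 7-16% for platelets and leukocytes across their clinical
ranges; no detector can beat it.

## The synthetic-data generator

`sample_patient()` draws a virtual patient from a cohort mixture (82%
normal, 2.2% thalassemia, 6.6% anemia, 9.2% infection; 58% female). The
per-condition analyte distributions are not published anywhere, so the
package documents its own: normal values are truncated Gaussians centered
in the sex-specific reference intervals; anemia places HB below the
sex-specific lower bound with smaller, more dispersed red cells;
thalassemia combines small red cells (mean diameter ~5.9 um) with an
elevated red-cell count; infection raises WBC above the upper bound with
a neutrophil-shifted differential and immature cells present with
probability 0.35. Platelet clumps occur in 3.8% of samples, matching the
positivity rate of point-of-care flagging studies. Passing tests on this
cohort demonstrates that the pipeline recovers what the generator encodes
(Poisson-placed, additively rendered cells with class-specific size and
hue); it does not certify behavior on real stained blood, where texture,
debris, and focus variation add failure modes the generator deliberately
omits.

`render_chamber()` places a Poisson number of cells of each class
uniformly over the field (the projected composite of a settled chamber)
and draws each as a radially symmetric Gaussian-profile disc whose
half-maximum diameter is the cell diameter. Red-cell diameters follow the
panel's mean and CV (normal: 7.4 um, CV 0.10); other classes use fixed
class means. Each cell's amplitude carries 5% multiplicative stain
jitter, clipped at +/-25%. Colors stand in for the differential stain;
the immature-cell stain is deliberately placed outside the convex hull of
the mature-class chromaticities so that no superposition of mature cells
can imitate it - a property a real stain designer would also want.
Background is flat at 0.03 with 0.01 per-pixel Gaussian noise; there is
no optical point-spread or vignetting model, because the detection
contract, not optics, is under test. Intensities are linear and additive,
so overlapping cells sum - the central difficulty the detector must
handle.

`render_strip()` models the hemoglobin strip as a saturating-exponential
(Beer-Lambert-like) map from HB to the mean green-channel value of the
reading window, `g(hb) = 0.05 + 0.90 exp(-hb / 9)`, strictly decreasing
over 4-19 g/dL. Replicate variability is a per-strip additive offset
(SD 0.0047 on the window mean) calibrated so that replicate HB
measurements at 14 g/dL show a CV near 1.6%, the repeatability level
reported for strip-based HB in this device class.

`simulate_reference_analyzer()` is the comparator: each analyte is
perturbed by a 2% proportional CV by default, derived indices are
recomputed from the perturbed HB and RBC, and nonpositive values are
clipped to a small positive floor with a warning.

## The reference detector

The paper-described detector is a trained network whose weights are not
public; `pocbc` ships a deterministic classical detector that honors the
same contract (boxes, class probabilities, confidence, tiled processing,
IoU deduplication). Stages:

1. **Tiling.** The field is cut into overlapping tiles (default 768 px,
   48 px overlap - more than the largest cell diameter), so every cell is
   seen whole by at least one tile. Detections whose region touches an
   interior tile seam are dropped; the neighboring tile re-detects them,
   and duplicates are merged by IoU.
2. **Chromatic projection.** Each projection is a linear combination of
   the RGB channels in which one cell family dominates. In chamber 2 the
   red-cell and platelet projections are mutually orthogonalized
   (Gram-Schmidt in color space), so a platelet sitting on top of a red
   cell appears on a near-zero background instead of being swallowed by a
   negative shadow.
3. **Segmentation.** Gaussian smoothing (sigma 1 px, replicate boundary -
   circular FFT convolution would wrap bright border cells into ghosts at
   the opposite edge), a fixed threshold of 0.12 above the tile
   background median, and an intensity-basin watershed.
4. **Overlap resolution.** Additive Gaussian profiles lose their
   two-maxima structure when two cells approach closer than about their
   diameter, so watershed alone cannot reach the required accuracy at
   2500 cells per field. Three model-based cues close the gap:
   *elongation* (the principal-axis second-moment ratio of a merged pair
   is >= 1.4, while single-cell basins, including basin halves cut at a
   watershed saddle, stay below ~1.35); *peak multiplicity* (fully
   superposed cells sum their peaks, and a single cell's jitter is
   bounded at 1.25x, so a peak at >= 1.5x the class prototype is
   unambiguous); and a *fragment guard* (a genuine cut leaves about one
   cell's visible flux on each side; cutting a lone cell leaves
   half-units, so such cuts are vetoed). Flagged regions are cut
   recursively perpendicular to their principal axis; pieces inherit the
   chain axis because the cut itself makes any piece look elongated along
   the cut line. Neighboring regions' modeled Gaussian tails are
   subtracted before shape statistics are computed, so crowding does not
   masquerade as elongation. The per-tile single-cell scale is
   self-calibrated as a lower quantile of the region width statistic
   (the median is biased upward by multi-cell regions).
5. **Sizing.** The equivalent diameter comes from the flux/peak ratio of
   the Gaussian profile model, corrected for the sub-threshold tail; cut
   pieces instead use the variance perpendicular to the cut axis, which a
   half-plane cut leaves untouched, corrected for threshold truncation.
6. **Classification.** Nearest prototype in (chromaticity, log-diameter)
   space with softmax-normalized scores; the color feature uses the
   near-peak core of the region so that a merged pair's hue is not a
   class mixture. A region whose best label is the immature class is
   additionally tested against every two-class superposition (color and
   summed peak jointly); if a mixture explains it clearly better, the two
   mature cells are emitted instead.
7. **Merging.** Duplicates are the connected components of the
   IoU >= 0.5 graph (threshold configurable); the highest-confidence
   member survives, ties broken by larger area, then lexicographic box
   origin - fully deterministic.

On default-density fields this detector reaches ~99% recall and
~99.6% precision against the generator truth with class counts unbiased
to within a few tenths of a percent - the property the quantitation
stage's unbiasedness tests actually require. The residual misses are
dense multi-cell tangles, the same configurations a human double-checker
would resolve on a real device.

## Quantitation

Counts become concentrations through the dilution/volume formula above.
The 4-part differential (neutrophils, lymphocytes, monocytes, combined
eosinophils/basophils - the scarcest populations are reported jointly,
as 3-part analyzers also do) is computed over mature cells only; immature
detections surface exclusively through flagging. HB is read by inverting
the fitted calibration curve. The calibration fit profiles the
saturating-exponential's decay scale: for fixed scale the model is linear
in its remaining coefficients, so the profiled residual sum of squares is
minimized in one dimension - robust where iterative exponential fitters
stall on noiseless standards. Non-monotone standards are refused, and
values outside the calibrated span are clamped and flagged rather than
extrapolated.

Hematocrit, MCV and MCH are not measured; they are estimated from HB and
RBC, mirroring the device's design. The default estimator is the
classical rule of three (HT = 3 x HB) with the standard index
definitions MCV = 10 x HT / RBC and MCH = 10 x HB / RBC; it is a named,
swappable strategy because the device's actual correlation model is
unpublished. Under the default, MCV/MCH = 3 identically - a deliberate
structural property, not a bug.

## Flagging

Three flag families, with documented default thresholds because none are
published: microcytosis below a mean equivalent diameter of 6.4 um,
macrocytosis above 8.4 um, anisocytosis above a diameter CV of 0.16
(normal cohorts sit near 0.10-0.12 after measurement noise); platelet
clumping by single-linkage clustering of platelet centers at 1.5 mean
platelet diameters with a minimum cluster of 3; immature cells at one or
more credible immature detections, where credible means at least 11 um -
fragments of split mature cells are far smaller than genuine precursors.
Morphology flags require at least 200 red-cell detections; with fewer the
flags are NA with a reason, never silently negative.

## Validation statistics

The battery mirrors standard method-comparison practice: Bland-Altman
bias with 1.96 x SD limits of agreement (sample SD, n-1; differences are
test minus reference), Pearson correlation, a two-sided paired t test,
Passing-Bablok regression (shifted median of pairwise slopes with the
K-shift for slopes below -1, ties discarded per the original procedure,
rank-based 95% intervals), a fitted-parameter Kolmogorov-Smirnov
normality check (the version standard statistics software reports; it is
conservative, which the tests account for), precision summaries against
the EFLM allowable-imprecision goals (PLT < 10%, RBC < 4%, HB < 3.6%,
WBC < 15.9%), and in/out-of-reference-range concordance with Cohen's
kappa and balanced accuracy, where "outside the range" is the positive,
disease-predictive class.

## Numerical and design choices

* **Seeding.** One root seed; independent streams derive via
  counter-based splitting (`split_seed`), and every stochastic function
  restores the caller's RNG state. Identical seeds give byte-identical
  images and CSVs.
* **Coordinates.** 0-based continuous pixel coordinates, half-open boxes,
  IoU on real-valued areas.
* **Storage.** Images are written as 16-bit TIFF at a fixed linear
  intensity scale of 4 (superposed cells exceed 1), with a JSON sidecar
  carrying geometry and ground truth; unit tags travel with every CSV and
  a mismatch on re-import is an error, not a rescale.
* **Precision-study ranges.** The default simulated targets sit in the
  clinical decision region of each analyte (RBC 3.5-5.75 x 10^6/mm^3,
  WBC 5-11 x 10^3/mm^3, PLT 200-425 x 10^3/mm^3, HB 8-17 g/dL). At the
  kit's 0.1 uL counted volume the Poisson floor exceeds the EFLM goal
  for platelet and leukocyte concentrations far below these ranges
  (e.g. PLT at 70 x 10^3/mm^3 has a floor of ~16% against a 10% goal),
  so a field instrument of this geometry cannot meet the goals there -
  a physical limitation of the counted volume, stated here rather than
  hidden in a threshold.
* **Composite precision samples.** Each simulated precision level sets
  all four analyte targets in one virtual sample, so a single rendered
  chamber serves every analyte it carries - as a physical sample would.
* **Problem sizes.** The test-suite simulations use 200-replicate runs at
  reduced-area chambers for bias/precision properties (identical
  per-area densities, hence identical overlap and crowding statistics),
  full- and half-size fields for the detection contract and
  flag-recovery checks, and 10 replicates per range for the simulated
  precision study - the same replicate count the clinical protocol uses.

## Known limitations

The generator's appearance model is far cleaner than real microscopy:
no debris, no focus gradients, no staining heterogeneity beyond scalar
jitter, no red-cell rouleaux. The detector's accuracy figures therefore
describe the contract on synthetic fields, not clinical performance.
EOS/BAS and monocyte counts rest on a handful of cells per field at this
counted volume, so their sample-level correlation with a comparator is
intrinsically modest - the same effect the clinical study observed for
EOS/BAS. The HT/MCV/MCH estimator reproduces the structure (estimated,
not measured) of the device without claiming its proprietary
coefficients.
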