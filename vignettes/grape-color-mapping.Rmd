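---
title: "Quantifying and mapping grape berry color from cluster images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and mapping grape berry color from cluster images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapecolor)
```

## The problem

Grape skin color is controlled by two major genes regulating anthocyanin
synthesis, but visual scales such as OIV descriptor 225 (six classes from
green-yellow to blue-black) compress continuous variation into a handful of
categories and hide the contribution of minor loci. `grapecolor`
implements a photographic alternative: clusters are photographed against a
white backdrop, images are color corrected, berry pixels are isolated by a
supervised color classifier, and the average berry color is expressed in
several color spaces. Those quantitative traits are then used as phenotypes
for QTL mapping in an F1 pseudo-testcross, where markers heterozygous in
one parent segregate 1:1 and each parental map is scanned separately.

## Color correction

Cameras and lighting drift; a reference card photographed in the scene
anchors the colors. We fit a least-squares affine map (a 3x3 matrix plus an
offset) from the measured card patch colors to their published sRGB values
and apply it per pixel, clipping to the valid range. The fit is performed in
the stored, display-referred pixel values (the whole downstream pipeline is
defined on display-referred images, so correcting in linear light would be
inconsistent with the extraction stage). With at least four
non-degenerate patches the affine map is identified; the bundled 24-patch
ColorChecker Classic reference is the default. Patch locations are supplied
by the user as pixel boxes -- automatic card detection is out of scope.
Images are handled as 8- or 16-bit PNG/TIFF with intensities on [0, 1]
internally (divide by 2^depth - 1); quantization on write rounds halves
away from zero so that write/read round trips are bit-exact. 16-bit output
uses TIFF, matching the usual camera-export format for that depth.

## Segmentation

The classifier mirrors the manual workflow of training-set-based food
color inspection tools: the user picks 3x3 pixel squares representative of
berry, rachis and background; each pick's mean color becomes a prototype;
and every pixel takes the class of its nearest prototype in Euclidean RGB
distance. Several picks per class give multi-prototype classes, which is
how light-colored clusters with highlights and shaded regions are handled.
Exact distance ties are broken by class priority (berry, then rachis, then
background -- berries being the trait of interest), then by pick order, so
segmentation is fully deterministic. No morphological post-processing is
applied. Accuracy is quantified against reference masks with
confusion-matrix metrics; `interior_only = TRUE` scores only pixels whose
3x3 neighborhood is single-class in the truth, excluding the one-pixel
boundary band where any pixel classifier is ambiguous.

## Color traits

Eleven traits summarize one cluster image: mean R, G, B of berry pixels
(0-255 scale); CIELAB L*, a*, b* (sRGB decoding, D65 two-degree observer,
white point Xn = 95.047, Yn = 100, Zn = 108.883); hue (degrees), saturation
([0, 1]) and intensity (0-255) from the arccos (Gonzalez-Woods) HSI
formulation; weighted greyscale (relative luminance, 0.299 R + 0.587 G +
0.114 B); and average greyscale (the channel mean). Intensity and average
grey are the same number by definition and are reported identically.

Two conventions are worth stating because they are genuinely open choices:

* **Mean-then-convert.** The berry-pixel RGB is averaged first and all
  other traits are derived from that single mean color. Averaging per-pixel
  hue is ill-defined across the 0/360 wrap, and the workflow's intent is
  "the average color of the cluster"; mean-then-convert makes every trait a
  function of one well-defined color.
* **Arithmetic hue averaging across images.** The twelve image summaries of
  a genotype (three clusters, four rotations) are averaged arithmetically,
  hue included. Berry hues within a genotype are tightly grouped far from
  the wrap point, so circular and arithmetic means agree in practice.

## QTL scans

Genotype probabilities along each chromosome come from a two-state hidden
Markov chain: transitions follow the Haldane map function
r = (1 - e^(-2d/100))/2 (no interference), emissions allow a symmetric
genotyping error rate (default 1e-4), and forward-backward gives the
posterior P(B allele) at every marker and at pseudomarkers on a regular
grid (default 1 cM). Three scan engines share these probabilities:

* **Simple interval mapping** by Haley-Knott regression: regress the trait
  on P(B); LOD = (n/2) log10(RSS0/RSS1). Deterministic and closed-form,
  and identical to the usual mixture-model scan at fully typed markers.
* **Nonparametric scan** for nonnormal traits: the trait is ranked
  (mid-ranks for ties) and the two-group Kruskal-Wallis statistic is
  extended to partial genotype information by using P(B) as each
  individual's group weight; LOD = statistic / (2 ln 10). At a fully typed
  marker this reduces exactly to the classical Kruskal-Wallis test,
  including the tie correction; the scan is invariant under monotone trait
  transformations.
* **Binary scan** for noir/nonnoir: logistic regression of the indicator
  on P(B), LOD = (LL1 - LL0)/ln 10, fitted by Newton iterations vectorized
  across positions. Complete separation gives a finite LOD bounded by the
  null log-likelihood and is flagged rather than inflated.

Significance uses permutation thresholds: phenotypes are shuffled against
genotypes (seeded, so thresholds are reproducible), and the 95th percentile
of the genome-wide maximum LOD -- or of each chromosome's maximum for
chromosome-wide tests -- is the alpha = 0.05 threshold. Each trait is
thresholded separately at alpha = 0.05 with no correction across traits.
Reported QTL carry the nearest named marker (ties toward the lower
position), a 1.5-LOD support interval (the contiguous run around the peak
within 1.5 LOD of the maximum, expanded one scan position outward and
clamped at the chromosome ends -- the expansion makes the interval
conservative on a discrete grid), and the percent variance explained
implied by the LOD, PVE = 100 (1 - 10^(-2 LOD / n)).

Individuals missing the scanned trait are dropped per trait. Scans of the
maternal and paternal maps are separate, mirroring how pseudo-testcross
QTL are reported per parental map.

## What the simulators emulate

`simulate_cross()` draws gametes per parental map under the Haldane model.
The default scenario is a 110-individual F1 with three 100-cM chromosomes
per parental map (markers every 5 cM), a major binary noir locus at 63 cM
on maternal chromosome 2 with penetrance 0.98, two minor additive loci
(effect 0.12 on a latent darkness scale), residual SD 0.117 and 5% missing
genotypes. With these values the major locus accounts for about 75% of the
latent variance (effect 0.5 on the darkness scale gives QTL variance
0.0625 of a total 0.0833). Darkness is mapped to berry RGB through fixed
anchors spanning green-yellow, rose, red, dark red-violet and blue-black --
the OIV 225 palette narrative -- and all eleven traits are derived from
that RGB with the package's own colorimetric conventions, so simulated
phenotypes and image-extracted phenotypes live on the same scale. OIV
scores follow fixed darkness thresholds; noir individuals always score 6.

`generate_cluster_image()` renders a white backdrop, a branched rachis
polyline, and overlapping berry disks with per-berry color jitter, mild
radial shading and occasional specular highlights, returning the image
together with its ground-truth label mask. `render_genotype()` produces
twelve images per genotype (emulating three clusters at four rotations as
independent draws -- no 3-D geometry), with berry base colors driven by the
genotype's simulated mean RGB.

What the simulators deliberately do not model: photorealistic texture,
shadows and inter-berry occlusion boundaries with mixed pixels, bloom or
wax on the berry surface, lens vignetting, and developmental or
environmental color gradients within a cluster. Passing tests on rendered
data therefore demonstrate the correctness of the pipeline's computations
and its statistical calibration, not field-readiness of the default
training picks for arbitrary photographs.

## Numerical choices and degenerate inputs

* Quantization: round-half-away-from-zero, stated so round trips are
  testable; image writers that truncate are compensated by a half-LSB
  nudge of pre-quantized values.
* Chi-square segregation tests are Pearson goodness-of-fit without
  continuity correction: observed counts of 66/55 give a statistic of
  exactly 1.000 and p = 0.317, which is the convention consistent with
  published 1:1 tests of this design.
* PCA standardizes traits (correlation-matrix PCA) because the traits mix
  0-255, degree and unit scales; component signs are fixed by making each
  component's largest-magnitude loading positive.
* Between-year correlation subsets: a genotype counts as noir (or nonnoir)
  only if it is that class in both years; class-switching genotypes stay in
  the "all" set. Correlations flag p >= 0.05 as not significant.
* Degenerate cases error early and by name: constant traits, one-class
  binary traits, missing training classes, rank-deficient color-card fits,
  constant PCA columns, empty berry masks.
* Perfect fits: zero residual variance in SIM is capped and flagged;
  logistic separation is flagged with its (finite) likelihood-bound LOD.
* Achromatic pixels get hue 0 with an explicit flag; saturation at black
  is defined as 0.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script validate the statistics at
simulation sizes chosen to make sampling noise small relative to the
quantities asserted: null threshold calibration uses 200 replicate
datasets (n = 110, two chromosomes of 20 markers, 200 permutations each);
major-QTL recovery uses 100 replicates of the default scenario with
200-permutation thresholds; segmentation accuracy pools 16 rendered
clusters per color class; end-to-end color recovery uses 50 genotypes with
12 images each. All are seeded and reproducible.

## Known limitations

* The internal classification rule of the segmentation tool the workflow
  is modeled on is unpublished; nearest-prototype in RGB is a documented
  stand-in that matches the described user interaction (pick representative
  colors, classify by color).
* One correction transform is fitted per image/card pairing; per-session
  batch correction is composed by the caller.
* The scans are single-QTL models; multi-QTL fits, composite interval
  mapping and epistasis are out of scope, as is linkage-map construction
  (maps are inputs).
* Hue arithmetic near the 0/360 wrap is only safe because berry hues are
  far from the wrap; reusing the colorimetry module for hue-diverse scenes
  would need circular statistics.
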