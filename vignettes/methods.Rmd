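---
title: "Quantification methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjquant)
```

nmjquant quantifies fluorescence microscopy of hiPSC-derived myotube and
myotube/motor-neuron cocultures: how far a culture has differentiated, how it
responds to acetylcholine, what its acetylcholine-receptor (nAChR) clusters
look like, and how fast surface receptors are internalized. This vignette
documents the measurement models, the parameters that matter, and the design
decisions taken where the workflow it formalizes was manual or ambiguous.

## The positivity threshold

Every "is this cell positive for marker X" call uses one rule: background
fluorescence is measured in a handful of regions, pooled at pixel level, and
the threshold is

$$T = \mu_{bg} + k\,\sigma_{bg}, \qquad k = 2 \text{ by default},$$

with *strictly greater than* counting as positive. The original workflow
chose five background boxes by hand; `estimate_background()` instead takes
the five darkest non-overlapping 32 px tiles, a reproducible surrogate that
lands on the same statistics when the background is stationary (explicit
region lists are accepted for parity). `sigma` is the pooled pixel SD over
the sampled regions, not the SD of the five region means — the latter shrinks
with region size and would push `T` to within a fraction of a noise SD of the
mean.

## Nuclei, muscle area, and the debris rule

`segment_nuclei()` is a classical instance segmenter: Gaussian smoothing
(sigma 2 px), a global Otsu cut, hole filling, then a distance-transform
watershed to split touching nuclei. A learned backend (e.g. an external
Cellpose server) can be plugged in through `backend=`, but nothing in the
package or its tests requires model weights. Otsu always returns *some*
split, so a separability guard (between-class over total variance, at least
0.8) returns an empty label map on images that contain no nuclei at all; a
unimodal Gaussian tops out near $2/\pi \approx 0.64$ on that statistic, well
clear of the bound.

Muscle (MYH1 or α-actinin) area runs median filtering (radius 2 px),
the threshold rule, connected components, the debris filter, and sums the
surviving region areas. The background model is estimated on the *unfiltered*
channel: the threshold is defined against acquisition noise, while the median
filter's job is only to keep speckle out of the mask. Estimating sigma after
filtering compresses the noise and drags `T` down to where edge pixels
bleed into the mask (a few percent of area on oblique myotubes).

The debris rule deletes a region iff its area is below 500 µm² *and* its
circularity ($4\pi A/P^2$) lies in [0.3, 1.0] — small-and-round, the
signature of debris, while small elongated fragments of real myotubes
survive. The conjunctive reading is the default; `mode = "area_only"` is
available because the prose rule it encodes parses both ways.

## Geometry estimators

Pixel-counting areas and naive boundary lengths do not coexist happily:
a staircase perimeter overestimates a disk's boundary by 4/π and would push
disk circularity to ~0.6. The package fixes one estimator set and documents
it:

* **Perimeter** — Moore-traced boundary chain with corner-corrected weights
  (0.948 per axial step, 1.340 per diagonal). Disk circularity then lands at
  1.00–1.02 across radii 8–64 px.
* **Circularity** — $4\pi A/P^2$, clamped to [0, 1] (tiny regions can
  otherwise exceed 1 under any corrected estimator).
* **Solidity** — region pixel count over the pixel count of the rasterized
  convex hull of the region's pixel centers. Digitally convex regions score
  exactly 1 by construction. The alternative (polygon area of a corner hull)
  biases digital disks to ~0.97, which would leak into the plaque-versus-
  fragmented contrast the solidity axis exists to measure.

These conventions matter most near the debris filter's 0.3 circularity
boundary and for small clusters; they are fixed package-wide and tested
against an independent gift-wrapping hull oracle.

## Myogenic readouts

With nuclei instances, a marker channel, and the muscle mask in hand, the
readouts are simple ratios, and each one guards its degenerate case
explicitly (zero nuclei and zero area yield an NA sentinel or an error, never
a silent 0/0):

* percentage of marker-positive nuclei (per-nucleus mean vs. `T`);
* differentiation index — percentage of all nuclei whose centroid falls in
  the muscle mask (centroid containment is the deterministic stand-in for
  by-eye membership; a fractional-overlap rule is available);
* MFI of positive cells — mean of per-region means, i.e. cell-level
  averaging, not pixel-level (flagged as an interpretation choice);
* myonuclear domain — total muscle area over myonuclei count, so
  `mnd * n == area` holds to machine precision;
* cluster density per 1000 µm² of muscle and αBGT integrated density
  (intensity sum × pixel area).

## Calcium kinetics

Traces are ROI means per frame. The baseline $F_0$ averages the 6 s window
ending at the stimulus — frames with $t \in (t_{stim}-6, t_{stim}]$, which at
a 2 s interval and a 60 s stimulus is exactly the frames at 56, 58 and 60 s.
The normalization is

$$\Delta F/F_0 = \frac{F - F_0}{F},$$

dividing by $F$, not $F_0$. That is the formula the source workflow printed,
kept as the default even though the symbol suggests otherwise; the
conventional $(F - F_0)/F_0$ is one flag away (`normalization = "f0"`).
Both are invariant under multiplicative gain, and the true peak of a
generator transient with baseline $F_0$ and amplitude $A$ is $A/(F_0+A)$
under the default.

The peak is the single-frame post-stimulus maximum (no smoothing, so no
amplitude bias; a 3-frame rolling mean is available for noisy data and off in
all tests). Responder calls and the sham-addition check compare against
3× a noise floor estimated as $\mathrm{MAD}(\Delta F/F_0\ \text{first
differences})/\sqrt{2}$ over the whole trace. A 3-frame baseline SD would
make a 3-sigma rule a coin flip; the differenced MAD ignores the slow
transient, is robust to isolated artifacts, and uses every frame. The sham
check passes when the maximum between sham addition and stimulus stays under
that threshold — the control that fluid addition alone does not trigger
calcium release.

## Cluster morphometry

Clusters are measured on max-z projections, cropped one cluster per ROI.
The reproducible default threshold is Otsu on the crop (the original
workflow thresholded by eye; per-ROI manual thresholds are accepted), and
only the largest component is kept. Side-view clusters distort projected
shape, so `flag_en_face()` operationalizes the by-eye "en face only" rule as
a z-extent/lateral-extent ratio at most 0.5, with the z-extent read from the
in-footprint intensity profile at half dynamic range. No minimum cluster
size is imposed beyond 1 µm² (none was stated; config-exposed).

## Pulse-chase puncta and the volumetric label pipeline

The pulse-chase readout is old-label puncta per 1000 µm³ of myotube. The
stack is cropped to a 40 µm length of myotube centered on the surface
cluster (clamped with a warning at stack borders). Myotube volume comes from
the new-label outline: saturated contrast stretch (0.5% tails — without
saturation the rare, very bright surface cluster dominates the threshold),
Otsu, largest 3-D component, and hole filling across Y-Z cross-sections,
where a tube cut is an annulus. Puncta detection replaces manual counting
with Gaussian smoothing at the punctum scale, 26-neighbourhood local maxima
above 5 robust SDs of the in-mask background, a merge radius of 0.5 µm, and
exclusion of both the surface-cluster zone (cluster mask dilated 0.5 µm —
whether the original counts excluded that footprint is unstated, so the zone
is explicit and configurable) and a 2-voxel border margin where padded
smoothing makes maxima unreliable.

The presynaptic-marker (vAChT) cleanup pipeline runs, in order: global Otsu;
3-D opening then dilation with radius-1 balls *in voxel units* (anisotropy
deliberately ignored, matching radius-in-voxels semantics of the ImageJ
ecosystem); 6-connected component labeling; an *inclusive* keep-window of
[1000, 115000] voxels (the prose excludes strictly smaller and strictly
larger); per-slice 2-D dilation by 2 px; Otsu re-binarization of the label
volume; and zeroing of all signal outside the mask. Component sizes are
counted at labeling time, i.e. after the first morphology block and before
the final dilation.

## Statistics selection

`select_and_run()` encodes the test-selection tree: per-sample Shapiro-Wilk,
then for two groups an F-test choosing Student's vs. Welch's t, with Welch
as the fallback when normality fails (the source procedure names only
"Welch's correction" as its alternative; Mann-Whitney is a flag). For three
or more groups, one-way ANOVA with Tukey HSD when all samples are normal and
Bartlett's test (the k-group generalization of the two-group F-test) is
quiet, Kruskal-Wallis otherwise. Screening uses the same alpha as the main
test. One consequence worth stating: under a clean normal null the Student
branch is taken with probability ≈ 0.95² × 0.95 ≈ 0.86, not 0.95 — the
screening steps spend error rate. The overall two-group type-I error stays
at nominal 5% because Student and Welch agree closely when both could apply.
Stars follow the strict ladder `*` < 0.05, `**` < 0.01, `***` < 0.001,
`****` < 0.0001. No multiplicity correction is applied across distinct
readouts; Tukey corrects within an ANOVA only.

Degenerate inputs are handled explicitly: identical values in every group
return p = 1 with a labeled "no variance" result, and internally-constant
samples fall back to ranks rather than crashing on an undefined t.

## The synthetic generator: what it emulates and what it does not

Every recovery claim in the test suite is against `scene_spec()` scenes with
exact ground truth: non-overlapping elliptical nuclei (bounded eccentricity,
rejection-sampled, placement failure is an error), capsule-shaped myotube
bands, Bernoulli marker positivity (so replicate fields vary binomially, as
wells do), flat-intensity structures plus additive Gaussian camera noise
rounded to integer AU (a Poisson shot-noise flag exists), cluster masks
built to solidity/area targets (interior-hole carving for single lobes —
the hull, and hence the removal budget, is then exact; ring-of-lobes
bisection for fragmented shapes), calcium movies with a linear rise and
exponential decay, and pulse-chase cylinders with Poisson-count puncta.

Defaults are fixed at realistic study conditions: 0.28 µm pixels for 2-D
fields, 0.56 µm and 2 s frames for calcium, 60 nuclei and 3 myotubes per
384 px field, background 100 ± 5 AU, marker levels 600/105 AU (negatives
carry faint near-background autofluorescence — a negative population parked
far above `T` would make the threshold rule trivially wrong for reasons that
have nothing to do with the measurement), stimulus at 60 s with a sham
addition at 30 s, puncta at 5 per 1000 µm³. Pulse-chase stacks default to
0.2 µm / 0.5 µm voxels over 96 px fields rather than the 0.045 µm / 0.3 µm
acquisition geometry — the measured quantities are calibration-normalized,
so recovery is tested at a tractable problem size and the unit arithmetic at
the acquisition calibration is tested directly.

What the generator does *not* emulate: optical PSF blur, photobleaching,
intensity gradients, overlapping nuclei, or realistic neurite morphology.
Passing recovery tests therefore demonstrates that the measurement chain is
correct and unbiased on images that satisfy its assumptions — not that
segmentation is robust to out-of-focus or crowded real-world fields.

## Numerical choices

* Images are stored as integer AU in [0, 65535]; 16-bit TIFF pages plus a
  JSON sidecar give exact round trips (`read_image` refuses to guess missing
  calibration; overrides come from arguments or YAML).
* Canonical array order is (Y, X, C, Z, T); every constructor permutes into
  it.
* Coordinates are 0-based pixel centers in physical units.
* All generators take an explicit seed, restore the caller's RNG state, and
  are bit-reproducible; the pipeline derives per-image child seeds from the
  global seed by a fixed affine map so stages can be rerun independently.
* Watershed tolerance defaults to 1; regions under 20 µm² are not counted
  as nuclei (well under any real nucleus at these calibrations).
* Problem sizes in the test suite (384–448 px fields, 96 px stacks, 20-seed
  sweeps, 2000-replicate null simulations) were chosen as the smallest sizes
  at which the estimated rates have comfortably narrower uncertainty than
  the tolerances they are checked against.

## Known limitations

Circularity and solidity are estimator-dependent at small region sizes; the
fixed conventions above are calibrated on disks ≥ 8 px radius. The automatic
background sampler assumes at least five tiles of pure background exist.
The en-face ratio bound (0.5) and the puncta exclusion radius (0.5 µm) are
operationalizations of by-eye rules and should be treated as tunable
conventions, not measured constants. The decision-tree statistics inherit
the usual caveats of screening-then-testing; the package reports the full
decision path so the choice is always auditable.
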