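# nmjquant

Quantitative image analysis for hiPSC-derived myotube and neuromuscular
junction (NMJ) cocultures.

Human iPSC-derived skeletal myotubes, alone or cocultured with motor
neurons, are characterized by a recurring set of fluorescence-microscopy
readouts: how many nuclei express myogenic markers, how much of the culture
is muscle, how myotubes respond to acetylcholine, what their acetylcholine
receptor (nAChR) clusters look like, and how quickly surface receptors are
internalized. In practice these measurements are often assembled from manual
ImageJ steps that are hard to reproduce. nmjquant implements the full chain
as tested, seeded, scriptable R functions, for labs running hiPSC myogenesis
or NMJ-on-a-dish experiments.

## What it computes

* **Marker positivity** — per-nucleus calls against the background
  threshold *T* = μ_bg + 2σ_bg (strictly greater); percentage of
  MyoG-positive nuclei; mean fluorescence intensity of positive cells.
* **Differentiation index** — percentage of all nuclei whose centroid lies
  within MYH1-positive muscle, after nuclei instance segmentation
  (smoothing → Otsu → watershed) and muscle segmentation (median filter →
  threshold → components → debris filter: delete iff area < 500 µm² *and*
  circularity ∈ [0.3, 1]).
* **Myonuclear domain** — total muscle area / myonuclei count (µm² per
  nucleus); cluster density per 1000 µm² and αBGT integrated density.
* **Calcium kinetics** — ROI traces from Fluo4 movies with
  ΔF/F₀ = (F − F₀)/F, F₀ averaged over the 6 s before stimulation; peak,
  time-to-peak, responder and sham-addition checks; percent peak reduction
  under receptor blockade.
* **Cluster morphometry** — area, perimeter, perimeter/area and solidity of
  single nAChR clusters on max-z projections, with en-face selection.
* **Pulse-chase turnover** — endocytosed puncta per 1000 µm³ of myotube
  volume in two-color αBGT stacks, plus the volumetric label-filter pipeline
  for presynaptic (vAChT) signal (Otsu → 3-D opening/dilation → components →
  inclusive 1000–115000 voxel window → dilation → re-mask).
* **Statistics** — the Shapiro-Wilk / F-test decision tree selecting Student
  t, Welch t, ANOVA + Tukey or Kruskal-Wallis, with the full decision path
  recorded and strict significance stars.
* **Synthetic microscopy** — a calibrated generator (fields, calcium movies,
  pulse-chase stacks, cluster shapes) with exact ground truth; every
  measurement above is validated by parameter recovery against it.

## Worked example

```r
library(nmjquant)

# a synthetic day-4 myotube field with known ground truth
field <- generate_myotube_field(scene_spec(rng_seed = 42))
myogenic_readout(field$image)
#> n_nuclei                60.00
#> pct_myog_positive       55.00
#> differentiation_index   28.33
#> mfi_myog_positive      593.03
#> total_muscle_area_um2 3886.99
#> n_myonuclei             17.00
#> mnd_area_um2           228.65
field$truth$pct_positive        # 55    -> recovered exactly
field$truth$muscle_area_um2     # 3874  -> recovered within 0.4%
```

60 nuclei were segmented, 55% call MyoG-positive (the generator drew 55%),
28.3% of nuclei sit inside MYH1-positive muscle, and each myonucleus
supports ~229 µm² of muscle area.

```r
# calcium response to agonist at t = 60 s, sham fluid addition at 30 s
mv <- generate_calcium_movie(scene_spec(field_px = 96, pixel_size_um = 0.56,
                                        rng_seed = 42))
tr <- extract_trace(mv$image, mv$roi_labels == 1, t_stim = 60, t_sham = 30)
summarize_transient(tr)
#> <transient_summary> peak dF/F0 = 0.3342 at 64 s (baseline SD 0.00443; responder)
sham_response_check(tr)         # TRUE: fluid addition alone caused nothing

# a fragmented receptor cluster built to area 10 um^2, solidity 0.7
m <- generate_cluster_mask(cluster_spec(10, target_solidity = 0.7, n_fragments = 4))
measure_cluster(m, pixel_size_um = 0.045)
#>   area_um2 perimeter_um perimeter_over_area_per_um solidity
#> 1   10.012        5.504                       0.55    0.698
```

The measured peak ΔF/F₀ of 0.334 matches the generator truth
amplitude/(F₀+amplitude) = 50/150, and the cluster's measured solidity hits
its 0.7 target within 0.002.

Pipelines run end to end from a config:

```r
run_pipeline(list(preset = "field", seed = 1, out_dir = "out",
                  groups = list(ctrl = list(marker_positive_fraction = 0.7),
                                mut  = list(marker_positive_fraction = 0.4))))
```

writing `readouts.csv`, `stats.csv` and a resolved config; reruns with the
same seed are byte-identical. A thin CLI wrapper lives at
`inst/scripts/nmjquant.R`.

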