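---
title: "Automated pair-wise forest disturbance mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated pair-wise forest disturbance mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`forestpair` maps forest disturbance from a single pair of co-registered
multispectral scenes — six reflective bands as top-of-atmosphere (TOA)
reflectance fractions plus a thermal brightness-temperature band, the
configuration of the Landsat TM/ETM+ sensors — with no manually drawn
training data. This vignette explains the model behind each stage, the
parameters that matter, what the synthetic generator does and does not
emulate, and the design choices we made where the method leaves room.

## The change signal

Forest clearing removes a closed canopy and exposes soil, slash and dry
vegetation. In the shortwave infrared (SWIR, ~1.65 um) this raises
reflectance sharply: mature forest sits near 0.10, fresh clearings near
0.25–0.30. The pipeline's primitive observable is therefore the SWIR
difference image

$$ d = \mathrm{SWIR}_{t_1} - \mathrm{SWIR}_{t_2}, $$

in which disturbance occupies the large-negative tail, regrowth the
positive tail, and the no-change majority forms an approximately Gaussian
bulk whose mean absorbs atmospheric and phenological offsets between the
dates. Because training is extracted from the very image pair being
classified, no atmospheric or radiometric correction is required — only
good geometric co-registration, which the `scene_pair` constructor
enforces.

## Stage by stage

### Cloud, shadow and water screening

Clouds mimic disturbance by brightening pixels between dates, so both
scenes are screened before anything else. The cloud test is a simplified
spectral–thermal screen: a candidate must be bright (blue > 0.20 and
SWIR-1 > 0.10), white (relative spread of the visible bands < 0.7) and,
when thermal data are present, cold (brightness temperature at least 4 K
below the scene median); the candidate layer is cleaned by a binary
opening. Shadows are found geometrically: each connected cloud object is
projected along the anti-solar azimuth over a sweep of candidate
cloud-base heights (200–3000 m by 200 m) and displaced by
$h \tan\theta_z$ / pixel-size; the projection best covered by dark-NIR
pixels (NIR < 0.10) is kept. This deliberately reimplements only the
geometric idea of full object-based cloud matching algorithms; it is a
screen, not a cloud climatology.

Water is spectrally distinctive: a pixel is water iff SWIR-1 < 25 % *and*
(reflectance decreases strictly from visible to infrared, red > NIR >
SWIR-1, *or* NDVI < 0.3). We read "decreasing trend" strictly — equality
fails — because any laxer reading admits soil lines.

### Forest delineation from the red-band dark peak

Closed-canopy forest is the darkest common cover in the red band. In
each local window (the same 400-pixel windows used for training
extraction) we histogram the red band (bin width 0.005), smooth with a
3-bin moving average, and look for the lowest-reflectance prominent mode
(count ≥ 5 % of the window's valid pixels). A mode qualifies as the
*forest peak* only if it lies at or below `forest_red_max` (default
0.10): without this qualifier a window of uniformly bright ground would
declare its own histogram mode "forest". The forest/non-forest threshold
is the peak location plus a margin of `max(FWHM, 2 bins)`, where FWHM is
the smoothed peak's full width at half its height. A margin is needed
because a threshold *at* the mode would halve the forest population; the
full width (rather than a half-width) keeps ≥ 99 % of a Gaussian forest
mode below the threshold at realistic noise levels. Windows with no
qualifying dark peak contribute no forest.

The analysis region is gated on the *early* date's forest mask only:
disturbance converts forest to non-forest, so requiring forest at both
dates would exclude exactly the pixels we want to map. The first date's
tasseled-cap values anchor pre-disturbance condition in the feature
stack for the same reason.

### Automated training extraction

Within each local window (default 400 × 400 pixels, tiled; the stride is
configurable) we compute the mean $\mu$ and standard deviation $\sigma$
of $d$ over valid pixels and label

* **disturbed**: $d < \mu - k\sigma$,
* **regrowth**: $d > \mu + k\sigma$,
* **no-change**: $|d - \mu| < 0.5\,\sigma$, subsampled to at most the
  size of the larger tail,

with $k = 1.5$ fixed across all windows and scenes. The local windows
are the point of the method: a global threshold is hostage to scene-wide
statistics, while window-local thresholds adapt to how much change each
neighbourhood actually contains.

A window contributes samples only if at least 25 % of it is valid and
its disturbed tail holds at least `min_tail_count` (25) pixels. The
regrowth tail is used when it also reaches that count, but its absence
does not disqualify the window: with the analysis region gated on
date-1 forest, regrowth pixels (non-forest at date 1) are structurally
scarce, and landscapes whose only change is clearing — the common case —
must still yield training data. Strict both-tails behaviour is available
as `require_both_tails`.

Two computational caps exist as explicit configuration, not method
changes: `max_samples_per_class` (2000) bounds the extracted set, and
`grid_subsample` (1500) bounds only the hyperparameter search; both are
stratified and seeded.

### Consensus filtering of mislabelled samples

Automatically extracted labels inherit every mask error and threshold
artefact, so the training set is passed through a consensus filter
before classification. Under stratified 10-fold cross-validation, four
classifier families — an RBF-kernel SVM, a depth-limited decision tree,
a 5-nearest-neighbour rule and a single-hidden-layer (16-unit) network —
are each trained on a stratified 70 % subsample (without replacement,
class proportions forced to match the full set) of the training folds
and predict the held-out fold. A sample is discarded only when **all
four** families misclassify it. Unanimity makes the filter conservative:
it removes samples inconsistent with any learnable structure, the way an
outlier is inconsistent with a regression model, and it will *not*
remove a coherent cluster of identically mislabelled pixels (for
example an agricultural field admitted by a faulty forest mask) — the
classifiers simply learn the cluster. The exact auxiliary
hyperparameters are deliberately unremarkable (the filter's authors note
the choice of algorithms is close to arbitrary; consensus is what
matters) and are fixed in the configuration.

Classes with fewer members than the fold count cannot be cross-validated
honestly and are exempted from removal with a warning.

### Features and classifier

Classification uses a six-plane multi-temporal Kauth–Thomas (tasseled
cap) stack: date-1 brightness, greenness and wetness, plus the change
components ΔB, ΔG, ΔW (late − early). Disturbance then reads as rising
brightness and falling greenness/wetness against a forest-anchored
date-1 state; the anchoring also separates forest clearing from shifting
agriculture, whose date-1 state is not forest-like. Packaged coefficient
sets are the TM reflectance-factor matrix (Crist 1985) and the ETM+
at-satellite-reflectance matrix (Huang et al. 2002); which set a study
used is rarely knowable, so the sensor tag is configuration
(default TM, the era of most archival pairs). A documented identity-like
`"synthetic"` matrix exists so unit tests do not hinge on literature
constants.

The final classifier is a multi-class (one-vs-one) C-SVM with an RBF
kernel. Features are standardized per plane with training statistics
stored in the model; RBF kernels are scale-sensitive and the KT indices
have unequal ranges. $C$ and $\gamma$ are selected by exhaustive search
over $C = 2^{-5}, 2^{-3}, \ldots, 2^{15}$ and
$\gamma = 2^{-15}, \ldots, 2^{3}$, maximizing stratified 5-fold
cross-validation accuracy; ties break toward smaller $C$, then smaller
$\gamma$ (prefer the smoother model). Grid search runs on the filtered
training set — the filtered set is what the final model is fitted to.

### From pixels to polygons

Per-pixel maps are noisy, so the label plane is post-processed:

1. **Opening** of the disturbed layer (erosion then dilation, 3 × 3);
   single-pixel commission speckle reverts to no-change.
2. **Segmentation** of the valid region on six bands (red, NIR, SWIR-1
   at both dates) by best-merge region growing: every pixel starts as a
   segment and the 8-connected pair with the smallest Euclidean distance
   between mean vectors merges while that distance is below
   `merge_threshold` (0.05 reflectance units — about five noise standard
   deviations, so noise merges and class boundaries survive).
3. **MMU enforcement**: every segment smaller than six pixels
   (≈ 0.5 ha) merges into its spectrally nearest neighbour. Isolated
   valid islands smaller than the MMU have no neighbour and are dropped
   to stable non-forest — below the minimum mapping unit nothing is
   asserted.
4. **Plurality labelling** of each segment, ties toward no-change: the
   method's dominant error mode is commission in the disturbance class,
   so ambiguity resolves conservatively.
5. **Composition** of the six-category map with precedence cloud >
   shadow > water > stable non-forest > classified labels; regrowth
   folds into stable forest because the product carries no regrowth
   class.

The segmenter is our own best-merge implementation honouring the
method's contract (six-band input, 8-connectivity, MMU, polygon
output); it is deterministic, with ties broken by segment id.

### Accuracy assessment

From the final polygon layer, up to 100 polygons per stratum are drawn
uniformly without replacement from the two assessed strata (disturbance,
stable forest). Each polygon is one assessment unit; the reference label
of a synthetic-truth polygon is the plurality of its true change pixels.
The report carries the confusion matrix, overall accuracy, per-class
user's and producer's accuracy, and the disturbance-class TPR/FPR (the
ROC point). Polygon weighting (not area weighting) matches a per-site
assessment design.

## The synthetic generator

`scene_spec()`/`generate_scene_pair()` define the study conditions under
which the package tests itself. A scene is a patchwork (axis-aligned
rectangles and dilated random walks, areas log-uniform on 40–2000 px so
a 512² scene holds tens of harvest-unit-sized patches) of stable forest
(0.55), disturbance (0.08), regrowth (0.04), agriculture (0.15), water
(0.05) and bare ground (remainder), plus 3 % cloud per date with
geometrically cast shadows. Spectra are class archetypes (documented
package constants chosen to satisfy the qualitative orderings the rules
rely on — they are not literature values) plus N(0, 0.01) band noise.
Agriculture is a per-field phenological continuum between a green-crop
and a bare-soil endmember (per-patch state per date, per-pixel jitter),
so cropping cycles flip brightness between dates and act as the change
confuser. A 2 % per-date "clutter" fraction receives an extra
broadband N(0, 0.08) perturbation, emulating the mixed pixels,
phenology and misregistration residuals of real imagery — this is the
mechanism that pushes individual no-change pixels across the local
training thresholds and creates label noise.

What the generator does **not** emulate: topographic illumination,
sensor artefacts (striping, SLC-off gaps), real phenological gradients,
sub-pixel mixing along every boundary, and — critically — the *rate* of
real-imagery label noise. Consequences for interpreting green tests:
rule-equivalence and geometry tests transfer directly to real data;
end-to-end accuracy (≈ 0.98 polygon-level on clean synthetic pairs)
does not — on real Landsat pairs the same design reports overall
accuracies broadly in the 80–95 % range. Similarly, the consensus filter
removes ~99 % of scattered injected label flips here, but the ~20 %
removal rates seen on real imagery arise from noise structures
(heterogeneous, borderline, analyst-invisible) that archetype-based
scenes produce only weakly; on clean synthetic training the filter
removes well under 2 %, which is the correct behaviour, not a shortfall.

## Numerical choices and degenerate inputs

* Windows with $\sigma = 0$ (constant difference) yield no tails and no
  no-change band; all-nodata windows are skipped; if *no* window passes
  sufficiency, extraction fails loudly rather than returning an empty
  set.
* NDVI is undefined where NIR + red ≤ 0 and such pixels are never water.
* Thermal-free scenes degrade the cloud screen to spectral-only with a
  warning rather than failing.
* All stochastic stages (no-change subsampling, fold assignment,
  subsampling caps, polygon sampling, classifier initialisation) derive
  from the single `rng_seed`, with fixed per-stage offsets, so a run is
  reproducible end-to-end; reruns are bit-identical.
* Reflectance is carried as float fractions; class rasters as 8-bit
  codes (lossless round trip); thermal Kelvin is scaled by 1/1000 into
  the float TIFF range with the factor recorded in the sidecar.

## Problem sizes used by the test-suite

Unit tests run on 64–128 px toys; the pipeline-level tests use a 96²
scene with a reduced 3 × 3 hyperparameter grid; the end-to-end
evaluation uses the full default configuration on a 512² pair, and the
paired filter experiment runs ten 128² replicates with the reduced
grid. These sizes are the package's chosen study conditions for a desk
machine; nothing in the method depends on them.

## Known limitations

* Regrowth is classified internally but not mapped: the six-category
  product folds it into stable forest, and with the analysis region
  gated on date-1 forest, regrowth training is structurally scarce.
* The filter cannot remove coherent mislabel clusters (e.g., a whole
  agricultural field admitted by a corrupted forest mask); the paired
  experiment therefore often shows equality rather than improvement on
  synthetic scenes.
* The cloud screen is a simplification; heavy or warm cloud decks will
  leak, and leaked cloud edges classify as disturbance — the same
  failure mode the full method exhibits.
* Harvest cannot be distinguished from natural disturbance or permanent
  land-cover conversion; the map reports spectral change consistent
  with stand removal.
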