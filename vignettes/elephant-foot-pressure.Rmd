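---
title: "Pedobarographic analysis of walking elephants: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedobarographic analysis of walking elephants: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedopress)
```

## The problem

Walking elephants load their feet in a characteristic way: peak plantar
pressures concentrate on the tips of the lateral toes (digits iii–v), the
compliant fat pad behind the toes keeps central and caudal pressures low, and
the centre of pressure (COP) — the pressure-weighted centroid of the contact
field at each instant — travels caudally to cranially over stance with a
lateral deviation at foot-strike. Quantifying these patterns from pressure
platform recordings requires a chain of image-analysis steps: isolating
individual footsteps from a recording that contains several overlapping
footfalls, aligning the prints of each foot so pixels correspond
anatomically, extracting pressures at anatomical landmarks, and comparing
COP trajectories between feet and between animals.

`pedopress` implements that chain for gridded pressure records (kPa on a
regular sensor grid at a fixed sampling frequency) and pairs it with a
synthetic gait generator that produces records with known ground truth, so
every stage has a recovery test.

## Plate geometry and conventions

The default `plate_spec()` is a 44 × 160 sensor walkway platform
(0.605 m × 2.122 m, 7040 sensors, 100 Hz). Coordinates: `x` is mediolateral
(columns), `y` cranio-caudal along the direction of travel (rows); physical
positions are sensor-cell centres, `x = (col − 0.5) · pitch`. Pressures are
kPa everywhere. Records are stored as a JSON header plus a sparse
`t,row,col,p_kpa` CSV (0-based in files, 1-based in memory) because a
footprint occupies well under 10% of the plate.

## The synthetic pressure model

A foot is an elliptical outline carrying a truncated Gaussian mixture:

* five sharp digit components on the cranial arc (nails of digits i–v,
  medial → lateral), default width 0.018 m (≈1.3 sensor pitches) — sharp
  enough to be realistic digit peaks, wide enough that bilinear resampling
  during registration is well behaved;
* one broad pad component (width 0.05 m) centred slightly caudal of the
  outline centre.

Default digit amplitudes (250, 300, 460, 430, 390 kPa, fore feet ×1.07) put
the largest peaks laterally and realize per-region peak pressures in the
one-to-few-hundred kPa range typical of walking elephants; the 7% fore/hind
amplitude gap mirrors the forelimbs' larger share of body weight. The
amplitude steps between neighbouring digits are kept moderate so that each
digit remains a distinct local maximum after resampling — with a much
stronger contrast, a weak digit's peak collapses into its neighbour's
shoulder and no landmark detector can recover it.

Loading over stance is a raised-cosine envelope (single-peaked total force).
Two time-varying mechanisms shape the COP path:

* mixture weights ramp from the pad (caudal) to the digits (cranial),
  producing the caudal-to-cranial progression;
* early in stance the lateral digits are over-weighted and the pad bears
  load lateral of its resting position, re-centring by mid-stance
  (`lateral_gain`, default 0.6), producing the lateral deviation at impact
  followed by the medial shift. Setting `lateral_gain = 0` gives a
  mediolaterally symmetric field, which the tests use as a symmetry oracle.

Sensor noise is i.i.d. Gaussian per sensor per frame, clipped at zero,
default 1 kPa: the 5 kPa activation threshold then sits at five noise
standard deviations, consistent with hardware on which a fixed 5 kPa
isocontour is usable, and supra-threshold noise specks are rare (they are
discarded by the minimum-cluster-size rule when they do occur).

The default trial places four footfalls (FL, FR, HL, HR) on one plate, left
feet on the high-`x` column, each hind foot landing just cranial to the
ipsilateral forefoot print after that forefoot has lifted. The real
experimental set-up used two plates side by side, one per side of the
animal; the generator merges them into one virtual plate, which is why the
default foot outline (semi-axes 0.11 × 0.13 m, a sub-adult scale) is chosen
to fit two footfall columns on a 0.605 m width with more than a
segmentation-gap of clearance.

### Ground truth

Truth is computed from the continuous generating field, independently of the
sensor sampling: per-frame COP as the centroid of the field restricted to
the 5 kPa isocontour by dense numerical integration on a 3× oversampled
grid (symmetric about the foot centre so truncation cannot bias it), and
per-ROI regional peaks as the σ = 1 px Gaussian 3 × 3 kernel functional of
the max-over-stance field at the digitized pixel. The kernel-functional
definition matters: with digit peaks ~1.3 pitches wide, a 3 × 3 kernel
average sits ~30% below the raw field maximum, so "the value the extraction
kernel measures" is the only truth against which percent-level recovery is
meaningful.

## Footstep isolation

Supra-threshold voxels `(t, row, col)` are clustered with a spatio-temporal
gap rule: two voxels connect when their in-plane Chebyshev distance is at
most `spatial_gap_cells + 1` **and** their frame distance is at most
`temporal_gap_frames + 1`. Defaults: threshold 5 kPa (the template
isocontour), gaps of 2 cells (≈2.7 cm) and 10 frames (0.1 s at 100 Hz),
minimum cluster 20 voxels. The gaps are chosen so an elephant print never
splits across its internal pressure minima while successive footfalls never
merge; all are configurable. The implementation (per-frame labeling, then
exact cluster-pair merging with bounding-box and overlap fast paths) is
checked against a brute-force union-find over the same adjacency graph, and
enlarging either gap can only merge clusters, never split them.

Completeness is operationalized conservatively: a step is spatially
incomplete if any voxel touches the outermost sensor row/column, temporally
incomplete if it is active in the first or last frame. Foot identity is a
heuristic with an explicit `"unknown"` escape: left/right from the step
centroid relative to the trackway centreline (median `x` of all steps), and
fore/hind from the footfall sequence — within a spatial cluster of
successive prints the earlier print is the forefoot, because a walking
elephant places the hind foot near the ipsilateral forefoot print.

## Registration

Prints of one foot are aligned to a template — the first spatio-temporally
complete peak-pressure image (per-cell maximum over stance), with its 5 kPa
isocontour mask. Transforms are rigid (translation in cells plus rotation
about the source's active-pixel centroid, which decouples the two in the
search); resampling is bilinear with zero fill, nearest-neighbour available
for mass-conservation checks. The automated optimizer minimizes the mean
squared pressure difference over the union support via a coarse grid
(±10 cells step 1; ±20° step 2°) plus Nelder–Mead refinement. The rotation
range is deliberately bounded: near-symmetric footprints invite a
symmetry-flip failure mode in unconstrained automatic registration, which is
why manual alignment remains common on elephant data — a manual mode
(explicit `dx, dy, θ`) is therefore kept. The transform found on the peak
image is re-applied to every frame of the step's time series with the same
rotation centre, so COPs of registered steps live in the template frame
(rigid maps commute with centroids; the tests check this equivariance).

## ROI extraction and sensitivity

Seven ROIs on the per-foot mean image: nails of digits i–v (1–5), mid-sole
(6), caudal heel (7). The regional peak pressure is a Gaussian-weighted
average over a 3 × 3 pixel window, σ = 1 px, weights renormalized over the
window. A "3-pixel area" with a σ = 1 px kernel admits several readings; the
3 × 3 window is the only one compatible with the four one-pixel sensitivity
neighbours, and both window and σ are arguments. Display smoothing
(`smooth_gaussian`, reflective borders) is never applied before extraction.

Each ROI carries four sensitivity positions (±1 pixel in each direction);
`sensitivity_table()` emits 35 rows per image and downstream summaries use
the 5-position mean per ROI. Auto-digitization — needed only so the
synthetic pipeline runs unattended; real data takes manual points from CSV —
finds the five cranial local maxima (falling back to value-ordered
non-maximum suppression at ≥3 cells separation when a digit peak has been
flattened into a neighbour's shoulder by resampling), orders them medial to
lateral using the foot side, and places ROI 6 at the active-mask centroid
and ROI 7 at the caudal-most mask pixel on the midline.

## COP trajectories and comparison

Per active frame (≥1 cell at the 5 kPa threshold) the COP is the
pressure-weighted centroid in metres. Trajectories are resampled to 101
stance-percent points by linear interpolation (the gait-analysis
convention; configurable), centred at their centroid — plate coordinates are
arbitrary per trial, and the centroid frame is the only one all feet share
(aligning start points instead is a documented alternative) — and averaged
pointwise per foot.

Pairs of mean trajectories are compared four ways, mirroring the published
pairwise tables: Pearson correlations of the mediolateral (`x_r`) and
cranio-caudal (`y_r`) coordinate sequences and RMSE on the untransformed
(centred) data, plus RMSD after ordinary Procrustes superimposition of the
second trajectory onto the first with scaling and reflection enabled. The
OPA solution is closed-form via SVD of the cross-covariance; with
`reflect = FALSE` the rotation determinant is constrained to +1 by flipping
the smallest singular direction. RMSD uses the number of points as
denominator, so it reads as a mean per-point distance. Tests verify the
implementation against a rotation-grid/golden-section oracle, against an
independent Procrustes implementation, and via its invariances
(rigid motions, reflection, source scaling; `rmsd ≤ rmse`;
`rmsd(scale+reflect) ≤ rmsd(scale) ≤ rmsd(neither)`).

## Descriptive statistics

`froude()` is the dimensionless walking speed `v²/(g·h)` with `h` hip
height. `weighted_mean()` supports step-weighted cohort masses.
`summarize_pressures()` reports mean ± s.e. with `n`; the standard error
uses the sample standard deviation (n − 1), a choice the upstream sources do
not pin down. Printed per-subject characteristics of the African cohort and
the published cohort-level means ship as plain CSVs
(`african_subjects()`, `published_cohort_values()`); note the printed
per-subject Froude numbers cannot be recomputed from the printed columns
because hip height is not tabulated, so `froude()` is validated
analytically rather than against those rows. Inferential modelling (mixed
models, ANOVA, post hoc tests) is deliberately out of scope: the ROI table
is emitted in the long format those tools consume, e.g.

```{r, eval = FALSE}
# lmerTest::lmer(peak_pressure_kpa ~ roi * foot * position + (1 | subject),
#                data = bundle$roi_table)
```

## The pipeline

`run_pipeline(pipeline_config(...))` chains simulate → segment → classify →
register → ROI → COP → compare → summarize. A single master seed fans out to
per-stage child seeds by stable string hashing, so any stage is reproducible
in isolation; rerunning an identical configuration reproduces every output
file byte-identically (the manifest records the configuration and its hash,
deliberately no timestamps). Subject-level variation is log-normal jitter on
amplitude (6%) and size (4%); trial-level variation jitters placements
(1–2 cm) and headings (±3°). An `exclude` predicate hook mirrors the
practice of dropping unsteady trials, with every exclusion logged; no
automatic gait-steadiness detector is claimed.

Default problem sizes: 5 subjects × 2 trials × 4 footsteps at 1.2 s stance
on the full 44 × 160 plate (the package's standard demonstration cohort,
~1 minute end to end); the test suite uses a scaled-down plate and shorter
stances so the full suite runs in about a minute.

```{r, eval = FALSE}
bundle <- run_pipeline(pipeline_config(seed = 1))
bundle$comparisons     # pairwise x_r / y_r / RMSE / RMSD table
bundle$cohort_summary  # grand mean, fore/hind means +- s.e., contrast
```

## What the synthetic tests do and do not show

The generator reproduces the *structure* of the real data — plate geometry,
sampling rate, overlapping sequential footfalls, five-digit lateral-biased
pressure anatomy, single-peaked loading, the lateral-impact/medial-shift
caudal-to-cranial COP shape, additive sensor noise — so passing tests show
the measurement chain recovers known inputs under that structure. It does
not emulate soft-tissue mechanics, substrate compliance, gait variability
beyond placement jitter, correlated sensor error, or calibration drift;
agreement on synthetic data therefore validates the software, not any
biological claim about real animals. Published grand means from real
recordings (which passed through manual registration and manual
digitization) are not bit-reproducible here; the package instead reproduces
the published quantities that are pure arithmetic on printed tables and
validates everything else by oracle equivalence and synthetic recovery.

## Numerical choices and limitations

* Bilinear interpolation everywhere a transform resamples; integer
  translations and exact 90° rotations are lossless; interior transforms
  conserve total pressure within 2%.
* The registration MSE is evaluated over the union of active supports;
  identity is always a candidate, so registration never worsens the
  residual.
* Segmentation adjacency is a Chebyshev box; the exact cluster-pair merge
  uses an `n₁·n₂ ≤ 4·10⁶` pairwise test with a rasterized-dilation fallback
  for larger pairs.
* Time normalization assumes the COP is well defined on every active frame;
  frames with all cells below threshold are skipped before resampling.
* Degenerate inputs fail loudly: empty images, zero-variance axes
  (correlation reported `NA`), zero centroid size in OPA, ROI windows
  clipped by the border.
* Foot classification assumes a single pass of steady walking along +y with
  both sides on the record; it returns `"unknown"` rather than guessing
  when geometry is ambiguous.
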