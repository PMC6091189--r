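---
title: "musclehca: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{musclehca: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic world does and does not establish, and
where the design was genuinely open. It states no empirical result that
the test suite does not itself compute.

## The measurement model

A muscle cross-section is a tessellation of near-convex fiber profiles
separated by the basal lamina, which a laminin immunostain renders as a
bright wall network. Everything in this package reduces to (1) recovering
that tessellation and (2) locating point-like objects (nuclei, Pax7⁺
cells, CD31⁺ vessels) relative to per-fiber zones whose margins scale
with fiber size.

**Segmentation.** The laminin channel is background-subtracted by a
grayscale opening (separable running min/max over a square window —
rolling-ball-style, and *exactly* invariant to constant offsets, which the
tests exploit) and contrast-enhanced by tile-based contrast-limited
adaptive equalization. Walls are thresholded by Otsu's method; the tissue
mask is the hole-filled morphological closing of the wall mask; fiber
interiors are the connected components of the complement. Interiors that
merge through wall gaps are split by a marker-based watershed on the
Euclidean distance transform. Finally a *half-maximum boundary
refinement* reassigns wall pixels below the midpoint of the interior and
wall median levels to their adjacent fiber by ascending-intensity
flooding: a global histogram threshold lands on the shoulder of the
blurred wall profile, and without this step fiber areas are biased low by
several percent (the half-maximum criterion is the standard edge
convention in light-microscopy morphometry).

**Watershed seeding.** Seeds are maxima of the (lightly smoothed)
distance transform with minimum separation `sqrt(min_fiber_area)/scale`
pixels. Because near-convex shapes can still carry several shallow maxima,
two seeds are merged when the distance transform along the segment joining
them never falls below 0.65 of the smaller peak — i.e. when there is no
real neck. Components with a single surviving seed are kept whole, so
clean fibers are never cut. The 0.65 ratio is a design choice of this
package: lower values over-merge genuinely touching nuclei, higher values
over-split elongated fibers; values in 0.55–0.75 behave identically on
the synthetic suite.

**Morphometry.** CSA is pixel count × scale²; Feret diameters come from
rotating calipers on the convex hull of boundary-pixel *corners* (so a
100-px square measures exactly 100 px, not 99); the perimeter uses
chain-code following with the Vossepoel–Smeulders corner correction;
circularity 4πA/P² is clamped to 1; the gravity center is the unweighted
pixel centroid (an intensity-weighted center was considered and rejected —
nothing downstream uses intensity weighting, and unweighted centroids are
rotation-exact).

**Regions of interest.** With d = minimum Feret diameter:
ROI_CNF = erosion of the fiber by round(d/5 ÷ scale) px,
ROI_SC = fiber \ ROI_CNF (exact set difference),
ROI_V = dilation by round(d/8 ÷ scale) px minus *every* fiber.
The erosion/dilation discs are Euclidean (thresholded distance
transform), so the construction is isotropic and rotation-equivariant.
The "−1/5" margin is read as an erosion *radius* of d/5, so the central
zone spans 3/5 of the diameter — the proportion that makes the central
and sub-laminal zones visually comparable, as published renderings of
this construction show; the geometrically defensible alternative (radius
d/10) is available through the `cnf_fraction` knob. When erosion would
empty a thin fiber, the ultimate-erosion pixel set (distance-transform
maxima) serves as its center, so every fiber has a defined
centronucleation test region. Peri-fiber bands of adjacent fibers
overlap each other by construction; they never overlap any fiber.

**Object detection.** Nuclei/Pax7/CD31 share one blob pipeline:
background opening, Otsu threshold, watershed splitting (same saddle
rule), and per-role area gates (nuclei 10–200 µm², Pax7 8–120 µm², CD31
5–400 µm² — generous envelopes around typical murine values). Objects are
located by their centroid pixel: centroid containment makes the
centronucleated/peripheral classes mutually exclusive by construction
(ROI_CNF and ROI_SC partition the fiber), whereas a partial-overlap rule
would need a tie-break. Satellite calling requires ≥ 90% of the Pax7 blob
area to be covered by the nuclei mask and the centroid to lie in some
ROI_SC; the 90% is a config default (`overlap_min`), and acceptance is
monotone in it. Vessel metrics: per-fiber counts use centroid-in-ROI_V
(an object may legitimately count for several adjacent fibers — the bands
overlap; this is recorded here and in the function docs), density divides
*unique* objects by tissue area in mm² (tissue = section mask, not the
full frame), and %area divides the CD31 mask area inside the section by
the section area.

**Fiber typing.** The per-channel threshold is
`mode + snr_factor × 1.4826·MAD` computed over non-fiber tissue pixels
(walls + interstitium). Mode/MAD was chosen over Otsu deliberately: a
histogram split fails when nearly all fibers are positive (or negative)
for a stain, while the wall background is always present and unaffected
by the positive fraction. The statistic is exactly invariant to constant
channel offsets (the mode shifts with the offset, the MAD does not
change). Positivity is mean intensity over the fiber mask versus the
threshold (`statistic = "median"` available); labels follow the
cardinality rule: {} → IIX, one stain → I/IIA/IIB, two → hybrid
(I-IIA, I-IIB, IIA-IIB), three → ND. Thresholds are always logged in the
summary table for auditability.

**Quality control.** Section level: fiber-area-to-section-area ratio;
the section is rejected when `1 − ratio` exceeds the user's artifact
tolerance. Note that in the synthetic world the laminin walls themselves
are unsegmented area (~15% of the tissue at 2 µm walls and ~1500 µm²
fibers), so meaningful tolerances start around 0.2 — the tolerance is the
user's statement about acceptable staining artifacts *on top of* the wall
fraction. Fiber level: single-pass removal of fibers with
CSA > mean + 3·SD, using the sample SD (R's `sd()`): for the rule's
worked reference case — 100 fibers of 100 µm² plus one of 5000 — this
gives SD ≈ 487.6 and cutoff ≈ 1611; the population-SD variant differs
negligibly (cutoff ≈ 1604) and removes the same fibers, so it is not
exposed as an option. Border-touching fibers are excluded before any QC
because their truncated CSA would bias the mean+3SD rule.

## Tunable parameters

| knob | default | unit | why this value |
|------|---------|------|----------------|
| `rolling_ball_radius_px` | 50 | px | larger than any wall, smaller than illumination gradients |
| `clahe_clip` | 2 | – | mild equalization; limits noise amplification in empty tiles |
| `min_fiber_area_um2` | 50 | µm² | below the smallest regenerating fibers |
| `artifact_tolerance` | 0.10 | fraction | the dialog-box default; raise to ≥ 0.2 for the synthetic world (wall fraction, above) |
| `csa_outlier_sd` | 3 | SD | the prescribed mean+3SD rule |
| `cnf_fraction`, `v_fraction` | 1/5, 1/8 | of min Feret | the prescribed proportional margins |
| `overlap_min` | 0.90 | fraction | the prescribed Pax7/DAPI double-positivity minimum |
| `snr_factor` | 3 | σ | 3-sigma above background mode; the synthetic positives sit ~8σ up |
| nucleus / pax7 / cd31 area gates | 10–200 / 8–120 / 5–400 | µm² | generous envelopes around murine object sizes |

## The synthetic world

`generate_section()` emulates: a contiguous elliptical section tessellated
into near-convex fibers (random seeds + Lloyd relaxation — real fiber
packings are space-filling and locally regular), bright laminin walls of
2 µm full thickness, peripheral myonuclei in the sub-laminal band
(1.8–5 µm inside the wall, ~5 per fiber), central nuclei near fiber
centers for a `cnf_fraction` of fibers, Pax7 discs co-centered with a
subset of peripheral nuclei (radius 0.75× the nucleus, so the 90% overlap
holds by construction), CD31 discs on walls (~4 planted per fiber),
per-fiber uniform typing intensities, Gaussian optical blur (σ 0.5 µm)
and additive Gaussian noise (σ 2% of full scale), quantized to 16-bit.
Defaults are the stated world: mean CSA 1500 µm² (healthy mouse hind-limb
scale), IIB-dominant type mix (I 5 / IIA 35 / IIB 45 / IIX 15%), sparse
satellites (~0.35 per fiber). The default pixel size is 0.325 µm/px (the
calibration of a 20x slide scanner, the typical acquisition for whole-section muscle imaging); the test suite
renders at 0.5 µm/px, a pure compute scale-down (2.4× fewer pixels) with
all biological parameters unchanged.

What it does **not** emulate — and hence what a green test does *not*
establish: staining heterogeneity and gradients within a section,
fibrosis/necrosis textures, out-of-focus z-structure, anisotropic point
spread, chromatic shift between channels, real CSA distributions of
dystrophic muscle (the generator's Lloyd-relaxed cells have CV ≈ 0.25 and
a short right tail; `csa_cv` trades relaxation steps for spread but is
advisory), and nucleus shapes other than discs. Green acceptance means
the *geometry and the rules* are implemented correctly, not that the
segmenter is robust to every real-world stain.

`degrade()` exercises the QC paths: `broken_walls` replaces patches with
bright unstructured signal (unsegmentable area → the section-level ratio
drops by ≈ severity × the baseline ratio), `uneven_illumination` applies
a left-right ramp (survivable by the background subtraction),
`debris` adds off-tissue blobs (changes no fiber count).

## Numerical choices and degenerate inputs

- All morphology uses the exact Euclidean distance transform
  (Felzenszwalb–Huttenlocher), so erosion/dilation are isotropic and
  deterministic; watershed ties break by insertion order (FIFO), making
  every run bit-reproducible.
- Otsu uses 256 fixed-width bins between the observed min/max; a constant
  image is "no tissue".
- The background mode for typing uses the fullest of 256 bins; a uniform
  channel gives σ = 0 and threshold = mode (any excess signal is then
  positive, as specified).
- Empty erosion → ultimate-erosion fallback (above). Empty blob channel →
  empty object list, never an error. Fewer than 2 fibers → outlier QC is
  a warning no-op. Sections whose laminin is constant, or below threshold
  everywhere, raise "no tissue".
- CSA cartography bins by within-section octiles (no fixed edges can fit
  every muscle and condition); explicit `class_edges` override the
  quantiles, and the legend
  always shows the palette actually painted. The centronuclei scale
  resolves the 1-vs-2-vs-"more than three" wording as 0/1/2/≥3 so every
  count has a class.
- Percentages always sum to 100 over their own denominator (fibers of the
  section for distributions; accepted objects for densities).

## Output conventions

Batch runs write the four-folder tree (`Artefacts`, `Cartography`,
`Results by file`, `ROI`) plus `RunGlobalResult_<run id>.txt` and a run
log with every config value and per-channel typing threshold.
Tab-delimited UTF-8 tables with "." decimals; ImageJ-compatible polygon
ROIs in a stored zip per image (ring-shaped regions — ROI_SC, ROI_V — are
stored by outer outline with their set-difference partner named in the
CSV index). Cartographies are written as lossless PNG; the JPEG mirror of
JPEG output was dropped because no JPEG encoder exists in
the supported dependency set, and PNG is the testable artifact anyway.
The run id defaults to a timestamp; fixing `run_id` in the config makes
re-runs byte-identical, which the acceptance suite verifies.

## Known limitations

- Only isotropic pixel sizes; anisotropic metadata is a hard error.
- TIFF support is the uncompressed grayscale baseline (8/16-bit, single
  or multi-page, either endianness) — the format the pipeline's own
  writer and mainstream microscope exports produce; compressed or tiled
  TIFFs are refused with a clear message rather than mis-read.
- Per-fiber vessel counts double-count across adjacent bands by design;
  use the unique-object density for section-level comparisons.
- The watershed saddle ratio (0.65) is a compromise; extremely dumbbell-
  shaped *fibers* (rare outside branching pathology) could be split.
- No interactive correction of outlines; the tool is deliberately
  headless and deterministic.
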