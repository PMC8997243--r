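---
title: "Midline tracking for limbless animals: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Midline tracking for limbless animals: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midliner)
```

## The problem

Larvae, fish and worms carry no joints, limbs or stable surface markers, so
pose estimators built on landmark detection have nothing to anchor on. What
such animals do offer is a high-contrast silhouette whose mid-line — the
body axis — carries the pose: peristaltic contraction shows up as mid-line
shortening, turning as mid-line curvature, swimming as a travelling wave
around it. `midliner` reconstructs that mid-line from nothing but the
contour, frame by frame, and derives locomotion statistics from it.

The pipeline is: temporal background projection → difference image →
normalize → binarize → (optional ROI) → erode → boundary extraction →
per-boundary ellipse Hough detection → rule-based and score-based
corrections → identity assignment → contour-seeded Voronoi skeleton →
shortest-path mid-line → calibration → kinematics.

## Detection model and assumptions

**Background.** The animal must move; any pixel it occupies in *every*
frame cannot be recovered by a temporal projection. For a dark animal on a
bright field the per-pixel maximum over time is the empty background, for
the inverse polarity the minimum, and the mean suits mildly varying
illumination (it is also the most robust choice under strong pixel noise,
which biases extreme-value projections). `compute_background()` exposes all
three; absolute differences make the downstream identical for both
polarities.

**Segmentation.** The difference image is normalized to its maximum so that
the binarization threshold (default 0.25) is contrast-independent.
Comparison is strict `>` with ties to background, so results are
deterministic. Erosion (disk, default radius 1 px) cuts thin contact
bridges between touching animals; it also shrinks each silhouette by about
one pixel per side, a bias the mid-line statistics tolerate because they
are ratios or differences. Connected components are labelled by
`EBImage::bwlabel`, which uses 4-connectivity; bodies more than a couple of
pixels wide — every realistic subject here — are unaffected by the
difference from 8-connectivity. Components smaller than `min_area`
(default `pi * (min_major/4)^2`) are treated as noise specks. That default
is tuned to compact larva-like bodies; for slender fish silhouettes it can
exceed the body area itself and should be set explicitly (the swimmer
examples use 150 px²).

**Ellipse detection.** The Hough stage treats every pair of edge points
whose separation lies in `[min_major, max_major]` as a hypothetical major
axis; all other edge points vote for the semi-minor length they would imply
(1-px accumulator bins, 3-bin box smoothing, ties toward the smaller
minor). Pairs are enumerated exhaustively up to 400 edge points and
subsampled reproducibly above. Detection quality is the peak vote count
normalized by the Ramanujan perimeter of the candidate — the vote count a
complete, 1-px-sampled ellipse would achieve — clipped to [0, 1]. A
partially occluded ellipse still votes coherently: with 30% of its arc
missing the candidate survives with proportionally lower quality, which is
exactly what the correction stages exploit.

Two duplicate-removal passes follow. First an *accumulator-echo* dedupe:
jittered endpoint pairs of one physical ellipse produce candidates with
near-identical centers and axes but slightly tilted (often mirrored)
orientations, and for thin bodies those echoes share less than 60% area, so
an area criterion alone cannot remove them; candidates within 3 px, 15% in
`a`, and 15 degrees (axially) of a better one are dropped. Then the area
NMS proper: greedy suppression at >60% intersection-over-minimum area.
Genuinely crossing animals differ strongly in orientation and survive both
passes for the correction stage to arbitrate.

## Corrections

With the user's animal-count prior `n_animals`, each frame is classified
into one of seven standard problems (surplus overlapping detections,
surplus disjoint detections, both, deficit, deficit with an oversized
"chain", chain splitting that still leaves a deficit, correct count with a
chain) and repaired: overlapping surplus loses its lowest-quality members,
disjoint surplus is deleted globally by quality, deficits are filled from
the kept sub-threshold candidates, and oversized detections — two animals
aligned end-to-end, fitted as one long ellipse — are split into
`round(major / expected_major)` ellipses of the expected size along the
detected axis. "Overlaying" is quantified as intersection-over-minimum
area at least `overlap_frac` (default 0.5) on the fitted ellipses; a
detection is a chain when its major axis reaches `chain_factor` (1.5)
times the expected single-animal major axis, where the expected size is
the mid-point of the user's `[min_major, max_major]` window throughout.
One geometric consequence worth knowing: a two-animal chain is only
*flaggable* if the size window both contains the chain
(`max_major >= chain span`) and keeps the expected size below
`span / 1.5`, which requires `max_major >= 3 * min_major` around such
events. After every rule application the frame is re-classified, so a rule
that exposes a different problem (e.g. splitting that leaves a deficit)
falls through to the matching rule next. A frame with the correct count
but overlapping, non-oversized detections matches none of the seven
problems and is left untouched.

Frames still short of the prior are rescued from their neighbours: each
remaining sub-threshold candidate is scored against the accepted detections
of the previous and next frames by three bounded estimators — position
`1/(1 + d/d0)` with `d0` the expected major axis, surface `min/max` ratio
of ellipse areas, contour `min/max` ratio of ellipse perimeters — combined
as a weighted mean (weights default `pos = 1, surf = 0.5, cont = 0.5`; a
zero weight omits an estimator). The estimator *shapes* are this package's
choice: each is dimensionless, monotone in the mismatch it measures, and
bounded in [0, 1]. Ties resolve by raw detection quality, then candidate
index. Every detection introduced or modified by any correction carries
quality −1, so downstream analyses can always separate first-pass Hough
hits from repaired ones.

Identities are propagated between consecutive frames by minimum
total-center-distance assignment (Hungarian method via `clue::solve_LSAP`);
surplus detections open new identities.

## Pose: Voronoi skeleton and mid-line

100 evenly spaced (by arc length) contour points seed a Voronoi
tessellation; only tessellation edges whose both endpoints lie strictly
inside the contour are kept. Those interior vertices approximate the medial
axis. The mid-line endpoints are the vertex pair maximizing the geodesic
distance on that graph penalized by each vertex's distance to the contour
— the medial axis approaches the boundary at the body ends, so the winning
pair combines maximal mutual path length with closeness to the boundary.
A rule based on boundary distance alone was tried first and proved
brittle: binarization noise carves shallow pockets into the contour whose
Voronoi vertices sit *closer* to the boundary than the genuine tip
vertices, occasionally truncating the mid-line by a third of the body; the
geodesic criterion removes those failures (worst-case length error on the
synthetic crawler corpus drops from ~35 px to ~4 px). The pseudo-skeleton
is the minimum-total-length path between the endpoints (Dijkstra via
`igraph`); on the interior-edge-only graph the shortest
endpoint-to-endpoint route follows the mid-line, which the rectangle
oracle in the test suite confirms (axis deviation well under a pixel over
the middle 80%). On a disconnected graph the pair is confined to the
largest component and the frame is flagged.

Two numerical details. The tessellation input is perturbed by a
deterministic 1e-4 px pattern because exactly symmetric seed sets (straight
capsules) can stall the incremental triangulation; the perturbation is far
below pixel noise. And by default each end of the path is extended to the
nearest contour point inside a 45-degree cone ahead of it: the raw Voronoi
path systematically stops about half a body width short of each tip (for a
capsule the medial axis ends at the cap centers), an 8–10% length bias
that the extension removes, bringing length recovery on synthetic crawlers
to ≲3% RMS.

## Kinematics

Body length is the skeleton length; a 5-frame running median absorbs
single-frame skeletonization glitches. Contraction amplitude over an
analysed interval is `A = (1 - min(L)/max(L)) * 100` percent.

The curvature index rotates the skeleton so its end-to-end chord lies on
the y-axis (both endpoint x-coordinates zero) and integrates the lateral
coordinate series `y_lat` by the trapezoidal rule over the point index
(101 equidistant points): `c = (∫|y_lat| − ∫y_lat) · (−sign(y_mid))`. A
straight or purely s-shaped posture gives small `c`; a C-bend gives large
`|c|` signed by turn direction. As printed, the formula is asymmetric — a
bend lying entirely on the positive lateral side yields `c = 0` while its
mirror yields `2∫|y_lat|` — and it is implemented exactly so; a
`variant = "symmetric"` option returns the mirror-symmetric pair
(`s_shape = I_abs − |I|`, `turn = |I|·sign`) for users who need
orientation-independent magnitudes. This variant is this package's
extension, not part of the original formulation.

Positions and orientations feeding the ego-centric decomposition come from
the skeleton when one exists: position is the centroid of the resampled
mid-line, axial orientation the principal axis of the mid-line. The raw
ellipse center and orientation of an undulating, tapered body oscillate
with the body wave (measured on the synthetic swimmer: ~5 px and ~5
degrees at the undulation frequency), and differentiation at 200 fps turns
that wobble into spurious saccades; the skeleton-based estimators reduce it
several-fold. The axial (mod-180) orientation is resolved into a directed
heading by alignment with the instantaneous velocity, with two safeguards:
below `speed_eps` (0.05 px/frame) the flip state is frozen, and a toggle
additionally requires the velocity to contradict the current heading by
more than ~102 degrees (hysteresis margin 0.2), so lateral jitter cannot
flip the heading. Derivatives are central differences scaled by the frame
rate, one-sided at the ends; `thrust^2 + slip^2` equals squared speed
identically. An optional moving-average pre-filter (`smooth_frames`,
default off; 9 frames = 45 ms is used for the 200-fps examples) trades a
~10% peak attenuation for stable derivatives — at high frame rates raw
pixel quantization otherwise dominates the velocity signal.

Saccades are yaw-velocity peaks above 200 deg/s, thrust strokes thrust
peaks above 0.10 m/s, both with a minimum separation of 0.1 s
(`locomotion_events()`); triggered averages drop incomplete windows and
report either a bootstrap 95% CI of the pointwise median or the pointwise
standard deviation. Group comparisons use a permutation test on the
difference of medians: exhaustive enumeration of all `C(n, nA)` relabelings
when feasible (exact proportion), otherwise sampled relabelings with the
add-one estimator `(hits + 1)/(N + 1)`; constant pooled data returns p = 1.

## The synthetic generators: what they emulate and what they do not

The generators exist so that every stage can be validated against known
ground truth without any recorded data. `make_crawler()` renders a
capsule-shaped larva (constant width, rounded caps) whose tip-to-tip length
oscillates sinusoidally with relative amplitude `A*`% — so
`min/max = 1 − A*/100` *by construction* — advancing at constant speed,
with scheduled C-bend turns; the defaults (34 fps, 110 px body, 15%
amplitude, 1 s period) mirror contact-imaging footage of a wandering
larva. `make_swimmer()` renders a tapered silhouette on an intermittent
burst–glide trajectory (200 fps, 0.5 mm/px): thrust events inject forward
speed that decays exponentially (τ = 0.25 s), saccades inject Gaussian
yaw-velocity pulses (σ = 40 ms), and a tapered travelling wave bends the
mid-line. `make_multianimal()` renders parallel crawlers with scheduled
end-to-end chaining and crossing windows. Two lighting regimes instantiate
"optimal" versus "difficult" recording conditions: uniform (flat field
0.85, contrast 0.7, noise σ = 0.005) and gradient (20% linear illumination
ramp, contrast 0.3, noise σ = 0.02). These regime constants are this
package's declared operating points, not measured properties of any
particular rig.

The generators deliberately omit: photorealistic texture, shadows and
reflections, lens distortion, fluid–body interaction, segment-level
biomechanics, and appearance differences between individuals. Passing
tests on this corpus therefore demonstrates correctness of the geometry
and statistics under controlled contrast and noise — not robustness to
every artefact of real footage. Conversely, the detection-rate figures the
acceptance script reports (fraction of frames with an accepted detection
after corrections, on 2 × 10 videos × 200 frames) are computed under
exactly these conditions.

Event scheduling interacts with background estimation: a body must clear
its own footprint within the recording (travel speed × duration greater
than body length), otherwise the temporal projection retains a smear. The
default trajectories satisfy this with margin; very short clips (≪100
frames at the default speeds) will not.

## Problem sizes and determinism

All randomness is seeded: the Hough subsampler, the generators, the
bootstrap and the sampled permutation test, so every pipeline output is
bit-reproducible. The test suite runs at desk scale — 200-frame videos,
10-video corpora per lighting regime, 100-matrix assignment sweeps,
1000-replicate null calibration — chosen so the whole suite completes in
minutes on one core while still exercising every code path; these sizes
are the package's own validation choices.

## Known limitations

* Input is image sequences and multi-page TIFF stacks; video containers
  must be exploded to frames first (no container decoder is linked).
* The seven correction rules assume a reliable animal-count prior; a wrong
  prior produces systematic over- or under-detection, though flagged with
  quality −1.
* Chain splitting places children of the *expected* size along the
  detected axis; strongly curved chains (two animals in a V) violate the
  collinearity assumption and are split suboptimally.
* Head/tail polarity is not anatomically resolved; headings rely on motion
  alignment and are undefined while an animal rests for long periods.
* The eccentricity series comes from the fitted ellipse, which for
  undulating bodies carries body-wave ripple.
* Calibration is a scalar similarity (isotropic scale + origin shift); no
  lens-distortion or perspective correction.
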