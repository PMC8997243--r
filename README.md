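# midliner

Markerless midline pose estimation and locomotion kinematics for limbless
animals (fly larvae, fish, worms) in R.

Limbless animals carry no joints, limbs or reliable surface markers, so
landmark-based pose estimators have nothing to attach to — yet their pose
is fully described by the body mid-line: peristalsis is mid-line
shortening, turning is mid-line curvature, swimming is a travelling wave
around it. `midliner` reconstructs that mid-line *de novo* from the
animal's contour in ordinary grayscale video, with no markers and no
training data, and turns it into locomotion statistics. It is aimed at
behavioural neuroscientists and ethologists quantifying crawling,
swimming, and undulatory locomotion.

## Method

Per frame, with a user prior on animal count `n` and admissible body size
`[min_major, max_major]` (px):

1. **Background** `B(x,y) = max_t I_t(x,y)` (or min/mean) — a temporal
   projection is animal-free wherever the animal keeps moving.
2. **Segmentation** — normalize `|I_t − B|` to its maximum, binarize at
   threshold 0.25 (strict `>`), optional ROI, disk erosion (radius 1) to
   cut contact bridges, then trace one closed outer contour per component.
3. **Ellipse Hough transform** — every edge-point pair with separation in
   `[min_major, max_major]` is a hypothetical major axis; remaining edge
   points vote for the implied semi-minor `b` in a 1-px accumulator.
   Candidate quality `q = votes / P(a, b)` with `P` the Ramanujan ellipse
   perimeter, so `q ≈ 1` for a complete boundary and degrades gracefully
   under partial occlusion.
4. **Corrections** — seven rule-based repairs driven by the count prior
   (surplus, deficit, and end-to-end "chaining" cases, including splitting
   an oversized detection at `1.5×` the expected size into
   `round(major/expected)` animals), then a neighbour-frame rescue that
   scores sub-threshold candidates by weighted position / surface /
   contour similarity. Everything a rule touches is flagged `q = −1`.
   Identities propagate by Hungarian minimum-cost matching.
5. **Pose** — 100 evenly spaced contour points seed a Voronoi
   tessellation; interior vertices approximate the medial axis, and the
   Dijkstra shortest path between the best endpoint pair is the
   pseudo-skeleton.
6. **Kinematics** — calibrated thrust/slip/yaw decomposition, body length
   `L_t`, contraction amplitude `A = (1 − min L / max L)·100%`, a signed
   curvature index from integrals of the rotated skeleton's lateral
   coordinates, saccade (yaw peaks > 200°/s) and thrust-stroke
   (> 10 cm/s) detection, triggered averages, and a permutation test on
   group medians.

A synthetic scene generator (`make_crawler`, `make_swimmer`,
`make_multianimal`) renders crawling, burst–glide swimming and
occlusion/chaining scenes with complete ground truth under two lighting
regimes, so the whole pipeline is validated without any recorded data.

## Worked example

Track a synthetic crawler with 15% programmed peristaltic contraction and
recover the amplitude:

```r
library(midliner)

scene <- make_crawler(n_frames = 200, amplitude = 15, seed = 42)
cfg   <- pipeline_config(min_major = 70, max_major = 150, n_animals = 1)
cal   <- build_calibration("line", rbind(c(0, 0), c(100, 0)), 0.05)  # 0.5 mm/px
res   <- run_pipeline(scene$seq, cfg, cal = cal)

res$summary$frac_accepted            # 1.0  — every frame has a detection
k <- res$kinematics[["1"]]
contraction_amplitude(na.omit(k$body_length))
#> 15.6        # percent; the generator programmed 15
median(k$thrust)
#> 0.0206      # m/s forward speed of the crawl
mean(k$bending_angle, na.rm = TRUE)
#> 173.8       # degrees; 180 = perfectly straight body
```

The tracked body length oscillates between 91 and 108 px — the programmed
peristaltic cycle — and the recovered amplitude (15.6%) sits within the
tracking error of the programmed 15%. `locomotion_events(k, fps = 34)`
returns saccade/thrust events at the canonical thresholds, and
`permutation_median_test(A_group1, A_group2)` compares groups.

A thin command-line driver is installed with the package
(`system.file("cli/midline-track.R", package = "midliner")`) with
`synth`, `run` and `balance` subcommands over the same functions.

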