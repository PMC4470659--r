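---
title: "Tracking fruit fly swarms in 3D: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking fruit fly swarms in 3D: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swarmtrack)
```

`swarmtrack` reconstructs per-individual 3D trajectories — position *and*
body orientation — of hundreds of fruit flies (*Drosophila melanogaster*)
flying in a 360 mm transparent cubic arena, from three synchronized,
calibrated, back-lit cameras. This vignette explains the underlying models,
the tunable parameters and their defaults, what the bundled synthetic data
generator does and does not emulate, and the design choices made where the
method description leaves freedom.

## The measurement model: back-lit silhouettes

Under back-lighting a fly appears as a dark silhouette on a bright, nearly
uniform background. Wings are semi-transparent membranes and, because a
wing stroke (< 4 ms) is faster than the exposure at 100 frames/s, they
smear into a faint halo; body pixels are much darker than wing pixels.
Detection exploits exactly this ordering:

1. **Background model.** Per-pixel mean `mu(i)` and standard deviation
   `sigma(i)` over a training sequence, with a floor `sigma >= 1` grey
   level so the normalized residual is always defined (`fit_background`).
2. **Segmentation.** Pixel `i` is foreground iff
   `(I(i) - mu(i)) / sigma(i) < -C1`, with `C1 = 1.5`. The test is
   one-sided: only darker-than-background pixels can be a fly
   (`segment_foreground`).
3. **Blobs.** Connected foreground components (8-connectivity, minimum
   area 3 px by default) become blobs carrying pixel locations and
   intensities (`extract_blobs`).
4. **Wing removal.** Within each blob a local Gaussian intensity model
   (`mu_b`, population `sigma_b`) separates the dark body core from wing
   and boundary pixels: keep `i` iff `(I(i) - mu_b) / sigma_b < -C2`,
   `C2 = 1.5` (`remove_wing_pixels`). This only works because wings + blur
   halo contribute the brighter majority of blob pixels — the reason the
   renderer models wing smear explicitly (below).
5. **Weighted ellipse.** A 2D Gaussian is fitted to the refined pixels with
   weights `w(i) = |I(i) - mu(i)| / sigma(i)`, giving a sub-pixel centre
   and a covariance whose eigenstructure yields the ellipse axes
   (`fit_ellipse_weighted`). Semi-axes are `2 * sqrt(eigenvalue)`
   (roughly the 95% mass contour; the scale factor is recorded in the
   configuration so it is auditable). The axis ratio
   `gamma = major/minor >= 1` gauges how elongated — and therefore how
   orientation-informative — a silhouette is.

A *measurement* is a refined blob plus its ellipse.

## The target model and the tracker

A fly is a directed line segment of fixed length `l = 2.73` mm (the average
body length): location `(x, y, z)` plus orientation angles `(theta, phi)` —
azimuth from the world x-axis and elevation from the horizontal plane. The
tracker runs one particle filter (200 particles) per target:

* **Dynamics.** First-order linear extrapolation:
  `x_t = 2 x_{t-1} - x_{t-2} + v_t`, `v_t ~ N(0, Sigma)`. The default
  `Sigma = (2 mm)^2 I` matches the per-frame displacement scale of a
  400 mm/s fly at 100 fps deviating from straight flight; it is
  configurable (`transition_sigma`).
* **Association (POT).** Each predicted particle is associated to at most
  one measurement per view by the pixels-occupancy test: project a
  discrete gate surface (a sphere of diameter `l`, 200 Fibonacci-lattice
  points) into each view, rasterize with deduplication, and score each
  blob by `eta = |gate pixels ∩ blob pixels| / |blob pixels|`. Candidates
  need `eta > eta_c`; a particle with an empty view is a *missing
  particle* (weight 0, excluded from the state expectation). The
  threshold schedule is 0.5 for the first 30 frames of a track, then
  0.25 — restrictive while the appearance model is young, permissive once
  the track is established. One measurement may serve several targets
  (2D occlusions make this necessary).
* **MMPs and orientation.** The per-view candidates form matched
  measurement tuples (one measurement per view; Cartesian product capped
  at the 3 best per view). For each tuple, the two views with the largest
  `gamma` are used, provided both reach `gamma >= 1.3`: the ellipse
  major-axis endpoints back-project to a plane through each camera
  centre, and the two planes intersect in the body axis. Below the
  threshold the major axis carries no axis information (near-circular
  silhouette) and the orientation is carried over from the previous
  frame instead.
* **Weights.** `w ∝ p_ol * p_al`. The orientation likelihood rewards
  temporal consistency of the body axis; with `c` the cosine between
  consecutive direction vectors the default form is `exp(c - 1)`
  (maximal for aligned axes). The printed form `exp(-c)` of the source
  description penalizes consistency, which contradicts its stated intent;
  both are available (`ol_mode = "consistency"` / `"literal"`) and the
  mode is recorded in the configuration. The appearance likelihood is
  `prod_v exp(eta * ncc)` with `ncc` the centroid-aligned,
  intensity-normalized cross-correlation between the measurement's blob
  and the stored appearance.
* **Estimate.** The state is the weighted expectation over non-missing
  particles; orientations average as unit vectors and renormalize.
  Systematic resampling runs at the start of every frame, so weights do
  not accumulate across frames.

### Validation and correction

After estimation the association re-runs with gate points sampled from a
*generative body shape* — a profile curve revolved around the centre-axis —
and the restrictive threshold `eta_c = 0.8`. Success requires at least one
qualifying measurement in every view (the best per view forms the
validated tuple). The validated centres triangulate to a candidate
location; if it is farther than `l` from the estimate, the location is
replaced by the midpoint of the two. On success the appearance store is
refreshed (blobs + time stamp). Failures increment a consecutive-failure
counter; `max_failures = 5` closes the track. The restrictive threshold
means validation fails routinely at ~1 px state error — by design it
certifies only tightly locked states; the failure counter, not a single
failure, decides a track's fate. The corrected offset is also applied to
the particle cloud so the posterior moves with the published state.

The body profile is a spindle `rho(u) = r_max sin(pi u)`, `r_max = l/6`
(aspect ratio 3:1, matching a fly silhouette). The profile is an injectable
function, so a measured profile can replace it.

### Track lifecycle

Track initiation and the first-frame bootstrap are not part of the original
method description and are artifact decisions: measurements that no active
track claimed are matched greedily across views by two-view triangulation
plus reprojection-error gating (2 px default), each accepted tuple seeding
a track with a stationary motion prior (`previous = current`). Identities
are deliberately not maintained across disappearances — a fly that lands
and relaunches re-enters as a new identity.

## Orientation conventions

`phi` is elevation from the horizontal plane, matching the geometric
definition of the target model; the direction vector is
`(cos phi cos theta, cos phi sin theta, sin phi)`. The printed direction
formula in the source description uses a polar-angle convention
inconsistent with that definition; the polar form is available via
`angles_to_dir(..., convention = "polar")`, and the elevation convention is
the package-wide default. The head/tail sign of the reconstructed axis is
fixed against the previous orientation, falling back to the flight
direction, falling back to the +x hemisphere.

## The synthetic data generator

Every downstream stage is testable without original videos because the
package simulates and renders its own ground-truthed swarms.

* **Behavioural motion** (`simulate_swarm`): a correlated random walk with
  speed fluctuating around 400 mm/s (sd 100 mm/s), slow heading diffusion,
  and Poisson-like saccades (probability 0.03/frame, large heading
  changes) — straight flight interspersed with rapid turns, at 100 fps,
  with reflective walls. Optional short-range repulsion and mid-range
  cohesion forces, plus a centre pull that emulates swarming around a
  fixed marker (keeping an interacting swarm off the walls), let tests
  build swarms with a known interaction rule.
  Orientation equals flight direction.
* **Brownian null** (`simulate_random_particles`): uniform initial
  positions, i.i.d. Gaussian steps (default 4 mm ≈ one frame of flight),
  reflective confinement, 3000 steps — the social-force-free null for the
  spatial-structure comparison.
* **Rendering** (`render_frame`): background grey 200 with sub-quantization
  noise (sd 0.5 grey levels — diffused LED panels are very stable, so the
  detection sigma floor dominates), body silhouettes at grey 60 drawn by
  projecting the generative shape surface, and wings as motion-blurred
  shells: span directions fanning over the stroke arc with elevation
  scatter, rendered at 60% opacity toward grey 150. Surfaces attenuate
  light by their per-pixel coverage, emulating the optical blur of a
  target a few pixels across; this yields the continuous intensity
  distribution (dark core, brighter fringe) on which wing removal relies.
  Renders are bit-identical per seed; wing geometry reseeds per frame
  (positional inconsistency between frames), image noise per frame and
  view.

What the renderer does **not** emulate: perspective-dependent appearance
(legs, head/thorax texture), lens distortion, motion blur of the body,
interreflections from the acrylic walls, and landed flies' folded-wing
silhouettes. Passing closed-loop tests therefore demonstrates the
*algorithmic* correctness of the chain on faithful silhouette geometry and
intensity ordering, not robustness to every nuisance of real footage.

### Camera rig geometry

The default rig places three cameras ~900 mm from the arena centre on
near-orthogonal, slightly tilted axes (so no world direction is degenerate
in two views at once). Covering the whole cube from 900 mm requires a
field of view of ~1.85 arena sides at the centre depth; at the default
1536 × 1536 px this gives ~0.43 mm/px, a 2.73 mm fly spanning ~6 px.
Full-arena coverage and large fly silhouettes cannot both be had at desk
scale, so the orientation-accuracy benchmark uses a dedicated two-camera
rig zoomed to a 120 mm field (0.23 mm/px, flies ~12 px) — the
body-resolving scale at which ellipse axis ratios are meaningful, matching
the proportions of the full 2040-px experimental rig.

## Numerical choices

* Triangulation is homogeneous linear DLT by SVD — deterministic, no
  initialization; rank deficiency (identical cameras, parallel rays)
  raises an error rather than returning garbage.
* Plane-plane intersection refuses near-parallel planes (cross-product
  norm below 1e-6).
* Ellipse fits need >= 3 non-collinear pixels; blob refinement drops
  near-uniform blobs (population sd < 1e-9); degenerate measurements are
  dropped, not patched.
* The power-law fit `y = A x^(-B) + C` uses Levenberg-Marquardt with
  multi-start initialization and non-negativity bounds; standard errors
  come from the residual covariance. Constant-response inputs fail fast
  with a clear message.
* Systematic resampling (single uniform offset) keeps resampling variance
  minimal and makes the 50/50-weight case split exactly.
* Ties in validation ("most likely measurement") break by highest `eta`,
  then smallest centre distance to the state's projection.

## Swarm statistics

`kinematics` uses central differences (optionally Savitzky-Golay smoothed);
angular velocity is defined on velocity direction, where flight saccades
live. `nnd` gates only the *focal* fly by the 20 mm wall margin —
wall-adjacent flies still serve as neighbours (the alternative is a flag).
`fit_power_law` pools per-frame (density, mean NND) pairs; density is the
instantaneous tracked-fly count over the arena volume.
`acceleration_direction_map` needs a rotation taking the world x-axis onto
the neighbour direction, which leaves a roll degree of freedom; the
minimal rotation (axis `x̂ × n̂`) is used, making azimuth and elevation
well-defined with the centre bin meaning "accelerating straight at the
neighbour". The histogram normalizes to a density over the angle rectangle;
a `solid_angle` flag reweights by `1/cos(elevation)` for per-steradian
densities. The null comparison fits the closed-form Poisson-process NND
law (Weibull, shape 3) to the particle sample and reports a Welch t-test.

## Problem sizes used by the test-suite benchmarks

Chosen as the package's own desk-scale study conditions: the
orientation-error benchmark renders 500 flies; the dense-detection check
uses 100-fly frames; the end-to-end tracking benchmark tracks 20 flies for
100 frames (1 s) at the default rig; the null-model comparison uses 400
random particles over 3000 steps and a 120-fly interacting swarm. The
power-law recovery study repeats 100 fits of 500 pooled points spanning
the density range of 150-600 flies per arena volume.

## Known limitations

* Identity persistence across landings is out of scope by design; analyses
  treat re-entries as new tracks.
* The tracker assumes >= 2 views with `gamma >= 1.3` appear regularly; a
  fly flying straight at a camera for many frames keeps a stale
  orientation (flagged via `n_valid_views` and `validated`).
* At the full-arena pixel scale (~6 px bodies) the restrictive validation
  threshold fails on roughly half the frames even for well-locked tracks;
  this costs track longevity, not accuracy, and is absorbed by the failure
  counter.
* Appearance correlation over ~10 px patches is weakly discriminative;
  in very dense swarms association ambiguity is resolved mostly by the
  occupancy gate and the orientation prior.
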