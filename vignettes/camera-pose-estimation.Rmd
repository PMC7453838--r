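---
title: "Estimating camera pose from image evidence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating camera pose from image evidence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camfit)
```

## The problem

Fixed cameras, time-lapse rigs and aerial photographs are routine tools for
monitoring animal populations — penguin colonies photographed from a rocky
outcrop or a helicopter are the motivating case for this package. Counting,
sizing or tracking animals in such images requires mapping pixels to metric
ground coordinates, and that mapping depends on two groups of camera
parameters:

* **intrinsic** — focal length, sensor and image dimensions, lens
  distortion: known from the camera's data sheet;
* **extrinsic** — where the camera was and how it was oriented: elevation
  above the ground plane, tilt, roll, heading and x/y position. These are
  rarely measured in the field.

`camfit` reconstructs the extrinsic parameters from evidence *inside* the
image — objects of roughly known height, the visible horizon, landmarks
with map coordinates, or a second viewpoint — and quantifies the
uncertainty of every estimate by Metropolis Monte-Carlo sampling.

## The camera model

World coordinates are metric, z up, with z = 0 the reference ground plane;
the camera sits at `(pos_x, pos_y, elevation)`. A world point is first
translated by minus the camera centre and rotated into the camera frame
(x right, y down, z along the optical axis):

$$\mathbf{p}_c = R_{\mathrm{roll}}\, R_{\mathrm{tilt}}\, R_{\mathrm{heading}}\,(\mathbf{p}_w - \mathbf{c}).$$

Heading rotates about the world z axis (clockwise from +y, map
convention); tilt rotates about the camera x axis with tilt = 0 pointing
straight down (nadir) and 90° horizontal; roll rotates about the optical
axis, zero when the lower sensor edge is level. All angles are degrees at
the interface and radians internally. Any internally consistent convention
reproduces the same fits; this one is fixed and documented so that
configuration files are unambiguous.

The pinhole (rectilinear) projection maps a camera-frame point to pixels
through the effective focal length
$f_\mathrm{pix} = f \cdot w_\mathrm{image}/w_\mathrm{sensor}$:

$$u = f_\mathrm{pix}\,x_c/z_c + w/2, \qquad v = f_\mathrm{pix}\,y_c/z_c + h/2,$$

with the principal point fixed at the image centre and square pixels
assumed (the focal length computed from the sensor height must agree
within 1%, otherwise the constructor warns). Panoramic cameras use the
cylindrical or equirectangular mapping, which replace $x_c/z_c$ by the
azimuth angle and (for equirectangular) $y_c$ by the elevation angle;
these cannot be written as a matrix product but invert the same way.
Radial lens distortion `r' = r(1 + k1 r^2 + k2 r^4 + k3 r^6)` acts on
normalized image coordinates before the pixel offset; its inverse has no
closed form and is computed by damped Newton iteration to 1e-10 in
normalized units, with an explicit error if coefficients are too extreme
to converge.

Pixel coordinates are continuous, 0-based, anchored at the top-left
*corner* of the top-left pixel — click tools differ on this, so it is
stated here. Points behind a rectilinear camera are flagged invisible and
given `NA` coordinates rather than raising, so batch projection of mixed
point sets is total.

**Backprojection** is underdetermined — a pixel fixes a ray, not a point —
so one constraint must be supplied. The two used throughout:

* intersection with a horizontal plane z = z₀ (`backproject_to_plane`),
  used for feet of objects standing on the ground;
* the vertical axis through a known foot point
  (`backproject_with_foot_constraint`): the head pixel's ray generally
  misses that axis by a small skew, so the point on the ray closest to the
  axis is returned and its z is the estimated object height. (An
  alternative reading — constraining only the world x coordinate — would
  tie the result to the heading convention; the full horizontal position
  is used instead.)

Rays within 1e-12 of parallel to the target plane are treated as parallel:
they would otherwise "intersect" astronomically far away and poison
likelihoods silently.

## The horizon

For a camera at height h above a spherical earth of radius R (fixed at
6 371 000 m), the astronomical horizon is dipped below the horizontal by
$\delta = \arccos\!\big(R/(R+h)\big) \approx \sqrt{2h/R}$ — about 0.13°
at 16 m. The projected horizon is the image of this cone of directions; it
is *not* exactly a straight line (a conic that bows by about a pixel
across a 63° field of view), so the distance from a clicked point to the
model horizon is evaluated against the horizon point at the click's own
viewing azimuth. That is exact for clicks on the trace, perpendicular to
first order near it, and well defined for all three projection models.

## Fitting by object height

The user marks foot and head pixels of n objects whose height distribution
is known (e.g. adult animals, 0.75 m). For candidate extrinsics the feet
are backprojected to z = 0, the heads onto the vertical axes through the
feet, and each implied height is scored under the height prior; heights
from feet "above" the model horizon are impossible and the pose is
rejected. Horizon clicks, when present, add an independent Gaussian term
on their pixel distance to the model horizon. The pixel click-noise scale
(default 1 px) is the only weighting between the two terms. Flat priors
are used on elevation (1–100 m), tilt (30–120°) and roll (±10°); the
height prior is the only informative one.

The prior spread may be a number or `"free"`; a free spread is sampled in
log-space to keep it positive. Use a free spread when the true size
variation of the population is unknown (the typical field situation); use
a fixed spread when heights are known exactly — as in the synthetic
validation scenes, where every object is exactly 0.75 m tall and the only
scatter comes from click noise.

Posteriors are sampled with random-walk Metropolis: symmetric Gaussian
proposals, acceptance `min(1, p1/p0)`. Chains default to 10 000 iterations
with the first 20% discarded as burn-in. During burn-in a global proposal
factor targets 20–40% acceptance and the per-parameter scales are reshaped
every 250 iterations to the running chain standard deviations
(the 2.38/√d rule); adaptation freezes at the end of burn-in so the
retained chain is a valid Metropolis sample. Summaries report mean, sd and
central 68%/95% credible intervals per parameter.

Random-walk chains converge reliably only when started in the posterior's
basin. The sampler is therefore preceded by a short multi-start
Nelder–Mead mode search (each start is run twice — the restart re-expands
a collapsed simplex). With horizon clicks present the search is
additionally seeded along the curve the horizon itself implies: for any
trial elevation, roll follows from the clicked line's slope and tilt from
its height at the image centre plus the dip. Without this, the horizon
term — a ridge a few hundredths of a degree wide in tilt — is easy for a
blind search to miss. Pure random initialization remains available via
`optimize_start = FALSE`.

Configurations with very little information (one object, no horizon)
complete and are flagged `wide` rather than failing: the posterior itself
is the diagnostic.

## Geo-registration

Near-nadir aerial images defeat the object-height fit (apparent sizes
barely change across the frame), but if ≥3 landmarks can be matched
between the image and a map, the pose follows from registering the
backprojected landmarks to their map coordinates. The measurement model is
Gaussian on the ground-plane distances (σ = 1 m by default); the sampled
parameters are elevation, tilt, x/y position and heading, with roll fixed
at 0 by default because near-nadir geometry makes roll and heading
partially degenerate (it can be unlocked). The posterior mean is polished
by a deterministic Nelder–Mead refinement of the RMS ground distance,
which on noiseless landmarks recovers the generating pose to numerical
precision. Geographic coordinates are converted to a local tangent plane
by an equirectangular approximation about the reference point — adequate
below ~10 km, and its inverse round-trips below 1e-9°; full geodesic
treatment is out of scope.

## Stereo

When object sizes are unknown, two viewpoints determine them, provided
corresponding points can be marked in both images and either the baseline
distance or one object's true size is known. The relative orientation is
estimated by minimizing the symmetric point-to-epipolar-line distance in
*pixels* (world-space ray distances weight near and far points
inconsistently). Five scale-free parameters are sampled: the baseline
direction (azimuth and inclination on the unit sphere — the epipolar cost
is blind to baseline length) and tilt/roll/heading offsets of the second
camera. Triangulated points must lie in front of both cameras; this
chirality term separates the mirror-image solution that the epipolar cost
alone cannot. The absolute scale is applied afterwards: either the given
baseline length, or the ratio of a known size to its triangulated value.
A "known object size" is implemented as the distance between *two*
corresponded points (e.g. the foot and head of one animal), since a size
is a distance between two world points. Triangulation returns the midpoint
of the common perpendicular between the two rays, with the perpendicular
gap reported as a quality measure and near-parallel pairs flagged.

The classical Eight-Point algorithm appears only as an independent test
oracle (a fundamental matrix assembled from known truth poses); it is not
a user-facing code path.

## The synthetic scene generator

All validation runs on generated scenes with known truth; no external data
is used anywhere. The object generator reproduces the reference survey
conditions by default: 50 rectangles 0.75 m tall and 0.30 m wide placed
uniformly by area over the visible ground wedge between 50 and 150 m from
a camera with a 14 mm lens on a 17.3 × 9.7 mm sensor (4608 × 2592 px) at
16.1 m elevation, 85.3° tilt, 0.3° roll. "Randomly placed" is interpreted
as area-uniform over the wedge ∩ annulus; objects whose noiseless foot or
head projection falls within 5 px of the frame edge are redrawn, so all
clicks are in-frame by construction. Click noise is isotropic Gaussian,
default σ = 1 px — a realistic scale for careful manual clicking; its true
magnitude for hand-marked data is unknowable, which is one reason the
validation tolerances are not tighter. Horizon clicks default to 3 points,
the minimum practical input. The aerial generator uses a 300 m, 25°-tilt
camera and 8 landmarks with 0.5 px noise; the stereo generator two
oblique cameras 5 m apart sharing 20 points.

The generators emulate geometry and click noise only. They do not model
occlusion, terrain relief, non-flat ground, refraction, rolling shutter or
mis-identified correspondences — so passing tests demonstrate correctness
of the geometry and inference, not robustness to those field realities.
On real data the flat-ground assumption (animals standing on level sea
ice) is the one most worth checking.

## Numerical choices and problem sizes

* Distortion inversion: Newton, tol 1e-10 (normalized), max 50 iterations,
  explicit failure beyond.
* Parallel-ray threshold in plane intersection: |dz| < 1e-12·|d|.
* Metropolis: 20% burn-in; acceptance-window 50, scale factors ×0.7 / ×1.4
  outside 20–40%; covariance reshaping every 250 burn-in iterations from
  the last 500 samples.
* Mode search: Nelder–Mead, 400 iterations, run twice per start; 6 starts
  (object-height fit, plus 6 horizon-seeded), 25 (geo-registration),
  12 (stereo, followed by a 1500-iteration polish).
* The test-suite experiments use 3000–6000 chain iterations and 10–20
  replicates per property; the acceptance analysis uses the full 10 000
  iterations and 20 replicate scenes. These sizes give Monte-Carlo error
  comfortably below the tolerances being tested.
* Heading is sampled unwrapped and reported modulo 360°; posteriors
  straddling 0°/360° would need circular summaries, which only matters if
  the heading is essentially unconstrained.

## Known limitations

* Flat-ground assumption throughout; no digital elevation models.
* Tangential/thin-prism distortion, fisheye models, rolling shutter and
  atmospheric refraction of the horizon are not modelled.
* The equirectangular tangent-plane conversion degrades beyond ~10 km.
* Epipolar "lines" are straight only for the rectilinear model; for
  panoramic projections the construction is a chord approximation.
* Single-chain sd estimates carry Monte-Carlo noise of a few percent;
  near-degenerate configurations (minimal landmark sets, coplanar stereo
  points) warrant longer chains or more evidence rather than trust in a
  single run.
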