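# camfit

Extrinsic camera calibration and perspective mapping for field imagery.

Quantitative analysis of wildlife-monitoring photographs — counting
animals, measuring their positions, sizes and huddle areas — requires
mapping image pixels to metric ground coordinates. That mapping needs the
camera's **extrinsic parameters** (elevation above the ground plane, tilt,
roll, heading, x/y position), which are rarely measured in the field.
`camfit` reconstructs them from evidence visible in the image itself and
quantifies their uncertainty:

* **objects of known height** — foot/head click pairs of animals of a
  known size distribution, optionally constrained by a clicked **horizon**;
* **geo-referenced landmarks** — point correspondences between an aerial
  image and a map, for near-nadir views where object sizes carry no
  information;
* **stereo correspondences** — the same points marked from two viewpoints,
  with either the camera baseline or one object's true size fixing the
  absolute scale.

At its core is a pinhole camera model (with cylindrical and
equirectangular panoramic variants and radial lens distortion)

    u = f_pix * x_c / z_c + w/2,   v = f_pix * y_c / z_c + h/2,
    f_pix = f * w_image / w_sensor,

where the camera-frame point `(x_c, y_c, z_c)` is obtained from world
coordinates by `R_roll R_tilt R_heading (p − c)`. Backprojection
(pixel → world) is underdetermined and is solved under an explicit
constraint: intersection with the ground plane z = 0, or the vertical axis
through a known foot point (which yields object heights). The spherical-
earth horizon, dipped `arccos(R/(R+h))` below horizontal, is both a fit
constraint and a validation oracle. Posteriors for all fitted parameters
come from Metropolis Monte-Carlo sampling of the corresponding likelihood:
object heights scored under a height prior, horizon-click distances,
landmark registration distances, or symmetric point-to-epipolar-line pixel
distances; the sampled chains give means, standard deviations and credible
intervals. Images can be warped to metric top views (`topview_map`) using
the fitted pose.

## Worked example

Generate a synthetic survey scene with known truth — 50 objects 0.75 m
tall scattered 50–150 m in front of a camera at 16.1 m elevation, 85.3°
tilt, 0.3° roll, clicked with 1 px noise plus 3 horizon points — and
recover the camera from the clicks alone:

```r
library(camfit)

spec  <- scene_spec(seed = 1)                       # study defaults
scene <- generate_object_scene(spec, horizon_points = 3)
scene$clicks
#> Click set: 50 foot/head pairs, 3 horizon points (noise 1 px)

fit <- fit_extrinsics(scene$clicks, spec$intrinsics,
                      n_iter = 10000, seed = 1)
fit
#> Metropolis chain: 8000 retained samples, acceptance 29.3%
#>                mean     sd ci68_lo ci68_hi ci95_lo ci95_hi
#> elevation_m 16.0560 0.1470 15.9068 16.2048 15.7778 16.3443
#> tilt_deg    85.3151 0.0088 85.3065 85.3238 85.2975 85.3320
#> roll_deg     0.2781 0.0175  0.2610  0.2954  0.2435  0.3117
#> height_sd_m  0.0464 0.0046  0.0418  0.0509  0.0383  0.0564
```

The generating values (16.1 m, 85.3°, 0.3°) are recovered within a
fraction of the posterior spread; `height_sd_m` is the fitted spread of
the implied object heights (here purely click-noise-induced, since the
synthetic objects are all exactly 0.75 m). With the fitted camera, pixels
map to metres on the ground:

```r
backproject_to_plane(scene$clicks$foot[1:3, ], spec$intrinsics, spec$pose)
#>         x_m    y_m z_m
#> [1,]  17.38  86.59   0
#> [2,] -18.65  97.96   0
#> [3,] -34.33 113.13   0
```

The same pattern drives the other fits: `fit_georeference()` for
landmark ↔ map registration and `fit_relative_orientation()` +
`triangulate()` for stereo rigs. A command-line interface wraps it all
(`inst/cli/camfit`): `camfit simulate | fit | georef | stereo | project |
topview`, each writing a `run_manifest.json` (input hashes, seed, version)
sufficient to replay the run exactly.

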