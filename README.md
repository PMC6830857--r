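# gastro3d

Post-processing toolkit for whole-organ 3D reconstruction from monocular
endoscope video.

Gastroenterologists can in principle obtain a full 3D model of a stomach
from an ordinary endoscope recording: spray a contrast dye, film the whole
cavity, and hand the frames to an off-line structure-from-motion (SfM)
tool.  What the SfM tool returns, however, is not a usable model — the
video contains runs of hardware-duplicated frames that poison feature
matching, the triangulated sparse cloud is riddled with spurious 3D points,
and a colored surface still has to be produced and navigated.  `gastro3d`
implements those surrounding stages for R, leaving SfM itself to the
external tool whose `cameras.txt / images.txt / points3D.txt` output it
reads and writes:

* **Frame pre-processing** — RGB channel separation and duplicated-frame
  removal: successor frames whose fraction of changed pixels is below a
  threshold φ (default 0.6) are dropped against a running reference.
* **Outlier removal** (the core algorithm) — a four-stage cascade on the
  sparse cloud `P`, all thresholds relative to the bounding-box diagonal
  `r`:
  1. drop points whose nearest neighbour is farther than `A·r`
     (A = 0.05) → `P′`;
  2. drop points with fewer than `M = 80` neighbours in radius `r`
     (at most the 100 nearest are used);
  3. fit a plane to each point's neighbourhood with RANSAC, record the
     point-to-plane distance `D`, and drop every point with `D` above the
     mean → `P̂`;
  4. build a deliberately smooth mesh from `P̂` and drop points farther
     than `B·σ` (B = 5) from it, σ the standard deviation of the
     point-to-mesh distances → `P̃`.
* **Meshing** — PCA normal estimation (100 nearest neighbours),
  orientation from the observing camera poses, normal smoothing, implicit
  surface reconstruction (signed-distance field + marching tetrahedra,
  resolution `2^depth`), and per-vertex color transfer from the frames that
  see each vertex best (score `cos θ / (1 + d / r_mesh)`).
* **Retrieval & localization** — frames ranked by Euclidean distance
  between image descriptors `d = ‖f(I_r) − f(I_t)‖` (pluggable descriptor;
  a deterministic downsample descriptor is built in, default N = 100), and
  ray-cast footprints that place any registered frame onto the mesh.
* **Synthetic scenes** — a fully labeled generator (bumpy closed cavity,
  planted isolated/near outliers, interior camera trajectory with feature
  tracks, duplicate-frame fixtures) so everything above is testable without
  clinical data.

## Worked example

```r
library(gastro3d)

surface <- make_surface(seed = 2)                 # bumpy cavity surface
scene   <- sample_cloud(surface, seed = 3)        # labeled noisy cloud
scene
#> <synthetic_scene> 6000 points ( INLIER=5000, NEAR_OUTLIER=500,
#>   ISOLATED_OUTLIER=500 ), noise_sigma = 0.03

cleaned <- run_outlier_removal(scene$points, cleaning_config(ransac_seed = 1))
cleaned$report
#> <cleaning_report>
#>   stage sizes: P=6000 P_prime=5500 P_hat=4013 P_tilde=4006
#>   removed: isolated=500 census=0 plane_fit=1487 mesh=7
#>   avg_D = 0.05861  sigma = 0.01301

evaluate_cleaning(scene, cleaned$stage)
#> <eval_report> outlier P/R = 0.5015 / 1  inlier precision = 1
#>   surface RMSE = 0.02684
```

Reading the numbers: the isolated filter removed exactly the 500 planted
isolated outliers; the plane-fit stage removed all 500 near-surface
outliers (recall 1.0) plus the upper tail of the inlier distance
distribution — the above-mean rule always trims that tail, which is why
the removal-based precision is ≈ 0.5 while every point that was *kept* is
a true inlier (inlier precision 1.0).  The kept points sit within ≈ 0.027
scene units RMS of the analytic surface (noise σ was 0.03).

From the cleaned cloud to a surface:

```r
normals <- smooth_normals(cleaned$stage$points,
                          orient_normals(cleaned$stage$points,
                                         estimate_normals(cleaned$stage$points)))
mesh <- reconstruct_mesh(cleaned$stage$points, normals, depth = 6)
mesh
#> <triangle_mesh> 23558 vertices, 47112 faces
write_ply_mesh("model.ply", mesh)
```

A thin command-line front end over the same functions ships in
`inst/cli/gastro3d.R`:

```sh
Rscript inst/cli/gastro3d.R synth --preset small --seed 0 --out demo
Rscript inst/cli/gastro3d.R clean --sparse demo/sparse --A 0.05 --M 80 --B 5 \
        --seed 0 --out cleaned.ply --report report.json
Rscript inst/cli/gastro3d.R mesh --cleaned cleaned.ply --sparse demo/sparse \
        --depth 7 --out model.ply
```

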