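# navreg

Two-stage rigid registration of sparse tracked-probe points to dense
CT-derived bone surfaces, for image-guided orthopaedic (hip) navigation.

The package implements the standard surgical patient-registration pipeline:

1. **Coarse alignment** — three paired anatomical landmarks, solved in closed
   form by the SVD/Kabsch method with a proper-rotation (reflection) guard.
2. **Fine refinement** — a robust sparse point-to-plane iterative closest
   point (ICP): point-to-plane residuals are penalized with an Lp
   sparsity-inducing norm (`p = 0.5`) and minimized by ADMM, alternating a
   hard-thresholding proximal step on auxiliary residuals, a linearized
   SE(3) pose solve, and a dual ascent. Outlier probe points (slips,
   cartilage stand-off) are effectively self-gated by the loss.

Everything needed for a desk-scale validation study ships with the package:
exact kd-tree neighbour search and PCA normal estimation (C++/Rcpp), STL/PLY/
OBJ and point/landmark/transform I/O, a synthetic bone-phantom generator with
hidden ground truth, and a repeated-paired-trials evaluation protocol (TRE,
RMSE, STD, MaxErr; ablations; probe-count sweeps). All computations are
deterministic given a seed.

## Worked example

Simulate a femoral-head phantom under realistic noise (0.2 mm probe noise,
20 % outliers displaced 2–5 mm, 2 mm landmark noise), then register its
probe points back to the CT-frame surface cloud:

```r
library(navreg)

cfg <- phantom_config("ball_shaft", probe_noise_sigma = 0.2,
                      outlier_fraction = 0.2, seed = 3)
ph <- make_phantom(cfg)
ph
#> <synthetic_phantom> ball_shaft: 50000 target points, 30 probe points (6 outliers), 4 fiducials
#>   probe noise sigma 0.20 mm, landmark noise sigma 2.00 mm, seed 3

out <- register_pipeline(ph$probe_points, ph$target_cloud,
                         ph$coarse_landmarks, method = "sparse_p2pl")
out$coarse
#> <coarse_solution>  rms residual 1.5954 mm  (singular values 1281, 294.7, 4.716e-15 mm^2)
#> <rigid_transform>  angle: 17.4289 deg  |t|: 52.7609 mm
#>             R1        R2       R3         t
#> [1,]  0.954156 -0.277613 0.111877 25.881171
#> [2,]  0.278907  0.960309 0.004232 45.923198
#> [3,] -0.108611  0.027165 0.993713  2.220917

evaluate_registration(ph, out$total)
#> <metrics_report> TRE 1.1647 mm | RMSE 1.4961 | STD 1.2854 | MaxErr 4.3658 (over 4 fiducials, 30 pairs)

evaluate_registration(ph, out$coarse$transform)$tre
#> [1] 6.179767
```

The fine stage reduces the target registration error from 6.18 mm (coarse
landmarks alone) to 1.16 mm despite six gross outliers among thirty probe
points.

## Study protocols

The paired ablation over the four configurations (coarse only, point-to-point,
point-to-plane, sparse point-to-plane), thirty repeats, identical inputs per
repeat:

```r
ab <- run_ablation(cfg, n_repeats = 30, base_seed = 1)
ab$summary[, c("method", "n", "tre_mean", "tre_sd")]
#>        method  n tre_mean   tre_sd
#> 1 coarse_only 30 6.463164 4.027321
#> 2        p2pt 30 4.743240 3.383186
#> 3        p2pl 30 3.896947 3.176935
#> 4 sparse_p2pl 30 1.805419 2.290409
```

and the probe-count sweep (`run_sample_sweep()`), which shows mean TRE
improving from 11.9 mm at 10 probe points to 1.8 mm at 30.

See the vignette (`vignettes/sparse-icp-registration.Rmd`) for the method
derivation, parameter table, phantom design rationale (including why
near-spherical surfaces are rotation-degenerate for point-to-plane metrics)
and limitations.

## Command line

A thin CLI wraps the exported functions:

```sh
Rscript inst/cli/navreg.R simulate --shape ball_shaft --seed 3 --out phantom_out
Rscript inst/cli/navreg.R register --source phantom_out/probe.csv \
    --target phantom_out/target.csv --landmarks phantom_out/landmarks.csv \
    --out transform.json
Rscript inst/cli/navreg.R ablate --out ablation.json --repeats 30
```

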