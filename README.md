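# mpodmapr

Macular pigment — the yellow xanthophyll carotenoids concentrated in the
fovea — screens blue light. Two-wavelength autofluorescence (2WAF)
imaging exploits this: the retina is imaged with blue (488 nm, absorbed
by the pigment) and green (514 nm, not absorbed) excitation, and the
macular pigment optical density (MPOD) at each pixel is

```
MPOD(p) = log10( G(p) / B(p) )  −  log10( G / B  at 9° eccentricity )
```

anchored to a peripheral reference annulus where pigment is assumed
absent. `mpodmapr` is an R toolchain for researchers working with such
image pairs. It provides:

* **MPOD maps** — per-pixel log-ratio rasters with validity masks,
  two-pass reference anchoring, and pseudocolor rendering;
* **five centration algorithms** for locating the center of the pigment
  distribution: `FOVEA` (externally supplied anatomical center), `MAX`
  (smoothed maximum), `CENTROID` (weighted average), `CONTOUR`
  (half-maximum iso-contour convex hull) and `HILLCLIMB` (iterated
  windowed centroid), plus method-comparison statistics with 95%
  prediction ellipses;
* **profiles** — radial circle bins, cumulative discs, and twelve
  30° clock-hour wedge profiles;
* **pattern classification** — automatic assignment of each wedge to the
  four canonical spatial patterns (peak / ring / mixed / dip) and a
  7-of-12 majority vote per eye, with manual-override bookkeeping;
* **agreement statistics** — Cohen's kappa, two-way ICC, Bland–Altman
  limits;
* **a synthetic phantom generator** producing 2WAF pairs with known
  pigment field, true center and true pattern, used as ground truth by
  the entire test suite;
* **batch processing** over JSON/YAML manifests with TSV/CSV/TIFF
  outputs, and a thin command-line interface
  (`inst/cli/mpodmapr.R`).

## Worked example

Simulate a noisy "ring" eye (central peak plus a parafoveal crest at
0.9°), run the full pipeline, and inspect the results:

```r
library(mpodmapr)

sim <- simulate_pair(default_phantom_spec("ring", noise_sigma = 0.02,
                                          seed = 11))
res <- process_eye(sim$pair)

res
#> eye_result 'eye': pattern ring (12/12), center (383.42, 383.46) [HILLCLIMB]

res$pattern
#> pattern_result: ring (vote 12/12)
#>   counts: peak=0 ring=12 mixed=0 dip=0
```

All 12 wedges vote ring, so the eye is labeled ring with confidence.
The radial profile shows why: MPOD falls from ~0.49 AU at the foveola to
~0.12 AU at 0.45°, then *rises again* to ~0.19 AU at the 0.95° crest —
the signature of a parafoveal ring:

```r
pr <- res$circles
round(pr[pr$bin_center %in% c(0.05, 0.45, 0.95),
         c("bin_center", "mean", "sd", "count")], 4)
#>    bin_center   mean     sd count
#> 1        0.05 0.4886 0.0277    20
#> 5        0.45 0.1157 0.0212   183
#> 10       0.95 0.1918 0.0178   379
```

The recovered center sits 0.09 px (~1 µm at 11.3 µm/px) from the true
phantom center:

```r
compare_centers(
  data.frame(eye_id = "eye", method = "HILLCLIMB",
             x = res$primary_center$x, y = res$primary_center$y),
  data.frame(eye_id = "eye", x = 383.5, y = 383.5))$per_eye
#>      method    dist_px   dist_um
#> 1 HILLCLIMB 0.08650068 0.9774576
```

From the shell, the same pipeline is:

```sh
Rscript inst/cli/mpodmapr.R simulate --pattern ring --seed 11 --out work/
Rscript inst/cli/mpodmapr.R classify --blue work/phantom_ring_blue.tif \
    --green work/phantom_ring_green.tif --out work/
```

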