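# actindisp

Entropy-based spatial dispersion of the F-actin cytoskeleton in
fluorescence micrographs.

## What it does and for whom

Cell biologists quantifying cytoskeletal organization — for example in
vascular smooth muscle cells, where disease mutations disorganize the
stress-fiber network — need an objective per-image score instead of
visual inspection of phalloidin/DAPI stainings. `actindisp` computes
one: the **spatial dispersion** `dsp ∈ [0, 1]`, the normalized Shannon
entropy of the joint distribution of stress-fiber positions and
orientations. Ordered networks (parallel fibers, regular placement
around the nucleus) score near 0; disorganized networks score near 1.

## The measure

For an RGB micrograph (actin green, nuclei blue), resized to
512 × 512:

1. Stress-fiber edges are outlined by Canny detection whose dual
   hysteresis thresholds adapt to the image's gradient statistics:
   `Tmax = M + 2S`, `Tmin = Tmax / T`, with `M`, `S` the mean and
   population SD of the Sobel gradient magnitude `G = √(Gx² + Gy²)` and
   `T` the reduction ratio (default 2).
2. Nuclei are segmented as blue regions in HSV space; small regions and
   short edges are filtered out.
3. Each edge segment `i` yields a feature point `(Davg_i, A_i)`: mean
   distance from the segment centroid to all nucleus centers, and the
   principal-axis orientation in `[0°, 180°)`.
4. The feature plane is divided into `n` cells (8 × 8 by default);
   with `p_j` the fraction of points in cell `j`,

   ```
   etp = Σ −p_j · log(p_j)        dsp = etp / log(n)
   ```

Groups of images are compared with the unpaired pooled-variance
Student t-test (mean ± SEM, t, df, two-sided p).

## Worked example

No real micrographs are needed: the package ships a seeded synthetic
generator with ground truth.

```r
library(actindisp)

pair <- ordered_vs_random_pair(fixture_spec(seed = 1))
compute_dispersion(pair$ordered$image)
#> <dispersion_result> dsp = 0.1421 (etp = 0.5908 nats, n = 64 bins)
#>   36 feature points from 36 edge segments, 1 nuclei
compute_dispersion(pair$disordered$image)
#> <dispersion_result> dsp = 0.7224 (etp = 3.0046 nats, n = 64 bins)
#>   26 feature points from 26 edge segments, 1 nuclei
```

The ordered member (parallel filaments on a ring at fixed distance from
the nucleus) concentrates its feature points in few cells, hence the low
entropy; the disordered member (uniform orientations and placement)
spreads them out. Batch use from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/actindisp.R", package = "actindisp"))')
Rscript $CLI fixtures --output fx --pairs 1 --singles 1 --seed 4
Rscript $CLI run --input fx --output res.csv
Rscript $CLI compare --group-a ctrl.csv --group-b mutant.csv --output cmp.json
#> t = -12.2474, df = 4, p = 0.0002552
#> group A: mean 0.1500 +/- 0.0289 SEM (n = 3)
#> group B: mean 0.6500 +/- 0.0289 SEM (n = 3)
```

Every result row carries `n_points`, `n_nuclei`, `n_bins`, `etp_nats`,
`dsp` and a hash of the full parameter record; `inspect` writes edge-map
and nucleus overlays plus per-segment tables for one image.

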