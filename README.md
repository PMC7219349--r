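# fsflicm

Robust unsupervised segmentation of noisy raster images by local fuzzy
clustering, in R.

Fuzzy c-means (FCM) segments an image by minimizing
`J = Σᵢ Σⱼ z_ij^m ‖xᵢ − vⱼ‖²` over soft memberships `z_ij` (rows on the
simplex) and class centers `vⱼ`, but treats every pixel in isolation, so
impulse or speckle noise shreds its label maps. The FLICM family repairs
this with a *fuzzy factor* `G_ij` that couples each pixel's membership to
its neighbors' memberships and intensities. This package implements that
family end to end:

* **`fcm`** — plain fuzzy c-means (the non-spatial baseline and the
  initializer for everything else);
* **`flicm`** — fuzzy local information c-means, with
  `G_ij = Σ_{β∈Nᵢ} (1+d̃_iβ)⁻¹ (1−z_βj)^m ‖x_β−vⱼ‖²`;
* **`iflicm`** — an improved FLICM whose fuzzy factor damps the spatial
  distance by the neighbor's own membership, `z_βj/(d̃_iβ z_βj + 1)`, and
  whose center update follows from one Lagrangian stationarity condition;
* **`fs` (`fsfcm()`)** — the main algorithm: feature-selection
  Gaussian-mixture local fuzzy clustering. Each pixel–class–feature triple
  carries a *saliency* `s_ijl ∈ (0,1)` deciding whether feature `l` is
  class-discriminative (distance to the class mean `μ_jl`) or background
  (distance to a common mean `ε_l`). KL-divergence penalties
  `λ Σ z log(z/π)` and `γ Σ z [s log(s/ρ) + (1−s) log((1−s)/(1−ρ))]` tie
  memberships to class priors `π_j` and saliencies to feature weights
  `ρ_l`. All updates are closed-form stationary points of the objective,
  and the membership softmax is additionally weighted by
  `H_ij^α`, the per-class **median of the neighbors' memberships** — a
  median-filter-like postprocessing that suppresses impulse noise.

Around the clusterers the package provides piecewise-constant phantom
generators with the four matching noise models (Gaussian, salt-and-pepper,
multiplicative/speckle, mixed), misclassification-rate (MCR) scoring with
optimal label-permutation matching, PSNR against class-mean
reconstructions, PNG/TIFF/PGM image I/O, and a command-line interface.

Intended users: anyone benchmarking robust clustering segmentation on
noisy single-channel (or RGB) images — remote sensing tiles, CT slices,
synthetic phantoms.

## Worked example

```r
library(fsflicm)

ph    <- make_phantom(64, 64, levels = c(40, 200), layout = "stripes", seed = 1)
noisy <- add_salt_pepper(ph$image, density = 0.2, seed = 7)

fit <- fuzzy_segment(noisy, C = 2, method = "fs", seed = 1)
fit
#> feature-selection local fuzzy clustering fit
#>   image: 64 x 64 pixels, 1 channel(s)
#>   classes: 2; fuzzifier m = 2
#>   300 iteration(s); not converged
#>   class centers:
#>         [,1]
#> [1,]  37.693
#> [2,] 204.388

score_segmentation(ph, predict(fit))
#> segmentation score: MCR = 0.879%, PSNR = 24.67 dB

score_segmentation(ph, predict(fuzzy_segment(noisy, C = 2, method = "fcm", seed = 1)))
#> segmentation score: MCR = 9.814%, PSNR = 14.58 dB
```

With 20% of pixels replaced by impulse extremes, plain FCM mislabels
about 10% of the image (roughly the half of the impulses that jump across
the decision boundary), while the feature-selection algorithm recovers the
two stripes to within 0.9% of pixels: its class centers (37.7, 204.4) sit
next to the true levels (40, 200) despite the corruption. `predict()`
returns the max-membership label map, `coef()` the class centers,
`fitted()` the piecewise-constant reconstruction, and `plot()` displays
the segmentation. A "not converged" flag after 300 iterations is common
under heavy impulse noise — a handful of boundary pixels can oscillate
under the lagged median field — and is reported honestly rather than
hidden; the label map is stable.

The same runs from the shell:

```sh
Rscript inst/scripts/fuzzyseg phantom --levels 40,200 --noise sp --density 0.2 \
        --height 64 --width 64 --seed 7 --out-dir ph/
Rscript inst/scripts/fuzzyseg segment --in ph/noisy.png --truth ph/truth.png \
        --algorithm fs --clusters 2 --seed 1 --out-dir run/
Rscript inst/scripts/fuzzyseg benchmark --algorithms fcm,flicm,iflicm,fs \
        --seeds 1,2,3 --noise gaussian --sigma 57 --levels 40,200 --out-dir bench/
```

Every run writes a `config.json` echo of all resolved parameters plus the
seed, so any artifact is reproducible on its own.

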