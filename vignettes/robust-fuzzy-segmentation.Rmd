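---
title: "Robust local fuzzy clustering segmentation: model and methods"
author: "fsflicm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust local fuzzy clustering segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsflicm)
```

This vignette is the package's own account of the models it implements,
the numerical choices behind them, and what the test suite does and does
not demonstrate.

## The segmentation problem

Given an image with $N$ pixels and $D$ feature channels ($D = 1$ for the
reference grayscale case), unsupervised segmentation into $C$ classes
means estimating a soft membership matrix $z \in [0,1]^{N \times C}$ with
unit row sums and hardening it by maximum membership. Plain fuzzy c-means
(FCM) minimizes $\sum_{ij} z_{ij}^m \lVert x_i - v_j\rVert^2$ and ignores
the pixel grid entirely, so a single impulse pixel flips its own label no
matter what its neighborhood looks like. The algorithms here add spatial
information through a *fuzzy factor*: a per-pixel, per-class penalty
accumulated over the window neighborhood $N_i$.

## The four clusterers

**FCM** (`fcm`) is the baseline and the initializer of the others:
seeded random memberships, alternating center/membership updates,
stopping when $\max_{ij} |z^{(\tau+1)} - z^{(\tau)}| < \delta$.

**FLICM** (`flicm`) adds
$G_{ij} = \sum_{\beta \in N_i} \frac{1}{1 + \tilde d_{i\beta}}
(1 - z_{\beta j})^m \lVert x_\beta - v_j \rVert^2$
to the squared distance in the membership update, where
$\tilde d_{i\beta}$ is the Euclidean distance between grid coordinates
(1 or $\sqrt 2$ in a $3\times3$ window). Neighbors that confidently
belong to class $j$ contribute nothing; confident outsiders far from
$v_j$ contribute a large penalty, which is what absorbs isolated noise
pixels into their region. Two damping conventions circulate in the
literature, $1/\tilde d$ and $1/(1+\tilde d)$; we default to
$1/(1+\tilde d)$, which avoids overweighting the four edge neighbors,
and expose `weighting = "inverse"` for the bare reciprocal.

**Improved FLICM** (`improved_flicm`) additionally damps the spatial
distance by the neighbor's own membership,
$u = z_{\beta j}/(\tilde d_{i\beta} z_{\beta j} + 1)$, and replaces the
plain FCM center update by the stationary point of the spatially coupled
objective: each center mixes the central pixels with their
membership-weighted neighbors,
$v_{jl} = \sum_i z_{ij}^m (x_{il} + \sum_\beta w_{i\beta} x_{\beta l}) /
\sum_i z_{ij}^m (1 + \sum_\beta w_{i\beta})$ with
$w_{i\beta} = (1-z_{\beta j})^m / (z_{\beta j}\tilde d_{i\beta} + 1)$,
so membership and center updates derive from one Lagrangian.

**Feature-selection local fuzzy clustering** (`fsfcm`, the method of
interest) starts from the observation that the two ancestors weigh every
feature equally. It attaches to each pixel–class–feature triple a
saliency $s_{ijl} \in (0,1)$: when salient, feature $l$ is measured
against the class mean $\mu_{jl}$; when not, against a common background
mean $\varepsilon_l$. The objective is

$$J = \sum_{ij} z_{ij}\,(d_{ij} + G_{ij})
  + \lambda \sum_{ij} z_{ij} \log\frac{z_{ij}}{\pi_j}
  + \gamma \sum_{ijl} z_{ij}\Big(s_{ijl}\log\frac{s_{ijl}}{\rho_l}
  + (1-s_{ijl})\log\frac{1-s_{ijl}}{1-\rho_l}\Big)$$

with $d_{ij} = \sum_l s_{ijl}(x_{il}-\mu_{jl})^2 +
(1-s_{ijl})(x_{il}-\varepsilon_l)^2$ and $G_{ij}$ its neighbor-weighted
analogue using $u_{i\beta j} = (1-z_{\beta j})^m/(z_{\beta j}\tilde
d_{i\beta}+1)$. The entropy (KL) terms pull memberships toward class
priors $\pi_j$ and saliencies toward per-feature weights $\rho_l$; this
is a Gaussian-mixture-flavored model in which the saliency plays the role
of a feature-relevance probability. Every update is the exact stationary
point of $J$ in its own block:

* $s_{ijl}$: logistic in the logit $t_{ijl}$ = (background distance) −
  (class distance), both neighbor-augmented;
* $\mu_{jl}, \varepsilon_l$: saliency-weighted means over pixel + neighbor
  terms;
* $\rho_l = \frac1N \sum_{ij} z_{ij} s_{ijl}$,
  $\pi_j = \frac1N \sum_i z_{ij}$;
* $z_{ij} \propto \pi_j \, H_{ij}^\alpha \, e^{-\eta_{ij}/\lambda}$,
  where $\eta_{ij}$ collects the saliency-weighted distances and saliency
  KL terms, and $H_{ij}$ is the **median of the neighbors' memberships**
  for class $j$ — a postprocessing weight (outside $J$) that acts like a
  median filter on the membership field and is provably monotone:
  raising $H_{ij}$ can only raise $z_{ij}$.

The iteration schedule is: FCM initialization of $\mu$ and $z$ (plus
diagnostic class/global variances), $\rho_l = 1/D$, $\pi_j = 1/C$,
$\varepsilon$ = global feature means; then repeat (median field →
saliency → membership → model) until the max-norm membership change drops
below $\delta$ or the iteration cap is reached. Hitting the cap is *not*
an error: the converged flag is reported as `FALSE`.

### Printed-form repairs

Several published statements of this model are internally inconsistent
(a pixel-level saliency logit where the derivation needs a per-feature
one; a self-referential normalizer for $\varepsilon$; a center update
that drops the neighbor terms its own stationarity condition contains).
We resolved every such conflict in favor of the Lagrangian derivation:
each implemented update must annihilate the numeric partial derivative of
the objective, and the test suite enforces this with an independent
oracle (central differences of a naive loop-based objective) at relative
tolerance $10^{-5}$ on dozens of random instances. The literal
"plain weighted mean" center update remains available as
`center_update = "printed"`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 2 | fuzzifier exponent; the universal FCM choice |
| `lambda` | 1000 | membership-entropy weight, calibrated against squared 0–255 intensity distances (features are deliberately **not** rescaled to [0,1]) |
| `gamma` | 1000 | saliency-KL weight, same scale as `lambda` |
| `alpha` | 2.0 | exponent on the median field; 0 disables the postprocessing |
| `window` | 3 | odd neighborhood side (3 or 5) |
| `tol` | 1e-4 | max-norm membership change threshold |
| `max_iter` | 300 | iteration cap |

Because distances are squared 0–255 intensities, $\eta/\lambda$ spans
roughly 0–600: the membership softmax is computed in log space
(log-sum-exp), the saliency logistic via `plogis`, and $s$, $\rho$, $H$,
$z$ are clamped to $[10^{-12}, 1-10^{-12}]$ before any logarithm or
denominator. Degenerate classes (total saliency-weighted membership
below $10^{-12}$) keep their previous mean with a warning rather than
dividing by zero. Singular zero distances in the FCM/FLICM membership
update give a crisp membership on the first such class
(deterministic tie-break). All randomness flows from one integer seed
through the membership initialization; fits are bitwise reproducible.

Boundary handling truncates windows at the image border (no padding or
mirroring): border pixels simply have fewer neighbors, and every
neighbor sum stays well defined. Even-sized neighbor sets take the mean
of the two central order statistics as their median; a pixel with no
neighbors at all keeps its own membership as $H$.

## Synthetic phantoms and noise models

`make_phantom` builds piecewise-constant multi-class scenes (stripes,
quadrants, or seeded Voronoi blobs, each class holding at least 5% of
pixels) with known labels. The noise operators emulate the standard
corruption models at 8-bit scale:

* `add_gaussian(sigma)` — i.i.d. $\mathcal N(0,\sigma^2)$ per pixel,
  clipped to range. Noise levels quoted in the source literature
  (57, 80, 140, 161) are read as **standard deviations on the 0–255
  scale**: values of that magnitude read as variances would be visually
  negligible; a `sigma_is_variance` flag keeps the other reading.
* `add_salt_pepper(density)` — an exact count `round(density·N)` of
  uniformly chosen pixels, half set to the range minimum and half to the
  maximum. Exact-count corruption makes the contract testable.
* `add_multiplicative(sigma)` — speckle `x·(1+n)`,
  $n \sim \mathcal N(0,(\sigma/255)^2)$; the 0–255-scale level is
  converted to a unit-relative spread. This parameterization is a stated
  package convention; speckle conventions vary across the literature.
* `add_mixed(sigma, density)` — Gaussian first, then impulse, so impulse
  pixels are pure extremes (order configurable).

The study conditions used by the tests and `scripts/acceptance.R` are
2-class 64×64 stripes at levels (40, 200) — interior gray levels, so that
range clipping does not quietly remove noise mass — with 20%
salt-and-pepper or Gaussian $\sigma = 57$; 3-class 64×64 stripes at
(50, 128, 210) with $\sigma = 10$ for parameter recovery; and a clean
32×32 phantom for exact recovery. These sizes keep the full suite in the
low minutes while leaving hundreds of noise pixels per image.

## Evaluation

`mcr` computes the misclassification percentage after choosing the label
permutation that maximizes agreement — clustering labels are arbitrary,
so without matching the number would be seed-dependent. The search is
exhaustive for $C \le 6$ and an exact Hungarian assignment beyond; both
agree wherever both run (tested). `psnr` is $10\log_{10}(\text{peak}^2 /
\text{MSE})$ with an `inf` sentinel for identical images.
`score_segmentation` computes PSNR between the clean phantom and the
class-mean reconstruction of the *predicted* labels: the original
experiments' PSNR reference is not stated anywhere we could verify, and
this convention makes PSNR computable from a phantom alone while
measuring segmentation fidelity.

## What the tests show — and what they do not

The property suite verifies: stationarity of every closed-form update
against numeric differentiation; simplex conservation of $z$ and $\pi$ at
every iteration; monotonicity of membership in the median field;
reduction of FLICM to FCM when the spatial term is disabled (bitwise,
shared seed); exact recovery of clean phantoms by all four algorithms;
class-mean recovery within ±5 gray levels under $\sigma = 10$ noise; and
the robustness ordering — the feature-selection algorithm beats FCM in at
least 8 of 10 seeds under both heavy impulse and heavy Gaussian noise
(in our runs, 10 of 10).

Piecewise-constant phantoms are a favorable setting: real remote-sensing
or CT scenes have textured classes, gradual boundaries, and non-i.i.d.
noise, none of which the generator emulates. Passing these tests shows
the implementation is faithful and noise-robust in the modeled sense; it
does not certify performance on real scenes. Two further honest
observations from our runs: on such simple 2-class phantoms plain FLICM
is already near-optimal and can edge out the feature-selection algorithm
(whose per-feature machinery has nothing to select with $D = 1$); and
with class levels at the intensity extremes the saliency escape hatch
($s \to 0$ lets a distant class fall back to the background mean) can
shift a stripe boundary by one row. Both behaviors follow from the model
itself — the updates remain verifiably stationary — and are limitations
of the method, not of the implementation.

A second known limitation: under heavy impulse noise the alternation
(with its one-iteration-lagged median field) can settle into a
period-two oscillation of a few boundary pixels instead of meeting the
max-norm threshold; the fit then runs to the iteration cap and reports
`converged = FALSE` while the hardened label map is stable.

## Design choices that were genuinely open

* **Class variances** $\sigma_j^2, \nu_l^2$ are computed at
  initialization but enter no update — the model's distances are
  unscaled squared intensities, not Gaussian log-densities. They are
  retained as diagnostics only; no variance-scaled mode is offered.
* **$\alpha$** is fixed at 2.0 by default (its conventional value) and
  exposed as a free parameter.
* **RGB input** contributes $D = 3$ features; the reference
  configuration is grayscale, and the CLI converts to gray on read.
* **Native intensity units** are kept throughout because
  $\lambda = \gamma = 1000$ are calibrated against squared 0–255
  distances; rescaling features to [0,1] would silently change the
  effective regularization by four orders of magnitude.
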