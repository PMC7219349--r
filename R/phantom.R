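# Synthetic piecewise-constant phantoms and the four noise models used in
# the segmentation benchmarks.  All noise operators clip to the image's
# intensity range and are deterministic given their seed.

#' Generate a piecewise-constant multi-class phantom
#'
#' Builds a ground-truth test image: each class occupies a region of the
#' grid and carries one constant gray level.  Layouts: `"stripes"`
#' (horizontal bands of equal height), `"quadrants"` (the four image
#' quadrants, classes assigned round-robin), and `"blobs"` (nearest-seed
#' Voronoi regions from seeded random points, re-drawn until every class
#' holds at least 5\% of the pixels).
#'
#' @param height,width grid shape in pixels.
#' @param levels strictly increasing class gray levels (one per class).
#' @param layout region layout.
#' @param seed integer seed (used by the `"blobs"` layout; the other
#'   layouts are deterministic).
#' @param intensity_range representable range, default `c(0, 255)`.
#' @return an object of class `phantom`: list with `image` (clean
#'   [feature_image()]), `truth` ([label_map()]), `class_levels`.
#' @examples
#' ph <- make_phantom(4, 4, levels = c(0, 255), layout = "stripes", seed = 1)
#' vec_to_grid(ph$truth$labels, 4, 4)
#' @export
make_phantom <- function(height, width, levels,
                         layout = c("stripes", "quadrants", "blobs"),
                         seed = 1L, intensity_range = c(0, 255)) {
  layout <- match.arg(layout)
  C <- length(levels)
  if (C < 1L) stop("need at least one class level", call. = FALSE)
  if (C > 1L && any(diff(levels) <= 0))
    stop("class levels must be strictly increasing", call. = FALSE)
  if (any(levels < intensity_range[1L] | levels > intensity_range[2L]))
    stop("class levels outside intensity range", call. = FALSE)
  n <- height * width
  lab <- switch(layout,
    stripes = {
      if (height < C) stop("stripes layout needs height >= C", call. = FALSE)
      band <- pmin((seq_len(height) - 1L) %/% (height / C), C - 1L)
      grid_to_vec(matrix(band, height, width))
    },
    quadrants = {
      if (height < 2L || width < 2L)
        stop("quadrants layout needs a 2 x 2 grid at least", call. = FALSE)
      if (C > 4L) stop("quadrants layout supports at most 4 classes",
                       call. = FALSE)
      top <- seq_len(height) <= height %/% 2L
      left <- seq_len(width) <= width %/% 2L
      quad <- outer(!top, !left, function(b, r) 2L * b + r)  # 0..3
      grid_to_vec(matrix(quad %% C, height, width))
    },
    blobs = {
      if (n < 4L * C) stop("blobs layout needs more pixels", call. = FALSE)
      lab <- NULL
      for (try in seq_len(50L)) {
        lab_try <- with_seed(seed + 7919L * (try - 1L), {
          k <- 3L * C
          pr <- stats::runif(k, 1, height); pc <- stats::runif(k, 1, width)
          cls <- rep(seq_len(C) - 1L, length.out = k)
          rr <- rep(seq_len(height), each = width)
          cc <- rep(seq_len(width), times = height)
          d2 <- outer(rr, pr, function(a, b) (a - b)^2) +
            outer(cc, pc, function(a, b) (a - b)^2)
          cls[max.col(-d2, ties.method = "first")]
        })
        if (min(tabulate(lab_try + 1L, nbins = C)) >= 0.05 * n) {
          lab <- lab_try; break
        }
      }
      if (is.null(lab))
        stop("blobs layout infeasible: could not give every class 5% of pixels",
             call. = FALSE)
      lab
    })
  shares <- tabulate(lab + 1L, nbins = C)
  if (min(shares) < 0.05 * n)
    stop("layout infeasible: a class holds under 5% of pixels",
         call. = FALSE)
  img <- feature_image(matrix(levels[lab + 1L], ncol = 1L),
                       height = height, width = width,
                       intensity_range = intensity_range)
  structure(list(image = img,
                 truth = label_map(lab, height = height, width = width,
                                   C = C),
                 class_levels = as.numeric(levels)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %d x %d pixels, %d classes at levels %s\n",
              x$image$height, x$image$width, x$truth$C,
              paste(x$class_levels, collapse = ", ")))
  invisible(x)
}

clip_to_range <- function(v, rng) pmin(pmax(v, rng[1L]), rng[2L])

#' Add zero-mean Gaussian noise
#'
#' Adds i.i.d. Gaussian deviates of standard deviation `sigma` (on the
#' 0--255 intensity scale) to every pixel and channel, then clips to the
#' intensity range.
#'
#' @param image a [feature_image()] (or coercible).
#' @param sigma noise standard deviation in intensity units; with
#'   `sigma_is_variance = TRUE`, `sigma` is read as a variance instead.
#' @param seed integer seed.
#' @param sigma_is_variance interpret `sigma` as a variance?
#' @return a noisy `feature_image` of the same shape.
#' @export
add_gaussian <- function(image, sigma, seed = 1L, sigma_is_variance = FALSE) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  image <- as.feature_image(image)
  if (isTRUE(sigma_is_variance)) sigma <- sqrt(sigma)
  v <- image$values
  if (sigma > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(length(v), 0, sigma),
                                    nrow(v), ncol(v)))
    v <- clip_to_range(v + noise, image$intensity_range)
  }
  feature_image(v, height = image$height, width = image$width,
                intensity_range = image$intensity_range)
}

#' Add salt-and-pepper (impulse) noise
#'
#' Replaces an exact count `round(density * N)` of uniformly chosen pixels:
#' half by the intensity minimum (pepper) and half by the maximum (salt).
#' Multi-channel images have whole pixels replaced.
#'
#' @inheritParams add_gaussian
#' @param density fraction of corrupted pixels in `[0, 1]`.
#' @return a noisy `feature_image`.
#' @export
add_salt_pepper <- function(image, density, seed = 1L) {
  if (density < 0 || density > 1)
    stop("density must be in [0, 1]", call. = FALSE)
  image <- as.feature_image(image)
  v <- image$values
  n <- nrow(v)
  k <- round(density * n)
  if (k > 0) {
    idx <- with_seed(seed, sample.int(n, k))
    n_salt <- round(k / 2)
    hi <- idx[seq_len(n_salt)]
    lo <- idx[setdiff(seq_len(k), seq_len(n_salt))]
    v[hi, ] <- image$intensity_range[2L]
    v[lo, ] <- image$intensity_range[1L]
  }
  feature_image(v, height = image$height, width = image$width,
                intensity_range = image$intensity_range)
}

#' Add multiplicative (speckle) noise
#'
#' Speckle model `out = in * (1 + n)` with `n ~ Normal(0, (sigma/255)^2)`:
#' the nominal noise level `sigma` is quoted on the 0--255 intensity scale
#' and converted to a unit-relative standard deviation.  Output is clipped
#' to the intensity range; zero-valued pixels are unchanged.
#'
#' @inheritParams add_gaussian
#' @param sigma nominal noise standard deviation on the 0--255 scale; with
#'   `sigma_is_variance = TRUE`, read as a variance before conversion.
#' @return a noisy `feature_image`.
#' @export
add_multiplicative <- function(image, sigma, seed = 1L,
                               sigma_is_variance = FALSE) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  image <- as.feature_image(image)
  if (isTRUE(sigma_is_variance)) sigma <- sqrt(sigma)
  v <- image$values
  if (sigma > 0) {
    rel <- sigma / 255
    noise <- with_seed(seed, matrix(stats::rnorm(length(v), 0, rel),
                                    nrow(v), ncol(v)))
    v <- clip_to_range(v * (1 + noise), image$intensity_range)
  }
  feature_image(v, height = image$height, width = image$width,
                intensity_range = image$intensity_range)
}

#' Add mixed Gaussian and salt-and-pepper noise
#'
#' Applies Gaussian noise first, then impulse noise, so that impulse pixels
#' remain pure intensity extremes.
#'
#' @inheritParams add_gaussian
#' @param sigma_gauss Gaussian noise standard deviation.
#' @param sp_density impulse noise density in `[0, 1]`.
#' @param order `"gauss_first"` (default) or `"sp_first"`.
#' @return a noisy `feature_image`.
#' @export
add_mixed <- function(image, sigma_gauss, sp_density, seed = 1L,
                      order = c("gauss_first", "sp_first")) {
  order <- match.arg(order)
  if (order == "gauss_first") {
    out <- add_gaussian(image, sigma_gauss, seed = seed)
    add_salt_pepper(out, sp_density, seed = seed + 1L)
  } else {
    out <- add_salt_pepper(image, sp_density, seed = seed + 1L)
    add_gaussian(out, sigma_gauss, seed = seed)
  }
}
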