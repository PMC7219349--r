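# Fuzzy c-means family: plain FCM, FLICM (fuzzy local information c-means),
# and the membership-constrained improved FLICM.  All three share the same
# alternating scheme: seeded random membership init -> centers -> (spatial
# penalty) -> membership update, stopping when max |z - z_prev| < tol.

# run body with a temporary RNG state derived from `seed`; the caller's RNG
# stream is left untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# seeded random membership matrix, rows on the simplex
init_memberships <- function(n, C, seed) {
  z <- with_seed(seed, matrix(stats::runif(n * C), n, C))
  z / rowSums(z)
}

# squared Euclidean distance of every pixel to every center: N x C
pixel_center_dist2 <- function(x, v) {
  n <- nrow(x); C <- nrow(v)
  d2 <- matrix(0, n, C)
  for (j in seq_len(C))
    d2[, j] <- rowSums((x - matrix(v[j, ], n, ncol(x), byrow = TRUE))^2)
  d2
}

# FCM/FLICM membership update from effective distances D = d2 + G.
# Pixels with a zero effective distance get a crisp membership on the first
# such class (standard singular-value convention).
membership_from_dist <- function(D, m) {
  p <- -1 / (m - 1)
  singular <- D <= 0
  has_sing <- rowSums(singular) > 0L
  Dp <- D^p                      # Inf where D == 0, handled below
  z <- Dp / rowSums(Dp)
  if (any(has_sing)) {
    for (i in which(has_sing)) {
      zi <- numeric(ncol(D))
      zi[which(singular[i, ])[1L]] <- 1
      z[i, ] <- zi
    }
  }
  z
}

# weighted center update v_j = sum_i w_ij x_i / sum_i w_ij  (C x D);
# a class with no weight keeps its previous center (or the data mean)
centers_from_weights <- function(x, wz, prev = NULL) {
  tot <- colSums(wz)
  v <- t(wz) %*% x / tot
  empty <- tot < 1e-12
  if (any(empty)) {
    fallback <- if (is.null(prev)) {
      matrix(colMeans(x), nrow(v), ncol(x), byrow = TRUE)
    } else prev
    v[empty, ] <- fallback[empty, , drop = FALSE]
  }
  v
}

# FLICM fuzzy factor for all pixels/classes at once: N x C matrix
# G_ij = sum_beta wdist(d) * (1 - z_beta_j)^m * d2[beta, j]
flicm_G <- function(spec, z, d2, m, weighting) {
  wfun <- if (weighting == "plus_one") function(d) 1 / (d + 1)
          else function(d) 1 / d
  G <- matrix(0, nrow(z), ncol(z))
  for (j in seq_len(ncol(z)))
    G[, j] <- neighbor_sum(spec, (1 - z[, j])^m * d2[, j], wfun)
  G
}

# improved-FLICM fuzzy factor: the spatial distance is damped by the
# neighbor's own membership, G_ij = sum_beta z_bj/(d*z_bj+1) (1-z_bj)^m d2_bj
iflicm_G <- function(spec, z, d2, m) {
  G <- matrix(0, nrow(z), ncol(z))
  for (j in seq_len(ncol(z))) {
    zc <- z[, j]
    h <- spec$height; w <- spec$width
    acc <- matrix(0, h, w)
    off <- spec$offsets
    base <- (1 - zc)^m * d2[, j]
    for (o in seq_len(nrow(off))) {
      wv <- zc / (off$dist[o] * zc + 1)
      acc <- acc + shift_grid(vec_to_grid(wv * base, h, w),
                              off$dr[o], off$dc[o], fill = 0)
    }
    G[, j] <- grid_to_vec(acc)
  }
  G
}

# per-offset neighbor aggregates used by the improved-FLICM center update:
# for class j, weight w_ib = (1 - z_bj)^m / (z_bj * d + 1)
iflicm_center_weights <- function(spec, zj, m) {
  h <- spec$height; w <- spec$width
  off <- spec$offsets
  wsum <- matrix(0, h, w)
  list(sum = function(v) {  # sum_beta w_ib * v_beta
    acc <- matrix(0, h, w)
    for (o in seq_len(nrow(off))) {
      wv <- (1 - zj)^m / (zj * off$dist[o] + 1)
      acc <- acc + shift_grid(vec_to_grid(wv * v, h, w),
                              off$dr[o], off$dc[o], fill = 0)
    }
    grid_to_vec(acc)
  })
}

fuzzy_fit_result <- function(method, z, v, m, iter, converged, trace, image,
                             extra = list()) {
  out <- c(list(method = method, z = z, centers = v, m = m,
                iterations = iter, converged = converged,
                objective_trace = trace,
                height = image$height, width = image$width,
                channels = image$channels,
                intensity_range = image$intensity_range),
           extra)
  class(out) <- c(method, "fuzzy_seg")
  out
}

fuzzy_engine <- function(image, C, m, tol, max_iter, seed, spec, method,
                         weighting = "plus_one", spatial_scale = 1) {
  image <- as.feature_image(image)
  x <- image$values
  n <- nrow(x)
  C <- as.integer(C)
  if (C < 1L || C > n) stop("C must be between 1 and N", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must exceed 1", call. = FALSE)
  if (method != "fcm" && is.null(spec))
    spec <- build_neighborhood(image$height, image$width)
  z <- init_memberships(n, C, seed)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  v <- NULL
  for (t in seq_len(max_iter)) {
    iter <- t
    wz <- z^m
    v <- centers_from_weights(x, wz, prev = v)
    if (method == "iflicm") {
      # Eq.-12-style center: central pixel mixed with weighted neighbors
      num <- matrix(0, C, ncol(x)); den <- numeric(C)
      for (j in seq_len(C)) {
        agg <- iflicm_center_weights(spec, z[, j], m)
        nb1 <- agg$sum(rep(1, n))
        v_num <- numeric(ncol(x))
        for (l in seq_len(ncol(x)))
          v_num[l] <- sum(wz[, j] * (x[, l] + agg$sum(x[, l])))
        num[j, ] <- v_num
        den[j] <- sum(wz[, j] * (1 + nb1))
      }
      v2 <- num / den
      bad <- den < 1e-12
      v2[bad, ] <- v[bad, , drop = FALSE]   # empty class: keep Eq.-4 center
      v <- v2
    }
    d2 <- pixel_center_dist2(x, v)
    G <- switch(method,
      fcm    = matrix(0, n, C),
      flicm  = spatial_scale * flicm_G(spec, z, d2, m, weighting),
      iflicm = spatial_scale * iflicm_G(spec, z, d2, m))
    z_new <- membership_from_dist(d2 + G, m)
    trace <- c(trace, sum(z_new^m * (d2 + G)))
    delta <- max(abs(z_new - z))
    z <- z_new
    if (delta < tol) { converged <- TRUE; break }
  }
  fuzzy_fit_result(method, z, v, m, iter, converged, trace, image,
                   extra = list(call_args = list(C = C, tol = tol,
                                                 max_iter = max_iter,
                                                 seed = seed)))
}

#' Fuzzy c-means clustering of a feature image
#'
#' Plain fuzzy c-means: alternates membership and center updates for the
#' objective `sum_ij z_ij^m ||x_i - v_j||^2` under the row-simplex
#' constraint, from a seeded random membership initialization.  No spatial
#' information is used; this is the non-spatial baseline and the
#' initializer for the spatially regularized algorithms.
#'
#' @param image a [feature_image()], matrix (single-channel image), or
#'   height x width x D array.
#' @param C number of clusters (2 <= C <= N).
#' @param m fuzzifier exponent (> 1); 2 is the standard choice.
#' @param tol convergence threshold on `max |z - z_prev|`.
#' @param max_iter maximum number of iterations.
#' @param seed integer seed for the random membership initialization.
#' @return an object of class `c("fcm", "fuzzy_seg")`: a list with
#'   memberships `z` (N x C, rows summing to 1), `centers` (C x D),
#'   `iterations`, `converged`, and `objective_trace`.
#' @examples
#' img <- feature_image(matrix(c(0, 0, 0, 100, 100, 100), 1, 6))
#' fit <- fcm(img, C = 2, seed = 1)
#' sort(fit$centers[, 1])
#' @export
fcm <- function(image, C, m = 2, tol = 1e-4, max_iter = 300L, seed = 1L) {
  fuzzy_engine(image, C, m, tol, max_iter, seed, spec = NULL, method = "fcm")
}

#' Fuzzy local information c-means (FLICM)
#'
#' FLICM augments the fuzzy c-means distance with a fuzzy factor `G_ij`
#' that couples each pixel's membership to its neighbors' memberships and
#' intensities, damped by spatial distance, which suppresses isolated noise
#' pixels without a smoothing parameter.
#'
#' @inheritParams fcm
#' @param window odd neighborhood window side (3 or 5); ignored when `spec`
#'   is supplied.
#' @param spec optional precomputed [build_neighborhood()] object.
#' @param weighting spatial damping of the fuzzy factor: `"plus_one"` for
#'   `1/(d+1)` (default) or `"inverse"` for `1/d`.
#' @param spatial_scale multiplier on the fuzzy factor; 0 disables the
#'   spatial term entirely, reducing the algorithm to plain FCM.
#' @return an object of class `c("flicm", "fuzzy_seg")`; see [fcm()].
#' @export
flicm <- function(image, C, m = 2, tol = 1e-4, max_iter = 300L, seed = 1L,
                  window = 3L, spec = NULL,
                  weighting = c("plus_one", "inverse"), spatial_scale = 1) {
  weighting <- match.arg(weighting)
  image <- as.feature_image(image)
  if (is.null(spec)) spec <- build_neighborhood(image$height, image$width,
                                                window)
  fuzzy_engine(image, C, m, tol, max_iter, seed, spec, "flicm",
               weighting = weighting, spatial_scale = spatial_scale)
}

#' Membership-constrained improved FLICM
#'
#' Variant of FLICM whose fuzzy factor damps the spatial distance by the
#' neighbor's own membership, `z_bj / (d * z_bj + 1)`, and whose center
#' update mixes each central pixel with its membership-weighted neighbors,
#' so that both updates follow from one Lagrangian stationarity condition.
#'
#' @inheritParams flicm
#' @return an object of class `c("iflicm", "fuzzy_seg")`; see [fcm()].
#' @export
improved_flicm <- function(image, C, m = 2, tol = 1e-4, max_iter = 300L,
                           seed = 1L, window = 3L, spec = NULL) {
  image <- as.feature_image(image)
  if (is.null(spec)) spec <- build_neighborhood(image$height, image$width,
                                                window)
  fuzzy_engine(image, C, m, tol, max_iter, seed, spec, "iflicm")
}

#' FLICM fuzzy factor of one pixel/class pair
#'
#' Evaluates `G_ij = sum_{b in N_i} w(d_ib) (1 - z_bj)^m ||x_b - v_j||^2`
#' for a fitted or hand-built state; mainly a testing and inspection hook.
#'
#' @param state a `fuzzy_seg` fit (needs `z`, `centers`, `m`) or a list with
#'   those elements plus `values` resolvable via `image`.
#' @param spec a [build_neighborhood()] object.
#' @param image the [feature_image()] the state refers to.
#' @param i pixel linear index; `j` class index (1-based).
#' @param j class index.
#' @param weighting see [flicm()].
#' @return the nonnegative scalar fuzzy factor.
#' @export
flicm_fuzzy_factor <- function(state, spec, image, i, j,
                               weighting = c("plus_one", "inverse")) {
  weighting <- match.arg(weighting)
  image <- as.feature_image(image)
  nb <- neighbor_weights_flicm(spec, i, weighting)
  if (j < 1L || j > ncol(state$z)) stop("class index out of range",
                                        call. = FALSE)
  xb <- image$values[nb$index, , drop = FALSE]
  vj <- state$centers[j, ]
  d2 <- rowSums((xb - matrix(vj, nrow(xb), length(vj), byrow = TRUE))^2)
  sum(nb$weight * (1 - state$z[nb$index, j])^state$m * d2)
}
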