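#' Spatial neighborhood system for a pixel grid
#'
#' Builds the square-window neighborhood system shared by all spatially
#' regularized clusterers: for every pixel i, the set `N_i` of in-window
#' neighbors (the pixel itself excluded) together with the Euclidean
#' distances between grid coordinates.  In a 3x3 window those distances are
#' 1 (edge neighbors) and sqrt(2) (diagonal neighbors).  Border pixels keep
#' only their in-bounds neighbors (truncation; no padding or mirroring).
#'
#' Internally the system is stored as the `window^2 - 1` coordinate offsets,
#' which lets the iterative algorithms compute neighbor sums as vectorized
#' shifted-grid operations rather than per-pixel loops.
#'
#' @param height,width grid shape in pixels.
#' @param window odd window side length (3 or 5 are the usual choices).
#' @return an object of class `neighborhood` with elements `height`, `width`,
#'   `window`, and `offsets` (data frame of `dr`, `dc`, `dist`).
#' @examples
#' spec <- build_neighborhood(3, 3, window = 3)
#' neighbors(spec, 5)   # center pixel of a 3x3 image: all 8 neighbors
#' @export
build_neighborhood <- function(height, width, window = 3L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (window > 2L * max(height, width) - 1L)
    stop("window too large for image", call. = FALSE)
  k <- (window - 1L) %/% 2L
  off <- expand.grid(dr = -k:k, dc = -k:k)
  off <- off[!(off$dr == 0L & off$dc == 0L), , drop = FALSE]
  off$dist <- sqrt(off$dr^2 + off$dc^2)
  rownames(off) <- NULL
  structure(list(height = as.integer(height), width = as.integer(width),
                 window = window, offsets = off),
            class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("neighborhood: %d x %d grid, %d x %d window (truncated borders)\n",
              x$height, x$width, x$window, x$window))
  invisible(x)
}

#' Neighbors and spatial distances of one pixel
#'
#' @param spec a [build_neighborhood()] object.
#' @param i linear pixel index (row-major, 1-based).
#' @return data frame with columns `index` (linear neighbor index) and
#'   `dist` (spatial Euclidean distance).
#' @export
neighbors <- function(spec, i) {
  n <- spec$height * spec$width
  if (length(i) != 1L || is.na(i) || i < 1L || i > n)
    stop("pixel index out of range", call. = FALSE)
  rc <- pixel_to_rc(i, spec$width)
  r <- rc[1L, 1L] + spec$offsets$dr
  c <- rc[1L, 2L] + spec$offsets$dc
  ok <- r >= 1L & r <= spec$height & c >= 1L & c <= spec$width
  data.frame(index = rc_to_pixel(r[ok], c[ok], spec$width),
             dist = spec$offsets$dist[ok])
}

#' FLICM spatial weights of one pixel
#'
#' Returns the reciprocal-distance weights the fuzzy local information term
#' attaches to each neighbor.  The default weighting is `1 / (d + 1)`; the
#' alternative `"inverse"` uses the bare reciprocal `1 / d`.
#'
#' @param spec a [build_neighborhood()] object.
#' @param i linear pixel index.
#' @param weighting `"plus_one"` (default) or `"inverse"`.
#' @return data frame with columns `index` and `weight`.
#' @export
neighbor_weights_flicm <- function(spec, i,
                                   weighting = c("plus_one", "inverse")) {
  weighting <- match.arg(weighting)
  nb <- neighbors(spec, i)
  w <- if (weighting == "plus_one") 1 / (nb$dist + 1) else 1 / nb$dist
  data.frame(index = nb$index, weight = w)
}

# ---- shifted-grid machinery (internal) -------------------------------------
#
# For an h x w grid matrix M, shift_grid(M, dr, dc) returns S with
# S[r, c] = M[r + dr, c + dc] when in bounds and `fill` outside.  A sum over
# neighbors beta of f(value at beta) then becomes a sum over the window
# offsets of shifted grids, which is O(window^2) vectorized operations.

shift_grid <- function(M, dr, dc, fill = 0) {
  h <- nrow(M); w <- ncol(M)
  S <- matrix(fill, h, w)
  rlo <- max(1L, 1L - dr); rhi <- min(h, h - dr)
  clo <- max(1L, 1L - dc); chi <- min(w, w - dc)
  if (rlo <= rhi && clo <= chi) {
    rs <- rlo:rhi; cs <- clo:chi
    S[rs, cs] <- M[rs + dr, cs + dc]
  }
  S
}

# sum over neighbors of per-neighbor values: `v` is an N-length row-major
# pixel vector; optional per-offset weight function wfun(dist) scales each
# offset's contribution.  Returns an N-length vector of neighbor sums.
neighbor_sum <- function(spec, v, wfun = NULL) {
  h <- spec$height; w <- spec$width
  M <- vec_to_grid(v, h, w)
  acc <- matrix(0, h, w)
  off <- spec$offsets
  for (o in seq_len(nrow(off))) {
    s <- shift_grid(M, off$dr[o], off$dc[o], fill = 0)
    if (!is.null(wfun)) s <- s * wfun(off$dist[o])
    acc <- acc + s
  }
  grid_to_vec(acc)
}

# stack of shifted grids as an N x K matrix (K = window^2 - 1 offsets),
# NA outside the image; used for neighborhood medians
neighbor_stack <- function(spec, v) {
  h <- spec$height; w <- spec$width
  M <- vec_to_grid(v, h, w)
  off <- spec$offsets
  out <- matrix(NA_real_, h * w, nrow(off))
  for (o in seq_len(nrow(off)))
    out[, o] <- grid_to_vec(shift_grid(M, off$dr[o], off$dc[o],
                                       fill = NA_real_))
  out
}

# row medians of an N x K matrix with NAs (borders).  Interior rows (no NA)
# go through a vectorized odd-even transposition sorting network -- K
# passes of column-adjacent pmin/pmax -- which sorts every row at once;
# border rows (few) fall back to stats::median.
row_median_na <- function(X) {
  K <- ncol(X)
  nna <- rowSums(is.na(X))
  out <- numeric(nrow(X))
  full <- nna == 0L
  if (any(full)) {
    Xf <- X[full, , drop = FALSE]
    for (pass in seq_len(K)) {
      start <- if (pass %% 2L == 1L) 1L else 2L
      q <- start
      while (q < K) {
        a <- Xf[, q]; b <- Xf[, q + 1L]
        sw <- a > b
        if (any(sw)) {
          Xf[sw, q] <- b[sw]
          Xf[sw, q + 1L] <- a[sw]
        }
        q <- q + 2L
      }
    }
    out[full] <- if (K %% 2L == 1L) Xf[, (K + 1L) %/% 2L]
                 else (Xf[, K %/% 2L] + Xf[, K %/% 2L + 1L]) / 2
  }
  for (i in which(!full)) out[i] <- stats::median(X[i, ], na.rm = TRUE)
  out
}
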