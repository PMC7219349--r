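#' Pixel feature matrix with grid geometry
#'
#' A `feature_image` holds an image as an N x D matrix of per-pixel feature
#' vectors (N = height x width pixels, D feature channels) together with the
#' grid shape, so that spatial neighborhoods can be recovered.  Pixels are
#' stored in row-major order: linear index `i = (r - 1) * width + c` for grid
#' coordinate `(r, c)`, both 1-based.  Values stay in the storage format's
#' native intensity units (0--255 for 8-bit images); no rescaling is applied.
#'
#' @param values numeric data: an `height x width` matrix (one channel, rows =
#'   image rows), an `height x width x D` array, or an N x D matrix already in
#'   row-major pixel order (then `height` and `width` must be given).
#' @param height,width grid shape in pixels; inferred from matrix/array input.
#' @param intensity_range length-2 numeric, the representable range of the
#'   storage format.  Defaults to `c(0, 255)` (8-bit).
#' @return An object of class `feature_image` with elements `values` (N x D
#'   matrix), `height`, `width`, `channels`, `intensity_range`.
#' @examples
#' img <- feature_image(matrix(c(0, 255, 128, 64), 2, 2, byrow = TRUE))
#' img$values
#' @export
feature_image <- function(values, height = NULL, width = NULL,
                          intensity_range = c(0, 255)) {
  if (is.array(values) && length(dim(values)) == 3L) {
    h <- dim(values)[1L]; w <- dim(values)[2L]; d <- dim(values)[3L]
    v <- vapply(seq_len(d), function(l) grid_to_vec(values[, , l]),
                numeric(h * w))
    v <- matrix(v, ncol = d)
  } else if (is.matrix(values) && is.null(height)) {
    h <- nrow(values); w <- ncol(values)
    v <- matrix(grid_to_vec(values), ncol = 1L)
  } else {
    v <- as.matrix(values)
    if (is.null(height) || is.null(width))
      stop("height and width are required for N x D matrix input",
           call. = FALSE)
    h <- as.integer(height); w <- as.integer(width)
    if (nrow(v) != h * w)
      stop("nrow(values) != height * width", call. = FALSE)
  }
  if (h < 1L || w < 1L) stop("zero-area image", call. = FALSE)
  if (!all(is.finite(v))) stop("non-finite pixel values", call. = FALSE)
  storage.mode(v) <- "double"
  structure(list(values = v, height = as.integer(h), width = as.integer(w),
                 channels = ncol(v),
                 intensity_range = as.numeric(intensity_range)),
            class = "feature_image")
}

#' @export
print.feature_image <- function(x, ...) {
  cat(sprintf("feature_image: %d x %d pixels, %d channel(s), range [%g, %g]\n",
              x$height, x$width, x$channels,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Coerce to a feature image
#'
#' Matrices are treated as single-channel images (rows = image rows), 3-d
#' arrays as multi-channel images; `feature_image` objects pass through.
#'
#' @param x object to coerce.
#' @param ... passed to [feature_image()].
#' @return a `feature_image`.
#' @export
as.feature_image <- function(x, ...) {
  if (inherits(x, "feature_image")) return(x)
  feature_image(x, ...)
}

# row-major <-> grid helpers; R matrices are column-major so conversion
# transposes.  All N-length pixel vectors in this package are row-major.
grid_to_vec <- function(m) as.vector(t(m))
vec_to_grid <- function(v, height, width) {
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

#' Convert between linear pixel index and grid coordinates
#'
#' Pixel order is row-major: `i = (r - 1) * width + c`.
#'
#' @param i linear index (1-based).
#' @param r,c row and column (1-based).
#' @param width image width in pixels.
#' @return `pixel_to_rc` gives a 2-column matrix of (row, col);
#'   `rc_to_pixel` gives the linear index.
#' @export
pixel_to_rc <- function(i, width) {
  cbind(r = (i - 1L) %/% width + 1L, c = (i - 1L) %% width + 1L)
}

#' @rdname pixel_to_rc
#' @export
rc_to_pixel <- function(r, c, width) (r - 1L) * width + c

#' Integer label map over an image grid
#'
#' Labels are integers in `{0, ..., C-1}` stored in row-major pixel order.
#'
#' @param labels integer vector (row-major) or matrix (rows = image rows).
#' @param height,width grid shape; inferred from matrix input.
#' @param C class count; defaults to `max(labels) + 1`.
#' @return object of class `label_map` with `labels`, `height`, `width`, `C`.
#' @export
label_map <- function(labels, height = NULL, width = NULL, C = NULL) {
  if (is.matrix(labels)) {
    height <- nrow(labels); width <- ncol(labels)
    labels <- grid_to_vec(labels)
  }
  if (is.null(height) || is.null(width))
    stop("height and width required for vector labels", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != height * width)
    stop("label count does not match grid", call. = FALSE)
  if (any(labels < 0L)) stop("labels must be >= 0", call. = FALSE)
  if (is.null(C)) C <- max(labels) + 1L
  C <- as.integer(C)
  if (any(labels >= C)) stop("labels must be < C", call. = FALSE)
  structure(list(labels = labels, height = as.integer(height),
                 width = as.integer(width), C = C),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d pixels, %d classes\n",
              x$height, x$width, x$C))
  invisible(x)
}

#' Replace each pixel by its class mean
#'
#' Builds the piecewise-constant reconstruction of an image under a
#' segmentation: every pixel's value is replaced, per channel, by the mean
#' value of all pixels sharing its label.  This is the reference image used
#' for segmentation PSNR.  The operation is idempotent for fixed labels.
#'
#' @param image a [feature_image()] (or coercible).
#' @param labels a [label_map()] on the same grid.
#' @return a `feature_image` of the same shape.
#' @export
class_mean_reconstruction <- function(image, labels) {
  image <- as.feature_image(image)
  if (image$height != labels$height || image$width != labels$width)
    stop("image and label map shapes differ", call. = FALSE)
  v <- image$values
  f <- factor(labels$labels, levels = sort(unique(labels$labels)))
  out <- v
  for (l in seq_len(ncol(v))) {
    mu <- tapply(v[, l], f, mean)
    out[, l] <- mu[as.character(f)]
  }
  feature_image(out, height = image$height, width = image$width,
                intensity_range = image$intensity_range)
}
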