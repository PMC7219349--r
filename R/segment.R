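#' Segment an image by robust fuzzy clustering
#'
#' Front door to the four clusterers: plain fuzzy c-means (`"fcm"`), fuzzy
#' local information c-means (`"flicm"`), the membership-constrained
#' improved FLICM (`"iflicm"`), and the feature-selection local fuzzy
#' clustering algorithm (`"fs"`, the default and the method of interest).
#' All return a `fuzzy_seg` fit supporting `print`, `summary`, `coef`,
#' `fitted`, `predict`, `residuals`, and `plot`.
#'
#' @param image a [feature_image()], numeric matrix (single-channel image),
#'   or height x width x D array.
#' @param C number of classes.
#' @param method clustering algorithm.
#' @param ... further arguments passed to [fsfcm()], [fcm()], [flicm()] or
#'   [improved_flicm()] (notably `lambda`, `gamma`, `alpha`, `m`, `window`,
#'   `tol`, `max_iter`, `seed`).
#' @return a `fuzzy_seg` object.
#' @examples
#' ph <- make_phantom(24, 24, levels = c(40, 200), layout = "stripes",
#'                    seed = 1)
#' noisy <- add_salt_pepper(ph$image, density = 0.1, seed = 2)
#' fit <- fuzzy_segment(noisy, C = 2, method = "fs", seed = 1)
#' score_segmentation(ph, predict(fit))
#' @export
fuzzy_segment <- function(image, C,
                          method = c("fs", "fcm", "flicm", "iflicm"), ...) {
  method <- match.arg(method)
  switch(method,
         fs     = fsfcm(image, C, ...),
         fcm    = fcm(image, C, ...),
         flicm  = flicm(image, C, ...),
         iflicm = improved_flicm(image, C, ...))
}

#' Hard labels by maximum membership
#'
#' Each pixel gets the class with the largest membership; ties break to the
#' lowest class index.  Labels are 0-based.
#'
#' @param object a `fuzzy_seg` fit.
#' @param ... unused.
#' @return a [label_map()].
#' @export
predict.fuzzy_seg <- function(object, ...) {
  lab <- max.col(object$z, ties.method = "first") - 1L
  label_map(lab, height = object$height, width = object$width,
            C = ncol(object$z))
}

#' @export
print.fuzzy_seg <- function(x, ...) {
  nm <- c(fcm = "fuzzy c-means",
          flicm = "fuzzy local information c-means (FLICM)",
          iflicm = "improved FLICM",
          fsfcm = "feature-selection local fuzzy clustering")
  cat(sprintf("%s fit\n", nm[[x$method]]))
  cat(sprintf("  image: %d x %d pixels, %d channel(s)\n", x$height, x$width,
              x$channels))
  cat(sprintf("  classes: %d; fuzzifier m = %g\n", ncol(x$z), x$m))
  cat(sprintf("  %d iteration(s); %s\n", x$iterations,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  cat("  class centers:\n")
  print(round(x$centers, 3))
  invisible(x)
}

#' @export
summary.fuzzy_seg <- function(object, ...) {
  lab <- predict(object)
  shares <- tabulate(lab$labels + 1L, nbins = ncol(object$z)) /
    length(lab$labels)
  structure(list(fit = object, class_shares = shares,
                 max_membership = mean(apply(object$z, 1L, max)),
                 objective = utils::tail(object$objective_trace, 1L)),
            class = "summary.fuzzy_seg")
}

#' @export
print.summary.fuzzy_seg <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean max membership: %.4f\n", x$max_membership))
  cat("  class shares:", paste(sprintf("%.3f", x$class_shares),
                               collapse = " "), "\n")
  if (length(x$objective))
    cat(sprintf("  final objective: %.6g\n", x$objective))
  invisible(x)
}

#' @export
coef.fuzzy_seg <- function(object, ...) object$centers

#' Class-mean reconstruction of the segmented image
#'
#' @param object a `fuzzy_seg` fit.
#' @param image optionally, the image to reconstruct (defaults to the class
#'   centers themselves, i.e. each pixel replaced by its class center).
#' @param ... unused.
#' @return a [feature_image()].
#' @export
fitted.fuzzy_seg <- function(object, image = NULL, ...) {
  lab <- predict(object)
  if (!is.null(image)) return(class_mean_reconstruction(image, lab))
  v <- object$centers[lab$labels + 1L, , drop = FALSE]
  feature_image(v, height = object$height, width = object$width,
                intensity_range = object$intensity_range)
}

#' @export
residuals.fuzzy_seg <- function(object, image, ...) {
  image <- as.feature_image(image)
  image$values - fitted(object)$values
}

#' Plot a segmentation result
#'
#' Displays the hard label map as a gray raster (classes spread evenly over
#' the gray range).
#'
#' @param x a `fuzzy_seg` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.fuzzy_seg <- function(x, ...) {
  lab <- predict(x)
  m <- vec_to_grid(lab$labels, lab$height, lab$width)
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(graphics::par(op))
  graphics::image(t(m)[, lab$height:1, drop = FALSE],
                  col = grDevices::gray.colors(max(lab$C, 2L), start = 0,
                                               end = 1),
                  axes = FALSE, asp = lab$height / lab$width, ...)
  invisible(x)
}
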