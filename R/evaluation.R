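# Segmentation scoring: misclassification rate with optimal label matching,
# and PSNR against the class-mean reconstruction.

#' Misclassification rate with optimal label matching
#'
#' Percent of pixels whose predicted label differs from ground truth, after
#' relabeling the prediction with the class permutation that maximizes
#' agreement (clustering label identities are arbitrary, so without
#' matching the rate would be seed-dependent).  Exhaustive search over all
#' permutations for up to 6 classes; an assignment-optimal (Hungarian)
#' matching beyond, which agrees with exhaustive search where both apply.
#'
#' @param pred predicted [label_map()].
#' @param truth ground-truth [label_map()] on the same grid.
#' @return percent misclassified in `[0, 100]`, with the matching used
#'   attached as attribute `"permutation"` (predicted class `j` maps to
#'   truth class `permutation[j + 1] - 1`).
#' @examples
#' t <- label_map(c(0, 0, 1, 1), height = 2, width = 2)
#' p <- label_map(c(1, 1, 0, 0), height = 2, width = 2)
#' mcr(p, t)  # 0: labels are matched
#' @export
mcr <- function(pred, truth) {
  if (pred$height != truth$height || pred$width != truth$width)
    stop("label map shapes differ", call. = FALSE)
  n <- length(truth$labels)
  C <- max(pred$C, truth$C)
  conf <- table(factor(pred$labels, levels = 0:(C - 1)),
                factor(truth$labels, levels = 0:(C - 1)))
  conf <- matrix(as.numeric(conf), C, C)
  perm <- if (C <= 6L) best_permutation(conf) else hungarian_max(conf)
  agree <- sum(conf[cbind(seq_len(C), perm)])
  structure((1 - agree / n) * 100, permutation = perm)
}

# exhaustive search over label permutations maximizing trace agreement
best_permutation <- function(conf) {
  C <- nrow(conf)
  perms <- all_permutations(C)
  scores <- vapply(perms, function(p) sum(conf[cbind(seq_len(C), p)]),
                   numeric(1))
  perms[[which.max(scores)]]
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) for (pos in seq_len(k)) {
    out[[idx]] <- append(p, k, after = pos - 1L)
    idx <- idx + 1L
  }
  out
}

# Hungarian algorithm (shortest augmenting path with potentials) for the
# maximum-agreement assignment; cost = max(conf) - conf turns it into a
# minimization.  O(C^3), exact.
hungarian_max <- function(conf) {
  C <- nrow(conf)
  cost <- max(conf) - conf
  INF <- sum(cost) + 1
  u <- numeric(C + 1L); v <- numeric(C + 1L)
  p <- integer(C + 1L)        # p[col] = row assigned to col (0 = none)
  for (i in seq_len(C)) {
    p[1L] <- i
    j0 <- 1L                  # columns are offset by 1 (j0 = 1 is virtual)
    minv <- rep(INF, C + 1L)
    used <- rep(FALSE, C + 1L)
    way <- integer(C + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(C + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(C + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(C)
  for (j in 2L:(C + 1L)) if (p[j] > 0L) perm[p[j]] <- j - 1L
  perm
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels, with the mean squared error
#' taken over all pixels and channels.  Identical images give `Inf`
#' (serialized as the string `"inf"` in metrics JSON).
#'
#' @param reference,test [feature_image()] objects (or coercible) of the
#'   same shape.
#' @param peak peak intensity (255 for 8-bit).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, test, peak = 255) {
  reference <- as.feature_image(reference)
  test <- as.feature_image(test)
  if (reference$height != test$height || reference$width != test$width ||
      reference$channels != test$channels)
    stop("image shapes differ", call. = FALSE)
  if (peak <= 0) stop("peak must be positive", call. = FALSE)
  mse <- mean((reference$values - test$values)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Score a segmentation against a phantom
#'
#' Bundles the evaluation protocol: MCR between the predicted labels and
#' the phantom's ground truth, and PSNR between the clean phantom image and
#' the class-mean reconstruction of the clean image under the predicted
#' labels (so PSNR measures how faithfully the segmentation's
#' piecewise-constant model reproduces the clean scene).
#'
#' @param phantom a [make_phantom()] object (or a list with `image` and
#'   `truth`).
#' @param pred predicted [label_map()].
#' @return an object of class `seg_score`: list with `mcr` (percent),
#'   `psnr` (dB), `matched_permutation`.
#' @export
score_segmentation <- function(phantom, pred) {
  m <- mcr(pred, phantom$truth)
  recon <- class_mean_reconstruction(phantom$image, pred)
  p <- psnr(phantom$image, recon)
  structure(list(mcr = as.numeric(m), psnr = p,
                 matched_permutation = attr(m, "permutation")),
            class = "seg_score")
}

#' @export
print.seg_score <- function(x, ...) {
  cat(sprintf("segmentation score: MCR = %.3f%%, PSNR = %s dB\n", x$mcr,
              if (is.infinite(x$psnr)) "inf" else sprintf("%.2f", x$psnr)))
  invisible(x)
}

# JSON-safe metrics record (Inf -> "inf" per the metrics schema)
metrics_record <- function(score, iterations = NA_integer_,
                           converged = NA) {
  list(psnr_db = if (is.infinite(score$psnr)) "inf" else score$psnr,
       mcr_percent = score$mcr,
       iterations = iterations,
       converged = converged)
}
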