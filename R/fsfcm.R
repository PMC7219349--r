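# Feature-selection Gaussian-mixture local fuzzy clustering with KL
# regularization and median-filtered membership postprocessing.
#
# The objective being minimized alternately is
#   J = sum_ij z_ij (d_ij + G_ij)
#     + lambda * sum_ij z_ij log(z_ij / pi_j)
#     + gamma  * sum_ijl z_ij [ s log(s/rho_l) + (1-s) log((1-s)/(1-rho_l)) ]
# with the saliency-weighted distances
#   d_ij  = sum_l [ s_ijl (x_il - mu_jl)^2 + (1 - s_ijl)(x_il - eps_l)^2 ]
#   G_ij  = sum_b u_ibj * sum_l [ s_ijl (x_bl - mu_jl)^2
#                                 + (1 - s_ijl)(x_bl - eps_l)^2 ]
#   u_ibj = (1 - z_bj)^m / (z_bj * d_ib + 1)
# Every closed-form update below is the exact stationary point of J in its
# own block (verified numerically in the test suite); the membership update
# additionally carries the median-neighborhood weight H_ij^alpha, which is a
# postprocessing term outside J.

#' Cluster model of the feature-selection algorithm
#'
#' Bundles the per-class means, class priors, common-background feature
#' means, and feature weights.  `sigma2` and `nu2` are the class and global
#' feature variances computed at initialization; they are diagnostics only
#' and never enter the updates.
#'
#' @param mu C x D matrix of class means (intensity units).
#' @param pi length-C class priors (nonnegative, summing to 1).
#' @param eps length-D common-background feature means.
#' @param rho length-D feature weights in (0, 1).
#' @param sigma2 optional C x D class variances (diagnostic).
#' @param nu2 optional length-D global feature variances (diagnostic).
#' @return an object of class `fs_model`.
#' @export
fs_model <- function(mu, pi, eps, rho, sigma2 = NULL, nu2 = NULL) {
  mu <- as.matrix(mu)
  if (abs(sum(pi) - 1) > 1e-6) stop("class priors must sum to 1",
                                    call. = FALSE)
  if (any(rho < 0) || any(rho > 1)) stop("rho must lie in [0, 1]",
                                         call. = FALSE)
  rho <- pmin(pmax(rho, 1e-6), 1 - 1e-6)  # keep weights strictly interior
  structure(list(mu = mu, pi = as.numeric(pi), eps = as.numeric(eps),
                 rho = as.numeric(rho), sigma2 = sigma2, nu2 = nu2),
            class = "fs_model")
}

#' @export
print.fs_model <- function(x, ...) {
  cat(sprintf("fs_model: %d classes, %d feature(s)\n", nrow(x$mu),
              ncol(x$mu)))
  cat("  class means:\n")
  print(round(x$mu, 3))
  cat("  priors:", paste(round(x$pi, 4), collapse = " "), "\n")
  cat("  feature weights rho:", paste(round(x$rho, 4), collapse = " "), "\n")
  invisible(x)
}

EPS_CLAMP <- 1e-12

clamp01 <- function(v, lo = EPS_CLAMP) pmin(pmax(v, lo), 1 - lo)

#' Membership-damped neighbor weight
#'
#' The weight `u_ibj = (1 - z_bj)^m / (z_bj * d_ib + 1)` a pixel's spatial
#' penalty attaches to neighbor `b` for class `j`: crisp agreeing neighbors
#' (`z_bj = 1`) contribute nothing, confidently different neighbors
#' contribute fully.
#'
#' @param z N x C membership matrix (previous iteration).
#' @param spec a [build_neighborhood()] object.
#' @param i pixel index; `beta` must be one of its neighbors.
#' @param beta neighbor pixel index.
#' @param j class index (1-based).
#' @param m fuzzifier exponent.
#' @return scalar weight in `[0, 1]`.
#' @export
neighbor_weight <- function(z, spec, i, beta, j, m = 2) {
  nb <- neighbors(spec, i)
  k <- match(beta, nb$index)
  if (is.na(k)) stop("beta is not a neighbor of i", call. = FALSE)
  zb <- z[beta, j]
  (1 - zb)^m / (zb * nb$dist[k] + 1)
}

# ---- neighborhood aggregates (internal) ------------------------------------
# For each class j and feature l, the engines need
#   B[i, j]      = sum_b u_ibj
#   Sx[i, j, l]  = sum_b u_ibj * x_bl
#   Sx2[i, j, l] = sum_b u_ibj * x_bl^2
# computed as shifted-grid sums (u depends on the offset distance, so each
# window offset contributes one vectorized shift).
fs_aggregates <- function(spec, z, x, m = 2) {
  n <- nrow(z); C <- ncol(z); D <- ncol(x)
  h <- spec$height; w <- spec$width
  off <- spec$offsets
  B <- matrix(0, n, C)
  Sx <- array(0, dim = c(n, C, D))
  Sx2 <- array(0, dim = c(n, C, D))
  for (j in seq_len(C)) {
    zj <- z[, j]
    accB <- matrix(0, h, w)
    accS <- vector("list", D); accS2 <- vector("list", D)
    for (l in seq_len(D)) { accS[[l]] <- matrix(0, h, w)
                            accS2[[l]] <- matrix(0, h, w) }
    for (o in seq_len(nrow(off))) {
      u <- (1 - zj)^m / (zj * off$dist[o] + 1)
      accB <- accB + shift_grid(vec_to_grid(u, h, w), off$dr[o], off$dc[o])
      for (l in seq_len(D)) {
        accS[[l]] <- accS[[l]] +
          shift_grid(vec_to_grid(u * x[, l], h, w), off$dr[o], off$dc[o])
        accS2[[l]] <- accS2[[l]] +
          shift_grid(vec_to_grid(u * x[, l]^2, h, w), off$dr[o], off$dc[o])
      }
    }
    B[, j] <- grid_to_vec(accB)
    for (l in seq_len(D)) {
      Sx[, j, l] <- grid_to_vec(accS[[l]])
      Sx2[, j, l] <- grid_to_vec(accS2[[l]])
    }
  }
  list(B = B, Sx = Sx, Sx2 = Sx2)
}

# quadratic neighbor-augmented distances to a per-class center mu (C x D)
# or a common center eps (length D): q[i, j, l] =
#   (x_il - c_jl)^2 + Sx2 - 2 c_jl Sx + c_jl^2 B
fs_quad <- function(x, agg, center) {
  n <- nrow(x); D <- ncol(x)
  C <- ncol(agg$B)
  q <- array(0, dim = c(n, C, D))
  cm <- if (is.matrix(center)) center else
    matrix(center, C, D, byrow = TRUE)
  for (j in seq_len(C)) for (l in seq_len(D)) {
    cc <- cm[j, l]
    q[, j, l] <- (x[, l] - cc)^2 +
      agg$Sx2[, j, l] - 2 * cc * agg$Sx[, j, l] + cc^2 * agg$B[, j]
  }
  q
}

#' Feature-saliency logit
#'
#' The log-odds statistic deciding how salient feature `l` is for class `j`
#' at pixel `i`: the neighbor-augmented squared distance to the common
#' background mean minus the one to the class mean.  Large positive values
#' mean the feature discriminates the class at that pixel.
#'
#' @inheritParams neighbor_weight
#' @param image a [feature_image()].
#' @param model an [fs_model()].
#' @param l feature index.
#' @return scalar logit `t_ijl`.
#' @export
saliency_logit <- function(image, z, model, spec, i, j, l, m = 2) {
  image <- as.feature_image(image)
  x <- image$values
  nb <- neighbors(spec, i)
  zb <- z[nb$index, j]
  u <- (1 - zb)^m / (zb * nb$dist + 1)
  de <- (x[i, l] - model$eps[l])^2 +
    sum(u * (x[nb$index, l] - model$eps[l])^2)
  dm <- (x[i, l] - model$mu[j, l])^2 +
    sum(u * (x[nb$index, l] - model$mu[j, l])^2)
  de - dm
}

#' Update the feature-saliency field
#'
#' Closed-form stationary point of the objective in the saliencies: the
#' logistic transform `s = rho * exp(t/gamma) / (1 - rho + rho *
#' exp(t/gamma))` of the saliency logit, computed overflow-safely and
#' clamped just inside (0, 1).
#'
#' @inheritParams saliency_logit
#' @param gamma feature-selection weight (> 0).
#' @return an N x C x D array of saliencies in (0, 1).
#' @export
update_saliency <- function(image, z, model, spec, gamma, m = 2) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  image <- as.feature_image(image)
  x <- image$values
  agg <- fs_aggregates(spec, z, x, m)
  fs_saliency_from_agg(x, agg, model, gamma)
}

fs_quad_pair <- function(x, agg, model) {
  list(qmu = fs_quad(x, agg, model$mu), qeps = fs_quad(x, agg, model$eps))
}

fs_saliency_from_quad <- function(quad, rho, gamma) {
  t <- quad$qeps - quad$qmu
  s <- t
  for (l in seq_len(dim(t)[3L])) {
    r <- clamp01(rho[l], 1e-15)
    s[, , l] <- stats::plogis(t[, , l] / gamma + log(r / (1 - r)))
  }
  clamp01(s)
}

fs_saliency_from_agg <- function(x, agg, model, gamma) {
  fs_saliency_from_quad(fs_quad_pair(x, agg, model), model$rho, gamma)
}

#' Class cost of one pixel/class pair
#'
#' The per-pixel cost `eta_ij` entering the membership softmax: the
#' saliency-weighted, neighbor-augmented squared distances plus the KL
#' penalties tying the saliencies to the feature weights.
#'
#' @inheritParams saliency_logit
#' @param saliency N x C x D saliency array from [update_saliency()].
#' @param gamma feature-selection weight.
#' @return scalar cost.
#' @export
class_cost <- function(image, z, model, saliency, spec, gamma, i, j, m = 2) {
  image <- as.feature_image(image)
  x <- image$values
  agg <- fs_aggregates(spec, z, x, m)
  eta <- fs_eta_from_agg(x, agg, model, saliency, gamma)
  eta[i, j]
}

fs_eta_from_quad <- function(quad, saliency, rho, gamma) {
  D <- dim(saliency)[3L]
  eta <- matrix(0, dim(saliency)[1L], dim(saliency)[2L])
  for (l in seq_len(D)) {
    s <- clamp01(saliency[, , l])
    r <- clamp01(rho[l], 1e-15)
    eta <- eta + s * (quad$qmu[, , l] + gamma * (log(s) - log(r))) +
      (1 - s) * (quad$qeps[, , l] + gamma * (log1p(-s) - log(1 - r)))
  }
  eta
}

fs_eta_from_agg <- function(x, agg, model, saliency, gamma) {
  fs_eta_from_quad(fs_quad_pair(x, agg, model), saliency, model$rho, gamma)
}

#' Median field of neighborhood memberships
#'
#' For every pixel and class, the median of the neighbors' memberships
#' (center pixel excluded).  Even neighbor counts use the mean of the two
#' central order statistics; a pixel with no neighbors keeps its own
#' membership.
#'
#' @inheritParams neighbor_weight
#' @return an N x C matrix `H` with entries in `[0, 1]`.
#' @export
median_field <- function(z, spec) {
  C <- ncol(z)
  H <- matrix(0, nrow(z), C)
  for (j in seq_len(C)) {
    st <- neighbor_stack(spec, z[, j])
    empty <- rowSums(!is.na(st)) == 0L
    Hj <- row_median_na(st)
    Hj[empty] <- z[empty, j]
    H[, j] <- Hj
  }
  H
}

#' Update the membership field
#'
#' The membership softmax `z_ij` proportional to `pi_j * H_ij^alpha *
#' exp(-eta_ij / lambda)`, computed in log space for numerical safety; rows
#' sum to one exactly.
#'
#' @inheritParams class_cost
#' @param H N x C median field from [median_field()] (previous iteration's
#'   memberships).
#' @param lambda entropy-regularization weight (> 0).
#' @param alpha neighborhood weight exponent (>= 0); 0 disables the median
#'   postprocessing.
#' @return an N x C membership matrix with rows summing to 1.
#' @export
update_membership <- function(image, z, model, saliency, H, spec, lambda,
                              gamma, alpha = 2, m = 2) {
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  image <- as.feature_image(image)
  x <- image$values
  agg <- fs_aggregates(spec, z, x, m)
  eta <- fs_eta_from_agg(x, agg, model, saliency, gamma)
  fs_membership_from_eta(eta, model$pi, H, lambda, alpha)
}

fs_membership_from_eta <- function(eta, pi, H, lambda, alpha) {
  lp <- matrix(log(pmax(pi, EPS_CLAMP)), nrow(eta), ncol(eta), byrow = TRUE)
  logit <- lp + alpha * log(pmax(H, EPS_CLAMP)) - eta / lambda
  mx <- apply(logit, 1L, max)
  e <- exp(logit - mx)
  e / rowSums(e)
}

#' Update the cluster model
#'
#' Closed-form stationary points of the objective in the class means,
#' background means, feature weights, and priors, given memberships and
#' saliencies.  The class-mean and background-mean updates include the
#' neighbor-augmented terms, so each is the exact zero of its own partial
#' derivative; `center_update = "printed"` selects the simpler
#' saliency-weighted mean without neighbor terms instead.
#'
#' A class whose total saliency-weighted membership falls below 1e-12 keeps
#' its previous mean (with a warning) rather than dividing by ~0.
#'
#' @inheritParams class_cost
#' @param model previous [fs_model()]; supplies the fallback means for
#'   degenerate classes and carries the diagnostic variances.
#' @param center_update `"lagrange"` (exact stationary point, default) or
#'   `"printed"` (plain saliency-weighted mean).
#' @return an updated `fs_model`.
#' @export
update_model <- function(image, z, saliency, spec, m = 2, model = NULL,
                         center_update = c("lagrange", "printed")) {
  center_update <- match.arg(center_update)
  image <- as.feature_image(image)
  x <- image$values
  agg <- fs_aggregates(spec, z, x, m)
  fs_model_from_agg(x, z, saliency, agg, center_update, model)
}

fs_model_from_agg <- function(x, z, saliency, agg, center_update, model) {
  n <- nrow(x); C <- ncol(z); D <- ncol(x)
  mu <- matrix(0, C, D)
  for (j in seq_len(C)) for (l in seq_len(D)) {
    s <- saliency[, j, l]
    wt <- z[, j] * s
    if (sum(wt) < EPS_CLAMP) {
      if (is.null(model))
        stop("degenerate class with no previous model", call. = FALSE)
      warning(sprintf("class %d, feature %d: degenerate weights; keeping previous mean",
                      j, l), call. = FALSE)
      mu[j, l] <- model$mu[j, l]
    } else if (center_update == "printed") {
      mu[j, l] <- sum(wt * x[, l]) / sum(wt)
    } else {
      num <- sum(wt * (x[, l] + agg$Sx[, j, l]))
      den <- sum(wt * (1 + agg$B[, j]))
      mu[j, l] <- num / den
    }
  }
  eps <- numeric(D)
  for (l in seq_len(D)) {
    wt <- z * (1 - saliency[, , l])            # N x C
    if (center_update == "printed") {
      num <- sum(wt * x[, l]); den <- sum(wt)
    } else {
      num <- 0; den <- 0
      for (j in seq_len(C)) {
        num <- num + sum(wt[, j] * (x[, l] + agg$Sx[, j, l]))
        den <- den + sum(wt[, j] * (1 + agg$B[, j]))
      }
    }
    # all-salient feature: no background evidence; keep the previous
    # background mean (or the global mean) instead of dividing by ~0
    eps[l] <- if (den < EPS_CLAMP) {
      if (!is.null(model)) model$eps[l] else mean(x[, l])
    } else num / den
  }
  rho <- numeric(D)
  for (l in seq_len(D))
    rho[l] <- sum(z * saliency[, , l]) / n
  rho <- pmin(pmax(rho, 1e-6), 1 - 1e-6)
  pi <- colSums(z) / n
  fs_model(mu, pi, eps, rho,
           sigma2 = if (!is.null(model)) model$sigma2,
           nu2 = if (!is.null(model)) model$nu2)
}

#' Objective value of the feature-selection clustering
#'
#' Evaluates the full regularized objective: saliency-weighted
#' neighbor-augmented distances, the entropy (KL) term on memberships
#' against the class priors, and the KL term on saliencies against the
#' feature weights.  `0 * log 0` is taken as 0.
#'
#' @inheritParams class_cost
#' @param lambda entropy-regularization weight.
#' @return scalar objective value.
#' @export
fs_objective <- function(image, z, model, saliency, spec, lambda, gamma,
                         m = 2) {
  image <- as.feature_image(image)
  x <- image$values
  agg <- fs_aggregates(spec, z, x, m)
  fs_objective_from_quad(z, saliency, fs_quad_pair(x, agg, model),
                         model$pi, model$rho, lambda, gamma)
}

fs_objective_from_quad <- function(z, saliency, quad, pi, rho, lambda,
                                   gamma) {
  D <- dim(saliency)[3L]
  dist_term <- 0
  kl_s <- 0
  for (l in seq_len(D)) {
    s <- clamp01(saliency[, , l])
    r <- clamp01(rho[l], 1e-15)
    dist_term <- dist_term +
      sum(z * (s * quad$qmu[, , l] + (1 - s) * quad$qeps[, , l]))
    kl_s <- kl_s + sum(z * (s * (log(s) - log(r)) +
                            (1 - s) * (log1p(-s) - log(1 - r))))
  }
  zl <- z * (log(pmax(z, EPS_CLAMP)) -
             matrix(log(pmax(pi, EPS_CLAMP)), nrow(z), ncol(z),
                    byrow = TRUE))
  zl[z <= 0] <- 0
  dist_term + lambda * sum(zl) + gamma * kl_s
}

#' Feature-selection local fuzzy clustering of an image
#'
#' Fits the full algorithm: FCM initialization of the class means and
#' memberships, then alternating updates of the median neighborhood field,
#' the feature saliencies, the memberships (softmax weighted by class
#' prior, median field to the power `alpha`, and the class cost), and the
#' model parameters, until the max-norm membership change falls below `tol`
#' or `max_iter` is reached.
#'
#' @inheritParams fcm
#' @param lambda entropy-regularization weight on the membership KL term;
#'   the default 1000 is calibrated to squared 0--255 intensity distances.
#' @param gamma feature-selection weight on the saliency KL term (same
#'   scale as `lambda`).
#' @param alpha exponent of the median neighborhood field in the membership
#'   update; 2 is the standard choice, 0 disables the postprocessing.
#' @param window odd neighborhood window side (3 or 5).
#' @param center_update see [update_model()].
#' @return an object of class `c("fsfcm", "fuzzy_seg")`: memberships `z`,
#'   `centers` (= model class means), the full `model`, the last `saliency`
#'   and median field `H`, `iterations`, `converged`, `objective_trace`.
#' @examples
#' ph <- make_phantom(16, 16, levels = c(40, 200), layout = "stripes",
#'                    seed = 1)
#' fit <- fsfcm(ph$image, C = 2, seed = 1)
#' table(predict(fit)$labels, ph$truth$labels)
#' @export
fsfcm <- function(image, C, lambda = 1e3, gamma = 1e3, alpha = 2, m = 2,
                  window = 3L, tol = 1e-4, max_iter = 300L, seed = 1L,
                  center_update = c("lagrange", "printed")) {
  center_update <- match.arg(center_update)
  if (lambda <= 0 || gamma <= 0)
    stop("lambda and gamma must be positive", call. = FALSE)
  image <- as.feature_image(image)
  x <- image$values
  n <- nrow(x); D <- ncol(x)
  C <- as.integer(C)
  if (C < 2L || C > n) stop("C must be between 2 and N", call. = FALSE)
  spec <- build_neighborhood(image$height, image$width, window)

  # initialization: FCM centers and memberships; flat feature weights and
  # priors; background model from global moments; variances kept as
  # diagnostics
  init <- fcm(image, C, m = m, tol = tol, max_iter = max_iter, seed = seed)
  z <- init$z
  mu <- init$centers
  sigma2 <- matrix(0, C, D)
  for (j in seq_len(C)) for (l in seq_len(D))
    sigma2[j, l] <- sum(z[, j] * (x[, l] - mu[j, l])^2) / max(sum(z[, j]),
                                                              EPS_CLAMP)
  eps <- colMeans(x)
  nu2 <- colMeans((x - matrix(eps, n, D, byrow = TRUE))^2)
  model <- fs_model(mu, rep(1 / C, C), eps, rep(1 / D, D), sigma2, nu2)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  saliency <- NULL; H <- NULL
  for (t in seq_len(max_iter)) {
    iter <- t
    agg <- fs_aggregates(spec, z, x, m)
    quad <- fs_quad_pair(x, agg, model)
    H <- median_field(z, spec)
    saliency <- fs_saliency_from_quad(quad, model$rho, gamma)
    eta <- fs_eta_from_quad(quad, saliency, model$rho, gamma)
    z_new <- fs_membership_from_eta(eta, model$pi, H, lambda, alpha)
    agg_new <- fs_aggregates(spec, z_new, x, m)
    model <- fs_model_from_agg(x, z_new, saliency, agg_new, center_update,
                               model)
    trace <- c(trace, fs_objective_from_quad(
      z_new, saliency, fs_quad_pair(x, agg_new, model),
      model$pi, model$rho, lambda, gamma))
    delta <- max(abs(z_new - z))
    z <- z_new
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- fuzzy_fit_result("fsfcm", z, model$mu, m, iter, converged, trace,
                          image,
                          extra = list(model = model, saliency = saliency,
                                       H = H,
                                       hyper = list(lambda = lambda,
                                                    gamma = gamma,
                                                    alpha = alpha,
                                                    window = window,
                                                    tol = tol,
                                                    max_iter = max_iter,
                                                    seed = seed,
                                                    center_update =
                                                      center_update)))
  out
}
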