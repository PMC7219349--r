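# Independent reference implementations used as oracles.  Everything here
# is written as plain per-pixel loops straight from the model definitions,
# deliberately sharing no code path with the vectorized package internals.

# neighbor weight u_ibj = (1 - z_bj)^m / (z_bj * d + 1)
ref_u <- function(zbj, d, m = 2) (1 - zbj)^m / (zbj * d + 1)

# full regularized objective: saliency-weighted neighbor-augmented
# distances + lambda * KL(z || pi) + gamma * KL(s || rho)
ref_objective <- function(x, z, model, s, spec, lambda, gamma, m = 2) {
  n <- nrow(x); C <- ncol(z); D <- ncol(x)
  mu <- model$mu; eps <- model$eps; rho <- model$rho; pi <- model$pi
  J <- 0
  for (i in seq_len(n)) {
    nb <- neighbors(spec, i)
    for (j in seq_len(C)) {
      dij <- 0; Gij <- 0
      for (l in seq_len(D)) {
        sij <- s[i, j, l]
        dij <- dij + sij * (x[i, l] - mu[j, l])^2 +
          (1 - sij) * (x[i, l] - eps[l])^2
        for (k in seq_len(nrow(nb))) {
          b <- nb$index[k]
          u <- ref_u(z[b, j], nb$dist[k], m)
          Gij <- Gij + u * (sij * (x[b, l] - mu[j, l])^2 +
                            (1 - sij) * (x[b, l] - eps[l])^2)
        }
      }
      kl_s <- 0
      for (l in seq_len(D)) {
        sij <- s[i, j, l]
        kl_s <- kl_s + sij * log(sij / rho[l]) +
          (1 - sij) * log((1 - sij) / (1 - rho[l]))
      }
      zij <- z[i, j]
      kl_z <- if (zij > 0) zij * log(zij / pi[j]) else 0
      J <- J + zij * (dij + Gij) + lambda * kl_z + gamma * zij * kl_s
    }
  }
  J
}

# random small test instance on a h x w grid
rand_instance <- function(seed, h = 4, w = 5, C = 3, D = 2) {
  set.seed(seed)
  n <- h * w
  x <- matrix(runif(n * D, 0, 255), n, D)
  img <- feature_image(x, height = h, width = w)
  z <- matrix(runif(n * C, 0.05, 1), n, C)
  z <- z / rowSums(z)
  mu <- matrix(runif(C * D, 0, 255), C, D)
  eps <- runif(D, 0, 255)
  rho <- runif(D, 0.2, 0.8)
  pi <- runif(C, 0.2, 1); pi <- pi / sum(pi)
  model <- fs_model(mu, pi, eps, rho)
  spec <- build_neighborhood(h, w, 3)
  list(img = img, x = x, z = z, model = model, spec = spec, n = n, C = C,
       D = D)
}

# central-difference derivative of f at t
num_deriv <- function(f, t, h) (f(t + h) - f(t - h)) / (2 * h)

# Newton displacement |g / c| of the stationary point along one coordinate;
# falls back to the raw gradient scale when curvature is ~0
stationary_displacement <- function(f, t, h) {
  fp <- f(t + h); fm <- f(t - h); f0 <- f(t)
  g <- (fp - fm) / (2 * h)
  c <- (fp + fm - 2 * f0) / h^2
  if (abs(c) > 1e-8 * (abs(f0) + 1)) abs(g / c) else
    abs(g) / (abs(f0) + 1)
}

# exhaustive best-permutation misclassification rate (oracle for mcr)
ref_mcr <- function(pred, truth) {
  C <- max(pred$C, truth$C)
  perms <- ref_perms(seq_len(C))
  best <- -1
  for (p in perms) {
    agree <- sum(p[pred$labels + 1L] - 1L == truth$labels)
    if (agree > best) best <- agree
  }
  (1 - best / length(truth$labels)) * 100
}

ref_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in ref_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# naive per-pixel median field
ref_median_field <- function(z, spec) {
  n <- nrow(z); C <- ncol(z)
  H <- matrix(0, n, C)
  for (i in seq_len(n)) {
    nb <- neighbors(spec, i)
    for (j in seq_len(C)) {
      H[i, j] <- if (nrow(nb) == 0L) z[i, j] else
        stats::median(z[nb$index, j])
    }
  }
  H
}

# standard phantom used across tests: 2-level stripes at the canonical
# (40, 200) gray levels
two_level_phantom <- function(h = 32, w = 32, seed = 1)
  make_phantom(h, w, levels = c(40, 200), layout = "stripes", seed = seed)
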