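# crisp membership matrix that zeroes all neighbor weights for a class
crisp_z <- function(n, C, class = 1L) {
  z <- matrix(0, n, C)
  z[, class] <- 1
  z
}

test_that("neighbor weight follows the membership-damped formula", {
  spec <- build_neighborhood(1, 2, 3)
  z <- matrix(c(0.5, 1, 0.5, 0), 2, 2)
  expect_equal(neighbor_weight(z, spec, 1, 2, 1, m = 2), 0)      # z_bj = 1
  expect_equal(neighbor_weight(z, spec, 1, 2, 2, m = 2), 1)      # z_bj = 0
  z[2, 1] <- 0.5
  expect_equal(neighbor_weight(z, spec, 1, 2, 1, m = 2), 0.25 / 1.5)
  expect_error(neighbor_weight(z, spec, 1, 1, 1), "not a neighbor")
})

test_that("saliency logit compares background and class distances", {
  spec <- build_neighborhood(1, 2, 3)
  img <- feature_image(matrix(c(5, 9), 1, 2))
  # mu = eps: symmetric cancellation
  m1 <- fs_model(matrix(c(3, 3), 2, 1), c(0.5, 0.5), eps = 3, rho = 0.5)
  expect_equal(saliency_logit(img, crisp_z(2, 2), m1, spec, 1, 1, 1), 0)
  # x_i = mu, neighbors silenced (crisp z), eps = x_i + 10 -> t = 100
  m2 <- fs_model(matrix(c(5, 0), 2, 1), c(0.5, 0.5), eps = 15, rho = 0.5)
  expect_equal(saliency_logit(img, crisp_z(2, 2), m2, spec, 1, 1, 1), 100)
})

test_that("saliency update is the clamped logistic of the logit", {
  spec <- build_neighborhood(1, 2, 3)
  img <- feature_image(matrix(c(5, 9), 1, 2))
  z <- crisp_z(2, 2)
  # mu = eps -> t = 0 -> s = rho exactly
  m1 <- fs_model(matrix(c(3, 3), 2, 1), c(0.5, 0.5), eps = 3, rho = 0.37)
  s <- update_saliency(img, z, m1, spec, gamma = 1000)
  expect_equal(as.numeric(s[, 1, 1]), rep(0.37, 2))
  # rho = 0.5, t/gamma = ln 3 -> s = 0.75: x = 0, mu = 0, eps^2 = ln3 * g
  g <- 1000
  img2 <- feature_image(matrix(c(0, 0), 1, 2))
  m2 <- fs_model(matrix(c(0, 0), 2, 1), c(0.5, 0.5),
                 eps = sqrt(log(3) * g), rho = 0.5)
  s2 <- update_saliency(img2, z, m2, spec, gamma = g)
  expect_equal(s2[1, 1, 1], 0.75)
  # logistic limits under extreme logits stay clamped inside (0, 1)
  m3 <- fs_model(matrix(c(0, 0), 2, 1), c(0.5, 0.5), eps = 255, rho = 0.5)
  s3 <- update_saliency(img2, z, m3, spec, gamma = 1e-6)
  expect_true(all(s3 > 0 & s3 < 1))
  expect_equal(s3[1, 1, 1], 1 - 1e-12)
  expect_error(update_saliency(img2, z, m3, spec, gamma = 0), "gamma")
})

test_that("saliency update agrees with the scalar logit everywhere", {
  inst <- rand_instance(21, h = 3, w = 4, C = 2, D = 2)
  s <- update_saliency(inst$img, inst$z, inst$model, inst$spec, gamma = 500)
  for (i in c(1, 5, 12)) for (j in 1:2) for (l in 1:2) {
    t <- saliency_logit(inst$img, inst$z, inst$model, inst$spec, i, j, l)
    rho <- inst$model$rho[l]
    expect_equal(s[i, j, l],
                 rho * exp(t / 500) / (1 - rho + rho * exp(t / 500)),
                 tolerance = 1e-10)
  }
})

test_that("class cost reduces to a saliency-weighted distance mix", {
  spec <- build_neighborhood(1, 2, 3)
  # crisp z silences neighbors; s = rho = 0.5 kills the KL terms;
  # (x - mu)^2 = 4, (x - eps)^2 = 16 -> eta = 0.5*4 + 0.5*16 = 10
  img <- feature_image(matrix(c(0, 0), 1, 2))
  mod <- fs_model(matrix(c(2, 0), 2, 1), c(0.5, 0.5), eps = 4, rho = 0.5)
  s <- array(0.5, dim = c(2, 2, 1))
  expect_equal(class_cost(img, crisp_z(2, 2), mod, s, spec, 1000, 1, 1), 10)

  # moving mu toward x strictly decreases the cost
  mod2 <- fs_model(matrix(c(1, 0), 2, 1), c(0.5, 0.5), eps = 4, rho = 0.5)
  expect_lt(class_cost(img, crisp_z(2, 2), mod2, s, spec, 1000, 1, 1), 10)
})

test_that("median field takes the neighbors-only median", {
  # corner pixel of a 2 x 2 grid has exactly 3 neighbors
  spec <- build_neighborhood(2, 2, 3)
  z <- matrix(c(0.7, 0.1, 0.5, 0.9), 4, 1)    # pixel 1 + neighbors 2,3,4
  H <- median_field(z, spec)
  expect_equal(H[1, 1], 0.5)

  # even neighbor count: 1 x 5 grid, window 5 -> interior pixel has 4
  spec5 <- build_neighborhood(1, 5, 5)
  z5 <- matrix(c(0.2, 0.4, 0.99, 0.6, 0.8), 5, 1)
  expect_equal(median_field(z5, spec5)[3, 1], 0.5)

  # constant memberships are a fixed point
  zc <- matrix(0.3, 4, 1)
  expect_equal(median_field(zc, spec)[, 1], rep(0.3, 4))

  # agrees with the naive per-pixel oracle on a random field
  inst <- rand_instance(33, h = 5, w = 6, C = 3, D = 1)
  expect_equal(median_field(inst$z, inst$spec),
               ref_median_field(inst$z, inst$spec))
})

test_that("membership update is the prior- and median-weighted softmax", {
  spec <- build_neighborhood(1, 2, 3)
  z <- matrix(0.5, 2, 2)     # symmetric: both classes see equal u weights
  H <- matrix(0.5, 2, 2)
  s <- array(0.5, dim = c(2, 2, 1))
  img <- feature_image(matrix(c(0, 0), 1, 2))
  # equal costs (|mu_1| = |mu_2|, x symmetric), uniform prior, alpha = 0
  m1 <- fs_model(matrix(c(2, -2), 2, 1), c(0.5, 0.5), eps = 0, rho = 0.5)
  z1 <- update_membership(img, z, m1, s, H, spec, lambda = 1,
                          gamma = 1000, alpha = 0)
  expect_equal(z1[1, ], c(0.5, 0.5))
  expect_lt(max(abs(rowSums(z1) - 1)), 1e-12)

  # eta difference of -lambda * ln 9 gives membership 0.9 (softmax closed
  # form).  With s = rho = 0.5, x = x_b = 0 and u = 0.25/1.5 for every
  # neighbor/class, eta_1 - eta_2 = 0.5 (mu_1^2 - mu_2^2)(1 + u).
  u <- 0.25 / 1.5
  d <- 2 * log(9) / (1 + u)                    # mu_2^2 - mu_1^2 = d
  m2 <- fs_model(matrix(c(0, sqrt(d)), 2, 1), c(0.5, 0.5), eps = 0,
                 rho = 0.5)
  z2 <- update_membership(img, z, m2, s, H, spec, lambda = 1,
                          gamma = 1000, alpha = 0)
  expect_equal(z2[1, 1], 0.9, tolerance = 1e-9)
  expect_error(update_membership(img, z, m2, s, H, spec, lambda = 0,
                                 gamma = 1000), "lambda")
})

test_that("raising the median field raises the membership monotonically", {
  set.seed(99)
  n <- 1000
  eta <- matrix(runif(3 * n, 0, 50), n, 3)
  H <- matrix(runif(3 * n, 0.05, 0.9), n, 3)
  pi <- c(0.2, 0.5, 0.3)
  z1 <- fsflicm:::fs_membership_from_eta(eta, pi, H, lambda = 10, alpha = 2)
  H2 <- H; H2[, 2] <- H2[, 2] + 0.01
  z2 <- fsflicm:::fs_membership_from_eta(eta, pi, H2, lambda = 10,
                                         alpha = 2)
  expect_true(all(z2[, 2] >= z1[, 2] - 1e-12))
})

test_that("model update preserves the prior simplex and collapses correctly", {
  inst <- rand_instance(5)
  s <- array(runif(inst$n * inst$C * inst$D, 0.2, 0.8),
             dim = c(inst$n, inst$C, inst$D))
  mod <- update_model(inst$img, inst$z, s, inst$spec)
  expect_equal(sum(mod$pi), 1, tolerance = 1e-12)
  expect_true(all(mod$pi >= 0))

  # s == 1 and the printed center form: mu reduces to the z-weighted mean
  # (m = 1 weights) and rho hits the upper clamp
  spec <- build_neighborhood(1, 4, 3)
  img <- feature_image(matrix(c(0, 2, 10, 12), 1, 4))
  z <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2)
  s1 <- array(1, dim = c(4, 2, 1))
  mod2 <- update_model(img, z, s1, spec, center_update = "printed")
  expect_equal(as.numeric(mod2$mu), c(1, 11))
  expect_equal(mod2$rho, 1 - 1e-6)
  expect_equal(mod2$pi, c(0.5, 0.5))

  # the neighborhood-consistent default mixes cross-boundary neighbors:
  # on this 1 x 4 grid only the class-boundary pair contributes (u = 1),
  # giving mu = ((0+0) + (2+10)) / 3 = 4 and ((10+2) + 12) / 3 = 8
  mod3 <- update_model(img, z, s1, spec)
  expect_equal(as.numeric(mod3$mu), c(4, 8))
})

test_that("degenerate classes keep their previous mean with a warning", {
  spec <- build_neighborhood(1, 4, 3)
  img <- feature_image(matrix(c(0, 2, 10, 12), 1, 4))
  z <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2)   # class 2 empty
  s <- array(1, dim = c(4, 2, 1))
  prev <- fs_model(matrix(c(5, 123), 2, 1), c(0.5, 0.5), eps = 6,
                   rho = 0.5)
  expect_warning(mod <- update_model(img, z, s, spec, model = prev),
                 "degenerate")
  expect_equal(mod$mu[2, 1], 123)
})

test_that("the vectorized objective matches the naive reference", {
  for (sd in c(2, 7, 19)) {
    inst <- rand_instance(sd, h = 3, w = 5, C = 2, D = 2)
    s <- array(runif(inst$n * 2 * 2, 0.1, 0.9), dim = c(inst$n, 2, 2))
    J_pkg <- fs_objective(inst$img, inst$z, inst$model, s, inst$spec,
                          lambda = 800, gamma = 600)
    J_ref <- ref_objective(inst$x, inst$z, inst$model, s, inst$spec,
                           lambda = 800, gamma = 600)
    expect_equal(J_pkg, J_ref, tolerance = 1e-10)
  }
})

test_that("the fit recovers a clean two-level phantom exactly", {
  ph <- two_level_phantom(32, 32)
  fit <- fsfcm(ph$image, C = 2, seed = 1)
  expect_equal(mcr(predict(fit), ph$truth), 0, ignore_attr = TRUE)
  expect_true(fit$converged)
  expect_lt(max(abs(rowSums(fit$z) - 1)), 1e-9)
  expect_equal(sum(fit$model$pi), 1, tolerance = 1e-9)
})

test_that("a uniform image is tolerated and centers equal the constant", {
  img <- feature_image(matrix(42, 8, 8))
  fit <- suppressWarnings(fsfcm(img, C = 2, seed = 3))
  expect_lt(max(abs(fit$centers - 42)), 1e-6)
  expect_lt(max(abs(rowSums(fit$z) - 1)), 1e-9)
  lab <- predict(fit)
  expect_true(all(lab$labels %in% c(0L, 1L)))
})

test_that("fits are bitwise deterministic given the seed", {
  ph <- two_level_phantom(16, 16)
  noisy <- add_salt_pepper(ph$image, 0.15, seed = 8)
  a <- fsfcm(noisy, C = 2, seed = 42, max_iter = 25)
  b <- fsfcm(noisy, C = 2, seed = 42, max_iter = 25)
  expect_identical(a$z, b$z)
  expect_identical(a$model$mu, b$model$mu)
  expect_identical(a$objective_trace, b$objective_trace)
})

test_that("labeling takes the maximum membership with low-index ties", {
  fake <- structure(list(z = rbind(c(0.2, 0.7, 0.1), c(0.5, 0.5, 0),
                                   c(1, 0, 0)),
                         height = 1L, width = 3L),
                    class = "fuzzy_seg")
  expect_equal(predict(fake)$labels, c(1L, 0L, 0L))
})

test_that("hyperparameter validation rejects bad values", {
  img <- feature_image(matrix(1:16, 4, 4))
  expect_error(fsfcm(img, C = 2, lambda = -1), "lambda")
  expect_error(fsfcm(img, C = 1), "C must be")
  expect_error(fsfcm(img, C = 2, window = 4), "odd")
})
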