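test_that("fcm separates well-separated 1-d groups", {
  img <- feature_image(matrix(c(0, 0, 0, 100, 100, 100), 1, 6))
  fit <- fcm(img, C = 2, m = 2, seed = 7)
  v <- sort(fit$centers[, 1])
  expect_lt(abs(v[1] - 0), 1)
  expect_lt(abs(v[2] - 100), 1)
  own <- apply(fit$z, 1, max)
  expect_true(all(own >= 0.99))
  expect_true(fit$converged)
})

test_that("a sample coincident with a center gets a crisp membership", {
  # zero effective distance -> membership 1 on that class, 0 elsewhere;
  # ties break to the first singular class
  z <- fsflicm:::membership_from_dist(matrix(c(0, 4), 1, 2), m = 2)
  expect_equal(as.numeric(z), c(1, 0))
  z2 <- fsflicm:::membership_from_dist(matrix(c(3, 0, 0), 1, 3), m = 2)
  expect_equal(as.numeric(z2), c(0, 1, 0))
  # regular rows are untouched by the singular handling
  z3 <- fsflicm:::membership_from_dist(matrix(c(1, 3), 1, 2), m = 2)
  expect_equal(as.numeric(z3), c(3 / 4, 1 / 4))
})

test_that("memberships stay on the simplex at every iteration budget", {
  ph <- two_level_phantom(8, 8)
  noisy <- add_gaussian(ph$image, 30, seed = 2)
  for (k in c(1L, 2L, 5L)) {
    for (fitter in list(fcm, flicm, improved_flicm)) {
      fit <- fitter(noisy, C = 2, seed = 5, max_iter = k)
      expect_lt(max(abs(rowSums(fit$z) - 1)), 1e-9)
      expect_true(all(fit$z >= 0 & fit$z <= 1))
    }
  }
})

test_that("the fcm objective is non-increasing across iterations", {
  set.seed(11)
  img <- feature_image(matrix(runif(100, 0, 255), 10, 10))
  fit <- fcm(img, C = 3, seed = 1, max_iter = 50)
  tr <- fit$objective_trace
  expect_gt(length(tr), 2)
  expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)])))
})

test_that("centers are convex combinations of the data", {
  ph <- two_level_phantom(10, 10)
  noisy <- add_salt_pepper(ph$image, 0.1, seed = 4)
  rng <- range(noisy$values)
  for (fitter in list(fcm, flicm, improved_flicm)) {
    fit <- fitter(noisy, C = 2, seed = 2, max_iter = 30)
    expect_true(all(fit$centers >= rng[1] - 1e-8 &
                    fit$centers <= rng[2] + 1e-8))
  }
})

test_that("flicm fuzzy factor matches hand-computed cases", {
  # 1 x 2 grid: pixel 1 has the single neighbor 2 at distance 1
  spec <- build_neighborhood(1, 2, 3)
  img <- feature_image(matrix(c(0, 2), 1, 2))
  state <- list(z = matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2),
                centers = matrix(c(0, 4), 2, 1), m = 2)
  # neighbor at x = 2, v_1 = 0: ||x_b - v||^2 = 4, weight 1/(1+1), (1-z)^2 =
  # 0.25 -> 0.5 * 0.25 * 4 = 0.5
  expect_equal(flicm_fuzzy_factor(state, spec, img, 1, 1), 0.5)

  # all neighbors fully in class j -> factor 0
  state$z <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(flicm_fuzzy_factor(state, spec, img, 1, 1), 0)

  # all neighbors exactly at the center -> factor 0
  state$z <- matrix(0.5, 2, 2)
  state$centers <- matrix(c(2, 4), 2, 1)
  expect_equal(flicm_fuzzy_factor(state, spec, img, 1, 1), 0)
})

test_that("flicm with the spatial term disabled reproduces fcm exactly", {
  ph <- two_level_phantom(8, 8)
  noisy <- add_gaussian(ph$image, 25, seed = 9)
  a <- fcm(noisy, C = 2, seed = 13, max_iter = 40)
  b <- flicm(noisy, C = 2, seed = 13, max_iter = 40, spatial_scale = 0)
  expect_lt(max(abs(a$z - b$z)), 1e-10)
  expect_lt(max(abs(a$centers - b$centers)), 1e-10)
  expect_equal(a$iterations, b$iterations)
})

test_that("flicm segments a clean two-level image perfectly", {
  ph <- two_level_phantom(16, 16)
  fit <- flicm(ph$image, C = 2, seed = 1)
  expect_equal(mcr(predict(fit), ph$truth), 0, ignore_attr = TRUE)
})

test_that("flicm absorbs an isolated salt pixel into its region", {
  ph <- two_level_phantom(12, 12)
  img <- ph$image
  salt <- rc_to_pixel(3L, 4L, 12L)           # interior of the dark stripe
  img$values[salt, 1] <- 255
  fit <- flicm(img, C = 2, seed = 2)
  lab <- predict(fit)$labels
  nb <- neighbors(build_neighborhood(12, 12, 3), salt)
  expect_equal(lab[salt], as.integer(names(which.max(table(lab[nb$index])))))
})

test_that("improved flicm handles degenerate and crisp configurations", {
  # uniform image: every center converges to the constant
  img <- feature_image(matrix(77, 6, 6))
  fit <- improved_flicm(img, C = 2, seed = 5, max_iter = 50)
  expect_lt(max(abs(fit$centers - 77)), 1e-6)
  expect_lt(max(abs(rowSums(fit$z) - 1)), 1e-9)

  # crisp memberships with agreeing neighbors: the center-update neighbor
  # weight (1 - z)^m / (z d + 1) vanishes identically, so the neighbor sum
  # in the Eq.-12-style center is zero and the update collapses to the
  # plain weighted mean
  spec <- build_neighborhood(4, 4, 3)
  agg <- fsflicm:::iflicm_center_weights(spec, rep(1, 16), m = 2)
  expect_equal(agg$sum(runif(16, 0, 255)), rep(0, 16))

  # and a perfectly separable phantom is still segmented exactly
  ph <- two_level_phantom(8, 8)
  fit2 <- improved_flicm(ph$image, C = 2, seed = 1)
  expect_equal(mcr(predict(fit2), ph$truth), 0, ignore_attr = TRUE)
})

test_that("improved flicm beats fcm on most salt-and-pepper seeds", {
  wins <- 0L
  for (sd in 1:10) {
    ph <- two_level_phantom(24, 24, seed = sd)
    noisy <- add_salt_pepper(ph$image, 0.2, seed = 100 + sd)
    m_i <- mcr(predict(improved_flicm(noisy, C = 2, seed = sd)), ph$truth)
    m_f <- mcr(predict(fcm(noisy, C = 2, seed = sd)), ph$truth)
    if (m_i < m_f) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("parameter errors are raised for invalid C and m", {
  img <- feature_image(matrix(1:4, 2, 2))
  expect_error(fcm(img, C = 5), "C must be")
  expect_error(fcm(img, C = 2, m = 1), "fuzzifier")
})
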