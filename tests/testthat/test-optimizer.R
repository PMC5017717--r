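test_that("SGD stays at a fixed point when the gradient is zero", {
  fn <- function(mu, t) list(cost = 0, gradient = rep(0, 4))
  res <- sgd_minimize(fn, c(1, 2, 3, 4), iterations = 25)
  expect_equal(res$par, c(1, 2, 3, 4))
})

test_that("SGD descends a quadratic monotonically with a small gain", {
  fn <- function(mu, t) list(cost = 0.5 * mu^2, gradient = mu)
  res <- sgd_minimize(fn, 10, iterations = 200, gain_a = 2)
  expect_lt(abs(res$par), abs(10))
  expect_true(all(diff(res$trace$cost) <= 1e-12))
})

test_that("SGD reduces the error on noisy quadratics in most seeded repeats", {
  set.seed(77)
  A <- crossprod(matrix(rnorm(100), 10, 10)) / 10 + diag(10) * 0.5
  wins <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    mu0 <- rnorm(10, 0, 5)
    rng <- local({ s <- r; function() { s <<- s + 1; set.seed(s); rnorm(10) } })
    fn <- function(mu, t) {
      g <- as.numeric(A %*% mu) + 0.5 * rng()
      list(cost = 0.5 * sum(mu * (A %*% mu)), gradient = g)
    }
    res <- sgd_minimize(fn, mu0, iterations = 150, step_target = 1)
    if (sqrt(sum(res$par^2)) < sqrt(sum(mu0^2))) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})

test_that("SGD errors on non-finite gradients and caps oversized steps", {
  fn <- function(mu, t) list(cost = NaN, gradient = rep(NaN, 2))
  expect_error(sgd_minimize(fn, c(0, 0), 5), "non-finite")
  # exploding gradient: the step cap keeps iterates bounded
  fn2 <- function(mu, t) list(cost = sum(mu^4), gradient = 4 * mu^3)
  res <- sgd_minimize(fn2, c(3, -3), iterations = 50, step_target = 0.5,
                      max_step = 0.5)
  expect_true(all(is.finite(res$par)))
  expect_lte(max(res$trace$step), 0.5 + 1e-12)
})

test_that("reg_control validates its schedule", {
  expect_error(reg_control(grid_spacings_mm = c(10, 20)), "non-increasing")
  expect_error(reg_control(pyramid_factors = c(2, 1)), "equal length")
  expect_error(reg_control(iterations_per_level = 0), ">= 1")
  ctl <- reg_control()
  expect_equal(ctl$grid_spacings_mm, c(80, 40, 20, 10))
  expect_equal(ctl$iterations_per_level, 500)
  expect_equal(ctl$samples_per_iteration, 2000)
})

# Small deformable problem reused below: a blob image and a 6 mm shift.
small_problem <- function() {
  img <- smooth_random_image(c(24, 24, 24), spacing = c(2, 2, 2),
                             sigma_vox = 1.5, seed = 31, mean = 100, sd = 60)
  mask <- image3d(array(0, c(24, 24, 24)), c(2, 2, 2))
  mask$voxels[5:20, 5:20, 5:20] <- 1
  shifted <- resample(img, rigid_transform(translation = c(6, 0, 0)), img,
                      "linear", default_value = mean(img$voxels))
  list(img = img, mask = mask, shifted = shifted)
}

small_control <- function(seed = 7)
  reg_control(grid_spacings_mm = c(32, 16), pyramid_factors = c(2, 1),
              iterations_per_level = 60, samples_per_iteration = 1000,
              seed = seed)

test_that("multiresolution registration recovers a known translation", {
  pr <- small_problem()
  # fixed = shifted image; moving = original: truth T(x) = x + (6, 0, 0)
  fit <- multires_register(pr$shifted, pr$img, pr$mask,
                           control = small_control())
  set.seed(8)
  pts <- matrix(runif(60, 14, 34), 20, 3)
  rec <- transform_points(fit$transform, pts, extrapolate = TRUE) - pts
  expect_lt(max(abs(sweep(rec, 2, c(6, 0, 0), "-"))), 2)
  expect_s3_class(fit, "reg_fit")
  expect_equal(length(coef(fit)), prod(fit$ffd$grid_shape) * 3)
  expect_equal(predict(fit, pts),
               transform_points(fit$transform, pts, extrapolate = TRUE))
})

test_that("registration is bit-identical for a fixed master seed", {
  pr <- small_problem()
  f1 <- multires_register(pr$shifted, pr$img, pr$mask,
                          control = small_control(seed = 13))
  f2 <- multires_register(pr$shifted, pr$img, pr$mask,
                          control = small_control(seed = 13))
  expect_identical(coef(f1), coef(f2))
  f3 <- multires_register(pr$shifted, pr$img, pr$mask,
                          control = small_control(seed = 14))
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("a zero-weight rigidity term reproduces the unregularized result exactly", {
  pr <- small_problem()
  cm <- build_coefficient_mask(c(24, 24, 24), pr$img, kernel_mm = 12,
                               feather_mm = 0)
  w0 <- rigidity_weights(alpha = c(0, 0))
  plain <- multires_register(pr$shifted, pr$img, pr$mask,
                             control = small_control(seed = 21))
  reg0 <- multires_register(pr$shifted, pr$img, pr$mask,
                            control = small_control(seed = 21),
                            rigidity = list(cmask = cm, weights = w0))
  expect_identical(coef(plain), coef(reg0))
})

test_that("the smoothed cost estimate does not increase over a level", {
  pr <- small_problem()
  fit <- multires_register(pr$shifted, pr$img, pr$mask,
                           control = small_control(seed = 5))
  tr <- fit$trace
  # window-averaged stochastic estimates; allow estimator noise
  for (l in unique(tr$level)) {
    d <- tr[tr$level == l, ]
    noise <- stats::sd(utils::tail(d$cost, 20))
    expect_lte(mean(utils::tail(d$cost, 20)),
               mean(utils::head(d$cost, 20)) + 2 * noise)
  }
  expect_output(print(fit), "reg_fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.reg_fit")
})

test_that("rigid registration recovers a small rigid motion", {
  img <- smooth_random_image(c(24, 24, 24), spacing = c(2, 2, 2),
                             sigma_vox = 1.5, seed = 41, mean = 100, sd = 60)
  mask <- image3d(array(0, c(24, 24, 24)), c(2, 2, 2))
  mask$voxels[6:19, 6:19, 6:19] <- 1
  truth <- rigid_transform(rotation_z(4), translation = c(3, -2, 1),
                           center = c(23, 23, 23))
  fixed <- resample(img, truth, img, "linear", default_value = mean(img$voxels))
  ctl <- reg_control(rigid_factors = c(2, 1), iterations_per_level = 120,
                     samples_per_iteration = 1500, seed = 3)
  fit <- rigid_register(fixed, img, mask, control = ctl)
  set.seed(9)
  pts <- matrix(runif(60, 14, 34), 20, 3)
  err <- sqrt(rowSums((transform_points(fit$transform, pts) -
                         transform_points(truth, pts))^2))
  expect_lt(mean(err), 1.5)
})
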