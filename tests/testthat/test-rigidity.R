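meta30 <- list(dim = c(31, 31, 31), spacing = c(1, 1, 1), origin = c(0, 0, 0))

test_that("coefficient mask dilation follows the odd-voxel rounding rule", {
  cm <- build_coefficient_mask(c(15, 15, 15), meta30, kernel_mm = c(10, 10, 10),
                               feather_mm = 0)
  expect_equal(sum(cm$field$voxels == 1), 11^3)   # >= 10 mm, odd count
  on <- which(cm$field$voxels == 1)
  ai <- arrayInd(on, c(31, 31, 31)) - 1L
  expect_true(all(abs(ai - 15) <= 5))
  # coincident seeds are idempotent
  cm2 <- build_coefficient_mask(rbind(c(15, 15, 15), c(15, 15, 15)), meta30,
                                kernel_mm = 10, feather_mm = 0)
  expect_equal(cm2$field$voxels, cm$field$voxels)
  expect_error(build_coefficient_mask(c(-5, 0, 0), meta30), "outside")
})

test_that("feathered mask keeps c = 1 at seeds and decays monotonically outward", {
  cm <- build_coefficient_mask(c(15, 15, 15), meta30, kernel_mm = 10,
                               feather_mm = 4)
  v <- cm$field$voxels
  expect_equal(v[16, 16, 16], 1)
  expect_lt(v[31, 31, 31], 1e-4)
  ray <- v[16:31, 16, 16]
  expect_true(all(diff(ray) <= 1e-12))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("rigidity terms take their closed-form values on embedded affine maps", {
  g <- ffd_for_domain(meta30, 8)
  pt <- c(15, 15, 15)
  t0 <- rigidity_terms(g, pt)
  expect_equal(t0$AC, array(0, c(3, 3, 3)))
  expect_equal(t0$OC, matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(t0$PC, 0, tolerance = 1e-12)
  rot <- embed_affine(g, rotation_z(30), center = c(15, 15, 15))
  tr <- rigidity_terms(rot, pt)
  expect_lt(max(abs(tr$OC)), 1e-9)
  expect_lt(abs(tr$PC), 1e-9)
  expect_lt(max(abs(tr$AC)), 1e-9)
  sc <- embed_affine(g, diag(c(2, 1, 1)), center = c(15, 15, 15))
  ts <- rigidity_terms(sc, pt)
  expect_equal(ts$OC, diag(c(3, 0, 0)), tolerance = 1e-9)
  expect_equal(sum(ts$OC^2), 9, tolerance = 1e-8)
  expect_equal(ts$PC, 1, tolerance = 1e-9)
  # cross-check J against finite differences
  h <- 1e-3
  Jfd <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- h
    Jfd[, j] <- (transform_points(sc, pt + e) - transform_points(sc, pt - e)) /
      (2 * h)
  }
  expect_equal(Jfd, diag(c(2, 1, 1)), tolerance = 1e-6)
})

test_that("rigidity penalty is zero for rigid motions and 11 for the stretch example", {
  g <- ffd_for_domain(meta30, 8)
  set.seed(1)
  ep <- matrix(runif(150, 8, 22), 50, 3)
  w <- rigidity_weights(c_AC = 0.7, c_OC = 1, c_PC = 2)
  rig <- embed_affine(g, euler_rotation(0.3, -0.2, 0.4), c(2, 1, -1),
                      center = c(15, 15, 15))
  expect_lt(rigidity_penalty(rig, NULL, w, ep), 1e-8)
  sc <- embed_affine(g, diag(c(2, 1, 1)), center = c(15, 15, 15))
  expect_equal(rigidity_penalty(sc, NULL, w, ep), 11, tolerance = 1e-8)
  # locality: c = 1 only where the FFD is rigid -> 0
  f <- random_ffd(meta30, grid_mm = 8, sd = 1, seed = 2)
  co <- f$coefficients
  nodes <- liverreg:::ffd_nodes(f)
  # zero all nodes whose cubic support (2 spacings per axis) can reach
  # the seed neighborhood, so the transform is exactly rigid there
  near <- sqrt(rowSums(sweep(nodes, 2, c(8, 8, 8), "-")^2)) < 32
  flat <- matrix(co, prod(f$grid_shape), 3)
  flat[near, ] <- 0
  f$coefficients <- array(flat, dim(co))
  cm <- build_coefficient_mask(c(8, 8, 8), meta30, kernel_mm = 4,
                               feather_mm = 0)
  ep2 <- matrix(rep(c(8, 8, 8), each = 8), 8, 3) +
    matrix(runif(24, -1, 1), 8, 3)
  expect_lt(rigidity_penalty(f, cm, w, ep2, c_transform = f), 1e-6)
})

test_that("penalty is invariant to composing a global rigid motion", {
  g <- ffd_for_domain(meta30, 8)
  set.seed(3)
  A <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
  w <- rigidity_weights()
  ep <- matrix(runif(90, 9, 21), 30, 3)
  base <- rigidity_penalty(embed_affine(g, A), NULL, w, ep)
  R <- euler_rotation(0.4, 0.1, -0.3)
  comp <- rigidity_penalty(embed_affine(g, R %*% A, rnorm(3)), NULL, w, ep)
  expect_equal(base, comp, tolerance = 1e-8)
})

test_that("penalty is linear in the term weights", {
  f <- random_ffd(meta30, grid_mm = 8, sd = 0.8, seed = 4)
  set.seed(5)
  ep <- matrix(runif(90, 9, 21), 30, 3)
  p_oc <- rigidity_penalty(f, NULL, rigidity_weights(0, 1, 0), ep)
  p_pc <- rigidity_penalty(f, NULL, rigidity_weights(0, 0, 1), ep)
  p_ac <- rigidity_penalty(f, NULL, rigidity_weights(1, 0, 0), ep)
  mix <- rigidity_penalty(f, NULL, rigidity_weights(2, 3, 4), ep)
  expect_equal(mix, 2 * p_ac + 3 * p_oc + 4 * p_pc, tolerance = 1e-10)
  expect_equal(rigidity_penalty(f, NULL, rigidity_weights(0, 0, 2), ep),
               2 * p_pc, tolerance = 1e-12)
})

test_that("rigidity gradient matches finite differences and respects locality", {
  f <- random_ffd(meta30, grid_mm = 8, sd = 1, seed = 6)
  w <- rigidity_weights()
  set.seed(7)
  ep <- matrix(runif(240, 9, 21), 80, 3)
  cm <- build_coefficient_mask(rbind(c(12, 12, 12), c(18, 18, 14)), meta30,
                               kernel_mm = 8, feather_mm = 3)
  rg <- rigidity_gradient(f, cm, w, ep, c_transform = f)
  co <- f$coefficients
  idx <- order(-abs(rg$gradient))[seq(1, 120, by = 8)]
  h <- 1e-4
  for (i in idx) {
    cp <- co; cp[i] <- cp[i] + h
    cmn <- co; cmn[i] <- cmn[i] - h
    pp <- rigidity_penalty(bspline_ffd(f$control_spacing, f$grid_origin,
                                       f$grid_shape, cp), cm, w, ep,
                           c_transform = f)
    pm <- rigidity_penalty(bspline_ffd(f$control_spacing, f$grid_origin,
                                       f$grid_shape, cmn), cm, w, ep,
                           c_transform = f)
    expect_equal(rg$gradient[i], (pp - pm) / (2 * h),
                 tolerance = 1e-2 * max(abs(rg$gradient)))
  }
  # control points far from all evaluation points: exactly zero entries
  nodes <- liverreg:::ffd_nodes(f)
  gflat <- matrix(rg$gradient, prod(f$grid_shape), 3)
  far <- apply(nodes, 1, function(nd)
    min(sqrt(rowSums(sweep(ep, 2, nd, "-")^2)))) > 40
  expect_true(all(gflat[far, ] == 0))
  # gradient vanishes at the zero-penalty minimum
  g0 <- ffd_for_domain(meta30, 8)
  rg0 <- rigidity_gradient(g0, cm, w, ep, c_transform = g0)
  expect_lt(max(abs(rg0$gradient)), 1e-10)
})

test_that("degenerate coefficient masks raise a classed error", {
  f <- random_ffd(meta30, grid_mm = 8, sd = 1, seed = 8)
  cm <- build_coefficient_mask(c(2, 2, 2), meta30, kernel_mm = 2,
                               feather_mm = 0)
  ep <- matrix(rep(c(25, 25, 25), 4), 4, 3, byrow = TRUE)
  expect_error(rigidity_penalty(f, cm, rigidity_weights(), ep,
                                c_transform = f),
               class = "liverreg_degenerate_mask")
})
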