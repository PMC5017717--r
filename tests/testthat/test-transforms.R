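domain20 <- list(dim = c(20, 20, 20), spacing = c(2, 2, 2),
                 origin = c(0, 0, 0))

test_that("FFD partition of unity: constant coefficients give a constant shift", {
  g <- ffd_for_domain(domain20, 10)
  for (v in list(c(5, 0, 0), c(-2, 3, 7))) {
    co <- array(rep(v, each = prod(g$grid_shape)), c(g$grid_shape, 3))
    f <- bspline_ffd(g$control_spacing, g$grid_origin, g$grid_shape, co)
    set.seed(1)
    p <- matrix(runif(60, 4, 34), 20, 3)
    expect_equal(transform_points(f, p), sweep(p, 2, v, "+"),
                 tolerance = 1e-12)
  }
  # all-zero coefficients: identity
  p <- matrix(runif(30, 4, 34), 10, 3)
  expect_equal(transform_points(g, p), p, tolerance = 1e-15)
})

test_that("FFD evaluation matches a brute-force tensor-product basis sum", {
  b3 <- function(u) c((1 - u)^3, 3 * u^3 - 6 * u^2 + 4,
                      -3 * u^3 + 3 * u^2 + 3 * u + 1, u^3) / 6
  f <- random_ffd(domain20, grid_mm = 10, sd = 3, seed = 2)
  set.seed(3)
  for (k in 1:20) {
    pt <- runif(3, 5, 33)
    t3 <- (pt - f$grid_origin) / f$control_spacing
    i0 <- floor(t3); u <- t3 - i0
    wx <- b3(u[1]); wy <- b3(u[2]); wz <- b3(u[3])
    acc <- c(0, 0, 0)
    for (a in 1:4) for (b in 1:4) for (cc in 1:4)
      acc <- acc + wx[a] * wy[b] * wz[cc] *
        f$coefficients[i0[1] - 1 + a, i0[2] - 1 + b, i0[3] - 1 + cc, ]
    expect_equal(as.numeric(transform_points(f, pt)), pt + acc,
                 tolerance = 1e-12)
  }
})

test_that("spatial Jacobian and second derivatives match finite differences", {
  f <- random_ffd(domain20, grid_mm = 10, sd = 3, seed = 4)
  set.seed(5)
  p <- matrix(runif(60, 6, 32), 20, 3)
  h <- 1e-3
  J <- spatial_jacobian(f, p)
  H <- transform_hessian(f, p)
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- h
    Jfd <- (transform_points(f, sweep(p, 2, e, "+")) -
              transform_points(f, sweep(p, 2, e, "-"))) / (2 * h)
    expect_equal(J[, , j], Jfd, tolerance = 1e-4, ignore_attr = TRUE)
    Hfd <- (spatial_jacobian(f, sweep(p, 2, e, "+")) -
              spatial_jacobian(f, sweep(p, 2, e, "-"))) / (2 * h)
    expect_equal(H[, , , j], Hfd, tolerance = 1e-4, ignore_attr = TRUE)
  }
  # symmetry of the second-derivative tensor
  expect_equal(H[, , 1, 2], H[, , 2, 1])
  expect_equal(H[, , 1, 3], H[, , 3, 1])
  # identity FFD: zero tensor; rigid: constant Jacobian = R
  g <- ffd_for_domain(domain20, 10)
  expect_true(all(transform_hessian(g, p) == 0))
  R <- rotation_z(30)
  Jr <- spatial_jacobian(rigid_transform(R), p)
  for (i in 1:3) for (j in 1:3) expect_equal(unique(Jr[, i, j]), R[i, j])
})

test_that("embed_affine reproduces affine maps exactly on the interior", {
  g <- ffd_for_domain(domain20, 10)
  set.seed(6)
  p <- matrix(runif(300, 6, 32), 100, 3)
  # identity / pure translation
  expect_equal(transform_points(embed_affine(g, diag(3)), p), p,
               tolerance = 1e-12)
  f_t <- embed_affine(g, diag(3), c(3, -2, 1))
  expect_equal(transform_points(f_t, p), sweep(p, 2, c(3, -2, 1), "+"),
               tolerance = 1e-12)
  # rotation agrees with the rigid evaluation to 1e-9 mm
  R <- rotation_z(20)
  f_r <- embed_affine(g, R)
  ref <- transform_points(rigid_transform(R), p)
  expect_lt(max(abs(transform_points(f_r, p) - ref)), 1e-9)
  # second derivatives of an affine-embedded field vanish
  H <- transform_hessian(embed_affine(g, matrix(rnorm(9), 3, 3), rnorm(3)), p)
  expect_lt(max(abs(H)), 1e-10)
})

test_that("grid refinement carries the displacement field across resolutions", {
  f <- random_ffd(domain20, grid_mm = 16, sd = 4, seed = 7)
  set.seed(8)
  p <- matrix(runif(300, 8, 30), 100, 3)
  # identity and translation survive refinement
  g <- ffd_for_domain(domain20, 16)
  expect_equal(transform_points(refine_grid(g, g$control_spacing / 2), p), p,
               tolerance = 1e-12)
  tr <- embed_affine(g, diag(3), c(4, 1, -2))
  expect_equal(transform_points(refine_grid(tr, g$control_spacing / 2), p),
               sweep(p, 2, c(4, 1, -2), "+"), tolerance = 1e-9)
  # dyadic subdivision is exact on random fields
  r2 <- refine_grid(f, f$control_spacing / 2)
  expect_lt(max(abs(transform_points(r2, p) - transform_points(f, p))), 1e-3)
  expect_error(refine_grid(f, f$control_spacing * 2), "<=")
})

test_that("rigid inverse composes to the identity", {
  set.seed(9)
  r <- rigid_transform(euler_rotation(0.2, -0.3, 0.5),
                       translation = c(5, -7, 2), center = c(10, 20, 30))
  comp <- composite_transform(invert_rigid(r), r)
  p <- matrix(runif(60, -50, 50), 20, 3)
  expect_lt(max(abs(transform_points(comp, p) - p)), 1e-9)
})

test_that("composite transforms apply right-to-left with chained Jacobians", {
  a <- rigid_transform(rotation_z(90))   # applied second
  b <- rigid_transform(translation = c(1, 0, 0))  # applied first
  comp <- composite_transform(a, b)
  expect_equal(as.numeric(transform_points(comp, c(0, 0, 0))),
               as.numeric(transform_points(a, transform_points(b, c(0, 0, 0)))))
  f <- random_ffd(domain20, grid_mm = 10, sd = 2, seed = 10)
  comp2 <- composite_transform(a, f)
  set.seed(11)
  p <- matrix(runif(30, 8, 30), 10, 3)
  J <- spatial_jacobian(comp2, p)
  h <- 1e-3
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- h
    fd <- (transform_points(comp2, sweep(p, 2, e, "+")) -
             transform_points(comp2, sweep(p, 2, e, "-"))) / (2 * h)
    expect_equal(J[, , j], fd, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("transform constructors validate their invariants", {
  expect_error(rigid_transform(matrix(2, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "orthonormal|determinant")
  expect_error(bspline_ffd(c(-1, 1, 1), c(0, 0, 0), c(4, 4, 4)), "> 0")
  expect_error(bspline_ffd(c(1, 1, 1), c(0, 0, 0), c(3, 4, 4)), ">= 4")
  g <- ffd_for_domain(domain20, 10)
  expect_error(transform_points(g, c(-100, 0, 0)), "supported")
  expect_equal(as.numeric(transform_points(g, c(-100, 0, 0),
                                           extrapolate = TRUE)),
               c(-100, 0, 0))
})
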