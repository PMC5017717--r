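# Shared fixtures, built in code.

# Small random geometry: orthonormal direction from a QR decomposition.
random_geometry <- function(dims = c(8, 9, 7), seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(dim = dims, spacing = runif(3, 0.5, 4), origin = rnorm(3, 0, 20),
       direction = q)
}

smooth_random_image <- function(dims = c(24, 24, 24), spacing = c(2, 2, 2),
                                sigma_vox = 2, seed = 1, mean = 50, sd = 30) {
  set.seed(seed)
  v <- array(rnorm(prod(dims), mean, sd), dims)
  sm <- liverreg:::cpp_gauss_smooth(v, rep(sigma_vox, 3))
  image3d(array(sm, dims), spacing = spacing)
}

full_mask <- function(img) image3d(array(1, dim(img$voxels)), img$spacing,
                                   img$origin, img$direction)

random_ffd <- function(meta, grid_mm = 16, sd = 1.5, seed = 1) {
  g <- ffd_for_domain(meta, grid_mm)
  set.seed(seed)
  co <- array(rnorm(prod(g$grid_shape) * 3, 0, sd), c(g$grid_shape, 3))
  bspline_ffd(g$control_spacing, g$grid_origin, g$grid_shape, co)
}

# Random binary blob mask on a small grid.
random_blob_mask <- function(dims = c(12, 12, 12), spacing = c(1, 1, 1),
                             seed = 1, n_seeds = 3, radius = 3) {
  set.seed(seed)
  m <- array(0, dims)
  ii <- arrayInd(seq_len(prod(dims)), dims)
  for (k in seq_len(n_seeds)) {
    c0 <- runif(3, 2, dims - 2)
    d2 <- (ii[, 1] - c0[1])^2 + (ii[, 2] - c0[2])^2 + (ii[, 3] - c0[3])^2
    m[d2 <= radius^2] <- 1
  }
  image3d(m, spacing = spacing)
}

# Memoised phantom registration cases shared by the acceptance tests.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# The validation phantom: 96 x 96 x 64 voxels at 2 x 2 x 3 mm (the
# anisotropic clinical spacing regime at a desk-scale matrix size), with
# the study conditions: 30 degree patient rotation, 15 mm smooth
# breathing deformation, contrast-enhanced D vs non-enhanced F.
acceptance_phantom <- function() memo("phantom", {
  spec <- phantom_spec(shape = c(96, 96, 64), spacing = c(2, 2, 3), seed = 5)
  simulate_case(spec, pose_z_deg = 30, deform_amplitude_mm = 15,
                contrast = FALSE, n_slices = 5)
})

# Reduced-iteration schedule used for phantom registrations in the tests
# (the clinical default of 500 iterations/level is unchanged).
acceptance_control <- function() reg_control(iterations_per_level = 80,
                                             rigid_iterations = 150,
                                             seed = 42)

acceptance_stage1 <- function() memo("stage1", {
  stage1(acceptance_phantom()$case, acceptance_control())
})
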