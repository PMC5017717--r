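test_that("world_from_index pins the voxel-center coordinate convention", {
  g <- list(dim = c(4, 4, 4), spacing = c(1, 1, 1), origin = c(0, 0, 0))
  expect_equal(as.numeric(world_from_index(g, c(0, 0, 0))), c(0, 0, 0))
  g2 <- list(dim = c(4, 4, 4), spacing = c(2, 2, 5), origin = c(10, 0, 0))
  expect_equal(as.numeric(world_from_index(g2, c(1, 1, 1))), c(12, 2, 5))
  expect_error(world_from_index(g, c(4, 0, 0)), "out of bounds")
})

test_that("world_from_index matches a direct affine oracle on random geometry", {
  for (s in 1:5) {
    g <- random_geometry(seed = s)
    set.seed(100 + s)
    idx <- cbind(sample(0:(g$dim[1] - 1), 10, TRUE),
                 sample(0:(g$dim[2] - 1), 10, TRUE),
                 sample(0:(g$dim[3] - 1), 10, TRUE))
    got <- world_from_index(g, idx)
    for (i in 1:10) {
      ref <- g$origin + g$direction %*% (g$spacing * idx[i, ])
      expect_equal(as.numeric(got[i, ]), as.numeric(ref), tolerance = 1e-12)
    }
    # affinity: increments independent of base point
    d1 <- world_from_index(g, idx[1, ] + c(1, 0, 1), check = FALSE) -
      world_from_index(g, idx[1, ], check = FALSE)
    d2 <- world_from_index(g, idx[2, ] + c(1, 0, 1), check = FALSE) -
      world_from_index(g, idx[2, ], check = FALSE)
    expect_equal(d1, d2, tolerance = 1e-12)
    # round trip through index_from_world
    expect_equal(index_from_world(g, got), idx * 1.0, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("resample with the identity transform copies voxels", {
  img <- smooth_random_image(c(10, 11, 9), seed = 2)
  for (interp in c("nearest", "linear", "cubic")) {
    out <- resample(img, NULL, img, interp)
    expect_equal(out$voxels, img$voxels, tolerance = 1e-12)
  }
  expect_error(resample(img, NULL, img, "sinc"))
})

test_that("resampling a one-voxel translation shifts the array and fills with the default", {
  img <- smooth_random_image(c(8, 8, 8), spacing = c(2, 2, 2), seed = 3)
  tr <- rigid_transform(translation = c(2, 0, 0))  # one voxel in x
  out <- resample(img, tr, img, "linear", default_value = -1000)
  expect_equal(out$voxels[1:7, , ], img$voxels[2:8, , ], tolerance = 1e-9)
  expect_true(all(out$voxels[8, , ] == -1000))
})

test_that("resample matches a per-voxel brute-force trilinear oracle", {
  img <- smooth_random_image(c(16, 16, 16), spacing = c(1.5, 1, 2), seed = 4)
  ffd <- random_ffd(img, grid_mm = 12, sd = 1, seed = 5)
  out <- resample(img, ffd, img, "linear", default_value = -7)
  v <- img$voxels
  interp1 <- function(ci) {
    if (any(ci < 0) || any(ci > dim(v) - 1)) return(-7)
    i0 <- pmin(floor(ci), dim(v) - 2)
    f <- ci - i0
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
        (if (cc) f[3] else 1 - f[3])
      acc <- acc + w * v[i0[1] + a + 1, i0[2] + b + 1, i0[3] + cc + 1]
    }
    acc
  }
  set.seed(6)
  for (k in 1:30) {
    ijk <- sapply(dim(v), function(n) sample(0:(n - 1), 1))
    x <- world_from_index(img, ijk)
    tx <- transform_points(ffd, x, extrapolate = TRUE)
    ci <- as.numeric(index_from_world(img, tx))
    expect_equal(out$voxels[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1],
                 interp1(ci), tolerance = 1e-9)
  }
})

test_that("gaussian pyramid preserves world geometry, constants and blob positions", {
  img <- smooth_random_image(c(32, 32, 32), spacing = c(2, 2, 2), seed = 7)
  lv <- gaussian_pyramid(img, c(1))
  expect_equal(lv[[1]]$voxels, img$voxels)
  const <- image3d(array(42, c(16, 16, 16)), spacing = c(1, 1, 1))
  for (l in gaussian_pyramid(const, c(4, 2, 1)))
    expect_equal(mean(l$voxels), 42, tolerance = 1e-12)
  expect_error(gaussian_pyramid(img, c(0)), "factor")
  expect_error(gaussian_pyramid(img, c(2, 4)), "non-increasing")
  # blob center of mass preserved across levels to within a coarse voxel
  blob <- array(0, c(32, 32, 32))
  ii <- arrayInd(seq_len(32^3), c(32, 32, 32))
  d2 <- (ii[, 1] - 20)^2 + (ii[, 2] - 12)^2 + (ii[, 3] - 16)^2
  blob[d2 <= 36] <- 100
  bimg <- image3d(blob, spacing = c(2, 2, 2), origin = c(5, -3, 2))
  pyr <- gaussian_pyramid(bimg, c(4, 2, 1))
  com <- function(im) {
    idx <- which(im$voxels > 1)
    w <- im$voxels[idx]
    ai <- arrayInd(idx, dim(im$voxels)) - 1L
    colSums(world_from_index(im, ai, check = FALSE) * w) / sum(w)
  }
  ref <- com(pyr[[3]])
  for (k in 1:2) {
    factor <- c(4, 2)[k]
    expect_lt(max(abs(com(pyr[[k]]) - ref)), 2 * factor)
  }
})

test_that("center of mass matches an explicit loop oracle", {
  m <- image3d(array(0, c(6, 6, 6)), spacing = c(1, 2, 3), origin = c(1, 1, 1))
  m$voxels[3, 4, 2] <- 1
  expect_equal(as.numeric(center_of_mass(m)),
               as.numeric(world_from_index(m, c(2, 3, 1))))
  cube <- image3d(array(1, c(5, 5, 5)), spacing = c(2, 2, 2))
  expect_equal(as.numeric(center_of_mass(cube)), c(4, 4, 4))
  rnd <- random_blob_mask(seed = 11)
  idx <- which(rnd$voxels != 0)
  acc <- c(0, 0, 0)
  for (i in idx) {
    ai <- arrayInd(i, dim(rnd$voxels)) - 1L
    acc <- acc + as.numeric(world_from_index(rnd, ai, check = FALSE))
  }
  expect_equal(as.numeric(center_of_mass(rnd)), acc / length(idx),
               tolerance = 1e-12)
  empty <- image3d(array(0, c(3, 3, 3)))
  expect_error(center_of_mass(empty), "empty")
})

test_that("image3d enforces its geometric invariants", {
  expect_error(image3d(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)), "> 0")
  expect_error(image3d(array(1, c(2, 2, 2)),
                       direction = matrix(1, 3, 3)), "orthonormal")
  expect_error(image3d(matrix(1, 2, 2)), "3D")
})
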