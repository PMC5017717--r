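test_that("sample drawing respects the mask support and is reproducible", {
  m <- image3d(array(0, c(6, 6, 6)), spacing = c(2, 2, 2))
  m$voxels[3, 4, 2] <- 1
  s <- draw_samples(m, 10, seed = 1)
  ctr <- world_from_index(m, c(2, 3, 1))
  expect_true(all(abs(sweep(s$points, 2, as.numeric(ctr), "-")) <= 1 + 1e-12))
  expect_identical(draw_samples(m, 10, seed = 1)$points, s$points)
  expect_false(identical(draw_samples(m, 10, seed = 2)$points, s$points))
  expect_error(draw_samples(image3d(array(0, c(3, 3, 3))), 5, 1), "empty")
})

test_that("two-blob sampling fractions match blob volume fractions", {
  m <- image3d(array(0, c(30, 10, 10)), spacing = c(1, 1, 1))
  m$voxels[1:6, 1:5, 1:5] <- 1       # 150 voxels
  m$voxels[20:29, 1:5, 1:9] <- 1     # 450 voxels
  s <- draw_samples(m, 6000, seed = 3)
  frac <- mean(s$points[, 1] < 10)
  p <- 150 / 600
  se <- sqrt(p * (1 - p) / 6000)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("joint histogram concentrates on the diagonal for identical images", {
  img <- smooth_random_image(c(12, 12, 12), seed = 21)
  s <- draw_samples(full_mask(img), 5000, seed = 4)
  h <- joint_histogram(img, img, NULL, s, bins = 16)
  fb <- floor(h$fb); mb <- h$mb
  # all Parzen mass within the window width of the matched bin pair
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  mi_self <- mutual_information(h)
  # far above the independence value of zero
  expect_gt(mi_self, 0.5)
  # constant fixed image: single nonzero histogram row (box binning)
  cimg <- image3d(array(7, c(12, 12, 12)))
  h2 <- joint_histogram(cimg, img, NULL, draw_samples(full_mask(cimg), 1000, 5),
                        bins = 8, parzen = FALSE)
  expect_equal(sum(rowSums(h2$counts) > 0), 1)
})

test_that("box-binned joint histogram matches brute-force pair counting", {
  set.seed(6)
  fa <- image3d(array(runif(8^3, 0, 100), c(8, 8, 8)))
  mb_ <- image3d(array(runif(8^3, 0, 100), c(8, 8, 8)))
  # samples at exact voxel centers so interpolation returns voxel values
  idx <- arrayInd(seq_len(8^3), c(8, 8, 8)) - 1L
  s <- structure(list(points = world_from_index(fa, idx, check = FALSE),
                      seed = 0), class = "sample_set")
  bins <- 6
  h <- joint_histogram(fa, mb_, NULL, s, bins = bins, parzen = FALSE)
  fr <- h$fixed_range; mr <- h$moving_range
  ref <- matrix(0, bins, bins)
  for (i in seq_len(8^3)) {
    fi <- min(max(floor((fa$voxels[i] - fr[1]) / (fr[2] - fr[1]) * bins), 0),
              bins - 1)
    mi <- min(max(floor((mb_$voxels[i] - mr[1]) / (mr[2] - mr[1]) * bins), 0),
              bins - 1)
    ref[fi + 1, mi + 1] <- ref[fi + 1, mi + 1] + 1
  }
  expect_equal(h$counts, ref)
})

test_that("mutual information has its closed-form and oracle values", {
  # independence: outer product of marginals -> 0
  pf <- c(0.2, 0.3, 0.5); pm <- c(0.1, 0.4, 0.5)
  expect_equal(mutual_information(outer(pf, pm)), 0, tolerance = 1e-14)
  # two equiprobable, perfectly paired classes -> log 2
  expect_equal(mutual_information(diag(c(0.5, 0.5))), log(2),
               tolerance = 1e-14)
  # random normalized histogram vs brute-force double sum
  set.seed(7)
  for (k in 1:5) {
    p <- matrix(rexp(64), 8, 8); p <- p / sum(p)
    ref <- 0
    for (i in 1:8) for (j in 1:8)
      if (p[i, j] > 0)
        ref <- ref + p[i, j] * log(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
    expect_equal(mutual_information(p), ref, tolerance = 1e-12)
    expect_gte(mutual_information(p), -1e-12)
  }
  expect_error(mutual_information(matrix(1, 2, 2)), "normalized")
})

test_that("MI of an image with itself peaks at the identity alignment", {
  img <- smooth_random_image(c(20, 20, 20), spacing = c(2, 2, 2), seed = 8)
  m <- full_mask(img)
  s <- draw_samples(m, 8000, seed = 9)
  rng <- range(img$voxels)
  h0 <- joint_histogram(img, img, NULL, s, 16, rng, rng)
  mi0 <- mutual_information(h0)
  for (off in list(c(4, 0, 0), c(0, -4, 0), c(0, 0, 4))) {
    h1 <- joint_histogram(img, img, rigid_transform(translation = off),
                          s, 16, rng, rng)
    expect_gt(mi0, mutual_information(h1))
  }
})

test_that("the sampled MI optimum sits within a small fraction of a voxel of true alignment", {
  img <- smooth_random_image(c(24, 24, 24), spacing = c(2, 2, 2), seed = 10)
  # dense, off-lattice samples (cell centers): no sampling noise, no
  # one-sided trilinear derivatives
  idx <- arrayInd(seq_len(23^3), c(23, 23, 23)) - 1L + 0.5
  s <- structure(list(points = world_from_index(img, idx, check = FALSE),
                      seed = 0), class = "sample_set")
  g <- ffd_for_domain(img, 24)
  rng <- range(img$voxels)
  mi_at <- function(t3) mi_gradient(img, img, embed_affine(g, diag(3), t3),
                                    s, 16, fixed_range = rng,
                                    moving_range = rng)$mi
  mi0 <- mi_at(c(0, 0, 0))
  # identity beats any offset of a quarter voxel or more
  for (t in c(-5, -2, -1, -0.5, 0.5, 1, 2, 5))
    for (ax in 1:3) {
      off <- c(0, 0, 0); off[ax] <- t
      expect_gt(mi0, mi_at(off))
    }
  # sub-voxel estimator bias: quadratic vertex within 0.15 mm per axis
  h <- 0.25
  for (ax in 1:3) {
    ep <- em <- c(0, 0, 0); ep[ax] <- h; em[ax] <- -h
    up <- mi_at(ep); dn <- mi_at(em)
    vertex <- h / 2 * (up - dn) / (2 * mi0 - up - dn)
    expect_lt(abs(vertex), 0.15)
  }
})

test_that("control points without samples in support get exactly zero gradient", {
  img <- smooth_random_image(c(20, 20, 20), spacing = c(2, 2, 2), seed = 12)
  m <- image3d(array(0, dim(img$voxels)), img$spacing)
  m$voxels[1:5, 1:5, 1:5] <- 1   # samples confined to one corner
  s <- draw_samples(m, 500, seed = 13)
  f <- random_ffd(img, grid_mm = 8, sd = 0.5, seed = 14)
  res <- mi_gradient(img, img, f, s, 8)
  nodes <- liverreg:::ffd_nodes(f)
  far <- rowSums(abs(sweep(nodes, 2, c(4, 4, 4), "-")) <
                   matrix(16, nrow(nodes), 3)) < 3
  gflat <- matrix(res$gradient, prod(f$grid_shape), 3)
  # nodes more than 2 control spacings from the sampled corner: zero
  d <- sqrt(rowSums(sweep(nodes, 2, c(4, 4, 4), "-")^2))
  expect_true(all(gflat[d > 40, ] == 0))
  expect_gt(max(abs(gflat[d < 10, ])), 0)
})

test_that("gross misalignment (most samples outside) raises an error", {
  img <- smooth_random_image(c(10, 10, 10), seed = 15)
  s <- draw_samples(full_mask(img), 200, seed = 16)
  far <- rigid_transform(translation = c(500, 0, 0))
  expect_error(joint_histogram(img, img, far, s, 8), "misalignment")
})
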