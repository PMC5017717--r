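#' Draw stochastic samples inside a mask
#'
#' Samples n points uniformly from the continuous region covered by the
#' nonzero voxels of a mask: a nonzero voxel is drawn uniformly, then the
#' point is jittered uniformly within that voxel's extent.  Reproducible
#' for a given seed.
#'
#' @param mask binary \code{image3d}.
#' @param n number of samples (>= 1).
#' @param seed integer RNG seed.
#' @param candidates optional precomputed linear indices of nonzero
#'   voxels (performance path for repeated draws).
#' @return object of class \code{sample_set}: list with \code{points}
#'   (n x 3 world mm) and \code{seed}.
#' @export
draw_samples <- function(mask, n, seed, candidates = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(candidates)) candidates <- which(mask$voxels != 0)
  if (length(candidates) == 0) stop("mask is empty")
  pts <- with_seed(seed, {
    pick <- candidates[sample.int(length(candidates), n, replace = TRUE)]
    ai <- arrayInd(pick, dim(mask$voxels)) - 1L
    jit <- matrix(runif(3 * n, -0.5, 0.5), n, 3)
    world_from_index(mask, ai + jit, check = FALSE)
  })
  structure(list(points = pts, seed = seed), class = "sample_set")
}

# Map intensities to continuous histogram-bin coordinates.  Both axes
# use cubic B-spline Parzen windows on histograms padded by two bins on
# each side (bins + 4 columns/rows), so the 4-bin window support always
# stays inside and the window weights sum to one.  A smooth window on
# the fixed axis too (rather than a box) keeps the MI gradient free of
# the bin-center attraction artifact, so a perfect alignment really is
# a stationary point of the sampled metric.
degenerate_range <- function(rng) {
  (rng[2] - rng[1]) <= 1e-9 * max(abs(rng), 1)
}
parzen_bin_coord <- function(v, rng, bins) {
  if (degenerate_range(rng)) return(rep(2, length(v)))
  vc <- pmin(pmax(v, rng[1]), rng[2])
  pmin(2 + (vc - rng[1]) / (rng[2] - rng[1]) * bins, bins + 2 - 1e-9)
}
fixed_bin_coord <- parzen_bin_coord
moving_bin_coord <- parzen_bin_coord
# box binning used by the counting-oracle path
box_bin_coord <- function(v, rng, bins) {
  if (degenerate_range(rng)) return(rep(0, length(v)))
  pmin(pmax((v - rng[1]) / (rng[2] - rng[1]) * bins, 0), bins - 1e-9)
}
moving_bins <- function(bins) bins + 4L

#' Joint intensity histogram under a transform
#'
#' Accumulates the pairs (I_F(x), I_M(T(x))) over a sample set into a 2D
#' histogram.  By default the moving intensity is spread with a cubic
#' B-spline Parzen window (making the histogram differentiable in the
#' transform parameters) and the fixed intensity uses a box window; with
#' \code{parzen = FALSE} both axes use plain box binning (useful as a
#' counting oracle).  Samples whose transformed location falls outside
#' the moving image are dropped; if more than half are dropped the
#' registration is considered grossly misaligned and an error is raised.
#'
#' @param fixed,moving \code{image3d} volumes.
#' @param transform transform mapping fixed-domain world points into the
#'   moving domain (\code{NULL} = identity).
#' @param samples a \code{\link{draw_samples}} result.
#' @param bins number of bins for both images (>= 2).
#' @param fixed_range,moving_range intensity ranges defining the
#'   regularly spaced bins; default: the sampled/whole-image ranges.
#' @param parzen use the differentiable Parzen windowing (default TRUE).
#' @param min_kept minimum fraction of retained samples (default 0.5).
#' @return object of class \code{joint_histogram} with counts,
#'   probabilities, marginals and bin metadata.
#' @export
joint_histogram <- function(fixed, moving, transform, samples, bins = 32,
                            fixed_range = NULL, moving_range = NULL,
                            parzen = TRUE, min_kept = 0.5) {
  if (bins < 2) stop("bins must be >= 2")
  pts <- samples$points
  fv <- cpp_interp(fixed$voxels, index_from_world(fixed, pts), 1L, NA_real_)
  tp <- if (is.null(transform)) pts else
    transform_points(transform, pts, extrapolate = TRUE)
  ci <- index_from_world(moving, tp)
  mg <- cpp_interp_grad(moving$voxels, ci, 0)
  kept <- mg$inside & !is.na(fv)
  if (mean(kept) < min_kept)
    stop("more than ", round(100 * (1 - min_kept)),
         "% of samples map outside the moving image: gross misalignment")
  fv <- fv[kept]; mv <- mg$value[kept]
  if (is.null(fixed_range)) fixed_range <- range(fv)
  if (is.null(moving_range)) moving_range <- range(mv)
  if (parzen) {
    fb <- fixed_bin_coord(fv, fixed_range, bins)
    mb <- moving_bin_coord(mv, moving_range, bins)
    counts <- cpp_joint_hist(fb, mb, moving_bins(bins), moving_bins(bins))
  } else {
    fb <- box_bin_coord(fv, fixed_range, bins)
    mb <- box_bin_coord(mv, moving_range, bins)
    counts <- box_joint_hist(fb, mb, bins, bins)
  }
  p <- counts / sum(counts)
  structure(list(counts = counts, p = p,
                 p_fixed = rowSums(p), p_moving = colSums(p),
                 bins = bins, fixed_range = fixed_range,
                 moving_range = moving_range, parzen = parzen,
                 n_kept = sum(kept), n_total = length(kept),
                 fb = fb, mb = mb, kept = kept),
            class = "joint_histogram")
}

# Box-binned variant used as the counting oracle path.
box_joint_hist <- function(fb, mb, nbf, nbm) {
  fi <- pmin(pmax(floor(fb), 0), nbf - 1)
  mi <- pmin(pmax(floor(mb), 0), nbm - 1)
  h <- matrix(0, nbf, nbm)
  tab <- table(factor(fi, levels = 0:(nbf - 1)),
               factor(mi, levels = 0:(nbm - 1)))
  h[] <- as.numeric(tab)
  h
}

#' Mutual information of a joint histogram
#'
#' \code{MI = sum p(f,m) log( p(f,m) / (pF(f) pM(m)) )} in natural-log
#' units, with the convention 0 log 0 = 0.
#'
#' @param h a \code{\link{joint_histogram}} (or a plain normalized
#'   matrix of joint probabilities).
#' @return scalar MI >= 0 (up to rounding).
#' @export
mutual_information <- function(h) {
  p <- if (inherits(h, "joint_histogram")) h$p else as.matrix(h)
  if (abs(sum(p) - 1) > 1e-8)
    stop("joint histogram must be normalized to sum 1")
  pf <- rowSums(p); pm <- colSums(p)
  L <- mi_log_ratio(p, pf, pm)
  sum(p * L)
}

# log(p / (pF pM)) with empty bins zeroed.
mi_log_ratio <- function(p, pf, pm) {
  L <- matrix(0, nrow(p), ncol(p))
  nz <- p > 0
  denom <- outer(pf, pm)
  L[nz] <- log(p[nz] / denom[nz])
  L
}

# Core cost/gradient evaluation shared by mi_gradient and the optimizer.
# Returns -MI and d(-MI)/d mu for the FFD component of
# T(x) = init(x + u(x)); init may be any fixed transform (its spatial
# Jacobian enters the chain rule).
mi_cost_grad <- function(fixed, moving, ffd, init, samples, bins,
                         fixed_range, moving_range, min_kept = 0.5) {
  pts <- samples$points
  fv <- cpp_interp(fixed$voxels, index_from_world(fixed, pts), 1L, NA_real_)
  y <- transform_points(ffd, pts, extrapolate = TRUE)
  z <- if (is.null(init)) y else transform_points(init, y, extrapolate = TRUE)
  ci <- index_from_world(moving, z)
  mg <- cpp_interp_grad(moving$voxels, ci, 0)
  kept <- mg$inside & !is.na(fv)
  frac_dropped <- 1 - mean(kept)
  if (mean(kept) < min_kept)
    stop("more than ", round(100 * (1 - min_kept)),
         "% of samples map outside the moving image: gross misalignment")
  n <- sum(kept)
  fb <- fixed_bin_coord(fv[kept], fixed_range, bins)
  mv <- mg$value[kept]
  mb <- moving_bin_coord(mv, moving_range, bins)
  counts <- cpp_joint_hist(fb, mb, moving_bins(bins), moving_bins(bins))
  tot <- sum(counts)
  p <- counts / tot
  pf <- rowSums(p); pm <- colSums(p)
  L <- mi_log_ratio(p, pf, pm)
  mi <- sum(p * L)
  # d MI / d (moving bin coordinate), per kept sample
  dmb <- cpp_mi_sample_deriv(fb, mb, L) / tot
  # chain to intensity, then to world position, then to mu
  w <- moving_range[2] - moving_range[1]
  dbin_dint <- if (w > 0) bins / w else 0
  inr <- mv > moving_range[1] & mv < moving_range[2]
  dint <- dmb * dbin_dint * inr
  # moving world-space intensity gradient at z
  gidx <- mg$gradient[kept, , drop = FALSE]
  gw <- sweep(gidx, 2, moving$spacing, "/") %*% t(moving$direction)
  if (!is.null(init)) {
    Ji <- spatial_jacobian(init, y[kept, , drop = FALSE], extrapolate = TRUE)
    gj <- matrix(0, n, 3)
    for (e in 1:3) for (j in 1:3) gj[, e] <- gj[, e] + gw[, j] * Ji[, j, e]
    gw <- gj
  }
  S <- matrix(0, nrow(pts), 3)
  S[kept, ] <- -dint * gw  # minus: cost is -MI
  grad <- cpp_ffd_project(ffd$coefficients, ffd$grid_origin,
                          ffd$control_spacing, pts, S, NULL, NULL)
  list(cost = -mi, mi = mi, gradient = grad, dropped = frac_dropped,
       n_kept = n)
}

#' Gradient of negated mutual information over FFD parameters
#'
#' Analytic d(-MI)/d mu by the chain rule through the Parzen joint
#' histogram, the moving image's spatial intensity gradient and the
#' cubic B-spline basis support; control points whose support contains
#' no sample get exactly zero entries.
#'
#' @inheritParams joint_histogram
#' @param ffd the \code{bspline_ffd} being optimized.
#' @param init optional fixed transform applied after the FFD
#'   (\code{T(x) = init(x + u(x))}).
#' @return list with \code{mi}, \code{cost} (= -mi) and \code{gradient}
#'   (array shaped like the FFD coefficients).
#' @export
mi_gradient <- function(fixed, moving, ffd, samples, bins = 32, init = NULL,
                        fixed_range = NULL, moving_range = NULL,
                        min_kept = 0.5) {
  if (is.null(fixed_range) || is.null(moving_range)) {
    h <- joint_histogram(fixed, moving,
                         if (is.null(init)) ffd else composite_transform(init, ffd),
                         samples, bins, fixed_range, moving_range,
                         min_kept = min_kept)
    fixed_range <- h$fixed_range
    moving_range <- h$moving_range
  }
  mi_cost_grad(fixed, moving, ffd, init, samples, bins,
               fixed_range, moving_range, min_kept)
}
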