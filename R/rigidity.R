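#' Rigidity penalty weights
#'
#' Weights of the three local-rigidity conditions and the overall
#' per-resolution penalty weight.  Defaults follow the clinical
#' parameterization: affine (linearity) condition 100, orthonormality 1,
#' properness 2, and per-resolution overall weights
#' \code{c(0.1, 0.1, 0.1, 4)} (the penalty is weighted strongly only at
#' the finest grid).
#'
#' @param c_AC affine-condition (second-derivative) weight, >= 0.
#' @param c_OC orthonormality-condition weight, >= 0.
#' @param c_PC properness-condition weight, >= 0.
#' @param alpha per-resolution overall weight (length = n resolutions).
#' @export
rigidity_weights <- function(c_AC = 100, c_OC = 1, c_PC = 2,
                             alpha = c(0.1, 0.1, 0.1, 4)) {
  stopifnot(c_AC >= 0, c_OC >= 0, c_PC >= 0, all(alpha >= 0))
  structure(list(c_AC = c_AC, c_OC = c_OC, c_PC = c_PC, alpha = alpha),
            class = "rigidity_weights")
}

#' Build a coefficient mask from user seed points
#'
#' Each seed's voxel is dilated by a cube whose side is
#' \code{kernel_mm} converted to voxels and rounded up to the nearest
#' odd count per axis (default 1x1x1 cm); the union of the dilated
#' regions receives coefficient c = 1.  A positive \code{feather_mm}
#' smooths the transition from 1 to 0 at the region boundary (Gaussian
#' smoothing, rescaled and clamped so the seed regions keep c = 1),
#' improving the smoothness between locally-rigid and free areas.
#'
#' @param seeds n x 3 matrix of seed world coordinates mm (or length-3).
#' @param meta geometry of the image the mask lives on (the moving /
#'   diagnostic image).
#' @param kernel_mm dilation cube size in mm (length 1 or 3, default 10).
#' @param feather_mm Gaussian feather width in mm (default 5; 0 gives a
#'   binary mask).
#' @return object of class \code{coefficient_mask}: a scalar field
#'   c(x) in [0, 1] on the image geometry.
#' @export
build_coefficient_mask <- function(seeds, meta, kernel_mm = c(10, 10, 10),
                                   feather_mm = 5) {
  g <- geometry_of(meta)
  seeds <- as_point_matrix(seeds)
  if (nrow(seeds) < 1) stop("need at least one seed point")
  kernel_mm <- vec3(kernel_mm, "kernel_mm")
  idx <- round(index_from_world(g, seeds))
  if (any(idx < 0) || any(sweep(idx, 2, g$dim - 1, ">")))
    stop("seed point outside the image domain")
  side <- ceiling(kernel_mm / g$spacing)
  side <- side + (side %% 2 == 0)  # round up to odd voxel count
  half <- (side - 1) / 2
  field <- array(0, g$dim)
  for (s in seq_len(nrow(idx))) {
    lo <- pmax(idx[s, ] - half, 0)
    hi <- pmin(idx[s, ] + half, g$dim - 1)
    field[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1] <- 1
  }
  if (feather_mm > 0) {
    sig <- feather_mm / g$spacing
    sm <- cpp_gauss_smooth(field, sig)
    field <- pmin(pmax(2 * sm, 0), 1)
    field <- array(field, g$dim)
  }
  structure(list(field = image3d(field, g$spacing, g$origin, g$direction),
                 seeds = seeds, kernel_mm = kernel_mm,
                 feather_mm = feather_mm),
            class = "coefficient_mask")
}

# Interpolate c(x) at world points; outside the field -> 0.
coefficient_at <- function(cmask, points) {
  ci <- index_from_world(cmask$field, as_point_matrix(points))
  v <- cpp_interp(cmask$field$voxels, ci, 1L, 0)
  pmin(pmax(v, 0), 1)
}

# Vectorized J (with identity), H, and derived quantities at points.
ffd_local_geometry <- function(ffd, points) {
  p <- as_point_matrix(points)
  J <- spatial_jacobian(ffd, p, extrapolate = TRUE)
  H <- transform_hessian(ffd, p, extrapolate = TRUE)
  n <- nrow(p)
  JtJ <- array(0, c(n, 3, 3))
  for (a in 1:3) for (b in 1:3) for (k in 1:3)
    JtJ[, a, b] <- JtJ[, a, b] + J[, k, a] * J[, k, b]
  OC <- JtJ
  for (a in 1:3) OC[, a, a] <- OC[, a, a] - 1
  detJ <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  list(points = p, J = J, H = H, OC = OC, PC = detJ - 1, n = n)
}

#' Local rigidity terms at a point
#'
#' The three conditions that jointly vanish iff the transform is locally
#' rigid: the affine condition AC (the second-derivative tensor), the
#' orthonormality condition \code{OC = J'J - I} and the properness
#' condition \code{PC = det(J) - 1}, where J is the spatial Jacobian of
#' the FFD transform.
#'
#' @param ffd a \code{bspline_ffd}.
#' @param point world point mm (single point).
#' @return list with \code{AC} (3x3x3), \code{OC} (3x3), \code{PC}
#'   (scalar).
#' @export
rigidity_terms <- function(ffd, point) {
  lg <- ffd_local_geometry(ffd, point)
  list(AC = array(lg$H[1, , , ], c(3, 3, 3)),
       OC = matrix(lg$OC[1, , ], 3, 3),
       PC = lg$PC[1])
}

#' Local rigidity penalty
#'
#' Coefficient-weighted mean, over the evaluation points, of
#' \code{c_AC * sum(AC^2) + c_OC * sum(OC^2) + c_PC * PC^2}, with the
#' coefficient c evaluated at each point's transformed location (the
#' mask lives on the moving image).  Zero for any locally rigid motion.
#'
#' @param ffd \code{bspline_ffd} whose non-rigid deformation is
#'   penalized.
#' @param cmask a \code{\link{build_coefficient_mask}} result, or
#'   \code{NULL} for a uniform c = 1.
#' @param weights a \code{\link{rigidity_weights}}.
#' @param eval_points n x 3 matrix of evaluation points (world mm),
#'   typically the control-point locations inside the image domain.
#' @param c_transform transform used to carry eval points into the
#'   coefficient-mask space (default: the FFD itself).
#' @return scalar penalty >= 0.
#' @export
rigidity_penalty <- function(ffd, cmask, weights, eval_points,
                             c_transform = NULL) {
  lg <- ffd_local_geometry(ffd, eval_points)
  cv <- penalty_coefficients(cmask, lg$points, ffd, c_transform)
  if (sum(cv) <= 0) stop_degenerate_mask()
  ac2 <- apply(lg$H^2, 1, sum)
  oc2 <- apply(lg$OC^2, 1, sum)
  pc2 <- lg$PC^2
  sum(cv * (weights$c_AC * ac2 + weights$c_OC * oc2 + weights$c_PC * pc2)) /
    sum(cv)
}

penalty_coefficients <- function(cmask, points, ffd, c_transform) {
  if (is.null(cmask)) return(rep(1, nrow(points)))
  tr <- if (is.null(c_transform)) ffd else c_transform
  coefficient_at(cmask, transform_points(tr, points, extrapolate = TRUE))
}

#' Gradient of the rigidity penalty over FFD parameters
#'
#' Analytic d P / d mu with the coefficient field treated as locally
#' constant with respect to mu (frozen-weight approximation).
#'
#' @inheritParams rigidity_penalty
#' @return list with \code{penalty} and \code{gradient} (array shaped
#'   like the FFD coefficients).
#' @export
rigidity_gradient <- function(ffd, cmask, weights, eval_points,
                              c_transform = NULL) {
  lg <- ffd_local_geometry(ffd, eval_points)
  cv <- penalty_coefficients(cmask, lg$points, ffd, c_transform)
  csum <- sum(cv)
  if (csum <= 0) stop_degenerate_mask()
  n <- lg$n
  J <- lg$J; OC <- lg$OC; PC <- lg$PC; H <- lg$H
  ac2 <- apply(H^2, 1, sum)
  oc2 <- apply(OC^2, 1, sum)
  penalty <- sum(cv * (weights$c_AC * ac2 + weights$c_OC * oc2 +
                         weights$c_PC * PC^2)) / csum
  # d(sum OC^2)/dJ = 4 J OC ; d(PC^2)/dJ = 2 PC cof(J)
  JOC <- array(0, c(n, 3, 3))
  for (k in 1:3) for (d in 1:3) for (m in 1:3)
    JOC[, k, d] <- JOC[, k, d] + J[, k, m] * OC[, m, d]
  cof <- array(0, c(n, 3, 3))
  for (k in 1:3) for (d in 1:3) {
    i2 <- setdiff(1:3, k); j2 <- setdiff(1:3, d)
    minor <- J[, i2[1], j2[1]] * J[, i2[2], j2[2]] -
      J[, i2[1], j2[2]] * J[, i2[2], j2[1]]
    cof[, k, d] <- (-1)^(k + d) * minor
  }
  A <- matrix(0, n, 9)
  for (e in 1:3) for (d in 1:3)
    A[, e + 3 * (d - 1)] <- (cv / csum) *
      (weights$c_OC * 4 * JOC[, e, d] + weights$c_PC * 2 * PC * cof[, e, d])
  B <- matrix(0, n, 27)
  for (e in 1:3) for (i in 1:3) for (j in 1:3)
    B[, e + 3 * (i - 1) + 9 * (j - 1)] <- (cv / csum) *
      weights$c_AC * 2 * H[, e, i, j]
  grad <- cpp_ffd_project(ffd$coefficients, ffd$grid_origin,
                          ffd$control_spacing, lg$points, NULL, A, B)
  list(penalty = penalty, gradient = grad)
}

stop_degenerate_mask <- function() {
  stop(errorCondition(
    "all coefficient weights are zero at the transformed evaluation points: degenerate mask",
    class = "liverreg_degenerate_mask"))
}
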