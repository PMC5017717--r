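#' Dice similarity coefficient
#'
#' Voxel-counting overlap \code{2 |X & Y| / (|X| + |Y|)} of two binary
#' masks on the same geometry.
#'
#' @param X,Y binary \code{image3d} masks with identical geometry.
#' @return overlap fraction in [0, 1].
#' @export
dice <- function(X, Y) {
  if (!same_geometry(X, Y)) stop("masks must share the same geometry")
  x <- X$voxels != 0; y <- Y$voxels != 0
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0) stop("both masks are empty")
  2 * sum(x & y) / (nx + ny)
}

# One-voxel binary erosion (6- or 26-connected structuring element).
erode_mask <- function(vox, connectivity = 6) {
  d <- dim(vox)
  m <- vox != 0
  shift <- function(arr, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  offs <- if (connectivity == 6)
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  else {
    g <- expand.grid(-1:1, -1:1, -1:1)
    g <- g[rowSums(abs(g)) > 0, ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  er <- m
  for (o in offs) {
    ax <- which(o != 0)
    sh <- m
    for (a in ax) sh <- shift(sh, a, -o[a])
    er <- er & sh
  }
  er
}

#' Surface voxels of a binary mask
#'
#' The mask minus its one-voxel erosion (6-connected structuring element
#' by default), per the surface definition used by the mean surface
#' distance.
#'
#' @param mask binary \code{image3d}.
#' @param connectivity 6 (default) or 26.
#' @return binary \code{image3d} marking surface voxels.
#' @export
extract_surface <- function(mask, connectivity = 6) {
  if (sum(mask$voxels != 0) == 0) stop("mask is empty")
  surf <- (mask$voxels != 0) & !erode_mask(mask$voxels, connectivity)
  image3d(array(surf * 1, dim(mask$voxels)), mask$spacing, mask$origin,
          mask$direction)
}

surface_world <- function(mask, connectivity = 6) {
  s <- extract_surface(mask, connectivity)
  idx <- which(s$voxels != 0)
  world_from_index(s, arrayInd(idx, dim(s$voxels)) - 1L, check = FALSE)
}

#' Symmetric mean surface distance
#'
#' Mean of the closest Euclidean distances (world mm, voxel centers)
#' from every surface voxel of X to the surface of Y and vice versa,
#' normalized by the total surface voxel count (n_X + n_Y).
#'
#' @inheritParams dice
#' @param connectivity structuring element for the surface erosion.
#' @return distance in mm.
#' @export
mean_surface_distance <- function(X, Y, connectivity = 6) {
  if (!same_geometry(X, Y)) stop("masks must share the same geometry")
  sx <- surface_world(X, connectivity)
  sy <- surface_world(Y, connectivity)
  dx <- cpp_min_dist(sx, sy)
  dy <- cpp_min_dist(sy, sx)
  (sum(dx) + sum(dy)) / (nrow(sx) + nrow(sy))
}

#' Mean corresponding landmark distance
#'
#' \code{(1/n) sum |a_i - T(b_i)|} between landmarks a in the moving
#' (diagnostic) image and transformed landmarks b from the fixed
#' (intra-operative) image; a target registration error.
#'
#' @param A_points landmarks in the image T maps into (n x 3 mm).
#' @param B_points corresponding landmarks in T's source domain.
#' @param transform transform mapping B-domain points toward A's space
#'   (\code{NULL} = identity).
#' @return mean distance mm (per-landmark distances as attribute
#'   \code{"per_landmark"}).
#' @export
mean_corresponding_distance <- function(A_points, B_points, transform = NULL) {
  a <- as_point_matrix(A_points)
  b <- as_point_matrix(B_points)
  if (nrow(a) != nrow(b)) stop("landmark counts differ")
  if (nrow(a) < 1) stop("need at least one landmark pair")
  tb <- if (is.null(transform)) b else
    transform_points(transform, b, extrapolate = TRUE)
  d <- sqrt(rowSums((a - tb)^2))
  structure(mean(d), per_landmark = d)
}

#' Assemble an evaluation report for one registered case
#'
#' Computes Dice overlap and mean surface distance between a mapped
#' segmentation and a reference segmentation, the mean corresponding
#' landmark distance when landmark pairs are supplied, and the success
#' classification.
#'
#' @param mapped binary mask mapped into the reference geometry.
#' @param reference reference binary mask.
#' @param landmarks_ref landmarks in the transform's target (moving)
#'   image, or NULL.
#' @param landmarks_fixed corresponding landmarks in the fixed image.
#' @param transform transform used for the landmark distances.
#' @param connectivity surface connectivity for the MSD.
#' @return object of class \code{evaluation_report}.
#' @export
evaluation_report <- function(mapped, reference, landmarks_ref = NULL,
                              landmarks_fixed = NULL, transform = NULL,
                              connectivity = 6) {
  dsc <- dice(mapped, reference)
  msd <- mean_surface_distance(mapped, reference, connectivity)
  mcd <- NULL; per <- numeric(0)
  if (!is.null(landmarks_ref) && !is.null(landmarks_fixed)) {
    m <- mean_corresponding_distance(landmarks_ref, landmarks_fixed, transform)
    mcd <- as.numeric(m)
    per <- attr(m, "per_landmark")
  }
  rep <- structure(list(dsc = dsc, msd = msd, mcd = mcd,
                        n_landmarks = length(per), per_landmark = per),
                   class = "evaluation_report")
  rep$success <- classify_success(rep)$success
  rep
}

#' Classify a registration as successful or needing refinement
#'
#' Success requires DSC > 0.80 and, when a landmark distance is
#' available, MCD < 10 mm (both strict).
#'
#' @param report an \code{evaluation_report} or a list with \code{dsc}
#'   and optionally \code{mcd}.
#' @return list with logicals \code{success} and \code{needs_refinement}.
#' @export
classify_success <- function(report) {
  if (is.null(report$dsc)) stop("report must contain a DSC value")
  ok <- report$dsc > 0.80 && (is.null(report$mcd) || report$mcd < 10)
  list(success = ok, needs_refinement = !ok)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> DSC %.1f%%, MSD %.2f mm", 100 * x$dsc, x$msd))
  if (!is.null(x$mcd))
    cat(sprintf(", MCD %.2f mm (%d landmarks)", x$mcd, x$n_landmarks))
  cat(sprintf("\n  %s\n", if (isTRUE(x$success)) "success"
              else "needs refinement"))
  invisible(x)
}

#' Non-rigid deviation of a transform over a region
#'
#' Root-mean-square residual of the transform's action on a point set
#' after removing the best-fit rigid motion (Kabsch algorithm); zero iff
#' the points move rigidly.  Used to quantify how strongly a deformable
#' registration distorts a region that should move rigidly.
#'
#' @param transform a spatial transform.
#' @param points n x 3 matrix of world points (n >= 3).
#' @return RMS residual in mm.
#' @export
nonrigid_residual <- function(transform, points) {
  x <- as_point_matrix(points)
  if (nrow(x) < 3) stop("need at least 3 points")
  y <- transform_points(transform, x, extrapolate = TRUE)
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(xc, yc))
  dsign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  res <- yc - xc %*% t(R)
  sqrt(mean(rowSums(res^2)))
}
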