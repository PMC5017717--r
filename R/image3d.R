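#' Geometry-aware 3D image
#'
#' A 3D scalar volume (Hounsfield-like units for CT) together with its
#' spatial calibration: voxel spacing in mm, the world coordinate of the
#' center of voxel index \code{(0,0,0)}, and a 3x3 direction matrix whose
#' columns are the unit world-space directions of the array axes.  Voxel
#' indices are 0-based and refer to voxel centers; every transform and
#' metric in this package operates in world millimetres.
#'
#' @param voxels 3D numeric array.
#' @param spacing voxel spacing in mm (length 1 or 3, all > 0).
#' @param origin world coordinate (mm) of the center of voxel (0,0,0).
#' @param direction 3x3 orthonormal direction matrix (columns are axis
#'   directions); identity by default.
#' @return An object of class \code{image3d}.
#' @export
image3d <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    direction = diag(3)) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1)) stop("all image dimensions must be >= 1")
  spacing <- vec3(spacing, "spacing")
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  origin <- vec3(origin, "origin")
  direction <- matrix(as.numeric(direction), 3, 3)
  if (!is_orthonormal(direction))
    stop("direction matrix must be orthonormal (tolerance 1e-6)")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image3d")
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image3d> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, intensity range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image3d <- function(x) dim(x$voxels)

# Geometry bundle (no voxels); accepted anywhere a "target geometry" is.
geometry_of <- function(x) {
  if (inherits(x, "image3d"))
    list(dim = dim(x$voxels), spacing = x$spacing, origin = x$origin,
         direction = x$direction)
  else if (is.list(x) && all(c("dim", "spacing", "origin") %in% names(x))) {
    if (is.null(x$direction)) x$direction <- diag(3)
    x[c("dim", "spacing", "origin", "direction")]
  } else stop("expected an image3d or a geometry list (dim, spacing, origin)")
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- geometry_of(a); gb <- geometry_of(b)
  all(ga$dim == gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) < tol &&
    max(abs(ga$origin - gb$origin)) < tol &&
    max(abs(ga$direction - gb$direction)) < tol
}

#' World coordinates of voxel indices
#'
#' Maps 0-based voxel indices (voxel centers) to world mm:
#' \code{origin + direction \%*\% (spacing * index)}.
#'
#' @param meta an \code{image3d} or geometry list.
#' @param index integer 0-based voxel index (length-3 vector or n x 3 matrix).
#' @param check check array bounds (default TRUE).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
world_from_index <- function(meta, index, check = TRUE) {
  g <- geometry_of(meta)
  idx <- as_point_matrix(index)
  if (check) {
    ok <- idx >= 0 & sweep(idx, 2, g$dim - 1, "<=")
    if (!all(ok)) stop("voxel index out of bounds")
  }
  sc <- sweep(idx, 2, g$spacing, "*")
  sweep(sc %*% t(g$direction), 2, g$origin, "+")
}

#' Continuous voxel indices of world coordinates
#'
#' Inverse of \code{\link{world_from_index}}; returns fractional 0-based
#' indices (not rounded, not bounds-checked).
#'
#' @inheritParams world_from_index
#' @param world world coordinates in mm (length-3 vector or n x 3 matrix).
#' @export
index_from_world <- function(meta, world) {
  g <- geometry_of(meta)
  w <- as_point_matrix(world)
  rel <- sweep(w, 2, g$origin, "-") %*% g$direction  # = t(D) %*% (w - o) rowwise
  sweep(rel, 2, g$spacing, "/")
}

# World coordinates of every voxel of a geometry, as an n x 3 matrix in
# array (column-major) order.
all_voxel_world <- function(meta) {
  g <- geometry_of(meta)
  d <- g$dim
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  world_from_index(g, cbind(i, j, k), check = FALSE)
}

#' Resample an image through a spatial transform
#'
#' Produces an image on the \code{target} geometry with
#' \code{output(x) = image(T(x))}: for each target voxel center x (world
#' mm) the transform gives the corresponding location in the source
#' image, which is interpolated there.  Locations outside the source
#' domain receive \code{default_value}.
#'
#' @param image source \code{image3d}.
#' @param transform a spatial transform mapping target-domain world
#'   coordinates into the source domain; \code{NULL} means identity.
#' @param target target geometry (an \code{image3d} or geometry list);
#'   defaults to the source geometry.
#' @param interpolation one of \code{"nearest"}, \code{"linear"},
#'   \code{"cubic"}.
#' @param default_value intensity for out-of-domain points (default
#'   -1000, air in Hounsfield units).
#' @return \code{image3d} on the target geometry.
#' @export
resample <- function(image, transform = NULL, target = image,
                     interpolation = c("linear", "nearest", "cubic"),
                     default_value = -1000) {
  interpolation <- match.arg(interpolation)
  mcode <- c(nearest = 0L, linear = 1L, cubic = 3L)[[interpolation]]
  g <- geometry_of(target)
  pts <- all_voxel_world(g)
  if (!is.null(transform)) pts <- transform_points(transform, pts, extrapolate = TRUE)
  ci <- index_from_world(image, pts)
  vals <- cpp_interp(image$voxels, ci, mcode, default_value)
  image3d(array(vals, g$dim), spacing = g$spacing, origin = g$origin,
          direction = g$direction)
}

#' Multiresolution Gaussian pyramid
#'
#' Level k is the image smoothed with a Gaussian of sigma
#' \code{factor/2} voxels (per axis) and decimated by the level's integer
#' factor; spacing and origin are updated so world coordinates are
#' preserved.  The last factor must be 1 (full resolution).
#'
#' @param image an \code{image3d}.
#' @param factors integer downsampling factors, monotone non-increasing.
#'   A single-axis factor can be limited per axis by supplying a list of
#'   3-vectors instead of scalars.
#' @return list of \code{image3d}, one per level (coarse to fine).
#' @export
gaussian_pyramid <- function(image, factors = c(8, 4, 2, 1)) {
  if (length(factors) < 1) stop("need at least one pyramid level")
  flist <- lapply(factors, vec3, what = "downsample factor")
  if (any(unlist(flist) < 1)) stop("downsample factors must be >= 1")
  for (i in seq_along(flist)[-1])
    if (any(flist[[i]] > flist[[i - 1]]))
      stop("downsample factors must be monotone non-increasing")
  lapply(flist, function(f) {
    sig <- ifelse(f > 1, f / 2, 0)
    sm <- cpp_gauss_smooth(image$voxels, sig)
    d <- dim(image$voxels)
    ii <- lapply(1:3, function(a) seq(1, d[a], by = f[a]))
    vox <- sm[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
    image3d(array(vox, vapply(ii, length, 1L)),
            spacing = image$spacing * f, origin = image$origin,
            direction = image$direction)
  })
}

#' Center of mass of a binary mask
#'
#' Unweighted mean of the world coordinates of nonzero voxels.
#'
#' @param mask an \code{image3d} with voxels in \{0, 1\}.
#' @return world point (length-3, mm).
#' @export
center_of_mass <- function(mask) {
  idx <- which(mask$voxels != 0)
  if (length(idx) == 0) stop("mask is empty")
  ai <- arrayInd(idx, dim(mask$voxels)) - 1L
  colMeans(world_from_index(mask, ai, check = FALSE))
}

# Downsample a mask to a pyramid level's geometry (nearest neighbor).
mask_to_geometry <- function(mask, target) {
  out <- resample(mask, NULL, target, interpolation = "nearest",
                  default_value = 0)
  out$voxels <- (out$voxels > 0.5) * 1
  out
}
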