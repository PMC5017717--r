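#' Rigid 3D transform
#'
#' Maps world points as \code{T(x) = center + R (x - center) + t}.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation in mm.
#' @param center rotation center in mm.
#' @return object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (!is_orthonormal(rotation) || abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = vec3(translation),
                 center = vec3(center)),
            class = c("rigid_transform", "spatial_transform"))
}

#' Rotation matrix about the z axis
#' @param degrees rotation angle in degrees.
#' @export
rotation_z <- function(degrees) {
  a <- degrees * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Euler z-y-x composition, angles in radians.
euler_rotation <- function(rx, ry, rz) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Invert a rigid transform
#' @param t a \code{rigid_transform}.
#' @export
invert_rigid <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  # y = c + R(x - c) + tr  =>  x = c + R'(y - c - tr)
  rigid_transform(rotation = Rt,
                  translation = -Rt %*% t$translation,
                  center = t$center)
}

#' Cubic B-spline free-form deformation
#'
#' A displacement field \code{u(x)} parameterized by 3-vector
#' displacements of a regular control-point grid, interpolated with
#' tensor-product cubic B-splines; the transform is
#' \code{T(x) = x + u(x)}.  A point is fully supported when its 4x4x4
#' control-point neighborhood lies inside the grid.
#'
#' @param control_spacing control-point spacing mm (length 1 or 3, > 0).
#' @param grid_origin world coordinate of control point (0,0,0).
#' @param grid_shape integer number of control points per axis (>= 4).
#' @param coefficients numeric array (nx, ny, nz, 3) of control-point
#'   displacements in mm; zeros (identity transform) by default.
#' @return object of class \code{bspline_ffd}.
#' @export
bspline_ffd <- function(control_spacing, grid_origin, grid_shape,
                        coefficients = NULL) {
  control_spacing <- vec3(control_spacing, "control_spacing")
  if (any(control_spacing <= 0)) stop("control_spacing must be > 0")
  grid_origin <- vec3(grid_origin, "grid_origin")
  grid_shape <- as.integer(vec3(grid_shape, "grid_shape"))
  if (any(grid_shape < 4)) stop("grid_shape must be >= 4 per axis")
  if (is.null(coefficients))
    coefficients <- array(0, c(grid_shape, 3))
  if (!all(dim(coefficients) == c(grid_shape, 3)))
    stop("coefficients must have dim (nx, ny, nz, 3)")
  storage.mode(coefficients) <- "double"
  structure(list(control_spacing = control_spacing, grid_origin = grid_origin,
                 grid_shape = grid_shape, coefficients = coefficients),
            class = c("bspline_ffd", "spatial_transform"))
}

#' B-spline grid covering an image domain
#'
#' Places a control grid at the requested spacing so that control points
#' extend at least \code{margin} spacings beyond the image bounding box
#' on every side, guaranteeing full cubic support everywhere inside the
#' image.
#'
#' @param meta image or geometry whose domain must be covered.
#' @param spacing_mm control spacing in mm (length 1 or 3).
#' @param margin number of extra control spacings beyond the box
#'   (default 2).
#' @return identity \code{bspline_ffd} on that grid.
#' @export
ffd_for_domain <- function(meta, spacing_mm, margin = 2) {
  g <- geometry_of(meta)
  sp <- vec3(spacing_mm, "spacing_mm")
  corners <- as.matrix(expand.grid(c(0, g$dim[1] - 1), c(0, g$dim[2] - 1),
                                   c(0, g$dim[3] - 1)))
  w <- world_from_index(g, corners, check = FALSE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  origin <- lo - margin * sp
  n <- ceiling((hi + margin * sp - origin) / sp) + 1
  bspline_ffd(sp, origin, pmax(n, 4))
}

# World coordinates of all control points, in array order.
ffd_nodes <- function(ffd) {
  s <- ffd$grid_shape
  i <- rep.int(seq_len(s[1]) - 1L, s[2] * s[3])
  j <- rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3])
  k <- rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  sweep(sweep(cbind(i, j, k), 2, ffd$control_spacing, "*"), 2,
        ffd$grid_origin, "+")
}

# Interior bounds (world mm) of the fully-supported FFD domain.
ffd_support_box <- function(ffd) {
  lo <- ffd$grid_origin + 1 * ffd$control_spacing
  hi <- ffd$grid_origin + (ffd$grid_shape - 2) * ffd$control_spacing
  list(lo = lo, hi = hi)
}

#' Composite spatial transform
#'
#' Ordered composition; like function composition, the \emph{last}
#' component is applied first:
#' \code{composite_transform(A, B)} maps \code{x} to \code{A(B(x))}.
#'
#' @param ... component transforms, outermost first.
#' @export
composite_transform <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "spatial_transform"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, TRUE, "spatial_transform")))
  structure(list(transforms = parts),
            class = c("composite_transform", "spatial_transform"))
}

#' Apply a spatial transform to world points
#'
#' @param transform a \code{rigid_transform}, \code{bspline_ffd} or
#'   \code{composite_transform}.
#' @param points length-3 vector or n x 3 matrix of world mm.
#' @param extrapolate for FFDs, treat points outside the fully-supported
#'   interior as having zero displacement instead of raising an error.
#' @return n x 3 matrix of transformed points (mm).
#' @export
transform_points <- function(transform, points, extrapolate = FALSE) {
  UseMethod("transform_points")
}

#' @export
transform_points.rigid_transform <- function(transform, points,
                                             extrapolate = FALSE) {
  p <- as_point_matrix(points)
  rel <- sweep(p, 2, transform$center, "-")
  sweep(rel %*% t(transform$rotation), 2,
        transform$center + transform$translation, "+")
}

#' @export
transform_points.bspline_ffd <- function(transform, points,
                                         extrapolate = FALSE) {
  p <- as_point_matrix(points)
  disp <- cpp_ffd_eval(transform$coefficients, transform$grid_origin,
                       transform$control_spacing, p, extrapolate)
  p + disp
}

#' @export
transform_points.composite_transform <- function(transform, points,
                                                 extrapolate = FALSE) {
  p <- as_point_matrix(points)
  for (t in rev(transform$transforms))
    p <- transform_points(t, p, extrapolate = extrapolate)
  p
}

#' Spatial Jacobian of a transform
#'
#' The 3x3 matrix \code{J[i, j] = dT_i / dx_j}, evaluated analytically
#' (rigid: the rotation matrix; FFD: identity plus the B-spline
#' displacement Jacobian; composite: chain rule).
#'
#' @inheritParams transform_points
#' @return array (n, 3, 3).
#' @export
spatial_jacobian <- function(transform, points, extrapolate = FALSE) {
  UseMethod("spatial_jacobian")
}

#' @export
spatial_jacobian.rigid_transform <- function(transform, points,
                                             extrapolate = FALSE) {
  p <- as_point_matrix(points)
  n <- nrow(p)
  out <- array(0, c(n, 3, 3))
  for (i in 1:3) for (j in 1:3) out[, i, j] <- transform$rotation[i, j]
  out
}

#' @export
spatial_jacobian.bspline_ffd <- function(transform, points,
                                         extrapolate = FALSE) {
  p <- as_point_matrix(points)
  jac <- cpp_ffd_jacobian(transform$coefficients, transform$grid_origin,
                          transform$control_spacing, p, extrapolate)
  out <- array(jac, c(nrow(p), 3, 3))  # [n, component, deriv axis]
  for (i in 1:3) out[, i, i] <- out[, i, i] + 1
  out
}

#' @export
spatial_jacobian.composite_transform <- function(transform, points,
                                                 extrapolate = FALSE) {
  p <- as_point_matrix(points)
  n <- nrow(p)
  total <- array(0, c(n, 3, 3))
  for (i in 1:3) total[, i, i] <- 1
  cur <- p
  for (t in rev(transform$transforms)) {
    Jt <- spatial_jacobian(t, cur, extrapolate = extrapolate)
    nxt <- array(0, c(n, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3)
      nxt[, i, j] <- nxt[, i, j] + Jt[, i, k] * total[, k, j]
    total <- nxt
    cur <- transform_points(t, cur, extrapolate = extrapolate)
  }
  total
}

#' Second spatial derivatives of a B-spline FFD transform
#'
#' The tensor \code{H[k, i, j] = d2 T_k / dx_i dx_j} (equal to the
#' displacement field's second derivatives since x is linear), symmetric
#' in (i, j).
#'
#' @inheritParams transform_points
#' @param ffd a \code{bspline_ffd}.
#' @return array (n, 3, 3, 3) indexed [point, component, i, j].
#' @export
transform_hessian <- function(ffd, points, extrapolate = FALSE) {
  stopifnot(inherits(ffd, "bspline_ffd"))
  p <- as_point_matrix(points)
  h <- cpp_ffd_hessian(ffd$coefficients, ffd$grid_origin,
                       ffd$control_spacing, p, extrapolate)
  array(h, c(nrow(p), 3, 3, 3))
}

#' Embed an affine map in a B-spline FFD
#'
#' Sets control-point displacements to \code{(A - I) x_cp + t}; by the
#' linear precision of cubic B-splines the resulting FFD reproduces the
#' affine map exactly on its fully-supported interior.
#'
#' @param grid an existing \code{bspline_ffd} supplying the grid (its
#'   coefficients are ignored).
#' @param A 3x3 matrix.
#' @param t length-3 translation mm.
#' @param center optional center c: the map is then
#'   \code{c + A (x - c) + t}.
#' @export
embed_affine <- function(grid, A, t = c(0, 0, 0), center = c(0, 0, 0)) {
  stopifnot(inherits(grid, "bspline_ffd"))
  A <- matrix(as.numeric(A), 3, 3)
  t <- vec3(t); center <- vec3(center)
  nodes <- ffd_nodes(grid)
  rel <- sweep(nodes, 2, center, "-")
  mapped <- sweep(rel %*% t(A), 2, center + t, "+")
  disp <- mapped - nodes
  bspline_ffd(grid$control_spacing, grid$grid_origin, grid$grid_shape,
              array(disp, c(grid$grid_shape, 3)))
}

#' Refine an FFD to a finer control grid
#'
#' Returns an FFD on the finer grid whose displacement field equals the
#' input's on the interior.  When the new spacing is exactly half the old
#' (the dyadic multiresolution schedule), exact B-spline subdivision is
#' used; otherwise the field is re-fit by cubic-spline interpolation at
#' the new control nodes.
#'
#' @param ffd a \code{bspline_ffd}.
#' @param new_spacing target control spacing mm, componentwise <= current.
#' @export
refine_grid <- function(ffd, new_spacing) {
  new_spacing <- vec3(new_spacing, "new_spacing")
  if (any(new_spacing > ffd$control_spacing + 1e-9))
    stop("new_spacing must be <= current control spacing componentwise")
  if (max(abs(new_spacing - ffd$control_spacing / 2)) < 1e-9)
    return(subdivide_ffd(ffd))
  if (max(abs(new_spacing - ffd$control_spacing)) < 1e-9)
    return(ffd)
  fit_ffd_to_field(ffd, new_spacing)
}

# Exact dyadic subdivision of a uniform cubic B-spline (two-scale masks
# [1 6 1]/8 at even nodes, [4 4]/8 at odd); grid extent preserved.
subdivide_ffd <- function(ffd) {
  subdiv1 <- function(c3, axis) {
    # c3: array (n1, n2, n3, 3); subdivide along `axis`
    perm <- c(axis, setdiff(1:3, axis), 4)
    a <- aperm(c3, perm)
    d <- dim(a)
    n <- d[1]
    m <- 2L * (n - 1L) + 1L
    flat <- matrix(a, n, prod(d[-1]))
    pad <- rbind(2 * flat[1, ] - flat[2, ], flat, 2 * flat[n, ] - flat[n - 1, ])
    out <- matrix(0, m, ncol(flat))
    ev <- seq_len(n)            # rows of pad: i-1 -> ev, i -> ev+1, i+1 -> ev+2
    out[seq(1, m, by = 2), ] <- (pad[ev, ] + 6 * pad[ev + 1, ] + pad[ev + 2, ]) / 8
    odd <- seq_len(n - 1)
    out[seq(2, m, by = 2), ] <- (pad[odd + 1, ] + pad[odd + 2, ]) / 2
    b <- array(out, c(m, d[-1]))
    aperm(b, order(perm))
  }
  co <- ffd$coefficients
  for (ax in 1:3) co <- subdiv1(co, ax)
  bspline_ffd(ffd$control_spacing / 2, ffd$grid_origin,
              2L * (ffd$grid_shape - 1L) + 1L, co)
}

# General re-fit: cubic-spline interpolation of the old displacement
# field at the new control nodes (tridiagonal prefilter per axis).
fit_ffd_to_field <- function(ffd, new_spacing) {
  box <- list(lo = ffd$grid_origin,
              hi = ffd$grid_origin + (ffd$grid_shape - 1) * ffd$control_spacing)
  n <- pmax(ceiling((box$hi - box$lo) / new_spacing) + 1, 4)
  new <- bspline_ffd(new_spacing, box$lo, n)
  nodes <- ffd_nodes(new)
  disp <- cpp_ffd_eval(ffd$coefficients, ffd$grid_origin,
                       ffd$control_spacing, nodes, TRUE)
  vals <- array(disp, c(new$grid_shape, 3))
  co <- vals
  for (ax in 1:3) co <- prefilter_axis(co, ax)
  bspline_ffd(new_spacing, box$lo, n, co)
}

# Solve (c * [1 4 1]/6) = v along one axis (replicate boundary).
prefilter_axis <- function(arr, axis) {
  perm <- c(axis, setdiff(1:3, axis), 4)
  a <- aperm(arr, perm)
  d <- dim(a)
  n <- d[1]
  flat <- matrix(a, n, prod(d[-1]))
  M <- diag(4 / 6, n)
  for (i in seq_len(n - 1)) { M[i, i + 1] <- 1 / 6; M[i + 1, i] <- 1 / 6 }
  M[1, 1] <- 5 / 6; M[n, n] <- 5 / 6
  sol <- solve(M, flat)
  aperm(array(sol, d), order(perm))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 6))
  cat(sprintf("  translation (%g, %g, %g) mm, center (%g, %g, %g) mm\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' @export
print.bspline_ffd <- function(x, ...) {
  cat(sprintf("<bspline_ffd> grid %d x %d x %d, spacing (%g, %g, %g) mm, max |u| = %.3g mm\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$control_spacing[1], x$control_spacing[2], x$control_spacing[3],
              max(abs(x$coefficients))))
  invisible(x)
}

#' @export
print.composite_transform <- function(x, ...) {
  cat(sprintf("<composite_transform> of %d components (last applied first)\n",
              length(x$transforms)))
  invisible(x)
}
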