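#' Specification of a synthetic abdominal CT phantom
#'
#' Parameters of the deformable CT phantom used to validate the
#' registration pipeline in the absence of clinical data: an ellipsoidal
#' liver (about 100 HU) with contrast-enhanced vessel branches (about
#' 180 HU) whose branch points serve as anatomical landmarks, a
#' hypodense tumor inside the liver, a soft-tissue body (about 40 HU)
#' with a few organ blobs, air background (-1000 HU) and additive
#' Gaussian noise.
#'
#' @param shape voxel counts per axis (default 128 x 128 x 96).
#' @param spacing voxel spacing mm (default 2 x 2 x 3, the anisotropic
#'   clinical regime).
#' @param liver_center liver center mm (default: volume center, shifted
#'   up-left as in a supine abdomen).
#' @param liver_axes ellipsoid semi-axes mm (default: 70 x 52 x 58,
#'   shrunk if needed so the liver fits the field of view).
#' @param roughness_mm amplitude of the smooth boundary perturbation.
#' @param asymmetry wedge-taper strength of the liver shape (0 gives a
#'   pure ellipsoid; the default emulates the narrowing of a real liver
#'   toward the left lobe, which makes the shape sensitive to rotation).
#' @param reg_mask_margin_mm dilation of the rough registration mask
#'   beyond the liver (the clinical masks are drawn slightly larger
#'   than the liver; 0 disables the separate registration mask).
#' @param n_branches number of vessel branches.
#' @param vessel_radius_mm vessel cylinder radius.
#' @param vessel_hu,liver_hu,tissue_hu,air_hu tissue intensities (HU).
#' @param noncontrast_vessel_hu vessel intensity in non-enhanced
#'   acquisitions: on unenhanced CT, blood in the portal and hepatic
#'   veins is subtly hypodense relative to parenchyma (about 20 HU),
#'   not invisible.
#' @param tumor_center tumor center mm (default: inside the right lobe).
#' @param tumor_radius_mm tumor radius.
#' @param tumor_hu_offset tumor intensity offset from liver (hypodense).
#' @param noise_sigma Gaussian noise standard deviation (HU).
#' @param seed RNG seed for all stochastic phantom features.
#' @export
phantom_spec <- function(shape = c(128, 128, 96), spacing = c(2, 2, 3),
                         liver_center = NULL, liver_axes = NULL,
                         roughness_mm = 2, asymmetry = 0.22,
                         reg_mask_margin_mm = 8,
                         n_branches = 5, vessel_radius_mm = 3,
                         vessel_hu = 180, liver_hu = 100, tissue_hu = 40,
                         air_hu = -1000, noncontrast_vessel_hu = 80,
                         tumor_center = NULL, tumor_radius_mm = 12,
                         tumor_hu_offset = -40,
                         noise_sigma = 10, seed = 1) {
  shape <- as.integer(vec3(shape, "shape"))
  spacing <- vec3(spacing, "spacing")
  extent <- (shape - 1) * spacing
  if (is.null(liver_center)) liver_center <- extent * c(0.42, 0.45, 0.5)
  liver_center <- vec3(liver_center)
  if (is.null(liver_axes))   # adult liver, shrunk to fit small test volumes
    liver_axes <- pmin(c(70, 52, 58),
                       0.95 * pmin(liver_center, extent - liver_center))
  liver_axes <- vec3(liver_axes, "liver_axes")
  if (any(liver_axes <= 0)) stop("liver semi-axes must be > 0")
  if (noise_sigma < 0) stop("noise sigma must be >= 0")
  if (is.null(tumor_center))
    tumor_center <- liver_center + liver_axes * c(0.35, 0.2, -0.15)
  tumor_center <- vec3(tumor_center)
  rel <- sqrt(sum(((tumor_center - liver_center) / liver_axes)^2))
  if (rel + tumor_radius_mm / min(liver_axes) > 0.95)
    stop("tumor does not fit inside the liver")
  structure(list(shape = shape, spacing = spacing, extent = extent,
                 liver_center = liver_center, liver_axes = liver_axes,
                 roughness_mm = roughness_mm, asymmetry = asymmetry,
                 reg_mask_margin_mm = reg_mask_margin_mm,
                 n_branches = n_branches,
                 vessel_radius_mm = vessel_radius_mm, vessel_hu = vessel_hu,
                 liver_hu = liver_hu, tissue_hu = tissue_hu, air_hu = air_hu,
                 noncontrast_vessel_hu = noncontrast_vessel_hu,
                 tumor_center = tumor_center,
                 tumor_radius_mm = tumor_radius_mm,
                 tumor_hu_offset = tumor_hu_offset,
                 noise_sigma = noise_sigma, seed = seed),
            class = "phantom_spec")
}

# World-coordinate grids (identity orientation, origin at 0).
phantom_grids <- function(spec) {
  d <- spec$shape; sp <- spec$spacing
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  list(X = array(rep(x, times = d[2] * d[3]), d),
       Y = array(rep(rep(y, each = d[1]), times = d[3]), d),
       Z = array(rep(z, each = d[1] * d[2]), d))
}

# Squared distance from each voxel (within a bounding box) to a segment.
rasterize_cylinder <- function(vox, grids, p0, p1, radius, value, spacing) {
  lo <- pmin(p0, p1) - radius - 2 * spacing
  hi <- pmax(p0, p1) + radius + 2 * spacing
  d <- dim(vox)
  idx <- lapply(1:3, function(a)
    max(1, ceiling(lo[a] / spacing[a])):min(d[a], floor(hi[a] / spacing[a]) + 1))
  X <- grids$X[idx[[1]], idx[[2]], idx[[3]]]
  Y <- grids$Y[idx[[1]], idx[[2]], idx[[3]]]
  Z <- grids$Z[idx[[1]], idx[[2]], idx[[3]]]
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (Z - p0[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (X - (p0[1] + t * v[1]))^2 + (Y - (p0[2] + t * v[2]))^2 +
    (Z - (p0[3] + t * v[3]))^2
  sub <- vox[idx[[1]], idx[[2]], idx[[3]]]
  sub[d2 <= radius^2] <- value
  vox[idx[[1]], idx[[2]], idx[[3]]] <- sub
  vox
}

#' Generate the diagnostic (contrast-enhanced) phantom volume
#'
#' Deterministic for a given spec seed.  Returns the noisy image, the
#' binary liver and tumor masks, vessel-branch-point landmarks (world
#' mm) and the noiseless tissue model (used internally to emulate
#' non-contrast acquisitions).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{image}, \code{liver_mask}, \code{tumor_mask},
#'   \code{landmarks}, \code{clean}, \code{vessel_mask}, \code{spec}.
#' @export
generate_diagnostic <- function(spec) {
  g <- phantom_grids(spec)
  d <- spec$shape
  ext <- spec$extent
  vox <- array(spec$air_hu, d)
  # body: soft-tissue ellipsoid filling most of the field of view
  bc <- ext / 2
  ba <- ext * c(0.47, 0.45, 0.65)
  body <- ((g$X - bc[1]) / ba[1])^2 + ((g$Y - bc[2]) / ba[2])^2 +
    ((g$Z - bc[3]) / ba[3])^2 <= 1
  vox[body] <- spec$tissue_hu
  rnd <- with_seed(spec$seed, list(
    rough = matrix(rnorm(9), 3, 3),
    phase = runif(3, 0, 2 * pi),
    branch_dir = matrix(rnorm(3 * spec$n_branches), spec$n_branches, 3),
    branch_len = runif(spec$n_branches, 0.45, 0.7),
    blob = matrix(runif(6), 2, 3)))
  # organ blobs in the surrounding tissue (e.g. kidney / stomach stand-ins)
  for (b in 1:2) {
    ctr <- ext * c(0.75, 0.25 + 0.5 * (b - 1), 0.35)
    blob <- ((g$X - ctr[1])^2 + (g$Y - ctr[2])^2 + (g$Z - ctr[3])^2) <=
      (18 + 6 * rnd$blob[b, 1])^2
    vox[blob & body] <- 80
  }
  # liver: ellipsoid with a smooth low-order boundary perturbation
  lc <- spec$liver_center; la <- spec$liver_axes
  u <- (g$X - lc[1]) / la[1]; v <- (g$Y - lc[2]) / la[2]
  w <- (g$Z - lc[3]) / la[3]
  r <- sqrt(u^2 + v^2 + w^2)
  # wedge taper: a real liver narrows toward the left lobe and
  # anteriorly, so the shape is strongly asymmetric about the z axis
  taper <- 1 - spec$asymmetry * u / pmax(r, 1e-9) * abs(u) / pmax(r, 1e-9) -
    0.55 * spec$asymmetry * v / pmax(r, 1e-9)
  thr <- pmax(taper, 0.4)
  if (spec$roughness_mm > 0) {
    pert <- 0
    for (j in 1:3)
      pert <- pert + sin(rnd$rough[j, 1] * 2 * u + rnd$rough[j, 2] * 2 * v +
                           rnd$rough[j, 3] * 2 * w + rnd$phase[j]) / 3
    thr <- thr + (spec$roughness_mm / mean(la)) * pert
  }
  liver <- r <= thr
  vox[liver] <- spec$liver_hu
  liver_mask <- array(liver * 1, d)
  # vessel tree: branches from the hilum toward the periphery; branch
  # endpoints and midpoints are the landmark set
  vessel <- array(0, d)
  root <- lc + la * c(-0.1, 0.1, 0)
  landmarks <- NULL
  for (b in seq_len(spec$n_branches)) {
    dir <- rnd$branch_dir[b, ]
    dir <- dir / sqrt(sum(dir^2))
    tip <- lc + (dir * la) * rnd$branch_len[b]
    vessel <- rasterize_cylinder(vessel, g, root, tip,
                                 spec$vessel_radius_mm, 1, spec$spacing)
    mid <- (root + tip) / 2
    sub_tip <- mid + ((tip - root) / 2)[c(2, 3, 1)] * 0.6
    vessel <- rasterize_cylinder(vessel, g, mid, sub_tip,
                                 spec$vessel_radius_mm * 0.8, 1, spec$spacing)
    landmarks <- rbind(landmarks, tip, mid, sub_tip)
  }
  li <- round(sweep(landmarks, 2, spec$spacing, "/"))
  ok <- li[, 1] >= 0 & li[, 1] <= d[1] - 1 & li[, 2] >= 0 &
    li[, 2] <= d[2] - 1 & li[, 3] >= 0 & li[, 3] <= d[3] - 1
  inside <- ok
  inside[ok] <- liver[cbind(li[ok, 1] + 1, li[ok, 2] + 1, li[ok, 3] + 1)]
  landmarks <- landmarks[inside, , drop = FALSE]
  vessel_mask <- array((vessel > 0 & liver) * 1, d)
  vox[vessel_mask > 0] <- spec$vessel_hu
  # tumor: hypodense sphere
  tum <- ((g$X - spec$tumor_center[1])^2 + (g$Y - spec$tumor_center[2])^2 +
            (g$Z - spec$tumor_center[3])^2) <= spec$tumor_radius_mm^2
  vox[tum] <- spec$liver_hu + spec$tumor_hu_offset
  tumor_mask <- array(tum * 1, d)
  clean <- vox
  if (spec$noise_sigma > 0)
    vox <- vox + with_seed(derive_seed(spec$seed, 7),
                           array(rnorm(prod(d), 0, spec$noise_sigma), d))
  mk <- function(a) image3d(a, spec$spacing, c(0, 0, 0))
  # rough registration mask: the liver dilated by a margin, emulating
  # the hand-drawn contours "slightly larger than the liver"
  reg_mask <- liver_mask
  if (spec$reg_mask_margin_mm > 0) {
    sig <- (spec$reg_mask_margin_mm / 2) / spec$spacing
    sm <- cpp_gauss_smooth(liver_mask, sig)
    reg_mask <- array((sm > 0.02) * 1, d)
  }
  list(image = mk(vox), liver_mask = mk(liver_mask),
       reg_mask = mk(reg_mask),
       tumor_mask = mk(tumor_mask), landmarks = unname(landmarks),
       clean = mk(clean), vessel_mask = mk(vessel_mask), spec = spec)
}

# Draw a smooth random FFD with max displacement about `amplitude` mm
# and guaranteed positive Jacobian determinant; retried at reduced
# amplitude if folding occurs.
random_smooth_ffd <- function(meta, amplitude, grid_mm, seed,
                              rigid_region = NULL, inplane_only = FALSE) {
  for (attempt in 1:6) {
    ffd <- ffd_for_domain(meta, grid_mm)
    n <- prod(ffd$grid_shape)
    co <- with_seed(derive_seed(seed, attempt), {
      v <- rnorm(n * 3, 0, amplitude / 2.5)
      pmin(pmax(v, -amplitude * 0.577), amplitude * 0.577)
    })
    co <- array(co, c(ffd$grid_shape, 3))
    if (inplane_only) co[, , , 3] <- 0
    if (!is.null(rigid_region)) {
      nodes <- ffd_nodes(ffd)
      dist <- sqrt(rowSums(sweep(nodes, 2, rigid_region$center, "-")^2))
      keep <- dist <= rigid_region$radius + 2 * max(vec3(grid_mm))
      flat <- matrix(co, n, 3)
      flat[keep, ] <- 0
      co <- array(flat, c(ffd$grid_shape, 3))
    }
    ffd$coefficients <- co
    if (min_jacobian_det(ffd, meta) > 0.05) return(ffd)
    amplitude <- amplitude * 0.85
  }
  stop("could not draw a fold-free deformation at the requested amplitude")
}

# Minimum det(J) of an FFD transform over a dense grid of the domain.
min_jacobian_det <- function(ffd, meta) {
  g <- geometry_of(meta)
  step <- pmax(ffd$control_spacing / 4, g$spacing)
  ext <- (g$dim - 1) * g$spacing
  pts <- as.matrix(expand.grid(seq(0, ext[1], by = step[1]),
                               seq(0, ext[2], by = step[2]),
                               seq(0, ext[3], by = step[3])))
  pts <- sweep(sweep(pts, 2, c(0, 0, 0), "-") , 2, g$origin, "+")
  J <- spatial_jacobian(ffd, pts, extrapolate = TRUE)
  detJ <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  min(detJ)
}

#' Generate the intra-operative phantom volume
#'
#' Applies a rigid pose change (z-rotation about the liver center of
#' mass plus a translation, emulating patient rotation for needle
#' access) followed by a smooth random free-form deformation (emulating
#' the breathing-state change) to the diagnostic phantom; optionally
#' removes the vessel contrast (non-enhanced acquisition).  The
#' ground-truth transform maps intra-operative world coordinates into
#' the diagnostic image, i.e. exactly what stage-1 registration must
#' recover.
#'
#' @param diag result of \code{\link{generate_diagnostic}}.
#' @param pose_z_deg patient z-rotation in degrees (default 30).
#' @param pose_translation rigid translation mm.
#' @param deform_amplitude_mm approximate maximum deformation (default
#'   15).
#' @param deform_grid_mm control spacing of the ground-truth deformation
#'   (default 50; deliberately different from the registration grids).
#' @param contrast keep vessel contrast (FALSE emulates the typical
#'   non-enhanced intra-operative scan).
#' @param rigid_region optional list(center, radius) mm: the deformation
#'   is zeroed there so the truth motion is locally rigid (refinement
#'   test bed).
#' @param seed RNG seed (default derived from the spec seed).
#' @return list with \code{image}, \code{liver_mask}, \code{tumor_mask},
#'   \code{landmarks}, \code{truth} (the F-to-D transform),
#'   \code{truth_ffd}, \code{truth_rigid}.
#' @export
make_intraoperative <- function(diag, pose_z_deg = 30,
                                pose_translation = c(8, -6, 4),
                                deform_amplitude_mm = 15,
                                deform_grid_mm = 50,
                                contrast = FALSE, rigid_region = NULL,
                                seed = NULL) {
  spec <- diag$spec
  if (is.null(seed)) seed <- derive_seed(spec$seed, 11)
  com <- center_of_mass(diag$liver_mask)
  rigid <- rigid_transform(rotation_z(pose_z_deg),
                           translation = vec3(pose_translation),
                           center = com)
  ffd <- if (deform_amplitude_mm > 0)
    random_smooth_ffd(diag$image, deform_amplitude_mm, deform_grid_mm, seed,
                      rigid_region = rigid_region)
  else ffd_for_domain(diag$image, deform_grid_mm)
  truth <- composite_transform(rigid, ffd)
  src <- diag$clean
  if (!contrast) {
    v <- src$voxels
    v[diag$vessel_mask$voxels > 0] <- spec$noncontrast_vessel_hu
    src <- image3d(v, src$spacing, src$origin, src$direction)
  }
  img <- resample(src, truth, diag$image, "linear", spec$air_hu)
  if (spec$noise_sigma > 0)
    img$voxels <- img$voxels +
      with_seed(derive_seed(seed, 3),
                array(rnorm(prod(dim(img$voxels)), 0, spec$noise_sigma),
                      dim(img$voxels)))
  lmask <- resample(diag$liver_mask, truth, diag$image, "nearest", 0)
  rmask <- resample(diag$reg_mask, truth, diag$image, "nearest", 0)
  tmask <- resample(diag$tumor_mask, truth, diag$image, "nearest", 0)
  lms <- invert_truth_points(truth, rigid, ffd, diag$landmarks)
  list(image = img, liver_mask = lmask, reg_mask = rmask,
       tumor_mask = tmask,
       landmarks = lms, truth = truth, truth_ffd = ffd,
       truth_rigid = rigid, pose_z_deg = pose_z_deg, seed = seed)
}

# Invert truth = rigid o ffd at points: solve x + u(x) = rigid^{-1}(a).
invert_truth_points <- function(truth, rigid, ffd, pts) {
  y <- transform_points(invert_rigid(rigid), pts)
  x <- y
  for (i in 1:200) {
    u <- transform_points(ffd, x, extrapolate = TRUE) - x
    xn <- y - u
    if (max(abs(xn - x)) < 1e-13) { x <- xn; break }
    x <- xn
  }
  x
}

#' Extract a limited field-of-view needle-check slab
#'
#' Applies a small rigid drift (the residual liver motion between the
#' initial intra-operative scan and the needle-check scan), crops the
#' volume to \code{n_slices} axial slices around \code{slab_center_mm},
#' and rasterizes a hyperdense needle (1.5 mm radius, 3000 HU) from an
#' entry point to a tip point.  An optional small in-plane deformation
#' emulates residual non-rigid motion; with the default 0 the
#' ground-truth F-to-N transform is exactly the rigid drift.
#'
#' @param intraop result of \code{\link{make_intraoperative}} (or the
#'   diagnostic output for a drift relative to D).
#' @param slab_center_mm axial (z) world coordinate of the slab center.
#' @param n_slices number of axial slices (3 <= n < full slice count).
#' @param drift a small \code{rigid_transform} (N-to-F), default 5 mm
#'   translation.
#' @param needle_entry,needle_tip world mm endpoints of the needle; NULL
#'   suppresses the needle.
#' @param deform_amplitude_mm small residual non-rigid motion (default 0).
#' @param deform_grid_mm spatial scale of that motion (default 25 mm;
#'   short enough to leave a genuinely non-rigid residual over the
#'   liver's in-plane footprint).
#' @param seed RNG seed for the optional deformation.
#' @return list with \code{image} (N), \code{truth} (F-to-N... the
#'   transform mapping N-domain points into F), \code{liver_mask}
#'   (truth liver in N), \code{n_slices}.
#' @export
extract_needle_slab <- function(intraop, slab_center_mm, n_slices = 5,
                                drift = rigid_transform(translation = c(3, -2, 3.5)),
                                needle_entry = NULL, needle_tip = NULL,
                                deform_amplitude_mm = 0, deform_grid_mm = 25,
                                seed = 1) {
  F_img <- intraop$image
  d <- dim(F_img$voxels)
  if (n_slices < 3) stop("needle slab must have at least 3 slices")
  if (n_slices >= d[3]) stop("slab must have fewer slices than the full volume")
  kz <- round(index_from_world(F_img, c(0, 0, slab_center_mm))[3])
  k0 <- kz - (n_slices - 1) %/% 2
  if (k0 < 0 || k0 + n_slices - 1 > d[3] - 1)
    stop("slab extends outside the volume")
  gN <- list(dim = c(d[1], d[2], n_slices), spacing = F_img$spacing,
             origin = F_img$origin + c(0, 0, k0 * F_img$spacing[3]),
             direction = F_img$direction)
  truth <- drift
  if (deform_amplitude_mm > 0) {
    ffd <- random_smooth_ffd(F_img, deform_amplitude_mm, deform_grid_mm, seed,
                             inplane_only = TRUE)
    truth <- composite_transform(drift, ffd)
  }
  img <- resample(F_img, truth, gN, "linear", -1000)
  if (!is.null(needle_entry) && !is.null(needle_tip)) {
    w <- all_voxel_world(gN)
    p0 <- vec3(needle_entry); p1 <- vec3(needle_tip)
    v <- p1 - p0
    t <- pmin(pmax(sweep(w, 2, p0, "-") %*% v / sum(v^2), 0), 1)
    closest <- sweep(t %*% t(v), 2, p0, "+")
    d2 <- rowSums((w - closest)^2)
    vox <- img$voxels
    vox[d2 <= 1.5^2] <- 3000
    img$voxels <- vox
  }
  lmask <- if (!is.null(intraop$liver_mask))
    resample(intraop$liver_mask, truth, gN, "nearest", 0) else NULL
  list(image = img, truth = truth, liver_mask = lmask, n_slices = n_slices,
       k0 = k0)
}

#' Simulate a complete registration case
#'
#' Generates the diagnostic phantom D, the intra-operative phantom F
#' (pose change + breathing deformation + contrast state) and the
#' limited field-of-view needle slab N, bundled as a
#' \code{\link{liver_case}} together with all ground-truth transforms.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param pose_z_deg,pose_translation,deform_amplitude_mm,contrast passed
#'   to \code{\link{make_intraoperative}}.
#' @param n_slices,drift,slab_deform_amplitude_mm,slab_deform_grid_mm
#'   passed to \code{\link{extract_needle_slab}}.
#' @param with_needle_slab generate N (default TRUE).
#' @return list with the \code{case} (a \code{liver_case}) and
#'   \code{truth} (D-F transform, F-N transform, landmark sets, masks).
#' @export
simulate_case <- function(spec = phantom_spec(),
                          pose_z_deg = 30, pose_translation = c(8, -6, 4),
                          deform_amplitude_mm = 15, contrast = FALSE,
                          n_slices = 5,
                          drift = rigid_transform(translation = c(3, -2, 3.5)),
                          slab_deform_amplitude_mm = 0,
                          slab_deform_grid_mm = 25,
                          with_needle_slab = TRUE) {
  D <- generate_diagnostic(spec)
  F_ <- make_intraoperative(D, pose_z_deg, pose_translation,
                            deform_amplitude_mm, contrast = contrast)
  N <- NULL
  if (with_needle_slab) {
    tumor_F <- center_of_mass(F_$tumor_mask)
    entry <- c(tumor_F[1] + 60, tumor_F[2], tumor_F[3])
    N <- extract_needle_slab(F_, tumor_F[3], n_slices, drift,
                             needle_entry = entry,
                             needle_tip = tumor_F + c(3, 0, 0),
                             deform_amplitude_mm = slab_deform_amplitude_mm,
                             deform_grid_mm = slab_deform_grid_mm,
                             seed = derive_seed(spec$seed, 21))
  }
  case <- liver_case(D = D$image, F = F_$image,
                     N = if (!is.null(N)) N$image else NULL,
                     liver_mask_D = D$liver_mask,
                     liver_mask_F = F_$liver_mask,
                     tumor_mask_D = D$tumor_mask,
                     landmarks_D = D$landmarks,
                     landmarks_F = F_$landmarks,
                     reg_mask_D = D$reg_mask,
                     reg_mask_F = F_$reg_mask,
                     z_rotation_deg = pose_z_deg)
  list(case = case, diagnostic = D, intraop = F_, slab = N,
       truth_DF = F_$truth, truth_FN = if (!is.null(N)) N$truth else NULL)
}
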