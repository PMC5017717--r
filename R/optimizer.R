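#' Registration control parameters
#'
#' The full parameter schedule of the multiresolution registration.
#' Defaults follow the clinical setting: four B-spline grid resolutions
#' of \code{c(80, 40, 20, 10)} mm, 500 iterations per resolution, 2000
#' stochastic samples per iteration, and a Robbins-Monro gain sequence
#' \code{a / (A + t)^decay} whose \code{a} is auto-scaled so the first
#' step moves control points by about a quarter of the current grid
#' spacing.
#'
#' @param grid_spacings_mm B-spline control-grid spacing per resolution,
#'   coarse to fine (mm).
#' @param pyramid_factors integer image-pyramid downsampling factor per
#'   resolution (last must be 1).
#' @param iterations_per_level SGD iterations per resolution.
#' @param samples_per_iteration stochastic samples per iteration.
#' @param bins histogram bins for both images.
#' @param gain_A,gain_decay gain-sequence parameters A and the decay
#'   exponent.
#' @param gain_a explicit gain numerator (NULL = auto-scale).
#' @param step_target_frac fraction of the grid spacing targeted by the
#'   auto-scaled first step.
#' @param seed master RNG seed; all stochastic sampling derives from it.
#' @param min_kept minimum fraction of samples that must land inside the
#'   moving image (gross-misalignment guard).
#' @param rigid_factors pyramid factors for rigid registrations.
#' @param rigid_iterations iterations per level for rigid registrations
#'   (NULL = same as \code{iterations_per_level}).
#' @param moving_floor_hu intensity floor used to pick the moving-image
#'   bin range when no moving mask is supplied.
#' @export
reg_control <- function(grid_spacings_mm = c(80, 40, 20, 10),
                        pyramid_factors = c(8, 4, 2, 1),
                        iterations_per_level = 500,
                        samples_per_iteration = 2000,
                        bins = 32,
                        gain_A = 50, gain_decay = 0.602, gain_a = NULL,
                        step_target_frac = 0.25,
                        seed = 20160909,
                        min_kept = 0.5,
                        rigid_factors = c(4, 2, 1),
                        rigid_iterations = NULL,
                        moving_floor_hu = -300) {
  if (any(diff(grid_spacings_mm) > 0))
    stop("grid spacings must be monotone non-increasing")
  if (length(pyramid_factors) != length(grid_spacings_mm))
    stop("pyramid_factors and grid_spacings_mm must have equal length")
  if (iterations_per_level < 1 || samples_per_iteration < 1)
    stop("iterations and samples must be >= 1")
  structure(list(grid_spacings_mm = grid_spacings_mm,
                 pyramid_factors = pyramid_factors,
                 iterations_per_level = iterations_per_level,
                 samples_per_iteration = samples_per_iteration,
                 bins = bins, gain_A = gain_A, gain_decay = gain_decay,
                 gain_a = gain_a, step_target_frac = step_target_frac,
                 seed = seed, min_kept = min_kept,
                 rigid_factors = rigid_factors,
                 rigid_iterations = rigid_iterations,
                 moving_floor_hu = moving_floor_hu),
            class = "reg_control")
}

#' Stochastic gradient descent with a Robbins-Monro gain sequence
#'
#' Iterates \code{mu_{t+1} = mu_t - a/(A + t)^decay * g_t} for exactly
#' \code{iterations} steps.  When \code{gain_a} is NULL it is set so the
#' first step's largest parameter motion equals \code{step_target}.
#'
#' @param fn function(mu, t) returning list(cost, gradient, ...).
#' @param mu0 initial parameter vector.
#' @param iterations number of steps.
#' @param gain_a,gain_A,gain_decay gain sequence parameters.
#' @param step_target desired first-step max parameter motion for
#'   auto-scaling (ignored when \code{gain_a} given).
#' @param max_step cap on the per-iteration max parameter motion; keeps
#'   the iteration stable when the gradient grows along the way (the
#'   rigidity penalty is quartic in the parameters).
#' @return list with \code{par}, \code{trace} (data.frame of cost and
#'   step norm per iteration) and \code{gain_a}.
#' @export
sgd_minimize <- function(fn, mu0, iterations, gain_a = NULL, gain_A = 50,
                         gain_decay = 0.602, step_target = 1,
                         max_step = Inf) {
  mu <- as.numeric(mu0)
  cost <- numeric(iterations)
  stepn <- numeric(iterations)
  dropped <- numeric(iterations)
  a <- gain_a
  for (t in seq_len(iterations)) {
    st <- fn(mu, t)
    g <- as.numeric(st$gradient)
    if (any(!is.finite(g)) || !is.finite(st$cost))
      stop("non-finite cost or gradient at iteration ", t)
    if (is.null(a)) {
      gmax <- max(abs(g))
      a <- if (gmax > 0) step_target * (gain_A + 1)^gain_decay / gmax else 0
    }
    gamma <- a / (gain_A + t)^gain_decay
    gmax <- max(abs(g))
    if (is.finite(max_step) && gamma * gmax > max_step)
      gamma <- max_step / gmax
    mu <- mu - gamma * g
    cost[t] <- st$cost
    stepn[t] <- gamma * gmax
    dropped[t] <- if (!is.null(st$dropped)) st$dropped else 0
  }
  list(par = mu, gain_a = if (is.null(a)) 0 else a,
       trace = data.frame(iteration = seq_len(iterations), cost = cost,
                          step = stepn, dropped = dropped))
}

# Per-axis pyramid factor, clamped so at least 4 voxels remain per axis.
effective_factor <- function(factor, dims) {
  f <- vec3(factor, "pyramid factor")
  pmax(pmin(f, pmax(dims %/% 4, 1)), 1)
}

level_images <- function(fixed, moving, fixed_mask, moving_mask, factor) {
  f <- effective_factor(factor, dim(fixed$voxels))
  fm <- effective_factor(factor, dim(moving$voxels))
  fx <- gaussian_pyramid(fixed, list(f))[[1]]
  mv <- gaussian_pyramid(moving, list(fm))[[1]]
  mk <- mask_to_geometry(fixed_mask, fx)
  mmk <- if (!is.null(moving_mask)) mask_to_geometry(moving_mask, mv) else NULL
  list(fixed = fx, moving = mv, mask = mk, moving_mask = mmk)
}

# Robust intensity range for histogram binning: extreme quantiles, so a
# handful of hyperdense voxels (surgical clips, the ablation needle)
# cannot compress the soft-tissue contrast into a single bin.
robust_range <- function(v) {
  r <- unname(stats::quantile(v, c(0.002, 0.998), names = FALSE))
  if (r[2] <= r[1]) r <- range(v)
  r
}

fixed_bin_range <- function(fixed_lvl, mask_lvl) {
  robust_range(fixed_lvl$voxels[mask_lvl$voxels > 0])
}

moving_bin_range <- function(moving_lvl, moving_mask_lvl, floor_hu) {
  v <- moving_lvl$voxels
  if (!is.null(moving_mask_lvl)) {
    sel <- v[moving_mask_lvl$voxels > 0]
    if (length(sel) > 1) return(robust_range(sel))
  }
  sel <- v[v > floor_hu]
  if (length(sel) > 1) robust_range(sel) else range(v)
}

#' Masked multiresolution B-spline registration
#'
#' Minimizes \code{-MI + alpha * P_rigid} (the rigidity term only when
#' enabled) by stochastic gradient descent over a B-spline free-form
#' deformation, in a coarse-to-fine schedule of control-grid spacings
#' and image-pyramid levels.  Samples are drawn inside the fixed mask;
#' the estimated parameters are carried between resolutions by exact
#' grid refinement.  The returned transform maps fixed-image world
#' coordinates into the moving image: \code{T(x) = init(x + u(x))}.
#'
#' @param fixed,moving \code{image3d} volumes (fixed = target domain).
#' @param fixed_mask binary \code{image3d} on the fixed geometry; the
#'   similarity is computed from samples inside it.
#' @param init optional initial transform (e.g. from
#'   \code{\link{initialize_alignment}}), applied after the FFD.
#' @param control a \code{\link{reg_control}}.
#' @param rigidity optional list(cmask = coefficient_mask, weights =
#'   rigidity_weights) enabling the local rigidity penalty.
#' @param moving_mask optional binary mask on the moving geometry, used
#'   only to pick the moving intensity bin range.
#' @return object of class \code{reg_fit}.
#' @export
multires_register <- function(fixed, moving, fixed_mask, init = NULL,
                              control = reg_control(), rigidity = NULL,
                              moving_mask = NULL) {
  stopifnot(inherits(fixed, "image3d"), inherits(moving, "image3d"))
  if (!same_geometry(fixed, fixed_mask))
    stop("fixed_mask must share the fixed image geometry")
  nlev <- length(control$grid_spacings_mm)
  alpha <- if (!is.null(rigidity)) rigidity$weights$alpha else rep(0, nlev)
  if (length(alpha) != nlev)
    stop("rigidity alpha schedule length must equal the number of resolutions")
  gfix <- geometry_of(fixed)
  corners <- world_from_index(gfix, as.matrix(expand.grid(
    c(0, gfix$dim[1] - 1), c(0, gfix$dim[2] - 1), c(0, gfix$dim[3] - 1))),
    check = FALSE)
  box_lo <- apply(corners, 2, min); box_hi <- apply(corners, 2, max)
  ffd <- NULL
  traces <- list()
  gains <- numeric(nlev)
  for (lev in seq_len(nlev)) {
    sp <- control$grid_spacings_mm[lev]
    li <- level_images(fixed, moving, fixed_mask, moving_mask,
                       control$pyramid_factors[lev])
    ffd <- if (is.null(ffd)) ffd_for_domain(fixed, sp)
           else refine_grid(ffd, vec3(sp))
    candidates <- which(li$mask$voxels != 0)
    if (length(candidates) == 0) stop("fixed mask is empty at pyramid level ", lev)
    fixed_range <- fixed_bin_range(li$fixed, li$mask)
    moving_range <- moving_bin_range(li$moving, li$moving_mask,
                                     control$moving_floor_hu)
    eval_pts <- NULL
    if (alpha[lev] > 0 && !is.null(rigidity)) {
      nodes <- ffd_nodes(ffd)
      keep <- nodes[, 1] >= box_lo[1] & nodes[, 1] <= box_hi[1] &
        nodes[, 2] >= box_lo[2] & nodes[, 2] <= box_hi[2] &
        nodes[, 3] >= box_lo[3] & nodes[, 3] <= box_hi[3]
      eval_pts <- nodes[keep, , drop = FALSE]
    }
    cdim <- dim(ffd$coefficients)
    lev_ffd <- ffd
    fn <- function(mu, t) {
      lev_ffd$coefficients <- array(mu, cdim)
      smp <- draw_samples(li$mask, control$samples_per_iteration,
                          derive_seed(control$seed, lev, t), candidates)
      res <- mi_cost_grad(li$fixed, li$moving, lev_ffd, init, smp,
                          control$bins, fixed_range, moving_range,
                          control$min_kept)
      cost <- res$cost
      grad <- res$gradient
      if (!is.null(eval_pts) && nrow(eval_pts) > 0) {
        ct <- if (is.null(init)) lev_ffd else composite_transform(init, lev_ffd)
        # a coarse grid may have no node inside the (small) coefficient
        # region: the penalty is then simply inactive at this level
        rg <- tryCatch(
          rigidity_gradient(lev_ffd, rigidity$cmask, rigidity$weights,
                            eval_pts, c_transform = ct),
          liverreg_degenerate_mask = function(e) NULL)
        if (!is.null(rg)) {
          cost <- cost + alpha[lev] * rg$penalty
          grad <- grad + alpha[lev] * rg$gradient
        }
      }
      list(cost = cost, gradient = grad, dropped = res$dropped)
    }
    opt <- sgd_minimize(fn, as.numeric(ffd$coefficients),
                        control$iterations_per_level,
                        gain_a = control$gain_a, gain_A = control$gain_A,
                        gain_decay = control$gain_decay,
                        step_target = control$step_target_frac * min(vec3(sp)),
                        max_step = control$step_target_frac * min(vec3(sp)))
    ffd$coefficients <- array(opt$par, cdim)
    gains[lev] <- opt$gain_a
    tr <- opt$trace
    tr$level <- lev
    traces[[lev]] <- tr
  }
  transform <- if (is.null(init)) ffd else composite_transform(init, ffd)
  structure(list(transform = transform, ffd = ffd, init = init,
                 control = control, rigidity = !is.null(rigidity),
                 trace = do.call(rbind, traces), gains = gains),
            class = "reg_fit")
}

#' Rigid mutual-information registration
#'
#' Multiresolution rigid registration (3 rotation + 3 translation
#' parameters about the fixed mask's center of mass) with the same
#' stochastic MI metric and gain schedule as the non-rigid stage;
#' used to align the limited field-of-view needle image to the full
#' intra-operative image.
#'
#' @inheritParams multires_register
#' @return object of class \code{reg_fit} whose transform is a
#'   \code{rigid_transform}.
#' @export
rigid_register <- function(fixed, moving, fixed_mask,
                           control = reg_control(), moving_mask = NULL) {
  if (!same_geometry(fixed, fixed_mask))
    stop("fixed_mask must share the fixed image geometry")
  center <- center_of_mass(fixed_mask)
  idx <- which(fixed_mask$voxels != 0)
  ai <- arrayInd(idx, dim(fixed_mask$voxels)) - 1L
  wm <- world_from_index(fixed_mask, ai, check = FALSE)
  L <- mean(sqrt(rowSums(sweep(wm, 2, center, "-")^2)))
  L <- max(L, 1)
  iters <- if (is.null(control$rigid_iterations))
    control$iterations_per_level else control$rigid_iterations
  theta <- rep(0, 6)  # scaled: (rx, ry, rz) * L, (tx, ty, tz)
  traces <- list()
  for (lev in seq_along(control$rigid_factors)) {
    li <- level_images(fixed, moving, fixed_mask, moving_mask,
                       control$rigid_factors[lev])
    candidates <- which(li$mask$voxels != 0)
    if (length(candidates) == 0) stop("fixed mask empty at rigid level ", lev)
    fixed_range <- fixed_bin_range(li$fixed, li$mask)
    moving_range <- moving_bin_range(li$moving, li$moving_mask,
                                     control$moving_floor_hu)
    fn <- function(phi, t) {
      smp <- draw_samples(li$mask, control$samples_per_iteration,
                          derive_seed(control$seed, 100 + lev, t), candidates)
      rigid_mi_cost_grad(li$fixed, li$moving, phi, L, center, smp,
                         control$bins, fixed_range, moving_range,
                         control$min_kept)
    }
    opt <- sgd_minimize(fn, theta, iters, gain_a = control$gain_a,
                        gain_A = control$gain_A,
                        gain_decay = control$gain_decay,
                        step_target = 2 / lev, max_step = 2 / lev)
    theta <- opt$par
    tr <- opt$trace; tr$level <- lev
    traces[[lev]] <- tr
  }
  transform <- rigid_from_params(theta, L, center)
  structure(list(transform = transform, ffd = NULL, init = NULL,
                 control = control, rigidity = FALSE, par = theta,
                 trace = do.call(rbind, traces)),
            class = c("reg_fit_rigid", "reg_fit"))
}

rigid_from_params <- function(phi, L, center) {
  ang <- phi[1:3] / L
  rigid_transform(euler_rotation(ang[1], ang[2], ang[3]),
                  translation = phi[4:6], center = center)
}

rigid_mi_cost_grad <- function(fixed, moving, phi, L, center, samples, bins,
                               fixed_range, moving_range, min_kept) {
  ang <- phi[1:3] / L
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, 3)
  dRx <- matrix(c(0, 0, 0, 0, -sin(ang[1]), cos(ang[1]),
                  0, -cos(ang[1]), -sin(ang[1])), 3, 3)
  dRy <- matrix(c(-sin(ang[2]), 0, -cos(ang[2]), 0, 0, 0,
                  cos(ang[2]), 0, -sin(ang[2])), 3, 3)
  dRz <- matrix(c(-sin(ang[3]), cos(ang[3]), 0, -cos(ang[3]), -sin(ang[3]), 0,
                  0, 0, 0), 3, 3)
  R <- Rz %*% Ry %*% Rx
  dR <- list(Rz %*% Ry %*% dRx, Rz %*% dRy %*% Rx, dRz %*% Ry %*% Rx)
  pts <- samples$points
  rel <- sweep(pts, 2, center, "-")
  z <- sweep(rel %*% t(R), 2, center + phi[4:6], "+")
  fv <- cpp_interp(fixed$voxels, index_from_world(fixed, pts), 1L, NA_real_)
  ci <- index_from_world(moving, z)
  mg <- cpp_interp_grad(moving$voxels, ci, 0)
  kept <- mg$inside & !is.na(fv)
  if (mean(kept) < min_kept)
    stop("more than ", round(100 * (1 - min_kept)),
         "% of samples map outside the moving image: gross misalignment")
  fb <- fixed_bin_coord(fv[kept], fixed_range, bins)
  mv <- mg$value[kept]
  mb <- moving_bin_coord(mv, moving_range, bins)
  counts <- cpp_joint_hist(fb, mb, moving_bins(bins), moving_bins(bins))
  tot <- sum(counts)
  p <- counts / tot
  pf <- rowSums(p); pm <- colSums(p)
  Lmat <- mi_log_ratio(p, pf, pm)
  mi <- sum(p * Lmat)
  dmb <- cpp_mi_sample_deriv(fb, mb, Lmat) / tot
  w <- moving_range[2] - moving_range[1]
  dbin <- if (w > 0) bins / w else 0
  inr <- mv > moving_range[1] & mv < moving_range[2]
  dint <- dmb * dbin * inr
  gidx <- mg$gradient[kept, , drop = FALSE]
  gw <- sweep(gidx, 2, moving$spacing, "/") %*% t(moving$direction)
  relk <- rel[kept, , drop = FALSE]
  grad <- numeric(6)
  for (i in 1:3) {
    dz <- relk %*% t(dR[[i]])
    grad[i] <- -sum(dint * rowSums(gw * dz)) / L
  }
  for (i in 1:3) grad[3 + i] <- -sum(dint * gw[, i])
  list(cost = -mi, gradient = grad, dropped = 1 - mean(kept))
}
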