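#' Bundle the images of one registration case
#'
#' Groups the diagnostic image D (contrast-enhanced, with liver and
#' tumor segmented), the full intra-operative image F acquired at the
#' start of the intervention, and optionally the limited field-of-view
#' needle image N, together with masks, landmarks and the manual
#' z-rotation pre-alignment angle.
#'
#' @param D,F,N \code{image3d} volumes (N optional).
#' @param liver_mask_D,liver_mask_F binary liver masks on D / F.
#' @param tumor_mask_D binary tumor mask on D (optional).
#' @param landmarks_D,landmarks_F paired landmarks (n x 3 world mm,
#'   optional; row i of each corresponds).
#' @param seeds refinement seed points in D world mm (optional).
#' @param reg_mask_D,reg_mask_F rough registration masks ("slightly
#'   larger than the liver", as drawn clinically); default: the liver
#'   masks themselves.  Registration samples inside these; the liver
#'   masks are the accurate segmentations used for evaluation.
#' @param z_rotation_deg manual z-rotation pre-alignment in degrees
#'   (patient rotation between acquisitions; 0 when the patient was not
#'   rotated).
#' @return object of class \code{liver_case}.
#' @export
liver_case <- function(D, F, N = NULL, liver_mask_D, liver_mask_F,
                       tumor_mask_D = NULL, landmarks_D = NULL,
                       landmarks_F = NULL, seeds = NULL,
                       reg_mask_D = NULL, reg_mask_F = NULL,
                       z_rotation_deg = 0) {
  stopifnot(inherits(D, "image3d"), inherits(F, "image3d"))
  if (!same_geometry(D, liver_mask_D))
    stop("liver_mask_D must share D's geometry")
  if (!same_geometry(F, liver_mask_F))
    stop("liver_mask_F must share F's geometry")
  if (!is.null(tumor_mask_D) && !same_geometry(D, tumor_mask_D))
    stop("tumor_mask_D must share D's geometry")
  if (!is.null(N) && dim(N$voxels)[3] >= dim(F$voxels)[3])
    stop("N must have fewer slices than F")
  if (!is.null(landmarks_D)) landmarks_D <- as_point_matrix(landmarks_D)
  if (!is.null(landmarks_F)) landmarks_F <- as_point_matrix(landmarks_F)
  if (!is.null(landmarks_D) && !is.null(landmarks_F) &&
      nrow(landmarks_D) != nrow(landmarks_F))
    stop("landmark sets must be paired (equal counts)")
  if (!is.null(reg_mask_D) && !same_geometry(D, reg_mask_D))
    stop("reg_mask_D must share D's geometry")
  if (!is.null(reg_mask_F) && !same_geometry(F, reg_mask_F))
    stop("reg_mask_F must share F's geometry")
  structure(list(D = D, F = F, N = N, liver_mask_D = liver_mask_D,
                 liver_mask_F = liver_mask_F, tumor_mask_D = tumor_mask_D,
                 landmarks_D = landmarks_D, landmarks_F = landmarks_F,
                 seeds = seeds,
                 reg_mask_D = reg_mask_D %||% liver_mask_D,
                 reg_mask_F = reg_mask_F %||% liver_mask_F,
                 z_rotation_deg = z_rotation_deg),
            class = "liver_case")
}

#' Initial rigid alignment from liver masks
#'
#' The manual z-rotation pre-alignment composed with the translation
#' aligning the centers of mass of the two liver masks: the returned
#' rigid transform maps the fixed mask's center of mass exactly onto the
#' moving mask's, rotating by \code{z_rotation_deg} about it.
#'
#' @param fixed_mask,moving_mask nonempty binary masks.
#' @param z_rotation_deg rotation about the cranio-caudal axis, degrees.
#' @return a \code{rigid_transform} (fixed-domain to moving-domain).
#' @export
initialize_alignment <- function(fixed_mask, moving_mask, z_rotation_deg = 0) {
  cf <- center_of_mass(fixed_mask)
  cm <- center_of_mass(moving_mask)
  rigid_transform(rotation_z(z_rotation_deg), translation = cm - cf,
                  center = cf)
}

#' Stage 1: non-rigid registration of D to F
#'
#' Masked multiresolution B-spline registration of the diagnostic image
#' to the full intra-operative image (fixed = F), initialized by
#' \code{\link{initialize_alignment}} with the case's z-rotation angle,
#' without rigidity regularization.
#'
#' @param case a \code{\link{liver_case}}.
#' @param control a \code{\link{reg_control}}.
#' @param use_init use the center-of-mass/z-rotation initialization
#'   (TRUE; FALSE exposes the uninitialized behavior).
#' @return object of class \code{pipeline_result} holding \code{T_DF}
#'   (a \code{reg_fit}; its transform maps F-domain points into D).
#' @export
stage1 <- function(case, control = reg_control(), use_init = TRUE) {
  init <- if (use_init)
    initialize_alignment(case$reg_mask_F, case$reg_mask_D,
                         case$z_rotation_deg)
  else NULL
  fit <- multires_register(case$F, case$D, case$reg_mask_F, init = init,
                           control = control,
                           moving_mask = case$liver_mask_D)
  structure(list(T_DF = fit, cmask = NULL, T_FN = NULL, T_DN = NULL,
                 control = control),
            class = "pipeline_result")
}

#' User-guided refinement of the stage-1 registration
#'
#' Builds the coefficient mask from the user's seed points (1x1x1 cm
#' dilation) and re-runs the complete multiresolution registration with
#' the local rigidity penalty enabled, replacing T_DF.  The failed
#' unregularized deformation is deliberately discarded rather than
#' warm-started.
#'
#' @param case a \code{\link{liver_case}}.
#' @param prior result of \code{\link{stage1}}.
#' @param seeds n x 3 matrix of seed world points in D (>= 1).
#' @param control a \code{\link{reg_control}}.
#' @param weights a \code{\link{rigidity_weights}}.
#' @param kernel_mm,feather_mm coefficient-mask construction parameters.
#' @return updated \code{pipeline_result} with the refined T_DF and the
#'   coefficient mask.
#' @export
refine <- function(case, prior, seeds, control = reg_control(),
                   weights = rigidity_weights(), kernel_mm = c(10, 10, 10),
                   feather_mm = 5) {
  if (is.null(prior$T_DF)) stop("run stage1 before refinement")
  if (is.null(seeds) || nrow(as_point_matrix(seeds)) < 1)
    stop("refinement needs at least one seed point")
  if (length(weights$alpha) != length(control$grid_spacings_mm))
    weights$alpha <- rep_len(weights$alpha, length(control$grid_spacings_mm))
  cmask <- build_coefficient_mask(seeds, case$D, kernel_mm, feather_mm)
  init <- initialize_alignment(case$reg_mask_F, case$reg_mask_D,
                               case$z_rotation_deg)
  fit <- multires_register(case$F, case$D, case$reg_mask_F, init = init,
                           control = control,
                           rigidity = list(cmask = cmask, weights = weights),
                           moving_mask = case$liver_mask_D)
  prior$T_DF <- fit
  prior$cmask <- cmask
  prior$weights <- weights
  prior
}

#' Stage 2: registration into the needle image
#'
#' Rigidly registers the full intra-operative image F to the needle
#' image N (fixed = N) with the stochastic MI metric, then non-rigidly
#' registers D to N starting from the composition T_DF o T_FN, using
#' only the finest grid resolutions (the composition is already close).
#' The stage-1 coefficient mask, when present, is carried into this
#' registration.  The fixed mask on N is the stage-1-mapped D liver mask
#' restricted to N's field of view.
#'
#' @param case a \code{\link{liver_case}} with N present.
#' @param prior result of \code{\link{stage1}} (and optionally
#'   \code{\link{refine}}).
#' @param control a \code{\link{reg_control}}.
#' @param skip_nonrigid only concatenate T_DF o T_FN (the
#'   "concatenated only" baseline) instead of running the final
#'   non-rigid registration.
#' @param n_fine_levels how many of the finest grid levels to use for
#'   the final non-rigid registration (default 2).
#' @return updated \code{pipeline_result} with \code{T_FN} and
#'   \code{T_DN}.
#' @export
stage2 <- function(case, prior, control = reg_control(),
                   skip_nonrigid = FALSE, n_fine_levels = 2) {
  if (is.null(prior$T_DF)) stop("run stage1 before stage2")
  if (is.null(case$N)) stop("case has no needle image N")
  if (dim(case$N$voxels)[3] < 3) stop("needle slab too thin (< 3 slices)")
  # liver region on N: stage-1-mapped D liver mask, cropped to N's FOV
  mapped_F <- map_annotation(case$liver_mask_D, prior$T_DF$transform, case$F)
  mask_N <- map_annotation(mapped_F, NULL, case$N)
  if (sum(mask_N$voxels) < 10)
    stop("mapped liver mask barely intersects the needle slab")
  fitFN <- rigid_register(case$N, case$F, mask_N, control = control,
                          moving_mask = case$liver_mask_F)
  prior$T_FN <- fitFN
  init <- composite_transform(prior$T_DF$transform, fitFN$transform)
  if (skip_nonrigid) {
    prior$T_DN <- list(transform = init, concatenated_only = TRUE)
    return(prior)
  }
  nlev <- length(control$grid_spacings_mm)
  keep <- seq(max(1, nlev - n_fine_levels + 1), nlev)
  fine <- control
  fine$grid_spacings_mm <- control$grid_spacings_mm[keep]
  fine$pyramid_factors <- control$pyramid_factors[keep]
  rigidity <- NULL
  if (!is.null(prior$cmask)) {
    w <- prior$weights
    w$alpha <- w$alpha[keep]
    rigidity <- list(cmask = prior$cmask, weights = w)
  }
  fitDN <- multires_register(case$N, case$D, mask_N, init = init,
                             control = fine, rigidity = rigidity,
                             moving_mask = case$liver_mask_D)
  prior$T_DN <- fitDN
  prior
}

#' Map an annotation mask through a transform
#'
#' Nearest-neighbor resampling of a binary mask (e.g. the tumor
#' segmented on D) onto a target geometry through a transform that maps
#' target-domain points into the mask's domain.
#'
#' @param mask_on_D binary \code{image3d}.
#' @param transform transform from the target domain into the mask's
#'   domain (\code{NULL} = identity).
#' @param target target image or geometry.
#' @return binary \code{image3d} on the target geometry.
#' @export
map_annotation <- function(mask_on_D, transform, target) {
  out <- resample(mask_on_D, transform, target, "nearest", 0)
  out$voxels <- (out$voxels > 0.5) * 1
  out
}

#' Evaluate a pipeline stage against reference data
#'
#' Maps the D liver mask with the estimated transform and compares it to
#' the reference mask (Dice, mean surface distance), adds the landmark
#' distance when the case carries landmark pairs, and classifies
#' success.
#'
#' @param case a \code{\link{liver_case}}.
#' @param result a \code{pipeline_result}.
#' @param stage \code{"stage1"} (against F) or \code{"stage2"} (against
#'   a supplied reference mask on N).
#' @param reference_mask_N truth liver mask on N (stage 2 only;
#'   phantoms provide it).
#' @return an \code{\link{evaluation_report}}.
#' @export
evaluate_stage <- function(case, result, stage = c("stage1", "stage2"),
                           reference_mask_N = NULL) {
  stage <- match.arg(stage)
  if (stage == "stage1") {
    tr <- result$T_DF$transform
    mapped <- map_annotation(case$liver_mask_D, tr, case$F)
    evaluation_report(mapped, case$liver_mask_F,
                      landmarks_ref = case$landmarks_D,
                      landmarks_fixed = case$landmarks_F,
                      transform = tr)
  } else {
    if (is.null(result$T_DN)) stop("stage2 has not been run")
    if (is.null(reference_mask_N)) stop("stage-2 evaluation needs a reference mask on N")
    tr <- result$T_DN$transform
    mapped <- map_annotation(case$liver_mask_D, tr, case$N)
    evaluation_report(mapped, reference_mask_N)
  }
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  T_DF:", if (is.null(x$T_DF)) "not run" else
    if (isTRUE(x$T_DF$rigidity)) "refined (rigidity-penalized)" else "stage-1", "\n")
  cat("  T_FN:", if (is.null(x$T_FN)) "not run" else "rigid", "\n")
  cat("  T_DN:", if (is.null(x$T_DN)) "not run" else
    if (isTRUE(x$T_DN$concatenated_only)) "concatenated only" else "non-rigid", "\n")
  invisible(x)
}
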