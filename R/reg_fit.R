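#' @export
print.reg_fit <- function(x, ...) {
  cat("<reg_fit> ")
  if (inherits(x, "reg_fit_rigid")) cat("rigid mutual-information registration\n")
  else cat(sprintf("B-spline registration, final grid spacing (%g, %g, %g) mm%s\n",
                   x$ffd$control_spacing[1], x$ffd$control_spacing[2],
                   x$ffd$control_spacing[3],
                   if (isTRUE(x$rigidity)) ", rigidity-penalized" else ""))
  nlev <- length(unique(x$trace$level))
  cat(sprintf("  %d resolution level(s), %d iterations total\n",
              nlev, nrow(x$trace)))
  last <- x$trace[x$trace$level == max(x$trace$level), ]
  cat(sprintf("  final cost estimate %.4f (level-start %.4f)\n",
              mean(utils::tail(last$cost, 25)),
              mean(utils::head(last$cost, 25))))
  invisible(x)
}

#' @export
summary.reg_fit <- function(object, ...) {
  tr <- object$trace
  by_lev <- do.call(rbind, lapply(split(tr, tr$level), function(d) {
    data.frame(level = d$level[1], iterations = nrow(d),
               cost_start = mean(utils::head(d$cost, 25)),
               cost_end = mean(utils::tail(d$cost, 25)),
               max_dropped = max(d$dropped))
  }))
  structure(list(levels = by_lev, rigidity = object$rigidity,
                 fit = object), class = "summary.reg_fit")
}

#' @export
print.summary.reg_fit <- function(x, ...) {
  print(x$fit)
  cat("  per-level smoothed cost (first/last 25 iterations):\n")
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' @export
coef.reg_fit <- function(object, ...) {
  if (is.null(object$ffd)) object$par else as.numeric(object$ffd$coefficients)
}

#' Apply a fitted registration to points
#'
#' Maps fixed-domain world points into the moving image domain with the
#' estimated transform.
#'
#' @param object a \code{reg_fit}.
#' @param newdata n x 3 matrix of world points mm.
#' @param ... unused.
#' @export
predict.reg_fit <- function(object, newdata, ...) {
  transform_points(object$transform, newdata, extrapolate = TRUE)
}

#' Landmark residuals of a fitted registration
#'
#' Per-pair Euclidean distances |a_i - T(b_i)| between moving-image
#' landmarks and transformed fixed-image landmarks.
#'
#' @param object a \code{reg_fit}.
#' @param fixed_points landmarks in the fixed image (n x 3 mm).
#' @param moving_points corresponding landmarks in the moving image.
#' @param ... unused.
#' @export
residuals.reg_fit <- function(object, fixed_points, moving_points, ...) {
  a <- as_point_matrix(moving_points)
  tb <- predict(object, fixed_points)
  sqrt(rowSums((a - tb)^2))
}

#' Plot the optimization trace of a registration
#'
#' Per-iteration stochastic cost estimate, colored by resolution level.
#'
#' @param x a \code{reg_fit}.
#' @param ... passed to \code{plot}.
#' @importFrom graphics lines legend
#' @export
plot.reg_fit <- function(x, ...) {
  tr <- x$trace
  tr$global <- seq_len(nrow(tr))
  plot(tr$global, tr$cost, type = "n", xlab = "iteration",
       ylab = "cost (-MI + penalty)", ...)
  levs <- sort(unique(tr$level))
  for (l in levs) {
    d <- tr[tr$level == l, ]
    lines(d$global, d$cost, col = l)
  }
  legend("topright", legend = paste("level", levs), col = levs, lty = 1,
         bty = "n")
  invisible(x)
}
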