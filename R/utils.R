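#' @useDynLib liverreg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd coef predict
#' @importFrom utils modifyList
NULL

# Run code under a fixed RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a master seed and a stream label; keeps all
# randomness attributable to one master seed (and below 2^31).
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 1000003 + as.numeric(p)) %% 2147483629
  as.integer(h)
}

vec3 <- function(x, what = "value") {
  x <- as.numeric(x)
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3) stop(what, " must have length 1 or 3", call. = FALSE)
  x
}

as_point_matrix <- function(pts) {
  if (is.null(dim(pts))) {
    if (length(pts) != 3) stop("points must be a length-3 vector or an n x 3 matrix")
    pts <- matrix(pts, 1, 3)
  }
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop("points must have 3 columns")
  storage.mode(pts) <- "double"
  pts
}

is_orthonormal <- function(R, tol = 1e-6) {
  max(abs(crossprod(R) - diag(3))) < tol
}
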