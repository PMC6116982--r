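#' Knot set for a cubic B-spline
#'
#' Bundles interior knot positions with the domain boundary. The boundary
#' knots are clamped (repeated degree + 1 times) when the basis is built, so
#' the spline interpolates its end coefficients at the boundary.
#'
#' @param interior sorted vector of interior knot positions (may be empty).
#' @param boundary length-2 numeric, the domain \code{c(lower, upper)}.
#' @return An object of class \code{knot_set} with elements \code{interior},
#'   \code{boundary} and \code{k} (number of interior knots).
#' @export
knot_set <- function(interior = numeric(0), boundary) {
  interior <- as.numeric(interior)
  if (length(boundary) != 2 || !is.numeric(boundary) ||
      boundary[1] >= boundary[2])
    stop("boundary must be c(lower, upper) with lower < upper", call. = FALSE)
  if (is.unsorted(interior))
    stop("interior knots must be sorted ascending", call. = FALSE)
  if (length(interior) &&
      (min(interior) <= boundary[1] || max(interior) >= boundary[2]))
    stop("interior knots must lie strictly inside the boundary", call. = FALSE)
  structure(list(interior = interior, boundary = as.numeric(boundary),
                 k = length(interior)),
            class = "knot_set")
}

# spline degree is fixed: cubic splines throughout
SPLINE_DEGREE <- 3L

#' B-spline basis matrix
#'
#' Evaluates the cubic B-spline basis at \code{x} using the Cox-de Boor
#' recursion with clamped boundary knots, yielding an
#' \code{n x (k + 4)} matrix whose rows sum to one (partition of unity).
#'
#' @param x evaluation points, all within the knot-set boundary.
#' @param knots a \code{\link{knot_set}}.
#' @param degree spline degree; fixed at 3.
#' @return Numeric matrix, \code{length(x)} rows, \code{knots$k + degree + 1}
#'   columns.
#' @export
basis_matrix <- function(x, knots, degree = SPLINE_DEGREE) {
  stopifnot(inherits(knots, "knot_set"))
  lo <- knots$boundary[1]; hi <- knots$boundary[2]
  if (any(x < lo) || any(x > hi))
    stop("evaluation points outside the spline boundary; widen the boundary",
         call. = FALSE)
  full <- c(rep(lo, degree + 1), knots$interior, rep(hi, degree + 1))
  splines::splineDesign(full, x, ord = degree + 1, outer.ok = FALSE)
}

#' Evaluate a spline
#'
#' @param x evaluation points.
#' @param knots a \code{\link{knot_set}}.
#' @param beta coefficient vector of length \code{knots$k + 4}.
#' @return \code{B(x) \%*\% beta} as a numeric vector.
#' @export
evaluate_spline <- function(x, knots, beta) {
  B <- basis_matrix(x, knots)
  if (ncol(B) != length(beta))
    stop(sprintf("coefficient length %d does not match basis dimension %d",
                 length(beta), ncol(B)), call. = FALSE)
  drop(B %*% beta)
}

#' Test whether spline coefficients are non-decreasing
#'
#' Non-decreasing B-spline coefficients imply a non-decreasing spline, the
#' property that makes the fitted bias function invertible for calibration.
#' A tolerance of -1e-12 absorbs floating-point ties.
#'
#' @param beta coefficient vector.
#' @return \code{TRUE} iff all successive differences are \eqn{\ge} -1e-12.
#' @export
is_monotone <- function(beta) {
  length(beta) < 2 || all(diff(beta) >= -1e-12)
}

# Boundary for latent-scale splines: observed range padded by a fraction of
# the range, so typical latent MH proposals stay inside the domain.
latent_boundary <- function(x, pad = 0.05) {
  r <- range(x)
  w <- diff(r)
  if (w <= 0) w <- max(abs(r[1]), 1)
  c(r[1] - pad * w, r[2] + pad * w)
}
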