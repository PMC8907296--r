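#' Equidistant clamped knot sequence for a predictor
#'
#' Boundary knots are placed at the minimum and maximum of the observed
#' values (the convention used throughout this package) and repeated to
#' multiplicity `degree + 1` (clamped), with `nInterior` equally spaced
#' interior knots strictly between them.
#'
#' @param x observed predictor values (>= 2 distinct values).
#' @param nInterior number of interior knots (>= 0).
#' @param degree spline polynomial degree.
#' @return full clamped knot vector.
#' @export
equidistantKnots <- function(x, nInterior = 2L, degree = 2L) {
  if (!is.numeric(x) || anyNA(x)) stop("x must be numeric without NAs")
  lo <- min(x); hi <- max(x)
  if (lo == hi) stop("degenerate predictor: x is constant")
  if (nInterior < 0L) stop("nInterior must be >= 0")
  interior <- if (nInterior > 0L)
    lo + (hi - lo) * seq_len(nInterior) / (nInterior + 1) else numeric()
  c(rep(lo, degree + 1L), interior, rep(hi, degree + 1L))
}

#' Construct a clamped B-spline basis
#'
#' @param x observed predictor values used to place the boundary knots, or
#'   `NULL` if `knots` is given directly.
#' @param nInterior number of equidistant interior knots.
#' @param degree polynomial degree (2 = quadratic, the package default; 3 =
#'   cubic).
#' @param knots optional full clamped knot vector overriding `x`/`nInterior`.
#' @return a [SplineBasis-class].
#' @examples
#' b <- splineBasis(c(0, 10), nInterior = 2)
#' rowSums(evalBasis(b, c(2.5, 7)))  # partition of unity
#' @export
splineBasis <- function(x = NULL, nInterior = 2L, degree = 2L, knots = NULL) {
  degree <- as.integer(degree)
  if (is.null(knots)) {
    if (is.null(x)) stop("either x or knots must be given")
    knots <- equidistantKnots(x, nInterior, degree)
  }
  q <- length(knots) - degree - 1L
  boundary <- range(knots)
  interior <- knots[knots > boundary[1] & knots < boundary[2]]
  new("SplineBasis", knots = as.numeric(knots), degree = degree,
      q = as.integer(q), boundary = boundary, interior = as.numeric(interior))
}

#' @rdname evalBasis
setMethod("evalBasis", "SplineBasis", function(object, x, deriv = 0L) {
  tol <- 1e-9 * max(1, diff(object@boundary))
  if (any(x < object@boundary[1] - tol | x > object@boundary[2] + tol))
    stop("evaluation point outside the boundary knots (no extrapolation)")
  x <- pmin(pmax(x, object@boundary[1]), object@boundary[2])
  if (deriv > object@degree)  # derivative of a lower-degree piecewise poly
    return(matrix(0, length(x), object@q))
  splines::splineDesign(object@knots, x, ord = object@degree + 1L,
                        derivs = rep(as.integer(deriv), length(x)))
})

#' @export
setMethod("show", "SplineBasis", function(object) {
  cat("SplineBasis: degree", object@degree, "(order", object@degree + 1L,
      "), q =", object@q, "basis functions\n")
  cat("  boundary knots:", format(object@boundary), "\n")
  cat("  interior knots:",
      if (length(object@interior)) format(object@interior) else "(none)", "\n")
})
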