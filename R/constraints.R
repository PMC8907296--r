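#' Monotonicity and concavity constraint matrices
#'
#' For a B-spline with coefficients `beta[1..q]`, monotone nondecrease is
#' implied by the first differences being nonnegative (`V beta >= 0`) and
#' concavity by the second differences being nonpositive (`W beta >= 0` with
#' `W` the negated second-difference matrix). When both are imposed, the
#' first `q - 2` monotonicity rows are redundant: nonpositive second
#' differences mean the first differences are nonincreasing, so requiring the
#' last one (`beta[q] - beta[q-1] >= 0`) forces all earlier ones to be
#' nonnegative too. `Z` stacks that last row of `V` over `W`.
#'
#' @param q number of basis functions (>= 3).
#' @return list with matrices `V` ((q-1) x q), `W` ((q-2) x q) and `Z`
#'   ((q-1) x q).
#' @export
constraintMatrices <- function(q) {
  q <- as.integer(q)
  if (q < 3L) stop("insufficient basis: q >= 3 required for shape constraints")
  V <- matrix(0, q - 1L, q)
  for (j in seq_len(q - 1L)) V[j, j:(j + 1L)] <- c(-1, 1)
  W <- matrix(0, q - 2L, q)
  for (j in seq_len(q - 2L)) W[j, j:(j + 2L)] <- c(-1, 2, -1)
  Z <- rbind(V[q - 1L, ], W)
  list(V = V, W = W, Z = Z)
}

# Affine transform absorbing zero-derivative equality rows E beta = 0.
# Each row eliminates one coefficient, pivoting on its last entry of largest
# usable magnitude; returns the q x (q - nrow(E)) matrix A with beta = A
# betaStar, identity rows for the kept coefficients.
.affineFromEqualities <- function(E, q) {
  keep <- seq_len(q)
  A <- diag(q)
  for (i in seq_len(nrow(E))) {
    c_red <- as.vector(E[i, , drop = FALSE] %*% A)  # constraint in current coords
    nz <- which(abs(c_red) > 1e-10 * max(abs(c_red), 1))
    if (!length(nz))
      stop("singular saturation constraint: derivative row is identically zero")
    piv <- nz[length(nz)]
    p <- ncol(A)
    Ei <- diag(p)[, -piv, drop = FALSE]
    Ei[piv, ] <- -c_red[-piv] / c_red[piv]
    A <- A %*% Ei
  }
  A
}

#' Saturation affine transform
#'
#' Encodes a steady state at the right boundary knot: the spline's first
#' derivative there is pinned to zero, which for the last two basis functions
#' (the only ones with nonzero slope at the right boundary) reads
#' `beta[q] = -dB[xR, q-1]/dB[xR, q] * beta[q-1]`. The returned matrix `A`
#' (q x (q-1)) is the identity on the first q-1 coefficients with that ratio
#' in its last row, so any `beta = A %*% betaStar` has zero slope at the
#' boundary.
#'
#' @param basis a [SplineBasis-class].
#' @return q x (q-1) matrix.
#' @export
saturationTransform <- function(basis) {
  xR <- basis@boundary[2]
  d1 <- evalBasis(basis, xR, deriv = 1L)
  q <- basis@q
  if (abs(d1[q]) < 1e-12)
    stop("singular saturation constraint: dB[xR, q] = 0")
  A <- diag(q)[, -q, drop = FALSE]
  A[q, q - 1L] <- -d1[q - 1L] / d1[q]
  A
}

#' Knot-spacing-aware shape constraint rows
#'
#' On evenly spaced knots, monotonicity and concavity of a B-spline reduce to
#' sign conditions on the raw first and second coefficient differences (the
#' `V`/`W` patterns). With clamped boundary knots the spacing is not even:
#' the slope attached to coefficient `j` is
#' `(beta_j - beta_{j-1}) / (k_{j+degree+1} - k_j)` (positive denominators),
#' so monotonicity is still the raw first differences, but concavity is the
#' condition that these *scaled* slopes are nonincreasing. These rows reduce
#' exactly to `W` when the knots are evenly spaced, and the constraint
#' reduction still applies: nonincreasing slopes plus a nonnegative last
#' slope force every slope to be nonnegative.
#'
#' @param basis a [SplineBasis-class].
#' @return list with `V` (first differences), `W` (scaled-slope differences)
#'   and `Z` (last row of `V` stacked over `W`).
#' @export
basisConstraintMatrices <- function(basis) {
  q <- basis@q
  if (q < 3L) stop("insufficient basis: q >= 3 required for shape constraints")
  kn <- basis@knots
  deg <- basis@degree
  gap <- vapply(2:q, function(j) kn[j + deg + 1L] - kn[j], 0)
  if (any(gap <= 0)) stop("degenerate knot spacing")
  V <- constraintMatrices(q)$V
  W <- matrix(0, q - 2L, q)
  for (j in 3:q) {
    # slope_{j-1} - slope_j >= 0
    W[j - 2L, j - 2L] <- -1 / gap[j - 2L]
    W[j - 2L, j - 1L] <- 1 / gap[j - 2L] + 1 / gap[j - 1L]
    W[j - 2L, j] <- -1 / gap[j - 1L]
  }
  list(V = V, W = W, Z = rbind(V[q - 1L, ], W))
}

#' Build the full constraint set for one spline block
#'
#' Combines the monotonicity/concavity inequality matrix with the saturation
#' equality rows (absorbed into the affine transform `A`) and precomputes the
#' reduced inequality matrix `M = ineq %*% A`, dropping rows that become
#' identically zero (for a clamped quadratic basis the last monotonicity row
#' is annihilated by the right-boundary saturation constraint).
#'
#' A decreasing direction is handled downstream by negating the block's
#' design columns, so the constraint cone itself is always the
#' increasing/concave one.
#'
#' `saturationAt = "secondRight"` pins the derivative to zero at both ends of
#' the final knot interval; a quadratic spline's derivative is linear within
#' the interval, so this makes the fit constant there (a steady state from
#' the second-right distinct knot onwards).
#'
#' @param basis a [SplineBasis-class].
#' @param direction `"increasing"` or `"decreasing"`.
#' @param monotone,concave,saturation shape flags.
#' @param saturationAt `"right"` or `"secondRight"`.
#' @return a [ShapeConstraints-class].
#' @export
shapeConstraints <- function(basis, direction = "increasing", monotone = TRUE,
                             concave = TRUE, saturation = TRUE,
                             saturationAt = "right") {
  q <- basis@q
  cm <- basisConstraintMatrices(basis)
  ineq <- if (monotone && concave) cm$Z
          else if (monotone) cm$V
          else if (concave) cm$W
          else matrix(0, 0L, q)
  eq <- matrix(0, 0L, q)
  if (saturation) {
    if (saturationAt == "right") {
      eq <- evalBasis(basis, basis@boundary[2], deriv = 1L)
    } else if (saturationAt == "secondRight") {
      distinct <- unique(basis@knots)
      if (length(distinct) < 3L)
        stop("secondRight saturation needs at least one interior knot")
      xSecond <- distinct[length(distinct) - 1L]
      eq <- rbind(evalBasis(basis, xSecond, deriv = 1L),
                  evalBasis(basis, basis@boundary[2], deriv = 1L))
    } else stop("unknown saturationAt: ", saturationAt)
  }
  A <- if (nrow(eq)) .affineFromEqualities(eq, q) else diag(q)
  M <- ineq %*% A
  if (nrow(M)) {
    live <- apply(abs(M), 1L, max) > 1e-10
    M <- M[live, , drop = FALSE]
  }
  new("ShapeConstraints", monotone = monotone, concave = concave,
      saturation = saturation, direction = direction,
      saturationAt = if (saturation) saturationAt else "none",
      ineq = ineq, eq = eq, A = A, M = M, q = as.integer(q),
      qReduced = as.integer(ncol(A)))
}

#' @export
setMethod("show", "ShapeConstraints", function(object) {
  cat("ShapeConstraints:",
      if (object@monotone) paste0("monotone ", object@direction) else NULL,
      if (object@concave) "concave" else NULL,
      if (object@saturation) paste0("saturating(", object@saturationAt, ")") else NULL,
      "\n")
  cat("  q =", object@q, "-> reduced", object@qReduced,
      "coefficients;", nrow(object@M), "inequality rows\n")
})
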