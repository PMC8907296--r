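#' Declare a shape-constrained model term for one confounder
#'
#' The default shape encodes the detection mechanics of integration-site
#' sequencing: more DNA, more vector copies or more reads can only reveal
#' more clonal diversity (monotone nondecreasing), with diminishing returns
#' (concave) and a plateau once everything present has been detected
#' (saturation: zero slope at the right boundary knot, on by default).
#'
#' @param variable metadata column name (e.g. `"dna_ng"`, `"vcn"`, `"sd"`,
#'   `"ps"`).
#' @param nInterior number of equidistant interior knots.
#' @param degree `"quadratic"`/`"cubic"` or the polynomial degree as integer.
#' @param saturation impose the right-boundary steady state.
#' @param direction `"increasing"` or `"decreasing"` (decreasing is fitted as
#'   the negated increasing problem, keeping concave-in-the-modeled-direction
#'   semantics).
#' @param monotone,concave shape flags.
#' @param saturationAt `"right"` or `"secondRight"` (flat on the final knot
#'   interval).
#' @return an [ScsTerm-class].
#' @export
scsTerm <- function(variable, nInterior = 2L, degree = "quadratic",
                    saturation = TRUE, direction = "increasing",
                    monotone = TRUE, concave = TRUE, saturationAt = "right") {
  if (is.character(degree))
    degree <- switch(degree, quadratic = 2L, cubic = 3L,
                     stop("degree must be 'quadratic', 'cubic' or an integer"))
  new("ScsTerm", variable = variable, nInterior = as.integer(nInterior),
      degree = as.integer(degree), monotone = monotone, concave = concave,
      saturation = saturation, direction = direction,
      saturationAt = saturationAt)
}

#' Declare lineage-by-vector time-decay factors of interest
#'
#' @param lineage,vector,time metadata column names for the cell lineage, the
#'   viral vector/treatment label and the time point.
#' @param nInterior interior knots for each decay spline.
#' @param degree polynomial degree.
#' @return an [ScsDecayFactors-class].
#' @export
scsDecayFactors <- function(lineage = "lineage", vector = "vector",
                            time = "time", nInterior = 2L, degree = 2L) {
  new("ScsDecayFactors", lineage = lineage, vector = vector, time = time,
      nInterior = as.integer(nInterior), degree = as.integer(degree))
}

#' Specify the log-entropy model
#'
#' @param confounders list of [ScsTerm-class] objects (the candidate
#'   technical confounders entering as shape-constrained splines).
#' @param factors `NULL` (no factors of interest, the in-vitro configuration),
#'   an [ScsDecayFactors-class] (the longitudinal mouse configuration), or a
#'   plain numeric matrix of unconstrained columns.
#' @return an [ScsModel-class].
#' @examples
#' scsModel(list(scsTerm("dna_ng", 1), scsTerm("vcn", 1), scsTerm("sd", 2)))
#' @export
scsModel <- function(confounders = list(), factors = NULL) {
  new("ScsModel", confounders = confounders, factors = factors)
}

#' Direction handling for a constraint set
#'
#' Increasing terms are fitted as-is. Decreasing terms are fitted by negating
#' the block's design columns while keeping the increasing-shape cone, so the
#' reduced constraint matrix and affine transform are unchanged and only a
#' sign flag differs; double negation is the identity.
#'
#' @param constraints a [ShapeConstraints-class].
#' @return list with `M`, `A` and `sign` (+1 increasing, -1 decreasing).
#' @export
applyDirection <- function(constraints) {
  list(M = constraints@M, A = constraints@A,
       sign = if (constraints@direction == "decreasing") -1 else +1)
}

# Build one shape-constrained block: anchored, saturation-absorbed design
# columns plus the reduced inequality matrix. Anchoring drops the first
# reduced coefficient (beta_1 = 0): the clamped basis spans constants, so the
# block's level is unidentified next to the global intercept; anchoring pins
# each effect to zero at its left boundary knot and keeps beta >= 0 implied
# by monotonicity.
.buildBlock <- function(x, term, role, rowsSel = NULL, n = length(x),
                        label = term@variable) {
  basis <- splineBasis(x, nInterior = term@nInterior, degree = term@degree)
  cons <- shapeConstraints(basis, direction = term@direction,
                           monotone = term@monotone, concave = term@concave,
                           saturation = term@saturation,
                           saturationAt = term@saturationAt)
  dir <- applyDirection(cons)
  pRed <- cons@qReduced
  if (pRed < 2L) stop("block '", label, "' has no free coefficients")
  D <- diag(pRed)[, -1L, drop = FALSE]           # anchor: drop first coef
  map <- dir$sign * (cons@A %*% D)               # q x (pRed - 1)
  M <- cons@M %*% D
  if (nrow(M)) {
    live <- apply(abs(M), 1L, max) > 1e-10
    M <- M[live, , drop = FALSE]
  }
  B <- evalBasis(basis, x)
  Xb <- matrix(0, n, ncol(map))
  vals <- B %*% map
  if (is.null(rowsSel)) Xb <- vals else Xb[rowsSel, ] <- vals
  colnames(Xb) <- paste0(label, ".s", seq_len(ncol(map)))
  list(label = label, role = role, basis = basis, constraints = cons,
       sign = dir$sign, map = map, M = M, X = Xb, rowsSel = rowsSel)
}

#' Assemble the design of the log-entropy model
#'
#' Builds the response `log(h)`, the intercept, one anchored
#' shape-constrained spline block per confounder, the factor block (empty,
#' unconstrained matrix, or block-diagonal lineage-by-vector decay splines
#' with shared per-lineage intercepts and no vector-specific intercept), and
#' the global inequality matrix `G` such that the feasible set is
#' `G theta >= 0`.
#'
#' @param entropyTable data.frame from [buildEntropyTable()] (columns
#'   `sample_id`, `h`, `log_h`, metadata).
#' @param model an [ScsModel-class].
#' @return an internal design bundle (list).
#' @export
buildDesign <- function(entropyTable, model) {
  et <- entropyTable
  if (is.null(et$log_h)) et$log_h <- log(et$h)
  if (anyNA(et$log_h) || any(!is.finite(et$log_h)))
    stop("log-entropy contains non-finite values")
  n <- nrow(et)
  y <- et$log_h
  blocks <- list()
  for (term in model@confounders) {
    v <- term@variable
    if (is.null(et[[v]]))
      stop("missing metadata column '", v, "'")
    x <- et[[v]]
    bad <- !is.finite(x)
    if (any(bad))
      stop("non-finite metadata: sample '", et$sample_id[which(bad)[1]],
           "', field '", v, "'")
    blocks[[length(blocks) + 1L]] <- .buildBlock(x, term, role = "confounder")
  }
  Xf <- NULL
  if (!is.null(model@factors)) {
    f <- model@factors
    if (is.matrix(f)) {
      if (nrow(f) != n) stop("factor matrix must have one row per sample")
      Xf <- f
      if (is.null(colnames(Xf))) colnames(Xf) <- paste0("f", seq_len(ncol(Xf)))
    } else if (is(f, "ScsDecayFactors")) {
      lin <- et[[f@lineage]]; vec <- et[[f@vector]]; tm <- et[[f@time]]
      if (is.null(lin) || is.null(vec) || is.null(tm))
        stop("factor metadata columns missing: need '", f@lineage, "', '",
             f@vector, "', '", f@time, "'")
      lineages <- unique(lin)
      for (l in lineages) {
        sel_l <- lin == l
        # reference coding: the first lineage's level is carried by the
        # global intercept, so its indicator is dropped
        if (l != lineages[1L]) {
          ic <- matrix(as.numeric(sel_l), n, 1L,
                       dimnames = list(NULL, paste0("lineage.", l)))
          Xf <- cbind(Xf, ic)
        }
        for (v in unique(vec[sel_l])) {
          sel <- sel_l & vec == v
          term <- new("ScsTerm", variable = f@time,
                      nInterior = f@nInterior, degree = f@degree,
                      monotone = TRUE, concave = FALSE, saturation = TRUE,
                      direction = "decreasing", saturationAt = "secondRight")
          blocks[[length(blocks) + 1L]] <-
            .buildBlock(tm[sel], term, role = "factor", rowsSel = sel, n = n,
                        label = paste0("decay.", l, ".", v))
        }
      }
    } else stop("unsupported factors specification")
  }
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  colIdx <- list()
  for (b in blocks) {
    colIdx[[b$label]] <- ncol(X) + seq_len(ncol(b$X))
    X <- cbind(X, b$X)
  }
  factorCols <- integer()
  if (!is.null(Xf)) {
    factorCols <- ncol(X) + seq_len(ncol(Xf))
    X <- cbind(X, Xf)
  }
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("rank-deficient design after transforms (", p, " columns, rank ",
         qr(X)$rank, ")")
  G <- matrix(0, 0L, p)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (nrow(b$M)) {
      Gi <- matrix(0, nrow(b$M), p)
      Gi[, colIdx[[b$label]]] <- b$M
      G <- rbind(G, Gi)
    }
  }
  confCols <- unlist(colIdx[vapply(blocks, function(b) b$role, "") == "confounder"],
                     use.names = FALSE)
  list(y = y, X = X, G = G, blocks = blocks, colIdx = colIdx,
       confCols = if (is.null(confCols)) integer() else confCols,
       factorCols = c(factorCols,
                      unlist(colIdx[vapply(blocks, function(b) b$role, "") == "factor"],
                             use.names = FALSE)),
       n = n, p = p)
}
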