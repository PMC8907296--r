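# Orthonormal basis of the null space of a constraint matrix (p columns).
.nullspace <- function(Amat, p) {
  if (is.null(Amat) || nrow(Amat) == 0L) return(diag(p))
  s <- svd(Amat, nu = 0, nv = p)
  tol <- max(dim(Amat)) * .Machine$double.eps * max(s$d, 0)
  r <- sum(s$d > tol)
  if (r >= p) return(matrix(0, p, 0L))
  s$v[, (r + 1L):p, drop = FALSE]
}

.rankOf <- function(Amat) {
  if (is.null(Amat) || nrow(Amat) == 0L) return(0L)
  qr(Amat)$rank
}

#' Restricted least squares over a polyhedral cone
#'
#' Minimizes `||y - X theta||^2` subject to `G theta >= 0` by quadratic
#' programming (active-set solver), followed by a KKT polishing step: the
#' active constraints at the numerical solution are treated as equalities and
#' the fit is re-solved exactly on that face, accepted when feasible and at
#' least as good. This makes solutions reproducible to near machine precision
#' and the landing face unambiguous.
#'
#' @param y response vector.
#' @param X design matrix (full column rank).
#' @param G inequality matrix (may have zero rows = unconstrained).
#' @param activeTol relative tolerance for declaring a constraint active.
#' @return list with `theta`, `active` (active row indices), `d` (cone-face
#'   dimension = p - rank of the active rows), and `kkt` diagnostics
#'   (stationarity residual, worst constraint violation).
#' @export
restrictedLS <- function(y, X, G, activeTol = 1e-8) {
  p <- ncol(X)
  H <- crossprod(X)
  cvec <- as.vector(crossprod(X, y))
  if (is.null(G)) G <- matrix(0, 0L, p)
  if (nrow(G) == 0L) {
    theta <- as.vector(solve(H, cvec))
    return(list(theta = theta, active = integer(),
                d = as.integer(p),
                kkt = c(stationarity = 0, violation = 0)))
  }
  qp <- pracma::quadprog(H, -cvec, A = -G, b = rep(0, nrow(G)))
  theta <- as.vector(qp$xmin)
  obj <- function(th) sum((y - X %*% th)^2)
  slack <- as.vector(G %*% theta)
  scl <- max(1, max(abs(slack)))
  act <- which(slack < activeTol * scl)
  # polish: exact solve on the face spanned by the active constraints
  if (length(act)) {
    N <- .nullspace(G[act, , drop = FALSE], p)
    cand <- if (ncol(N) == 0L) rep(0, p) else
      as.vector(N %*% solve(crossprod(N, H %*% N), crossprod(N, cvec)))
    if (min(G %*% cand) >= -1e-9 * scl && obj(cand) <= obj(theta) + 1e-10)
      theta <- cand
  } else {
    cand <- as.vector(solve(H, cvec))
    if (min(G %*% cand) >= -1e-9 * scl) theta <- cand
  }
  slack <- as.vector(G %*% theta)
  act <- which(slack < activeTol * max(1, max(abs(slack))))
  d <- p - .rankOf(G[act, , drop = FALSE])
  grad <- as.vector(H %*% theta - cvec)
  stat <- if (length(act)) {
    lam <- qr.solve(t(G[act, , drop = FALSE]), -grad)
    max(abs(grad + as.vector(t(G[act, , drop = FALSE]) %*% lam)))
  } else max(abs(grad))
  list(theta = theta, active = as.integer(act), d = as.integer(d),
       kkt = c(stationarity = stat, violation = max(0, -min(slack))))
}

#' Residual variance of a cone-projection fit
#'
#' `sigma2 = RSS / (n - 1.5 d)`: the divisor discounts the effective
#' dimension `d` of the cone face by the factor 1.5 to account for the
#' data-dependent face selection.
#'
#' @param residuals residual vector.
#' @param n number of observations.
#' @param d cone-face dimension.
#' @export
estimateVariance <- function(residuals, n, d) {
  if (n <= 1.5 * d) stop("n must exceed 1.5 * d to estimate the variance")
  sum(residuals^2) / (n - 1.5 * d)
}

#' Fit the shape-constrained log-entropy model
#'
#' Solves the restricted least-squares problem: log-entropies regressed on an
#' intercept, monotone-increasing/concave (optionally saturating) spline
#' effects of each confounder, and any factors of interest, subject to the
#' cone constraints, via quadratic programming with KKT polishing.
#'
#' @param entropyTable data.frame from [buildEntropyTable()].
#' @param model an [ScsModel-class].
#' @param activeTol tolerance for active-constraint identification.
#' @return an [ScsFit-class].
#' @examples
#' set.seed(1)
#' et <- simulateEntropyDataset(n = 60, seed = 1)
#' fit <- fitScs(et, scsModel(list(scsTerm("dna_ng", 1), scsTerm("sd", 2))))
#' faceDim(fit); head(rescaleEntropies(fit))
#' @export
fitScs <- function(entropyTable, model, activeTol = 1e-8) {
  des <- buildDesign(entropyTable, model)
  if (des$n <= des$p)
    stop("need more observations (", des$n, ") than parameters (", des$p, ")")
  sol <- restrictedLS(des$y, des$X, des$G, activeTol = activeTol)
  if (sol$kkt["stationarity"] > 1e-6 * max(1, max(abs(crossprod(des$X, des$y)))))
    warning("QP solution has large KKT residual: ",
            format(sol$kkt["stationarity"]))
  theta <- setNames(sol$theta, colnames(des$X))
  fitted <- as.vector(des$X %*% sol$theta)
  resid <- des$y - fitted
  sigma2 <- estimateVariance(resid, des$n, sol$d)
  new("ScsFit", model = model, design = des, theta = theta,
      beta0 = unname(theta["(Intercept)"]), fitted = fitted,
      residuals = resid, sigma2 = sigma2, d = sol$d,
      activeRows = sol$active, kkt = sol$kkt, entropyTable = entropyTable)
}

#' Landing face of the constraint cone
#'
#' Identifies the inequality constraints active at the solution (within
#' tolerance), an orthonormal basis of the directions spanning the face, and
#' its dimension `d` (the effective parameter count).
#'
#' @param fit an [ScsFit-class].
#' @return list with `active` (row indices), `span` (p x d basis matrix) and
#'   `d`.
#' @export
coneFace <- function(fit) {
  G <- fit@design$G
  act <- fit@activeRows
  N <- .nullspace(G[act, , drop = FALSE], fit@design$p)
  list(active = act, span = N, d = fit@d)
}

#' Evaluate a fitted spline effect on new predictor values
#'
#' @param fit an [ScsFit-class].
#' @param label block label (a confounder's variable name, or
#'   `"decay.<lineage>.<vector>"` for factor decays).
#' @param x evaluation points inside the block's boundary knots.
#' @return numeric vector of effect values (anchored at zero at the left
#'   boundary knot).
#' @export
termEffect <- function(fit, label, x) {
  blocks <- fit@design$blocks
  labs <- vapply(blocks, function(b) b$label, "")
  i <- match(label, labs)
  if (is.na(i)) stop("unknown term '", label, "'; available: ",
                     paste(labs, collapse = ", "))
  b <- blocks[[i]]
  cols <- fit@design$colIdx[[label]]
  as.vector(evalBasis(b$basis, x) %*% b$map %*% fit@theta[cols])
}

# Summed confounder contribution C betaC per sample.
.confEffect <- function(fit) {
  cc <- fit@design$confCols
  if (!length(cc)) return(rep(0, fit@design$n))
  as.vector(fit@design$X[, cc, drop = FALSE] %*% fit@theta[cc])
}

#' @rdname faceDim
setMethod("faceDim", "ScsFit", function(object) object@d)

#' @rdname sigmaSq
setMethod("sigmaSq", "ScsFit", function(object) object@sigma2)

#' @describeIn ScsFit coefficient vector in reduced coordinates.
#' @export
setMethod("coef", "ScsFit", function(object, ...) object@theta)

#' @describeIn ScsFit fitted log-entropies.
#' @export
setMethod("fitted", "ScsFit", function(object, ...) object@fitted)

#' @describeIn ScsFit residual log-entropies.
#' @export
setMethod("residuals", "ScsFit", function(object, ...) object@residuals)

#' @export
setMethod("show", "ScsFit", function(object) {
  cat("ScsFit: shape-constrained log-entropy model\n")
  cat("  n =", object@design$n, "samples,", object@design$p,
      "parameters, cone-face dimension d =", object@d, "\n")
  labs <- vapply(object@design$blocks, function(b) b$label, "")
  roles <- vapply(object@design$blocks, function(b) b$role, "")
  cat("  confounders:", paste(labs[roles == "confounder"], collapse = ", "),
      "\n")
  if (any(roles == "factor"))
    cat("  factor decays:", paste(labs[roles == "factor"], collapse = ", "),
        "\n")
  cat("  sigma^2 =", format(object@sigma2, digits = 4),
      " (RSS/(n - 1.5 d));", length(object@activeRows),
      "active constraints\n")
})
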