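#' Evaluate a spline basis (or one of its derivatives)
#'
#' @param object a [SplineBasis-class].
#' @param x evaluation points, inside the boundary knots (no extrapolation).
#' @param deriv derivative order (0 = basis values).
#' @return numeric matrix, `length(x)` rows by `q` columns.
#' @export
setGeneric("evalBasis", function(object, x, deriv = 0L) standardGeneric("evalBasis"))

#' Assemble a per-sample Shannon entropy table
#'
#' Computes the Shannon entropy of each sample's clone-abundance vector and
#' binds it to the sample metadata. Samples whose entropy is zero (a single
#' clone) cannot enter the log-linear model; by default they are dropped with
#' a warning rather than pseudocounted.
#'
#' @param x an [ISAbundanceExperiment-class] or a list of abundance samples
#'   (each a list with `sample_id`, `abundances` and metadata fields).
#' @param dropNonpositive drop samples with zero entropy (warn) instead of
#'   raising an error.
#' @return `data.frame` with columns `sample_id`, `h`, `log_h` and the
#'   metadata columns.
#' @export
setGeneric("buildEntropyTable",
           function(x, dropNonpositive = TRUE) standardGeneric("buildEntropyTable"))

#' Confounder-free rescaled entropies
#'
#' Removes the fitted (or model-averaged) confounder spline effects from the
#' observed entropies: `h_res = exp(log h - C betaC)`. Factor-of-interest
#' terms are deliberately left in: they carry the biology.
#'
#' @param object an [ScsFit-class] or [ScsModelAverage-class].
#' @return numeric vector of strictly positive rescaled entropies, aligned to
#'   the fitted entropy table.
#' @export
setGeneric("rescaleEntropies", function(object) standardGeneric("rescaleEntropies"))

#' Cone-face dimension of a constrained fit
#'
#' The number of linearly independent directions spanning the face of the
#' constraint cone on which the projection of the response lands; used as the
#' effective parameter count in AICc/BIC and the variance divisor.
#' @param object an [ScsFit-class].
#' @export
setGeneric("faceDim", function(object) standardGeneric("faceDim"))

#' Residual variance estimate of a constrained fit
#'
#' RSS / (n - 1.5 d), with d the cone-face dimension.
#' @param object an [ScsFit-class].
#' @export
setGeneric("sigmaSq", function(object) standardGeneric("sigmaSq"))

#' Corrected Akaike information criterion of a fit
#'
#' Gaussian log-likelihood with profiled variance, penalized by the effective
#' parameter count p = d (the cone-face dimension):
#' `AICc = -2 log L + 2p + 2p(p+1)/(n-p)`.
#' @param object an [ScsFit-class].
#' @export
setGeneric("aicc", function(object) standardGeneric("aicc"))

#' Bayesian information criterion of a fit
#'
#' `BIC = -2 log L + p log n` with p = d, used for model-averaging weights.
#' @param object an [ScsFit-class].
#' @export
setGeneric("bic", function(object) standardGeneric("bic"))
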