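#' @import methods
#' @importFrom stats coef fitted residuals rnorm rpois rlnorm runif qnorm rmultinom
#'   cor.test sd setNames quantile
NULL

#' Clamped B-spline basis
#'
#' Holds a clamped (boundary knots repeated to multiplicity degree + 1) knot
#' sequence and polynomial degree, and evaluates basis functions and their
#' derivatives by the Cox--de Boor recursion (via [splines::splineDesign()]).
#'
#' @slot knots full nondecreasing knot vector, boundary knots repeated
#'   `degree + 1` times.
#' @slot degree polynomial degree (2 = quadratic, the default in this package).
#' @slot q number of basis functions, `length(knots) - degree - 1`.
#' @slot boundary the two boundary knots.
#' @slot interior interior knots (possibly empty).
#' @export
setClass("SplineBasis",
  representation(knots = "numeric", degree = "integer", q = "integer",
                 boundary = "numeric", interior = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@knots)) msg <- c(msg, "knots must be nondecreasing")
    if (object@degree < 0L) msg <- c(msg, "degree must be >= 0")
    if (object@q != length(object@knots) - object@degree - 1L)
      msg <- c(msg, "q must equal length(knots) - degree - 1")
    if (length(object@boundary) != 2L || object@boundary[1] >= object@boundary[2])
      msg <- c(msg, "boundary must be two increasing values")
    if (length(msg)) msg else TRUE
  })

#' Shape constraints for one spline block
#'
#' Inequality matrix on the full coefficient vector (monotonicity first
#' differences, negated concavity second differences, or their non-redundant
#' stack), zero-derivative equality rows encoding saturation, and the affine
#' transform `A` that absorbs the equalities, so that `beta = A %*% betaStar`.
#'
#' @slot monotone,concave,saturation logicals describing the cone.
#' @slot direction `"increasing"` or `"decreasing"` (decreasing is fitted by
#'   negating the block's design columns).
#' @slot saturationAt `"right"` (zero slope at the right boundary knot),
#'   `"secondRight"` (flat on the whole final knot interval) or `"none"`.
#' @slot ineq inequality matrix on full coefficients (rows x q).
#' @slot eq equality rows (zero-derivative constraints), 0 or more rows x q.
#' @slot A affine transform, q x qReduced.
#' @slot M reduced inequality matrix `ineq %*% A` with identically-zero rows
#'   dropped.
#' @slot q,qReduced full and reduced coefficient counts.
#' @export
setClass("ShapeConstraints",
  representation(monotone = "logical", concave = "logical",
                 saturation = "logical", direction = "character",
                 saturationAt = "character", ineq = "matrix", eq = "matrix",
                 A = "matrix", M = "matrix", q = "integer",
                 qReduced = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@direction %in% c("increasing", "decreasing"))
      msg <- c(msg, "direction must be 'increasing' or 'decreasing'")
    if (ncol(object@A) != object@qReduced || nrow(object@A) != object@q)
      msg <- c(msg, "A must be q x qReduced")
    if (length(msg)) msg else TRUE
  })

#' One shape-constrained model term
#'
#' Declares how one confounder (or factor decay) enters the model: number of
#' interior knots, spline degree, shape direction and saturation behaviour.
#'
#' @slot variable metadata column name.
#' @slot nInterior number of equidistant interior knots.
#' @slot degree polynomial degree.
#' @slot monotone,concave,saturation shape flags.
#' @slot direction `"increasing"` or `"decreasing"`.
#' @slot saturationAt where the zero-derivative constraint is pinned.
#' @export
setClass("ScsTerm",
  representation(variable = "character", nInterior = "integer",
                 degree = "integer", monotone = "logical", concave = "logical",
                 saturation = "logical", direction = "character",
                 saturationAt = "character"))

#' Factor-of-interest specification: lineage x vector time-decay splines
#'
#' Block-diagonal factor design over cell lineages: per lineage a shared
#' intercept column plus, for each vector/treatment, a monotone-decreasing
#' quadratic time spline held flat on the final knot interval (the study stops
#' when the last pooled mouse dies, so no further entropy change is modelled).
#' The vector-specific intercept is zero by construction: both decay splines
#' are anchored at zero at the earliest time point, so all arms share the
#' lineage's baseline diversity.
#'
#' @slot lineage,vector,time metadata column names.
#' @slot nInterior,degree spline settings for the decay splines.
#' @export
setClass("ScsDecayFactors",
  representation(lineage = "character", vector = "character",
                 time = "character", nInterior = "integer", degree = "integer"))

#' Model specification: confounder terms plus optional factors of interest
#'
#' @slot confounders list of [ScsTerm-class] objects, one per candidate
#'   technical confounder.
#' @slot factors `NULL`, an [ScsDecayFactors-class] specification, or a plain
#'   numeric matrix of unconstrained columns (one row per sample).
#' @export
setClass("ScsModel",
  representation(confounders = "list", factors = "ANY"),
  validity = function(object) {
    msg <- character()
    if (!length(object@confounders) && is.null(object@factors))
      msg <- c(msg, "model needs at least one confounder or factor")
    if (length(object@confounders) &&
        !all(vapply(object@confounders, is, TRUE, "ScsTerm")))
      msg <- c(msg, "confounders must be ScsTerm objects")
    nm <- vapply(object@confounders, function(t) t@variable, "")
    if (anyDuplicated(nm)) msg <- c(msg, "duplicate confounder variables")
    if (length(msg)) msg else TRUE
  })

#' Restricted-least-squares fit of the log-entropy model
#'
#' Result of projecting the log-entropy vector onto the polyhedral cone of
#' shape-constrained spline effects. Besides estimates and residuals it keeps
#' the active constraint set and the dimension `d` of the cone face the
#' projection lands on, which acts as the effective parameter count.
#'
#' @slot model the [ScsModel-class] fitted.
#' @slot design internal design bundle (design matrix, per-block transforms,
#'   global constraint matrix).
#' @slot theta solution in reduced coordinates (named).
#' @slot beta0 intercept.
#' @slot fitted,residuals fitted values and residuals on the log scale.
#' @slot sigma2 variance estimate RSS / (n - 1.5 d).
#' @slot d cone-face dimension.
#' @slot activeRows indices of active inequality rows.
#' @slot kkt KKT diagnostics (stationarity residual, max constraint violation).
#' @slot entropyTable the data the model was fitted to.
#' @export
setClass("ScsFit",
  representation(model = "ScsModel", design = "list", theta = "numeric",
                 beta0 = "numeric", fitted = "numeric", residuals = "numeric",
                 sigma2 = "numeric", d = "integer", activeRows = "integer",
                 kkt = "numeric", entropyTable = "data.frame"))

#' Frequentist model average over confounder subsets
#'
#' @slot models per-model summary (subset, face dimension d, AICc, BIC,
#'   weight).
#' @slot weights BIC weights, summing to one.
#' @slot betaFma averaged coefficients in the full layout (absent blocks
#'   zero-embedded).
#' @slot inclusionProbs marginal confounder inclusion probabilities.
#' @slot fits the underlying [ScsFit-class] objects.
#' @slot confEffectAvg weight-averaged confounder effect per sample (the
#'   model-averaged `C %*% betaC` used for rescaling).
#' @export
setClass("ScsModelAverage",
  representation(models = "data.frame", weights = "numeric",
                 betaFma = "numeric", inclusionProbs = "numeric",
                 fits = "list", confEffectAvg = "numeric"),
  validity = function(object) {
    if (abs(sum(object@weights) - 1) > 1e-8) "weights must sum to 1" else TRUE
  })

#' Integration-site abundance experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay `counts`
#' holds clone abundances (integration sites x samples) and whose `colData`
#' carries the per-sample technical metadata (`dna_ng`, `vcn`, `sd`, and
#' optionally `ps`, `time`, `lineage`, `vector`).
#'
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("ISAbundanceExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "assay 'counts' is required")
    else {
      cnt <- SummarizedExperiment::assay(object, "counts")
      if (any(cnt < 0, na.rm = TRUE)) msg <- c(msg, "abundances must be nonnegative")
      if (anyDuplicated(colnames(cnt))) msg <- c(msg, "duplicate sample ids")
    }
    if (length(msg)) msg else TRUE
  })
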