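#' All nonempty confounder subsets
#'
#' Candidate models for selection/averaging: every nonempty subset of the
#' candidate confounders (`2^K - 1` models), each always paired with the
#' fixed factor block.
#'
#' @param candidates character vector of K confounder names (K >= 1).
#' @return list of character vectors, ordered by subset size then position.
#' @examples
#' length(enumerateConfounderModels(c("dna_ng", "vcn", "ps", "sd")))  # 15
#' @export
enumerateConfounderModels <- function(candidates) {
  K <- length(candidates)
  if (K < 1L) stop("need at least one candidate confounder")
  out <- list()
  for (k in seq_len(K))
    out <- c(out, utils::combn(candidates, k, simplify = FALSE))
  out
}

# Gaussian log-likelihood with the variance profiled at its MLE.
.profileLogLik <- function(fit) {
  n <- fit@design$n
  rss <- sum(fit@residuals^2)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

#' @rdname aicc
setMethod("aicc", "ScsFit", function(object) {
  n <- object@design$n
  p <- object@d
  if (n <= p) stop("AICc requires n > p (p = cone-face dimension d)")
  -2 * .profileLogLik(object) + 2 * p + 2 * p * (p + 1) / (n - p)
})

#' @rdname bic
setMethod("bic", "ScsFit", function(object) {
  n <- object@design$n
  p <- object@d
  if (n <= p) stop("BIC requires n > p")
  -2 * .profileLogLik(object) + p * log(n)
})

#' BIC model-averaging weights
#'
#' `lambda_l = exp(-BIC_l/2) / sum_j exp(-BIC_j/2)`, computed with
#' max-subtraction for numerical stability. Invariant to adding a constant
#' to all BIC values.
#'
#' @param bics numeric vector of BIC values.
#' @export
bicWeights <- function(bics) {
  w <- exp(-(bics - min(bics)) / 2)
  w / sum(w)
}

#' Fit the model on every confounder subset
#'
#' @param entropyTable data.frame from [buildEntropyTable()].
#' @param model full [ScsModel-class]; its confounder list defines the
#'   candidates, its factor block is kept fixed in every candidate model.
#' @param subsets optional list of confounder-name subsets (defaults to all
#'   nonempty subsets).
#' @return named list of [ScsFit-class] objects, names like `"dna_ng+sd"`.
#' @export
fitConfounderSubsets <- function(entropyTable, model, subsets = NULL) {
  nm <- vapply(model@confounders, function(t) t@variable, "")
  if (is.null(subsets)) subsets <- enumerateConfounderModels(nm)
  fits <- lapply(subsets, function(s) {
    sub <- scsModel(model@confounders[match(s, nm)], factors = model@factors)
    fitScs(entropyTable, sub)
  })
  names(fits) <- vapply(subsets, paste, "", collapse = "+")
  fits
}

#' Frequentist model averaging over confounder subsets
#'
#' Fits all `2^K - 1` confounder-subset models (factors fixed), weights them
#' by `exp(-BIC/2)` (interpretable as approximate posterior model
#' probabilities under a uniform prior), averages the coefficients with
#' absent confounder blocks embedded as zero, and reports marginal
#' confounder inclusion probabilities.
#'
#' @inheritParams fitConfounderSubsets
#' @return an [ScsModelAverage-class].
#' @export
modelAverage <- function(entropyTable, model, subsets = NULL) {
  nm <- vapply(model@confounders, function(t) t@variable, "")
  if (is.null(subsets)) subsets <- enumerateConfounderModels(nm)
  fits <- fitConfounderSubsets(entropyTable, model, subsets)
  aiccs <- vapply(fits, aicc, 0)
  bics <- vapply(fits, bic, 0)
  lambda <- bicWeights(bics)
  # full coefficient layout from the union of all fitted columns
  full <- fitScs(entropyTable, model)
  layout <- names(full@theta)
  betaFma <- setNames(rep(0, length(layout)), layout)
  confAvg <- rep(0, nrow(entropyTable))
  for (l in seq_along(fits)) {
    th <- fits[[l]]@theta
    betaFma[names(th)] <- betaFma[names(th)] + lambda[l] * th
    confAvg <- confAvg + lambda[l] * .confEffect(fits[[l]])
  }
  incl <- vapply(nm, function(v)
    sum(lambda[vapply(subsets, function(s) v %in% s, TRUE)]), 0)
  models <- data.frame(
    subset = names(fits),
    d = vapply(fits, faceDim, 0L),
    aicc = aiccs, bic = bics, weight = lambda,
    row.names = NULL, stringsAsFactors = FALSE)
  new("ScsModelAverage", models = models, weights = unname(lambda),
      betaFma = betaFma, inclusionProbs = incl, fits = fits,
      confEffectAvg = confAvg)
}

#' @export
setMethod("show", "ScsModelAverage", function(object) {
  cat("ScsModelAverage:", nrow(object@models), "candidate models\n")
  top <- object@models[order(-object@models$weight), ][
    seq_len(min(5L, nrow(object@models))), ]
  cat("  top models by weight:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-24s w = %.3f  d = %d  BIC = %.1f\n",
                top$subset[i], top$weight[i], top$d[i], top$bic[i]))
  cat("  inclusion probabilities:",
      paste(sprintf("%s = %.3f", names(object@inclusionProbs),
                    object@inclusionProbs), collapse = ", "), "\n")
})
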