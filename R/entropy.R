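#' Shannon diversity index of a clone-abundance vector
#'
#' `h = -sum(p_i * log(p_i))` with `p_i = a_i / sum(a)`, natural logarithm.
#' Zero abundances contribute nothing (the limit `x log x -> 0`). In
#' integration-site studies `h` measures how many clones are present and how
#' evenly their abundances are distributed: the maximum `log(n)` is attained
#' only for a uniform distribution over `n` clones.
#'
#' @param abundances nonnegative numeric vector with at least one positive
#'   entry (raw clone counts or estimated abundances; any positive rescaling
#'   gives the same entropy).
#' @return nonnegative scalar.
#' @examples
#' shannonEntropy(c(1, 1, 1, 1))  # log(4)
#' shannonEntropy(5)              # 0: a single clone
#' @export
shannonEntropy <- function(abundances) {
  if (!is.numeric(abundances) || length(abundances) == 0L)
    stop("invalid abundance vector: must be a nonempty numeric vector")
  if (anyNA(abundances)) stop("invalid abundance vector: NA values")
  if (any(abundances < 0)) stop("invalid abundance vector: negative entries")
  tot <- sum(abundances)
  if (tot <= 0) stop("invalid abundance vector: all entries are zero")
  p <- abundances[abundances > 0] / tot
  -sum(p * log(p))
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `D_KL(p || q) = sum(p_i * log(p_i / q_i))`, natural logarithm. Shannon
#' entropy is its special case (up to sign) against the uniform reference:
#' `D_KL(p || uniform_n) = log(n) - h(p)`.
#'
#' @param p,q probability vectors of equal length summing to one; `q` may be
#'   zero only where `p` is zero.
#' @param tol tolerance for the sum-to-one check.
#' @return nonnegative scalar.
#' @export
klDivergence <- function(p, q, tol = 1e-8) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol)
    stop("p and q must each sum to 1")
  if (any(q == 0 & p > 0)) stop("support violation: q is zero where p is positive")
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

.entropyTableFromSamples <- function(samples, dropNonpositive) {
  if (!length(samples)) stop("empty sample list")
  meta_fields <- c("dna_ng", "vcn", "sd", "ps", "time", "lineage", "vector")
  present <- meta_fields[vapply(meta_fields, function(f)
    any(vapply(samples, function(s) !is.null(s[[f]]), TRUE)), TRUE)]
  rows <- lapply(samples, function(s) {
    h <- shannonEntropy(s$abundances)
    out <- data.frame(sample_id = s$sample_id, h = h,
                      log_h = if (h > 0) log(h) else NA_real_,
                      stringsAsFactors = FALSE)
    for (f in present) out[[f]] <- if (is.null(s[[f]])) NA else s[[f]]
    out
  })
  tab <- do.call(rbind, rows)
  zero <- tab$h <= 0
  if (any(zero)) {
    if (!dropNonpositive)
      stop("sample(s) with zero entropy (single clone): ",
           paste(tab$sample_id[zero], collapse = ", "))
    warning("dropping ", sum(zero), " sample(s) with zero entropy: ",
            paste(tab$sample_id[zero], collapse = ", "))
    tab <- tab[!zero, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no samples left after dropping zero-entropy samples")
  rownames(tab) <- NULL
  tab
}

#' @rdname buildEntropyTable
setMethod("buildEntropyTable", "list", function(x, dropNonpositive = TRUE) {
  .entropyTableFromSamples(x, dropNonpositive)
})

#' @rdname buildEntropyTable
setMethod("buildEntropyTable", "ISAbundanceExperiment",
  function(x, dropNonpositive = TRUE) {
    cnt <- SummarizedExperiment::assay(x, "counts")
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    samples <- lapply(seq_len(ncol(cnt)), function(j) {
      s <- list(sample_id = colnames(cnt)[j], abundances = cnt[, j])
      for (f in colnames(cd)) s[[f]] <- cd[j, f]
      s
    })
    .entropyTableFromSamples(samples, dropNonpositive)
  })
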