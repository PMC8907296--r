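.asCounts <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    warning("non-integer abundances rounded to integers for count-based normalization")
    counts <- round(counts)
  }
  as.integer(round(counts))
}

#' Rarefaction (RAR) of a count vector
#'
#' Repeatedly subsamples `target` reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]), computes the Shannon entropy of
#' each rarefied replicate and summarizes by the mean.
#'
#' @param counts nonnegative integer vector.
#' @param target rarefaction depth (<= `sum(counts)`).
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @param keepReplicates also return the rarefied count matrix (reps x
#'   species).
#' @return list with `entropy` (mean over replicates), `perReplicate`
#'   (entropy per replicate), `target`, `reps`, and (optionally)
#'   `replicates`.
#' @export
rarefyCounts <- function(counts, target, reps = 1000L, seed = NULL,
                         keepReplicates = FALSE) {
  counts <- .asCounts(counts)
  if (target > sum(counts)) stop("rarefaction target exceeds the total count")
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(counts, nrow = 1L)
  keep <- if (keepReplicates)
    matrix(0L, reps, length(counts)) else NULL
  per <- vapply(seq_len(reps), function(r) {
    # rrarefy warns (advisory only) when the smallest nonzero count is > 1
    sub <- suppressWarnings(vegan::rrarefy(m, target))
    if (keepReplicates) keep[r, ] <<- as.integer(sub)
    shannonEntropy(as.vector(sub))
  }, 0)
  out <- list(entropy = mean(per), perReplicate = per,
              target = as.integer(target), reps = as.integer(reps))
  if (keepReplicates) out$replicates <- keep
  out
}

#' Scaling with ranked subsampling (SRS) of a count vector
#'
#' Counts are scaled by `target / sum(counts)`; integer parts are kept and
#' the remaining deficit is filled by adding one count to the species ranked
#' by descending fractional part, ties broken uniformly at random. The
#' output always sums exactly to `target` and never inverts the rank order
#' of the input counts.
#'
#' @param counts nonnegative integer vector.
#' @param target normalization depth (<= `sum(counts)`).
#' @param seed RNG seed (used only to break fractional-part ties).
#' @return integer vector summing to `target`.
#' @export
srsCounts <- function(counts, target, seed = NULL) {
  counts <- .asCounts(counts)
  tot <- sum(counts)
  if (target > tot) stop("SRS target exceeds the total count")
  scaled <- counts * (target / tot)
  out <- floor(scaled)
  deficit <- target - sum(out)
  if (deficit > 0) {
    frac <- scaled - out
    if (!is.null(seed)) set.seed(seed)
    ord <- order(-frac, sample.int(length(frac)))  # random tie-break
    out[ord[seq_len(deficit)]] <- out[ord[seq_len(deficit)]] + 1L
  }
  as.integer(out)
}

#' Baseline rescaled entropies by rarefaction or ranked subsampling
#'
#' Applies RAR or SRS to every sample of an abundance matrix, normalizing to
#' the total count of the shallowest sample (the sample with the lowest
#' sequencing depth), and returns observed and normalized entropies.
#'
#' @param x an [ISAbundanceExperiment-class] or a counts matrix
#'   (integration sites x samples).
#' @param method `"rar"` or `"srs"`.
#' @param reps rarefaction replicates (RAR only).
#' @param seed RNG seed.
#' @param target optional normalization depth; defaults to the minimum
#'   sample total.
#' @return data.frame with columns `sample_id`, `h` (observed), `h_res`
#'   (normalized entropy) and `method`.
#' @export
baselineRescaledEntropies <- function(x, method = c("rar", "srs"),
                                      reps = 1000L, seed = NULL,
                                      target = NULL) {
  method <- match.arg(method)
  cnt <- if (is(x, "ISAbundanceExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  if (is.null(colnames(cnt))) colnames(cnt) <- paste0("S", seq_len(ncol(cnt)))
  totals <- colSums(cnt)
  if (is.null(target)) target <- min(totals)
  if (!is.null(seed)) set.seed(seed)
  hres <- vapply(seq_len(ncol(cnt)), function(j) {
    if (method == "rar")
      rarefyCounts(cnt[, j], target, reps = reps)$entropy
    else
      shannonEntropy(srsCounts(cnt[, j], target))
  }, 0)
  data.frame(sample_id = colnames(cnt),
             h = apply(cnt, 2L, shannonEntropy),
             h_res = hres, method = method,
             row.names = NULL, stringsAsFactors = FALSE)
}
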