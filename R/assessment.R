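#' Two-sided Spearman rank-correlation test
#'
#' Tests `H0: rho = 0` against `H1: rho != 0` with average-rank tie handling.
#' For n <= 9 without ties the p-value comes from the exact permutation
#' distribution; otherwise the t-approximation is used. Rank correlation is
#' preferred over Pearson here because confounder-entropy relationships are
#' monotone but typically nonlinear.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return one-row data.frame: `rho`, `p_value`, `n`, `method`
#'   (`"exact"`/`"approximate"`).
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 4L) stop("need at least 4 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: constant vector")
  hasTies <- anyDuplicated(x) || anyDuplicated(y)
  exact <- length(x) <= 9L && !hasTies
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", alternative = "two.sided",
             exact = exact))
  data.frame(rho = unname(ct$estimate), p_value = ct$p.value,
             n = length(x), method = if (exact) "exact" else "approximate",
             stringsAsFactors = FALSE)
}

#' Residual-confounding report across normalization methods
#'
#' For each (method, confounder) pair, the absolute Spearman correlation and
#' its two-sided p-value between the method's entropies and the confounder.
#' Each table must carry the confounder columns; the tested value is the
#' `h_res` column when present, the observed `h` otherwise (so the raw
#' observed entropies can be included as their own "method").
#'
#' @param entropyTables named list of data.frames (method -> table).
#' @param confounders character vector of confounder column names.
#' @return data.frame with columns `method`, `confounder`, `abs_rho`,
#'   `p_value`, `n`.
#' @export
residualConfoundingReport <- function(entropyTables, confounders) {
  if (is.null(names(entropyTables)) || any(names(entropyTables) == ""))
    stop("entropyTables must be a named list")
  out <- list()
  for (m in names(entropyTables)) {
    tab <- entropyTables[[m]]
    val <- if (!is.null(tab$h_res)) tab$h_res else tab$h
    if (is.null(val)) stop("table '", m, "' has neither h_res nor h")
    for (cf in confounders) {
      if (is.null(tab[[cf]]))
        stop("table '", m, "' lacks confounder column '", cf, "'")
      st <- spearmanTest(val, tab[[cf]])
      out[[length(out) + 1L]] <- data.frame(
        method = m, confounder = cf, abs_rho = abs(st$rho),
        p_value = st$p_value, n = st$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
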