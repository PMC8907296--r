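#' Construct an integration-site abundance experiment
#'
#' @param counts numeric matrix, rows = integration sites (identifiers
#'   `"chr:pos:strand"`), columns = samples.
#' @param sampleData data.frame of per-sample metadata, rownames (or a
#'   `sample_id` column) matching the count columns.
#' @return an [ISAbundanceExperiment-class].
#' @export
ISAbundanceExperiment <- function(counts, sampleData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sampleData))
    sampleData <- data.frame(row.names = colnames(counts))
  if (!is.null(sampleData$sample_id)) {
    rownames(sampleData) <- sampleData$sample_id
    sampleData$sample_id <- NULL
  }
  if (!is.null(colnames(counts))) {
    missing <- setdiff(colnames(counts), rownames(sampleData))
    if (length(missing) && ncol(sampleData))
      stop("metadata missing for sample(s): ", paste(missing, collapse = ", "))
    if (ncol(sampleData)) sampleData <- sampleData[colnames(counts), , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sampleData))
  new("ISAbundanceExperiment", se)
}

.isIdPattern <- "^[A-Za-z0-9_.]+:[0-9]+:[+-]$"

#' Read an IS abundance matrix (and optional metadata) from TSV
#'
#' The abundance file is tab-separated with a header row; the first column
#' holds integration-site identifiers `"chr:pos:strand"` (1-based position),
#' remaining columns per-sample abundances. The metadata file is keyed by
#' `sample_id`. When depth metadata (`sd`) is present, per-sample totals are
#' checked against it and a mismatch warns (abundances may be estimated
#' rather than raw reads).
#'
#' @param path abundance TSV path.
#' @param metadataPath optional metadata TSV path.
#' @return an [ISAbundanceExperiment-class].
#' @export
readAbundanceMatrix <- function(path, metadataPath = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("abundance matrix needs an id column plus samples")
  ids <- as.character(tab[[1L]])
  bad <- !grepl(.isIdPattern, ids)
  if (any(bad))
    stop("malformed IS identifier(s): ", paste(utils::head(ids[bad], 3), collapse = ", "))
  if (anyDuplicated(colnames(tab)[-1L]))
    stop("duplicate sample column(s) in abundance matrix")
  cnt <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(cnt)) stop("abundances must be numeric")
  if (any(cnt < 0)) stop("negative abundance values")
  rownames(cnt) <- ids
  meta <- NULL
  if (!is.null(metadataPath)) {
    meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
    if (is.null(meta$sample_id)) stop("metadata must have a sample_id column")
    if (!is.null(meta$sd)) {
      tot <- colSums(cnt)[meta$sample_id]
      off <- is.finite(meta$sd) & abs(tot - meta$sd) > 0.5
      if (any(off, na.rm = TRUE))
        warning("per-sample totals differ from declared sd for: ",
                paste(meta$sample_id[which(off)], collapse = ", "))
    }
  }
  ISAbundanceExperiment(cnt, meta)
}

#' Write an IS abundance matrix (and its metadata) to TSV
#'
#' @param x an [ISAbundanceExperiment-class].
#' @param path abundance TSV path.
#' @param metadataPath optional metadata TSV path.
#' @export
writeAbundanceMatrix <- function(x, path, metadataPath = NULL) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  out <- data.frame(IS = rownames(cnt), cnt, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath)) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd <- data.frame(sample_id = rownames(cd), cd, check.names = FALSE)
    utils::write.table(cd, metadataPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
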