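#' Read and validate a run configuration (YAML)
#'
#' @param path YAML file. Recognized keys: `abundance`, `metadata` (TSV
#'   paths), `method` (`scs`/`rar`/`srs`), `seed`, `out`, `model` (with
#'   `confounders`: list of `{variable, interior_knots, degree, saturation,
#'   direction}`, optional `factors`: `{lineage, vector, time,
#'   interior_knots}`), `selection` (`enable`), `ci` (`alpha`, `n_sims`,
#'   `terms`), `rar_replicates`.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as parsed from YAML).
#' @export
validateRunConfig <- function(cfg) {
  cfg$method <- cfg$method %||% "scs"
  if (!cfg$method %in% c("scs", "rar", "srs"))
    stop("method must be one of scs, rar, srs")
  ci <- cfg$ci %||% list()
  ci$alpha <- ci$alpha %||% 0.05
  ci$n_sims <- ci$n_sims %||% 1000L
  if (ci$alpha <= 0 || ci$alpha >= 1) stop("ci alpha must be in (0, 1)")
  cfg$ci <- ci
  if (cfg$method == "scs") {
    if (is.null(cfg$model$confounders) || !length(cfg$model$confounders))
      stop("scs method needs model$confounders")
    for (tc in cfg$model$confounders) {
      if (is.null(tc$variable)) stop("each confounder needs a variable name")
      if (!is.null(tc$interior_knots) && tc$interior_knots < 0)
        stop("interior_knots must be >= 0")
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an [ScsModel-class] from a config subtree
#'
#' @param modelCfg the `model` entry of a run config.
#' @return an [ScsModel-class].
#' @export
modelFromConfig <- function(modelCfg) {
  terms <- lapply(modelCfg$confounders, function(tc)
    scsTerm(tc$variable,
            nInterior = tc$interior_knots %||% 2L,
            degree = tc$degree %||% "quadratic",
            saturation = tc$saturation %||% TRUE,
            direction = tc$direction %||% "increasing"))
  factors <- NULL
  if (!is.null(modelCfg$factors)) {
    fc <- modelCfg$factors
    factors <- scsDecayFactors(lineage = fc$lineage %||% "lineage",
                               vector = fc$vector %||% "vector",
                               time = fc$time %||% "time",
                               nInterior = fc$interior_knots %||% 2L)
  }
  scsModel(terms, factors = factors)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full normalization workflow
#'
#' entropy -> (model selection/averaging ->) fit -> rescale -> assess, or a
#' competitor normalization (`rar`/`srs`) that skips the fitting stages.
#' Writes TSV outputs plus a machine-readable JSON run manifest (seed,
#' config, versions) to the output directory.
#'
#' @param config config list (see [readRunConfig()]) or a YAML path.
#' @param seed overrides the config seed.
#' @param outDir overrides the config output directory.
#' @return invisible list with the in-memory results (`entropy`, and per
#'   method: `fit`/`average`/`baseline`, `rescaled`, `assessment`).
#' @export
runPipeline <- function(config, seed = NULL, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  seed <- seed %||% config$seed %||% 1L
  outDir <- outDir %||% config$out %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ise <- .stage("read", readAbundanceMatrix(config$abundance, config$metadata))
  et <- .stage("entropy", buildEntropyTable(ise))
  utils::write.table(et, file.path(outDir, "entropy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res <- list(entropy = et)
  if (config$method == "scs") {
    model <- .stage("config", modelFromConfig(config$model))
    if (isTRUE(config$selection$enable)) {
      avg <- .stage("select", modelAverage(et, model))
      utils::write.table(avg@models, file.path(outDir, "models.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(confounder = names(avg@inclusionProbs),
                   inclusion_prob = avg@inclusionProbs),
        file.path(outDir, "inclusion.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      hres <- .stage("rescale", rescaleEntropies(avg))
      coefs <- avg@betaFma
      res$average <- avg
    } else {
      fit <- .stage("fit", fitScs(et, model))
      hres <- .stage("rescale", rescaleEntropies(fit))
      coefs <- coef(fit)
      res$fit <- fit
    }
    utils::write.table(
      data.frame(coefficient = names(coefs), estimate = unname(coefs)),
      file.path(outDir, "coefficients.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  } else {
    bl <- .stage("normalize", baselineRescaledEntropies(
      ise, method = config$method, reps = config$rar_replicates %||% 1000L,
      seed = seed))
    hres <- setNames(bl$h_res, bl$sample_id)[et$sample_id]
    res$baseline <- bl
  }
  rescaled <- data.frame(sample_id = et$sample_id, h = et$h,
                         h_res = unname(hres[et$sample_id]))
  utils::write.table(rescaled, file.path(outDir, "rescaled.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$rescaled <- rescaled
  confNames <- if (config$method == "scs")
    vapply(config$model$confounders, function(tc) tc$variable, "")
  else intersect(c("dna_ng", "vcn", "sd", "ps"), colnames(et))
  asTab <- et
  asTab$h_res <- rescaled$h_res
  report <- .stage("assess", residualConfoundingReport(
    list(observed = et, rescaled = asTab), confNames))
  utils::write.table(report, file.path(outDir, "assessment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$assessment <- report
  manifest <- list(seed = seed, method = config$method, config = config,
                   package = as.character(utils::packageVersion("scsEntropy")),
                   r_version = R.version.string,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
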