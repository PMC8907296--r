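#' @rdname rescaleEntropies
setMethod("rescaleEntropies", "ScsFit", function(object) {
  hres <- exp(object@design$y - .confEffect(object))
  names(hres) <- object@entropyTable$sample_id
  hres
})

#' @rdname rescaleEntropies
setMethod("rescaleEntropies", "ScsModelAverage", function(object) {
  fit1 <- object@fits[[1L]]
  hres <- exp(fit1@design$y - object@confEffectAvg)
  names(hres) <- fit1@entropyTable$sample_id
  hres
})
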