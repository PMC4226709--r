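#' @include AllGenerics.R
NULL

#' @rdname quantileNormalize
setMethod("quantileNormalize", "matrix", function(x) {
  .assert(ncol(x) >= 2, "quantile normalization needs at least 2 samples")
  .assert(all(is.finite(x)), "expression values must be finite")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
setMethod("quantileNormalize", "UlmExperiment", function(x) {
  assay(x) <- quantileNormalize(assay(x))
  x
})
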