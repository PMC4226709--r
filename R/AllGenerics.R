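#' @include AllClasses.R
NULL

#' Accessors for CoexMatrix objects
#'
#' `corMatrix()` returns the Pearson coefficient matrix, `triMatrix()` the
#' trichotomized \{-1, 0, +1\} matrix, `corCutoff()` the |r| threshold,
#' `undefinedCount()` the number of cells left undefined by zero-variance
#' features, and `triCounts()` the full positive/negative/none/undefined
#' tally (which always sums to `nrow * ncol`).
#'
#' @param x a [CoexMatrix-class] object.
#' @return `corMatrix()` and `triMatrix()` return matrices; `corCutoff()`
#'   and `undefinedCount()` single numbers; `triCounts()` a named integer
#'   vector.
#' @aliases corMatrix triMatrix corCutoff undefinedCount triCounts
#' @name CoexMatrix-accessors
NULL

#' @rdname CoexMatrix-accessors
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname CoexMatrix-accessors
#' @export
setGeneric("triMatrix", function(x) standardGeneric("triMatrix"))

#' @rdname CoexMatrix-accessors
#' @export
setGeneric("corCutoff", function(x) standardGeneric("corCutoff"))

#' @rdname CoexMatrix-accessors
#' @export
setGeneric("undefinedCount", function(x) standardGeneric("undefinedCount"))

#' @rdname CoexMatrix-accessors
#' @export
setGeneric("triCounts", function(x) standardGeneric("triCounts"))

#' @rdname CoexMatrix-accessors
setMethod("corMatrix", "CoexMatrix", function(x) x@r)

#' @rdname CoexMatrix-accessors
setMethod("triMatrix", "CoexMatrix", function(x) x@tri)

#' @rdname CoexMatrix-accessors
setMethod("corCutoff", "CoexMatrix", function(x) x@cutoff)

#' @rdname CoexMatrix-accessors
setMethod("undefinedCount", "CoexMatrix", function(x) {
  sum(is.na(x@r))
})

#' @rdname CoexMatrix-accessors
setMethod("triCounts", "CoexMatrix", function(x) {
  tri <- x@tri
  c(
    positive = sum(tri == 1L, na.rm = TRUE),
    negative = sum(tri == -1L, na.rm = TRUE),
    none = sum(tri == 0L, na.rm = TRUE),
    undefined = sum(is.na(tri))
  )
})

#' Quantile normalization
#'
#' Forces every sample (column) to share the identical sorted value
#' multiset: each rank is replaced by the mean across samples of the values
#' at that rank, with tied values receiving the mean of their tied rank
#' means. Backed by [limma::normalizeQuantiles()]. The operation is
#' idempotent up to floating point.
#'
#' @param x a numeric matrix (features x samples) or
#'   [UlmExperiment-class].
#' @return an object of the same class with normalized values; dimnames
#'   and metadata are preserved.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantileNormalize(m) # both columns become (2.5, 3.5, 4.5)
#' @export
setGeneric("quantileNormalize", function(x) standardGeneric("quantileNormalize"))

#' Accessors for UlmExperiment objects
#'
#' `sampleSheet()` returns the study design (sample, patient, tissue, size)
#' as a data.frame; `featureBiotypes()` the named biotype vector.
#'
#' @param x a [UlmExperiment-class].
#' @return a data.frame, or a named character vector.
#' @aliases sampleSheet featureBiotypes
#' @name UlmExperiment-accessors
NULL

#' @rdname UlmExperiment-accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname UlmExperiment-accessors
#' @export
setGeneric("featureBiotypes", function(x) standardGeneric("featureBiotypes"))

#' @rdname UlmExperiment-accessors
setMethod("sampleSheet", "UlmExperiment", function(x) {
  cd <- colData(x)
  data.frame(
    sample = rownames(cd),
    patient = cd$patient,
    tissue = cd$tissue,
    size = cd$size,
    stringsAsFactors = FALSE
  )
})

#' @rdname UlmExperiment-accessors
setMethod("featureBiotypes", "UlmExperiment", function(x) {
  setNames(as.character(rowData(x)$biotype), rownames(x))
})

#' Accessors for TruthManifest objects
#'
#' @param x a [TruthManifest-class].
#' @return `truthDECalls()` and `truthCisPairs()` return data.frames;
#'   `truthEnrichedSets()` a character vector; `truthModule()` a list with
#'   elements `mrnas`, `lncrnas`, `rho`.
#' @aliases truthDECalls truthCisPairs truthEnrichedSets truthModule
#' @name TruthManifest-accessors
NULL

#' @rdname TruthManifest-accessors
#' @export
setGeneric("truthDECalls", function(x) standardGeneric("truthDECalls"))

#' @rdname TruthManifest-accessors
#' @export
setGeneric("truthCisPairs", function(x) standardGeneric("truthCisPairs"))

#' @rdname TruthManifest-accessors
#' @export
setGeneric("truthEnrichedSets", function(x) standardGeneric("truthEnrichedSets"))

#' @rdname TruthManifest-accessors
#' @export
setGeneric("truthModule", function(x) standardGeneric("truthModule"))

#' @rdname TruthManifest-accessors
setMethod("truthDECalls", "TruthManifest", function(x) x@deCalls)

#' @rdname TruthManifest-accessors
setMethod("truthCisPairs", "TruthManifest", function(x) x@cisPairs)

#' @rdname TruthManifest-accessors
setMethod("truthEnrichedSets", "TruthManifest", function(x) x@enrichedSets)

#' @rdname TruthManifest-accessors
setMethod("truthModule", "TruthManifest", function(x) {
  list(mrnas = x@moduleMrnas, lncrnas = x@moduleLncrnas, rho = x@moduleRho)
})
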