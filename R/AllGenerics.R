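#' @rdname IRHits-accessors
#' @export
setGeneric("mismatchTotal", function(x) standardGeneric("mismatchTotal"))

#' @rdname IRHits-accessors
#' @export
setGeneric("mismatchStem", function(x) standardGeneric("mismatchStem"))

#' @rdname IRHits-accessors
#' @export
setGeneric("gapCount", function(x) standardGeneric("gapCount"))

#' @rdname IRHits-accessors
#' @export
setGeneric("irStructure", function(x) standardGeneric("irStructure"))

#' @rdname IRHits-accessors
#' @export
setGeneric("irSequence", function(x) standardGeneric("irSequence"))

#' @rdname IRHits-accessors
#' @export
setGeneric("isPerfect", function(x) standardGeneric("isPerfect"))

#' @rdname IRHits-accessors
#' @export
setGeneric("asGRanges", function(x) standardGeneric("asGRanges"))

#' @rdname findPerfectIRs
#' @export
setGeneric("findPerfectIRs",
    function(x, minLength = 10L, maxLength = 1000L, maximalOnly = FALSE)
        standardGeneric("findPerfectIRs"))

#' @rdname findImperfectIRs
#' @export
setGeneric("findImperfectIRs",
    function(x, minLength = 20L, maxLength = 1000L, maxMismatch = 6L)
        standardGeneric("findImperfectIRs"))
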