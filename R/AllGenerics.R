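#' @include AllClasses.R
NULL

#' @rdname IntensityExperiment-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname IntensityExperiment-class
#' @export
setGeneric("peptideCounts", function(x) standardGeneric("peptideCounts"))

#' @rdname IntensityExperiment-class
#' @export
setGeneric("controlCondition", function(x) standardGeneric("controlCondition"))

#' @rdname IntensityExperiment-class
#' @export
setGeneric("baitNames", function(x) standardGeneric("baitNames"))

#' @rdname normalizeByTotal
#' @export
setGeneric("normalizeByTotal", function(x) standardGeneric("normalizeByTotal"))

#' @rdname conditionMeans
#' @export
setGeneric("conditionMeans", function(x) standardGeneric("conditionMeans"))

#' @rdname RipExperiment-class
#' @export
setGeneric("transcriptLengths", function(x) standardGeneric("transcriptLengths"))

#' @rdname RipExperiment-class
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname RipExperiment-class
#' @export
setGeneric("ipGroup", function(x) standardGeneric("ipGroup"))
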