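#' @rdname IntensityExperiment-class
#' @export
IntensityExperiment <- function(intensity, peptides, condition, replicate,
                                controlCondition) {
  intensity <- as.matrix(intensity)
  peptides <- as.matrix(peptides)
  if (!identical(dim(intensity), dim(peptides))) {
    stop("'intensity' and 'peptides' must have identical dimensions")
  }
  if (is.null(rownames(intensity))) {
    stop("intensity matrix must have protein IDs as row names")
  }
  if (anyDuplicated(rownames(intensity))) {
    stop("duplicate protein IDs: ",
         paste(unique(rownames(intensity)[duplicated(rownames(intensity))]),
               collapse = ", "))
  }
  if (length(condition) != ncol(intensity) ||
      length(replicate) != ncol(intensity)) {
    stop("'condition' and 'replicate' must have one entry per sample")
  }
  storage.mode(peptides) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity, peptides = peptides),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   replicate = replicate,
                                   row.names = colnames(intensity))
  )
  methods::new("IntensityExperiment", se,
               controlCondition = as.character(controlCondition))
}

#' @rdname IntensityExperiment-class
#' @export
setMethod("intensities", "IntensityExperiment", function(x) {
  SummarizedExperiment::assay(x, "intensity")
})

#' @rdname IntensityExperiment-class
#' @export
setMethod("peptideCounts", "IntensityExperiment", function(x) {
  SummarizedExperiment::assay(x, "peptides")
})

#' @rdname IntensityExperiment-class
#' @export
setMethod("controlCondition", "IntensityExperiment", function(x) {
  x@controlCondition
})

#' @rdname IntensityExperiment-class
#' @export
setMethod("baitNames", "IntensityExperiment", function(x) {
  setdiff(unique(SummarizedExperiment::colData(x)$condition),
          x@controlCondition)
})

setMethod("show", "IntensityExperiment", function(object) {
  methods::callNextMethod()
  cat("control condition:", object@controlCondition, "\n")
  cat("baits:", paste(baitNames(object), collapse = ", "), "\n")
  if (isTRUE(S4Vectors::metadata(object)$normalized)) {
    cat("batch-normalized to the maximum sample total\n")
  }
})

#' @rdname RipExperiment-class
#' @export
RipExperiment <- function(counts, lengths, group, replicate) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("count matrix must have transcript IDs as row names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate transcript IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (length(lengths) != nrow(counts)) {
    stop("'lengths' must have one entry per transcript")
  }
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length = as.numeric(lengths)),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   replicate = replicate,
                                   row.names = colnames(counts))
  )
  methods::new("RipExperiment", se)
}

#' @rdname RipExperiment-class
#' @export
setMethod("transcriptLengths", "RipExperiment", function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$length, rownames(x))
})

#' @rdname RipExperiment-class
#' @export
setMethod("librarySizes", "RipExperiment", function(x) {
  colSums(SummarizedExperiment::assay(x, "counts"))
})

#' @rdname RipExperiment-class
#' @export
setMethod("ipGroup", "RipExperiment", function(x) {
  SummarizedExperiment::colData(x)$group
})

setMethod("show", "RipExperiment", function(object) {
  methods::callNextMethod()
  gg <- table(ipGroup(object))
  cat(sprintf("IP samples: %d; control samples: %d\n",
              gg[["IP"]], gg[["control"]]))
})
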