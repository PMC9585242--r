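#' Container for AP-MS protein intensities with a bait/control design
#'
#' `IntensityExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] and holds two parallel
#' assays: `intensity`, the label-free quantification (LFQ) signal per
#' (protein, sample) in arbitrary units with 0 meaning "not detected", and
#' `peptides`, the integer peptide count supporting each (protein, sample).
#' Column metadata records the immunoprecipitation `condition` (one tagged
#' bait per condition, plus exactly one negative-control condition) and the
#' biological `replicate`. All samples in one object form one normalization
#' batch.
#'
#' @param intensity numeric matrix (proteins x samples), non-negative; 0 is a
#'   non-detection.
#' @param peptides integer matrix of the same shape; must be 0 wherever
#'   `intensity` is 0.
#' @param condition character vector, one entry per sample.
#' @param replicate vector identifying replicates within condition.
#' @param controlCondition the condition name of the negative-control bait.
#' @param x an `IntensityExperiment`.
#'
#' @return `IntensityExperiment()` returns an object of the class.
#'   `intensities()` and `peptideCounts()` return the respective assays,
#'   `controlCondition()` the control condition name and `baitNames()` the
#'   non-control condition names.
#'
#' @examples
#' sim <- simulateIpms(IpmsSimConfig(n_background = 20,
#'   partner_sets = list(B1 = "P1"), bait_names = "B1", seed = 1))
#' ie <- sim$experiment
#' controlCondition(ie)
#' baitNames(ie)
#' @aliases intensities peptideCounts controlCondition baitNames
#' @export
setClass("IntensityExperiment",
  contains = "SummarizedExperiment",
  representation(controlCondition = "character")
)

setValidity("IntensityExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("intensity", "peptides") %in% an)) {
    return("assays must include 'intensity' and 'peptides'")
  }
  ii <- SummarizedExperiment::assay(object, "intensity")
  pp <- SummarizedExperiment::assay(object, "peptides")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'condition' and 'replicate'")
  }
  if (any(ii < 0, na.rm = TRUE)) msg <- c(msg, "intensities must be >= 0")
  if (any(pp < 0, na.rm = TRUE)) msg <- c(msg, "peptide counts must be >= 0")
  if (any(pp[ii == 0] != 0)) {
    msg <- c(msg, "peptide count must be 0 wherever intensity is 0 (non-detection)")
  }
  if (length(object@controlCondition) != 1L) {
    msg <- c(msg, "exactly one control condition is required")
  } else if ("condition" %in% colnames(cd) &&
             !object@controlCondition %in% cd$condition) {
    msg <- c(msg, sprintf("control condition '%s' has no samples",
                          object@controlCondition))
  }
  if (length(msg)) msg else TRUE
})

#' Container for RIP-seq/CLIP-seq transcript counts
#'
#' `RipExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a single `counts`
#' assay of raw mapped reads per (transcript, sample), transcript lengths in
#' nucleotides in `rowData(x)$length`, and a two-group design in
#' `colData(x)`: `group` is `"IP"` (the co-precipitated fraction) or
#' `"control"` (the negative control), `replicate` identifies replicates.
#' Library sizes are the raw column totals; no between-sample scaling beyond
#' that is applied.
#'
#' @param counts integer matrix (transcripts x samples) of raw read counts.
#' @param lengths positive transcript lengths (nucleotides), one per row.
#' @param group character vector per sample, `"IP"` or `"control"`.
#' @param replicate vector identifying replicates within group.
#' @param x a `RipExperiment`.
#'
#' @return `RipExperiment()` returns an object of the class.
#'   `transcriptLengths()` returns the length vector, `librarySizes()` the
#'   per-sample column totals and `ipGroup()` the group factor.
#'
#' @examples
#' sim <- simulateRip(RipSimConfig(n_transcripts = 50, n_enriched = 5, seed = 1))
#' re <- sim$experiment
#' head(librarySizes(re))
#' @aliases transcriptLengths librarySizes ipGroup
#' @export
setClass("RipExperiment", contains = "SummarizedExperiment")

setValidity("RipExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is required")
  }
  cc <- SummarizedExperiment::assay(object, "counts")
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!"length" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain transcript 'length'")
  } else if (any(rd$length <= 0)) {
    msg <- c(msg, "transcript lengths must be positive")
  }
  if (any(cc < 0) || any(cc != round(cc))) {
    msg <- c(msg, "counts must be non-negative integers")
  }
  if (!all(c("group", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'group' and 'replicate'")
  } else {
    if (!all(cd$group %in% c("IP", "control"))) {
      msg <- c(msg, "group must be 'IP' or 'control'")
    }
    if (!all(c("IP", "control") %in% cd$group)) {
      msg <- c(msg, "both an IP group and a control group are required")
    }
  }
  if (length(msg)) msg else TRUE
})
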