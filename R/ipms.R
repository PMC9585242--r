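#' Batch normalization by total sample intensity
#'
#' Scales every sample of one AP-MS batch so that all sample totals equal the
#' largest total in the batch: each sample's intensities are multiplied by
#' (maximum total over samples) / (that sample's total). All samples present
#' in the object form a single normalization batch (for a 4-bait + 1-control
#' triplicate design, that is one batch of 15 samples). Zeros stay zero and
#' peptide counts are untouched. The operation is idempotent and the
#' post-normalization enrichment ratios are invariant to rescaling any one
#' sample by a positive constant.
#'
#' @param x an [IntensityExperiment-class].
#' @return the normalized `IntensityExperiment`;
#'   `metadata(x)$normalized` is set to `TRUE` and
#'   `metadata(x)$scale_factors` records the per-sample factors.
#' @examples
#' sim <- simulateIpms(IpmsSimConfig(n_background = 50, seed = 1))
#' norm <- normalizeByTotal(sim$experiment)
#' range(colSums(intensities(norm)))  # all equal
#' @rdname normalizeByTotal
#' @export
setMethod("normalizeByTotal", "IntensityExperiment", function(x) {
  ii <- intensities(x)
  totals <- colSums(ii)
  if (any(totals <= 0)) {
    stop("cannot normalize sample(s) with zero total intensity: ",
         paste(colnames(ii)[totals <= 0], collapse = ", "))
  }
  f <- max(totals) / totals
  SummarizedExperiment::assay(x, "intensity") <-
    sweep(ii, 2, f, "*")
  S4Vectors::metadata(x)$normalized <- TRUE
  S4Vectors::metadata(x)$scale_factors <- f
  methods::validObject(x)
  x
})

#' Per-condition replicate means
#'
#' Arithmetic mean of the (normalized) intensities over all replicates of
#' each condition. Non-detections enter the mean as 0; no imputation or
#' exclusion of zeros is performed.
#'
#' @param x an [IntensityExperiment-class], normally after
#'   [normalizeByTotal()].
#' @return numeric matrix, proteins x conditions.
#' @examples
#' sim <- simulateIpms(IpmsSimConfig(n_background = 50, seed = 1))
#' cm <- conditionMeans(normalizeByTotal(sim$experiment))
#' head(cm)
#' @rdname conditionMeans
#' @export
setMethod("conditionMeans", "IntensityExperiment", function(x) {
  cond <- SummarizedExperiment::colData(x)$condition
  conds <- unique(cond)
  ii <- intensities(x)
  out <- vapply(conds, function(cc) {
    idx <- which(cond == cc)
    if (!length(idx)) stop("condition with no samples: ", cc)
    rowMeans(ii[, idx, drop = FALSE])
  }, numeric(nrow(ii)))
  dimnames(out) <- list(rownames(ii), conds)
  out
})

#' Enrichment ratio with the infinite/undefined convention
#'
#' Ratio of a bait-condition mean intensity to the negative-control mean.
#' When the control mean is zero but the bait mean is positive the ratio is
#' reported as `Inf` (the protein was never detected in the control, so the
#' enrichment cannot be quantified but is treated as passing every fold
#' threshold). When both means are zero the ratio is undefined and reported
#' as `NaN`; undefined entries are never reported as interactors.
#'
#' @param bait_mean,control_mean non-negative mean intensities (vectorized).
#' @return numeric vector of ratios (finite, `Inf`, or `NaN`).
#' @examples
#' enrichmentRatio(c(8, 4, 0), c(2, 0, 0))  # 4, Inf, NaN
#' @export
enrichmentRatio <- function(bait_mean, control_mean) {
  .ratioConvention(bait_mean, control_mean)
}

#' Peptide-support filter
#'
#' A protein is considered supported in one bait condition when at least two
#' of that condition's replicates identified it with two or more peptides.
#'
#' @param peptide_counts integer vector of per-replicate peptide counts for
#'   one (protein, condition) group, or a matrix with replicates in columns.
#' @param min_peptides minimum peptides per replicate (default 2).
#' @param min_replicates minimum replicates reaching `min_peptides`
#'   (default 2).
#' @return logical; for a matrix, one value per row.
#' @examples
#' peptideSupport(c(2, 2, 0))  # TRUE
#' peptideSupport(c(3, 1, 1))  # FALSE
#' @export
peptideSupport <- function(peptide_counts, min_peptides = 2,
                           min_replicates = 2) {
  if (is.matrix(peptide_counts)) {
    rowSums(peptide_counts >= min_peptides) >= min_replicates
  } else {
    sum(peptide_counts >= min_peptides) >= min_replicates
  }
}

#' Assign reporting flags and fold-change tiers
#'
#' Applies the reporting rule and the fold-change tiers to an enrichment
#' table: a protein is `reported` for a bait when its ratio is at least
#' `report_fold` (or `Inf`) and it has peptide support; tiers are `"low"`
#' (ratio > 1.5), `"highlight"` (ratio > `highlight_fold`, strict) and
#' `"top"` (ratio > `top_fold` and bait mean intensity above
#' `intensity_floor`). Infinite ratios qualify for every fold tier;
#' undefined (`NaN`) ratios get tier `"none"` and are never reported.
#'
#' @param table a data.frame with at least columns `ratio`, `bait_mean` and
#'   `peptide_support` (as built by [ipmsEnrichment()]).
#' @param report_fold inclusive reporting threshold (default 2).
#' @param low_fold strict lower bound of the low tier (default 1.5).
#' @param highlight_fold strict highlight threshold (default 4).
#' @param top_fold strict top-tier threshold (default 8).
#' @param intensity_floor minimum bait mean intensity for the top tier
#'   (default 1e6).
#' @return the table with columns `tier` (factor: none < low < highlight <
#'   top) and `reported` added or replaced.
#' @examples
#' tab <- data.frame(ratio = c(4.14, 3.9, 9), bait_mean = c(2e6, 2e6, 5e5),
#'                   peptide_support = TRUE)
#' assignTiers(tab)$tier
#' @export
assignTiers <- function(table, report_fold = 2, low_fold = 1.5,
                        highlight_fold = 4, top_fold = 8,
                        intensity_floor = 1e6) {
  r <- table$ratio
  tier <- rep("none", length(r))
  ok <- !is.nan(r)
  tier[ok & r > low_fold] <- "low"
  tier[ok & r > highlight_fold] <- "highlight"
  tier[ok & r > top_fold & table$bait_mean > intensity_floor] <- "top"
  table$tier <- factor(tier, levels = c("none", "low", "highlight", "top"),
                       ordered = TRUE)
  table$reported <- ok & r >= report_fold & table$peptide_support
  table
}

#' AP-MS enrichment scoring against the negative-control bait
#'
#' Runs the full co-IP scoring chain on one normalization batch: batch
#' normalization by total intensity (unless the object is already
#' normalized), replicate averaging per condition with zeros included,
#' enrichment ratio of each bait mean to the control mean (with the
#' `Inf`/`NaN` convention of [enrichmentRatio()]), the peptide-support
#' filter evaluated on each bait condition's own replicates, and tier and
#' reporting assignment via [assignTiers()]. Rows are ordered per bait by
#' decreasing ratio (`Inf` first), ties broken by decreasing bait mean
#' intensity and then protein ID.
#'
#' @param x an [IntensityExperiment-class].
#' @param normalize run [normalizeByTotal()] first (default `TRUE`; set to
#'   `FALSE` if `x` is already normalized).
#' @inheritParams assignTiers
#' @param min_peptides,min_replicates peptide-support rule, see
#'   [peptideSupport()].
#' @return a data.frame with one row per (protein, bait): `id`, `bait`,
#'   `bait_mean`, `control_mean`, `ratio`, `peptide_support`, `tier`,
#'   `reported`.
#' @examples
#' sim <- simulateIpms(IpmsSimConfig(n_background = 50, seed = 1))
#' enr <- ipmsEnrichment(sim$experiment)
#' head(subset(enr, reported))
#' @export
ipmsEnrichment <- function(x, normalize = TRUE, report_fold = 2,
                           low_fold = 1.5, highlight_fold = 4, top_fold = 8,
                           intensity_floor = 1e6, min_peptides = 2,
                           min_replicates = 2) {
  stopifnot(methods::is(x, "IntensityExperiment"))
  if (normalize && !isTRUE(S4Vectors::metadata(x)$normalized)) {
    x <- normalizeByTotal(x)
  }
  cm <- conditionMeans(x)
  ctrl <- controlCondition(x)
  baits <- baitNames(x)
  cond <- SummarizedExperiment::colData(x)$condition
  pep <- peptideCounts(x)

  out <- do.call(rbind, lapply(baits, function(b) {
    ratio <- enrichmentRatio(cm[, b], cm[, ctrl])
    supp <- peptideSupport(pep[, cond == b, drop = FALSE],
                           min_peptides, min_replicates)
    data.frame(id = rownames(cm), bait = b,
               bait_mean = cm[, b], control_mean = cm[, ctrl],
               ratio = ratio, peptide_support = supp,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out <- assignTiers(out, report_fold = report_fold, low_fold = low_fold,
                     highlight_fold = highlight_fold, top_fold = top_fold,
                     intensity_floor = intensity_floor)
  # deterministic ranking: Inf sorts above any finite ratio; NaN last
  key <- out$ratio
  key[is.nan(key)] <- -Inf
  out[order(out$bait, -key, -out$bait_mean, out$id, method = "radix"), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
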