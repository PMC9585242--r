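# Tab-separated, UTF-8, "." decimal is the single tabular dialect.
# Infinite ratios are rendered as the literal "Inf"; undefined (NaN) rows
# are omitted from result files and counted in the run log.

.readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.checkNumericCells <- function(df, path) {
  for (j in seq_along(df)[-1]) {
    v <- df[[j]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("malformed numeric value '%s' at row %d, column '%s' of %s",
                     v[bad[1]], bad[1], colnames(df)[j], path))
      }
      df[[j]] <- num
    }
  }
  df
}

.readDesign <- function(path, sampleIds, required = c("sample_id", "condition",
                                                      "replicate")) {
  d <- .readTsv(path)
  if (!all(required %in% colnames(d))) {
    stop("design table must have columns: ", paste(required, collapse = ", "))
  }
  missing <- setdiff(d$sample_id, sampleIds)
  if (length(missing)) {
    stop("design references sample column(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(sampleIds, d$sample_id)
  if (length(extra)) {
    stop("matrix sample(s) missing from the design: ",
         paste(extra, collapse = ", "))
  }
  d[match(sampleIds, d$sample_id), , drop = FALSE]
}

#' Read an AP-MS intensity experiment from TSV files
#'
#' Reads a protein x sample intensity matrix, a parallel peptide-count
#' matrix of identical shape, and a design table (columns `sample_id`,
#' `condition`, `replicate`) into an [IntensityExperiment-class]. The first
#' column of each matrix holds protein IDs; remaining columns are samples.
#' Duplicate IDs, malformed numerics (reported with row/column coordinates)
#' and design/matrix sample mismatches are errors.
#'
#' @param intensity_path,peptide_path,design_path TSV file paths.
#' @param control the control condition name.
#' @return an `IntensityExperiment`.
#' @export
readIntensityExperiment <- function(intensity_path, peptide_path, design_path,
                                    control) {
  ii <- .checkNumericCells(.readTsv(intensity_path), intensity_path)
  pp <- .checkNumericCells(.readTsv(peptide_path), peptide_path)
  if (anyDuplicated(ii[[1]])) {
    stop("duplicate protein ID(s) in ", intensity_path, ": ",
         paste(unique(ii[[1]][duplicated(ii[[1]])]), collapse = ", "))
  }
  im <- as.matrix(ii[, -1, drop = FALSE])
  rownames(im) <- ii[[1]]
  pm <- as.matrix(pp[, -1, drop = FALSE])
  rownames(pm) <- pp[[1]]
  if (!identical(dim(im), dim(pm)) ||
      !identical(colnames(im), colnames(pm)) ||
      !identical(rownames(im), rownames(pm))) {
    stop("intensity and peptide tables must have identical proteins and samples")
  }
  d <- .readDesign(design_path, colnames(im))
  IntensityExperiment(im, pm, d$condition, d$replicate, control)
}

#' Read a RIP-seq count experiment from TSV files
#'
#' Reads a transcript x sample count matrix whose first column holds
#' transcript IDs and which contains a `length` column, plus a design table
#' (columns `sample_id`, `group`, `replicate`; group `IP` or `control`),
#' into a [RipExperiment-class].
#'
#' @param count_path,design_path TSV file paths.
#' @return a `RipExperiment`.
#' @export
readRipExperiment <- function(count_path, design_path) {
  cc <- .checkNumericCells(.readTsv(count_path), count_path)
  if (!"length" %in% colnames(cc)) {
    stop("count table must contain a 'length' column")
  }
  if (anyDuplicated(cc[[1]])) {
    stop("duplicate transcript ID(s) in ", count_path, ": ",
         paste(unique(cc[[1]][duplicated(cc[[1]])]), collapse = ", "))
  }
  lens <- cc$length
  sampleCols <- setdiff(colnames(cc)[-1], "length")
  cm <- as.matrix(cc[, sampleCols, drop = FALSE])
  rownames(cm) <- cc[[1]]
  d <- .readDesign(design_path, colnames(cm),
                   required = c("sample_id", "group", "replicate"))
  RipExperiment(cm, lens, d$group, d$replicate)
}

#' Read an annotation table
#'
#' ID -> description (and optionally category) lookup used to annotate
#' enrichment tables and drive [categorize()].
#'
#' @param path TSV with at least columns `id` and `description`.
#' @return a data.frame.
#' @export
readAnnotation <- function(path) {
  d <- .readTsv(path)
  if (!all(c("id", "description") %in% colnames(d))) {
    stop("annotation table must have columns 'id' and 'description'")
  }
  d
}

#' Read a category rule set
#'
#' @param path TSV with columns `category` and `pattern` (ordered,
#'   first-match-wins; an empty pattern is the fallback). An optional
#'   `priority` column re-orders rules (ascending).
#' @return rule data.frame for [categorize()].
#' @export
readCategoryRules <- function(path) {
  d <- .readTsv(path)
  if (!all(c("category", "pattern") %in% colnames(d))) {
    stop("rule table must have columns 'category' and 'pattern'")
  }
  if ("priority" %in% colnames(d)) d <- d[order(d$priority), , drop = FALSE]
  d$pattern[is.na(d$pattern)] <- ""
  d
}

#' Write a result table as TSV with a provenance header
#'
#' Writes a data.frame tab-separated with a single leading comment line
#' recording the package version, a configuration hash and the seed, so
#' outputs are self-describing and re-runs can be compared. Infinite values
#' are rendered as the literal `Inf`. Rows whose `ratio` (or `log2_ratio`)
#' is undefined (`NaN`) are omitted; the number omitted is reported via a
#' message and returned invisibly.
#'
#' @param table a data.frame.
#' @param path output file path.
#' @param config_hash short hash identifying the run configuration.
#' @param seed the run seed (or `NA`).
#' @return invisibly, the number of undefined rows omitted.
#' @export
writeResultTable <- function(table, path, config_hash = "none", seed = NA) {
  dropped <- 0L
  for (col in intersect(c("ratio", "log2_ratio"), colnames(table))) {
    bad <- is.nan(table[[col]])
    dropped <- dropped + sum(bad)
    table <- table[!bad, , drop = FALSE]
  }
  if (dropped > 0) {
    message(sprintf("omitting %d row(s) with undefined ratios from %s",
                    dropped, basename(path)))
  }
  for (j in seq_along(table)) {
    if (is.numeric(table[[j]])) table[[j]] <- .fmtNum(table[[j]])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# coPrecip %s\tconfig=%s\tseed=%s",
                     as.character(utils::packageVersion("coPrecip")),
                     config_hash, as.character(seed)), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dropped)
}

#' Write an experiment back to the TSV dialect
#'
#' Serializes an [IntensityExperiment-class] or [RipExperiment-class] to the
#' same TSV files the readers consume, enabling lossless round trips.
#'
#' @param x the experiment object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of files written.
#' @export
writeExperiment <- function(x, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  w <- function(df, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- p
    p
  }
  if (methods::is(x, "IntensityExperiment")) {
    ii <- intensities(x)
    w(data.frame(id = rownames(ii), ii, check.names = FALSE), "intensity")
    pp <- peptideCounts(x)
    w(data.frame(id = rownames(pp), pp, check.names = FALSE), "peptides")
    cd <- SummarizedExperiment::colData(x)
    w(data.frame(sample_id = rownames(cd), condition = cd$condition,
                 replicate = cd$replicate), "design")
  } else if (methods::is(x, "RipExperiment")) {
    cc <- SummarizedExperiment::assay(x, "counts")
    w(data.frame(id = rownames(cc), length = transcriptLengths(x), cc,
                 check.names = FALSE), "counts")
    cd <- SummarizedExperiment::colData(x)
    w(data.frame(sample_id = rownames(cd), group = cd$group,
                 replicate = cd$replicate), "design")
  } else {
    stop("unsupported experiment class: ", class(x)[1])
  }
  invisible(unlist(files))
}
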