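#' Per-bait sets of reported interactors
#'
#' Extracts, from an [ipmsEnrichment()] table, the set of protein IDs
#' reported for each bait (ratio at least the reporting fold, peptide
#' support).
#'
#' @param table a data.frame as returned by [ipmsEnrichment()].
#' @return named list of character vectors, one per bait.
#' @examples
#' sim <- simulateIpms(IpmsSimConfig(n_background = 50, seed = 1))
#' sets <- baitSets(ipmsEnrichment(sim$experiment))
#' lengths(sets)
#' @export
baitSets <- function(table) {
  stopifnot(all(c("id", "bait", "reported") %in% colnames(table)))
  lapply(split(table[table$reported, , drop = FALSE],
               factor(table$bait[table$reported],
                      levels = unique(table$bait))),
         function(d) unique(d$id))
}

#' Exclusivity and overlap of bait interactomes
#'
#' For each bait set, counts how many of its members are found with no other
#' bait (exclusive) and how many are shared with each other single bait,
#' reporting counts and fractions of the set size (the "15 of 20 exclusive"
#' style of summary). Fractions for an empty set are `NA`.
#'
#' @param sets named list of character vectors (e.g. from [baitSets()]);
#'   at least two sets.
#' @return a data.frame with one row per bait: `bait`, `n`, `n_exclusive`,
#'   `frac_exclusive`, and for every other bait `shared_n_<bait>` and
#'   `shared_frac_<bait>`.
#' @examples
#' exclusivity(list(E3 = c("A", "B", "C"), G4 = c("B", "C", "D")))
#' @export
exclusivity <- function(sets) {
  if (length(sets) < 2) stop("at least two sets are required")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be named by bait")
  }
  sets <- lapply(sets, unique)
  baits <- names(sets)
  rows <- lapply(baits, function(b) {
    s <- sets[[b]]
    others <- unlist(sets[setdiff(baits, b)], use.names = FALSE)
    nexcl <- sum(!s %in% others)
    row <- data.frame(bait = b, n = length(s), n_exclusive = nexcl,
                      frac_exclusive = if (length(s)) nexcl / length(s) else NA_real_,
                      stringsAsFactors = FALSE)
    for (o in setdiff(baits, b)) {
      ns <- sum(s %in% sets[[o]])
      row[[paste0("shared_n_", o)]] <- ns
      row[[paste0("shared_frac_", o)]] <-
        if (length(s)) ns / length(s) else NA_real_
    }
    row
  })
  cols <- unique(unlist(lapply(rows, colnames)))
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, colnames(r))] <- NA
    r[cols]
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise bait-versus-bait enrichment
#'
#' Compares the mean normalized intensities of two baits from the same
#' normalization batch, protein by protein, using the same finite /
#' `Inf` / `NaN` ratio convention as the bait-versus-control scoring.
#' Proteins absent from one table enter with mean 0 (the protein universes
#' are unioned). Proteins whose A:B ratio reaches `fold` (or is `Inf`) are
#' flagged as enriched in A over B, and symmetrically for B over A.
#'
#' @param table_a,table_b data.frames from [ipmsEnrichment()] (or any tables
#'   with `id` and `bait_mean` columns), both from one normalized batch;
#'   each must concern a single bait.
#' @param fold flagging threshold (inclusive; default 2).
#' @return a data.frame with columns `id`, `mean_a`, `mean_b`, `ratio`
#'   (A over B), `enriched_a`, `enriched_b`.
#' @examples
#' sim <- simulateIpms(IpmsSimConfig(n_background = 50, seed = 1))
#' enr <- ipmsEnrichment(sim$experiment)
#' pw <- pairwiseEnrichment(subset(enr, bait == "EIF4E3"),
#'                          subset(enr, bait == "EIF4E4"))
#' head(pw[pw$enriched_a, ])
#' @export
pairwiseEnrichment <- function(table_a, table_b, fold = 2) {
  for (tb in list(table_a, table_b)) {
    stopifnot(all(c("id", "bait_mean") %in% colnames(tb)))
    if ("bait" %in% colnames(tb) && length(unique(tb$bait)) > 1) {
      stop("each table must concern a single bait; subset first")
    }
  }
  ids <- union(table_a$id, table_b$id)
  ma <- stats::setNames(rep(0, length(ids)), ids)
  mb <- ma
  ma[table_a$id] <- table_a$bait_mean
  mb[table_b$id] <- table_b$bait_mean
  ratio <- .ratioConvention(ma, mb)
  data.frame(id = ids, mean_a = unname(ma), mean_b = unname(mb),
             ratio = unname(ratio),
             enriched_a = !is.nan(ratio) & ratio >= fold,
             enriched_b = !is.nan(ratio) & (1 / ratio) >= fold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default functional-category rules
#'
#' An ordered, first-match-wins rule set mapping protein/transcript
#' description strings to the molecular-function categories used for
#' interactome summaries (ribosomal proteins -- including organellar ones --,
#' translation initiation factors, protein kinases/phosphatases, RNA-binding
#' proteins, enzymes, generic binding activity, chaperones, intracellular
#' transport), with an "Undefined Function" fallback that collects
#' hypothetical/unknown proteins and everything not matched. Matching is by
#' case-insensitive regular expression on the description. The rule set is a
#' reproducible approximation of a manual GO-term based classification and
#' can be replaced or reordered by the user.
#'
#' @return a data.frame with columns `category` and `pattern`, in match
#'   order, with the fallback (empty pattern) last.
#' @examples
#' defaultCategoryRules()
#' @export
defaultCategoryRules <- function() {
  data.frame(
    category = c("Ribosomal Protein",
                 "Translation Initiation Factor",
                 "Protein Kinase/Phosphatase",
                 "RNA-Binding",
                 "Chaperone",
                 "Intracellular transport",
                 "Enzyme",
                 "Binding Activity",
                 "Undefined Function"),
    pattern = c("ribosomal protein",
                "initiation factor|\\beif[0-9]",
                "protein kinase|casein kinase|phosphatase",
                "rna[- ]binding|zinc finger|helicase|\\brnp\\b|ribonucleoprotein|polyadenylate",
                "chaperone|heat shock|\\bhsp[0-9]|valosin|dnaj",
                "transport|kinesin|dynein|flagel|centrin|calmodulin|emp24|importin|exportin",
                "ase\\b|enzyme|synthase|synthetase",
                "binding",
                ""),
    stringsAsFactors = FALSE
  )
}

#' Classify descriptions into functional categories
#'
#' Deterministic first-match assignment of each description to a category.
#' Rules are tried in order; the first rule whose pattern matches
#' (case-insensitively) wins, and the fallback rule (empty pattern) matches
#' everything, so every entry is classified.
#'
#' @param descriptions character vector of free-text descriptions.
#' @param rules ordered rule data.frame with columns `category` and
#'   `pattern`; defaults to [defaultCategoryRules()]. The last rule with an
#'   empty pattern acts as fallback; if none is supplied, an
#'   `"Undefined Function"` fallback is appended.
#' @return factor of categories, levels in rule order.
#' @examples
#' categorize(c("60S ribosomal protein L10a", "Hypothetical protein"))
#' @export
categorize <- function(descriptions, rules = defaultCategoryRules()) {
  stopifnot(all(c("category", "pattern") %in% colnames(rules)))
  if (!any(rules$pattern == "")) {
    rules <- rbind(rules, data.frame(category = "Undefined Function",
                                     pattern = "",
                                     stringsAsFactors = FALSE))
  }
  out <- rep(NA_character_, length(descriptions))
  for (i in seq_len(nrow(rules))) {
    pat <- rules$pattern[i]
    hit <- if (pat == "") rep(TRUE, length(descriptions)) else {
      grepl(pat, descriptions, ignore.case = TRUE, perl = TRUE)
    }
    out[is.na(out) & hit] <- rules$category[i]
  }
  factor(out, levels = unique(rules$category))
}

#' Category counts and fractions
#'
#' Summarizes a [categorize()] assignment into per-category counts and
#' fractions of the total; fractions sum to 1 because the fallback rule
#' guarantees full coverage.
#'
#' @param categories factor from [categorize()].
#' @param drop_empty drop categories with zero members (default `FALSE`).
#' @return data.frame with columns `category`, `n`, `fraction`.
#' @examples
#' categoryCounts(categorize(c("60S ribosomal protein L2", "kinesin")))
#' @export
categoryCounts <- function(categories, drop_empty = FALSE) {
  tab <- table(categories)
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    fraction = as.numeric(tab) / max(1L, length(categories)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (drop_empty) out <- out[out$n > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
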