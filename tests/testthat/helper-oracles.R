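# independent brute-force oracles and small fixture generators; everything
# here is deliberately written as plain loops, independent of the package's
# vectorized implementations

randomIntensityFixture <- function(n_prot = 50, conds = c("B1", "B2", "CTRL"),
                                   n_rep = 3, zero_frac = 0.15) {
  m <- length(conds) * n_rep
  ids <- sprintf("P%03d", seq_len(n_prot))
  cond <- rep(conds, each = n_rep)
  repl <- rep(seq_len(n_rep), times = length(conds))
  samples <- paste(cond, repl, sep = "_")
  ii <- matrix(stats::rlnorm(n_prot * m, meanlog = 10, sdlog = 1),
               n_prot, m, dimnames = list(ids, samples))
  ii[matrix(stats::runif(n_prot * m) < zero_frac, n_prot, m)] <- 0
  pp <- matrix(0L, n_prot, m, dimnames = dimnames(ii))
  pp[ii > 0] <- 1L + stats::rpois(sum(ii > 0), 3)
  IntensityExperiment(ii, pp, cond, repl, controlCondition = "CTRL")
}

# cell-by-cell renormalization oracle
bruteNormalize <- function(mat) {
  totals <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) totals[j] <- sum(mat[, j])
  out <- mat
  for (j in seq_len(ncol(mat))) {
    for (i in seq_len(nrow(mat))) {
      out[i, j] <- mat[i, j] * max(totals) / totals[j]
    }
  }
  out
}

# straight-line recomputation of the whole AP-MS scoring chain
bruteIpmsChain <- function(ii, pp, cond, control,
                           report_fold = 2, low_fold = 1.5,
                           highlight_fold = 4, top_fold = 8,
                           intensity_floor = 1e6) {
  nm <- bruteNormalize(ii)
  baits <- setdiff(unique(cond), control)
  rows <- list()
  for (b in baits) {
    for (i in seq_len(nrow(nm))) {
      bm <- mean(nm[i, cond == b])
      cm <- mean(nm[i, cond == control])
      ratio <- if (cm > 0) bm / cm else if (bm > 0) Inf else NaN
      pep <- pp[i, cond == b]
      supp <- sum(pep >= 2) >= 2
      tier <- "none"
      if (!is.nan(ratio)) {
        if (ratio > low_fold) tier <- "low"
        if (ratio > highlight_fold) tier <- "highlight"
        if (ratio > top_fold && bm > intensity_floor) tier <- "top"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = rownames(nm)[i], bait = b, bait_mean = bm, control_mean = cm,
        ratio = ratio, peptide_support = supp, tier = tier,
        reported = !is.nan(ratio) && ratio >= report_fold && supp,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# textbook step-up implementation
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# membership double loop
bruteExclusive <- function(sets, b) {
  cnt <- 0L
  for (el in sets[[b]]) {
    found <- FALSE
    for (o in names(sets)) {
      if (o != b && el %in% sets[[o]]) found <- TRUE
    }
    if (!found) cnt <- cnt + 1L
  }
  cnt
}

# unpooled two-proportion z-test oracle
zTestP <- function(x1, n1, x2, n2) {
  p1 <- sum(x1) / sum(n1)
  p2 <- sum(x2) / sum(n2)
  se <- sqrt(p1 * (1 - p1) / sum(n1) + p2 * (1 - p2) / sum(n2))
  2 * stats::pnorm(-abs((p1 - p2) / se))
}

extdataPath <- function(f) system.file("extdata", f, package = "coPrecip")
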