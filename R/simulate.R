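#' Configuration for the AP-MS co-IP simulator
#'
#' Parameters describing a synthetic affinity-purification experiment:
#' a set of tagged baits plus one negative-control bait, each
#' immunoprecipitated in `n_replicates` biological replicates and quantified
#' by label-free MS. Background (non-partner) protein intensities are drawn
#' log-normally; a true partner of bait B receives a multiplicative
#' `enrichment_fold` intensity boost in B's samples only, while the control
#' condition is pure background. Non-detection is modelled as independent
#' Bernoulli zeroing (`dropout_prob`) after the intensity draw; peptide
#' counts are `1 + Poisson(peptide_rate - 1)` where a protein is detected and
#' 0 where it is not, so the peptide-support filter is exercised through
#' dropout rather than an independent mechanism.
#'
#' @param n_background number of background (non-partner) proteins.
#' @param partner_sets named list, bait name -> character vector of true
#'   partner protein IDs. Defaults to 50 synthetic partners per bait.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   baseline intensity (arbitrary LFQ units, natural-log scale).
#' @param enrichment_fold multiplicative boost of a true partner in its own
#'   bait's samples; must be >= 1 (1 gives a null experiment).
#' @param dropout_prob per-(protein, sample) probability of a zero intensity,
#'   in [0, 1).
#' @param peptide_rate expected peptide count of a detected protein (>= 1).
#' @param n_replicates replicates per condition (>= 2; triplicates by
#'   default).
#' @param bait_names names of the tagged baits.
#' @param control_name name of the negative-control condition; must differ
#'   from all bait names.
#' @param seed integer seed; the simulator uses one local RNG stream per call
#'   and never touches global RNG state.
#'
#' @return an `IpmsSimConfig` object for [simulateIpms()].
#' @examples
#' cfg <- IpmsSimConfig(n_background = 100, seed = 7)
#' cfg
#' @export
IpmsSimConfig <- function(n_background = 2000,
                          partner_sets = NULL,
                          baseline_log_mean = log(1e6),
                          baseline_log_sd = 0.12,
                          enrichment_fold = 8,
                          dropout_prob = 0.1,
                          peptide_rate = 5,
                          n_replicates = 3,
                          bait_names = c("EIF4E3", "EIF4E4", "EIF4G3", "EIF4G4"),
                          control_name = "DRBD4",
                          seed = 1) {
  if (is.null(partner_sets)) {
    partner_sets <- lapply(stats::setNames(bait_names, bait_names),
                           function(b) sprintf("PTN_%s_%03d", b, seq_len(50)))
  }
  cfg <- structure(list(n_background = as.integer(n_background),
                        partner_sets = partner_sets,
                        baseline_log_mean = baseline_log_mean,
                        baseline_log_sd = baseline_log_sd,
                        enrichment_fold = enrichment_fold,
                        dropout_prob = dropout_prob,
                        peptide_rate = peptide_rate,
                        n_replicates = as.integer(n_replicates),
                        bait_names = as.character(bait_names),
                        control_name = as.character(control_name),
                        seed = as.integer(seed)),
                   class = "IpmsSimConfig")
  validateIpmsSimConfig(cfg)
  cfg
}

validateIpmsSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "IpmsSimConfig"))
  if (cfg$n_background < 1) stop("configuration error: n_background must be positive")
  if (cfg$enrichment_fold < 1) stop("configuration error: enrichment_fold must be >= 1")
  if (cfg$dropout_prob < 0 || cfg$dropout_prob >= 1) {
    stop("configuration error: dropout_prob must be in [0, 1)")
  }
  if (cfg$peptide_rate < 1) stop("configuration error: peptide_rate must be >= 1")
  if (cfg$n_replicates < 2) stop("configuration error: n_replicates must be >= 2")
  if (cfg$control_name %in% cfg$bait_names) {
    stop("configuration error: control name must differ from all bait names")
  }
  if (!all(names(cfg$partner_sets) %in% cfg$bait_names)) {
    stop("configuration error: partner_sets names must be bait names")
  }
  invisible(TRUE)
}

#' @export
print.IpmsSimConfig <- function(x, ...) {
  cat("IpmsSimConfig:", x$n_background, "background proteins;",
      sum(lengths(x$partner_sets)), "partner assignments over",
      length(x$bait_names), "baits (+ control", paste0("'", x$control_name, "');"),
      x$n_replicates, "replicates\n")
  cat(sprintf("  fold %.3g, dropout %.3g, peptide rate %.3g, seed %d\n",
              x$enrichment_fold, x$dropout_prob, x$peptide_rate, x$seed))
  invisible(x)
}

#' Simulate an AP-MS co-IP intensity matrix with ground truth
#'
#' Draws one batch of (baits + control) x replicates samples under the model
#' described in [IpmsSimConfig()] and returns both the
#' [IntensityExperiment-class] and a ground-truth table for recovery tests.
#' The run is fully reproducible for a fixed seed.
#'
#' @param config an [IpmsSimConfig()].
#' @return a list with elements `experiment` (an `IntensityExperiment`) and
#'   `truth`, a data.frame with columns `id`, `label`
#'   (`"partner"`/`"background"`), `bait` (the bait(s) whose samples carry the
#'   boost, `NA` for background) and `fold` (1 for background).
#' @examples
#' sim <- simulateIpms(IpmsSimConfig(n_background = 50, seed = 1))
#' table(sim$truth$label)
#' @export
simulateIpms <- function(config) {
  validateIpmsSimConfig(config)
  withLocalSeed(config$seed, {
    partners <- unique(unlist(config$partner_sets, use.names = FALSE))
    ids <- c(sprintf("BG_%04d", seq_len(config$n_background)), partners)
    if (anyDuplicated(ids)) {
      stop("configuration error: partner IDs collide with background IDs")
    }
    conds <- c(config$bait_names, config$control_name)
    cond <- rep(conds, each = config$n_replicates)
    repl <- rep(seq_len(config$n_replicates), times = length(conds))
    samples <- paste(cond, paste0("r", repl), sep = "_")

    n <- length(ids)
    m <- length(samples)
    meanlog <- matrix(config$baseline_log_mean, n, m,
                      dimnames = list(ids, samples))
    for (b in names(config$partner_sets)) {
      rows <- match(config$partner_sets[[b]], ids)
      meanlog[rows, cond == b] <- config$baseline_log_mean +
        log(config$enrichment_fold)
    }
    intensity <- matrix(stats::rlnorm(n * m, meanlog = meanlog,
                                      sdlog = config$baseline_log_sd),
                        n, m, dimnames = dimnames(meanlog))
    if (config$dropout_prob > 0) {
      drop <- matrix(stats::runif(n * m) < config$dropout_prob, n, m)
      intensity[drop] <- 0
    }
    peptides <- matrix(0L, n, m, dimnames = dimnames(meanlog))
    det <- intensity > 0
    peptides[det] <- 1L + stats::rpois(sum(det), config$peptide_rate - 1)

    experiment <- IntensityExperiment(intensity, peptides, cond, repl,
                                      config$control_name)
    baitOf <- vapply(ids, function(id) {
      hit <- names(config$partner_sets)[vapply(config$partner_sets,
                                               function(s) id %in% s, logical(1))]
      if (length(hit)) paste(hit, collapse = ";") else NA_character_
    }, character(1))
    truth <- data.frame(id = ids,
                        label = ifelse(is.na(baitOf), "background", "partner"),
                        bait = baitOf,
                        fold = ifelse(is.na(baitOf), 1, config$enrichment_fold),
                        row.names = NULL, stringsAsFactors = FALSE)
    list(experiment = experiment, truth = truth)
  })
}

#' Configuration for the RIP-seq/CLIP-seq count simulator
#'
#' Parameters describing a synthetic RNA co-precipitation experiment with an
#' IP group and a negative-control group, each sequenced in `n_replicates`
#' replicates. Baseline relative expression is log-normal across transcripts;
#' a spiked subset has IP-group expected counts equal to `enrichment_fold`
#' times its control-group expected counts. Counts are negative-binomial with
#' dispersion `nb_dispersion` (variance `mu + nb_dispersion * mu^2`;
#' 0 gives Poisson). Control-sample expected totals equal `library_sizes`;
#' spiking adds reads on top of that baseline in the IP samples, so IP totals
#' exceed the target in proportion to the spiked mass (the fold contract on
#' expected counts is kept exact).
#'
#' @param n_transcripts number of transcripts.
#' @param n_enriched number of spiked (truly IP-enriched) transcripts.
#' @param enrichment_fold IP/control ratio of expected counts for spiked
#'   transcripts; >= 1 (1 gives a null experiment).
#' @param mean_log_expression,sd_log_expression log-normal parameters of
#'   baseline relative expression (only relative scale matters).
#' @param nb_dispersion negative-binomial overdispersion (>= 0).
#' @param length_range min/max transcript length in nucleotides.
#' @param library_sizes expected total counts per sample; a scalar or one
#'   value per sample (IP replicates first, then controls).
#' @param n_replicates replicates per group (>= 2).
#' @param seed integer seed (local RNG stream).
#'
#' @return a `RipSimConfig` object for [simulateRip()].
#' @examples
#' RipSimConfig(n_transcripts = 200, n_enriched = 10, seed = 3)
#' @export
RipSimConfig <- function(n_transcripts = 2000,
                         n_enriched = 100,
                         enrichment_fold = 8,
                         mean_log_expression = 5,
                         sd_log_expression = 1,
                         nb_dispersion = 0.05,
                         length_range = c(500, 5000),
                         library_sizes = 2e6,
                         n_replicates = 3,
                         seed = 1) {
  cfg <- structure(list(n_transcripts = as.integer(n_transcripts),
                        n_enriched = as.integer(n_enriched),
                        enrichment_fold = enrichment_fold,
                        mean_log_expression = mean_log_expression,
                        sd_log_expression = sd_log_expression,
                        nb_dispersion = nb_dispersion,
                        length_range = length_range,
                        library_sizes = library_sizes,
                        n_replicates = as.integer(n_replicates),
                        seed = as.integer(seed)),
                   class = "RipSimConfig")
  validateRipSimConfig(cfg)
  cfg
}

validateRipSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "RipSimConfig"))
  if (cfg$n_transcripts < 1) stop("configuration error: n_transcripts must be positive")
  if (cfg$n_enriched < 0 || cfg$n_enriched > cfg$n_transcripts) {
    stop("configuration error: n_enriched must be in [0, n_transcripts]")
  }
  if (cfg$enrichment_fold < 1) stop("configuration error: enrichment_fold must be >= 1")
  if (cfg$nb_dispersion < 0) stop("configuration error: nb_dispersion must be >= 0")
  if (length(cfg$length_range) != 2 || any(cfg$length_range <= 0) ||
      cfg$length_range[1] > cfg$length_range[2]) {
    stop("configuration error: length_range must be a positive min/max pair")
  }
  if (any(cfg$library_sizes <= 0)) {
    stop("configuration error: library sizes must be positive")
  }
  if (cfg$n_replicates < 2) stop("configuration error: n_replicates must be >= 2")
  invisible(TRUE)
}

#' @export
print.RipSimConfig <- function(x, ...) {
  cat("RipSimConfig:", x$n_transcripts, "transcripts,", x$n_enriched,
      sprintf("spiked at fold %.3g;", x$enrichment_fold),
      x$n_replicates, "replicates per group\n")
  cat(sprintf("  NB dispersion %.3g, lengths [%g, %g] nt, seed %d\n",
              x$nb_dispersion, x$length_range[1], x$length_range[2], x$seed))
  invisible(x)
}

#' Simulate a RIP-seq count matrix with ground truth
#'
#' Draws counts under the model described in [RipSimConfig()] and returns the
#' [RipExperiment-class] together with ground-truth labels. Spiked
#' transcripts are chosen uniformly at random within the seeded stream; the
#' run is fully reproducible for a fixed seed.
#'
#' @param config a [RipSimConfig()].
#' @return a list with elements `experiment` (a `RipExperiment`) and `truth`,
#'   a data.frame with columns `id`, `label` (`"enriched"`/`"background"`)
#'   and `fold` (1 for background).
#' @examples
#' sim <- simulateRip(RipSimConfig(n_transcripts = 100, n_enriched = 10, seed = 2))
#' table(sim$truth$label)
#' @export
simulateRip <- function(config) {
  validateRipSimConfig(config)
  withLocalSeed(config$seed, {
    nt <- config$n_transcripts
    k <- config$n_replicates
    ids <- sprintf("TX_%04d", seq_len(nt))
    lengths <- round(stats::runif(nt, config$length_range[1],
                                  config$length_range[2]))
    lam <- stats::rlnorm(nt, config$mean_log_expression,
                         config$sd_log_expression)
    rel <- lam / sum(lam)
    spiked <- sort(sample.int(nt, config$n_enriched))
    fold <- rep(1, nt)
    fold[spiked] <- config$enrichment_fold

    group <- rep(c("IP", "control"), each = k)
    repl <- rep(seq_len(k), times = 2)
    samples <- paste(group, paste0("r", repl), sep = "_")
    libs <- rep_len(config$library_sizes, 2 * k)

    mu <- matrix(0, nt, 2 * k, dimnames = list(ids, samples))
    for (j in seq_len(2 * k)) {
      mu[, j] <- rel * libs[j] * (if (group[j] == "IP") fold else 1)
    }
    counts <- if (config$nb_dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$nb_dispersion),
             nt, 2 * k, dimnames = dimnames(mu))
    } else {
      matrix(stats::rpois(length(mu), mu), nt, 2 * k,
             dimnames = dimnames(mu))
    }
    experiment <- RipExperiment(counts, lengths, group, repl)
    truth <- data.frame(id = ids,
                        label = ifelse(fold > 1, "enriched", "background"),
                        fold = fold, row.names = NULL,
                        stringsAsFactors = FALSE)
    list(experiment = experiment, truth = truth)
  })
}
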