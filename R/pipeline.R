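#' Assemble a run configuration
#'
#' Collects input paths, thresholds and the seed for [runPipeline()] into a
#' validated list, filling in the standard defaults (reporting at 2-fold,
#' highlight at >4-fold, top tier at >8-fold with a 1e6 intensity floor,
#' a 50-read minimum, log2 ratio > 1, FDR 1\% and an RPKM floor of 50).
#'
#' @param mode `"ipms"` or `"rip"`.
#' @param outdir output directory.
#' @param simulate logical; when `TRUE`, inputs are generated with
#'   [simulateIpms()]/[simulateRip()] using `sim` and `seed`.
#' @param sim an [IpmsSimConfig()] or [RipSimConfig()] (when simulating).
#' @param intensity_path,peptide_path,design_path,count_path,annotation_path
#'   input TSVs (when not simulating; annotation optional).
#' @param control control condition name (ipms file input).
#' @param report_fold,low_fold,highlight_fold,top_fold,intensity_floor AP-MS
#'   thresholds, see [ipmsEnrichment()].
#' @param min_mean_reads,min_log2,fdr,min_rpkm RIP thresholds, see
#'   [ripEnrichment()].
#' @param seed integer seed recorded in all outputs.
#' @return a `RunConfig` list.
#' @export
RunConfig <- function(mode = c("ipms", "rip"), outdir = ".",
                      simulate = TRUE, sim = NULL,
                      intensity_path = NULL, peptide_path = NULL,
                      design_path = NULL, count_path = NULL,
                      annotation_path = NULL, control = NULL,
                      report_fold = 2, low_fold = 1.5, highlight_fold = 4,
                      top_fold = 8, intensity_floor = 1e6,
                      min_mean_reads = 50, min_log2 = 1, fdr = 0.01,
                      min_rpkm = 50, seed = 1) {
  mode <- match.arg(mode)
  thresholds <- c(report_fold = report_fold, low_fold = low_fold,
                  highlight_fold = highlight_fold, top_fold = top_fold,
                  intensity_floor = intensity_floor,
                  min_mean_reads = min_mean_reads, min_log2 = min_log2,
                  fdr = fdr, min_rpkm = min_rpkm)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  if (simulate && is.null(sim)) {
    sim <- if (mode == "ipms") IpmsSimConfig(seed = seed)
           else RipSimConfig(seed = seed)
  }
  structure(list(mode = mode, outdir = outdir, simulate = simulate,
                 sim = sim, intensity_path = intensity_path,
                 peptide_path = peptide_path, design_path = design_path,
                 count_path = count_path, annotation_path = annotation_path,
                 control = control, thresholds = as.list(thresholds),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' The YAML mirrors the [RunConfig()] fields; `sim:` sub-fields are passed
#' to [IpmsSimConfig()] or [RipSimConfig()] according to `mode`.
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file's values.
#' @return a `RunConfig`.
#' @export
readRunConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  simArgs <- y$sim
  y$sim <- NULL
  cfg <- do.call(RunConfig, y)
  if (!is.null(simArgs)) {
    cfg$sim <- do.call(if (cfg$mode == "ipms") IpmsSimConfig else RipSimConfig,
                       simArgs)
  }
  cfg
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "outdir")]), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

#' Run an end-to-end analysis
#'
#' Chains the pipeline stages for one experiment: for `mode = "ipms"`,
#' simulate or read an [IntensityExperiment-class], score it with
#' [ipmsEnrichment()], derive per-bait reported sets, [exclusivity()] and
#' all pairwise bait comparisons, and (when an annotation is available)
#' [categorize()] summaries; for `mode = "rip"`, simulate or read a
#' [RipExperiment-class] and score it with [ripEnrichment()]. All result
#' tables are written as TSV with a provenance header (version, config
#' hash, seed); a `run_log.txt` records every threshold and the seed.
#' Re-running with identical inputs produces byte-identical outputs.
#'
#' @param config a [RunConfig()] (or YAML path for [readRunConfig()]).
#' @return invisibly, a list with the in-memory results and the paths of
#'   the files written.
#' @examples
#' cfg <- RunConfig("rip", outdir = tempfile(),
#'                  sim = RipSimConfig(n_transcripts = 100, n_enriched = 10))
#' res <- runPipeline(cfg)
#' names(res$files)
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  th <- config$thresholds
  files <- character()
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(tab, name) {
    p <- file.path(config$outdir, paste0(name, ".tsv"))
    writeResultTable(tab, p, config_hash = hash, seed = config$seed)
    files[[name]] <<- p
  }

  if (config$mode == "ipms") {
    x <- stage("input", {
      if (config$simulate) {
        sim <- simulateIpms(config$sim)
        results$truth <- sim$truth
        sim$experiment
      } else {
        readIntensityExperiment(config$intensity_path, config$peptide_path,
                                config$design_path, config$control)
      }
    })
    enr <- stage("ipms-enrich", ipmsEnrichment(
      x, report_fold = th$report_fold, low_fold = th$low_fold,
      highlight_fold = th$highlight_fold, top_fold = th$top_fold,
      intensity_floor = th$intensity_floor))
    results$enrichment <- enr
    for (b in unique(enr$bait)) {
      emit(enr[enr$bait == b, , drop = FALSE], paste0("enrichment_", b))
    }
    sets <- baitSets(enr)
    results$sets <- sets
    if (length(sets) >= 2) {
      excl <- stage("exclusivity", exclusivity(sets))
      results$exclusivity <- excl
      emit(excl, "exclusivity")
      baits <- names(sets)
      pw <- do.call(rbind, lapply(utils::combn(baits, 2, simplify = FALSE),
        function(pair) {
          tab <- pairwiseEnrichment(
            enr[enr$bait == pair[1], , drop = FALSE],
            enr[enr$bait == pair[2], , drop = FALSE],
            fold = th$report_fold)
          cbind(bait_a = pair[1], bait_b = pair[2], tab)
        }))
      results$pairwise <- pw
      emit(pw, "pairwise")
    }
    if (!is.null(config$annotation_path)) {
      ann <- stage("annotation", readAnnotation(config$annotation_path))
      desc <- ann$description[match(enr$id, ann$id)]
      cat_assign <- categorize(ifelse(is.na(desc), "", desc))
      summary <- categoryCounts(cat_assign[enr$reported])
      results$categories <- summary
      emit(summary, "category_summary")
    }
  } else {
    x <- stage("input", {
      if (config$simulate) {
        sim <- simulateRip(config$sim)
        results$truth <- sim$truth
        sim$experiment
      } else {
        readRipExperiment(config$count_path, config$design_path)
      }
    })
    enr <- stage("rip-enrich", ripEnrichment(
      x, min_mean_reads = th$min_mean_reads, min_log2 = th$min_log2,
      fdr = th$fdr, min_rpkm = th$min_rpkm))
    results$enrichment <- enr
    emit(enr, "rip_enrichment")
  }

  logPath <- file.path(config$outdir, "run_log.txt")
  writeLines(c(
    sprintf("coPrecip %s", as.character(utils::packageVersion("coPrecip"))),
    sprintf("mode: %s", config$mode),
    sprintf("config hash: %s", hash),
    sprintf("seed: %d", config$seed),
    sprintf("%s: %s", names(th), unlist(th))
  ), logPath)
  files[["run_log"]] <- logPath
  results$files <- files
  invisible(results)
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over the package functions, used by the
#' `inst/scripts/coprecip` Rscript. Subcommands: `simulate-ipms`,
#' `simulate-rip` (write synthetic TSV inputs plus ground truth),
#' `ipms-enrich`, `rip-enrich` (run the respective pipeline on files or
#' simulations), `ipms-compare` (alias of `ipms-enrich`; the exclusivity
#' and pairwise tables are always produced) and `report` (print a run log).
#' Flags: `--config <yaml>`, `--out <dir>`, `--seed <int>`, plus any
#' threshold name (e.g. `--fdr 0.05`). Logging goes to stderr; data never
#' mixes with it.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, 0 on success (invisible).
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: coprecip <simulate-ipms|simulate-rip|ipms-enrich|",
                 "ipms-compare|rip-enrich|report> [--config file.yaml]",
                 "[--out dir] [--seed n] [--<threshold> value]")
  status <- tryCatch({
    if (!length(args)) stop(usage)
    cmd <- args[1]
    flags <- list()
    rest <- args[-1]
    while (length(rest)) {
      if (!startsWith(rest[1], "--") || length(rest) < 2) {
        stop("malformed flag: ", rest[1])
      }
      key <- sub("^--", "", rest[1])
      val <- rest[2]
      num <- suppressWarnings(as.numeric(val))
      flags[[key]] <- if (!is.na(num)) num else val
      rest <- rest[-(1:2)]
    }
    outdir <- if (!is.null(flags$out)) flags$out else "."
    seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else 1L
    thNames <- c("report_fold", "low_fold", "highlight_fold", "top_fold",
                 "intensity_floor", "min_mean_reads", "min_log2", "fdr",
                 "min_rpkm")
    mkConfig <- function(mode, simulate) {
      base <- list(mode = mode, outdir = outdir, simulate = simulate,
                   seed = seed,
                   intensity_path = flags$intensity, peptide_path = flags$peptides,
                   design_path = flags$design, count_path = flags$counts,
                   annotation_path = flags$annotation, control = flags$control)
      base <- base[!vapply(base, is.null, logical(1))]
      base <- c(base, flags[intersect(names(flags), thNames)])
      if (!is.null(flags$config)) {
        do.call(readRunConfig, c(list(path = flags$config), base))
      } else {
        do.call(RunConfig, base)
      }
    }
    switch(cmd,
      "simulate-ipms" = {
        sim <- simulateIpms(IpmsSimConfig(seed = seed))
        writeExperiment(sim$experiment, outdir, "ipms")
        utils::write.table(sim$truth, file.path(outdir, "ipms_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      "simulate-rip" = {
        sim <- simulateRip(RipSimConfig(seed = seed))
        writeExperiment(sim$experiment, outdir, "rip")
        utils::write.table(sim$truth, file.path(outdir, "rip_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      "ipms-enrich" = ,
      "ipms-compare" = {
        runPipeline(mkConfig("ipms", is.null(flags$intensity)))
      },
      "rip-enrich" = {
        runPipeline(mkConfig("rip", is.null(flags$counts)))
      },
      "report" = {
        lg <- file.path(outdir, "run_log.txt")
        if (!file.exists(lg)) stop("no run log found in ", outdir)
        cat(readLines(lg), sep = "\n")
      },
      stop("unknown subcommand '", cmd, "'\n", usage)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
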