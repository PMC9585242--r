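test_that("simulators are deterministic for a fixed seed and leave global RNG alone", {
  cfg <- IpmsSimConfig(n_background = 100, seed = 42)
  set.seed(999)
  before <- .Random.seed
  a <- simulateIpms(cfg)
  expect_identical(.Random.seed, before)
  b <- simulateIpms(cfg)
  expect_identical(intensities(a$experiment), intensities(b$experiment))
  expect_identical(peptideCounts(a$experiment), peptideCounts(b$experiment))
  expect_identical(a$truth, b$truth)

  rcfg <- RipSimConfig(n_transcripts = 100, n_enriched = 10, seed = 42)
  r1 <- simulateRip(rcfg)
  r2 <- simulateRip(rcfg)
  expect_identical(SummarizedExperiment::assay(r1$experiment, "counts"),
                   SummarizedExperiment::assay(r2$experiment, "counts"))
  expect_identical(r1$truth, r2$truth)
  # different seeds diverge
  r3 <- simulateRip(RipSimConfig(n_transcripts = 100, n_enriched = 10, seed = 43))
  expect_false(identical(SummarizedExperiment::assay(r1$experiment, "counts"),
                         SummarizedExperiment::assay(r3$experiment, "counts")))
})

test_that("ground-truth labels are complete and consistent with spiked folds", {
  sim <- simulateIpms(IpmsSimConfig(n_background = 80, seed = 5))
  expect_equal(sort(sim$truth$id), sort(rownames(sim$experiment)))
  expect_false(anyDuplicated(sim$truth$id) > 0)
  expect_true(all(sim$truth$fold[sim$truth$label == "background"] == 1))
  expect_true(all(sim$truth$fold[sim$truth$label == "partner"] == 8))

  rs <- simulateRip(RipSimConfig(n_transcripts = 150, n_enriched = 15, seed = 5))
  expect_equal(rs$truth$id, rownames(rs$experiment))
  expect_equal(sum(rs$truth$label == "enriched"), 15)
  expect_true(all(rs$truth$fold[rs$truth$label == "background"] == 1))
})

test_that("null co-IP configuration (fold 1, no dropout) yields no enrichment signal", {
  sim <- simulateIpms(IpmsSimConfig(n_background = 300, enrichment_fold = 1,
                                    dropout_prob = 0, seed = 3))
  enr <- ipmsEnrichment(sim$experiment)
  # partners are indistinguishable from background: ratios concentrate at 1
  ptn <- enr[enr$id %in% sim$truth$id[sim$truth$label == "partner"], ]
  expect_true(all(is.finite(ptn$ratio)))
  expect_lt(abs(mean(ptn$ratio) - 1), 0.05)
  # nothing clears the 2-fold reporting bar
  expect_equal(sum(enr$reported), 0)
})

test_that("spiked co-IP partners show the configured fold in the raw matrix", {
  sim <- simulateIpms(IpmsSimConfig(seed = 1))  # 2000 bg, 50/bait, fold 8, dropout 0.1
  ii <- intensities(sim$experiment)
  cond <- SummarizedExperiment::colData(sim$experiment)$condition
  ratios <- vapply(names(which(lengths(split(sim$truth$id, sim$truth$bait)) > 0)),
                   function(b) {
    ptn <- sim$truth$id[!is.na(sim$truth$bait) & sim$truth$bait == b]
    mean(ii[ptn, cond == b]) / mean(ii[ptn, cond == "DRBD4"])
  }, numeric(1))
  expect_true(all(ratios >= 6 & ratios <= 10))
})

test_that("marginal intensity calibration holds without dropout", {
  cfg <- IpmsSimConfig(n_background = 500, dropout_prob = 0, seed = 9)
  sim <- simulateIpms(cfg)
  bg <- sim$truth$id[sim$truth$label == "background"]
  lv <- log(intensities(sim$experiment)[bg, ])
  se <- cfg$baseline_log_sd / sqrt(length(lv))
  expect_lt(abs(mean(lv) - cfg$baseline_log_mean), 3 * se)
})

test_that("RIP counts are Poisson in the zero-dispersion limit", {
  rs <- simulateRip(RipSimConfig(n_transcripts = 1000, n_enriched = 0,
                                 enrichment_fold = 1, nb_dispersion = 0,
                                 seed = 4))
  cnt <- SummarizedExperiment::assay(rs$experiment, "counts")
  vm <- apply(cnt, 1, stats::var) / rowMeans(cnt)
  expect_lt(abs(mean(vm) - 1), 0.05)
  # and clearly overdispersed when dispersion is positive
  rs2 <- simulateRip(RipSimConfig(n_transcripts = 1000, n_enriched = 0,
                                  enrichment_fold = 1, nb_dispersion = 0.05,
                                  seed = 4))
  cnt2 <- SummarizedExperiment::assay(rs2$experiment, "counts")
  vm2 <- apply(cnt2, 1, stats::var) / rowMeans(cnt2)
  expect_gt(mean(vm2), 2)
})

test_that("spiked transcripts carry the configured IP/control count ratio", {
  rs <- simulateRip(RipSimConfig(seed = 1))  # 2000 transcripts, 100 at fold 8
  cnt <- SummarizedExperiment::assay(rs$experiment, "counts")
  grp <- ipGroup(rs$experiment)
  sp <- rs$truth$id[rs$truth$label == "enriched"]
  r <- mean(cnt[sp, grp == "IP"]) / mean(cnt[sp, grp == "control"])
  expect_gte(r, 6)
  expect_lte(r, 10)
  # per-sample control totals sit within sampling noise of the target
  libs <- librarySizes(rs$experiment)[grp == "control"]
  expect_true(all(abs(libs - 2e6) / 2e6 < 0.05))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(IpmsSimConfig(n_background = 0), "n_background")
  expect_error(IpmsSimConfig(dropout_prob = 1), "dropout_prob")
  expect_error(IpmsSimConfig(enrichment_fold = 0.5), "enrichment_fold")
  expect_error(IpmsSimConfig(n_replicates = 1), "n_replicates")
  expect_error(IpmsSimConfig(control_name = "EIF4E3"), "control")
  expect_error(RipSimConfig(nb_dispersion = -0.1), "nb_dispersion")
  expect_error(RipSimConfig(n_enriched = 300, n_transcripts = 200), "n_enriched")
  expect_error(RipSimConfig(length_range = c(0, 100)), "length_range")
  expect_error(RipSimConfig(library_sizes = -1), "library sizes")
})
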