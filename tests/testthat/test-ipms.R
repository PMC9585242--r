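test_that("total-intensity normalization equalizes sample totals and scales correctly", {
  ii <- matrix(c(60, 40, 30, 20), 2, 2,
               dimnames = list(c("P1", "P2"), c("s1", "s2")))
  pp <- matrix(2L, 2, 2, dimnames = dimnames(ii))
  x <- IntensityExperiment(ii, pp, c("A", "CTRL"), c(1, 1), "CTRL")
  nx <- normalizeByTotal(x)
  # totals 100 and 50: every intensity of the second sample doubles
  expect_equal(intensities(nx)[, "s2"], c(P1 = 60, P2 = 40))
  expect_equal(intensities(nx)[, "s1"], ii[, "s1"])
  expect_equal(unname(colSums(intensities(nx))), c(100, 100))
  expect_identical(peptideCounts(nx), pp)

  # already-equal totals: identity
  ii2 <- matrix(c(60, 40, 70, 30), 2, 2,
                dimnames = list(c("P1", "P2"), c("s1", "s2")))
  x2 <- IntensityExperiment(ii2, pp, c("A", "CTRL"), c(1, 1), "CTRL")
  expect_equal(intensities(normalizeByTotal(x2)), ii2)

  # a sample with zero total cannot be scaled, and the error names it
  ii3 <- matrix(c(1, 2, 0, 0), 2, 2,
                dimnames = list(c("P1", "P2"), c("s1", "bad")))
  pp3 <- matrix(c(2L, 2L, 0L, 0L), 2, 2, dimnames = dimnames(ii3))
  x3 <- IntensityExperiment(ii3, pp3, c("A", "CTRL"), c(1, 1), "CTRL")
  expect_error(normalizeByTotal(x3), "bad")
})

test_that("all samples of a bait/control design normalize together as one batch", {
  sim <- simulateIpms(IpmsSimConfig(n_background = 40, seed = 2))
  x <- sim$experiment
  expect_equal(ncol(x), 15)  # 4 baits + 1 control, triplicate
  nx <- normalizeByTotal(x)
  totals <- colSums(intensities(nx))
  expect_equal(length(S4Vectors::metadata(nx)$scale_factors), 15)
  expect_true(all(abs(totals - max(totals)) < 1e-6 * max(totals)))
})

test_that("condition means average over all replicates with zeros included", {
  ii <- matrix(c(3, 3, 3, 6, 0, 0, 2, 4, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("P1", "P2", "P3"), c("a1", "a2", "a3")))
  pp <- matrix(0L, 3, 3, dimnames = dimnames(ii)); pp[ii > 0] <- 2L
  x <- IntensityExperiment(ii, pp, rep("A", 3), 1:3, "A")
  # control==bait here is irrelevant for the mean computation
  cm <- conditionMeans(x)
  expect_equal(unname(cm[, "A"]), c(3, 2, 2))
})

test_that("condition means match a brute-force per-cell recomputation", {
  withr::with_seed(11, x <- randomIntensityFixture())
  cm <- conditionMeans(x)
  ii <- intensities(x)
  cond <- SummarizedExperiment::colData(x)$condition
  for (cc in unique(cond)) {
    for (i in seq_len(nrow(ii))) {
      expect_equal(cm[i, cc], mean(ii[i, cond == cc]))
    }
  }
})

test_that("enrichment ratios follow the finite/Inf/NaN convention", {
  expect_equal(enrichmentRatio(8, 2), 4)
  expect_identical(enrichmentRatio(4.1e5, 0), Inf)
  expect_identical(enrichmentRatio(0, 0), NaN)
  expect_equal(enrichmentRatio(c(8, 4, 0, 0), c(2, 0, 0, 5)),
               c(4, Inf, NaN, 0))
  expect_error(enrichmentRatio(-1, 2), "non-negative")
})

test_that("peptide support requires two peptides in at least two replicates", {
  expect_true(peptideSupport(c(2, 2, 0)))
  expect_false(peptideSupport(c(3, 1, 1)))
  expect_false(peptideSupport(c(1, 1, 1)))
  expect_true(peptideSupport(c(5, 0, 2)))
  m <- rbind(c(2, 2, 0), c(3, 1, 1))
  expect_equal(unname(peptideSupport(m)), c(TRUE, FALSE))
})

test_that("tier assignment honors strict fold bounds, the intensity floor and Inf", {
  tab <- data.frame(
    ratio = c(4.14, 3.9, 9, 9, Inf, Inf, NaN, 4, 1.5, 2),
    bait_mean = c(2e6, 2e6, 5e5, 2e6, 2e6, 5e5, 0, 1e5, 1e5, 1e5),
    peptide_support = TRUE)
  out <- assignTiers(tab)
  expect_equal(as.character(out$tier),
               c("highlight", "low", "highlight", "top", "top", "highlight",
                 "none", "low", "none", "low"))
  # reporting is inclusive at 2-fold, Inf qualifies, NaN never does
  expect_equal(out$reported,
               c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  out2 <- assignTiers(data.frame(ratio = 1.99, bait_mean = 1e7,
                                 peptide_support = TRUE))
  expect_false(out2$reported)
  # without peptide support nothing is reported
  out3 <- assignTiers(data.frame(ratio = 10, bait_mean = 1e7,
                                 peptide_support = FALSE))
  expect_false(out3$reported)
  expect_equal(as.character(out3$tier), "top")
})

test_that("normalization is idempotent and ratios are scale invariant", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      x <- randomIntensityFixture(n_prot = 30, zero_frac = 0.2)
      nx <- normalizeByTotal(x)
      nnx <- normalizeByTotal(nx)
      expect_equal(intensities(nnx), intensities(nx))
      # rescale one sample by a positive constant: ratios unchanged
      ii <- intensities(x)
      j <- sample(ncol(ii), 1)
      ii[, j] <- ii[, j] * stats::runif(1, 0.1, 10)
      x2 <- IntensityExperiment(ii, peptideCounts(x),
                                SummarizedExperiment::colData(x)$condition,
                                SummarizedExperiment::colData(x)$replicate,
                                controlCondition(x))
      e1 <- ipmsEnrichment(x)
      e2 <- ipmsEnrichment(x2)
      expect_equal(e1$ratio, e2$ratio, tolerance = 1e-10)
    }
  })
})

test_that("the full scoring chain matches a straight-line brute-force oracle", {
  withr::with_seed(31, x <- randomIntensityFixture(n_prot = 50,
                                                   conds = c("B1", "B2", "B3",
                                                             "B4", "CTRL")))
  got <- ipmsEnrichment(x)
  want <- bruteIpmsChain(intensities(x), peptideCounts(x),
                         SummarizedExperiment::colData(x)$condition, "CTRL")
  key <- paste(want$id, want$bait)
  got <- got[match(key, paste(got$id, got$bait)), ]
  expect_equal(got$bait_mean, want$bait_mean)
  expect_equal(got$control_mean, want$control_mean)
  expect_equal(got$ratio, want$ratio)
  expect_equal(got$peptide_support, want$peptide_support)
  expect_equal(as.character(got$tier), want$tier)
  expect_equal(got$reported, want$reported)
})

test_that("ranking is deterministic with Inf first and ties broken by intensity then ID", {
  ii <- matrix(c(5, 5, 0, 0,
                 8, 8, 0, 4,
                 2, 2, 0, 1), nrow = 3, byrow = TRUE,
               dimnames = list(c("PB", "PA", "PC"),
                               c("B_1", "B_2", "C_1", "C_2")))
  pp <- matrix(0L, nrow(ii), ncol(ii), dimnames = dimnames(ii))
  pp[ii > 0] <- 3L
  x <- IntensityExperiment(ii, pp, c("B", "B", "C", "C"), c(1, 2, 1, 2), "C")
  enr <- ipmsEnrichment(x, normalize = FALSE)
  # PB: control 0 -> Inf; PA and PC finite 4x; PA has larger bait mean
  expect_equal(enr$id, c("PB", "PA", "PC"))
  expect_true(is.infinite(enr$ratio[1]))
})
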