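test_that("TPM normalizes by length and sums to one million per sample", {
  expect_equal(tpm(c(10, 10), c(100, 200)),
               c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
  expect_equal(tpm(5, 1234), 1e6)
  m <- matrix(c(10, 10, 3, 9), 2, 2, dimnames = list(c("t1", "t2"),
                                                     c("s1", "s2")))
  tt <- tpm(m, c(100, 200))
  expect_equal(unname(colSums(tt)), c(1e6, 1e6))
  m0 <- cbind(m, bad = c(0, 0))
  expect_error(tpm(m0, c(100, 200)), "bad")
  expect_error(tpm(c(1, 2), c(0, 100)), "positive")
})

test_that("RPKM follows its closed form", {
  expect_equal(rpkm(50, 1000, 1e6), 50)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(50, 1000, 2e6), 25)  # doubling the library halves RPKM
  m <- matrix(c(50, 100, 50, 100), 2, 2)
  expect_equal(rpkm(m, c(1000, 2000), c(1e6, 2e6)),
               matrix(c(50, 50, 25, 25), 2, 2))
  expect_error(rpkm(5, 0, 1e6), "length")
  expect_error(rpkm(5, 100, 0), "library")
})

test_that("the beta-binomial test is symmetric, antisymmetric and guarded", {
  x <- c(120, 130, 125); n <- rep(1e5, 3)
  same <- baggerlyTest(x, n, x, n)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  y <- c(40, 35, 42)
  ab <- baggerlyTest(x, n, y, n)
  ba <- baggerlyTest(y, n, x, n)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p.value, ba$p.value)
  expect_gt(ab$statistic, 0)
  expect_true(ab$p.value >= 0 && ab$p.value <= 1)

  expect_error(baggerlyTest(c(1, 2), c(10, 10), 5, 10), "two replicates")
  expect_error(baggerlyTest(c(20, 2), c(10, 10), c(1, 2), c(10, 10)),
               "exceed")
  expect_error(baggerlyTest(x, n, y, n, dispersion = -1), "dispersion")
})

test_that("with no extra-binomial variation the test reduces to the z-test", {
  # Poisson counts, large libraries: wherever the moment estimate of the
  # between-replicate component is zero the p-value must equal the unpooled
  # two-proportion z-test exactly; overall the two agree closely
  withr::with_seed(7, {
    nt <- 500
    rel <- stats::rlnorm(nt, 5, 1); rel <- rel / sum(rel)
    mu <- outer(rel, rep(5e6, 6))
    cnt <- matrix(stats::rpois(length(mu), mu), nt, 6)
    ns <- colSums(cnt)
    dp <- exact <- numeric(nt)
    for (g in seq_len(nt)) {
      bb <- baggerlyTest(cnt[g, 1:3], ns[1:3], cnt[g, 4:6], ns[4:6])
      pz <- zTestP(cnt[g, 1:3], ns[1:3], cnt[g, 4:6], ns[4:6])
      dp[g] <- abs(bb$p.value - pz)
      exact[g] <- is.infinite(bb$df)
    }
    expect_gt(mean(exact), 0.4)           # zero-estimate rows are common
    expect_lt(max(dp[exact == 1]), 1e-10) # and agree exactly with z
    expect_lt(median(dp), 0.02)           # overall close agreement
  })
})

test_that("supplying a known dispersion gives a normal reference", {
  x <- c(120, 180, 125); n <- rep(1e5, 3)
  y <- c(40, 35, 60)
  bb <- baggerlyTest(x, n, y, n, dispersion = 0.02)
  expect_true(is.infinite(bb$df))
  expect_equal(bb$p.value, 2 * stats::pnorm(-abs(bb$statistic)))
})

test_that("BH adjustment matches the hand computation and a brute-force step-up", {
  expect_equal(bhFdr(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhFdr(c(0.5, NA)), "\\[0, 1\\]")
  withr::with_seed(13, {
    for (rep in 1:10) {
      p <- stats::runif(sample(5:200, 1))^sample(1:3, 1)
      q <- bhFdr(p)
      expect_equal(q, bruteBH(p))
      expect_true(all(q >= p))
      # permutation invariance
      o <- sample(length(p))
      expect_equal(bhFdr(p[o]), q[o])
    }
  })
})

test_that("CLIP and SOLiD filters bind at their stated boundaries", {
  enr <- data.frame(
    ip_mean_reads = c(49.9, 50, 60, 60, 60),
    log2_ratio = c(5, 2, 0, 1, Inf),
    q_value = c(0.001, 0.009, 0.001, 0.02, 0.009),
    mean_rpkm = c(100, 50, 100, 100, 49))
  expect_equal(clipFilter(enr), c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # the SOLiD rule has no raw-read floor, so the first row passes
  expect_equal(solidFilter(enr), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # boundary case: q = 0.009, RPKM exactly 50, log2 = 1.5 -> pass
  one <- data.frame(ip_mean_reads = 60, log2_ratio = 1.5, q_value = 0.009,
                    mean_rpkm = 50)
  expect_true(solidFilter(one))
  expect_false(solidFilter(transform(one, q_value = 0.02)))
  # log2(40/10) = 2 passes the CLIP fold rule
  expect_true(clipFilter(data.frame(ip_mean_reads = 60,
                                    log2_ratio = log2(40 / 10))))
})

test_that("transcript enrichment tables are complete and internally consistent", {
  sim <- simulateRip(RipSimConfig(n_transcripts = 300, n_enriched = 30,
                                  seed = 6))
  enr <- ripEnrichment(sim$experiment)
  expect_equal(nrow(enr), 300)
  expect_equal(enr$id, rownames(sim$experiment))
  expect_true(all(enr$p_value >= 0 & enr$p_value <= 1))
  expect_true(all(enr$q_value >= enr$p_value))
  expect_equal(enr$q_value, bhFdr(enr$p_value))
  expect_equal(enr$passes_clip, clipFilter(enr))
  expect_equal(enr$passes_solid, solidFilter(enr))
  # group means recompute from the raw matrix
  cnt <- SummarizedExperiment::assay(sim$experiment, "counts")
  grp <- ipGroup(sim$experiment)
  expect_equal(enr$ip_mean_reads,
               unname(rowMeans(cnt[, grp == "IP"])))
  tt <- tpm(cnt, transcriptLengths(sim$experiment))
  expect_equal(enr$ip_mean_tpm, unname(rowMeans(tt[, grp == "IP"])))
  expect_equal(enr$log2_ratio,
               unname(log2(enrichmentRatio(rowMeans(tt[, grp == "IP"]),
                                           rowMeans(tt[, grp == "control"])))))
  expect_error(ripEnrichment(sim$experiment, dispersion = "bogus"),
               "dispersion")
})

test_that("few transcripts pass the 1% FDR under the null across seeds", {
  fracs <- vapply(c(101, 102, 103), function(s) {
    sim <- simulateRip(RipSimConfig(n_transcripts = 1000, n_enriched = 0,
                                    enrichment_fold = 1, seed = s))
    mean(ripEnrichment(sim$experiment)$q_value <= 0.01)
  }, numeric(1))
  expect_true(all(fracs <= 0.02))
})
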