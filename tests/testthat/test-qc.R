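## Minimal probe table builder: nProbes x samples with 3 housekeeping rows,
## two plate sets each holding two reference samples.
.probeFixture <- function(counts, nHk = 3, sets = NULL, pairs = NULL,
                          isRef = NULL) {
  nP <- nrow(counts); nS <- ncol(counts)
  if (is.null(rownames(counts)) || any(rownames(counts) == ""))
    rownames(counts) <- c(sprintf("p%02d", seq_len(nP - nHk)),
                          sprintf("HK%d", seq_len(nHk)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%02d", seq_len(nS))
  if (is.null(sets)) sets <- rep("set01", nS)
  if (is.null(isRef)) isRef <- rep(FALSE, nS)
  if (is.null(pairs)) pairs <- rep(NA_character_, nS)
  dielNet:::ProbeCountTable(
    counts,
    probeData = data.frame(probe = rownames(counts),
                           housekeeping = c(rep(FALSE, nP - nHk),
                                            rep(TRUE, nHk))),
    sampleData = data.frame(sample_id = colnames(counts), set = sets,
                            is_reference = isRef, pair_id = pairs,
                            condition = rep(c("WW", "D"), length.out = nS),
                            zt = 1, replicate = "B1"))
}

test_that("identical samples normalize to themselves; doubling is removed", {
  set.seed(8)
  base <- matrix(rpois(10 * 6, 500), 10, 6)
  base[] <- rep(base[, 1], 6)                     # identical columns
  pct <- .probeFixture(base)
  norm <- normalizeProbeCounts(pct, steps = "content")
  expect_equal(probeCounts(norm), probeCounts(pct), tolerance = 1e-12)

  doubled <- base; doubled[, 3] <- doubled[, 3] * 2
  n2 <- normalizeProbeCounts(.probeFixture(doubled), steps = "content")
  expect_equal(probeCounts(n2)[, 3], probeCounts(n2)[, 1], tolerance = 1e-9)
})

test_that("housekeeping geometric means equalize and the step is idempotent", {
  set.seed(9)
  counts <- matrix(rpois(12 * 8, 400) * rep(runif(8, 0.5, 2), each = 12), 12, 8)
  pct <- .probeFixture(counts)
  n1 <- normalizeProbeCounts(pct, steps = "content")
  hk <- probeData(n1)$housekeeping
  gm <- apply(probeCounts(n1)[hk, ], 2, function(x) exp(mean(log(x))))
  expect_lt(max(gm) - min(gm), 1e-9)
  n2 <- normalizeProbeCounts(n1, steps = "content")
  expect_equal(probeCounts(n2), probeCounts(n1), tolerance = 1e-9)
})

test_that("codeset step equalizes reference rows across sets", {
  set.seed(10)
  lam <- rpois(12, 600)
  mk <- function(f) sapply(1:4, function(i) rpois(12, lam * f))
  counts <- cbind(mk(1), mk(1.8))
  sets <- rep(c("set01", "set02"), each = 4)
  isRef <- rep(c(FALSE, FALSE, TRUE, TRUE), 2)
  pct <- .probeFixture(counts, sets = sets, isRef = isRef)
  norm <- normalizeProbeCounts(pct, steps = "codeset")
  refGeo <- vapply(c("set01", "set02"), function(s) {
    ix <- which(sets == s & isRef)
    exp(mean(log(probeCounts(norm)[, ix])))
  }, numeric(1))
  expect_equal(refGeo[[1]], refGeo[[2]], tolerance = 1e-9)
  ## zero housekeeping count rejects the sample by name
  bad <- counts; bad[12, 2] <- 0
  expect_error(normalizeProbeCounts(.probeFixture(bad, sets = sets,
                                                  isRef = isRef)), "s02")
})

test_that("modified Z-score matches the hand-computed example", {
  x <- c(10, 12, 11, 10, 11, 50)
  counts <- matrix(rep(x, each = 2), 2, 6, byrow = FALSE)
  counts <- rbind(matrix(x, 1), matrix(rep(300, 6), 3, 6))   # probe + 3 hk
  f <- modifiedZscoreFilter(.probeFixture(counts, nHk = 3), cut = 3)
  ## median 11, MAD 1: M(50) = 0.6745 * 39 = 26.3
  expect_equal(f$zscores[1, 6], 0.6745 * 39, tolerance = 1e-12)
  expect_true(f$flags[1, 6])
  expect_equal(sum(f$flags), 1)
  expect_true(is.na(probeCounts(f$table)[1, 6]))
  ## constant probes produce no flags (MAD and meanAD both 0)
  expect_false(any(f$flags[2:4, ]))
  expect_true(all(rownames(counts)[2:4] %in% f$fallbackProbes))
})

test_that("MAD = 0 fallback uses the mean absolute deviation", {
  x <- c(rep(100, 7), 1000)
  counts <- rbind(x, matrix(200, 3, 8))
  f <- modifiedZscoreFilter(.probeFixture(counts, nHk = 3), cut = 3)
  med <- 100; meanAD <- mean(abs(x - med))
  expect_equal(f$zscores[1, 8], 0.7979 * 900 / meanAD, tolerance = 1e-12)
  expect_true(rownames(probeCounts(f$table))[1] %in% f$fallbackProbes)
})

test_that("whole-probe removal mode drops the probe entirely", {
  x <- c(10, 12, 11, 10, 11, 50)
  counts <- rbind(x, matrix(300, 3, 6))
  f <- modifiedZscoreFilter(.probeFixture(counts, nHk = 3), cut = 3,
                            wholeProbe = TRUE)
  expect_true(all(is.na(probeCounts(f$table)[1, ])))
})

test_that("planted spikes are fully masked with low false masking", {
  cfg <- simulationConfig(seed = 13, amplitudeRel = 0)
  sim <- simulateExperiment(cfg)
  pc <- simulateProbeCounts(sim$truth, cfg)
  f <- modifiedZscoreFilter(normalizeProbeCounts(pc$table), cut = 3)
  spk <- spikeMatrix(pc)
  expect_equal(mean(f$flags[spk]), 1)
  expect_lte(mean(f$flags[!spk]), 0.01)
})

test_that("technical-replicate choice keeps the cleaner member", {
  set.seed(15)
  lam <- rpois(12, 500)
  counts <- sapply(1:6, function(i) rpois(12, lam))
  pairs <- c("pr1", "pr1", "pr2", "pr2", NA, NA)
  counts[3, 2] <- counts[3, 2] * 10               # spike in pair pr1 member 2
  pct <- .probeFixture(counts, pairs = pairs)
  out <- chooseTechnicalReplicate(pct)
  ch <- attr(out, "choice")
  expect_true("s01" %in% ch$kept)
  expect_true("s02" %in% ch$discarded)
  expect_equal(ncol(probeCounts(out)), 4)
  ## the kept member always has the lower max |M|
  z <- modifiedZscoreFilter(pct, cut = Inf)$zscores
  mx <- apply(abs(z), 2, max)
  expect_lte(mx[ch$kept[1]], mx[ch$discarded[1]])
  ## identical members: lexicographically first sample id kept
  same <- .probeFixture(cbind(counts[, 1], counts[, 1], counts[, 3:6]),
                        pairs = pairs)
  chSame <- attr(chooseTechnicalReplicate(same), "choice")
  expect_true("s01" %in% chSame$kept)
  badPair <- .probeFixture(counts, pairs = c("pr1", NA, NA, NA, NA, NA))
  expect_error(chooseTechnicalReplicate(badPair), "two members")
})

test_that("replicate summaries match hand computation and flip symmetry", {
  set.seed(16)
  counts <- rbind(p1 = c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15),
                  matrix(rpois(30, 300), 3, 10))
  pct <- .probeFixture(counts, nHk = 3)
  sdf <- pct@sampleData
  sdf$condition <- rep(c("WW", "D"), each = 5)
  pct <- dielNet:::ProbeCountTable(probeCounts(pct), probeData(pct), sdf)
  rs <- replicateSummaryTests(pct, conditions = c("D", "WW"),
                              alternative = "greater")
  s <- rs$summary[rs$summary$probe == "p01" & rs$summary$condition == "WW", ]
  expect_equal(s$mean, 3)
  expect_equal(s$se, sqrt(2.5) / sqrt(5), tolerance = 1e-12)
  pGreater <- rs$tests$p[rs$tests$probe == "p01"]
  rs2 <- replicateSummaryTests(pct, conditions = c("WW", "D"),
                               alternative = "greater")
  expect_equal(rs2$tests$p[rs2$tests$probe == "p01"], 1 - pGreater,
               tolerance = 1e-12)
  expect_true(all(rs$tests$sig05 == (rs$tests$p < 0.05)))
})

test_that("enrichment matches the closed form and brute-force tail", {
  universe <- sprintf("g%03d", 1:100)
  ann <- data.frame(gene = universe[1:10], term = "T1")
  res <- enrichmentTest(universe[1:5], ann, universe, minTermSize = 5)
  expect_equal(res$p, choose(10, 5) / choose(100, 5) * 0 +
                 sum(dhyper(5:5, 10, 90, 5)), tolerance = 1e-12)
  expect_equal(res$p, 1 / choose(100, 5) * choose(10, 5), tolerance = 1e-12)
  ## term covering the whole universe is never enriched
  annAll <- data.frame(gene = universe, term = "ALL")
  expect_equal(enrichmentTest(universe[1:5], annAll, universe)$p, 1)
  ## brute-force tail equality on random instances with N <= 30
  set.seed(3)
  for (i in 1:10) {
    N <- sample(10:30, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(5:N, 1)
    ann2 <- data.frame(gene = uni[seq_len(K)], term = "T")
    n <- sample(2:N, 1)
    setg <- sample(uni, n)
    res2 <- enrichmentTest(setg, ann2, uni, minTermSize = 5)
    k <- sum(setg %in% ann2$gene)
    expect_equal(res2$p, sum(dhyper(k:min(K, n), K, N - K, n)),
                 tolerance = 1e-10)
  }
  expect_error(enrichmentTest(character(), ann, universe), "empty")
  expect_error(enrichmentTest("NOT_THERE", ann, universe), "within")
})

test_that("uniformly drawn gene sets give roughly uniform enrichment p", {
  set.seed(27)
  universe <- sprintf("g%03d", 1:200)
  ann <- data.frame(gene = universe[1:40], term = "T1")
  p <- replicate(300, enrichmentTest(sample(universe, 20), ann, universe)$p)
  ## discrete and conservative; mean should be near or above 0.4
  expect_gt(mean(p), 0.35)
})
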