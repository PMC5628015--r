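## Shared fixtures and independent oracles, all built in code.

## Standard 12-ZT x 2-replicate single-condition design (ZT1..ZT45 every 4 h).
dielDesign <- function(cond = "WW", nRep = 2, zts = seq(1, 45, by = 4)) {
  zt <- rep(zts, each = nRep)
  rep_ <- rep(seq_len(nRep), length(zts))
  data.frame(sample_id = sprintf("%s_ZT%02d_R%d", cond, zt, rep_),
             condition = cond, zt = zt, day = 3 + (zt >= 24),
             replicate = paste0("R", rep_))
}

## DielExpression from a bare matrix on the standard design.
makeDiel <- function(m, meta = NULL, scale = "fpkm", cond = "WW") {
  if (is.null(meta)) meta <- dielDesign(cond, nRep = ncol(m) / 12)
  colnames(m) <- meta$sample_id
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  DielExpression(m, meta, scale = scale)
}

## Naive O(n^3) signed-TOM oracle, straight from the definition.
naiveTOM <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(a[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- sum(sapply(setdiff(seq_len(n), c(i, j)), function(u) a[i, u] * a[u, j]))
    tom[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

## Brute-force null of Kendall's S by full enumeration of permutations of
## the data against a (possibly tied) reference.
enumKendallNull <- function(ref) {
  n <- length(ref)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  refS <- sign(ref[ij[, 2]] - ref[ij[, 1]])
  svals <- vapply(perms(seq_len(n)), function(x)
    sum(sign(x[ij[, 2]] - x[ij[, 1]]) * refS), numeric(1))
  table(svals) / length(svals)
}

## Planted-truth ModuleSet (labels re-ordered by size) plus the map from
## planted module id to the relabelled id.
truthModules <- function(truth, genes) {
  tg <- truthGenes(truth)
  lab0 <- setNames(tg$module, tg$gene)[genes]
  lab <- dielNet:::.relabelBySize(lab0)
  map <- vapply(sort(unique(lab0[lab0 > 0])), function(m)
    unique(lab[lab0 == m]), integer(1))
  names(map) <- sort(unique(lab0[lab0 > 0]))
  list(modules = dielNet:::ModuleSet(lab), map = map, planted = lab0)
}

## Spike indicator matrix aligned to a probe table.
spikeMatrix <- function(pc) {
  m <- matrix(FALSE, nrow(probeCounts(pc$table)), ncol(probeCounts(pc$table)),
              dimnames = dimnames(probeCounts(pc$table)))
  if (nrow(pc$spikes))
    m[cbind(match(pc$spikes$probe, rownames(m)),
            match(pc$spikes$sample_id, colnames(m)))] <- TRUE
  m
}
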