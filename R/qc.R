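## Probe-count (NanoString-style) normalization and QC, replicate summary
## statistics, and generic over-representation testing.

#' Two-step housekeeping normalization of probe counts
#'
#' CodeSet step: every plate set is scaled by the ratio of the geometric
#' mean of the pooled-RNA reference-row counts across all sets to the set's
#' own reference geometric mean, removing set-to-set scale. Content step:
#' every sample is scaled by (average across samples of the housekeeping
#' geometric means) / (the sample's housekeeping geometric mean), so all
#' samples end with identical housekeeping geometric means; applying the
#' content step twice changes nothing. Geometric means are used throughout
#' (multiplicative count model). A sample with any zero housekeeping count
#' cannot be normalized and is rejected with a report.
#'
#' @param pct a \linkS4class{ProbeCountTable} with housekeeping flags and,
#'   for the CodeSet step, reference-row samples per set.
#' @param steps normalization steps to apply, subset of
#'   c("codeset", "content").
#' @return the normalized \linkS4class{ProbeCountTable}.
#' @export
normalizeProbeCounts <- function(pct, steps = c("codeset", "content")) {
  steps <- match.arg(steps, c("codeset", "content"), several.ok = TRUE)
  counts <- pct@counts
  sd <- pct@sampleData
  hk <- pct@probeData$housekeeping
  if ("content" %in% steps) {
    bad <- colnames(counts)[apply(counts[hk, , drop = FALSE] == 0, 2, any,
                                  na.rm = TRUE)]
    if (length(bad))
      stop("zero housekeeping count in sample(s): ", paste(bad, collapse = ", "))
  }
  if ("codeset" %in% steps) {
    if (!any(sd$is_reference))
      stop("CodeSet normalization requires reference-row samples")
    refMean <- vapply(split(seq_len(ncol(counts)), sd$set), function(idx) {
      ref <- idx[sd$is_reference[idx]]
      if (!length(ref)) stop("set without reference-row samples")
      .geomean(as.numeric(counts[, ref, drop = FALSE]) + 0)
    }, numeric(1))
    target <- .geomean(refMean)
    f <- target / refMean
    counts <- sweep(counts, 2, f[sd$set], `*`)
  }
  if ("content" %in% steps) {
    hkMean <- apply(counts[hk, , drop = FALSE], 2, .geomean)
    f <- mean(hkMean) / hkMean
    counts <- sweep(counts, 2, f, `*`)
  }
  new("ProbeCountTable", counts = counts, probeData = pct@probeData,
      sampleData = sd, normalized = union(pct@normalized, steps))
}

#' Mask spurious probe counts by the modified Z-score
#'
#' For each probe across samples, the modified Z-score is
#' M_i = 0.6745 (x_i - median) / MAD with the (unscaled) median absolute
#' deviation; cells with |M| > \code{cut} are masked as missing -- the
#' occasional spurious single-sample probe count. If MAD = 0 the
#' mean-absolute-deviation fallback M_i = 0.7979 (x_i - median) / meanAD
#' is used and the probe flagged; an entirely constant probe
#' yields M = 0 everywhere and nothing is masked. With
#' \code{wholeProbe = TRUE} any flagged cell removes the whole probe
#' instead.
#'
#' @param pct a \linkS4class{ProbeCountTable} (>= 4 samples).
#' @param cut |M| threshold (default 3).
#' @param wholeProbe drop entire probes instead of masking cells.
#' @return list: \code{table} (counts with masked cells NA), \code{flags}
#'   (logical probe x sample matrix), \code{zscores}, \code{fallbackProbes}.
#' @export
modifiedZscoreFilter <- function(pct, cut = 3, wholeProbe = FALSE) {
  counts <- pct@counts
  if (ncol(counts) < 4) stop("need >= 4 samples per probe")
  z <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  fallback <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    med <- median(x, na.rm = TRUE)
    mad0 <- median(abs(x - med), na.rm = TRUE)
    if (mad0 > 0) {
      z[i, ] <- 0.6745 * (x - med) / mad0
    } else {
      meanAD <- mean(abs(x - med), na.rm = TRUE)
      fallback[i] <- TRUE
      z[i, ] <- if (meanAD > 0) 0.7979 * (x - med) / meanAD else 0
    }
  }
  flags <- !is.na(z) & abs(z) > cut
  masked <- counts
  if (wholeProbe) {
    drop <- rowSums(flags) > 0
    masked[drop, ] <- NA
  } else {
    masked[flags] <- NA
  }
  out <- new("ProbeCountTable", counts = pmax(masked, 0), probeData = pct@probeData,
             sampleData = pct@sampleData, normalized = pct@normalized)
  list(table = out, flags = flags, zscores = z,
       fallbackProbes = rownames(counts)[fallback])
}

#' Choose one member of each technical-replicate pair
#'
#' For every pair, keeps the member whose maximum |modified Z-score| over
#' probes is smaller (the cleaner replicate); ties are broken by
#' lexicographic sample id. Unpaired samples listed with a pair id are
#' rejected.
#'
#' @param pct a \linkS4class{ProbeCountTable} whose sampleData has
#'   \code{pair_id} (NA for unpaired samples).
#' @return the \linkS4class{ProbeCountTable} with the discarded members
#'   removed; kept/discarded ids in attribute "choice".
#' @export
chooseTechnicalReplicate <- function(pct) {
  sdf <- pct@sampleData
  paired <- !is.na(sdf$pair_id)
  if (!any(paired)) return(pct)
  tab <- table(sdf$pair_id[paired])
  if (any(tab != 2))
    stop("pair(s) without exactly two members: ",
         paste(names(tab)[tab != 2], collapse = ", "))
  z <- modifiedZscoreFilter(pct, cut = Inf)$zscores
  maxAbs <- apply(abs(z), 2, max, na.rm = TRUE)
  drop <- character()
  for (p in names(tab)) {
    idx <- which(sdf$pair_id == p)
    ids <- sdf$sample_id[idx]
    o <- order(maxAbs[idx], ids)
    drop <- c(drop, ids[o[2]])
  }
  keep <- !sdf$sample_id %in% drop
  out <- new("ProbeCountTable", counts = pct@counts[, keep, drop = FALSE],
             probeData = pct@probeData, sampleData = sdf[keep, ],
             normalized = pct@normalized)
  attr(out, "choice") <- list(kept = setdiff(sdf$sample_id[paired], drop),
                              discarded = drop)
  out
}

#' Per-probe per-time-point replicate summary and one-tailed t-tests
#'
#' Averages the biological replicates of each (probe, condition, ZT) cell,
#' computes the standard error, and compares the two conditions at every
#' time point with an unpaired Student's t-test in the supplied direction.
#' Significance is flagged at p < 0.05. Masked (NA) cells are omitted from
#' the summaries.
#'
#' @param pct a normalized \linkS4class{ProbeCountTable} whose sampleData
#'   has condition and zt (reference-row samples are ignored).
#' @param conditions two condition labels, compared as first vs second.
#' @param alternative "less", "greater" or "two.sided" for mean(first) vs
#'   mean(second).
#' @return list: \code{summary} (probe, condition, zt, n, mean, se),
#'   \code{tests} (probe, zt, t, df, p, sig05).
#' @export
replicateSummaryTests <- function(pct, conditions = c("D", "WW"),
                                  alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  sdf <- pct@sampleData
  use <- !sdf$is_reference & sdf$condition %in% conditions
  counts <- pct@counts[, use, drop = FALSE]
  sdf <- sdf[use, ]
  cells <- expand.grid(probe = rownames(counts),
                       condition = conditions,
                       zt = sort(unique(sdf$zt)), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- sdf$condition == cells$condition[i] & sdf$zt == cells$zt[i]
    x <- counts[cells$probe[i], sel]
    x <- x[!is.na(x)]
    data.frame(probe = cells$probe[i], condition = cells$condition[i],
               zt = cells$zt[i], n = length(x), mean = mean(x),
               se = sd(x) / sqrt(length(x)))
  }))
  zts <- sort(unique(sdf$zt))
  tests <- do.call(rbind, lapply(rownames(counts), function(pr) {
    do.call(rbind, lapply(zts, function(z) {
      x <- counts[pr, sdf$condition == conditions[1] & sdf$zt == z]
      y <- counts[pr, sdf$condition == conditions[2] & sdf$zt == z]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2)
        stop("need >= 2 biological replicates per group (probe ", pr,
             ", ZT", z, ")")
      tt <- studentTTest(x, y, alternative = alternative)
      data.frame(probe = pr, zt = z, t = tt$t, df = tt$df, p = tt$p)
    }))
  }))
  tests$sig05 <- tests$p < 0.05
  rownames(summ) <- rownames(tests) <- NULL
  list(summary = summ, tests = tests)
}

#' Hypergeometric over-representation test for a gene set
#'
#' One-sided enrichment of annotation terms in a gene set against a
#' universe: per term with at least \code{minTermSize} annotated genes in
#' the universe, p = P(X >= k) for X ~ Hypergeometric(N = |universe|,
#' K = term size, n = |set|), with Benjamini-Hochberg correction across the
#' tested terms.
#'
#' @param geneSet character vector (must be a subset of \code{universe}).
#' @param annotation data.frame with columns \code{gene}, \code{term}.
#' @param universe character vector of all considered genes.
#' @param minTermSize smallest term tested (default 5).
#' @param topK optionally return only the K most significant terms.
#' @return data.frame: term, k, K, n, N, p, q, ordered by p.
#' @export
enrichmentTest <- function(geneSet, annotation, universe, minTermSize = 5,
                           topK = NULL) {
  if (!length(universe) || !length(geneSet)) stop("empty universe or gene set")
  if (!all(geneSet %in% universe)) stop("gene set must be within the universe")
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  termSize <- table(ann$term)
  terms <- names(termSize)[termSize >= minTermSize]
  if (!length(terms))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  N <- length(universe); n <- length(geneSet)
  rows <- lapply(terms, function(tm) {
    members <- unique(ann$gene[ann$term == tm])
    K <- length(members)
    k <- length(intersect(geneSet, members))
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = .hyperTail(k, K, n, N))
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  if (!is.null(topK)) out <- head(out, topK)
  out
}
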