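## Module correspondence between two condition networks: overlap counts with
## one-sided Fisher (hypergeometric) significance, module resolution, and
## consensus modules from the element-wise minimum TOM.

#' Module overlap matrix with Fisher significance
#'
#' Over the shared gene universe (the intersection of the genes present in
#' both assignments, including unassigned genes), counts the genes in common
#' between every module of network A and every module of network B and
#' computes the one-sided hypergeometric (Fisher over-representation)
#' p-value P(X >= k) for X ~ Hypergeometric(N = |universe|, K = |A_a|,
#' n = |B_b|). Display values are -log10(p) capped at \code{cap} (default
#' 50, i.e. p = 1e-50). Unassigned (label 0) genes contribute to N but have
#' no overlap cell.
#'
#' @param modA,modB \linkS4class{ModuleSet}s from the two networks.
#' @param cap display cap for -log10(p).
#' @return an \linkS4class{OverlapResult}.
#' @export
overlapMatrix <- function(modA, modB, cap = 50) {
  la <- moduleLabels(modA); lb <- moduleLabels(modB)
  universe <- intersect(names(la), names(lb))
  if (!length(universe)) stop("empty shared gene universe")
  la <- la[universe]; lb <- lb[universe]
  aMods <- sort(unique(la[la > 0])); bMods <- sort(unique(lb[lb > 0]))
  N <- length(universe)
  counts <- matrix(0L, length(aMods), length(bMods),
                   dimnames = list(paste0("A", aMods), paste0("B", bMods)))
  p <- matrix(1, length(aMods), length(bMods), dimnames = dimnames(counts))
  for (i in seq_along(aMods)) for (j in seq_along(bMods)) {
    K <- sum(la == aMods[i]); n <- sum(lb == bMods[j])
    k <- sum(la == aMods[i] & lb == bMods[j])
    counts[i, j] <- k
    p[i, j] <- .hyperTail(k, K, n, N)
  }
  display <- pmin(-log10(p), cap)
  new("OverlapResult", counts = counts, p = p, display = display,
      universeSize = N, cap = cap)
}

#' @describeIn overlapMatrix overlap counts matrix
#' @param x an OverlapResult
#' @export
overlapCounts <- function(x) x@counts

#' @describeIn overlapMatrix one-sided hypergeometric p-values
#' @export
overlapP <- function(x) x@p

#' @describeIn overlapMatrix capped -log10(p) display values
#' @export
overlapDisplay <- function(x) x@display

#' Resolve one module of network A across the modules of network B
#'
#' Reports the fraction of the A-module's genes (restricted to the shared
#' universe) falling in each B-module, sorted descending; genes unassigned
#' in B make up the remainder, so the fractions sum to <= 1. With an
#' expression matrix, the mean expression profile of each sub-group is
#' attached (the "module resolution" view of how one control-network module
#' splits under treatment).
#'
#' @param modA,modB \linkS4class{ModuleSet}s.
#' @param moduleId module label in A to resolve.
#' @param em optional \linkS4class{DielExpression} for sub-group profiles.
#' @return data.frame (module_b, n, fraction), with attribute "profiles"
#'   (list of mean per-sample profiles) when \code{em} is given.
#' @export
resolveModule <- function(modA, moduleId, modB, em = NULL) {
  la <- moduleLabels(modA); lb <- moduleLabels(modB)
  if (!moduleId %in% la) stop("unknown module id: ", moduleId)
  universe <- intersect(names(la), names(lb))
  genes <- intersect(names(la)[la == moduleId], universe)
  tgt <- lb[genes]
  tab <- table(tgt[tgt > 0])
  out <- data.frame(module_b = as.integer(names(tab)), n = as.integer(tab),
                    fraction = as.integer(tab) / length(genes))
  out <- out[order(-out$fraction, out$module_b), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(em)) {
    v <- exprValues(em)
    profs <- lapply(out$module_b, function(b) {
      gs <- intersect(names(tgt)[tgt == b], rownames(v))
      colMeans(v[gs, , drop = FALSE])
    })
    names(profs) <- paste0("B", out$module_b)
    attr(out, "profiles") <- profs
  }
  out
}

#' Consensus modules from two condition networks
#'
#' Restricts both TOMs to the shared gene universe, optionally rescales the
#' second so its upper quantile matches the first (preventing a globally
#' weaker network from dominating the minimum), takes the element-wise
#' minimum as the consensus TOM, and runs the standard module detection and
#' eigengene merging on it. Only co-expression supported in both conditions
#' survives the minimum.
#'
#' @param tomA,tomB TOM matrices with gene dimnames.
#' @param minSize minimum module size (default 30).
#' @param mergeCut eigengene merge threshold (default 0.25); merging needs
#'   \code{em}.
#' @param em optional \linkS4class{DielExpression} or list of the two
#'   condition matrices used for the merge step; if NULL, merging is
#'   skipped.
#' @param scaleQuantile quantile used for the calibration (default 0.95);
#'   NULL disables scaling.
#' @return a \linkS4class{ModuleSet} on the shared universe.
#' @export
consensusModules <- function(tomA, tomB, minSize = 30, mergeCut = 0.25,
                             em = NULL, scaleQuantile = 0.95) {
  .checkSquareSym(tomA, "TOM A"); .checkSquareSym(tomB, "TOM B")
  shared <- intersect(rownames(tomA), rownames(tomB))
  if (!length(shared)) stop("disjoint gene universes")
  a <- tomA[shared, shared]; b <- tomB[shared, shared]
  if (!is.null(scaleQuantile)) {
    qa <- quantile(a[upper.tri(a)], scaleQuantile)
    qb <- quantile(b[upper.tri(b)], scaleQuantile)
    if (qb > 0) b <- pmin(b * (qa / qb), 1)
    diag(b) <- 1
  }
  cons <- pmin(a, b)
  mods <- detectModules(cons, minSize = minSize)
  if (!is.null(em) && length(moduleSizes(mods)) > 1) {
    ems <- if (is.list(em)) em else list(em)
    ems <- lapply(ems, function(e) e[intersect(rownames(e), shared), ])
    mods <- mergeCloseModules(ems, mods, mergeCut = mergeCut)
  }
  mods
}
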