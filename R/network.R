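## Signed weighted co-expression network construction and module detection.
##
## All time points x replicates of one condition form that condition's
## network input; replicates are not averaged (more columns stabilize the
## correlations). Pearson correlation is used throughout.

.checkSquareSym <- function(m, what, tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop(what, " must be symmetric")
  invisible(TRUE)
}

#' Signed soft-thresholded adjacency
#'
#' \deqn{a_{ij} = ((1 + cor(x_i, x_j))/2)^\beta}
#' with Pearson correlation and unit diagonal. The signed rescaling maps
#' anti-correlated genes toward adjacency 0 rather than folding them onto
#' positive correlations; the soft power beta (default 16) emphasizes strong
#' co-expression without a hard cutoff. Zero-variance genes are dropped with
#' a warning before the correlation.
#'
#' @param em a \linkS4class{DielExpression} on the log2 scale with >= 4
#'   samples.
#' @param beta soft-threshold power (> 0).
#' @return genes x genes adjacency matrix in [0,1] with attribute "beta".
#' @export
signedAdjacency <- function(em, beta = 16) {
  if (beta <= 0) stop("beta must be positive")
  if (exprScale(em) != "log2")
    stop("network construction expects log2-scale values")
  v <- exprValues(em)
  if (ncol(v) < 4) stop("need >= 4 samples")
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s)")
    v <- v[sds > 0, , drop = FALSE]
    if (nrow(v) == 0) stop("no genes with non-zero variance remain")
  }
  a <- ((1 + cor(t(v))) / 2)^beta
  a <- (a + t(a)) / 2
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Signed topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' for i != j, where \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} counts the
#' shared weighted neighborhood and \eqn{k_i = \sum_{u \ne i} a_{iu}} is the
#' connectivity; TOM_ii = 1. 1 - TOM is the clustering dissimilarity.
#'
#' @param adj symmetric adjacency in [0,1] with unit diagonal (from
#'   \code{\link{signedAdjacency}}).
#' @return genes x genes TOM matrix in [0,1] with unit diagonal.
#' @export
topologicalOverlap <- function(adj) {
  .checkSquareSym(adj, "adjacency")
  if (any(adj < -1e-12) || any(adj > 1 + 1e-12))
    stop("adjacency values must lie in [0,1]")
  a <- adj
  diag(a) <- 1
  L <- a %*% a - 2 * a            # removes the u = i and u = j terms (a_ii = 1)
  k <- colSums(a) - 1
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- dimnames(adj)
  tom
}

## Adaptive top-down branch decomposition of an average-linkage tree.
## A node whose join height exceeds cutHeight is split into its children;
## a node at or below cutHeight becomes a module if it holds >= minSize
## leaves. Loose background genes chain together near the maximum merge
## height, so with cutHeight just below it they dissolve into sub-minSize
## fragments and stay unassigned.
.cutBranches <- function(hc, minSize, cutHeight) {
  n <- length(hc$order)
  nm <- nrow(hc$merge)
  members <- vector("list", nm)
  for (k in seq_len(nm)) {
    ch <- hc$merge[k, ]
    members[[k]] <- c(if (ch[1] < 0) -ch[1] else members[[ch[1]]],
                      if (ch[2] < 0) -ch[2] else members[[ch[2]]])
  }
  labels <- integer(n)
  nextLab <- 0L
  stack <- nm                      # root
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node < 0) next             # single leaf: unassigned
    if (hc$height[node] > cutHeight) {
      stack <- c(stack, hc$merge[node, ])
    } else if (length(members[[node]]) >= minSize) {
      nextLab <- nextLab + 1L
      labels[members[[node]]] <- nextLab
    }
  }
  names(labels) <- hc$labels
  labels
}

#' Detect modules by adaptive branch cutting of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on 1 - TOM followed by a top-down
#' adaptive branch decomposition: starting from the root, any node joining
#' its children above the cut height is split, and branches of at least
#' \code{minSize} genes below the cut become modules; all other genes get
#' label 0 (unassigned). The cut height defaults to
#' \code{cutHeightFrac * max(merge heights)}, placing it just below the
#' loose top-level joins so incoherent background genes fall apart into
#' sub-threshold fragments instead of forming spurious modules. A static
#' single-height cut (\code{method = "static"} with \code{cutHeight}) is
#' available as a fallback. Labels are ordered by decreasing module size.
#'
#' Accepted branches are then trimmed by intramodular connectivity: a
#' member whose mean TOM to the rest of the module is below
#' \code{trimFrac} times the module's median member connectivity is
#' returned to the background (such genes are loosely attached passengers
#' picked up near the cut height, not part of the co-expressed core).
#' Modules falling below \code{minSize} after trimming are dissolved.
#'
#' @param tom TOM matrix from \code{\link{topologicalOverlap}}.
#' @param minSize minimum module size (default 30, >= 2).
#' @param cutHeightFrac fraction of the maximum merge height used as the
#'   adaptive cut (default 0.99).
#' @param method "adaptive" (default) or "static".
#' @param cutHeight explicit cut height for \code{method = "static"}.
#' @param trimFrac connectivity-trimming fraction in [0,1); 0 disables
#'   trimming (default 0.5).
#' @return a \linkS4class{ModuleSet} (dendrogram attached).
#' @export
detectModules <- function(tom, minSize = 30, cutHeightFrac = 0.99,
                          method = c("adaptive", "static"), cutHeight = NULL,
                          trimFrac = 0.5) {
  method <- match.arg(method)
  if (minSize < 2) stop("minSize must be >= 2")
  .checkSquareSym(tom, "TOM")
  if (nrow(tom) < 2 * minSize)
    stop("need at least 2 * minSize genes")
  if (is.null(rownames(tom)))
    rownames(tom) <- colnames(tom) <- paste0("g", seq_len(nrow(tom)))
  d <- as.dist(1 - tom)
  hc <- hclust(d, method = "average")
  if (method == "adaptive") {
    h <- cutHeightFrac * max(hc$height)
    labels <- .cutBranches(hc, minSize, h)
  } else {
    if (is.null(cutHeight)) cutHeight <- cutHeightFrac * max(hc$height)
    cl <- cutree(hc, h = cutHeight)
    keep <- names(which(table(cl) >= minSize))
    labels <- ifelse(cl %in% as.integer(keep), cl, 0L)
    names(labels) <- hc$labels
  }
  if (trimFrac > 0) {
    for (m in setdiff(unique(labels), 0L)) {
      members <- which(labels == m)
      sub <- tom[members, members, drop = FALSE]
      kim <- (rowSums(sub) - 1) / (length(members) - 1)
      drop <- kim < trimFrac * median(kim)
      if (any(drop)) labels[members[drop]] <- 0L
      if (sum(labels == m) < minSize) labels[labels == m] <- 0L
    }
  }
  labels <- .relabelBySize(labels)
  ModuleSet(labels,
            params = list(minSize = minSize, method = method,
                          cutHeightFrac = cutHeightFrac, trimFrac = trimFrac),
            dendrogram = hc)
}

#' Module eigengenes: first principal component per module
#'
#' Each member gene is standardized across samples (z-score); the eigengene
#' is the first right singular vector of the module's standardized
#' submatrix, normalized to unit Euclidean norm and oriented so that it
#' correlates non-negatively with the module's mean standardized profile
#' (tie-break for a degenerate mean profile: non-negative loading on the
#' lexicographically first member gene). The variance explained is the first
#' squared singular value over the total.
#'
#' @param em the \linkS4class{DielExpression} the modules were built from.
#' @param modules a \linkS4class{ModuleSet}.
#' @return an \linkS4class{EigengeneSet} with rows "ME1", "ME2", ...
#' @export
moduleEigengenes <- function(em, modules) {
  labels <- moduleLabels(modules)
  labels <- labels[labels > 0]
  if (!length(labels)) stop("no assigned modules")
  v <- exprValues(em)
  if (ncol(v) < 3) stop("need >= 3 samples")
  miss <- setdiff(names(labels), rownames(v))
  if (length(miss)) stop("module genes absent from expression matrix")
  mods <- sort(unique(labels))
  me <- matrix(NA_real_, length(mods), ncol(v),
               dimnames = list(paste0("ME", mods), colnames(v)))
  ve <- numeric(length(mods))
  for (i in seq_along(mods)) {
    genes <- sort(names(labels)[labels == mods[i]])
    x <- v[genes, , drop = FALSE]
    z <- t(scale(t(x)))
    if (nrow(z) == 1) {
      warning("module ", mods[i], " has a single gene; eigengene is its z-score")
      vec <- as.numeric(z)
      vec <- vec / sqrt(sum(vec^2))
      me[i, ] <- vec
      ve[i] <- 1
      next
    }
    sv <- svd(z, nu = 1, nv = 1)
    vec <- sv$v[, 1]
    meanProf <- colMeans(z)
    orient <- sum(vec * meanProf)
    if (abs(orient) < 1e-10) orient <- sv$u[1, 1]   # first (sorted) member gene
    if (orient < 0) vec <- -vec
    me[i, ] <- vec / sqrt(sum(vec^2))
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  new("EigengeneSet", eigengenes = me, varianceExplained = ve,
      sampleData = colData(em)[, c("condition", "zt", "day", "replicate")])
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity 1 - cor(ME_a, ME_b) while it is below \code{mergeCut},
#' recomputing eigengenes after every merge until stable. With a list of
#' expression matrices (consensus use), the dissimilarity is the maximum
#' over the conditions, so modules merge only if their eigengenes agree in
#' every condition.
#'
#' @param em a \linkS4class{DielExpression}, or a list of them.
#' @param modules a \linkS4class{ModuleSet}.
#' @param mergeCut dissimilarity threshold in (0,1), default 0.25.
#' @return the merged \linkS4class{ModuleSet} (labels re-ordered by size).
#' @export
mergeCloseModules <- function(em, modules, mergeCut = 0.25) {
  if (mergeCut <= 0 || mergeCut >= 1) stop("mergeCut must lie in (0,1)")
  ems <- if (is.list(em)) em else list(em)
  labels <- moduleLabels(modules)
  repeat {
    ms <- ModuleSet(labels, params = modules@params)
    mods <- as.integer(names(moduleSizes(ms)))
    if (length(mods) < 2) break
    diss <- matrix(0, length(mods), length(mods))
    for (e in ems) {
      meMat <- eigengenes(moduleEigengenes(e, ms))
      diss <- pmax(diss, 1 - cor(t(meMat)))
    }
    diag(diss) <- Inf
    if (min(diss) >= mergeCut) break
    idx <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    a <- mods[min(idx)]; b <- mods[max(idx)]
    labels[labels == b] <- a
    labels <- .relabelBySize(labels)
  }
  ModuleSet(.relabelBySize(labels),
            params = c(modules@params, list(mergeCut = mergeCut)),
            dendrogram = modules@dendrogram)
}

#' Module membership (kME) with Student p-values
#'
#' MM_gm = Pearson correlation between gene g's profile and module m's
#' eigengene, with the two-sided Student p-value from
#' t = r sqrt(n-2) / sqrt(1-r^2). Hub genes are the highest |MM| within
#' their own module.
#'
#' @param em a \linkS4class{DielExpression} (samples aligned with the
#'   eigengenes).
#' @param egs an \linkS4class{EigengeneSet}.
#' @return list with matrices \code{mm} and \code{p} (genes x modules).
#' @export
moduleMembership <- function(em, egs) {
  v <- exprValues(em)
  me <- eigengenes(egs)
  if (!identical(colnames(v), colnames(me)))
    stop("samples of the expression matrix and eigengenes are not aligned")
  n <- ncol(v)
  mm <- cor(t(v), t(me))
  tstat <- mm * sqrt(n - 2) / sqrt(pmax(1 - mm^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  list(mm = mm, p = p)
}

#' Export a thresholded network edge list and node table
#'
#' Writes undirected edges with TOM weight >= threshold (diagonal excluded)
#' annotated with the endpoint module labels, and a node table with module
#' label and own-module |MM| ("hubness") when membership is supplied.
#'
#' @param tom TOM matrix.
#' @param modules a \linkS4class{ModuleSet}.
#' @param mm optional result of \code{\link{moduleMembership}}.
#' @param threshold minimum edge weight in [0,1] (default 0.1).
#' @param edgeFile,nodeFile optional TSV output paths.
#' @return list with data.frames \code{edges} (source, target, weight,
#'   source_module, target_module) and \code{nodes}.
#' @export
exportNetworkEdges <- function(tom, modules, mm = NULL, threshold = 0.1,
                               edgeFile = NULL, nodeFile = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0,1]")
  .checkSquareSym(tom, "TOM")
  labels <- moduleLabels(modules)
  genes <- rownames(tom)
  ut <- upper.tri(tom)
  keep <- which(ut & tom >= threshold, arr.ind = TRUE)
  edges <- data.frame(source = genes[keep[, 1]], target = genes[keep[, 2]],
                      weight = tom[keep],
                      source_module = unname(labels[genes[keep[, 1]]]),
                      target_module = unname(labels[genes[keep[, 2]]]))
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  nodes <- data.frame(gene = genes, module = unname(labels[genes]))
  if (!is.null(mm)) {
    own <- rep(NA_real_, length(genes))
    assigned <- nodes$module > 0
    own[assigned] <- abs(mm$mm[cbind(match(nodes$gene[assigned], rownames(mm$mm)),
                                     match(paste0("ME", nodes$module[assigned]),
                                           colnames(mm$mm)))])
    nodes$hubness <- own
  }
  if (!is.null(edgeFile))
    write.table(edges, edgeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nodeFile))
    write.table(nodes, nodeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(edges = edges, nodes = nodes))
}
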