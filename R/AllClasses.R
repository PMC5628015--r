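#' @import methods
#' @importFrom stats cor sd median quantile pt phyper p.adjust hclust cutree
#'   as.dist rnorm rlnorm rpois runif setNames approx aggregate
#' @importFrom utils head write.table read.delim
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData rowData
NULL

## Central container: a genes x samples expression table for one or both
## watering conditions of a diel time course, with per-sample Zeitgeber time,
## day, condition and replicate, and a scale flag (fpkm or log2).

#' DielExpression: expression matrix with diel sample metadata
#'
#' An extension of \linkS4class{SummarizedExperiment} holding a genes x
#' samples expression matrix together with the sample design of a diel time
#' course: watering \code{condition} (\code{"WW"} well-watered or \code{"D"}
#' droughted), Zeitgeber time \code{zt} in hours since first lights-on,
#' \code{day} of the course, and biological \code{replicate}. The measurement
#' scale (\code{"fpkm"} or \code{"log2"}) is carried in
#' \code{metadata(x)$scale}; FPKM-scale values must be non-negative.
#'
#' Columns are stored in the deterministic order (condition, zt, replicate)
#' so identical data always yield identical matrices.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}
#' @export
setClass("DielExpression", contains = "SummarizedExperiment")

.validDielExpression <- function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("condition", "zt", "day", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("fpkm", "log2"))
    msg <- c(msg, "metadata(x)$scale must be 'fpkm' or 'log2'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  v <- assay(object, 1)
  if (!all(is.finite(v)))
    msg <- c(msg, "expression values must be finite")
  else if (identical(sc, "fpkm") && any(v < 0))
    msg <- c(msg, "FPKM-scale values must be non-negative")
  if (!length(miss) && any(!cd$condition %in% c("WW", "D")))
    msg <- c(msg, "condition must be 'WW' or 'D'")
  if (length(msg)) msg else TRUE
}
setValidity("DielExpression", .validDielExpression)

#' Construct a DielExpression object
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param sampleData data.frame or DataFrame with one row per sample and
#'   columns \code{sample_id}, \code{condition} ("WW"/"D"), \code{zt} (hours),
#'   \code{day}, \code{replicate}. Rows are matched to matrix columns by
#'   \code{sample_id}; every column must be described exactly once.
#' @param scale "fpkm" or "log2".
#' @return A \linkS4class{DielExpression} with columns ordered by
#'   (condition, zt, replicate).
#' @export
DielExpression <- function(values, sampleData, scale = c("fpkm", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  sampleData <- as.data.frame(sampleData)
  if (is.null(colnames(values)))
    stop("expression matrix must have sample ids as colnames")
  if (anyDuplicated(sampleData$sample_id))
    stop("duplicate sample_id in sample metadata")
  missing <- setdiff(colnames(values), sampleData$sample_id)
  if (length(missing))
    stop("expression column(s) absent from sample metadata: ",
         paste(missing, collapse = ", "))
  sampleData <- sampleData[match(colnames(values), sampleData$sample_id), , drop = FALSE]
  ord <- order(sampleData$condition, sampleData$zt, sampleData$replicate,
               sampleData$sample_id)
  values <- values[, ord, drop = FALSE]
  sampleData <- sampleData[ord, , drop = FALSE]
  cd <- DataFrame(sampleData, row.names = sampleData$sample_id)
  se <- SummarizedExperiment(assays = list(expr = values), colData = cd,
                             metadata = list(scale = scale))
  new("DielExpression", se)
}

#' Module assignment for a co-expression network
#'
#' Gene -> module labels produced by \code{\link{detectModules}} /
#' \code{\link{mergeCloseModules}}. Label 0 is reserved for unassigned
#' (background) genes; assigned modules are labelled with dense positive
#' integers ordered by decreasing size.
#'
#' @slot labels named integer vector, one entry per gene.
#' @slot params list of the detection parameters (minSize, mergeCut, ...).
#' @slot dendrogram the \code{hclust} tree the modules were cut from (or NULL).
#' @export
setClass("ModuleSet",
         representation(labels = "integer", params = "list", dendrogram = "ANY"))

.validModuleSet <- function(object) {
  msg <- character()
  lab <- object@labels
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    msg <- c(msg, "labels must be named by unique gene ids")
  if (any(lab < 0)) msg <- c(msg, "labels must be >= 0")
  pos <- lab[lab > 0]
  if (length(pos)) {
    k <- max(pos)
    sizes <- tabulate(pos, nbins = k)
    if (any(sizes == 0))
      msg <- c(msg, "module labels must be dense 1..k")
    if (is.unsorted(rev(sizes)))
      msg <- c(msg, "module labels must be ordered by decreasing size")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ModuleSet", .validModuleSet)

ModuleSet <- function(labels, params = list(), dendrogram = NULL) {
  storage.mode(labels) <- "integer"
  new("ModuleSet", labels = labels, params = params, dendrogram = dendrogram)
}

#' @describeIn ModuleSet gene -> module label vector
#' @param x a ModuleSet
#' @export
moduleLabels <- function(x) x@labels

#' @describeIn ModuleSet sizes of the assigned modules (named by label)
#' @export
moduleSizes <- function(x) {
  pos <- x@labels[x@labels > 0]
  if (!length(pos)) return(integer())
  setNames(tabulate(pos, nbins = max(pos)), seq_len(max(pos)))
}

#' Module eigengenes (first principal components)
#'
#' One unit-norm sample profile per module: the first right singular vector of
#' the module's z-scored expression submatrix, oriented so it correlates
#' non-negatively with the module's mean standardized profile.
#'
#' @slot eigengenes modules x samples matrix, rows named "ME<label>",
#'   each row unit Euclidean norm.
#' @slot varianceExplained fraction of the module's standardized variance
#'   captured by the eigengene.
#' @slot sampleData per-sample design (condition, zt, day, replicate).
#' @export
setClass("EigengeneSet",
         representation(eigengenes = "matrix", varianceExplained = "numeric",
                        sampleData = "DataFrame"))

.validEigengeneSet <- function(object) {
  msg <- character()
  e <- object@eigengenes
  if (nrow(e)) {
    nrm <- sqrt(rowSums(e^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "eigengene rows must have unit Euclidean norm")
  }
  if (length(object@varianceExplained) != nrow(e))
    msg <- c(msg, "varianceExplained must have one entry per module")
  if (nrow(object@sampleData) != ncol(e))
    msg <- c(msg, "sampleData rows must match eigengene columns")
  if (length(msg)) msg else TRUE
}
setValidity("EigengeneSet", .validEigengeneSet)

#' @describeIn EigengeneSet modules x samples eigengene matrix
#' @param x an EigengeneSet
#' @export
eigengenes <- function(x) x@eigengenes

#' @describeIn EigengeneSet variance explained per module
#' @export
varianceExplained <- function(x) x@varianceExplained

#' Per-gene rhythmicity statistics for one condition
#'
#' Result of \code{\link{jtkCycle}}: per gene the best Kendall tau against
#' the cosine reference set, the exact-null p-value after Bonferroni
#' correction over the (antiphase-collapsed) reference family, the
#' Benjamini-Hochberg q-value across genes, the fitted period, the phase
#' (LAG, hours in [0, period)) and cosinor amplitude (AMP, FPKM units).
#'
#' @slot table data.frame with columns gene, tau, S, p, p_adj, q, period,
#'   lag, amp, rhythmic.
#' @slot period test period (hours).
#' @slot qCut rhythmicity q-value cutoff.
#' @slot exact TRUE if the exact permutation null was used.
#' @export
setClass("RhythmResult",
         representation(table = "data.frame", period = "numeric",
                        qCut = "numeric", exact = "logical"))

.validRhythmResult <- function(object) {
  msg <- character()
  tb <- object@table
  need <- c("gene", "tau", "S", "p", "p_adj", "q", "period", "lag", "amp", "rhythmic")
  if (!all(need %in% colnames(tb)))
    msg <- c(msg, "rhythm table lacks required columns")
  else {
    if (any(tb$amp < 0)) msg <- c(msg, "AMP must be >= 0")
    ok <- !is.na(tb$lag)
    if (any(tb$lag[ok] < 0 | tb$lag[ok] >= object@period))
      msg <- c(msg, "LAG must lie in [0, period)")
    if (!identical(tb$rhythmic, tb$q < object@qCut))
      msg <- c(msg, "rhythmic flag must equal q < qCut")
  }
  if (length(msg)) msg else TRUE
}
setValidity("RhythmResult", .validRhythmResult)

#' @describeIn RhythmResult per-gene statistics table
#' @param x a RhythmResult
#' @export
rhythmTable <- function(x) x@table

#' Planted ground truth of a synthetic experiment
#'
#' @slot genes data.frame: gene, module, rhythmic_ww, rhythmic_d, amp_ww,
#'   amp_d (FPKM units; 0 iff the rhythmic flag is FALSE), phase_ww, phase_d
#'   (hours), baseline.
#' @slot traits data.frame: trait, module, sign.
#' @export
setClass("SyntheticTruth",
         representation(genes = "data.frame", traits = "data.frame"))

.validSyntheticTruth <- function(object) {
  msg <- character()
  g <- object@genes
  if (anyDuplicated(g$gene))
    msg <- c(msg, "every gene must have exactly one truth record")
  if (any((g$amp_ww == 0) != !g$rhythmic_ww) ||
      any((g$amp_d == 0) != !g$rhythmic_d))
    msg <- c(msg, "amp must be 0 iff the rhythmic flag is FALSE")
  if (length(msg)) msg else TRUE
}
setValidity("SyntheticTruth", .validSyntheticTruth)

#' @describeIn SyntheticTruth per-gene truth records
#' @param x a SyntheticTruth
#' @export
truthGenes <- function(x) x@genes

#' @describeIn SyntheticTruth trait -> module coupling records
#' @export
truthTraits <- function(x) x@traits

#' Probe x sample count table (NanoString-style)
#'
#' @slot counts probes x samples non-negative counts.
#' @slot probeData data.frame: probe, housekeeping flag.
#' @slot sampleData data.frame: sample_id, set (plate/cartridge lane),
#'   is_reference (pooled-RNA reference-row sample), pair_id (technical
#'   replicate pairing token or NA), condition, zt, replicate.
#' @slot normalized character vector of normalization steps applied.
#' @export
setClass("ProbeCountTable",
         representation(counts = "matrix", probeData = "data.frame",
                        sampleData = "data.frame", normalized = "character"))

.validProbeCountTable <- function(object) {
  msg <- character()
  if (nrow(object@probeData) != nrow(object@counts) ||
      nrow(object@sampleData) != ncol(object@counts))
    msg <- c(msg, "probeData/sampleData dimensions must match counts")
  if (any(is.infinite(object@counts)) || any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be finite and non-negative (NA = masked)")
  if (sum(object@probeData$housekeeping) < 3)
    msg <- c(msg, "at least 3 housekeeping probes are required")
  if (length(msg)) msg else TRUE
}
setValidity("ProbeCountTable", .validProbeCountTable)

ProbeCountTable <- function(counts, probeData, sampleData,
                            normalized = character()) {
  new("ProbeCountTable", counts = as.matrix(counts),
      probeData = as.data.frame(probeData),
      sampleData = as.data.frame(sampleData), normalized = normalized)
}

#' @describeIn ProbeCountTable probe x sample count matrix
#' @param x a ProbeCountTable
#' @export
probeCounts <- function(x) x@counts

#' @describeIn ProbeCountTable per-probe metadata
#' @export
probeData <- function(x) x@probeData

#' Module overlap between two condition networks
#'
#' @slot counts modules(A) x modules(B) shared-gene counts over the common
#'   gene universe.
#' @slot p one-sided hypergeometric (Fisher) p-value per cell.
#' @slot display -log10(p) capped at \code{cap}.
#' @slot universeSize size of the shared gene universe.
#' @slot cap display cap.
#' @export
setClass("OverlapResult",
         representation(counts = "matrix", p = "matrix", display = "matrix",
                        universeSize = "integer", cap = "numeric"))

## show methods -------------------------------------------------------------

setMethod("show", "DielExpression", function(object) {
  v <- assay(object, 1)
  cat("DielExpression:", nrow(v), "genes x", ncol(v), "samples",
      sprintf("[%s scale]\n", metadata(object)$scale))
  cd <- colData(object)
  cat("  conditions:", paste(unique(cd$condition), collapse = ", "),
      "| ZT:", paste(range(cd$zt), collapse = "-"),
      "| replicates:", length(unique(cd$replicate)), "\n")
})

setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat("ModuleSet:", length(sz), "modules,",
      sum(object@labels == 0), "unassigned of", length(object@labels), "genes\n")
  if (length(sz)) cat("  sizes:", paste(head(sz, 10), collapse = ", "),
                      if (length(sz) > 10) "..." else "", "\n")
})

setMethod("show", "EigengeneSet", function(object) {
  cat("EigengeneSet:", nrow(object@eigengenes), "module eigengenes over",
      ncol(object@eigengenes), "samples\n")
})

setMethod("show", "RhythmResult", function(object) {
  tb <- object@table
  cat("RhythmResult:", nrow(tb), "genes, period", object@period, "h;",
      sum(tb$rhythmic), sprintf("rhythmic at q < %g\n", object@qCut))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@genes), "genes,",
      nrow(object@traits), "coupled traits\n")
})

setMethod("show", "ProbeCountTable", function(object) {
  cat("ProbeCountTable:", nrow(object@counts), "probes x",
      ncol(object@counts), "samples;",
      sum(object@probeData$housekeeping), "housekeeping;",
      if (length(object@normalized))
        paste("normalized:", paste(object@normalized, collapse = "+"))
      else "raw", "\n")
})

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult:", nrow(object@counts), "x", ncol(object@counts),
      "modules over a universe of", object@universeSize, "genes\n")
})

## shared accessors ----------------------------------------------------------

#' Expression values of a DielExpression
#' @param x a DielExpression
#' @return numeric matrix genes x samples
#' @export
exprValues <- function(x) assay(x, 1)

#' Measurement scale ("fpkm" or "log2")
#' @param x a DielExpression
#' @export
exprScale <- function(x) metadata(x)$scale

#' Per-sample design table
#' @param x a DielExpression or EigengeneSet
#' @export
sampleInfo <- function(x) {
  if (is(x, "DielExpression")) as.data.frame(colData(x)) else as.data.frame(x@sampleData)
}
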