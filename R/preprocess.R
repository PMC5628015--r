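## Reading, filtering, log transform and the sample-level clustering check
## (does time of day dominate treatment?).

#' Read an expression table and its sample metadata
#'
#' Reads a tab-delimited genes x samples table (header row of sample ids,
#' first column of gene ids) and a sample-metadata table with columns
#' \code{sample_id}, \code{condition}, \code{zt}, \code{day},
#' \code{replicate}, and returns a \linkS4class{DielExpression} with columns
#' in the deterministic (condition, zt, replicate) order.
#'
#' @param path expression TSV path.
#' @param metadataPath sample metadata TSV path.
#' @param scale "fpkm" (default) or "log2".
#' @return a \linkS4class{DielExpression}.
#' @export
readExpressionTable <- function(path, metadataPath, scale = "fpkm") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (!file.exists(metadataPath)) stop("metadata file not found: ", metadataPath)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene <- as.character(tab[[1]])
  if (anyDuplicated(gene))
    stop("duplicate gene id(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(tab[, -1, drop = FALSE], 2, function(x)
      all(!is.na(suppressWarnings(as.numeric(x))))))
    stop("non-numeric cell(s) in column(s): ",
         paste(colnames(tab)[-1][bad], collapse = ", "))
  }
  rownames(m) <- gene
  meta <- read.delim(metadataPath, stringsAsFactors = FALSE)
  DielExpression(m, meta, scale = scale)
}

#' Write a DielExpression and its metadata to TSV
#'
#' @param em a \linkS4class{DielExpression}.
#' @param path expression TSV path (first column \code{gene}).
#' @param metadataPath sample metadata TSV path.
#' @return invisibly, \code{c(path, metadataPath)}.
#' @export
writeExpressionTable <- function(em, path, metadataPath) {
  v <- exprValues(em)
  out <- data.frame(gene = rownames(v), v, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sampleInfo(em), metadataPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path, metadataPath))
}

#' Abundance filter: keep genes reaching a minimum FPKM
#'
#' Removes genes that never reach \code{minFpkm} in any sample of the
#' dataset (the filter is inclusive: a single value exactly equal to
#' \code{minFpkm} keeps the gene). Applied per condition dataset, so the two
#' condition networks may retain different gene sets. Kept/dropped counts
#' are recorded in \code{metadata(x)$filter}.
#'
#' @param em a \linkS4class{DielExpression} on the FPKM scale.
#' @param minFpkm threshold (default 10).
#' @return the filtered \linkS4class{DielExpression}.
#' @export
filterLowExpression <- function(em, minFpkm = 10) {
  if (exprScale(em) != "fpkm")
    stop("abundance filter is defined on FPKM-scale values")
  v <- exprValues(em)
  keep <- apply(v, 1, max) >= minFpkm
  out <- em[keep, ]
  metadata(out)$filter <- list(minFpkm = minFpkm,
                               kept = sum(keep), dropped = sum(!keep))
  out
}

#' Log2 transform of FPKM values
#'
#' \code{value -> log2(value + offset)}; the default offset of 1 makes the
#' transform defined at zero FPKM (log2(1) = 0) and order-preserving. A
#' matrix already on the log2 scale is rejected.
#'
#' @param em a \linkS4class{DielExpression} on the FPKM scale.
#' @param offset pseudo-count added before the log (default 1).
#' @return the transformed \linkS4class{DielExpression} (scale "log2").
#' @export
logTransform <- function(em, offset = 1) {
  if (exprScale(em) != "fpkm")
    stop("input is already log2-transformed")
  v <- log2(exprValues(em) + offset)
  out <- em
  assay(out, 1) <- v
  metadata(out)$scale <- "log2"
  metadata(out)$log_offset <- offset
  out
}

#' Hierarchical clustering of samples by expression correlation
#'
#' Agglomerative average-linkage clustering of sample columns using distance
#' 1 - Pearson correlation, used to ask whether samples group by time of day
#' rather than by treatment. Columns are taken in lexicographic sample-id
#' order so the result is invariant to input order.
#'
#' @param em a \linkS4class{DielExpression} on the log2 scale.
#' @param samples optional character vector of sample ids to cluster
#'   (default: all).
#' @return an \code{hclust} object (merge order, heights, leaf order) with
#'   the correlation-distance matrix attached as attribute "dist".
#' @export
clusterSamples <- function(em, samples = NULL) {
  if (exprScale(em) != "log2")
    stop("sample clustering expects log2-scale values")
  v <- exprValues(em)
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(v))
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  if (ncol(v) < 3) stop("need at least 3 samples to cluster")
  v <- v[, order(colnames(v)), drop = FALSE]
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    stop("zero-variance sample column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  d <- as.dist(1 - cor(v))
  hc <- hclust(d, method = "average")
  attr(hc, "dist") <- d
  hc
}
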