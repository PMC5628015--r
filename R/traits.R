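## Physiology-side statistics and the module-trait correlation stage.
##
## Trait tables are long-format data.frames with columns trait, condition,
## zt, replicate, value (one row per replicate measurement).

#' Intrinsic water-use efficiency, WUE = A / gs
#'
#' Joins per-record net assimilation (A) and stomatal conductance (gs)
#' series on (condition, zt, replicate) and forms their ratio. Records with
#' gs = 0 are undefined and dropped with a warning. The two inputs must
#' describe exactly the same records.
#'
#' @param aSeries,gsSeries long-format trait data.frames (columns condition,
#'   zt, replicate, value) for A and gs.
#' @return a long-format data.frame with trait = "WUE".
#' @export
computeWUE <- function(aSeries, gsSeries) {
  keyA <- paste(aSeries$condition, aSeries$zt, aSeries$replicate)
  keyG <- paste(gsSeries$condition, gsSeries$zt, gsSeries$replicate)
  if (anyDuplicated(keyA) || anyDuplicated(keyG) ||
      !setequal(keyA, keyG) || length(keyA) != length(keyG))
    stop("A and gs records are not aligned on (condition, zt, replicate)")
  gsSeries <- gsSeries[match(keyA, keyG), ]
  zero <- gsSeries$value == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " record(s) with gs = 0 (WUE undefined)")
    aSeries <- aSeries[!zero, ]; gsSeries <- gsSeries[!zero, ]
  }
  data.frame(trait = "WUE", condition = aSeries$condition, zt = aSeries$zt,
             replicate = aSeries$replicate,
             value = aSeries$value / gsSeries$value)
}

#' Per-time-point one-tailed Student's t-tests between conditions
#'
#' Unpaired equal-variance t-test at every shared ZT, one-tailed in the
#' supplied direction (the direction must be chosen per trait from the
#' expected physiology; there is no silent default for two-sided use either
#' -- pass "two.sided" explicitly if wanted). Significance is flagged both
#' at p < 0.01 and at p < 0.05, the two conventions used for physiology and
#' probe-count panels respectively.
#'
#' @param traitX,traitY long-format single-trait data.frames (columns zt,
#'   value; typically one condition each). The alternative is for
#'   mean(X) versus mean(Y): \code{"less"} tests mean(X) < mean(Y).
#' @param alternative "less", "greater" or "two.sided".
#' @param varEqual pool variances (default TRUE, Student); FALSE for Welch.
#' @return data.frame: zt, n_x, n_y, t, df, p, sig01, sig05.
#' @export
timepointTTests <- function(traitX, traitY,
                            alternative = c("less", "greater", "two.sided"),
                            varEqual = TRUE) {
  alternative <- match.arg(alternative)
  zts <- sort(intersect(unique(traitX$zt), unique(traitY$zt)))
  rows <- lapply(zts, function(z) {
    x <- traitX$value[traitX$zt == z]
    y <- traitY$value[traitY$zt == z]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 replicates per group at ZT", z)
    tt <- studentTTest(x, y, alternative = alternative, varEqual = varEqual)
    data.frame(zt = z, n_x = length(x), n_y = length(y), t = tt$t,
               df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$sig01 <- out$p < 0.01
  out$sig05 <- out$p < 0.05
  out
}

## Per-sample trait values: the trait's per-ZT mean (within the sample's
## condition) assigned to every replicate column of that ZT. missingZT
## controls ZTs sampled in the expression data but absent from the trait
## (e.g. NSC at ZT9): "error" rejects naming the ZT, "interpolate" fills
## linearly along ZT, "drop" removes those samples from the correlation.
.expandTrait <- function(trait, sampleDf,
                         missingZT = c("error", "interpolate", "drop")) {
  missingZT <- match.arg(missingZT)
  means <- aggregate(value ~ condition + zt, data = trait, FUN = mean)
  key <- paste(sampleDf$condition, sampleDf$zt)
  val <- means$value[match(key, paste(means$condition, means$zt))]
  if (anyNA(val)) {
    bad <- sampleDf$zt[is.na(val)]
    if (missingZT == "error")
      stop("trait lacks measurements at ZT ",
           paste(sort(unique(bad)), collapse = ", "))
    if (missingZT == "drop") return(list(values = val, keep = !is.na(val)))
    for (cond in unique(sampleDf$condition)) {
      sel <- sampleDf$condition == cond & is.na(val)
      if (!any(sel)) next
      src <- means[means$condition == cond, ]
      if (nrow(src) < 2) stop("cannot interpolate trait for condition ", cond)
      val[sel] <- approx(src$zt, src$value, xout = sampleDf$zt[sel],
                         rule = 2)$y
    }
  }
  list(values = val, keep = rep(TRUE, nrow(sampleDf)))
}

#' Correlate module eigengenes with diel physiology traits
#'
#' For every (module, trait) pair: the trait's per-ZT mean values are
#' expanded onto the eigengene's sample axis (both replicates of a ZT get
#' the ZT mean) and the Pearson correlation and its two-sided Student
#' p-value are computed.
#'
#' @param egs an \linkS4class{EigengeneSet} (one condition's network).
#' @param traits long-format trait data.frame (may hold several traits;
#'   records are matched to the eigengene samples by condition and ZT).
#' @param missingZT how to handle ZTs missing from a trait: "error"
#'   (default), "interpolate", or "drop".
#' @return list with matrices \code{r} and \code{p} (modules x traits).
#' @export
moduleTraitCorrelation <- function(egs, traits,
                                   missingZT = c("error", "interpolate", "drop")) {
  missingZT <- match.arg(missingZT)
  me <- eigengenes(egs)
  sampleDf <- as.data.frame(egs@sampleData)
  traitNames <- sort(unique(traits$trait))
  r <- p <- matrix(NA_real_, nrow(me), length(traitNames),
                   dimnames = list(rownames(me), traitNames))
  for (tn in traitNames) {
    ex <- .expandTrait(traits[traits$trait == tn, ], sampleDf, missingZT)
    tv <- ex$values[ex$keep]
    n <- length(tv)
    for (m in seq_len(nrow(me))) {
      rr <- cor(me[m, ex$keep], tv)
      r[m, tn] <- rr
      tt <- rr * sqrt(n - 2) / sqrt(pmax(1 - rr^2, .Machine$double.eps))
      p[m, tn] <- 2 * pt(-abs(tt), n - 2)
    }
  }
  list(r = r, p = p)
}

#' Gene significance: |correlation| between expression and a trait
#'
#' GS_g = |cor(x_g, trait per-ZT means expanded to the sample axis)|.
#' Zero-variance genes have undefined GS and are reported as NA.
#'
#' @param em a \linkS4class{DielExpression}.
#' @param trait long-format single-trait data.frame.
#' @param missingZT see \code{\link{moduleTraitCorrelation}}.
#' @return named numeric vector in [0,1] (NA for zero-variance genes).
#' @export
geneSignificance <- function(em, trait,
                             missingZT = c("error", "interpolate", "drop")) {
  missingZT <- match.arg(missingZT)
  v <- exprValues(em)
  ex <- .expandTrait(trait, sampleInfo(em), missingZT)
  tv <- ex$values[ex$keep]
  x <- v[, ex$keep, drop = FALSE]
  sds <- apply(x, 1, sd)
  gs <- rep(NA_real_, nrow(x))
  ok <- sds > 0
  gs[ok] <- abs(as.numeric(cor(t(x[ok, , drop = FALSE]), tv)))
  names(gs) <- rownames(x)
  gs
}

#' Correlation between gene significance and module membership
#'
#' Within one module, correlates GS with |MM| across the member genes. A
#' significant positive correlation means the module's hub genes are also
#' the genes most correlated with the physiology measure.
#'
#' @param gs named GS vector from \code{\link{geneSignificance}}.
#' @param mm result of \code{\link{moduleMembership}}.
#' @param modules a \linkS4class{ModuleSet}.
#' @param module module label (>= 3 genes).
#' @return list(r, p); both NA when a side has zero variance.
#' @export
gsMMCorrelation <- function(gs, mm, modules, module) {
  labels <- moduleLabels(modules)
  genes <- names(labels)[labels == module]
  if (length(genes) < 3) stop("module must have >= 3 genes")
  g <- gs[genes]
  m <- abs(mm$mm[genes, paste0("ME", module)])
  ok <- !is.na(g) & !is.na(m)
  g <- g[ok]; m <- m[ok]
  if (length(g) < 3 || sd(g) == 0 || sd(m) == 0)
    return(list(r = NA_real_, p = NA_real_))
  r <- cor(g, m)
  n <- length(g)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}
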