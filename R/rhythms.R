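## Nonparametric rhythmicity detection: Kendall's S between each gene and a
## family of phase-shifted cosine references, with an exact permutation null
## (a JTK-CYCLE style procedure), cosinor amplitude estimation, and the
## two-criterion selection of drought-responsive transcripts.

#' Phase-shifted cosine reference waveforms
#'
#' One cosine reference per phase offset on the sampling-interval grid:
#' reference value for a sample at ZT t is cos(2 pi (t - phi) / period).
#' Samples sharing a reference value (replicates, and time points one full
#' period apart) are tied in the reference ranking, which the exact null
#' accounts for.
#'
#' @param zt per-sample ZT hours (replicates repeated).
#' @param period test period in hours (default 24).
#' @param phaseStep spacing of the phase offsets; defaults to the sampling
#'   interval and must divide the period.
#' @return object of class "ReferenceWaveformSet": list(period, phases, zt,
#'   values) with \code{values} a samples x phases matrix.
#' @export
buildReferences <- function(zt, period = 24, phaseStep = NULL) {
  uz <- sort(unique(zt))
  if (length(uz) < 2) stop("need at least two distinct time points")
  if (is.null(phaseStep)) phaseStep <- min(diff(uz))
  if (abs(period / phaseStep - round(period / phaseStep)) > 1e-9)
    stop("phaseStep must divide the period")
  ## anchor the phase grid at the first sampled ZT so that a cosine peaking
  ## exactly at a sampled time has a perfectly concordant reference
  phases <- sort((uz[1] + seq(0, period - phaseStep, by = phaseStep)) %% period)
  values <- sapply(phases, function(ph) cos(2 * pi * (zt - ph) / period))
  colnames(values) <- sprintf("phi%g", phases)
  structure(list(period = period, phases = phases, zt = zt, values = values),
            class = "ReferenceWaveformSet")
}

## Gaussian binomial coefficient [m+n choose n]_q as an integer coefficient
## vector: the exact count of Mann-Whitney U outcomes for group sizes m, n.
.gaussBinom <- function(m, n) {
  prev <- list(1)                         # a = 0: only b = 0
  for (a in seq_len(m + n)) {
    bmax <- min(a, n)
    cur <- vector("list", bmax + 1)
    cur[[1]] <- 1
    for (b in seq_len(bmax)) {
      p1 <- prev[[b]]                     # [a-1 choose b-1]
      p2 <- if (b + 1 <= length(prev)) prev[[b + 1]] else NULL  # [a-1 choose b]
      if (is.null(p2)) { cur[[b + 1]] <- p1; next }
      p2s <- c(numeric(b), p2)            # q^b shift
      len <- max(length(p1), length(p2s))
      cur[[b + 1]] <- c(p1, numeric(len - length(p1))) +
        c(p2s, numeric(len - length(p2s)))
    }
    prev <- cur
  }
  prev[[n + 1]]
}

.polyMul <- function(x, y) {
  out <- numeric(length(x) + length(y) - 1)
  for (i in seq_along(x))
    out[i + seq_along(y) - 1] <- out[i + seq_along(y) - 1] + x[i] * y
  out
}

#' Exact null distribution of Kendall's S against a tied reference
#'
#' Distribution of the concordant-minus-discordant statistic S between a
#' tie-free data vector and a reference with tied groups of sizes
#' \code{tiePattern}, under uniformly random permutation of the data. S
#' decomposes over reference groups as a Jonckheere-Terpstra statistic, so
#' the exact probability mass function is the convolution of Mann-Whitney U
#' count polynomials (Gaussian binomial coefficients), computed by dynamic
#' programming. Counts are exact integers in doubles whenever the total
#' arrangement count is below 2^53; beyond \code{exactLimit} points a normal
#' approximation with continuity correction and tie-corrected variance is
#' returned, flagged with \code{exact = FALSE}.
#'
#' @param tiePattern integer vector of tied-group sizes in the reference
#'   (sum = number of points).
#' @param exactLimit largest number of points for exact mode (default 26).
#' @return list(S, pmf, M, exact, sd): support (step 2 from -M to M, where
#'   M is the number of comparable pairs), its pmf, and the null sd.
#' @export
exactNullDistribution <- function(tiePattern, exactLimit = 26) {
  ties <- as.integer(tiePattern)
  if (any(ties < 1)) stop("tie-group sizes must be positive")
  n <- sum(ties)
  M <- (n^2 - sum(ties^2)) / 2
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (n > exactLimit)
    return(list(S = NULL, pmf = NULL, M = M, exact = FALSE, sd = sqrt(varS)))
  cum <- cumsum(ties)
  polys <- lapply(seq_along(ties)[-1],
                  function(g) .gaussBinom(cum[g - 1], ties[g]))
  total <- prod(vapply(seq_along(ties)[-1],
                       function(g) choose(cum[g], ties[g]), numeric(1)))
  if (total >= 2^53)                       # keep convolution well-conditioned
    polys <- lapply(polys, function(p) p / sum(p))
  pmf <- Reduce(.polyMul, polys, accumulate = FALSE)
  pmf <- pmf / sum(pmf)
  list(S = 2 * (seq_along(pmf) - 1) - M, pmf = pmf, M = M, exact = TRUE,
       sd = sqrt(varS))
}

## Two-sided p-value P(|S| >= |s|) from an exact or approximate null.
.nullPTwoSided <- function(s, null) {
  s <- abs(s)
  if (null$exact) {
    sum(null$pmf[abs(null$S) >= s - 1e-9])
  } else {
    if (s == 0) return(1)
    min(1, 2 * stats::pnorm(-(s - 1) / null$sd))
  }
}

#' Rank-based rhythmicity test against cosine references
#'
#' For every gene and every reference phase, computes Kendall's S between
#' the expression values and the reference, takes the exact two-sided
#' permutation p-value (see \code{\link{exactNullDistribution}}), picks the
#' best (maximum-S) reference, and Bonferroni-corrects over the reference
#' family counting antiphase pairs once (a tau of -1 at phase phi is +1 at
#' phi + 12, so the family of k phases has k/2 effective members).
#' Benjamini-Hochberg q-values are computed across the genes of the matrix;
#' a gene is rhythmic iff q < \code{qCut}. LAG is the phase of the best
#' reference; AMP is the least-squares cosinor amplitude on the FPKM scale
#' (see \code{\link{estimateAmplitude}}).
#'
#' The test is rank-based, so p-values are invariant under strictly
#' monotone transforms of the expression values; AMP is not, which is why
#' the matrix must be on the FPKM scale. Ties among expression values
#' (e.g. zeros) contribute zero to S, making the test conservative there.
#'
#' @param em a \linkS4class{DielExpression} on the FPKM scale covering at
#'   least two full periods.
#' @param refs a \code{\link{buildReferences}} result (default: built from
#'   the sample ZTs at period 24).
#' @param qCut rhythmicity cutoff on the BH q-value (default 0.01).
#' @param exactLimit see \code{\link{exactNullDistribution}}.
#' @return a \linkS4class{RhythmResult}.
#' @export
jtkCycle <- function(em, refs = NULL, qCut = 0.01, exactLimit = 26) {
  if (exprScale(em) != "fpkm")
    stop("rhythmicity testing expects FPKM-scale values (AMP is in FPKM units)")
  zt <- sampleInfo(em)$zt
  if (is.null(refs)) refs <- buildReferences(zt, period = 24)
  if (diff(range(zt)) < 2 * refs$period - max(diff(sort(unique(zt)))))
    stop("need at least two full periods of data")
  v <- exprValues(em)
  n <- ncol(v)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ip <- pr[, 1]; jq <- pr[, 2]

  nPhase <- length(refs$phases)
  refSign <- matrix(0, nrow(pr), nPhase)
  nulls <- vector("list", nPhase)
  keys <- character(nPhase)
  for (k in seq_len(nPhase)) {
    r <- signif(refs$values[, k], 10)
    refSign[, k] <- sign(r[ip] - r[jq])
    pat <- sort(as.integer(table(r)))
    keys[k] <- paste(pat, collapse = ",")
    prev <- match(keys[k], keys[seq_len(k - 1)])
    nulls[[k]] <- if (!is.na(prev) && k > 1) nulls[[prev]]
      else exactNullDistribution(pat, exactLimit)
  }
  M <- vapply(nulls, `[[`, numeric(1), "M")

  D <- v[, ip, drop = FALSE] - v[, jq, drop = FALSE]
  S <- sign(D) %*% refSign                          # genes x phases

  best <- apply(S, 1, which.max)                    # first max: smallest phase
  bestS <- S[cbind(seq_len(nrow(S)), best)]
  pPerPhase <- matrix(1, nrow(S), nPhase)
  for (k in seq_len(nPhase)) {
    ## tabulate once per phase over the attainable |S| values
    sAbs <- abs(S[, k])
    uniq <- sort(unique(sAbs))
    pv <- vapply(uniq, .nullPTwoSided, numeric(1), null = nulls[[k]])
    pPerPhase[, k] <- pv[match(sAbs, uniq)]
  }
  pMin <- apply(pPerPhase, 1, min)
  pAdj <- pmin(1, pMin * nPhase / 2)
  q <- p.adjust(pAdj, method = "BH")

  amp <- vapply(seq_len(nrow(v)), function(g)
    estimateAmplitude(v[g, ], zt, period = refs$period), numeric(1))

  tb <- data.frame(gene = rownames(v),
                   tau = bestS / M[best],
                   S = bestS,
                   p = pMin,
                   p_adj = pAdj,
                   q = q,
                   period = refs$period,
                   lag = refs$phases[best],
                   amp = amp,
                   rhythmic = q < qCut,
                   row.names = NULL)
  new("RhythmResult", table = tb, period = refs$period, qCut = qCut,
      exact = all(vapply(nulls, `[[`, logical(1), "exact")))
}

#' Cosinor amplitude at a fixed period
#'
#' Least-squares fit of y = m + a cos(2 pi t / period) + b sin(2 pi t /
#' period); the amplitude is sqrt(a^2 + b^2), half the fitted peak-to-trough
#' range, in the units of y (FPKM for expression).
#'
#' @param values numeric response vector.
#' @param zt time of each value (hours); at least 4 distinct times.
#' @param period fixed period in hours (default 24).
#' @return the fitted amplitude (>= 0).
#' @export
estimateAmplitude <- function(values, zt, period = 24) {
  if (length(unique(zt)) < 4) stop("need at least 4 distinct time points")
  .cosinor(values, zt, period)$amp
}

#' Select drought-responsive genes by gained rhythm or amplitude change
#'
#' Within the modules of interest (the droughted-network modules correlated
#' with the chosen physiology traits), candidates are genes that either
#' (1) gained rhythmicity: not rhythmic under well-watered conditions
#' (q_ww >= qCut) but rhythmic under drought (q_d < qCut); or
#' (2) changed amplitude: rhythmic under both conditions with
#' |AMP_d - AMP_ww| > ampCut. The amplitude delta is recorded signed
#' (amplitude may increase or decrease).
#'
#' @param rww,rd \linkS4class{RhythmResult}s for the well-watered and
#'   droughted data (gene universes are intersected).
#' @param modules \linkS4class{ModuleSet} of the droughted network.
#' @param modulesOfInterest integer module labels to restrict to; if empty
#'   or NULL, all assigned modules are used with a warning.
#' @param ampCut amplitude-difference threshold in FPKM units (default 10).
#' @param qCut rhythmicity q cutoff (default 0.01).
#' @return data.frame: gene, module, criterion ("gained_rhythm" or
#'   "amplitude_change"), amp_ww, amp_d, delta.
#' @export
selectDroughtResponsive <- function(rww, rd, modules, modulesOfInterest = NULL,
                                    ampCut = 10, qCut = 0.01) {
  tw <- rhythmTable(rww); td <- rhythmTable(rd)
  genes <- intersect(tw$gene, td$gene)
  tw <- tw[match(genes, tw$gene), ]; td <- td[match(genes, td$gene), ]
  labels <- moduleLabels(modules)
  if (is.null(modulesOfInterest) || !length(modulesOfInterest)) {
    warning("empty module filter: using all assigned modules")
    modulesOfInterest <- sort(unique(labels[labels > 0]))
  }
  mod <- labels[genes]
  inMod <- !is.na(mod) & mod %in% modulesOfInterest
  gained <- tw$q >= qCut & td$q < qCut
  ampChange <- tw$q < qCut & td$q < qCut & abs(td$amp - tw$amp) > ampCut
  sel <- inMod & (gained | ampChange)
  data.frame(gene = genes[sel], module = unname(mod[sel]),
             criterion = ifelse(gained[sel], "gained_rhythm", "amplitude_change"),
             amp_ww = tw$amp[sel], amp_d = td$amp[sel],
             delta = td$amp[sel] - tw$amp[sel], row.names = NULL)
}

#' Rank candidate genes within modules by module membership
#'
#' Within each module, candidates are sorted by |MM| with the module's own
#' eigengene, descending, ties broken by gene id, and the top \code{topN}
#' are returned (all, if the module has fewer candidates).
#'
#' @param candidates data.frame from \code{\link{selectDroughtResponsive}}.
#' @param mm result of \code{\link{moduleMembership}} on the droughted
#'   network.
#' @param topN genes to keep per module (default 3).
#' @return the ranked subset with columns mm_own and rank added.
#' @export
rankCandidatesByMM <- function(candidates, mm, topN = 3) {
  if (!nrow(candidates))
    return(cbind(candidates, mm_own = numeric(0), rank = integer(0)))
  own <- abs(mm$mm[cbind(match(candidates$gene, rownames(mm$mm)),
                         match(paste0("ME", candidates$module),
                               colnames(mm$mm)))])
  if (anyNA(own)) stop("module membership missing for some candidates")
  candidates$mm_own <- own
  out <- do.call(rbind, lapply(split(candidates, candidates$module), function(d) {
    d <- d[order(-d$mm_own, d$gene), , drop = FALSE]
    d <- head(d, topN)
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  out
}
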