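## Seeded generator for synthetic diel drought experiments. The defaults
## emulate the assumed design: 12 time points every 4 h over 48 h starting at
## ZT1, two pooled biological replicates per condition, cosine diel rhythms
## with module-shared phases, drought-induced amplitude/phase changes and
## gained/lost rhythmicity, trait waveforms coupled to specific modules, and
## probe-count tables with occasional single-cell spikes.

#' Configuration for a synthetic diel drought experiment
#'
#' All parameters of \code{\link{simulateExperiment}} and
#' \code{\link{simulateProbeCounts}} with defaults describing the emulated
#' study design. Expression for a rhythmic gene g in module m at time t is
#' \deqn{\max(0,\; B_g (1 + A_m \cos(2\pi (t-\phi_m)/P)) + \epsilon),\quad
#'   \epsilon \sim N(0, (\sigma_{rel} B_g)^2)}
#' with lognormal baselines B_g, so the planted FPKM amplitude of gene g is
#' \code{B_g * amplitudeRel[m]}.
#'
#' @param nModules number of planted co-expression modules.
#' @param genesPerModule genes per module.
#' @param nNoiseGenes unstructured background genes (module label 0).
#' @param timepoints ZT hours sampled (default 1, 5, ..., 45: every 4 h over
#'   48 h beginning 1 h after lights-on).
#' @param nReplicates pooled biological replicates per condition per ZT.
#' @param period diel period in hours.
#' @param modulePhases peak phase per module, hours in [0, period); default
#'   spreads the modules uniformly over the day.
#' @param baselineLogMean,baselineLogSd lognormal baseline FPKM parameters.
#' @param amplitudeRel relative cosine amplitude per module (recycled).
#' @param noiseSdRel residual noise sd as a fraction of the gene baseline.
#' @param droughtEffects data.frame with one row per module and columns
#'   \code{module}, \code{ampScale} (amplitude multiplier under drought),
#'   \code{phaseShift} (hours), \code{gainFraction} (fraction of the module's
#'   genes flat under WW but rhythmic under drought), \code{loseFraction}
#'   (fraction rhythmic under WW but flat under drought).
#' @param traitCoupling data.frame with columns \code{trait}, \code{module},
#'   \code{sign} (+1/-1), \code{mean}, \code{amplitude}, \code{noiseSd} in
#'   the trait's own units. Defaults emulate diel leaf physiology: net CO2
#'   assimilation A (umol m-2 s-1), stomatal conductance gs (mmol m-2 s-1),
#'   PSII efficiency Fv'/Fm' (dimensionless, clamped to [0,1]) and NSC
#'   (dry-weight fraction).
#' @param traitReplicates biological replicates per trait per time point.
#' @param traitDropZT named list trait -> ZT hours not measured (default:
#'   NSC lacks ZT9 on both days, as no sugar extraction is performed then).
#' @param nProbes,nHousekeeping,probeScale,probeReplicates,spikeFraction,
#'   spikeFactor,nTechPairs,setSize,setSdLog probe-count table parameters:
#'   panel size, flat housekeeping probes, counts per FPKM, biological
#'   replicates per condition/ZT, fraction of probe x sample cells hit by a
#'   spurious spike, the spike multiplier, number of technical-replicate
#'   pairs, samples per plate set, and the lognormal sd of per-set scale
#'   factors the CodeSet normalization must remove.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return a validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(nModules = 5,
                             genesPerModule = 100,
                             nNoiseGenes = 250,
                             timepoints = seq(1, 45, by = 4),
                             nReplicates = 2,
                             period = 24,
                             modulePhases = NULL,
                             baselineLogMean = log(100),
                             baselineLogSd = 0.8,
                             amplitudeRel = 0.5,
                             noiseSdRel = 0.1,
                             droughtEffects = NULL,
                             traitCoupling = NULL,
                             traitReplicates = 8,
                             traitDropZT = list(NSC = c(9, 33)),
                             nProbes = 36,
                             nHousekeeping = 3,
                             probeScale = 5,
                             probeReplicates = 5,
                             spikeFraction = 0.01,
                             spikeFactor = 10,
                             nTechPairs = 6,
                             setSize = 12,
                             setSdLog = 0.15,
                             seed = 1L) {
  if (nModules < 1 || genesPerModule < 1 || nNoiseGenes < 0 ||
      nReplicates < 1 || traitReplicates < 2)
    stop("non-positive dimensions in simulation config")
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing")
  if (is.null(modulePhases))
    modulePhases <- (seq_len(nModules) - 1) * period / nModules
  if (length(modulePhases) != nModules)
    stop("modulePhases must have one entry per module")
  if (any(modulePhases < 0 | modulePhases >= period))
    stop("phases must lie in [0, period)")
  amplitudeRel <- rep_len(amplitudeRel, nModules)
  if (any(amplitudeRel < 0)) stop("amplitudeRel must be >= 0")
  if (is.null(droughtEffects))
    droughtEffects <- data.frame(
      module = seq_len(nModules),
      ampScale = ifelse(seq_len(nModules) == 1, 1.5, 1),
      phaseShift = ifelse(seq_len(nModules) == 2, 4, 0),
      gainFraction = ifelse(seq_len(nModules) == 4, 0.3, 0),
      loseFraction = ifelse(seq_len(nModules) == 3, 0.3, 0))
  de <- droughtEffects
  if (!all(seq_len(nModules) %in% de$module))
    stop("droughtEffects must cover every module")
  if (any(de$gainFraction < 0 | de$gainFraction > 1 |
          de$loseFraction < 0 | de$loseFraction > 1))
    stop("gain/lose fractions must lie in [0, 1]")
  if (any(de$gainFraction + de$loseFraction > 1))
    stop("gain and lose fractions of a module must sum to <= 1")
  if (is.null(traitCoupling))
    traitCoupling <- data.frame(
      trait = c("A", "gs", "FvFm", "NSC"),
      module = c(1, 1, 2, 5),
      sign = c(1, 1, 1, -1),
      mean = c(8, 220, 0.65, 0.10),
      amplitude = c(4, 80, 0.05, 0.04),
      noiseSd = c(1.5, 30, 0.02, 0.02))
  traitCoupling$module <- pmin(traitCoupling$module, nModules)
  if (spikeFraction < 0 || spikeFraction > 1)
    stop("spike fraction outside [0,1]")
  if (nHousekeeping < 3) stop(">=3 housekeeping probes are required")
  cfg <- list(nModules = nModules, genesPerModule = genesPerModule,
              nNoiseGenes = nNoiseGenes, timepoints = timepoints,
              nReplicates = nReplicates, period = period,
              modulePhases = modulePhases,
              baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
              amplitudeRel = amplitudeRel, noiseSdRel = noiseSdRel,
              droughtEffects = de, traitCoupling = traitCoupling,
              traitReplicates = traitReplicates, traitDropZT = traitDropZT,
              nProbes = nProbes, nHousekeeping = nHousekeeping,
              probeScale = probeScale, probeReplicates = probeReplicates,
              spikeFraction = spikeFraction, spikeFactor = spikeFactor,
              nTechPairs = nTechPairs, setSize = setSize, setSdLog = setSdLog,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

## cosine + noise expression for one condition, clipped at zero
.simCondition <- function(truth, ampCol, phaseCol, config, cond) {
  zt <- config$timepoints
  grid <- expand.grid(replicate = seq_len(config$nReplicates), zt = zt)
  grid <- grid[order(grid$zt, grid$replicate), ]
  ids <- sprintf("%s_ZT%02d_R%d", cond, grid$zt, grid$replicate)
  n <- nrow(truth)
  m <- matrix(0, n, nrow(grid), dimnames = list(truth$gene, ids))
  cosArg <- outer(truth[[phaseCol]], grid$zt,
                  function(ph, t) cos(2 * pi * (t - ph) / config$period))
  signal <- truth$baseline + truth[[ampCol]] * cosArg
  noise <- matrix(rnorm(n * nrow(grid), 0, config$noiseSdRel * truth$baseline),
                  n, nrow(grid))
  m[] <- pmax(0, signal + noise)
  meta <- data.frame(sample_id = ids, condition = cond, zt = grid$zt,
                     day = 3 + (grid$zt >= config$period),
                     replicate = paste0("R", grid$replicate))
  DielExpression(m, meta, scale = "fpkm")
}

#' Simulate a two-condition diel expression experiment with ground truth
#'
#' Generates well-watered (WW) and droughted (D) FPKM matrices, per-replicate
#' physiology trait series coupled to planted modules, and a
#' \linkS4class{SyntheticTruth} record for every gene. Drought effects
#' rescale module amplitudes, shift phases, and convert configured fractions
#' of each module's genes to gained (flat under WW, rhythmic under D) or lost
#' rhythmicity. Traits share the coupled module's condition-specific phase
#' (flipped for negative coupling). Identical config and seed give
#' bit-identical output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{ww}, \code{d} (DielExpression),
#'   \code{traits} (long data.frame: trait, condition, zt, replicate, value)
#'   and \code{truth} (SyntheticTruth).
#' @export
simulateExperiment <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nGenes <- config$nModules * config$genesPerModule + config$nNoiseGenes
  gene <- sprintf("G%05d", seq_len(nGenes))
  module <- c(rep(seq_len(config$nModules), each = config$genesPerModule),
              rep(0L, config$nNoiseGenes))
  baseline <- rlnorm(nGenes, config$baselineLogMean, config$baselineLogSd)

  de <- config$droughtEffects[match(pmax(module, 1), config$droughtEffects$module), ]
  ampRel <- c(config$amplitudeRel, 0)[ifelse(module == 0, config$nModules + 1, module)]
  phase <- c(config$modulePhases, 0)[ifelse(module == 0, config$nModules + 1, module)]

  ## gained / lost rhythmicity: leading fractions of each module's gene block
  gained <- lost <- logical(nGenes)
  for (m in seq_len(config$nModules)) {
    idx <- which(module == m)
    nm <- length(idx)
    ng <- round(de$gainFraction[idx[1]] * nm)
    nl <- round(de$loseFraction[idx[1]] * nm)
    if (ng > 0) gained[idx[seq_len(ng)]] <- TRUE
    if (nl > 0) lost[idx[ng + seq_len(nl)]] <- TRUE
  }

  ampWW <- ifelse(module == 0 | gained, 0, baseline * ampRel)
  ampD <- ifelse(module == 0 | lost, 0,
                 baseline * ampRel * de$ampScale)
  phaseWW <- ifelse(ampWW > 0, phase, 0)
  phaseD <- ifelse(ampD > 0, (phase + de$phaseShift) %% config$period, 0)

  genesDf <- data.frame(gene = gene, module = module, baseline = baseline,
                        rhythmic_ww = ampWW > 0, rhythmic_d = ampD > 0,
                        amp_ww = ampWW, amp_d = ampD,
                        phase_ww = phaseWW, phase_d = phaseD)
  ww <- .simCondition(genesDf, "amp_ww", "phase_ww", config, "WW")
  d <- .simCondition(genesDf, "amp_d", "phase_d", config, "D")

  ## trait waveforms: cosine at the coupled module's condition-specific phase
  tc <- config$traitCoupling
  traitRows <- list()
  for (i in seq_len(nrow(tc))) {
    m <- tc$module[i]
    eff <- config$droughtEffects[config$droughtEffects$module == m, ]
    for (cond in c("WW", "D")) {
      ph <- if (cond == "D")
        (config$modulePhases[m] + eff$phaseShift) %% config$period
      else config$modulePhases[m]
      ampT <- tc$amplitude[i] * if (cond == "D") eff$ampScale else 1
      zts <- setdiff(config$timepoints, config$traitDropZT[[tc$trait[i]]])
      g <- expand.grid(replicate = seq_len(config$traitReplicates), zt = zts)
      val <- tc$mean[i] + tc$sign[i] * ampT *
        cos(2 * pi * (g$zt - ph) / config$period) +
        rnorm(nrow(g), 0, tc$noiseSd[i])
      val <- pmax(val, 0)
      if (tc$trait[i] == "FvFm") val <- pmin(val, 1)
      traitRows[[length(traitRows) + 1]] <-
        data.frame(trait = tc$trait[i], condition = cond, zt = g$zt,
                   replicate = paste0("R", g$replicate), value = val)
    }
  }
  traits <- do.call(rbind, traitRows)

  truth <- new("SyntheticTruth", genes = genesDf,
               traits = data.frame(trait = tc$trait, module = tc$module,
                                   sign = tc$sign))
  list(ww = ww, d = d, traits = traits, truth = truth)
}

#' Simulate a probe x sample count table with planted spikes
#'
#' Builds a NanoString-style panel from the planted truth: candidate probes
#' follow each gene's condition-specific cosine profile scaled to counts,
#' plus flat housekeeping probes at low/medium/high levels. Samples are laid
#' out in plate sets carrying multiplicative set factors; each set contains
#' pooled-RNA reference samples (the reference row) used by the CodeSet
#' normalization, and a configured number of technical-replicate pairs is
#' generated. Counts are Poisson around the scaled profile; a configured
#' fraction of probe x sample cells is multiplied by \code{spikeFactor} and
#' recorded.
#'
#' @param truth a \linkS4class{SyntheticTruth} from
#'   \code{\link{simulateExperiment}}.
#' @param config the same \code{\link{simulationConfig}}.
#' @return list with \code{table} (\linkS4class{ProbeCountTable}) and
#'   \code{spikes} (data.frame probe, sample_id of planted outliers).
#' @export
simulateProbeCounts <- function(truth, config = simulationConfig()) {
  stopifnot(is(truth, "SyntheticTruth"), inherits(config, "SimulationConfig"))
  set.seed(config$seed + 99991L)
  g <- truthGenes(truth)
  nCand <- config$nProbes - config$nHousekeeping
  cand <- g[g$module > 0, ][seq_len(nCand), ]
  ## low/medium/high expression, but high enough that the housekeeping
  ## anchor's own counting noise stays well below the outlier threshold
  hkLevels <- exp(seq(log(200), log(5000), length.out = config$nHousekeeping))
  probes <- c(cand$gene, sprintf("HK%d", seq_len(config$nHousekeeping)))
  hk <- c(rep(FALSE, nCand), rep(TRUE, config$nHousekeeping))

  grid <- expand.grid(replicate = seq_len(config$probeReplicates),
                      zt = config$timepoints, condition = c("WW", "D"),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("NS_%s_ZT%02d_B%d", grid$condition, grid$zt,
                            grid$replicate)
  grid$is_reference <- FALSE
  grid$pair_id <- NA_character_

  ## technical replicate pairs: duplicate the first nTechPairs samples
  if (config$nTechPairs > 0) {
    tp <- grid[seq_len(min(config$nTechPairs, nrow(grid))), ]
    tp$pair_id <- sprintf("pair%02d", seq_len(nrow(tp)))
    grid$pair_id[seq_len(nrow(tp))] <- tp$pair_id
    tp$sample_id <- paste0(tp$sample_id, "_T2")
    grid <- rbind(grid, tp)
  }

  ## plate sets, each with pooled-RNA reference-row samples
  grid$set <- sprintf("set%02d", (seq_len(nrow(grid)) - 1) %/% config$setSize + 1)
  sets <- unique(grid$set)
  refs <- do.call(rbind, lapply(sets, function(s)
    data.frame(replicate = 1:2, zt = NA_real_, condition = "REF",
               sample_id = sprintf("REF_%s_R%d", s, 1:2),
               is_reference = TRUE, pair_id = NA_character_, set = s)))
  grid <- rbind(grid, refs)

  ## expected counts: cosine profile per condition, flat for housekeeping;
  ## reference samples share one pooled profile across all sets
  lambdaFor <- function(cond, zt) {
    lam <- numeric(length(probes))
    pool <- cond == "REF"
    if (pool) { cond <- "D"; zt <- 5 }
    amp <- if (cond == "D") cand$amp_d else cand$amp_ww
    ph <- if (cond == "D") cand$phase_d else cand$phase_ww
    lam[seq_len(nCand)] <- config$probeScale *
      pmax(0.1, cand$baseline + amp * cos(2 * pi * (zt - ph) / config$period))
    lam[nCand + seq_len(config$nHousekeeping)] <- hkLevels
    lam
  }
  setFactor <- setNames(exp(rnorm(length(sets), 0, config$setSdLog)), sets)
  counts <- sapply(seq_len(nrow(grid)), function(j)
    rpois(length(probes),
          lambdaFor(grid$condition[j], grid$zt[j]) * setFactor[grid$set[j]]))
  dimnames(counts) <- list(probes, grid$sample_id)

  ## spikes hit candidate probes only: the housekeeping probes anchor the
  ## normalization, and a spiked housekeeping cell would corrupt every other
  ## probe of its sample rather than the single cell being emulated
  spikeMask <- matrix(runif(length(counts)) < config$spikeFraction,
                      nrow(counts), ncol(counts))
  spikeMask[hk, ] <- FALSE
  spikeMask[, grid$is_reference] <- FALSE   # the reference row only calibrates
  counts[spikeMask] <- counts[spikeMask] * config$spikeFactor
  spikes <- data.frame(probe = probes[row(counts)[spikeMask]],
                       sample_id = grid$sample_id[col(counts)[spikeMask]])

  tab <- ProbeCountTable(
    counts = counts,
    probeData = data.frame(probe = probes, housekeeping = hk),
    sampleData = data.frame(sample_id = grid$sample_id, set = grid$set,
                            is_reference = grid$is_reference,
                            pair_id = grid$pair_id, condition = grid$condition,
                            zt = grid$zt,
                            replicate = paste0("B", grid$replicate)))
  list(table = tab, spikes = spikes)
}

#' Write a simulated experiment to tab-delimited files
#'
#' Writes expression and sample-metadata TSVs per condition, the long-format
#' trait table, and the per-gene truth table into \code{dir}. All files are
#' UTF-8, tab-delimited, '.' decimal, with a header row.
#'
#' @param sim result of \code{\link{simulateExperiment}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(ww = file.path(dir, "expression_WW.tsv"),
             ww_meta = file.path(dir, "samples_WW.tsv"),
             d = file.path(dir, "expression_D.tsv"),
             d_meta = file.path(dir, "samples_D.tsv"),
             traits = file.path(dir, "traits.tsv"),
             truth = file.path(dir, "truth_genes.tsv"))
  writeExpressionTable(sim$ww, paths["ww"], paths["ww_meta"])
  writeExpressionTable(sim$d, paths["d"], paths["d_meta"])
  write.table(sim$traits, paths["traits"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truthGenes(sim$truth), paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
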