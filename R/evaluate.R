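#' Super-enhancer calls for one sample
#'
#' The per-sample identification chain: dual-stringency peak calling on
#' the raw H3K27ac track, collapsed union of both peak sets, optional
#' amplicon exclusion, TSS exclusion, stitching, hockey-stick ranking,
#' and expressed-gene assignment by promoter activity.
#'
#' @param track raw-count H3K27ac [CoverageTrack-class].
#' @param annotation gene annotation data.frame.
#' @param pThresholds two peak-calling tail probabilities
#'   (strict, lenient), emulating dual MACS parameter sets.
#' @param minPeakLength minimum peak length in bp.
#' @param exclusion optional exclusion region ([GenomicRanges::GRanges]
#'   or region string) whose contacting peaks are discarded.
#' @param stitchDistance,tssExclusionBp ROSE stitching parameters
#'   (defaults 12500 and 1000).
#' @param controlTrack optional control track (raw counts) for signal
#'   subtraction in ranking.
#' @return list with \code{seCalls} ([rankAndCut()] output plus
#'   \code{assignedGene}), \code{peaks}, \code{regions},
#'   \code{expressed} (gene ids) and \code{rpmTrack}.
#' @export
sampleSuperEnhancers <- function(track, annotation,
                                 pThresholds = c(1e-9, 1e-5),
                                 minPeakLength = 200L,
                                 exclusion = NULL,
                                 stitchDistance = 12500L,
                                 tssExclusionBp = 1000L,
                                 controlTrack = NULL) {
  peakSets <- lapply(pThresholds, function(p)
    callPeaksSimple(track, pThreshold = p,
                    minLength = minPeakLength))
  peaks <- collapsePeakSets(peakSets)
  if (!is.null(exclusion))
    peaks <- excludeRegion(peaks, exclusion)
  kept <- tssExclude(peaks, annotation, t = tssExclusionBp)
  regions <- stitchPeaks(kept, s = stitchDistance)
  rpmTrack <- rpmNormalize(track)
  rpmControl <- if (!is.null(controlTrack)) {
    if (trackUnits(controlTrack) == "raw_counts")
      rpmNormalize(controlTrack) else controlTrack
  } else NULL
  calls <- rankAndCut(regions, rpmTrack, rpmControl,
                      constituents = kept)
  pa <- promoterActivity(annotation, rpmTrack)
  expressed <- pa$gene_id[pa$is_expressed]
  calls$assignedGene <- assignEnhancer(calls, annotation, expressed)
  list(seCalls = calls, peaks = peaks, regions = regions,
       expressed = expressed, rpmTrack = rpmTrack)
}

# F1 of called vs planted SE spans: a planted SE is recovered when
# called super regions cover >= half of it; a called super region is a
# false positive when it overlaps no planted SE.
seRecoveryF1 <- function(called, trueSE) {
  calledSuper <- called[called$isSuper]
  if (length(calledSuper) == 0L) return(0)
  hits <- findOverlaps(trueSE, calledSuper)
  ovWidth <- width(IRanges::pintersect(
    IRanges(start(trueSE)[queryHits(hits)], end(trueSE)[queryHits(hits)]),
    IRanges(start(calledSuper)[subjectHits(hits)],
            end(calledSuper)[subjectHits(hits)])))
  cov <- numeric(length(trueSE))
  agg <- tapply(ovWidth, queryHits(hits), sum)
  cov[as.integer(names(agg))] <- agg
  cov <- cov / width(trueSE)
  tp <- sum(cov >= 0.5)
  fn <- length(trueSE) - tp
  fp <- sum(!overlapsAny(calledSuper, trueSE))
  2 * tp / (2 * tp + fn + fp)
}

#' Run the full pipeline on one synthetic study and score recovery
#'
#' Executes every stage — per-condition super-enhancer identification,
#' collapsed-union differential coverage, TF occupancy and CRC
#' inference, and spike-in normalized expression — on one seeded draw of
#' a [syntheticDesign()], and scores each stage against the design's
#' ground-truth manifest.
#'
#' @param design a [syntheticDesign()].
#' @param seed integer seed for [simulateStudy()].
#' @param noise noise mode passed to [simulateStudy()].
#' @return list of metrics: \code{seF1} (per condition + mean),
#'   \code{diffSensitivity}, \code{diffPrecision}, \code{crcExact}
#'   (logical, both conditions recovered exactly), \code{crcMembers},
#'   \code{occupancyAccuracy}, \code{medianDownLog2fc}, plus the
#'   intermediate \code{samples}, \code{diff} and \code{crc} objects.
#' @export
evaluateRecovery <- function(design, seed = 1L, noise = "poisson") {
  sim <- simulateStudy(design, seed = seed, noise = noise)
  conds <- design$conditions
  samples <- lapply(conds, function(cond)
    sampleSuperEnhancers(sim$tracks[[cond]][["H3K27ac"]],
                         sim$annotation,
                         stitchDistance = design$stitchDistance,
                         tssExclusionBp = design$tssExclusion))
  names(samples) <- conds
  seF1 <- vapply(conds, function(cond)
    seRecoveryF1(samples[[cond]]$seCalls,
                 sim$manifest$trueSE[[cond]]), 0)

  unionSE <- collapseSeUnion(lapply(samples, function(s)
    granges(s$seCalls)[s$seCalls$isSuper]))
  acTracks <- lapply(conds, function(cond)
    sim$tracks[[cond]][["H3K27ac"]])
  names(acTracks) <- conds
  diff <- differentialCoverage(
    unionSE, acTracks, setNames(conds, conds),
    conditionOrder = conds, annotation = sim$annotation)
  clusters <- gr0(design$seClusters$chrom, design$seClusters$start0,
                  design$seClusters$end0)
  hit <- findOverlaps(diff, clusters, select = "first")
  truth <- ifelse(is.na(hit), "stable",
                  design$seClusters$seClass[hit])
  changed <- truth %in% c("gained", "lost")
  calledChanged <- diff$status %in% c("gained", "lost")
  diffSens <- if (any(changed))
    sum(diff$status[changed] == truth[changed]) / sum(changed) else NA
  diffPrec <- if (any(calledChanged))
    sum(diff$status[calledChanged] == truth[calledChanged]) /
      sum(calledChanged) else NA

  crc <- lapply(conds, function(cond) {
    tfTracks <- lapply(design$tfs, function(tf)
      rpmNormalize(sim$tracks[[cond]][[tf]]))
    names(tfTracks) <- design$tfs
    inferCRC(design$tfs, samples[[cond]]$seCalls,
             samples[[cond]]$expressed, tfTracks,
             rpmNormalize(sim$tracks[[cond]][["IgG"]]),
             condition = cond)
  })
  names(crc) <- conds
  crcExact <- all(vapply(conds, function(cond)
    setequal(crcMembers(crc[[cond]]),
             sim$manifest$crcMembers[[cond]]), TRUE))

  occAcc <- mean(unlist(lapply(conds, function(cond) {
    active <- sim$manifest$trueSE[[cond]]
    igg <- rpmNormalize(sim$tracks[[cond]][["IgG"]])
    unlist(lapply(design$tfs, function(tf) {
      pred <- enrichmentCall(rpmNormalize(sim$tracks[[cond]][[tf]]),
                             active, igg)
      isMember <- tf %in% sim$manifest$crcMembers[[cond]]
      truthBound <- isMember &
        active$gene %in% sim$manifest$crcMembers[[cond]]
      pred == truthBound
    }))
  })))

  fc <- foldChanges(sim$counts, sim$sampleConditions,
                    sim$lengths, conditionOrder = conds)
  down <- fc$gene_id %in% sim$manifest$plantedDown & fc$passes_filter
  medianDown <- median(fc$log2_fold_change[down])

  list(seF1 = seF1, meanSeF1 = mean(seF1),
       diffSensitivity = diffSens, diffPrecision = diffPrec,
       crcExact = crcExact,
       crcMembers = lapply(crc, crcMembers),
       occupancyAccuracy = occAcc,
       medianDownLog2fc = medianDown,
       samples = samples, diff = diff, crc = crc)
}

#' Multi-seed recovery study
#'
#' Repeats [evaluateRecovery()] over several seeds and aggregates the
#' stage-level recovery metrics.
#'
#' @param design a [syntheticDesign()].
#' @param seeds integer vector of seeds (default 20 seeds from
#'   \code{baseSeed}).
#' @param baseSeed first seed when \code{seeds} is NULL.
#' @param nSeeds number of seeds when \code{seeds} is NULL.
#' @return list with \code{meanSeF1}, \code{diffSensitivity},
#'   \code{diffPrecision} (means over seeds), \code{crcExactRuns},
#'   \code{nRuns}, \code{medianDownLog2fc} (median over seeds),
#'   \code{occupancyAccuracy} and the per-seed metric data.frame
#'   \code{perSeed}.
#' @export
recoveryStudy <- function(design, seeds = NULL, baseSeed = 1L,
                          nSeeds = 20L) {
  if (is.null(seeds))
    seeds <- baseSeed + seq_len(nSeeds) - 1L
  rows <- lapply(seeds, function(s) {
    m <- evaluateRecovery(design, seed = s)
    data.frame(seed = s, meanSeF1 = m$meanSeF1,
               diffSensitivity = m$diffSensitivity,
               diffPrecision = m$diffPrecision,
               crcExact = m$crcExact,
               occupancyAccuracy = m$occupancyAccuracy,
               medianDownLog2fc = m$medianDownLog2fc)
  })
  perSeed <- do.call(rbind, rows)
  list(meanSeF1 = mean(perSeed$meanSeF1),
       diffSensitivity = mean(perSeed$diffSensitivity, na.rm = TRUE),
       diffPrecision = mean(perSeed$diffPrecision, na.rm = TRUE),
       crcExactRuns = sum(perSeed$crcExact),
       nRuns = nrow(perSeed),
       medianDownLog2fc = median(perSeed$medianDownLog2fc),
       occupancyAccuracy = mean(perSeed$occupancyAccuracy),
       perSeed = perSeed)
}

#' Head-to-head global-shift identifiability
#'
#' Simulates a study whose treated condition carries a global
#' transcriptome multiplier (spike-ins unaffected) and compares the
#' median log2 fold change over highly expressed genes under spike-in
#' versus library-size normalization.  Spike-in factors recover the
#' planted shift; library-size factors cancel it by construction.
#'
#' @param globalShift planted global multiplier (default 0.5, a 2x
#'   depression).
#' @param seed integer seed.
#' @param design optional design override; default
#'   \code{syntheticDesign(globalShift = globalShift)} with no planted
#'   per-gene changes (\code{deFold} effects removed by using the
#'   global shift only).
#' @return list with \code{spikeinMedian}, \code{librarySizeMedian}
#'   and \code{trueLog2Shift}.
#' @export
globalShiftComparison <- function(globalShift = 0.5, seed = 1L,
                                  design = NULL) {
  if (is.null(design)) {
    design <- syntheticDesign(globalShift = globalShift)
    # isolate the global shift: no planted per-gene DE
    design$effect[] <- 1
    design$manifest$expression$true_log2fc <- log2(globalShift)
  }
  sim <- simulateStudy(design, seed = seed)
  conds <- design$conditions
  fcSpike <- foldChanges(sim$counts, sim$sampleConditions,
                         sim$lengths, conditionOrder = conds)
  fcLib <- foldChanges(sim$counts, sim$sampleConditions, sim$lengths,
                       conditionOrder = conds,
                       sizeFactors = librarySizeFactors(sim$counts))
  keep <- fcSpike$passes_filter
  list(spikeinMedian = median(fcSpike$log2_fold_change[keep]),
       librarySizeMedian = median(fcLib$log2_fold_change[keep]),
       trueLog2Shift = log2(design$globalShift))
}
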