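#' Resolved pipeline parameter set
#'
#' Collects every tunable parameter with its conventional default:
#' 50-bp bins, 200-bp read extension, ROSE stitching \code{-s 12500 -t
#' 1000}, promoter window TSS +/- 500 bp, expressed = top two-thirds of
#' promoter coverage, base-mean TPM filter 10, fold threshold 2 with
#' pseudocount 1, enrichment fold 3 with floor 0.5.  Overrides are
#' applied over the defaults; the resolved list is logged by
#' [runPipeline()].
#'
#' @param ... named overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    binWidth = 50L, extension = 200L,
    stitchDistance = 12500L, tssExclusionBp = 1000L,
    promoterWindow = 500L, expressedQuantile = 1 / 3,
    pThresholds = c(1e-9, 1e-5), minPeakLength = 200L,
    foldThreshold = 2, diffPseudocount = 1,
    enrichmentMinFold = 3, enrichmentFloor = 0.5,
    tpmFilter = 10, fcPseudocount = 0.5,
    exclusion = NULL, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

writeOccupancyTable <- function(se, path) {
  gr <- rowRanges(se)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  sig <- assay(se, "signal")
  colnames(sig) <- paste0("signal_", colnames(sig))
  enr <- assay(se, "enriched")
  colnames(enr) <- paste0("enriched_", colnames(enr))
  write.table(cbind(df, sig, enr), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Run the whole analysis on a synthetic study and write every stage's
#' outputs
#'
#' The "run-all" entry point: simulates a study from a
#' [syntheticDesign()] under \code{seed}, then chains the stages in
#' analysis order — per-condition peak calling, collapsing and
#' super-enhancer identification; collapsed-union differential
#' coverage; per-target occupancy matrix; CRC inference and
#' cross-condition comparison; spike-in normalized expression — writing
#' TSV/BED/JSON outputs plus a machine-readable run log (package
#' version, resolved parameters, output MD5 hashes).  Outputs are pure
#' functions of (design, config, seed): two runs with the same
#' arguments produce hash-identical files.
#'
#' @param outDir output directory (created if needed).
#' @param design a [syntheticDesign()].
#' @param seed integer seed for the simulation.
#' @param config a [pipelineConfig()].
#' @param writeTracks also write every simulated track as bedGraph
#'   (large; off by default).
#' @param quiet suppress the startup parameter banner.
#' @return Invisibly, a list with the run log and the per-stage result
#'   objects.
#' @export
runPipeline <- function(outDir, design = syntheticDesign(),
                        seed = 1L, config = pipelineConfig(),
                        writeTracks = FALSE, quiet = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(seed)
  if (!quiet) {
    message("resolved parameters:")
    for (k in names(config))
      message("  ", k, " = ",
              paste(format(config[[k]]), collapse = ", "))
  }
  ok <- FALSE
  outputs <- character(0)
  on.exit(if (!ok) unlink(file.path(outDir, outputs)), add = TRUE)
  emit <- function(name) {
    outputs <<- c(outputs, name)
    file.path(outDir, name)
  }

  sim <- simulateStudy(design, seed = seed)
  conds <- design$conditions
  writeAnnotation(sim$annotation[, c("gene_id", "gene_name", "chrom",
                                     "tss", "strand")],
                  emit("annotation.tsv"))
  writeCounts(sim$counts, emit("counts.tsv"), lengths = sim$lengths)
  writeChromSizes(design$seqlengths, emit("genome.chrom.sizes"))

  samples <- list()
  for (cond in conds) {
    s <- sampleSuperEnhancers(
      sim$tracks[[cond]][["H3K27ac"]], sim$annotation,
      pThresholds = config$pThresholds,
      minPeakLength = config$minPeakLength,
      exclusion = config$exclusion,
      stitchDistance = config$stitchDistance,
      tssExclusionBp = config$tssExclusionBp)
    samples[[cond]] <- s
    writeBed(s$peaks, emit(paste0("peaks_", cond, ".bed")))
    writeSeTable(s$seCalls,
                 emit(paste0("superenhancers_", cond, ".tsv")),
                 bedPath = emit(paste0("superenhancers_", cond,
                                       ".bed")))
  }

  unionSE <- collapseSeUnion(lapply(samples, function(s)
    granges(s$seCalls)[s$seCalls$isSuper]))
  acTracks <- lapply(conds, function(cond)
    sim$tracks[[cond]][["H3K27ac"]])
  names(acTracks) <- conds
  diff <- differentialCoverage(
    unionSE, acTracks, setNames(conds, conds),
    conditionOrder = conds, foldThreshold = config$foldThreshold,
    pseudocount = config$diffPseudocount, annotation = sim$annotation)
  writeDifferentialTable(
    diff, emit("differential_superenhancers.tsv"),
    gainedBed = emit("gained.bed"), lostBed = emit("lost.bed"),
    scatterPath = emit("scatter.tsv"))

  occ <- list()
  crc <- list()
  for (cond in conds) {
    tr <- sim$tracks[[cond]]
    targets <- setdiff(names(tr), c("IgG", "H3K27me3"))
    peakSets <- lapply(targets, function(tg)
      callPeaksSimple(tr[[tg]], minLength = config$minPeakLength))
    candidates <- collapsePeakSets(peakSets)
    candidates <- tssExclude(candidates, sim$annotation,
                             t = config$tssExclusionBp)
    rpm <- lapply(tr, function(x) rpmNormalize(x))
    occ[[cond]] <- buildOccupancyMatrix(
      rpm[c(targets, "IgG")], candidates,
      minFold = config$enrichmentMinFold,
      signalFloor = config$enrichmentFloor)
    writeOccupancyTable(occ[[cond]],
                        emit(paste0("occupancy_", cond, ".tsv")))
    crc[[cond]] <- inferCRC(
      design$tfs, samples[[cond]]$seCalls, samples[[cond]]$expressed,
      rpm[design$tfs], rpm[["IgG"]], condition = cond,
      minFold = config$enrichmentMinFold,
      signalFloor = config$enrichmentFloor)
  }
  delta <- compareCRCs(crc[[conds[1L]]], crc[[conds[2L]]])
  writeCrcReport(crc, emit("crc_report.json"), delta = delta)

  fc <- foldChanges(sim$counts, sim$sampleConditions, sim$lengths,
                    conditionOrder = conds,
                    filterTpm = config$tpmFilter,
                    pseudocount = config$fcPseudocount)
  write.table(fc, emit("expression_fold_changes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (writeTracks) {
    for (cond in conds)
      for (tg in names(sim$tracks[[cond]]))
        writeBedGraphTrack(sim$tracks[[cond]][[tg]],
                           emit(paste0("track_", cond, "_", tg,
                                       ".bedGraph")))
  }

  hashes <- md5sum(file.path(outDir, base::sort(outputs)))
  names(hashes) <- base::sort(outputs)
  log <- list(
    package = "enhancerCircuits",
    version = as.character(utils::packageVersion("enhancerCircuits")),
    seed = as.integer(seed),
    parameters = config[setdiff(names(config), "exclusion")],
    outputs = as.list(hashes))
  write_json(log, file.path(outDir, "runlog.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ok <- TRUE
  invisible(list(log = log, samples = samples, diff = diff,
                 occupancy = occ, crc = crc, delta = delta,
                 foldChanges = fc, outputs = names(hashes)))
}
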