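# 0-based half-open block -> 1-based closed GRanges
gr0 <- function(chrom, start0, end0)
  GRanges(chrom, IRanges(start = start0 + 1, end = end0))

#' Describe a two-condition synthetic regulatory-genomics study
#'
#' Lays out a small genome with planted typical enhancers,
#' super-enhancer (SE) clusters that are stable, decommissioned
#' ("lost") or formed de novo ("gained") between a reference and a
#' treated condition, TF occupancy wired to a known per-condition core
#' regulatory circuit, promoter H3K27ac for expressed genes, and an
#' expression count table with ERCC spike-ins encoding planted fold
#' changes and an optional global shift.  All coordinates are
#' deterministic functions of the parameters; randomness enters only in
#' [simulateStudy()].
#'
#' The default genome (2 chromosomes x 5 Mb, 60 genes, 6 candidate TFs,
#' 20 SE clusters of 4 x 1.5-kb constituents spaced 2.5 kb, 44 typical
#' enhancers) keeps a full end-to-end run to a few seconds while giving
#' every pipeline stage planted structure to recover.  Per chromosome
#' one TF loses its SE under treatment, one keeps it, and one gains one
#' — mirroring the decommissioned / shared / de novo circuit geometry
#' of retinoid-treated adrenergic neuroblastoma (GATA3, PHOX2B lost;
#' HAND2, ISL1 shared; MEIS1, SOX4 gained).
#'
#' @param chromLength length of each of the two chromosomes (bp).
#' @param binWidth track bin width (bp).
#' @param extension nominal read extension length (bp).
#' @param conditions length-2 condition labels (reference, treated).
#' @param background mean background bin count of the H3K27ac track.
#' @param typicalIntensity added mean bin count of typical enhancers.
#' @param seIntensity added mean bin count of active SE constituents.
#' @param seOffIntensity added intensity of an SE in its "off"
#'   condition (0 = fully decommissioned / not yet formed).
#' @param promoterIntensity added H3K27ac at expressed promoters
#'   (TSS +/- 500 bp).
#' @param tfBindIntensity added TF CUT&RUN signal at bound SE
#'   constituents.
#' @param tfBackground,iggBackground,me3Background flat background of
#'   the TF, IgG and H3K27me3 tracks.
#' @param me3Intensity added H3K27me3 at promoters silenced in a
#'   condition.
#' @param exposure Poisson exposure multiplier for all tracks (signal
#'   to noise knob; larger = cleaner).
#' @param reps expression replicates per condition.
#' @param baseCount expected count of an expressed gene in the
#'   reference condition.
#' @param silentCount expected count of a silent gene.
#' @param deFold planted differential-expression fold (treated genes
#'   move by \code{deFold} or \code{1/deFold}).
#' @param globalShift global multiplier applied to every biological
#'   gene in the treated condition (spike-ins are unaffected); 1 = no
#'   shift, 0.5 = planted 2x global depression.
#' @param nSpikes number of ERCC spike-in species.
#' @param stitchDistance,tssExclusion stitching parameters the planted
#'   clusters are designed to respect (defaults 12500 and 1000).
#' @return A \code{SyntheticDesign} list with the genome, annotation,
#'   planted block table, SE cluster table, expression truth and a
#'   ground-truth \code{manifest} (expressed genes, per-condition SE
#'   spans, differential status, CRC membership and edges, expression
#'   log2 fold changes).
#' @export
syntheticDesign <- function(chromLength = 5e6, binWidth = 50L,
                            extension = 200L,
                            conditions = c("DMSO", "ATRA"),
                            background = 1, typicalIntensity = 10,
                            seIntensity = 30, seOffIntensity = 0,
                            promoterIntensity = 15,
                            tfBindIntensity = 10, tfBackground = 1,
                            iggBackground = 1, me3Background = 0.5,
                            me3Intensity = 8, exposure = 1,
                            reps = 3L, baseCount = 600,
                            silentCount = 5, deFold = 4,
                            globalShift = 1, nSpikes = 24L,
                            stitchDistance = 12500L,
                            tssExclusion = 1000L) {
  # the fixed gene/enhancer layout needs ~90 kb between genes so
  # planted elements of neighboring genes stay beyond stitching range
  stopifnot(length(conditions) == 2L, chromLength >= 3e6,
            deFold > 1, globalShift > 0, reps >= 1L)
  chroms <- c("chr1", "chr2")
  seqlengths <- setNames(rep(chromLength, 2L), chroms)
  nPerChrom <- 30L
  geneSpacing <- floor((chromLength - 300000) / nPerChrom / binWidth) *
    binWidth
  tfNames <- list(chr1 = c(lost = "GATA3", shared = "HAND2",
                           gained = "MEIS1"),
                  chr2 = c(lost = "PHOX2B", shared = "ISL1",
                           gained = "SOX4"))
  roleByIndex <- function(i) {
    if (i == 3L) "tf_lost" else if (i == 10L) "tf_shared"
    else if (i == 17L) "tf_gained"
    else if (i %in% c(5L, 7L, 24L)) "se_stable"
    else if (i %in% c(12L, 26L)) "se_lost"
    else if (i %in% c(21L, 28L)) "se_gained"
    else if (i %in% c(1L, 2L, 4L, 6L, 8L, 9L, 11L, 13L, 14L, 15L,
                      16L)) "typical"
    else "silent"
  }
  ann <- do.call(rbind, lapply(chroms, function(chrom) {
    idx <- seq_len(nPerChrom)
    role <- vapply(idx, roleByIndex, "")
    tss0 <- 150000 + (idx - 1L) * geneSpacing
    id <- sprintf("G%s%02d", toupper(substring(chrom, 4)), idx)
    tfRole <- sub("tf_", "", role[startsWith(role, "tf_")])
    id[startsWith(role, "tf_")] <- tfNames[[chrom]][tfRole]
    data.frame(gene_id = id, gene_name = id, chrom = chrom,
               tss = tss0 + 1, strand = "+", role = role)
  }))
  rownames(ann) <- NULL

  # --- planted enhancer blocks ----------------------------------------
  consWidth <- 1500; consGap <- 2500; nCons <- 4L
  seSpan <- nCons * consWidth + (nCons - 1L) * consGap  # 13500 bp
  stopifnot(consGap <= stitchDistance)
  onOff <- function(cls) switch(cls,
    stable = c(seIntensity, seIntensity),
    lost   = c(seIntensity, seOffIntensity),
    gained = c(seOffIntensity, seIntensity))
  seRoles <- c(tf_lost = "lost", tf_shared = "stable",
               tf_gained = "gained", se_stable = "stable",
               se_lost = "lost", se_gained = "gained")
  seGenes <- ann[ann$role %in% names(seRoles), ]
  seClusters <- data.frame(
    id = paste0("SE_", seGenes$gene_id),
    chrom = seGenes$chrom, gene = seGenes$gene_id,
    seClass = unname(seRoles[seGenes$role]),
    start0 = (seGenes$tss - 1) + 8000,
    end0 = (seGenes$tss - 1) + 8000 + seSpan)
  blocks <- do.call(rbind, lapply(seq_len(nrow(seClusters)), function(k) {
    s0 <- seClusters$start0[k] + (seq_len(nCons) - 1L) *
      (consWidth + consGap)
    iv <- onOff(seClusters$seClass[k])
    data.frame(chrom = seClusters$chrom[k], start0 = s0,
               width = consWidth, intensityA = iv[1L],
               intensityB = iv[2L], kind = "se_constituent",
               cluster = seClusters$id[k], gene = seClusters$gene[k])
  }))
  typHosts <- ann[ann$role == "typical", ]
  typBlocks <- do.call(rbind, lapply(c(30000, 70000), function(off) {
    data.frame(chrom = typHosts$chrom,
               start0 = (typHosts$tss - 1) + off, width = 1000,
               intensityA = typicalIntensity,
               intensityB = typicalIntensity, kind = "typical",
               cluster = paste0("T_", typHosts$gene_id, "_", off),
               gene = typHosts$gene_id)
  }))
  blocks <- rbind(blocks, typBlocks)

  # --- expression truth -----------------------------------------------
  expressedIn <- function(role, cond) {
    if (role == "silent") return(FALSE)
    if (role == "tf_lost") return(cond == 1L)
    if (role == "tf_gained") return(cond == 2L)
    TRUE
  }
  exprA <- vapply(ann$role, expressedIn, TRUE, cond = 1L)
  exprB <- vapply(ann$role, expressedIn, TRUE, cond = 2L)
  deDown <- ann$gene_id[ann$role == "tf_lost" |
    (ann$role == "typical" &
       ave(seq_len(nrow(ann)), ann$chrom, FUN = seq_along) %in%
       c(1L, 2L, 4L, 6L))]
  deUp <- ann$gene_id[ann$role == "tf_gained" |
    (ann$role == "typical" &
       ave(seq_len(nrow(ann)), ann$chrom, FUN = seq_along) %in%
       c(8L, 9L, 11L, 13L))]
  baseA <- ifelse(exprA | exprB, baseCount, silentCount)
  baseA[ann$role == "tf_gained"] <- baseCount / deFold
  effect <- rep(1, nrow(ann))
  effect[ann$gene_id %in% deDown] <- 1 / deFold
  effect[ann$gene_id %in% deUp] <- deFold
  lengths <- 1000 + (seq_len(nrow(ann)) * 137) %% 2000
  spikes <- data.frame(
    id = sprintf("ERCC-%04d", seq_len(nSpikes)),
    concentration = round(2 ^ seq(5, 12, length.out = nSpikes)))
  nSamples <- 2L * reps
  depths <- 1 + 0.08 * ((seq_len(nSamples) %% 3L) - 1L)

  tfs <- unlist(lapply(tfNames, unname), use.names = FALSE)
  crcMembersTrue <- list(
    ann$gene_id[ann$role %in% c("tf_lost", "tf_shared")],
    ann$gene_id[ann$role %in% c("tf_shared", "tf_gained")])
  names(crcMembersTrue) <- conditions

  manifest <- list(
    expressed = setNames(list(ann$gene_id[exprA], ann$gene_id[exprB]),
                         conditions),
    seClusters = seClusters,
    trueSE = setNames(lapply(1:2, function(ci) {
      keep <- if (ci == 1L) seClusters$seClass %in% c("stable", "lost")
              else seClusters$seClass %in% c("stable", "gained")
      gr <- gr0(seClusters$chrom[keep], seClusters$start0[keep],
                seClusters$end0[keep])
      gr$gene <- seClusters$gene[keep]
      gr
    }), conditions),
    seStatus = setNames(seClusters$seClass, seClusters$id),
    crcMembers = crcMembersTrue,
    crcEdges = lapply(crcMembersTrue, function(m) {
      e <- matrix(TRUE, length(m), length(m), dimnames = list(m, m))
      e
    }),
    expression = data.frame(
      gene_id = ann$gene_id,
      true_log2fc = log2(effect * globalShift),
      planted_down = ann$gene_id %in% deDown,
      planted_up = ann$gene_id %in% deUp),
    plantedDown = deDown, plantedUp = deUp,
    sizeFactorTruth = depths / exp(mean(log(depths))))

  structure(list(
    seqlengths = seqlengths, binWidth = as.integer(binWidth),
    extension = as.integer(extension), conditions = conditions,
    annotation = ann, blocks = blocks, seClusters = seClusters,
    tfs = tfs, background = background,
    promoterIntensity = promoterIntensity,
    tfBindIntensity = tfBindIntensity, tfBackground = tfBackground,
    iggBackground = iggBackground, me3Background = me3Background,
    me3Intensity = me3Intensity, exposure = exposure,
    reps = as.integer(reps), baseA = baseA, effect = effect,
    geneLengths = setNames(lengths, ann$gene_id),
    globalShift = globalShift, spikes = spikes, depths = depths,
    stitchDistance = as.integer(stitchDistance),
    tssExclusion = as.integer(tssExclusion),
    manifest = manifest), class = "SyntheticDesign")
}

#' @export
print.SyntheticDesign <- function(x, ...) {
  cat(sprintf(
    "SyntheticDesign: %d chromosomes (%.1f Mb), %d genes, %d TFs\n",
    length(x$seqlengths), sum(x$seqlengths) / 1e6,
    nrow(x$annotation), length(x$tfs)))
  cat(sprintf("  SE clusters: %d (%s)\n", nrow(x$seClusters),
              paste(names(table(x$seClusters$seClass)),
                    table(x$seClusters$seClass),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  conditions: %s; reps: %d; global shift: %g\n",
              paste(x$conditions, collapse = " vs "), x$reps,
              x$globalShift))
  invisible(x)
}

# Per-bin Poisson means of one target track in one condition.
trackLambda <- function(design, condition, target) {
  ci <- match(condition, design$conditions)
  stopifnot(!is.na(ci))
  bw <- design$binWidth
  lam <- lapply(design$seqlengths, function(L)
    numeric(as.integer(ceiling(L / bw))))
  addBlock <- function(lam, chrom, start0, width, value) {
    if (value == 0) return(lam)
    f <- start0 %/% bw + 1L
    l <- (start0 + width - 1L) %/% bw + 1L
    lam[[chrom]][f:l] <- lam[[chrom]][f:l] + value
    lam
  }
  ann <- design$annotation
  expressed <- design$manifest$expressed[[condition]]
  if (target == "H3K27ac") {
    lam <- lapply(lam, function(v) v + design$background)
    bl <- design$blocks
    int <- if (ci == 1L) bl$intensityA else bl$intensityB
    for (k in seq_len(nrow(bl)))
      lam <- addBlock(lam, bl$chrom[k], bl$start0[k], bl$width[k],
                      int[k])
    prom <- ann[ann$gene_id %in% expressed, ]
    for (k in seq_len(nrow(prom)))
      lam <- addBlock(lam, prom$chrom[k], prom$tss[k] - 1 - 500, 1000,
                      design$promoterIntensity)
  } else if (target == "H3K27me3") {
    lam <- lapply(lam, function(v) v + design$me3Background)
    other <- design$manifest$expressed[[design$conditions[3L - ci]]]
    silenced <- ann[ann$gene_id %in% setdiff(other, expressed), ]
    for (k in seq_len(nrow(silenced)))
      lam <- addBlock(lam, silenced$chrom[k],
                      silenced$tss[k] - 1 - 500, 1000,
                      design$me3Intensity)
  } else if (target == "IgG") {
    lam <- lapply(lam, function(v) v + design$iggBackground)
  } else if (target %in% design$tfs) {
    lam <- lapply(lam, function(v) v + design$tfBackground)
    members <- design$manifest$crcMembers[[condition]]
    if (target %in% members) {
      bound <- design$blocks[design$blocks$kind == "se_constituent" &
                               design$blocks$gene %in% members, ]
      for (k in seq_len(nrow(bound)))
        lam <- addBlock(lam, bound$chrom[k], bound$start0[k],
                        bound$width[k], design$tfBindIntensity)
    }
  } else stop("unknown target: ", target)
  lam
}

#' Generate a complete synthetic study from a design
#'
#' Draws every track and the count table from the design's Poisson
#' model: bin counts ~ Poisson(intensity x exposure), TF occupancy
#' placed at the SE constituents of the condition's CRC members, gene
#' counts encoding the planted fold changes and global shift, and
#' spike-in counts ~ Poisson(concentration x depth) independent of the
#' biological shift.  Deterministic given \code{seed} (the global RNG
#' is seeded); \code{noise = "none"} replaces draws by rounded means
#' for oracle tests.
#'
#' @param design a [syntheticDesign()].
#' @param seed integer seed.
#' @param noise \code{"poisson"} or \code{"none"} (exact-mean mode).
#' @return list with \code{tracks} (per condition, named raw-count
#'   [CoverageTrack-class]s for H3K27ac, H3K27me3, each TF, IgG),
#'   \code{counts} (genes + spike-ins x samples), \code{lengths},
#'   \code{sampleConditions}, \code{annotation}, \code{manifest},
#'   \code{design} and \code{seed}.
#' @export
simulateStudy <- function(design, seed = 1L,
                          noise = c("poisson", "none")) {
  stopifnot(inherits(design, "SyntheticDesign"))
  noise <- match.arg(noise)
  missingTf <- setdiff(design$tfs, design$annotation$gene_id)
  if (length(missingTf))
    stop("CRC gene absent from annotation: ",
         paste(missingTf, collapse = ", "))
  set.seed(as.integer(seed))
  draw <- function(lambda) {
    if (noise == "none") round(lambda)
    else rpois(length(lambda), lambda)
  }
  targets <- c("H3K27ac", "H3K27me3", design$tfs, "IgG")
  tracks <- lapply(design$conditions, function(cond) {
    tl <- lapply(targets, function(tg) {
      lam <- trackLambda(design, cond, tg)
      bins <- lapply(lam, function(v) draw(v * design$exposure))
      CoverageTrack(bins, seqlengths = design$seqlengths,
                    binWidth = design$binWidth)
    })
    names(tl) <- targets
    tl
  })
  names(tracks) <- design$conditions

  reps <- design$reps
  samples <- paste(rep(design$conditions, each = reps),
                   rep(seq_len(reps), 2L), sep = "_")
  sampleConditions <- setNames(rep(design$conditions, each = reps),
                               samples)
  geneLam <- cbind(design$baseA %o% rep(1, reps),
                   (design$baseA * design$effect *
                      design$globalShift) %o% rep(1, reps))
  lam <- rbind(geneLam,
               design$spikes$concentration %o% rep(1, 2L * reps))
  lam <- sweep(lam, 2, design$depths, "*")
  counts <- matrix(draw(lam), nrow = nrow(lam),
                   dimnames = list(c(design$annotation$gene_id,
                                     design$spikes$id), samples))
  lengths <- c(design$geneLengths,
               setNames(rep(1000, nrow(design$spikes)),
                        design$spikes$id))
  list(tracks = tracks, counts = counts, lengths = lengths,
       sampleConditions = sampleConditions,
       annotation = design$annotation, manifest = design$manifest,
       design = design, seed = as.integer(seed))
}

#' Simulate read placements for one target track
#'
#' Draws BED-style 5' read positions whose extended (+\code{extension}
#' bp) coverage reproduces the design's mean bin intensities up to edge
#' effects, to exercise the read-level path
#' ([extendReads()] then [binCoverage()]).  Reads are placed uniformly
#' so that the expected extended-read depth within each planted block
#' (and the background) matches the block's intensity.
#'
#' @param design a [syntheticDesign()].
#' @param condition condition label.
#' @param target track target (default H3K27ac).
#' @param seed integer seed.
#' @return data.frame with \code{chrom}, \code{pos}, \code{strand}.
#' @export
simulateReads <- function(design, condition, target = "H3K27ac",
                          seed = 1L) {
  set.seed(as.integer(seed))
  lam <- trackLambda(design, condition, target)
  ext <- design$extension
  bw <- design$binWidth
  out <- lapply(names(lam), function(chrom) {
    v <- lam[[chrom]] * design$exposure
    # expected reads per bin so that extended reads overlapping a bin
    # match the bin mean: one read overlaps ~ext/bw bins
    n <- rpois(length(v), v * bw / ext)
    bin <- rep(seq_along(v), n)
    if (!length(bin))
      return(data.frame(chrom = character(0), pos = numeric(0),
                        strand = character(0)))
    L <- design$seqlengths[[chrom]]
    pos <- (bin - 1) * bw + floor(runif(length(bin), 0, bw))
    strand <- ifelse(runif(length(bin)) < 0.5, "+", "-")
    pos <- ifelse(strand == "-", pmin(pos + ext, L), pos)
    data.frame(chrom = chrom, pos = pos, strand = strand)
  })
  do.call(rbind, out)
}
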