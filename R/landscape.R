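#' Promoter H3K27ac activity and expressed-gene calls
#'
#' Scores each gene by its promoter H3K27ac coverage — the
#' [regionSignal()] of the RPM track over \code{TSS +/- window} — and
#' calls a gene expressed when it lies in the top two-thirds of promoter
#' coverage, the operational expression definition used when no RNA-seq
#' is at hand.  Ties at the boundary are expressed.
#'
#' @param annotation gene annotation data.frame (see
#'   [readAnnotation()]).
#' @param track RPM [CoverageTrack-class] (H3K27ac).
#' @param window promoter half-width in bp (default 500).
#' @param quantileCut fraction of genes excluded from the bottom
#'   (default 1/3, i.e. keep the top two-thirds).
#' @return data.frame with columns \code{gene_id},
#'   \code{promoter_coverage} and \code{is_expressed}.
#' @export
promoterActivity <- function(annotation, track, window = 500L,
                             quantileCut = 1 / 3) {
  if (nrow(annotation) == 0L) stop("empty annotation")
  if (trackUnits(track) != "RPM")
    stop("track must be RPM-normalized")
  # 0-based promoter window [tss0 - window, tss0 + window)
  prom <- GRanges(annotation$chrom,
                  IRanges(start = pmax(annotation$tss - window, 1),
                          end = annotation$tss + window - 1))
  cov <- regionSignal(track, prom)
  n <- length(cov)
  thr <- base::sort(cov)[floor(n * quantileCut) + 1]
  data.frame(gene_id = annotation$gene_id,
             promoter_coverage = cov,
             is_expressed = cov >= thr)
}

#' Assign enhancers to the nearest expressed gene
#'
#' Each enhancer is assigned to the single expressed gene whose TSS is
#' nearest the enhancer's center (\code{floor((start0 + end0) / 2)} in
#' the 0-based frame).  Equidistant ties break to the leftmost TSS.
#' Enhancers on chromosomes without expressed genes are assigned
#' \code{NA}.
#'
#' @param enhancers a [GenomicRanges::GRanges].
#' @param annotation gene annotation data.frame.
#' @param expressed character vector of expressed \code{gene_id}s (e.g.
#'   from [promoterActivity()]), or NULL for all genes.
#' @return Character vector of assigned \code{gene_id}s, one per
#'   enhancer (\code{NA} when unassignable).
#' @export
assignEnhancer <- function(enhancers, annotation, expressed = NULL) {
  genes <- if (is.null(expressed)) annotation else
    annotation[annotation$gene_id %in% expressed, , drop = FALSE]
  out <- rep(NA_character_, length(enhancers))
  if (length(enhancers) == 0L || nrow(genes) == 0L) return(out)
  # 0-based center: start0 = start - 1, end0 = end
  center0 <- floor((start(enhancers) - 1 + end(enhancers)) / 2)
  chroms <- as.character(seqnames(enhancers))
  for (chrom in unique(chroms)) {
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0L) next
    sel <- which(chroms == chrom)
    tss0 <- g$tss - 1
    ord <- order(tss0, g$gene_id)
    g <- g[ord, , drop = FALSE]; tss0 <- tss0[ord]
    for (i in sel) {
      dist <- abs(tss0 - center0[i])
      best <- which(dist == min(dist))[1L]  # leftmost TSS on ties
      out[i] <- g$gene_id[best]
    }
  }
  out
}

#' Collapse per-sample super-enhancer lists into one union region set
#'
#' Overlap-merges the super-enhancer regions identified separately in
#' each sample into a single disjoint, sorted set — the region universe
#' of the cross-condition differential analysis.
#'
#' @param seSets list of [GenomicRanges::GRanges] (e.g.
#'   \code{isSuper} regions from [rankAndCut()] per sample).
#' @return Disjoint, sorted [GenomicRanges::GRanges].
#' @export
collapseSeUnion <- function(seSets) {
  stopifnot(is.list(seSets), length(seSets) >= 1L)
  reduce(sort(do.call(c, unname(lapply(seSets, granges)))),
         min.gapwidth = 1L)
}

#' Differential coverage over a collapsed region union
#'
#' Quantifies each union region in every sample (per-million normalized
#' [regionSignal()]), averages within condition, and computes
#' \code{log2FC = log2((B + c) / (A + c))} with pseudocount \code{c}.
#' Regions are \code{gained} when \code{log2FC >= log2(foldThreshold)},
#' \code{lost} when \code{<= -log2(foldThreshold)}, else \code{stable};
#' the scatter diagonal (equal signal) is always \code{stable}.  Each
#' region is assigned to the nearest gene expressed in \emph{any}
#' sample (union of the per-sample expressed sets).
#'
#' @param unionRegions disjoint [GenomicRanges::GRanges] (see
#'   [collapseSeUnion()]).
#' @param tracks named list of [CoverageTrack-class], one per sample.
#'   Raw-count tracks are RPM-normalized on the fly using their
#'   \code{mappedReads}; tracks must carry a positive \code{mappedReads}.
#' @param conditions named character vector mapping sample name to
#'   condition label; exactly two distinct conditions.
#' @param conditionOrder optional length-2 character giving (A, B) =
#'   (reference, treatment); default: sorted unique conditions.
#' @param foldThreshold fold-change threshold (> 1; default 2).
#' @param pseudocount pseudocount \code{c} in normalized signal units
#'   (default 1).
#' @param annotation gene annotation data.frame; with NULL no genes are
#'   assigned.
#' @return A [GenomicRanges::GRanges] with per-sample coverage columns
#'   (\code{cov_<sample>}), \code{meanA}, \code{meanB}, \code{log2FC},
#'   \code{status} and \code{assignedGene}.
#' @export
differentialCoverage <- function(unionRegions, tracks, conditions,
                                 conditionOrder = NULL,
                                 foldThreshold = 2, pseudocount = 1,
                                 annotation = NULL) {
  stopifnot(is.list(tracks), length(tracks) >= 2L)
  if (foldThreshold <= 1) stop("foldThreshold must be > 1")
  if (is.null(names(tracks)) ||
      !all(names(tracks) %in% names(conditions)))
    stop("tracks must be named and covered by 'conditions'")
  conds <- conditions[names(tracks)]
  if (is.null(conditionOrder))
    conditionOrder <- base::sort(unique(conds))
  if (length(unique(conds)) != 2L ||
      !setequal(unique(conds), conditionOrder))
    stop("exactly two conditions are required; got: ",
         paste(unique(conds), collapse = ", "))
  covs <- vapply(names(tracks), function(s) {
    tr <- tracks[[s]]
    if (mappedReads(tr) <= 0)
      stop("track '", s, "' lacks a positive mappedReads")
    sig <- regionSignal(tr, unionRegions)
    if (trackUnits(tr) == "raw_counts")
      sig <- sig * 1e6 / mappedReads(tr)
    sig
  }, numeric(length(unionRegions)))
  covs <- matrix(covs, nrow = length(unionRegions),
                 dimnames = list(NULL, names(tracks)))
  meanA <- rowMeans(covs[, conds == conditionOrder[1L], drop = FALSE])
  meanB <- rowMeans(covs[, conds == conditionOrder[2L], drop = FALSE])
  log2FC <- log2((meanB + pseudocount) / (meanA + pseudocount))
  lim <- log2(foldThreshold)
  status <- ifelse(log2FC >= lim, "gained",
                   ifelse(log2FC <= -lim, "lost", "stable"))
  out <- granges(unionRegions)
  for (s in colnames(covs))
    mcols(out)[[paste0("cov_", s)]] <- covs[, s]
  out$meanA <- meanA
  out$meanB <- meanB
  out$log2FC <- log2FC
  out$status <- status
  if (!is.null(annotation)) {
    expressedAny <- unique(unlist(lapply(names(tracks), function(s) {
      tr <- tracks[[s]]
      if (trackUnits(tr) == "raw_counts") tr <- rpmNormalize(tr)
      pa <- promoterActivity(annotation, tr)
      pa$gene_id[pa$is_expressed]
    })))
    out$assignedGene <- assignEnhancer(out, annotation, expressedAny)
  } else {
    out$assignedGene <- NA_character_
  }
  out
}

#' Write differential-coverage results
#'
#' TSV of region coordinates (BED-frame), per-sample coverage, log2
#' fold change, status and assigned gene; optional BEDs of gained and
#' lost regions and a two-column scatter-ready table.
#'
#' @param diff output of [differentialCoverage()].
#' @param path TSV output path.
#' @param gainedBed,lostBed,scatterPath optional extra output paths.
#' @return \code{path}, invisibly.
#' @export
writeDifferentialTable <- function(diff, path, gainedBed = NULL,
                                   lostBed = NULL, scatterPath = NULL) {
  df <- data.frame(chrom = as.character(seqnames(diff)),
                   start = start(diff) - 1L, end = end(diff))
  df <- cbind(df, as.data.frame(mcols(diff)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gainedBed))
    writeBed(granges(diff)[diff$status == "gained"], gainedBed)
  if (!is.null(lostBed))
    writeBed(granges(diff)[diff$status == "lost"], lostBed)
  if (!is.null(scatterPath))
    write.table(data.frame(A = diff$meanA, B = diff$meanB),
                scatterPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
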