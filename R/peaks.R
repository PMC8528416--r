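#' Call peaks on a raw-count track by a Poisson background model
#'
#' A deliberately simple caller used to make the pipeline self-contained
#' on binned tracks: bins whose count exceeds the upper-tail Poisson
#' quantile of a (global) background rate are marked, and runs of
#' consecutive marked bins at least \code{minLength} bp long become
#' peaks.  Externally called peaks (MACS narrowPeak/BED) are accepted
#' interchangeably everywhere downstream.
#'
#' @param track raw-count [CoverageTrack-class].
#' @param backgroundRate \code{"auto"} (genome-wide mean bin count) or a
#'   positive Poisson rate per bin.
#' @param pThreshold upper-tail probability in (0, 1); a bin is marked
#'   when its count exceeds \code{qpois(1 - pThreshold, backgroundRate)}.
#' @param minLength minimum peak length in bp.
#' @return A [GenomicRanges::GRanges] of peaks with metadata column
#'   \code{score} = mean bin count within the peak.
#' @export
callPeaksSimple <- function(track, backgroundRate = "auto",
                            pThreshold = 1e-4, minLength = 200L) {
  stopifnot(is(track, "CoverageTrack"))
  if (track@units != "raw_counts")
    stop("peak calling expects a raw-count track")
  if (pThreshold <= 0 || pThreshold >= 1)
    stop("pThreshold must be in (0, 1)")
  if (identical(backgroundRate, "auto"))
    backgroundRate <- mean(unlist(track@bins))
  if (backgroundRate <= 0)  # all-zero track
    return(GRanges(seqlengths = track@seqlengths))
  cutoff <- qpois(1 - pThreshold, backgroundRate)
  bw <- track@binWidth
  minBins <- max(1L, as.integer(ceiling(minLength / bw)))
  peaks <- lapply(names(track@bins), function(chrom) {
    v <- track@bins[[chrom]]
    marked <- v > cutoff
    if (!any(marked)) return(NULL)
    r <- rle(marked)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minBins
    if (!any(keep)) return(NULL)
    starts <- starts[keep]; ends <- ends[keep]
    score <- vapply(seq_along(starts),
                    function(i) mean(v[starts[i]:ends[i]]), 0)
    GRanges(chrom,
            IRanges(start = (starts - 1L) * bw + 1L,
                    end = pmin(ends * bw, track@seqlengths[[chrom]])),
            score = score, seqlengths = track@seqlengths)
  })
  peaks <- peaks[!vapply(peaks, is.null, TRUE)]
  if (!length(peaks))
    return(GRanges(seqlengths = track@seqlengths))
  sort(do.call(c, unname(peaks)))
}

#' Collapse several peak sets into their merged union
#'
#' Overlapping or book-ended peaks across all sets are merged into
#' maximal disjoint intervals — the "collapsed union" used both to merge
#' dual-stringency peak calls before stitching and to merge per-sample
#' super-enhancer lists before differential analysis.  The merged score
#' is the maximum of constituent scores (advisory only; signal is always
#' re-measured from tracks downstream), or is re-measured from
#' \code{scoreTrack} when given.
#'
#' @param peakSets list of [GenomicRanges::GRanges] peak sets.
#' @param scoreTrack optional [CoverageTrack-class] from which merged
#'   scores are re-measured as mean bin signal.
#' @return Sorted, disjoint [GenomicRanges::GRanges] with a
#'   \code{score} column.
#' @export
collapsePeakSets <- function(peakSets, scoreTrack = NULL) {
  stopifnot(is.list(peakSets), length(peakSets) >= 1L)
  all <- do.call(c, unname(lapply(peakSets, granges)))
  merged <- reduce(sort(all), min.gapwidth = 1L)
  if (length(merged) == 0L) {
    merged$score <- numeric(0)
    return(merged)
  }
  if (!is.null(scoreTrack)) {
    merged$score <- regionSignal(scoreTrack, merged) /
      (width(merged) / binWidth(scoreTrack))
  } else {
    scores <- unlist(lapply(peakSets, function(p) {
      if (!is.null(p$score)) p$score else rep(0, length(p))
    }))
    hits <- findOverlaps(all, merged)
    merged$score <- vapply(seq_along(merged), function(j) {
      s <- scores[queryHits(hits)[subjectHits(hits) == j]]
      if (length(s)) max(s) else 0
    }, 0)
  }
  merged
}

#' Discard peaks contacting an exclusion region
#'
#' Removes every peak overlapping the exclusion region(s) by at least
#' one base ("contact").  Used to drop peaks inside high-copy amplicons
#' — e.g. the MYCN-proximal region \code{chr2:14817188-17228298} — whose
#' apparent enrichment reflects DNA copy number, not chromatin state.
#'
#' @param peaks a [GenomicRanges::GRanges].
#' @param exclusion a [GenomicRanges::GRanges] or region string(s)
#'   parsed by [parseRegion()].
#' @return The retained peaks, coordinates untouched.
#' @export
excludeRegion <- function(peaks, exclusion) {
  if (is.character(exclusion))
    exclusion <- parseRegion(exclusion)
  # seqlevels disjoint from the exclusion simply cannot overlap
  hit <- suppressWarnings(overlapsAny(peaks, exclusion))
  peaks[!hit]
}
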