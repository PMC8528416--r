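#' Remove peaks fully contained in promoter-proximal windows
#'
#' ROSE-style TSS exclusion: peaks lying entirely within
#' \code{[TSS - t, TSS + t)} of any annotated TSS are removed before
#' stitching, so promoter signal does not seed super-enhancers.
#' Partially overlapping peaks are retained.  \code{t = 0} is the
#' identity.
#'
#' @param peaks a [GenomicRanges::GRanges].
#' @param annotation gene annotation data.frame (see
#'   [readAnnotation()]).
#' @param t half-width of the exclusion window in bp (default 1000, the
#'   conventional \code{-t 1000}).
#' @return The retained peaks.
#' @export
tssExclude <- function(peaks, annotation, t = 1000L) {
  t <- as.integer(t)
  if (is.na(t) || t < 0L) stop("t must be >= 0")
  if (t == 0L || length(peaks) == 0L) return(peaks)
  # 0-based window [tss0 - t, tss0 + t) with tss0 = tss - 1
  windows <- GRanges(annotation$chrom,
                     IRanges(start = pmax(annotation$tss - t, 1),
                             end = annotation$tss + t - 1))
  contained <- suppressWarnings(
    overlapsAny(peaks, windows, type = "within"))
  peaks[!contained]
}

#' Stitch nearby peaks into enhancer regions
#'
#' Same-chromosome peaks whose gap is at most \code{s} bp are merged
#' transitively (the ROSE \code{-s} parameter; default 12500).  The
#' output is disjoint and sorted, consecutive regions are more than
#' \code{s} bp apart, and the union of outputs covers the union of
#' inputs.  \code{s = 0} reduces to plain overlap/book-ended merging.
#'
#' @param peaks a [GenomicRanges::GRanges].
#' @param s maximum stitching gap in bp.
#' @return Stitched [GenomicRanges::GRanges] regions.
#' @export
stitchPeaks <- function(peaks, s = 12500L) {
  s <- as.integer(s)
  if (is.na(s) || s < 0L) stop("s must be >= 0")
  reduce(sort(granges(peaks)), min.gapwidth = s + 1L)
}

#' Rank stitched regions and place the hockey-stick cutoff
#'
#' Ranks candidate regions by integrated signal
#' ([regionSignal()] on the RPM track, minus the control track's signal
#' when given, floored at 0) and classifies super-enhancers with the
#' ROSE tangent rule: with regions sorted ascending and both the rank
#' index and the signal rescaled to \eqn{[0, 1]}, the cutoff sits where
#' the curve's slope equals 1 — found by scanning for the point
#' maximizing the distance \eqn{x - y} below the diagonal, which is
#' equivalent for the convex "hockey stick" curves ranked enhancer
#' signal produces.  Regions with signal strictly above the cutoff are
#' super-enhancers.  Ties at the maximum distance break toward the
#' higher signal (fewer super-enhancers).  Degenerate curves with fewer
#' than three distinct signal values yield zero super-enhancers with a
#' warning.
#'
#' @param regions candidate stitched regions ([GenomicRanges::GRanges]).
#' @param signalTrack RPM [CoverageTrack-class] (e.g. H3K27ac).
#' @param controlTrack optional RPM control (input/IgG) track whose
#'   region signal is subtracted, floored at 0.
#' @param constituents optional peak set; when given a
#'   \code{nConstituents} count per region is recorded.
#' @return A [GenomicRanges::GRanges] sorted by descending signal with
#'   metadata columns \code{signal}, \code{rank} (1 = highest),
#'   \code{isSuper} and optionally \code{nConstituents}.
#' @examples
#' tr <- CoverageTrack(list(chr1 = c(rep(1, 50), rep(30, 50))),
#'                     c(chr1 = 5000), units = "RPM", mappedReads = 1e6)
#' @export
rankAndCut <- function(regions, signalTrack, controlTrack = NULL,
                       constituents = NULL) {
  if (length(regions) == 0L) stop("no candidate regions")
  if (trackUnits(signalTrack) != "RPM")
    stop("signalTrack must be RPM-normalized")
  sig <- regionSignal(signalTrack, regions)
  if (!is.null(controlTrack)) {
    if (trackUnits(controlTrack) != "RPM")
      stop("controlTrack must be RPM-normalized")
    sig <- pmax(sig - regionSignal(controlTrack, regions), 0)
  }
  cutoff <- hockeyStickCutoff(sig)
  out <- granges(regions)
  out$signal <- sig
  ord <- order(sig, decreasing = TRUE)
  out <- out[ord]
  out$rank <- seq_along(out)
  out$isSuper <- out$signal > cutoff$cutoff
  if (!is.null(constituents))
    out$nConstituents <- countOverlaps(out, constituents)
  attr(out, "cutoff") <- cutoff$cutoff
  out
}

#' Tangent-rule cutoff on a vector of signals
#'
#' Internal engine of [rankAndCut()], exposed for diagnostics: rescales
#' the ascending (rank, signal) curve to the unit square and returns the
#' signal value at the point maximizing \eqn{x - y}, where the rescaled
#' slope equals one.
#'
#' @param sig numeric signal vector.
#' @return list with \code{cutoff} (signal value; \code{Inf} for
#'   degenerate curves so nothing is super), \code{index} (position in
#'   the ascending order) and \code{x} (rescaled rank at the cutoff).
#' @export
hockeyStickCutoff <- function(sig) {
  n <- length(sig)
  if (length(unique(sig)) < 3L || n < 3L) {
    warning("degenerate signal curve: no super-enhancers called")
    return(list(cutoff = Inf, index = NA_integer_, x = NA_real_))
  }
  s <- base::sort(sig)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1L]) / (s[n] - s[1L])
  d <- x - y
  k <- max(which(d == max(d)))  # ties -> higher signal, conservative
  list(cutoff = s[k], index = k, x = x[k])
}

#' Write a ROSE-like super-enhancer table
#'
#' TSV with region coordinates, constituent count, signal, rank and the
#' super-enhancer flag, plus a BED of the super-enhancer regions when
#' \code{bedPath} is given.
#'
#' @param calls output of [rankAndCut()].
#' @param path TSV output path.
#' @param bedPath optional BED output path for \code{isSuper} regions.
#' @return \code{path}, invisibly.
#' @export
writeSeTable <- function(calls, path, bedPath = NULL) {
  df <- data.frame(
    chrom = as.character(seqnames(calls)),
    start = start(calls) - 1L,  # BED-frame coordinates in the table
    end = end(calls),
    nConstituents = if (!is.null(calls$nConstituents))
      calls$nConstituents else NA_integer_,
    signal = calls$signal,
    rank = calls$rank,
    isSuper = calls$isSuper)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bedPath))
    writeBed(granges(calls)[calls$isSuper], bedPath)
  invisible(path)
}
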