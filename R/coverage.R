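#' Extend aligned read positions to fixed-length intervals
#'
#' ChIP-seq/CUT&RUN density tracks are built from the 5' alignment
#' position of each read, artificially extended to the expected fragment
#' length (200 bp by default) in the read's strand direction, then
#' binned.  Positions are BED-style 0-based: a plus-strand read at
#' position \eqn{p} becomes the 0-based interval \eqn{[p, p+L)}, a
#' minus-strand read \eqn{[p-L, p)}.  Intervals are clipped at
#' chromosome ends rather than rejected.
#'
#' @param reads data.frame with columns \code{chrom}, \code{pos}
#'   (0-based 5' position) and \code{strand} (\code{"+"} or \code{"-"}).
#' @param seqlengths named numeric vector of chromosome lengths.
#' @param extension target interval length in bp (> 0); default 200.
#' @return A [GenomicRanges::GRanges] with one range per input read, in
#'   input order.
#' @examples
#' reads <- data.frame(chrom = "chr1", pos = c(1000, 1000),
#'                     strand = c("+", "-"))
#' extendReads(reads, c(chr1 = 1e5))
#' @export
extendReads <- function(reads, seqlengths, extension = 200L) {
  stopifnot(is.data.frame(reads),
            all(c("chrom", "pos", "strand") %in% names(reads)))
  extension <- as.integer(extension)
  if (is.na(extension) || extension <= 0L)
    stop("extension must be a positive integer")
  bad <- setdiff(unique(as.character(reads$chrom)), names(seqlengths))
  if (length(bad))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  if (!all(reads$strand %in% c("+", "-")))
    stop("read strand must be '+' or '-'")
  len <- seqlengths[as.character(reads$chrom)]
  if (any(reads$pos < 0 | reads$pos > len))
    stop("read position outside chromosome bounds")
  plus <- reads$strand == "+"
  # 0-based half-open [s0, e0), then to 1-based closed
  s0 <- ifelse(plus, reads$pos, reads$pos - extension)
  e0 <- ifelse(plus, reads$pos + extension, reads$pos)
  s0 <- pmax(s0, 0)
  e0 <- pmin(e0, len)
  e0 <- pmax(e0, s0 + 1)  # keep boundary reads as >= 1 bp
  GRanges(as.character(reads$chrom),
          IRanges(start = s0 + 1, end = e0),
          strand = reads$strand,
          seqlengths = seqlengths)
}

#' Bin interval coverage into a raw-count track
#'
#' Computes the per-bin interval density: each interval contributes 1 to
#' every bin it overlaps by at least one base.  Bins tile each
#' chromosome from coordinate 0 at \code{binWidth} bp (50 by default,
#' the conventional ChIP-seq track resolution); the final bin may be
#' partial.
#'
#' @param intervals a [GenomicRanges::GRanges] of (extended) reads or
#'   fragments.
#' @param seqlengths named numeric chromosome lengths.
#' @param binWidth bin width in bp.
#' @param mappedReads depth denominator recorded on the track; defaults
#'   to the number of input intervals.
#' @return A [CoverageTrack-class] in raw counts.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200))
#' binCoverage(gr, c(chr1 = 400))
#' @export
binCoverage <- function(intervals, seqlengths, binWidth = 50L,
                        mappedReads = length(intervals)) {
  binWidth <- as.integer(binWidth)
  if (is.na(binWidth) || binWidth <= 0L)
    stop("binWidth must be a positive integer")
  bad <- setdiff(as.character(unique(seqnames(intervals))),
                 names(seqlengths))
  if (length(bad))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  bins <- lapply(names(seqlengths), function(chrom) {
    nb <- as.integer(ceiling(seqlengths[[chrom]] / binWidth))
    sel <- as.character(seqnames(intervals)) == chrom
    if (!any(sel)) return(numeric(nb))
    s0 <- start(intervals)[sel] - 1L  # 0-based inclusive start
    e0 <- end(intervals)[sel]        # 0-based exclusive end
    f <- pmin(s0 %/% binWidth + 1L, nb)
    l <- pmin((e0 - 1L) %/% binWidth + 1L, nb)
    # difference-array accumulation of +1 over bins f..l per interval
    delta <- tabulate(f, nbins = nb + 1L) -
      tabulate(l + 1L, nbins = nb + 1L)
    cumsum(delta)[seq_len(nb)]
  })
  names(bins) <- names(seqlengths)
  CoverageTrack(bins, seqlengths = seqlengths, binWidth = binWidth,
                units = "raw_counts", mappedReads = mappedReads)
}

#' Normalize a raw-count track to reads per million
#'
#' Multiplies every bin by \code{1e6 / mappedReads} so tracks of
#' different sequencing depth are comparable.
#'
#' @param track a raw-count [CoverageTrack-class] with
#'   \code{mappedReads > 0}.
#' @return The track in RPM units.
#' @export
rpmNormalize <- function(track) {
  stopifnot(is(track, "CoverageTrack"))
  if (track@units == "RPM")
    stop("track is already RPM-normalized")
  if (track@mappedReads <= 0)
    stop("mappedReads must be > 0 for RPM normalization")
  k <- 1e6 / track@mappedReads
  track@bins <- lapply(track@bins, function(v) v * k)
  track@units <- "RPM"
  track
}

#' Integrated signal of regions over a binned track
#'
#' For each region, sums bin values weighted by the fraction of the bin
#' the region overlaps (\code{overlap_bp / binWidth}).  This is the
#' quantity ranked by the super-enhancer cutoff and compared across
#' conditions in the differential analysis.
#'
#' @param track a [CoverageTrack-class].
#' @param regions a [GenomicRanges::GRanges]; every chromosome must be
#'   present in the track.
#' @return Numeric vector, one value per region.
#' @examples
#' tr <- CoverageTrack(list(chr1 = c(3, 4)), c(chr1 = 100))
#' regionSignal(tr, GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50)))
#' @export
regionSignal <- function(track, regions) {
  stopifnot(is(track, "CoverageTrack"))
  chroms <- as.character(seqnames(regions))
  bad <- setdiff(unique(chroms), names(track@bins))
  if (length(bad))
    stop("region chromosome(s) absent from track: ",
         paste(bad, collapse = ", "))
  bw <- as.numeric(track@binWidth)
  out <- numeric(length(regions))
  for (chrom in unique(chroms)) {
    sel <- chroms == chrom
    v <- track@bins[[chrom]]
    L <- track@seqlengths[[chrom]]
    s0 <- pmax(start(regions)[sel] - 1, 0)
    e0 <- pmin(end(regions)[sel], L)
    if (any(e0 <= s0))
      stop("region outside chromosome bounds on ", chrom)
    nb <- length(v)
    f <- pmin(s0 %/% bw + 1, nb)
    l <- pmin((e0 - 1) %/% bw + 1, nb)
    cs <- c(0, cumsum(v))
    full <- cs[l + 1] - cs[f]
    left <- (s0 - (f - 1) * bw) / bw
    right <- (l * bw - e0) / bw
    out[sel] <- full - v[f] * left - v[l] * right
  }
  out
}
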