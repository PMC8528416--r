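#' Read a chrom.sizes table
#'
#' Two-column TSV of chromosome name and length in bp, the UCSC
#' \code{chrom.sizes} convention.
#'
#' @param path file path.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  if (any(is.na(df$size)) || any(df$size <= 0))
    stop("invalid chromosome size in ", path)
  setNames(df$size, df$chrom)
}

#' @rdname readChromSizes
#' @param seqlengths named numeric chromosome lengths.
#' @export
writeChromSizes <- function(seqlengths, path) {
  write.table(data.frame(names(seqlengths),
                         format(seqlengths, scientific = FALSE,
                                trim = TRUE)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read intervals from BED or narrowPeak
#'
#' BED coordinates (0-based half-open) are converted to the 1-based
#' closed convention of [GenomicRanges::GRanges].  For
#' \code{.narrowPeak} files the ENCODE extra columns are parsed; only
#' the first six columns are interpreted downstream.
#'
#' @param path file path (\code{.bed} or \code{.narrowPeak}).
#' @return A [GenomicRanges::GRanges].
#' @export
readBed <- function(path) {
  if (grepl("\\.narrowPeak$", path, ignore.case = TRUE)) {
    rtracklayer::import(path, format = "bed",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
  } else {
    rtracklayer::import(path, format = "bed")
  }
}

#' @rdname readBed
#' @param gr a [GenomicRanges::GRanges] to write.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read or write a binned coverage track as bedGraph
#'
#' bedGraph intervals (0-based half-open) are mapped onto the track's
#' fixed bins.  Writing run-length compresses equal-valued adjacent
#' bins; zero runs are kept so the round trip is exact.
#'
#' @param path file path.
#' @param seqlengths named numeric chromosome lengths.
#' @param binWidth bin width in bp.
#' @param mappedReads depth denominator to record on the track.
#' @param units track units to record.
#' @return \code{readBedGraphTrack}: a [CoverageTrack-class].
#' @export
readBedGraphTrack <- function(path, seqlengths, binWidth = 50L,
                              mappedReads = NA, units = "raw_counts") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  trackFromRanges(gr, gr$score, seqlengths, binWidth, mappedReads,
                  units)
}

#' @rdname readBedGraphTrack
#' @param track a [CoverageTrack-class] to write.
#' @export
writeBedGraphTrack <- function(track, path) {
  stopifnot(is(track, "CoverageTrack"))
  bw <- track@binWidth
  grl <- lapply(names(track@bins), function(chrom) {
    v <- track@bins[[chrom]]
    r <- rle(v)
    n <- length(r$lengths)
    e0 <- pmin(cumsum(r$lengths) * bw, track@seqlengths[[chrom]])
    s0 <- cumsum(c(0, r$lengths[-n])) * bw
    GRanges(chrom, IRanges(start = s0 + 1, end = e0),
            score = r$values, seqlengths = track@seqlengths)
  })
  gr <- do.call(c, unname(grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# Project scored ranges onto fixed bins (last write wins within a bin
# only when ranges are unaligned; aligned inputs map one-to-one).
trackFromRanges <- function(gr, values, seqlengths, binWidth,
                            mappedReads = NA, units = "raw_counts") {
  binWidth <- as.integer(binWidth)
  bins <- lapply(names(seqlengths), function(chrom) {
    numeric(as.integer(ceiling(seqlengths[[chrom]] / binWidth)))
  })
  names(bins) <- names(seqlengths)
  chroms <- as.character(seqnames(gr))
  bad <- setdiff(unique(chroms), names(seqlengths))
  if (length(bad))
    stop("track file covers unknown chromosome(s): ",
         paste(bad, collapse = ", "))
  for (chrom in unique(chroms)) {
    sel <- which(chroms == chrom)
    nb <- length(bins[[chrom]])
    s0 <- start(gr)[sel] - 1L
    e0 <- pmin(end(gr)[sel], seqlengths[[chrom]])
    f <- pmin(s0 %/% binWidth + 1L, nb)
    l <- pmin((e0 - 1L) %/% binWidth + 1L, nb)
    for (i in seq_along(sel))
      bins[[chrom]][f[i]:l[i]] <- values[sel[i]]
  }
  if (is.na(mappedReads)) mappedReads <- sum(unlist(bins))
  CoverageTrack(bins, seqlengths = seqlengths, binWidth = binWidth,
                units = units, mappedReads = mappedReads)
}

#' Read or write a binned coverage track as fixedStep WIG
#'
#' The WIG format is 1-based; \code{fixedStep} blocks with
#' \code{step == span == binWidth} map one value per bin, the layout
#' produced by MACS-style density tracks.  Malformed lines are rejected
#' with their line number.
#'
#' @param path file path.
#' @param seqlengths named numeric chromosome lengths.
#' @param binWidth expected bin width in bp.
#' @param mappedReads depth denominator to record on the track.
#' @param units track units to record.
#' @return \code{readWigTrack}: a [CoverageTrack-class].
#' @export
readWigTrack <- function(path, seqlengths, binWidth = 50L,
                         mappedReads = NA, units = "raw_counts") {
  binWidth <- as.integer(binWidth)
  lines <- readLines(path)
  bins <- lapply(names(seqlengths), function(chrom) {
    numeric(as.integer(ceiling(seqlengths[[chrom]] / binWidth)))
  })
  names(bins) <- names(seqlengths)
  chrom <- NA_character_
  bin <- NA_integer_
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "track") ||
        startsWith(line, "#"))
      next
    if (startsWith(line, "fixedStep")) {
      fields <- strsplit(line, "[ \t]+")[[1]][-1]
      kv <- strsplit(fields, "=")
      if (any(lengths(kv) != 2))
        stop("malformed fixedStep declaration at line ", i)
      keys <- vapply(kv, `[`, "", 1)
      vals <- setNames(vapply(kv, `[`, "", 2), keys)
      if (!all(c("chrom", "start", "step") %in% keys))
        stop("fixedStep missing chrom/start/step at line ", i)
      chrom <- vals[["chrom"]]
      if (!chrom %in% names(seqlengths))
        stop("unknown chromosome '", chrom, "' at line ", i)
      wstart <- suppressWarnings(as.integer(vals[["start"]]))
      step <- suppressWarnings(as.integer(vals[["step"]]))
      span <- if ("span" %in% keys)
        suppressWarnings(as.integer(vals[["span"]])) else 1L
      if (anyNA(c(wstart, step, span)) || wstart < 1L)
        stop("malformed fixedStep declaration at line ", i)
      if (step != binWidth || span != binWidth)
        stop("fixedStep step/span must equal binWidth (", binWidth,
             ") at line ", i)
      if ((wstart - 1L) %% binWidth != 0L)
        stop("fixedStep start not bin-aligned at line ", i)
      bin <- (wstart - 1L) %/% binWidth + 1L
    } else {
      if (is.na(chrom))
        stop("value before any fixedStep declaration at line ", i)
      value <- suppressWarnings(as.numeric(line))
      if (is.na(value))
        stop("malformed value at line ", i)
      if (bin > length(bins[[chrom]]))
        stop("value beyond chromosome end at line ", i)
      bins[[chrom]][bin] <- value
      bin <- bin + 1L
    }
  }
  if (is.na(mappedReads)) mappedReads <- sum(unlist(bins))
  CoverageTrack(bins, seqlengths = seqlengths, binWidth = binWidth,
                units = units, mappedReads = mappedReads)
}

#' @rdname readWigTrack
#' @param track a [CoverageTrack-class] to write.
#' @export
writeWigTrack <- function(track, path) {
  stopifnot(is(track, "CoverageTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  bw <- track@binWidth
  for (chrom in names(track@bins)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       chrom, bw, bw), con)
    writeLines(format(track@bins[[chrom]], trim = TRUE,
                      scientific = FALSE, digits = 10), con)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns \code{gene_id}, \code{gene_name}, \code{chrom},
#' \code{tss} (1-based TSS position) and \code{strand}; one TSS per
#' record, unique \code{gene_id}.
#'
#' @param path file path.
#' @return data.frame of the annotation.
#' @export
readAnnotation <- function(path) {
  df <- read.delim(path, colClasses = c(
    gene_id = "character", gene_name = "character",
    chrom = "character", tss = "numeric", strand = "character"))
  need <- c("gene_id", "gene_name", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation")
  df
}

#' @rdname readAnnotation
#' @param annotation annotation data.frame to write.
#' @export
writeAnnotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read or write a gene-by-sample count table
#'
#' TSV with a \code{gene_id} column, an optional \code{length} column of
#' effective gene lengths (bp, used for TPM), and one integer column per
#' sample.  ERCC spike-in rows are recognized downstream by the
#' \code{"ERCC-"} prefix.
#'
#' @param path file path.
#' @return \code{readCounts}: list with \code{counts} (integer matrix,
#'   genes x samples) and \code{lengths} (named numeric or NULL).
#' @export
readCounts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!"gene_id" %in% names(df))
    stop("count table must have a gene_id column")
  lengths <- NULL
  if ("length" %in% names(df))
    lengths <- setNames(as.numeric(df$length), df$gene_id)
  samples <- setdiff(names(df), c("gene_id", "length"))
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "numeric"
  if (any(counts < 0, na.rm = TRUE))
    stop("negative counts in ", path)
  list(counts = counts, lengths = lengths)
}

#' @rdname readCounts
#' @param counts genes x samples matrix with rownames.
#' @param lengths optional named numeric effective gene lengths.
#' @export
writeCounts <- function(counts, path, lengths = NULL) {
  df <- data.frame(gene_id = rownames(counts), check.names = FALSE)
  if (!is.null(lengths))
    df$length <- as.numeric(lengths[rownames(counts)])
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a region string
#'
#' Parses \code{"chrom:start-end"} as 0-based half-open coordinates, the
#' frame in which BED-based exclusion lists (such as the MYCN-amplicon
#' region \code{chr2:14817188-17228298}) are written, and returns the
#' equivalent 1-based closed [GenomicRanges::GRanges].  If the source of
#' a region string used 1-based inclusive coordinates its span differs
#' by one base at the left edge; callers for whom that base matters
#' should construct the \code{GRanges} directly.
#'
#' @param x region string(s) like \code{"chr2:14817188-17228298"};
#'   whitespace and thousands commas are tolerated.
#' @return A [GenomicRanges::GRanges].
#' @export
parseRegion <- function(x) {
  x <- gsub("[ ,]", "", x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop("cannot parse region string: ", paste(x[bad], collapse = ", "))
  chrom <- vapply(m, `[`, "", 2)
  s0 <- as.numeric(vapply(m, `[`, "", 3))
  e0 <- as.numeric(vapply(m, `[`, "", 4))
  if (any(e0 <= s0))
    stop("region end must exceed start: ", paste(x[e0 <= s0],
                                                 collapse = ", "))
  GRanges(chrom, IRanges(start = s0 + 1, end = e0))
}
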