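#' CoverageTrack: per-chromosome binned signal
#'
#' A \code{CoverageTrack} stores genome-wide signal in fixed-width bins
#' that tile each chromosome from coordinate 0, the working currency of
#' ChIP-seq/CUT&RUN density tracks.  Values are either raw per-bin read
#' (or fragment) counts or reads-per-million (RPM) normalized densities;
#' the depth denominator travels with the object in \code{mappedReads}.
#'
#' @slot bins named list, one numeric vector per chromosome; element
#'   \code{i} covers bases \code{[(i-1)*binWidth, i*binWidth)} (0-based).
#'   The final bin may be partial.
#' @slot binWidth integer bin width in bp (default 50).
#' @slot units \code{"raw_counts"} or \code{"RPM"}.
#' @slot mappedReads total aligned reads in the source sample; the RPM
#'   denominator.
#' @slot seqlengths named numeric, chromosome lengths in bp.
#'
#' @seealso [binCoverage()], [rpmNormalize()], [regionSignal()]
#' @export
setClass("CoverageTrack",
  representation(
    bins = "list",
    binWidth = "integer",
    units = "character",
    mappedReads = "numeric",
    seqlengths = "numeric"
  )
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@binWidth) != 1L || is.na(object@binWidth) ||
      object@binWidth <= 0L)
    msg <- c(msg, "binWidth must be a single positive integer")
  if (!object@units %in% c("raw_counts", "RPM"))
    msg <- c(msg, "units must be 'raw_counts' or 'RPM'")
  if (length(object@mappedReads) != 1L || is.na(object@mappedReads) ||
      object@mappedReads < 0)
    msg <- c(msg, "mappedReads must be a single non-negative number")
  if (is.null(names(object@seqlengths)) ||
      any(!nzchar(names(object@seqlengths))))
    msg <- c(msg, "seqlengths must be named by chromosome")
  if (!identical(sort(names(object@bins)),
                 sort(names(object@seqlengths))))
    msg <- c(msg, "bins and seqlengths must cover the same chromosomes")
  if (length(msg) == 0L) {
    for (chrom in names(object@bins)) {
      v <- object@bins[[chrom]]
      nb <- as.integer(ceiling(object@seqlengths[[chrom]] /
                                 object@binWidth))
      if (length(v) != nb) {
        msg <- c(msg, sprintf(
          "chromosome %s: expected %d bins, found %d", chrom, nb,
          length(v)))
      } else if (anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
        msg <- c(msg, sprintf(
          "chromosome %s: bin values must be finite and >= 0", chrom))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param bins named list of per-chromosome numeric bin vectors.
#' @param seqlengths named numeric vector of chromosome lengths (bp).
#' @param binWidth bin width in bp.
#' @param units signal units, \code{"raw_counts"} or \code{"RPM"}.
#' @param mappedReads total mapped reads of the source sample.  Defaults
#'   to the sum of all bin values (each bin-count unit counted once), a
#'   convention the synthetic generator shares.
#' @return A [CoverageTrack-class] object.
#' @examples
#' tr <- CoverageTrack(list(chr1 = c(1, 2, 0, 4)),
#'                     seqlengths = c(chr1 = 200), binWidth = 50L)
#' @export
CoverageTrack <- function(bins, seqlengths, binWidth = 50L,
                          units = "raw_counts",
                          mappedReads = sum(unlist(bins))) {
  new("CoverageTrack", bins = bins[names(seqlengths)],
      binWidth = as.integer(binWidth), units = units,
      mappedReads = as.numeric(mappedReads),
      seqlengths = seqlengths)
}

#' @describeIn CoverageTrack-class bin width in bp.
#' @param x,object a \code{CoverageTrack}.
#' @export
binWidth <- function(x) x@binWidth

#' @describeIn CoverageTrack-class signal units.
#' @export
trackUnits <- function(x) x@units

#' @describeIn CoverageTrack-class RPM denominator (total mapped reads).
#' @export
mappedReads <- function(x) x@mappedReads

#' @describeIn CoverageTrack-class per-chromosome bin vectors; pass
#'   \code{chrom} for a single chromosome.
#' @param chrom optional chromosome name.
#' @export
binValues <- function(x, chrom = NULL) {
  if (is.null(chrom)) return(x@bins)
  if (!chrom %in% names(x@bins))
    stop("unknown chromosome: ", chrom)
  x@bins[[chrom]]
}

#' @export
setMethod("seqlengths", "CoverageTrack", function(x) x@seqlengths)

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf(
    "CoverageTrack: %d chromosome(s), %d-bp bins, units=%s\n",
    length(object@bins), object@binWidth, object@units))
  cat(sprintf("  mappedReads: %.0f; total signal: %.4g\n",
              object@mappedReads, sum(unlist(object@bins))))
  for (chrom in names(object@bins))
    cat(sprintf("  %s: %d bins (%.0f bp)\n", chrom,
                length(object@bins[[chrom]]),
                object@seqlengths[[chrom]]))
})


#' CRCGraph: a TF-to-TF binding graph with inferred CRC membership
#'
#' Directed graph over candidate transcription-factor genes for one
#' condition.  An edge \eqn{i \to j} records that TF \eqn{i}'s binding is
#' enriched at the super-enhancer assigned to TF \eqn{j}.  The core
#' regulatory circuitry (CRC) members are the largest admissible set
#' forming a complete directed subgraph including self-loops — each
#' member binds its own and every other member's super-enhancer.
#'
#' @slot condition condition label.
#' @slot candidates candidate TF gene ids.
#' @slot admissible candidates that are expressed and assigned a
#'   super-enhancer in this condition.
#' @slot edges logical adjacency matrix over candidates; \code{[i, j]}
#'   is \code{TRUE} when TF i binds TF j's super-enhancer.
#' @slot members the inferred CRC member genes.
#' @export
setClass("CRCGraph",
  representation(
    condition = "character",
    candidates = "character",
    admissible = "character",
    edges = "matrix",
    members = "character"
  )
)

setValidity("CRCGraph", function(object) {
  msg <- character()
  n <- length(object@candidates)
  if (!is.logical(object@edges) ||
      !identical(dim(object@edges), c(n, n)))
    msg <- c(msg, "edges must be an n x n logical matrix over candidates")
  if (!all(object@admissible %in% object@candidates))
    msg <- c(msg, "admissible genes must be candidates")
  if (!all(object@members %in% object@admissible))
    msg <- c(msg, "members must be admissible candidates")
  if (length(msg) == 0L && length(object@members)) {
    idx <- match(object@members, object@candidates)
    if (!all(object@edges[idx, idx, drop = FALSE]))
      msg <- c(msg, "members must form a complete subgraph incl. self-loops")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CRCGraph-class inferred CRC member genes.
#' @param x,object a \code{CRCGraph}.
#' @export
crcMembers <- function(x) x@members

#' @describeIn CRCGraph-class candidate TF gene ids.
#' @export
crcCandidates <- function(x) x@candidates

#' @describeIn CRCGraph-class logical TF-by-TF binding adjacency matrix.
#' @export
crcEdges <- function(x) x@edges

#' @describeIn CRCGraph-class condition label.
#' @export
crcCondition <- function(x) x@condition

setMethod("show", "CRCGraph", function(object) {
  cat(sprintf("CRCGraph [%s]: %d candidate TFs, %d admissible\n",
              object@condition, length(object@candidates),
              length(object@admissible)))
  cat(sprintf("  edges: %d of %d possible\n", sum(object@edges),
              length(object@edges)))
  cat("  CRC members:",
      if (length(object@members)) paste(object@members, collapse = ", ")
      else "(none)", "\n")
})
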