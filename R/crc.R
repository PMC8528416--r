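#' Call enrichment of a target over the IgG control in regions
#'
#' A region is enriched for a target when its integrated target signal
#' is at least \code{minFold} times the control signal, with the control
#' floored at \code{signalFloor} so empty control regions cannot inflate
#' the ratio.
#'
#' @param targetTrack RPM [CoverageTrack-class] for the target
#'   (TF CUT&RUN or histone ChIP).
#' @param regions a [GenomicRanges::GRanges].
#' @param controlTrack RPM control (IgG) track.
#' @param minFold minimum target/control fold (default 3).
#' @param signalFloor control floor in integrated RPM units
#'   (default 0.5).
#' @return Logical vector, one call per region.
#' @export
enrichmentCall <- function(targetTrack, regions, controlTrack,
                           minFold = 3, signalFloor = 0.5) {
  if (trackUnits(targetTrack) != "RPM" ||
      trackUnits(controlTrack) != "RPM")
    stop("tracks must be RPM-normalized")
  target <- regionSignal(targetTrack, regions)
  control <- pmax(regionSignal(controlTrack, regions), signalFloor)
  target >= minFold * control
}

#' Build the genome-wide co-occupancy matrix
#'
#' Retains the candidate regions enriched (per [enrichmentCall()]) for
#' at least one non-control target, fills a regions-by-targets signal
#' matrix, and orders rows by descending integrated H3K27ac signal —
#' the layout of a genome-wide co-occupancy heatmap.
#'
#' @param tracks named list of RPM [CoverageTrack-class], one per
#'   target; must include \code{h3k27ac} and \code{control}.
#' @param candidateRegions a [GenomicRanges::GRanges].
#' @param h3k27ac name of the H3K27ac track (default \code{"H3K27ac"}).
#' @param control name of the IgG/control track (default \code{"IgG"});
#'   excluded from the enrichment filter but kept as a matrix column.
#' @param minFold,signalFloor enrichment parameters, see
#'   [enrichmentCall()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{signal} (regions x targets), \code{rowRanges} the retained
#'   regions, and a logical assay \code{enriched}.  Empty (with a
#'   warning) when no region is enriched for any target.
#' @export
buildOccupancyMatrix <- function(tracks, candidateRegions,
                                 h3k27ac = "H3K27ac", control = "IgG",
                                 minFold = 3, signalFloor = 0.5) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (!h3k27ac %in% names(tracks))
    stop("tracks must include the H3K27ac track ('", h3k27ac, "')")
  if (!control %in% names(tracks))
    stop("tracks must include the control track ('", control, "')")
  targets <- names(tracks)
  signal <- vapply(targets, function(t)
    regionSignal(tracks[[t]], candidateRegions),
    numeric(length(candidateRegions)))
  signal <- matrix(signal, nrow = length(candidateRegions),
                   dimnames = list(NULL, targets))
  enriched <- vapply(setdiff(targets, control), function(t)
    enrichmentCall(tracks[[t]], candidateRegions, tracks[[control]],
                   minFold, signalFloor),
    logical(length(candidateRegions)))
  enriched <- matrix(enriched, nrow = length(candidateRegions),
                     dimnames = list(NULL, setdiff(targets, control)))
  keep <- rowSums(enriched) >= 1L
  if (!any(keep))
    warning("no region is enriched for any target; empty matrix")
  ord <- order(signal[keep, h3k27ac], decreasing = TRUE)
  rows <- which(keep)[ord]
  enrichedFull <- cbind(enriched,
                        matrix(FALSE, nrow(enriched), 1L,
                               dimnames = list(NULL, control)))
  enrichedFull <- enrichedFull[, targets, drop = FALSE]
  SummarizedExperiment(
    assays = list(signal = signal[rows, , drop = FALSE],
                  enriched = enrichedFull[rows, , drop = FALSE]),
    rowRanges = granges(candidateRegions)[rows])
}

#' Infer core regulatory circuitry membership for one condition
#'
#' A candidate TF is admissible when its gene is expressed and has at
#' least one assigned super-enhancer in this condition.  A directed
#' edge \eqn{i \to j} is drawn when TF \eqn{i}'s binding is enriched
#' (per [enrichmentCall()]) at any super-enhancer assigned to TF
#' \eqn{j}.  The CRC members are the largest admissible set forming a
#' complete directed subgraph including self-loops — every member binds
#' its own and every other member's super-enhancer — found by exact
#' search over the admissible TFs with self-loops (candidate sets are
#' small, so exact enumeration is cheap and always agrees with a
#' brute-force oracle).  Among equally large sets the tie breaks to the
#' lexicographically first in candidate order.  A relaxed criterion is
#' available via \code{minIn}: members need binding from at least
#' \code{minIn} members (plus their own self-loop) instead of all.
#'
#' @param candidates character vector of candidate TF \code{gene_id}s.
#' @param seCalls [rankAndCut()] output (or any GRanges with
#'   \code{isSuper}) whose \code{assignedGene} column links
#'   super-enhancers to genes; alternatively a named list mapping
#'   \code{gene_id} to a [GenomicRanges::GRanges] of its
#'   super-enhancer(s).
#' @param expressed character vector of expressed \code{gene_id}s.
#' @param tfTracks named list of RPM [CoverageTrack-class], one per
#'   candidate TF (names = \code{gene_id}).
#' @param controlTrack RPM IgG control track.
#' @param condition condition label stored on the result.
#' @param minFold,signalFloor enrichment parameters.
#' @param minIn NULL for the strict complete-subgraph criterion, or an
#'   integer k for the relaxed "bound by >= k members" rule.
#' @return A [CRCGraph-class].
#' @export
inferCRC <- function(candidates, seCalls, expressed, tfTracks,
                     controlTrack, condition = "",
                     minFold = 3, signalFloor = 0.5, minIn = NULL) {
  if (is.list(seCalls) && !is(seCalls, "GRanges")) {
    seByGene <- seCalls
  } else {
    if (is.null(seCalls$assignedGene))
      stop("seCalls must carry an assignedGene column")
    sup <- seCalls[if (!is.null(seCalls$isSuper)) seCalls$isSuper
                   else rep(TRUE, length(seCalls))]
    seByGene <- split(granges(sup), sup$assignedGene)
  }
  admissible <- candidates[candidates %in% expressed &
                             candidates %in% names(seByGene)]
  n <- length(candidates)
  edges <- matrix(FALSE, n, n, dimnames = list(candidates, candidates))
  if (length(admissible) == 0L) {
    warning("no admissible candidate TFs; empty CRC")
    return(new("CRCGraph", condition = condition,
               candidates = candidates, admissible = character(0),
               edges = edges, members = character(0)))
  }
  missing <- setdiff(admissible, names(tfTracks))
  if (length(missing))
    stop("no binding track for candidate(s): ",
         paste(missing, collapse = ", "))
  for (i in admissible) {
    for (j in admissible) {
      hits <- enrichmentCall(tfTracks[[i]], seByGene[[j]],
                             controlTrack, minFold, signalFloor)
      edges[i, j] <- any(hits)  # enriched at any assigned SE
    }
  }
  members <- selectCircuitMembers(edges, admissible, minIn)
  new("CRCGraph", condition = condition, candidates = candidates,
      admissible = admissible, edges = edges, members = members)
}

#' Select CRC members from a TF binding graph
#'
#' Given the directed binding adjacency matrix over candidate TFs,
#' returns the largest admissible set forming a complete directed
#' subgraph including self-loops: every member binds its own and every
#' other member's super-enhancer.  The search is exact — maximum
#' cliques of the mutual-binding graph restricted to self-looped nodes
#' — and ties between equally large sets break to the set that comes
#' first lexicographically in candidate order, so the result is
#' deterministic.  With \code{minIn} set, the relaxed criterion keeps
#' the largest set in which every member has a self-loop and is bound
#' by at least \code{minIn} members (computed by iterative pruning).
#'
#' @param edges n x n logical matrix with candidate names as dimnames;
#'   \code{edges[i, j]} means TF i binds TF j's super-enhancer.
#' @param admissible candidate names eligible for membership (default
#'   all).
#' @param minIn NULL for the strict complete-subgraph rule, or the
#'   minimum number of in-binding members for the relaxed rule.
#' @return Character vector of members, in candidate order.
#' @export
selectCircuitMembers <- function(edges, admissible = rownames(edges),
                                 minIn = NULL) {
  candidates <- rownames(edges)
  stopifnot(is.logical(edges), !is.null(candidates),
            identical(rownames(edges), colnames(edges)))
  idx <- match(admissible, candidates)
  stopifnot(!anyNA(idx))
  looped <- idx[edges[cbind(idx, idx)]]
  if (!length(looped)) return(character(0))
  if (!is.null(minIn)) {
    # iteratively drop nodes with in-degree (from current set) < minIn
    cur <- looped
    repeat {
      if (!length(cur)) break
      indeg <- colSums(edges[cur, cur, drop = FALSE])
      drop <- cur[indeg < minIn]
      if (!length(drop)) break
      cur <- setdiff(cur, drop)
    }
    return(candidates[base::sort(cur)])
  }
  mutual <- edges[looped, looped, drop = FALSE] &
    t(edges[looped, looped, drop = FALSE])
  diag(mutual) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(mutual, mode = "undirected")
  cl <- igraph::largest_cliques(g)
  sets <- lapply(cl, function(s) base::sort(looped[as.integer(s)]))
  # deterministic tie-break: lexicographically first in candidate order
  key <- vapply(sets, function(s)
    paste(sprintf("%06d", s), collapse = ","), "")
  candidates[sets[[order(key)[1L]]]]
}

#' Compare CRC membership between two conditions
#'
#' @param graphA,graphB [CRCGraph-class] objects over the same candidate
#'   universe.
#' @return list with \code{shared}, \code{lost} (members of A only) and
#'   \code{gained} (members of B only).
#' @export
compareCRCs <- function(graphA, graphB) {
  if (!setequal(crcCandidates(graphA), crcCandidates(graphB)))
    stop("CRC graphs must share one candidate universe")
  a <- crcMembers(graphA); b <- crcMembers(graphB)
  list(shared = base::sort(intersect(a, b)),
       lost = base::sort(setdiff(a, b)),
       gained = base::sort(setdiff(b, a)))
}

#' Write a CRC report as JSON
#'
#' @param graphs list of [CRCGraph-class] (typically one per
#'   condition).
#' @param path output path.
#' @param delta optional [compareCRCs()] result to include.
#' @return \code{path}, invisibly.
#' @export
writeCrcReport <- function(graphs, path, delta = NULL) {
  rep <- lapply(graphs, function(g) {
    ed <- which(crcEdges(g), arr.ind = TRUE)
    list(condition = crcCondition(g),
         candidates = crcCandidates(g),
         admissible = g@admissible,
         edges = data.frame(
           from = crcCandidates(g)[ed[, 1L]],
           to = crcCandidates(g)[ed[, 2L]]),
         members = crcMembers(g))
  })
  names(rep) <- vapply(graphs, crcCondition, "")
  out <- list(conditions = rep)
  if (!is.null(delta)) out$delta <- delta
  write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
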