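# Independent brute-force oracles.  Each works per base (or per
# subset) and never calls the interval machinery it is used to check.

# random intervals on one small chromosome, as a 0-based (start0, end0)
# data.frame
randIntervals0 <- function(n, chromLen = 5000, maxWidth = 300,
                           chrom = "chr1") {
  s0 <- sample.int(chromLen - 2L, n, replace = TRUE) - 1L
  w <- sample.int(maxWidth, n, replace = TRUE)
  data.frame(chrom = chrom, start0 = s0,
             end0 = pmin(s0 + w, chromLen))
}

toGR <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start0 + 1,
                                          end = df$end0))
}

# per-base boolean mask union -> maximal runs, as 0-based intervals
oracleMaskUnion <- function(df, chromLen) {
  mask <- logical(chromLen)
  for (i in seq_len(nrow(df)))
    mask[(df$start0[i] + 1):df$end0[i]] <- TRUE
  r <- rle(mask)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  data.frame(start0 = s[r$values], end0 = e[r$values])
}

# iterated pairwise merge to fixpoint under "gap <= s"
oracleStitch <- function(df, s) {
  iv <- df[order(df$start0, df$end0), c("start0", "end0")]
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(iv)) {
      if (iv$start0[i + 1L] - iv$end0[i] <= s) {
        iv$end0[i] <- max(iv$end0[i], iv$end0[i + 1L])
        iv <- iv[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  rownames(iv) <- NULL
  iv
}

# containment scan: drop intervals fully inside any [tss0-t, tss0+t)
oracleTssExclude <- function(df, tss0, t) {
  keep <- vapply(seq_len(nrow(df)), function(i) {
    !any(df$start0[i] >= tss0 - t & df$end0[i] <= tss0 + t)
  }, TRUE)
  df[keep, , drop = FALSE]
}

# exhaustive nearest-TSS scan with leftmost tie-break
oracleAssign <- function(center0, geneTss0, geneIds) {
  d <- abs(geneTss0 - center0)
  cand <- which(d == min(d))
  geneIds[cand[which.min(geneTss0[cand])]]
}

# sort-and-slice expressed set: drop the bottom third, boundary ties in
oracleExpressed <- function(cov) {
  thr <- sort(cov)[floor(length(cov) / 3) + 1]
  which(cov >= thr)
}

# per-base accumulation of bin-fraction-weighted signal
oracleRegionSignal <- function(bins, binWidth, start0, end0) {
  total <- 0
  for (b in seq(start0, end0 - 1)) {
    total <- total + bins[b %/% binWidth + 1] / binWidth
  }
  total
}

# per-interval, per-bin >=1 bp overlap counting
oracleBinCoverage <- function(df, binWidth, chromLen) {
  nb <- ceiling(chromLen / binWidth)
  v <- numeric(nb)
  for (b in seq_len(nb)) {
    b0 <- (b - 1) * binWidth
    b1 <- min(b0 + binWidth, chromLen)
    v[b] <- sum(df$start0 < b1 & df$end0 > b0)
  }
  v
}

# exhaustive maximum complete-subgraph-with-self-loops over all 2^n
# subsets, same lexicographic-in-candidate-order tie-break
oracleCircuitMembers <- function(edges) {
  n <- nrow(edges)
  best <- integer(0)
  for (code in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    if (length(members) <= length(best)) next
    if (all(edges[members, members, drop = FALSE]))
      best <- members
  }
  if (length(best) == 0L) return(character(0))
  # revisit ties at the best size in lexicographic candidate order
  size <- length(best)
  cands <- list()
  for (code in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    if (length(members) != size) next
    if (all(edges[members, members, drop = FALSE]))
      cands[[length(cands) + 1L]] <- members
  }
  key <- vapply(cands, function(s)
    paste(sprintf("%06d", s), collapse = ","), "")
  rownames(edges)[cands[[order(key)[1L]]]]
}

# one-bin-per-region scored track for rank/cutoff tests: region i is
# bin 2i (even bins), value sig[i]
signalTrackFromValues <- function(sig, binWidth = 50) {
  nb <- 2 * length(sig) + 2
  bins <- numeric(nb)
  bins[2 * seq_along(sig)] <- sig
  L <- nb * binWidth
  track <- CoverageTrack(list(chr1 = bins), c(chr1 = L),
                         binWidth = binWidth, units = "RPM",
                         mappedReads = 1e6)
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = (2 * seq_along(sig) - 1) * binWidth + 1,
    end = 2 * seq_along(sig) * binWidth))
  list(track = track, regions = regions)
}

# two-condition region fixture: nChanged gained, nChanged lost (at
# `ratio`), nStable unchanged regions with Poisson bin noise
diffFixture <- function(seed = 151, ratio = 4, nChanged = 10,
                        nStable = 200, noise = TRUE) {
  set.seed(seed)
  n <- 2 * nChanged + nStable
  bw <- 50
  # regions of 10 bins each, separated by 10 near-empty bins
  nb <- n * 20 + 10
  startBin <- (seq_len(n) - 1) * 20 + 5
  lamA <- rep(0.01, nb); lamB <- rep(0.01, nb)
  base <- 40
  status <- c(rep("gained", nChanged), rep("lost", nChanged),
              rep("stable", nStable))
  for (i in seq_len(n)) {
    bins <- startBin[i] + 1:10
    lamA[bins] <- if (status[i] == "gained") base / ratio else base
    lamB[bins] <- if (status[i] == "lost") base / ratio else base
  }
  mk <- function(lam) CoverageTrack(
    list(chr1 = if (noise) rpois(nb, lam) else lam),
    c(chr1 = nb * bw), binWidth = bw, mappedReads = 1e6)
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(startBin * bw + 1, (startBin + 10) * bw))
  list(trA = mk(lamA), trB = mk(lamB), regions = regions,
       status = status)
}
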