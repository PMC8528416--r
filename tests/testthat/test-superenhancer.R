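test_that("TSS exclusion removes only fully contained peaks", {
  ann <- data.frame(gene_id = "A", gene_name = "A", chrom = "chr1",
                    tss = 1001, strand = "+")  # 0-based TSS 1000
  # fully inside [0-based 0, 2000)
  inside <- GRanges("chr1", IRanges(991, 1010))
  expect_length(tssExclude(inside, ann, t = 1000), 0)
  # straddling the window edge is retained
  straddle <- GRanges("chr1", IRanges(1900, 2100))
  expect_length(tssExclude(straddle, ann, t = 1000), 1)
  # t = 0 is the identity
  expect_length(tssExclude(inside, ann, t = 0), 1)
})

test_that("TSS exclusion matches the brute-force containment oracle", {
  set.seed(81)
  for (rep in 1:4) {
    df <- randIntervals0(100, chromLen = 5000, maxWidth = 500)
    tss0 <- sort(sample.int(4900, 10))
    ann <- data.frame(gene_id = paste0("G", 1:10),
                      gene_name = paste0("G", 1:10), chrom = "chr1",
                      tss = tss0 + 1, strand = "+")
    kept <- tssExclude(toGR(df), ann, t = 300)
    want <- oracleTssExclude(df, tss0, 300)
    expect_equal(start(kept) - 1, want$start0)
    expect_equal(end(kept), want$end0)
  }
})

test_that("stitching merges within the gap and matches the fixpoint
           oracle", {
  a <- GRanges("chr1", IRanges(1, 1000))       # [0,1000)
  b <- GRanges("chr1", IRanges(5001, 6000))    # [5000,6000), gap 4000
  st <- stitchPeaks(c(a, b), s = 12500)
  expect_length(st, 1)
  expect_equal(c(start(st), end(st)), c(1, 6000))

  far <- GRanges("chr1", IRanges(20001, 21000))  # gap 19000
  expect_length(stitchPeaks(c(a, far), s = 12500), 2)

  set.seed(91)
  for (rep in 1:4) {
    df <- randIntervals0(300, chromLen = 50000, maxWidth = 400)
    s <- sample(c(0, 100, 1000), 1)
    st <- stitchPeaks(toGR(df), s = s)
    want <- oracleStitch(df, s)
    expect_equal(start(st) - 1, want$start0)
    expect_equal(end(st), want$end0)
    # idempotent, disjoint, gaps > s
    expect_equal(granges(stitchPeaks(st, s = s)), granges(st))
    if (length(st) > 1)
      expect_true(all(start(st)[-1] - head(end(st), -1) - 1 > s))
  }
})

test_that("the tangent cutoff finds the closed-form point of y = x^4", {
  n <- 1000
  sig <- ((seq_len(n) - 1) / (n - 1))^4
  cut <- hockeyStickCutoff(sig)
  expect_lt(abs(cut$x - (1 / 4)^(1 / 3)), 1 / (n - 1) + 1e-12)
})

test_that("ranking is scale-invariant and flags the planted outliers", {
  set.seed(101)
  # 500 typical enhancers with bounded spread, 20 planted at 10x
  sig <- c(runif(500, 8, 12), runif(20, 95, 105))
  st <- signalTrackFromValues(sig)
  calls <- rankAndCut(st$regions, st$track)
  expect_equal(base::sort(calls$rank), seq_along(sig))
  planted <- which(sig > 50)
  ord <- GenomicRanges::findOverlaps(st$regions, calls,
                                     select = "first")
  expect_setequal(which(calls$isSuper[ord]), planted)

  # multiplying all signals by a positive constant changes nothing
  st2 <- signalTrackFromValues(sig * 37.5)
  calls2 <- rankAndCut(st2$regions, st2$track)
  expect_equal(calls2$isSuper[GenomicRanges::findOverlaps(
    st2$regions, calls2, select = "first")],
    calls$isSuper[ord])
})

test_that("degenerate signal curves call zero super-enhancers", {
  st <- signalTrackFromValues(rep(5, 40))
  expect_warning(calls <- rankAndCut(st$regions, st$track),
                 "degenerate")
  expect_false(any(calls$isSuper))
})

test_that("super calls form an upper set in signal with an interior
           cutoff on convex curves", {
  set.seed(111)
  for (rep in 1:50) {
    n <- sample(20:80, 1)
    sig <- abs(rnorm(n, 5, 2))^sample(2:4, 1)
    cut <- hockeyStickCutoff(sig)
    super <- sig > cut$cutoff
    # everything above any called region is also called
    if (any(super))
      expect_true(all(sig[sig > min(sig[super])] > cut$cutoff))
    # the cutoff is an attained signal value strictly below the max
    expect_true(cut$cutoff %in% sig)
    expect_lt(cut$cutoff, max(sig))
  }
})

test_that("control subtraction floors region signal at zero", {
  sig <- c(1, 2, 3, 4, 50, 60)
  st <- signalTrackFromValues(sig)
  ctrl <- signalTrackFromValues(rep(10, length(sig)))
  calls <- rankAndCut(st$regions, st$track, controlTrack = ctrl$track)
  expect_true(all(calls$signal >= 0))
  expect_equal(max(calls$signal), 50)  # 60 - 10
})

test_that("the ROSE-like table writes ranks, signal and the flag", {
  sig <- c(abs(rnorm(50, 10, 1)), 100, 120)
  st <- signalTrackFromValues(sig)
  calls <- rankAndCut(st$regions, st$track)
  path <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeSeTable(calls, path, bedPath = bed)
  df <- read.delim(path)
  expect_equal(nrow(df), length(sig))
  expect_equal(df$rank, seq_along(sig))
  expect_equal(sum(df$isSuper), length(readLines(bed)))
})
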