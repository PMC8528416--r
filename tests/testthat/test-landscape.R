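promTrack <- function(covPerGene, tss, chromLen = 1e5) {
  # one flat 20-bin promoter block per gene carrying cov/20 per bin
  bins <- numeric(chromLen / 50)
  for (i in seq_along(tss)) {
    f <- (tss[i] - 1 - 500) %/% 50 + 1
    bins[f:(f + 19)] <- covPerGene[i] / 20
  }
  CoverageTrack(list(chr1 = bins), c(chr1 = chromLen), binWidth = 50,
                units = "RPM", mappedReads = 1e6)
}

annFor <- function(tss) {
  data.frame(gene_id = sprintf("G%02d", seq_along(tss)),
             gene_name = sprintf("G%02d", seq_along(tss)),
             chrom = "chr1", tss = tss, strand = "+")
}

test_that("expressed calls keep the top two-thirds with inclusive ties", {
  tss <- c(10001, 30001, 50001)
  ann <- annFor(tss)
  pa <- promoterActivity(ann, promTrack(c(0, 5, 10), tss))
  expect_equal(pa$is_expressed, c(FALSE, TRUE, TRUE))
  expect_equal(pa$promoter_coverage, c(0, 5, 10))

  # all-equal coverage: boundary ties are all expressed
  pa <- promoterActivity(ann, promTrack(c(4, 4, 4), tss))
  expect_true(all(pa$is_expressed))

  expect_error(promoterActivity(ann[0, ], promTrack(c(1), 10001)),
               "empty")
})

test_that("expressed set matches the sort-and-slice oracle", {
  set.seed(121)
  tss <- seq(2001, by = 2000, length.out = 99)
  ann <- annFor(tss)
  for (rep in 1:3) {
    cov <- round(runif(99, 0, 50))
    pa <- promoterActivity(ann, promTrack(cov, tss, chromLen = 3e5))
    expect_equal(which(pa$is_expressed), oracleExpressed(cov))
  }
})

test_that("enhancers go to the nearest expressed TSS, leftmost on ties", {
  ann <- annFor(c(10001, 20001))
  enh <- GRanges("chr1", IRanges(12001, 13000))
  expect_equal(assignEnhancer(enh, ann, "G01"), "G01")
  # center 0-based 15000 is equidistant from TSS0 10000 and 20000
  tie <- GRanges("chr1", IRanges(14501, 15500))
  expect_equal(assignEnhancer(tie, ann, c("G01", "G02")), "G01")
  # no expressed gene on the chromosome
  expect_true(is.na(assignEnhancer(enh, ann, character(0))))
})

test_that("assignment matches the exhaustive distance-scan oracle", {
  set.seed(131)
  tss <- sort(sample.int(99000, 20)) + 1
  ann <- annFor(tss)
  expressed <- ann$gene_id[sample(c(TRUE, FALSE), 20,
                                  replace = TRUE, prob = c(.7, .3))]
  df <- randIntervals0(100, chromLen = 99000, maxWidth = 2000)
  got <- assignEnhancer(toGR(df), ann, expressed)
  g <- ann[ann$gene_id %in% expressed, ]
  want <- vapply(seq_len(nrow(df)), function(i)
    oracleAssign(floor((df$start0[i] + df$end0[i]) / 2),
                 g$tss - 1, g$gene_id), "")
  expect_equal(got, want)
})

test_that("the SE union collapse is idempotent, order-invariant and
           matches the mask oracle", {
  set.seed(141)
  sets <- lapply(1:4, function(i) toGR(randIntervals0(40)))
  u <- collapseSeUnion(sets)
  want <- oracleMaskUnion(
    do.call(rbind, lapply(sets, function(g)
      data.frame(start0 = start(g) - 1, end0 = end(g)))), 5000)
  expect_equal(start(u) - 1, want$start0)
  expect_equal(end(u), want$end0)
  expect_equal(collapseSeUnion(rev(sets)), u)
  expect_equal(collapseSeUnion(list(u, u)), u)
  disjointSets <- list(GRanges("chr1", IRanges(1, 10)),
                       GRanges("chr1", IRanges(100, 110)))
  expect_length(collapseSeUnion(disjointSets), 2)
})

test_that("equal conditions are stable and empty regions are not NaN", {
  fx <- diffFixture(noise = FALSE)
  d <- differentialCoverage(fx$regions,
                            list(a = fx$trA, b = fx$trA),
                            c(a = "A", b = "B"),
                            conditionOrder = c("A", "B"))
  expect_true(all(d$status == "stable"))
  expect_true(all(d$log2FC == 0))

  emptyRegion <- GRanges("chr1", IRanges(1, 200))
  d0 <- differentialCoverage(emptyRegion,
                             list(a = fx$trA, b = fx$trB),
                             c(a = "A", b = "B"),
                             conditionOrder = c("A", "B"))
  expect_false(is.nan(d0$log2FC))
})

test_that("planted 4x gains and losses classify correctly at default
           noise", {
  fx <- diffFixture()
  d <- differentialCoverage(fx$regions,
                            list(a = fx$trA, b = fx$trB),
                            c(a = "A", b = "B"),
                            conditionOrder = c("A", "B"))
  expect_equal(d$status, fx$status)
})

test_that("swapping condition labels maps gained and lost exactly", {
  fx <- diffFixture(seed = 161)
  fwd <- differentialCoverage(fx$regions,
                              list(a = fx$trA, b = fx$trB),
                              c(a = "A", b = "B"),
                              conditionOrder = c("A", "B"))
  rev <- differentialCoverage(fx$regions,
                              list(a = fx$trA, b = fx$trB),
                              c(a = "A", b = "B"),
                              conditionOrder = c("B", "A"))
  expect_equal(rev$log2FC, -fwd$log2FC)
  expect_equal(rev$status == "gained", fwd$status == "lost")
  expect_equal(rev$status == "lost", fwd$status == "gained")
})

test_that("differential analysis rejects bad designs", {
  fx <- diffFixture()
  expect_error(differentialCoverage(fx$regions, list(a = fx$trA),
                                    c(a = "A")))
  expect_error(differentialCoverage(
    fx$regions, list(a = fx$trA, b = fx$trB), c(a = "A", b = "B"),
    foldThreshold = 1), "foldThreshold")
})
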