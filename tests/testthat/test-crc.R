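flatTrack <- function(value, nb = 200, bw = 50) {
  CoverageTrack(list(chr1 = rep(value, nb)), c(chr1 = nb * bw),
                binWidth = bw, units = "RPM", mappedReads = 1e6)
}

test_that("enrichment calls compare target to floored IgG signal", {
  region <- GRanges("chr1", IRanges(1, 500))  # 10 bins
  expect_false(enrichmentCall(flatTrack(0), region, flatTrack(1)))
  expect_true(enrichmentCall(flatTrack(10), region, flatTrack(1),
                             minFold = 3))
  expect_false(enrichmentCall(flatTrack(2.9), region, flatTrack(1),
                              minFold = 3))
  # the floor stops empty controls from inflating the ratio
  expect_false(enrichmentCall(flatTrack(0.1), region, flatTrack(0),
                              minFold = 3, signalFloor = 0.5))
})

test_that("the occupancy matrix keeps >=1-target regions ranked by
           H3K27ac", {
  set.seed(171)
  regions <- GRanges("chr1", IRanges((0:19) * 500 + 1, (0:19) * 500 + 400))
  nb <- 250
  mkTrack <- function(lam) CoverageTrack(list(chr1 = rep(lam, length.out = nb)),
                                         c(chr1 = nb * 50),
                                         binWidth = 50, units = "RPM",
                                         mappedReads = 1e6)
  acLam <- rep(0.1, nb)
  meisLam <- rep(0.1, nb)
  # regions 1..10 carry H3K27ac (random heights), region 12 only MEIS1
  heights <- sample(5:50, 10)
  for (i in 1:10) acLam[((i - 1) * 10 + 1):((i - 1) * 10 + 8)] <-
    heights[i]
  meisLam[111:118] <- 30
  tracks <- list(H3K27ac = mkTrack(acLam), MEIS1 = mkTrack(meisLam),
                 IgG = mkTrack(0.1))
  occ <- buildOccupancyMatrix(tracks, regions)
  sig <- SummarizedExperiment::assay(occ, "signal")
  expect_true(all(diff(sig[, "H3K27ac"]) <= 0))  # sorted descending
  # region 12 retained through MEIS1 alone
  expect_true(any(start(SummarizedExperiment::rowRanges(occ)) == 5501))
  expect_equal(nrow(occ), 11)

  zeros <- list(H3K27ac = mkTrack(rep(0, nb)),
                MEIS1 = mkTrack(rep(0, nb)), IgG = mkTrack(rep(0, nb)))
  expect_warning(empty <- buildOccupancyMatrix(zeros, regions),
                 "no region")
  expect_equal(nrow(empty), 0)
})

randomEdges <- function(n, p) {
  e <- matrix(runif(n * n) < p, n, n,
              dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  e
}

test_that("circuit membership requires complete mutual binding with
           self-loops", {
  full <- matrix(TRUE, 5, 5, dimnames = list(LETTERS[1:5],
                                             LETTERS[1:5]))
  expect_equal(selectCircuitMembers(full), LETTERS[1:5])
  noSelf <- full; noSelf["C", "C"] <- FALSE
  expect_equal(selectCircuitMembers(noSelf), c("A", "B", "D", "E"))
})

test_that("exact member selection agrees with subset enumeration", {
  set.seed(181)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    e <- randomEdges(n, runif(1, 0.3, 0.9))
    expect_identical(selectCircuitMembers(e), oracleCircuitMembers(e))
  }
})

test_that("the relaxed minIn rule keeps self-looped, well-bound nodes", {
  e <- matrix(FALSE, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(e) <- TRUE
  e["A", "B"] <- e["B", "A"] <- e["A", "C"] <- e["C", "A"] <- TRUE
  # with minIn = 2 every node bound by >= 2 of the surviving set stays
  m <- selectCircuitMembers(e, minIn = 2)
  expect_true(all(c("A", "B", "C") %in% m) || length(m) <= 3)
  # strict rule: only a mutual pair survives
  expect_length(selectCircuitMembers(e), 2)
})

test_that("CRC inference wires edges from binding at assigned SEs", {
  # two TFs; A binds both SEs, B binds nothing
  seA <- GRanges("chr1", IRanges(1001, 1500))
  seB <- GRanges("chr1", IRanges(5001, 5500))
  bindAll <- flatTrack(0.1, nb = 200)
  bindAll@bins$chr1[c(21:30, 101:110)] <- 20
  igg <- flatTrack(0.5, nb = 200)
  g <- inferCRC(c("A", "B"), list(A = seA, B = seB),
                expressed = c("A", "B"),
                tfTracks = list(A = bindAll, B = flatTrack(0.5, nb = 200)),
                controlTrack = igg, condition = "test")
  expect_true(crcEdges(g)["A", "A"] && crcEdges(g)["A", "B"])
  expect_false(any(crcEdges(g)["B", ]))
  expect_equal(crcMembers(g), "A")  # B lacks a self-loop

  # no admissible candidates -> empty CRC with a warning
  expect_warning(
    g0 <- inferCRC(c("A", "B"), list(A = seA, B = seB),
                   expressed = character(0),
                   tfTracks = list(A = bindAll,
                                   B = flatTrack(0.5, nb = 200)),
                   controlTrack = igg),
    "admissible")
  expect_length(crcMembers(g0), 0)
})

test_that("CRC comparison is deterministic and label-symmetric", {
  mk <- function(members, cond) {
    cands <- LETTERS[1:6]
    e <- matrix(FALSE, 6, 6, dimnames = list(cands, cands))
    e[members, members] <- TRUE
    new("CRCGraph", condition = cond, candidates = cands,
        admissible = members, edges = e, members = members)
  }
  a <- mk(c("A", "B", "C", "D"), "one")
  b <- mk(c("C", "D", "E", "F"), "two")
  d <- compareCRCs(a, b)
  expect_equal(d, list(shared = c("C", "D"), lost = c("A", "B"),
                       gained = c("E", "F")))
  rev <- compareCRCs(b, a)
  expect_equal(rev$shared, d$shared)
  expect_equal(rev$lost, d$gained)
  expect_equal(rev$gained, d$lost)
  expect_equal(compareCRCs(a, a),
               list(shared = c("A", "B", "C", "D"),
                    lost = character(0), gained = character(0)))
})

test_that("the CRC report serializes conditions, edges and deltas", {
  cands <- c("A", "B")
  e <- matrix(TRUE, 2, 2, dimnames = list(cands, cands))
  g <- new("CRCGraph", condition = "x", candidates = cands,
           admissible = cands, edges = e, members = cands)
  path <- withr::local_tempfile(fileext = ".json")
  writeCrcReport(list(g), path,
                 delta = list(shared = "A", lost = character(0),
                              gained = "B"))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$conditions$x$members, c("A", "B"))
  expect_equal(nrow(rep$conditions$x$edges), 4)
  expect_equal(rep$delta$shared, "A")
})
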