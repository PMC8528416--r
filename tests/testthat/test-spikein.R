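spikedCounts <- function(seed = 1, nGenes = 50, nSpikes = 10,
                         depths = c(1, 1, 1, 1)) {
  set.seed(seed)
  base <- rpois(nGenes, 500) + 50
  conc <- round(2 ^ seq(5, 11, length.out = nSpikes))
  counts <- vapply(depths, function(d)
    c(rpois(nGenes, base * d), rpois(nSpikes, conc * d)),
    numeric(nGenes + nSpikes))
  rownames(counts) <- c(sprintf("G%03d", seq_len(nGenes)),
                        sprintf("ERCC-%04d", seq_len(nSpikes)))
  colnames(counts) <- paste0("s", seq_along(depths))
  counts
}

test_that("identical samples get unit factors; scaling a sample scales
           its factor", {
  counts <- spikedCounts()
  counts[] <- rep(counts[, 1], 4)  # make samples identical
  f <- spikeinSizeFactors(counts)
  expect_equal(unname(f), rep(1, 4))

  doubled <- counts
  doubled[, 2] <- counts[, 2] * 2
  f2 <- spikeinSizeFactors(doubled)
  # factors are relative: the doubled sample's factor is 2x the others'
  expect_equal(f2[["s2"]] / f2[["s1"]], 2)
  # normalized counts are invariant up to one global scalar (the
  # geometric-mean reference rescales by 2^(1/S))
  norm1 <- sweep(counts, 2, f, "/")
  norm2 <- sweep(doubled, 2, f2, "/")
  ratio <- norm2 / norm1
  expect_equal(ratio / ratio[1, 1],
               matrix(1, nrow(counts), 4,
                      dimnames = dimnames(norm1)))
  expect_equal(ratio[1, 1], 2^(1 / 4))
})

test_that("size factors reject tables without usable spike-ins", {
  counts <- spikedCounts()
  noSpike <- counts[!startsWith(rownames(counts), "ERCC-"), ]
  expect_error(spikeinSizeFactors(noSpike), "spike-in")
  dead <- counts
  dead[startsWith(rownames(dead), "ERCC-"), 1] <- 0
  expect_error(spikeinSizeFactors(dead), "nonzero")
})

test_that("spike-in factors agree with the DESeq2 control-gene
           estimator", {
  skip_if_not_installed("DESeq2")
  counts <- spikedCounts(seed = 3, depths = c(1, 1.4, 0.7, 1.1))
  ours <- spikeinSizeFactors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(
    counts, controlGenes = startsWith(rownames(counts), "ERCC-"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("TPM is length-weighted, sums to 1e6 and excludes spike-ins", {
  counts <- matrix(c(100), 1, dimnames = list("A", "s1"))
  expect_equal(tpm(counts, c(A = 1000))[1, 1], 1e6)

  counts <- matrix(c(100, 100), 2, dimnames = list(c("A", "B"), "s1"))
  t2 <- tpm(counts, c(A = 1000, B = 2000))
  expect_equal(unname(t2[, 1]), c(2e6 / 3, 1e6 / 3))

  counts <- spikedCounts(seed = 5)
  lengths <- setNames(rep(c(1500, 800), length.out = nrow(counts)),
                      rownames(counts))
  tt <- tpm(counts, lengths)
  expect_false(any(startsWith(rownames(tt), "ERCC-")))
  expect_equal(unname(colSums(tt)), rep(1e6, 4), tolerance = 1e-9)
})

test_that("fold changes are zero for identical conditions and the TPM
           filter is strict", {
  counts <- spikedCounts(seed = 7)
  counts[, 3:4] <- counts[, 1:2]
  conds <- c(s1 = "C", s2 = "C", s3 = "T", s4 = "T")
  lengths <- setNames(rep(1000, nrow(counts)), rownames(counts))
  fc <- foldChanges(counts, conds, lengths,
                    conditionOrder = c("C", "T"))
  expect_true(all(fc$log2_fold_change == 0))

  # a gene engineered to sit exactly at base-mean TPM 10 fails `> 10`
  # (equal lengths: TPM share = count share; 1 of 100000 -> TPM 10)
  c3 <- cbind(s1 = c(1, 99999, 100), s2 = c(1, 99999, 100))
  rownames(c3) <- c("A", "B", "ERCC-0001")
  fc3 <- foldChanges(c3, c(s1 = "C", s2 = "T"),
                     c(A = 1000, B = 1000, `ERCC-0001` = 1000),
                     conditionOrder = c("C", "T"))
  expect_equal(fc3$base_mean_tpm[fc3$gene_id == "A"], 10)
  expect_false(fc3$passes_filter[fc3$gene_id == "A"])
})

test_that("planted 4x down-regulation is recovered at median -2", {
  medians <- vapply(1:20, function(seed) {
    set.seed(seed)
    nGenes <- 1000; nSpikes <- 20
    base <- rpois(nGenes, 400) + 100
    eff <- rep(1, nGenes); eff[1:100] <- 0.25
    conc <- round(2 ^ seq(5, 11, length.out = nSpikes))
    counts <- cbind(
      c1 = c(rpois(nGenes, base), rpois(nSpikes, conc)),
      c2 = c(rpois(nGenes, base), rpois(nSpikes, conc)),
      t1 = c(rpois(nGenes, base * eff), rpois(nSpikes, conc)),
      t2 = c(rpois(nGenes, base * eff), rpois(nSpikes, conc)))
    rownames(counts) <- c(sprintf("G%04d", seq_len(nGenes)),
                          sprintf("ERCC-%04d", seq_len(nSpikes)))
    lengths <- setNames(rep(1000, nrow(counts)), rownames(counts))
    fc <- foldChanges(counts,
                      c(c1 = "C", c2 = "C", t1 = "T", t2 = "T"),
                      lengths, conditionOrder = c("C", "T"))
    median(fc$log2_fold_change[fc$gene_id %in%
                                 sprintf("G%04d", 1:100)])
  }, 0)
  expect_lt(abs(median(medians) + 2), 0.15)
  expect_true(all(abs(medians + 2) < 0.3))
})
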