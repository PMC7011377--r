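snpTable <- function(df) {
  n <- nrow(df)
  base <- data.frame(chrom = rep("A01", n), pos = seq_len(n) * 1000L,
                     ref = rep("A", n), alt = rep("G", n))
  SnpCountTable(cbind(base, df))
}

test_that("depth screen keeps SNPs covered in both pools", {
  x <- snpTable(data.frame(ref_G = c(5, 3, 0), alt_G = c(5, 0, 2),
                           ref_Y = c(5, 25, 50), alt_Y = c(5, 25, 0)))
  scr <- screenDifferential(x)
  expect_equal(nrow(snpCounts(scr)), 1L)
  expect_equal(snpCounts(scr)$ref_G, 5L)
  empty <- snpTable(data.frame(ref_G = integer(), alt_G = integer(),
                               ref_Y = integer(), alt_Y = integer()))
  expect_equal(nrow(snpCounts(screenDifferential(empty))), 0L)
})

test_that("ED matches the two-coordinate closed form and brute oracle", {
  x <- snpTable(data.frame(ref_G = c(10, 20, 8), alt_G = c(10, 0, 7),
                           ref_Y = c(15, 0, 0), alt_Y = c(15, 20, 30)))
  ed <- edStatistic(x)
  ## fG = fY = 0.5 -> 0;  fG = 0, fY = 1 -> sqrt(2)
  expect_equal(ed$ed[1], 0)
  expect_equal(ed$ed5[1], 0)
  expect_equal(ed$ed[2], sqrt(2))
  expect_equal(ed$ed5[2], 2^2.5)
  ## expected causal-locus frequencies: fG = 7/15, fY = 1
  y <- snpTable(data.frame(ref_G = 8, alt_G = 7, ref_Y = 0, alt_Y = 30))
  edy <- edStatistic(y)
  expect_equal(edy$ed, bruteED(7 / 15, 1))
  expect_equal(edy$ed, sqrt(2) * 8 / 15, tolerance = 1e-12)
  expect_equal(edy$ed5, (sqrt(2) * 8 / 15)^5, tolerance = 1e-12)
  ## random tables agree with the brute-force formula
  set.seed(6)
  rg <- rbinom(50, 40, 0.5); ag <- 40 - rg
  ry <- rbinom(50, 40, 0.3); ay <- 40 - ry
  r <- edStatistic(snpTable(data.frame(ref_G = rg, alt_G = ag,
                                       ref_Y = ry, alt_Y = ay)))
  expect_equal(r$ed, bruteED(ag / 40, ay / 40))
  ## symmetric in the pools
  swapped <- edStatistic(snpTable(data.frame(ref_G = ry, alt_G = ay,
                                             ref_Y = rg, alt_Y = ag)))
  expect_equal(r$ed, swapped$ed)
  ## zero depth errors
  expect_error(edStatistic(snpTable(data.frame(ref_G = 0, alt_G = 0,
                                               ref_Y = 5, alt_Y = 5))),
               "zero depth")
})

test_that("top-quantile threshold flags ceil(f*n) loci, ties included", {
  set.seed(7)
  v <- sample(seq_len(1000)) / 1000
  sig <- significanceThreshold(v, 0.01)
  expect_equal(sig$nFlagged, 10L)
  expect_equal(sig$flagged, bruteTopFlags(v, 0.01))
  ## all equal: tie rule includes everything
  expect_equal(significanceThreshold(rep(0.5, 20), 0.05)$nFlagged, 20L)
  ## a single locus is flagged
  expect_equal(significanceThreshold(3, 0.01)$nFlagged, 1L)
  ## random vectors match the sort-based oracle
  for (s in 1:5) {
    set.seed(s)
    v <- round(rexp(200), 2)  # with ties
    expect_equal(significanceThreshold(v, 0.03)$flagged,
                 bruteTopFlags(v, 0.03))
  }
  expect_error(significanceThreshold(v, 0), "topFraction")
})

test_that("region calling reproduces printed-geometry arithmetic", {
  ## 19 loci spanning 9,207,067..10,833,976 with sub-gap spacing
  pos <- as.integer(round(seq(9207067, 10833976, length.out = 19)))
  ed <- data.frame(chrom = "A07", pos = pos, significant = TRUE)
  rg <- callRegions(ed, maxGapBp = 2000000L, minLoci = 2L)
  expect_equal(length(rg), 1L)
  expect_equal(GenomicRanges::start(rg), 9207067L)
  expect_equal(GenomicRanges::end(rg), 10833976L)
  expect_equal(S4Vectors::mcols(rg)$n_loci, 19L)
  expect_equal(S4Vectors::mcols(rg)$length_bp, 1626909L)
})

test_that("region calling honours gaps, minimum size and the brute oracle", {
  ## an isolated flagged locus yields no region
  ed1 <- data.frame(chrom = "A01", pos = 5e6, significant = TRUE)
  expect_equal(length(callRegions(ed1, minLoci = 2L)), 0L)
  ## two clusters split by a large gap merge under a larger maxGap
  ed2 <- data.frame(chrom = "A01",
                    pos = c(1e6, 1.5e6, 2e6, 9e6, 9.5e6),
                    significant = TRUE)
  two <- callRegions(ed2, maxGapBp = 2e6)
  one <- callRegions(ed2, maxGapBp = 8e6)
  expect_equal(length(two), 2L)
  expect_equal(length(one), 1L)
  expect_true(all(GenomicRanges::width(one) >= GenomicRanges::width(two)))
  ## brute-force clustering oracle on random inputs (<= 200 loci)
  for (s in 1:5) {
    set.seed(100 + s)
    pos <- sort(sample.int(3e7, 150))
    ed <- data.frame(chrom = "A05", pos = pos, significant = TRUE)
    got <- callRegions(ed, maxGapBp = 1.2e6, minLoci = 3L)
    want <- bruteClusters(pos, 1.2e6, 3L)
    expect_equal(length(got), length(want))
    if (length(want)) {
      expect_equal(GenomicRanges::start(got),
                   as.integer(vapply(want, `[[`, numeric(1), "start")))
      expect_equal(GenomicRanges::end(got),
                   as.integer(vapply(want, `[[`, numeric(1), "end")))
      expect_equal(S4Vectors::mcols(got)$n_loci,
                   as.integer(vapply(want, `[[`, numeric(1), "n")))
    }
  }
})

test_that("ED^5 is monotone in the pool frequency difference", {
  f <- seq(0.5, 1, by = 0.05)  # strictly increasing |fG - fY|
  ed5 <- (sqrt(2) * abs(f - 0.5))^5
  x <- snpTable(data.frame(ref_G = round(100 * (1 - f)), alt_G = round(100 * f),
                           ref_Y = 50, alt_Y = 50))
  r <- edStatistic(x)
  expect_true(all(diff(r$ed5) > 0))
  expect_equal(r$ed5, ed5, tolerance = 1e-10)
})

test_that("null pools flag ~ the top fraction and yield no region", {
  set.seed(12)
  n <- 200
  dp <- 30
  aG <- rbinom(n, dp, 0.5); aY <- rbinom(n, dp, 0.5)
  x <- SnpCountTable(data.frame(
    chrom = rep(sprintf("A%02d", 1:10), each = n / 10),
    pos = rep(seq(1e6, 28e6, length.out = n / 10), 10),
    ref = "A", alt = "G",
    ref_G = dp - aG, alt_G = aG, ref_Y = dp - aY, alt_Y = aY))
  scan <- bsrScan(x, topFraction = 0.01)
  expect_lte(sum(scan$track$significant), 6L)  # ceil(2) plus possible ties
  expect_equal(length(scan$regions), 0L)
})
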