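mgtFromCalls <- function(calls, pos = seq_along(calls[[1]]) * 1e5) {
  geno <- do.call(rbind, calls)
  MarkerGenotypeTable(geno, data.frame(id = sprintf("MK%02d", seq_len(ncol(geno))),
                                       chrom = "A09", pos = pos))
}

test_that("recessive-class gamete counting matches direct counts", {
  ## all A: co-segregation, r = 0
  x <- MarkerGenotypeTable(matrix("A", 1520, 1),
                           data.frame(id = "M1", chrom = "A09", pos = 1e6))
  lt <- recombFractionRecessive(x)
  expect_equal(lt$R, 0L)
  expect_equal(lt$twoN, 3040L)
  expect_equal(lt$r, 0)
  expect_equal(lt$cM, 0)
  ## 4 H among 1520 individuals: r = 4/3040
  g <- matrix("A", 1520, 1); g[1:4] <- "H"
  lt <- recombFractionRecessive(
    MarkerGenotypeTable(g, data.frame(id = "M1", chrom = "A09", pos = 1e6)))
  expect_equal(lt$R, 4L)
  expect_equal(lt$r, 4 / 3040)
  expect_equal(lt$cM, kosambiCM(4 / 3040))
  ## all B: r = 1, flagged unlinked
  lt <- recombFractionRecessive(
    MarkerGenotypeTable(matrix("B", 10, 1),
                        data.frame(id = "M1", chrom = "A09", pos = 1e6)))
  expect_equal(lt$r, 1)
  expect_false(lt$linked)
  expect_true(is.na(lt$cM))
  ## missing cells reduce the scored gametes
  g <- matrix(c("A", "H", NA, "A"), 4, 1)
  lt <- recombFractionRecessive(
    MarkerGenotypeTable(g, data.frame(id = "M1", chrom = "A09", pos = 1e6)))
  expect_equal(lt$twoN, 6L)
  expect_equal(lt$R, 1L)
  expect_error(recombFractionRecessive(
    MarkerGenotypeTable(matrix(NA_character_, 3, 1),
                        data.frame(id = "M1", chrom = "A09", pos = 1e6))),
    "missing")
})

test_that("Kosambi function: closed form, limits and Haldane bound", {
  expect_equal(kosambiCM(0), 0)
  expect_equal(kosambiCM(0.25), 25 * log(3))
  expect_equal(kosambiCM(0.001316), 0.1316, tolerance = 1e-3)
  expect_error(kosambiCM(0.5), "0.5")
  expect_error(kosambiCM(-0.1))
  r <- seq(0.001, 0.499, by = 0.002)
  d <- kosambiCM(r)
  expect_true(all(diff(d) > 0))                 # strictly increasing
  expect_true(all(100 * r <= d + 1e-12))        # lower bound
  expect_true(all(d <= haldaneCM(r) + 1e-12))   # below Haldane
  expect_equal(kosambiCM(1e-5) / (100 * 1e-5), 1, tolerance = 1e-6)
})

test_that("recombination-fraction recovery across r and N", {
  for (r in c(0.001, 0.01, 0.05)) {
    for (n in c(200L, 1520L)) {
      mgt <- simulateRecessiveClass(n, rep(r, 3), seed = round(1e4 * r) + n)
      lt <- recombFractionRecessive(mgt)
      se <- sqrt(r * (1 - r) / (2 * n))
      expect_true(all(abs(lt$r - r) <= 3 * se + 1e-9),
                  info = sprintf("r=%g n=%d", r, n))
    }
  }
})

test_that("interval delimitation uses flanking recombinant markers", {
  ## L (r>0, left), M (co-segregating), R (r>0, right)
  lt <- data.frame(marker = c("L", "M", "Rk"), chrom = "A09",
                   pos = c(1e6, 2e6, 3e6), R = c(4L, 0L, 6L),
                   twoN = 3040L, r = c(4, 0, 6) / 3040,
                   cM = kosambiCM(c(4, 0, 6) / 3040), linked = TRUE)
  iv <- delimitInterval(lt)
  expect_equal(iv$start, 1e6)
  expect_equal(iv$end, 3e6)
  expect_equal(unname(iv$flanks), c("L", "Rk"))
  expect_false(iv$oneSided)
  expect_equal(iv$table$side[iv$table$marker == "M"], "inside")
  ## all recombinants on one side: flagged
  lt1 <- lt[1:2, ]
  expect_warning(iv1 <- delimitInterval(lt1), "one side")
  expect_true(iv1$oneSided)
  ## the interval always contains every co-segregating marker position
  set.seed(9)
  for (i in 1:10) {
    n <- 600L
    r <- c(0.02, 0.008, 0, 0, 0.006, 0.03)
    mgt <- simulateRecessiveClass(n, r,
                                  markers = data.frame(
                                    id = sprintf("MK%d", 1:6), chrom = "A09",
                                    pos = c(1, 2, 3, 4, 5, 6) * 1e6))
    lt <- recombFractionRecessive(mgt)
    iv <- tryCatch(delimitInterval(lt), warning = function(w) NULL)
    if (!is.null(iv)) {
      coseg <- lt$pos[lt$R == 0]
      expect_true(all(coseg >= iv$start & coseg <= iv$end))
    }
  }
})

test_that("mapped intervals contain the target locus (1860-plant design)", {
  ## markers bracketing the locus at 15 Mb, three per side
  mk <- data.frame(id = sprintf("MK%d", 1:6), chrom = "A07",
                   pos = c(13.5e6, 14.4e6, 14.85e6, 15.15e6, 15.6e6, 16.5e6))
  r <- c(0.02, 0.008, 0.003, 0.003, 0.008, 0.02)
  hit <- 0L
  for (s in 1:50) {
    mgt <- simulateRecessiveClass(1860L, r, markers = mk, seed = 7000 + s)
    lt <- recombFractionRecessive(mgt)
    iv <- suppressWarnings(delimitInterval(lt))
    if (!iv$oneSided && iv$start <= 15e6 && iv$end >= 15e6) hit <- hit + 1L
  }
  expect_gte(hit, 48L)  # >= 95% of 50 seeds
})

test_that("genes in interval follow the any-overlap rule", {
  ## 34 genes inside, 6 outside (3 each flank), one straddling the boundary
  inside <- GenomicRanges::GRanges(
    "A09", IRanges::IRanges(seq(23.9e6, 27.2e6, length.out = 34),
                            width = 2000))
  outside <- GenomicRanges::GRanges(
    "A09", IRanges::IRanges(c(20e6, 21e6, 22e6, 28e6, 29e6, 29.5e6),
                            width = 2000))
  ann <- c(inside, outside)
  S4Vectors::mcols(ann)$gene_id <- sprintf("g%02d", seq_along(ann))
  ann <- BiocGenerics::sort(ann)
  iv <- list(chrom = "A09", start = 23811435, end = 27563122)
  got <- genesInInterval(ann, iv)
  expect_equal(length(got), 34L)
  ## a gene straddling the boundary is included
  strad <- GenomicRanges::GRanges("A09",
                                  IRanges::IRanges(23811435 - 1000, width = 2000))
  S4Vectors::mcols(strad)$gene_id <- "straddle"
  expect_equal(length(genesInInterval(c(ann, strad), iv)), 35L)
  ## an interval touching nothing returns empty
  expect_equal(length(genesInInterval(ann, list(chrom = "A09",
                                                start = 100, end = 100))), 0L)
})
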