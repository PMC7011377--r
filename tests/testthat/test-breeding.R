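test_that("phenotype is yellow only for the double homozygous mutant", {
  expect_equal(phenotypeOf(c(2, 2)), "yellow")
  expect_equal(phenotypeOf(c(1, 2)), "green")
  expect_equal(phenotypeOf(c(2, 1)), "green")
  expect_equal(phenotypeOf(c(0, 0)), "green")
  expect_equal(phenotypeOf(rbind(c(2, 2), c(0, 2), c(2, 2))),
               c("yellow", "green", "yellow"))
  expect_error(phenotypeOf(c(2, NA)), "missing causal genotype")
  expect_error(phenotypeOf(matrix(numeric(), 1, 0)), "missing causal genotype")
})

test_that("meiosis respects map distances (Haldane oracle)", {
  ## two markers 0 cM apart: only parental two-locus haplotypes
  gm0 <- oneChromGenome(markerCM = c(20, 20), markerPos = c(6e6, 6.1e6))
  f1 <- makeOffspring(makeFounder(gm0, "wild"), makeFounder(gm0, "mutant"),
                      n = 1)
  set.seed(1)
  g <- drawGametes(f1, 1, 500)$A01
  mkCols <- which(!gm0@loci$causal)
  expect_true(all(g[, mkCols[1]] == g[, mkCols[2]]))

  ## 50 cM apart: empirical r matches (1 - exp(-1))/2
  gm50 <- oneChromGenome(markerCM = c(25, 75))
  f1 <- makeOffspring(makeFounder(gm50, "wild"), makeFounder(gm50, "mutant"),
                      n = 1)
  set.seed(2)
  g <- drawGametes(f1, 1, 200000)$A01
  mkCols <- which(!gm50@loci$causal)
  rHat <- mean(g[, mkCols[1]] != g[, mkCols[2]])
  rTrue <- (1 - exp(-1)) / 2
  expect_lt(abs(rHat - rTrue), 3 * sqrt(rTrue * (1 - rTrue) / 200000))

  ## loci on different chromosomes assort independently
  gm <- makeGenomeModel(nChrom = 2L, markersPerChrom = 1L,
                        causal = data.frame(locus = "PY1", chrom = "A01",
                                            pos = 2.9e7))
  f1 <- makeOffspring(makeFounder(gm, "wild"), makeFounder(gm, "mutant"),
                      n = 1)
  set.seed(3)
  g <- drawGametes(f1, 1, 100000)
  rHat <- mean(g$A01[, 1] != g$A02[, 1])
  expect_lt(abs(rHat - 0.5), 3 * sqrt(0.25 / 100000))
})

test_that("crosses produce the expected genotypes and phenotypes", {
  gm <- sparseGenome()
  wild <- makeFounder(gm, "wild")
  mut <- makeFounder(gm, "mutant")
  f1 <- makeOffspring(mut, wild, n = 10)
  expect_true(all(phenotypes(f1) == "green"))
  expect_true(all(causalGenotypes(f1) == 1L))

  selfMut <- makeOffspring(mut, mut, n = 10)
  expect_true(all(phenotypes(selfMut) == "yellow"))

  set.seed(4)
  f2 <- makeOffspring(f1, f1, n = 16000)
  yf <- mean(phenotypes(f2) == "yellow")
  expect_lt(abs(yf - 1 / 16), 3 * sqrt((1 / 16) * (15 / 16) / 16000))
})

test_that("simulateStudy conserves counts and matches binomial expectations", {
  ds <- simulateStudy(studyDesign(seed = 11), sparseGenome())
  for (nm in names(studyPopulations(ds))) {
    pc <- phenotypeCounts(studyPopulation(ds, nm))
    expect_identical(pc$green + pc$yellow, pc$total)
  }
  pc <- phenotypeCounts(studyPopulation(ds, "F2"))
  expect_identical(pc$total, 2376L)
  bc <- phenotypeCounts(studyPopulation(ds, "BC1_mutant"))
  expect_lt(abs(bc$yellow / bc$total - 1 / 4), 3 * sqrt(0.25 * 0.75 / 720))
  bw <- phenotypeCounts(studyPopulation(ds, "BC1_wild"))
  expect_identical(bw$yellow, 0L)
  ## family sizes follow the design
  f23 <- phenotypeCounts(studyPopulation(ds, "F23"), byFamily = TRUE)
  expect_identical(nrow(f23), 20L)
  expect_true(all(f23$total == 100L))
})

test_that("pool allele frequencies at causal loci match the enumeration oracle", {
  ds <- simulateStudy(studyDesign(seed = 21, generations = c("F1", "F2")),
                      sparseGenome())
  f2 <- studyPopulation(ds, "F2")
  dos <- causalGenotypes(f2)
  green <- phenotypes(f2) == "green"
  expect_equal(enumPoolFreq("yellow"), 1)
  expect_equal(enumPoolFreq("green"), 7 / 15)
  expect_true(all(dos[!green, ] == 2L))
  fG <- mean(dos[green, "PY1"]) / 2
  expect_lt(abs(fG - 7 / 15), 3 * sqrt((7 / 15) * (8 / 15) / (2 * sum(green))))
})

test_that("pooled SNP counts reflect the sampled bulks", {
  ds <- simulateStudy(studyDesign(seed = 31, generations = c("F1", "F2")),
                      sparseGenome())
  f2 <- studyPopulation(ds, "F2")
  sct <- simulateBulkCounts(f2, bulkSpec("G-pool", errorRate = 0),
                            bulkSpec("Y-pool", errorRate = 0), seed = 31)
  d <- snpCounts(sct)
  causal <- d$pos %in% genomeModel(f2)@causal$pos &
    d$chrom %in% genomeModel(f2)@causal$chrom
  ## yellow plants are homozygous mutant at both causal loci
  expect_true(all(d$ref_Y[causal] == 0L))
  expect_true(all(d$alt_Y[causal] > 0L))
  ## a pool bigger than the family errors
  expect_error(simulateBulkCounts(f2, bulkSpec("G-pool"),
                                  bulkSpec("Y-pool", size = 10000L)),
               "insufficient yellow")
  expect_error(bulkSpec("G-pool", errorRate = 0.6), "errorRate")
})

test_that("expression counts follow the configured fold changes", {
  gm <- sparseGenome()
  genes <- makeGeneAnnotation(gm, genesPerChrom = 30L)
  expect_error(
    simulateExpressionCounts(genes, data.frame(gene_id = "G_A01_0001",
                                               fold_change = 0)),
    "positive")
  ids <- S4Vectors::mcols(genes)$gene_id
  de <- data.frame(gene_id = ids[1:2], fold_change = c(1, 0.25),
                   base_count = 5000)
  et <- simulateExpressionCounts(genes, de, seed = 7)
  cnt <- SummarizedExperiment::assay(et, "counts")
  expect_lt(abs(log2(cnt[1, "Y"] / cnt[1, "G"])), 0.15)
  expect_lt(abs(log2(cnt[2, "Y"] / cnt[2, "G"]) - (-2)), 0.25)
})
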