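## Independent brute-force oracles and small fixtures used across tests.
## These re-derive expected values by enumeration or naive algorithms and
## must stay independent of the package implementation they check.

## Euclidean distance over both allele-frequency coordinates, written out.
bruteED <- function(fG, fY) {
  sqrt((fG - fY)^2 + ((1 - fG) - (1 - fY))^2)
}

## Top-fraction flags by full sort.
bruteTopFlags <- function(v, frac) {
  k <- ceiling(frac * length(v))
  thr <- sort(v, decreasing = TRUE)[k]
  v >= thr
}

## Naive single-linkage clustering of flagged positions on one chromosome:
## grow clusters left to right with an explicit inner loop.
bruteClusters <- function(pos, maxGap, minLoci) {
  pos <- sort(pos)
  clusters <- list()
  cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur[length(cur)] <= maxGap) cur <- c(cur, p)
    else {
      clusters[[length(clusters) + 1]] <- cur
      cur <- p
    }
  }
  clusters[[length(clusters) + 1]] <- cur
  keep <- vapply(clusters, length, integer(1)) >= minLoci
  lapply(clusters[keep], function(cl)
    c(start = min(cl), end = max(cl), n = length(cl)))
}

## Exhaustive F2 enumeration for the two-locus recessive model: all 16 x 16
## combinations of two-locus parental gametes from a double heterozygote.
## Returns the 16 offspring genotype combinations (dosage at each locus) --
## each gamete carries allele 0 or 1 at each locus with equal probability.
enumF2 <- function() {
  gam <- expand.grid(a1 = 0:1, a2 = 0:1)  # one gamete, both loci
  out <- expand.grid(g1 = seq_len(4), g2 = seq_len(4))
  data.frame(d1 = gam$a1[out$g1] + gam$a1[out$g2],
             d2 = gam$a2[out$g1] + gam$a2[out$g2])
}

## Expected mutant-allele frequency at locus 1 among green/yellow F2 plants,
## by the enumeration above.
enumPoolFreq <- function(pool = c("green", "yellow")) {
  pool <- match.arg(pool)
  f2 <- enumF2()
  yellow <- f2$d1 == 2 & f2$d2 == 2
  sel <- if (pool == "yellow") yellow else !yellow
  mean(f2$d1[sel]) / 2
}

## One-chromosome genome with markers at chosen cM positions (bp positions
## may be supplied separately so that loci 0 cM apart keep distinct physical
## coordinates); used for meiosis tests.
oneChromGenome <- function(markerCM, causalPos = 29e6,
                           markerPos = NULL) {
  lenBp <- 3e7
  pos <- if (is.null(markerPos)) as.integer(round(markerCM / 100 * lenBp))
  else as.integer(markerPos)
  makeGenomeModel(nChrom = 1L, chromLengthBp = lenBp, chromLengthCM = 100,
                  markersPerChrom = 2L,
                  causal = data.frame(locus = "PY1", chrom = "A01",
                                      pos = causalPos)) -> base
  mk <- data.frame(id = sprintf("MM%02d", seq_along(pos)), chrom = "A01",
                   pos = pos, cM = markerCM)
  lo <- rbind(data.frame(id = mk$id, chrom = mk$chrom, pos = mk$pos,
                         cM = mk$cM, causal = FALSE),
              data.frame(id = "PY1", chrom = "A01", pos = causalPos,
                         cM = causalPos / lenBp * 100, causal = TRUE))
  lo <- lo[order(lo$pos), ]
  rownames(lo) <- NULL
  methods::new("GenomeModel", chromosomes = base@chromosomes, markers = mk,
               causal = base@causal, loci = lo)
}

## Sparse two-locus genome (fast segregation-only simulations).
sparseGenome <- function() makeGenomeModel(markersPerChrom = 2L)
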