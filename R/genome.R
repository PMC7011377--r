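#' Build the default study genome
#'
#' Ten chromosomes named A01-A10 of 30 Mb / 100 cM each with a uniform
#' physical-to-genetic map, an evenly spaced marker panel, and two causal
#' recessive loci: PY1 on A09 and PY2 on A07 (inside the regions a
#' bulked-segregant scan of this design highlights). A single causal locus
#' may be supplied for monogenic control runs.
#'
#' @param nChrom number of chromosomes.
#' @param chromLengthBp physical chromosome length (bp).
#' @param chromLengthCM genetic chromosome length (cM).
#' @param markersPerChrom markers per chromosome, evenly spaced.
#' @param causal data.frame with columns \code{locus}, \code{chrom},
#'   \code{pos}; defaults to PY1 at A09:25,000,000 and PY2 at A07:13,000,000.
#' @return a \linkS4class{GenomeModel}.
#' @examples
#' gm <- makeGenomeModel(markersPerChrom = 10)
#' gm
#' @export
makeGenomeModel <- function(nChrom = 10L,
                            chromLengthBp = 3e7,
                            chromLengthCM = 100,
                            markersPerChrom = 600L,
                            causal = data.frame(
                              locus = c("PY1", "PY2"),
                              chrom = c("A09", "A07"),
                              pos = c(25000000L, 13000000L))) {
  chroms <- sprintf("A%02d", seq_len(nChrom))
  chromosomes <- data.frame(chrom = chroms, length_bp = chromLengthBp,
                            length_cM = chromLengthCM)
  bp2cM <- function(pos) pos / chromLengthBp * chromLengthCM
  mk <- do.call(rbind, lapply(chroms, function(cc) {
    pos <- as.integer(round(chromLengthBp * (seq_len(markersPerChrom) - 0.5) /
                              markersPerChrom))
    data.frame(id = sprintf("M_%s_%03d", cc, seq_len(markersPerChrom)),
               chrom = cc, pos = pos, cM = bp2cM(pos))
  }))
  causal <- as.data.frame(causal)
  causal$cM <- bp2cM(causal$pos)
  ## merged locus index; causal positions are guaranteed distinct from marker
  ## positions by the half-step marker grid
  lo <- rbind(
    data.frame(id = mk$id, chrom = mk$chrom, pos = mk$pos, cM = mk$cM,
               causal = FALSE),
    data.frame(id = causal$locus, chrom = causal$chrom, pos = causal$pos,
               cM = causal$cM, causal = TRUE))
  lo <- lo[order(match(lo$chrom, chroms), lo$pos), , drop = FALSE]
  rownames(lo) <- NULL
  new("GenomeModel", chromosomes = chromosomes, markers = mk,
      causal = causal, loci = lo)
}

#' Synthesise a gene annotation for a genome
#'
#' Evenly spaced gene models across each chromosome; the gene nearest each
#' causal locus is shifted to contain it and flagged \code{causal = TRUE}
#' (these stand in for the chlorophyll-pathway genes disrupted in the mutant).
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param genesPerChrom number of genes per chromosome.
#' @param geneLength gene model length in bp.
#' @return a sorted \code{GRanges} with mcols \code{gene_id}, \code{causal}
#'   and \code{annotation}.
#' @export
makeGeneAnnotation <- function(genome, genesPerChrom = 60L, geneLength = 2000L) {
  ch <- genome@chromosomes
  tab <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    cc <- ch$chrom[i]
    centre <- round(ch$length_bp[i] * (seq_len(genesPerChrom) - 0.5) / genesPerChrom)
    d <- data.frame(chrom = cc, centre = centre,
                    gene_id = sprintf("G_%s_%04d", cc, seq_len(genesPerChrom)),
                    causal = FALSE, annotation = "hypothetical protein")
    cidx <- which(genome@causal$chrom == cc)
    if (length(cidx)) {
      pos <- genome@causal$pos[cidx]
      k <- which.min(abs(centre - pos))
      d$centre[k] <- pos
      d$causal[k] <- TRUE
      d$annotation[k] <- "chlorophyll biosynthesis pathway gene"
    }
    d
  }))
  gr <- GenomicRanges::GRanges(
    factor(tab$chrom, levels = ch$chrom),
    IRanges::IRanges(as.integer(tab$centre - geneLength %/% 2),
                     width = geneLength),
    strand = "+")
  S4Vectors::mcols(gr)$gene_id <- tab$gene_id
  S4Vectors::mcols(gr)$causal <- tab$causal
  S4Vectors::mcols(gr)$annotation <- tab$annotation
  gr <- sort(gr)
  names(gr) <- S4Vectors::mcols(gr)$gene_id
  gr
}
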