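## Central S4 containers. Genotypes are stored as per-chromosome haplotype
## matrices (individuals x loci, alleles coded 0 = wild/reference parent,
## 1 = mutant parent), which keeps meiosis and pool-frequency computations
## fully vectorised.

#' GenomeModel: chromosomes, markers and causal loci
#'
#' Describes the simulated genome: chromosome physical (bp) and genetic (cM)
#' lengths, a marker panel, and the causal recessive loci (two unlinked loci
#' for the digenic trait; a single locus is accepted for monogenic control
#' experiments). The \code{loci} slot is the merged, position-sorted table of
#' markers plus causal loci that indexes every haplotype matrix.
#'
#' @slot chromosomes data.frame with columns \code{chrom}, \code{length_bp},
#'   \code{length_cM}.
#' @slot markers data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{cM}.
#' @slot causal data.frame with columns \code{locus}, \code{chrom}, \code{pos},
#'   \code{cM}; one row per causal locus, each on a distinct chromosome.
#' @slot loci data.frame of all loci (markers + causal) sorted by chromosome
#'   and position, with columns \code{id}, \code{chrom}, \code{pos}, \code{cM},
#'   \code{causal}.
#' @export
setClass("GenomeModel", slots = c(
  chromosomes = "data.frame",
  markers = "data.frame",
  causal = "data.frame",
  loci = "data.frame"
))

setValidity("GenomeModel", function(object) {
  msg <- character()
  ch <- object@chromosomes
  if (!all(c("chrom", "length_bp", "length_cM") %in% names(ch)))
    msg <- c(msg, "chromosomes must have chrom, length_bp, length_cM")
  ca <- object@causal
  if (nrow(ca) < 1L || nrow(ca) > 2L)
    msg <- c(msg, "one or two causal loci are supported")
  if (anyDuplicated(ca$chrom))
    msg <- c(msg, "causal loci must lie on distinct chromosomes (unlinked)")
  if (!all(ca$chrom %in% ch$chrom))
    msg <- c(msg, "causal locus chromosome not in chromosome table")
  lo <- object@loci
  for (cc in unique(lo$chrom)) {
    sub <- lo[lo$chrom == cc, ]
    if (is.unsorted(sub$pos, strictly = TRUE))
      msg <- c(msg, sprintf("loci positions not strictly increasing on %s", cc))
    if (is.unsorted(sub$cM))
      msg <- c(msg, sprintf("cM positions not non-decreasing with bp on %s", cc))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %d chromosomes, %d markers, %d causal locus/loci\n",
              nrow(object@chromosomes), nrow(object@markers), nrow(object@causal)))
  for (i in seq_len(nrow(object@causal)))
    cat(sprintf("  %s at %s:%s (%.1f cM)\n", object@causal$locus[i],
                object@causal$chrom[i],
                format(object@causal$pos[i], big.mark = ","),
                object@causal$cM[i]))
})

#' Population: a set of diploid individuals
#'
#' Holds the pedigree metadata and the phased genotypes of one simulated
#' population (founders, an F2, a set of F2:3 families, ...). Haplotypes are
#' stored per chromosome as two integer matrices (\code{h1} maternal,
#' \code{h2} paternal; individuals in rows, loci in columns, alleles coded
#' 0 = wild-parent, 1 = mutant-parent). Phenotype is a pure function of the
#' genotype at the causal loci (yellow iff homozygous mutant at all of them).
#'
#' @slot genome the \linkS4class{GenomeModel}.
#' @slot info data.frame with columns \code{id}, \code{generation},
#'   \code{family}, \code{mother}, \code{father}, \code{phenotype}.
#' @slot haps named list (one element per chromosome) of
#'   \code{list(h1 = , h2 = )} integer matrices.
#' @export
setClass("Population", slots = c(
  genome = "GenomeModel",
  info = "data.frame",
  haps = "list"
))

setValidity("Population", function(object) {
  msg <- character()
  n <- nrow(object@info)
  lo <- object@genome@loci
  need <- c("id", "generation", "family", "mother", "father", "phenotype")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "info must have id, generation, family, mother, father, phenotype")
  if (!all(object@info$phenotype %in% c("green", "yellow")))
    msg <- c(msg, "phenotype must be 'green' or 'yellow'")
  for (cc in names(object@haps)) {
    m <- sum(lo$chrom == cc)
    for (h in c("h1", "h2")) {
      hm <- object@haps[[cc]][[h]]
      if (!is.matrix(hm) || nrow(hm) != n || ncol(hm) != m)
        msg <- c(msg, sprintf("haplotype matrix %s/%s has wrong dimensions", cc, h))
      else if (!all(hm %in% c(0L, 1L)))
        msg <- c(msg, sprintf("alleles on %s must be 0/1", cc))
    }
  }
  if (!identical(sort(names(object@haps)), sort(unique(lo$chrom))))
    msg <- c(msg, "haps must have one entry per chromosome")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Population", function(object) {
  pc <- table(factor(object@info$phenotype, c("green", "yellow")))
  cat(sprintf("Population of %d individuals (%s): %d green, %d yellow\n",
              nrow(object@info),
              paste(unique(object@info$generation), collapse = ", "),
              pc[["green"]], pc[["yellow"]]))
})

#' @describeIn Population number of individuals.
#' @param x a Population.
#' @export
setMethod("nIndividuals", "Population", function(x) nrow(x@info))

#' @describeIn Population phenotype vector ("green"/"yellow").
#' @export
setMethod("phenotypes", "Population", function(x) x@info$phenotype)

#' @describeIn Population the genome model.
#' @export
setMethod("genomeModel", "Population", function(x) x@genome)

#' @describeIn Population green/yellow counts, optionally by family.
#' @param byFamily split counts by the family column.
#' @export
setMethod("phenotypeCounts", "Population", function(x, byFamily = FALSE) {
  ph <- factor(x@info$phenotype, c("green", "yellow"))
  if (!byFamily) {
    tab <- table(ph)
    data.frame(total = length(ph), green = as.integer(tab[["green"]]),
               yellow = as.integer(tab[["yellow"]]))
  } else {
    fam <- x@info$family
    tab <- table(fam, ph)
    data.frame(family = rownames(tab),
               total = as.integer(rowSums(tab)),
               green = as.integer(tab[, "green"]),
               yellow = as.integer(tab[, "yellow"]),
               row.names = NULL)
  }
})

#' Subset a Population by individual index
#' @param x a Population.
#' @param i integer or logical index over individuals.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "Population", function(x, i, j, ..., drop = FALSE) {
  haps <- lapply(x@haps, function(hh)
    list(h1 = hh$h1[i, , drop = FALSE], h2 = hh$h2[i, , drop = FALSE]))
  new("Population", genome = x@genome, info = x@info[i, , drop = FALSE],
      haps = haps)
})

#' @describeIn Population mutant-allele dosage (0/1/2) at each causal locus;
#'   matrix of individuals x causal loci.
#' @export
setMethod("causalGenotypes", "Population", function(x) {
  lo <- x@genome@loci
  ca <- x@genome@causal
  out <- matrix(NA_integer_, nIndividuals(x), nrow(ca),
                dimnames = list(NULL, ca$locus))
  for (j in seq_len(nrow(ca))) {
    cc <- ca$chrom[j]
    idx <- which(lo$pos[lo$chrom == cc] == ca$pos[j] & lo$causal[lo$chrom == cc])
    hh <- x@haps[[cc]]
    out[, j] <- hh$h1[, idx] + hh$h2[, idx]
  }
  out
})

#' SnpCountTable: per-SNP pooled allele depths
#'
#' One row per SNP with reference/alternate read counts in the green (G) and
#' yellow (Y) extreme bulks. The alternate allele is the mutant-parent allele.
#' Positions are 1-based and strictly increasing within a chromosome.
#'
#' @slot snps data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{ref_G}, \code{alt_G}, \code{ref_Y}, \code{alt_Y}.
#' @export
setClass("SnpCountTable", slots = c(snps = "data.frame"))

.SNP_COLS <- c("chrom", "pos", "ref", "alt", "ref_G", "alt_G", "ref_Y", "alt_Y")

setValidity("SnpCountTable", function(object) {
  d <- object@snps
  msg <- character()
  if (!all(.SNP_COLS %in% names(d)))
    return(sprintf("snps must have columns: %s", paste(.SNP_COLS, collapse = ", ")))
  cnt <- as.matrix(d[, c("ref_G", "alt_G", "ref_Y", "alt_Y")])
  if (nrow(d) && (any(!is.finite(cnt)) || any(cnt < 0)))
    msg <- c(msg, "read counts must be finite and non-negative")
  for (cc in unique(d$chrom)) {
    p <- d$pos[d$chrom == cc]
    if (is.unsorted(p, strictly = TRUE))
      msg <- c(msg, sprintf("positions not strictly increasing on %s", cc))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SnpCountTable
#' @param snps data.frame with columns chrom, pos, ref, alt, ref_G, alt_G,
#'   ref_Y, alt_Y (rows sorted by chromosome and position).
#' @return a \linkS4class{SnpCountTable}.
#' @export
SnpCountTable <- function(snps) {
  snps <- as.data.frame(snps)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  snps$pos <- as.integer(snps$pos)
  for (cc in c("ref_G", "alt_G", "ref_Y", "alt_Y"))
    snps[[cc]] <- as.integer(snps[[cc]])
  new("SnpCountTable", snps = snps)
}

setMethod("show", "SnpCountTable", function(object) {
  d <- object@snps
  cat(sprintf("SnpCountTable: %d SNPs on %d chromosome(s)\n",
              nrow(d), length(unique(d$chrom))))
  if (nrow(d)) {
    dp <- rowSums(d[, c("ref_G", "alt_G", "ref_Y", "alt_Y")])
    cat(sprintf("  mean total depth %.1f\n", mean(dp)))
  }
})

#' @describeIn SnpCountTable the underlying data.frame.
#' @param x a SnpCountTable.
#' @export
setMethod("snpCounts", "SnpCountTable", function(x) x@snps)

#' ExpressionTable: pooled per-gene read counts
#'
#' A \code{RangedSummarizedExperiment} with a single \code{counts} assay of
#' two columns (pools \code{G} and \code{Y}), gene coordinates as row ranges
#' (mcols: \code{gene_id}, \code{length_bp}, optional \code{causal}), and
#' library sizes (total mapped reads per pool) in \code{colData$libSize}.
#'
#' @export
setClass("ExpressionTable", contains = "RangedSummarizedExperiment")

setValidity("ExpressionTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("ExpressionTable needs a 'counts' assay")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (ncol(cnt) != 2L || !identical(colnames(cnt), c("G", "Y")))
    msg <- c(msg, "counts must have exactly the two pool columns G and Y")
  if (nrow(cnt) && any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  if (!"libSize" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry libSize")
  else {
    ls <- SummarizedExperiment::colData(object)$libSize
    if (any(ls <= 0)) msg <- c(msg, "library sizes must be positive")
    if (nrow(cnt) && any(apply(cnt, 2, max) > ls))
      msg <- c(msg, "library sizes must be >= per-gene counts")
  }
  gl <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))$length_bp
  if (!is.null(gl) && any(gl <= 0)) msg <- c(msg, "gene lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionTable
#'
#' @param counts integer matrix, genes x 2, column names \code{G} and \code{Y}.
#' @param genes \code{GRanges} of gene models with an mcols column
#'   \code{gene_id} (and optionally \code{length_bp}; defaults to the range
#'   width).
#' @param libSize numeric length-2 vector of total mapped reads per pool;
#'   defaults to the assay column sums.
#' @return an \linkS4class{ExpressionTable}.
#' @export
ExpressionTable <- function(counts, genes, libSize = colSums(counts)) {
  counts <- as.matrix(counts)
  colnames(counts) <- c("G", "Y")
  if (is.null(S4Vectors::mcols(genes)$length_bp))
    S4Vectors::mcols(genes)$length_bp <- GenomicRanges::width(genes)
  names(genes) <- S4Vectors::mcols(genes)$gene_id
  rownames(counts) <- names(genes)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = genes,
    colData = S4Vectors::DataFrame(pool = c("G", "Y"), libSize = as.numeric(libSize),
                                   row.names = c("G", "Y")))
  new("ExpressionTable", se)
}

#' @describeIn ExpressionTable gene lengths in bp.
#' @param x an ExpressionTable.
#' @export
setMethod("geneLengths", "ExpressionTable", function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$length_bp)

#' @describeIn ExpressionTable library sizes (total mapped reads per pool).
#' @export
setMethod("libSizes", "ExpressionTable", function(x)
  stats::setNames(SummarizedExperiment::colData(x)$libSize, c("G", "Y")))

#' MarkerGenotypeTable: recessive-class mapping genotypes
#'
#' Marker genotypes of a recessive-class mapping population (all individuals
#' homozygous mutant at the target locus). Cells are \code{"A"} (homozygous
#' mutant-parent allele), \code{"H"} (heterozygous), \code{"B"} (homozygous
#' wild-parent allele) or \code{NA} (missing).
#'
#' @slot geno character matrix, individuals x markers.
#' @slot markers data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   matching the genotype columns.
#' @export
setClass("MarkerGenotypeTable", slots = c(geno = "matrix", markers = "data.frame"))

setValidity("MarkerGenotypeTable", function(object) {
  msg <- character()
  if (!all(object@geno %in% c("A", "H", "B", NA)))
    msg <- c(msg, "genotype cells must be A, H, B or NA")
  if (ncol(object@geno) != nrow(object@markers))
    msg <- c(msg, "marker table must match genotype columns")
  if (!all(c("id", "chrom", "pos") %in% names(object@markers)))
    msg <- c(msg, "markers must have id, chrom, pos")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerGenotypeTable
#' @param geno character matrix (individuals x markers) of A/H/B/NA calls.
#' @param markers data.frame with id, chrom, pos for each marker column.
#' @return a \linkS4class{MarkerGenotypeTable}.
#' @export
MarkerGenotypeTable <- function(geno, markers) {
  geno <- as.matrix(geno)
  markers <- as.data.frame(markers)
  colnames(geno) <- markers$id
  new("MarkerGenotypeTable", geno = geno, markers = markers)
}

#' @describeIn MarkerGenotypeTable the genotype matrix.
#' @param x a MarkerGenotypeTable.
#' @export
setMethod("genotypeMatrix", "MarkerGenotypeTable", function(x) x@geno)

#' @describeIn MarkerGenotypeTable the marker position table.
#' @export
setMethod("markerInfo", "MarkerGenotypeTable", function(x) x@markers)

setMethod("show", "MarkerGenotypeTable", function(object) {
  cat(sprintf("MarkerGenotypeTable: %d individuals x %d markers\n",
              nrow(object@geno), ncol(object@geno)))
})

#' StudyDataset: all simulated generations of a crossing design
#'
#' @slot genome the \linkS4class{GenomeModel}.
#' @slot populations named list of \linkS4class{Population} objects (P1, P2,
#'   F1_forward, F1_reverse, F2, BC1_wild, BC1_mutant, F23, F34 as simulated).
#' @slot design the design list the dataset was simulated from.
#' @export
setClass("StudyDataset", slots = c(
  genome = "GenomeModel",
  populations = "list",
  design = "list"
))

setMethod("show", "StudyDataset", function(object) {
  cat("StudyDataset with populations:\n")
  for (nm in names(object@populations)) {
    pc <- phenotypeCounts(object@populations[[nm]])
    cat(sprintf("  %-12s n=%5d  green=%5d  yellow=%5d\n",
                nm, pc$total, pc$green, pc$yellow))
  }
})

#' @describeIn StudyDataset named list of member populations.
#' @param x a StudyDataset.
#' @export
setMethod("studyPopulations", "StudyDataset", function(x) x@populations)

#' @describeIn StudyDataset one member population by name.
#' @param name population name (e.g. \code{"F2"}).
#' @export
setMethod("studyPopulation", "StudyDataset", function(x, name) {
  if (!name %in% names(x@populations))
    stop("no population '", name, "' in this dataset", call. = FALSE)
  x@populations[[name]]
})

#' @describeIn StudyDataset the genome model.
#' @export
setMethod("genomeModel", "StudyDataset", function(x) x@genome)
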