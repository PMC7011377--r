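## Fine mapping in recessive-class populations. Every mapping individual is
## homozygous mutant at the target locus, so each of its two gametes is
## independently scored at a linked marker: a heterozygous call carries one
## recombinant gamete, a homozygous wild-parent call two.

#' Recombination fractions in a recessive-class population
#'
#' Gamete-counting estimator: each individual contributes two scored gametes
#' per marker; an H call contributes one recombinant gamete, a B call two and
#' an A call none; missing cells reduce the scored-gamete count. Markers with
#' r >= 0.5 are flagged unlinked.
#'
#' @param x a \linkS4class{MarkerGenotypeTable}.
#' @return data.frame with marker, chrom, pos, R (recombinant gametes),
#'   twoN (scored gametes), r, cM (Kosambi; NA when unlinked) and linked.
#' @export
recombFractionRecessive <- function(x) {
  g <- genotypeMatrix(x)
  mk <- markerInfo(x)
  out <- lapply(seq_len(ncol(g)), function(j) {
    col <- g[, j]
    scored <- sum(!is.na(col))
    if (scored == 0L)
      stop("all genotypes missing for marker ", mk$id[j], call. = FALSE)
    R <- sum(col == "H", na.rm = TRUE) + 2L * sum(col == "B", na.rm = TRUE)
    twoN <- 2L * scored
    r <- R / twoN
    data.frame(marker = mk$id[j], chrom = mk$chrom[j], pos = mk$pos[j],
               R = R, twoN = twoN, r = r,
               cM = if (r < 0.5) kosambiCM(r) else NA_real_,
               linked = r < 0.5)
  })
  do.call(rbind, out)
}

#' Kosambi map distance
#'
#' \code{d = 25 * ln((1 + 2r) / (1 - 2r))} centimorgans, the mapping function
#' allowing partial crossover interference.
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @return map distance(s) in cM.
#' @examples
#' kosambiCM(0.25)  # 25 * log(3)
#' @export
kosambiCM <- function(r) {
  if (any(r < 0) || any(r >= 0.5))
    stop("Kosambi distance requires 0 <= r < 0.5", call. = FALSE)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Haldane map distance
#'
#' \code{d = -50 * ln(1 - 2r)} centimorgans (no interference); the inverse of
#' the recombination fraction induced by a Poisson crossover process, used as
#' the simulator's closed-form oracle.
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @return map distance(s) in cM.
#' @export
haldaneCM <- function(r) {
  if (any(r < 0) || any(r >= 0.5))
    stop("Haldane distance requires 0 <= r < 0.5", call. = FALSE)
  -50 * log(1 - 2 * r)
}

#' Simulate recessive-class marker genotypes
#'
#' Direct sampling under the gamete model: for a marker at recombination
#' fraction r from the target locus, each of an individual's two gametes
#' carries the wild-parent allele with probability r, so the genotype call is
#' Binomial(2, r) wild alleles mapped to A/H/B. Used for parameter-recovery
#' checks of \code{\link{recombFractionRecessive}}.
#'
#' @param n number of individuals.
#' @param r vector of recombination fractions, one per marker.
#' @param markers optional data.frame (id, chrom, pos); synthesised if NULL
#'   on a uniform 300 kb/cM physical scale around a target at 15 Mb.
#' @param missingRate probability a cell is missing.
#' @param seed optional integer seed.
#' @return a \linkS4class{MarkerGenotypeTable}.
#' @export
simulateRecessiveClass <- function(n, r, markers = NULL, missingRate = 0,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(r >= 0), all(r <= 1))
  m <- length(r)
  if (is.null(markers)) {
    d <- vapply(pmin(r, 0.499), kosambiCM, numeric(1L))
    side <- rep_len(c(-1, 1), m)
    markers <- data.frame(id = sprintf("MK%02d", seq_len(m)), chrom = "A01",
                          pos = as.integer(15e6 + side * d * 3e5))
  }
  wild <- matrix(stats::rbinom(n * m, 2L, rep(r, each = n)), nrow = n)
  geno <- matrix(c("A", "H", "B")[wild + 1L], nrow = n)
  if (missingRate > 0)
    geno[stats::runif(n * m) < missingRate] <- NA
  MarkerGenotypeTable(geno, markers)
}

#' Delimit the mapping interval from per-marker linkage results
#'
#' Co-segregating markers (R = 0) lie inside the interval and cannot bound
#' it; the flanking pair is the minimum-r marker with R > 0 on each physical
#' side of the anchor (the span of co-segregating markers, or failing that
#' the minimum-r marker position). Recombinants on only one side give a
#' one-sided interval, which is flagged.
#'
#' @param linkTable data.frame from \code{\link{recombFractionRecessive}}.
#' @return list with \code{chrom}, \code{start}, \code{end}, \code{flanks}
#'   (marker ids), \code{oneSided}, and the \code{table} with a \code{side}
#'   column (left/inside/right relative to the interval anchor).
#' @export
delimitInterval <- function(linkTable) {
  lt <- linkTable[order(linkTable$pos), , drop = FALSE]
  if (length(unique(lt$chrom)) != 1L)
    stop("markers must come from one chromosome", call. = FALSE)
  coseg <- lt$R == 0L
  if (any(coseg)) {
    anchorLo <- min(lt$pos[coseg])
    anchorHi <- max(lt$pos[coseg])
  } else {
    anchorLo <- anchorHi <- lt$pos[which.min(lt$r)]
  }
  lt$side <- ifelse(lt$pos < anchorLo, "left",
                    ifelse(lt$pos > anchorHi, "right", "inside"))
  leftC <- lt$side == "left" & lt$R > 0L & lt$linked
  rightC <- lt$side == "right" & lt$R > 0L & lt$linked
  pick <- function(sel) {
    idx <- which(sel)
    if (!length(idx)) return(NA_integer_)
    idx[which.min(lt$r[idx])]
  }
  li <- pick(leftC)
  ri <- pick(rightC)
  oneSided <- is.na(li) || is.na(ri)
  if (oneSided)
    warning("recombinants on only one side of the target; one-sided interval",
            call. = FALSE)
  list(chrom = lt$chrom[1L],
       start = if (is.na(li)) NA_integer_ else lt$pos[li],
       end = if (is.na(ri)) NA_integer_ else lt$pos[ri],
       flanks = c(left = if (is.na(li)) NA_character_ else lt$marker[li],
                  right = if (is.na(ri)) NA_character_ else lt$marker[ri]),
       oneSided = oneSided,
       table = lt)
}

#' Genes overlapping a mapped interval
#'
#' Any-overlap rule: a gene is returned when its span intersects the interval
#' at all (a gene straddling a boundary is included), in positional order.
#'
#' @param annotation \code{GRanges} of gene models (mcols \code{gene_id}).
#' @param interval list with \code{chrom}, \code{start}, \code{end} (as from
#'   \code{\link{delimitInterval}}) or a \code{GRanges} of length 1.
#' @return the overlapping genes as a sorted \code{GRanges}.
#' @export
genesInInterval <- function(annotation, interval) {
  if (!methods::is(interval, "GRanges")) {
    if (is.na(interval$start) || is.na(interval$end))
      stop("cannot intersect a one-sided interval", call. = FALSE)
    interval <- GenomicRanges::GRanges(
      interval$chrom, IRanges::IRanges(interval$start, interval$end))
  }
  sort(IRanges::subsetByOverlaps(annotation, interval))
}

#' Extract marker genotypes from simulated individuals
#'
#' Converts stored haplotypes at selected markers into A/H/B calls (A =
#' homozygous mutant-parent allele). Used to assemble recessive-class mapping
#' populations from simulated F3:4 families.
#'
#' @param x a \linkS4class{Population}.
#' @param markers data.frame of markers (id, chrom, pos), typically a subset
#'   of the genome's marker table.
#' @param ... unused.
#' @return a \linkS4class{MarkerGenotypeTable}.
#' @export
setMethod("markerGenotypes", "Population", function(x, markers, ...) {
  lo <- x@genome@loci
  g <- vapply(seq_len(nrow(markers)), function(j) {
    cc <- markers$chrom[j]
    idx <- which(lo$pos[lo$chrom == cc] == markers$pos[j])
    if (length(idx) != 1L)
      stop("marker ", markers$id[j], " not in the genome's locus table",
           call. = FALSE)
    x@haps[[cc]]$h1[, idx] + x@haps[[cc]]$h2[, idx]
  }, integer(nIndividuals(x)))
  if (is.null(dim(g))) g <- matrix(g, nrow = nIndividuals(x))
  geno <- matrix(c("B", "H", "A")[g + 1L], nrow = nrow(g))
  MarkerGenotypeTable(geno, markers)
})
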