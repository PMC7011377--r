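## The ED^5 bulked-segregant statistic. Per SNP, the two pools' alternate
## allele frequencies define points (f, 1-f) on the allele-frequency simplex;
## ED is the Euclidean distance between the two pools' points, so
## ED = sqrt(2) * |fG - fY|, and raising it to the fifth power suppresses
## background noise before the top-quantile threshold.

#' Depth screen for differential SNP analysis
#'
#' Keeps SNPs whose total read depth exceeds 3x in each pool (i.e. depth
#' >= \code{minDepth} with the default of 4), the screen applied before ED
#' calculation. Row order is preserved.
#'
#' @param x a \linkS4class{SnpCountTable}.
#' @param minDepth minimum total depth per pool.
#' @return the screened \linkS4class{SnpCountTable}.
#' @export
screenDifferential <- function(x, minDepth = 4L) {
  d <- snpCounts(x)
  keep <- (d$ref_G + d$alt_G) >= minDepth & (d$ref_Y + d$alt_Y) >= minDepth
  SnpCountTable(d[keep, , drop = FALSE])
}

#' Per-SNP Euclidean distance between pools
#'
#' Computes each pool's alternate (mutant) allele frequency and the Euclidean
#' distance between the pools' two-coordinate allele-frequency vectors,
#' \code{ed = sqrt((fG-fY)^2 + ((1-fG)-(1-fY))^2)}, plus its fifth power.
#'
#' @param x a \linkS4class{SnpCountTable} (already depth-screened; zero depth
#'   in either pool is an error).
#' @return data.frame with chrom, pos, freq_G, freq_Y, ed, ed5.
#' @export
edStatistic <- function(x) {
  d <- snpCounts(x)
  dpG <- d$ref_G + d$alt_G
  dpY <- d$ref_Y + d$alt_Y
  if (any(dpG == 0) || any(dpY == 0))
    stop("zero depth in a pool; apply screenDifferential() first",
         call. = FALSE)
  fG <- d$alt_G / dpG
  fY <- d$alt_Y / dpY
  ed <- sqrt((fG - fY)^2 + ((1 - fG) - (1 - fY))^2)
  data.frame(chrom = d$chrom, pos = d$pos, freq_G = fG, freq_Y = fY,
             ed = ed, ed5 = ed^5)
}

#' Top-quantile significance threshold
#'
#' The threshold is the k-th largest value with k = ceiling(topFraction * n);
#' all loci with \code{ed5 >= threshold} are flagged, so ties at the
#' threshold are all included.
#'
#' @param ed5 numeric vector of ED^5 values.
#' @param topFraction fraction of loci to flag (default 0.01, the top 1%).
#' @return list with \code{threshold}, logical \code{flagged}, and
#'   \code{nFlagged}.
#' @export
significanceThreshold <- function(ed5, topFraction = 0.01) {
  if (!length(ed5)) stop("no ED^5 values", call. = FALSE)
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]", call. = FALSE)
  k <- ceiling(topFraction * length(ed5))
  thr <- sort(ed5, decreasing = TRUE)[k]
  flagged <- ed5 >= thr
  list(threshold = thr, flagged = flagged, nFlagged = sum(flagged))
}

#' Call candidate regions from flagged loci
#'
#' Clusters significant loci: consecutive flagged loci on one chromosome
#' whose gap does not exceed \code{maxGapBp} join one region; regions with
#' fewer than \code{minLoci} members are discarded. Region start/end are the
#' first/last member positions and the reported length is \code{end - start}.
#'
#' @param ed data.frame with \code{chrom}, \code{pos} (sorted within
#'   chromosome) and a logical \code{significant} column, as produced by
#'   \code{\link{bsrScan}}; alternatively supply \code{significant}.
#' @param significant optional logical vector overriding \code{ed$significant}.
#' @param maxGapBp maximum within-region gap between consecutive flagged loci.
#' @param minLoci minimum flagged loci per region.
#' @return \code{GRanges} of candidate regions with mcols \code{n_loci} and
#'   \code{length_bp}.
#' @export
callRegions <- function(ed, significant = ed$significant,
                        maxGapBp = 2000000L, minLoci = 2L) {
  stopifnot(!is.null(significant))
  flag <- ed[significant, c("chrom", "pos"), drop = FALSE]
  out <- list()
  for (cc in unique(flag$chrom)) {
    p <- sort(flag$pos[flag$chrom == cc])
    if (!length(p)) next
    grp <- cumsum(c(1L, diff(p) > maxGapBp))
    for (g in unique(grp)) {
      pg <- p[grp == g]
      if (length(pg) < minLoci) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start = min(pg), end = max(pg), n_loci = length(pg))
    }
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(n_loci = integer(),
                                                 length_bp = integer())
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr)$n_loci <- df$n_loci
  S4Vectors::mcols(gr)$length_bp <- df$end - df$start
  sort(gr)
}

#' Run the full bulked-segregant scan
#'
#' Depth screen, ED/ED^5 computation, top-quantile threshold and candidate
#' region calling in one step.
#'
#' @param x a \linkS4class{SnpCountTable}.
#' @param minDepth per-pool depth screen (kept if depth >= minDepth).
#' @param topFraction top quantile of ED^5 to flag.
#' @param maxGapBp,minLoci region-calling parameters (see
#'   \code{\link{callRegions}}).
#' @return list with the per-SNP \code{track} (data.frame incl.
#'   \code{significant}), the \code{threshold}, and \code{regions}
#'   (\code{GRanges}).
#' @examples
#' gm <- makeGenomeModel(markersPerChrom = 20)
#' ds <- simulateStudy(studyDesign(f2 = 2376, generations = c("F1", "F2"),
#'                                 seed = 3), gm)
#' sct <- simulateBulkCounts(studyPopulation(ds, "F2"), seed = 3)
#' scan <- bsrScan(sct)
#' scan$regions
#' @export
bsrScan <- function(x, minDepth = 4L, topFraction = 0.01,
                    maxGapBp = 2000000L, minLoci = 2L) {
  scr <- screenDifferential(x, minDepth)
  track <- edStatistic(scr)
  sig <- significanceThreshold(track$ed5, topFraction)
  track$significant <- sig$flagged
  regions <- callRegions(track, maxGapBp = maxGapBp, minLoci = minLoci)
  list(track = track, threshold = sig$threshold, regions = regions)
}
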