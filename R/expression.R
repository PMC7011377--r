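#' RPKM expression measure
#'
#' Reads per kilobase of gene model per million mapped reads:
#' \code{1e9 * count / (libSize * lengthBp)}.
#'
#' @param count read count(s).
#' @param lengthBp gene length(s) in bp (> 0).
#' @param libSize total mapped reads in the library (> 0).
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, lengthBp, libSize) {
  if (any(lengthBp <= 0)) stop("gene length must be positive", call. = FALSE)
  if (any(libSize <= 0)) stop("library size must be positive", call. = FALSE)
  1e9 * count / (libSize * lengthBp)
}

#' Expressed-gene filter
#'
#' A gene counts as expressed when its RPKM reaches \code{rpkmMin} in at
#' least one pool (boundary included).
#'
#' @param x an \linkS4class{ExpressionTable}.
#' @param rpkmMin RPKM threshold (default 0.1).
#' @return character vector of expressed gene ids.
#' @export
detectExpressed <- function(x, rpkmMin = 0.1) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  ls <- libSizes(x)
  len <- geneLengths(x)
  rG <- rpkm(cnt[, "G"], len, ls[["G"]])
  rY <- rpkm(cnt[, "Y"], len, ls[["Y"]])
  rownames(cnt)[rG >= rpkmMin | rY >= rpkmMin]
}

#' Call differentially expressed genes between the pools
#'
#' For each expressed gene, the fold change is computed on
#' pseudocount-stabilised library-normalised counts,
#' \code{log2fc = log2((cY + c)/N_Y) - log2((cG + c)/N_G)}, and the p-value
#' comes from the conditional exact two-proportion test of the two counts
#' against the library-size split (\code{stats::binom.test} of cY out of
#' cY + cG with p = N_Y/(N_G + N_Y)); Benjamini-Hochberg adjustment is
#' applied over all tested genes. A gene is a DEG iff |log2fc| >= 1 and
#' FDR <= 0.05 (both thresholds configurable). The test is pluggable via
#' \code{testFun}.
#'
#' @param x an \linkS4class{ExpressionTable}.
#' @param pseudocount stabilising count added to both pools for the fold
#'   change (default 1 read).
#' @param log2fcMin absolute log2 fold-change threshold.
#' @param fdrMax FDR threshold.
#' @param rpkmMin expressed-gene filter applied before testing.
#' @param testFun function(countG, countY, libG, libY) returning a p-value;
#'   defaults to the conditional exact binomial test.
#' @return data.frame (one row per tested gene) with gene_id, chrom, start,
#'   end, count_G, count_Y, rpkm_G, rpkm_Y, log2fc, p_value, fdr, is_deg and
#'   direction ("up"/"down", yellow pool relative to green).
#' @export
callDegs <- function(x, pseudocount = 1, log2fcMin = 1, fdrMax = 0.05,
                     rpkmMin = 0.1, testFun = NULL) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  ls <- libSizes(x)
  len <- geneLengths(x)
  gr <- SummarizedExperiment::rowRanges(x)
  keep <- rownames(cnt) %in% detectExpressed(x, rpkmMin)
  cnt <- cnt[keep, , drop = FALSE]
  gr <- gr[keep]
  len <- len[keep]
  cG <- cnt[, "G"]
  cY <- cnt[, "Y"]
  log2fc <- log2((cY + pseudocount) / ls[["Y"]]) -
    log2((cG + pseudocount) / ls[["G"]])
  if (is.null(testFun)) {
    pSplit <- ls[["Y"]] / sum(ls)
    testFun <- function(countG, countY, libG, libY)
      stats::binom.test(countY, countY + countG, p = pSplit)$p.value
  }
  p <- vapply(seq_along(cG), function(i) {
    if (cG[i] + cY[i] == 0) return(1)
    testFun(cG[i], cY[i], ls[["G"]], ls[["Y"]])
  }, numeric(1L))
  fdr <- stats::p.adjust(p, method = "BH")
  isDeg <- abs(log2fc) >= log2fcMin & fdr <= fdrMax
  data.frame(gene_id = rownames(cnt),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             count_G = cG, count_Y = cY,
             rpkm_G = rpkm(cG, len, ls[["G"]]),
             rpkm_Y = rpkm(cY, len, ls[["Y"]]),
             log2fc = log2fc, p_value = p, fdr = fdr, is_deg = isDeg,
             direction = ifelse(log2fc > 0, "up", "down"),
             row.names = NULL)
}

#' Candidate genes: DEGs inside a mapped interval
#'
#' Intersects the DEG calls with the genes overlapping a mapped interval
#' (any-overlap rule): candidates are genes that are both inside the interval
#' and flagged as differentially expressed.
#'
#' @param degs data.frame from \code{\link{callDegs}}.
#' @param interval interval list (chrom/start/end) or length-1 \code{GRanges}.
#' @param annotation \code{GRanges} gene annotation.
#' @return data.frame of candidate DEG rows (zero rows when the interval
#'   holds no DEG).
#' @export
candidateGenes <- function(degs, interval, annotation) {
  inside <- genesInInterval(annotation, interval)
  out <- degs[degs$is_deg & degs$gene_id %in% S4Vectors::mcols(inside)$gene_id,
              , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Relative qPCR expression of a target gene in the mutant versus the
#' wild-type calibrator, each normalised to a reference gene:
#' \code{2^-((ctTargetMut - ctRefMut) - (ctTargetWt - ctRefWt))}.
#'
#' @param ctTargetMut,ctRefMut Ct values of target and reference gene in the
#'   mutant sample.
#' @param ctTargetWt,ctRefWt Ct values in the wild-type calibrator sample.
#' @return relative expression fold value(s).
#' @examples
#' ddctRelativeExpression(22, 18, 20, 18)  # ddCt = 2 -> 0.25
#' @export
ddctRelativeExpression <- function(ctTargetMut, ctRefMut, ctTargetWt, ctRefWt) {
  if (any(!is.finite(c(ctTargetMut, ctRefMut, ctTargetWt, ctRefWt))))
    stop("Ct values must be finite", call. = FALSE)
  2^-((ctTargetMut - ctRefMut) - (ctTargetWt - ctRefWt))
}
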