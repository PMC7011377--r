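#' Specification of an extreme phenotype bulk
#'
#' @param pool \code{"G-pool"} (green) or \code{"Y-pool"} (yellow).
#' @param size number of pooled individuals (study design: 100).
#' @param meanDepth mean sequencing depth per SNP (Poisson mean); the study
#'   does not report a depth target, 30x is this package's default.
#' @param errorRate symmetric base-substitution error rate e, so the sampled
#'   mutant-allele frequency is f(1-e) + (1-f)e.
#' @return a bulk specification list.
#' @export
bulkSpec <- function(pool = c("G-pool", "Y-pool"), size = 100L,
                     meanDepth = 30, errorRate = 0.001) {
  pool <- match.arg(pool)
  stopifnot(size >= 1L, meanDepth > 0)
  if (errorRate < 0 || errorRate >= 0.5)
    stop("errorRate must be in [0, 0.5)", call. = FALSE)
  list(pool = pool, size = size, meanDepth = meanDepth, errorRate = errorRate)
}

## True mutant-allele frequency of a sampled pool at every locus.
.poolFrequencies <- function(pop, idx) {
  unlist(lapply(names(pop@haps), function(cc) {
    hh <- pop@haps[[cc]]
    colMeans(hh$h1[idx, , drop = FALSE] + hh$h2[idx, , drop = FALSE]) / 2
  }), use.names = FALSE)
}

#' Simulate pooled SNP read counts from an F2
#'
#' Samples the two extreme bulks (without replacement) from an F2 family,
#' computes each pool's true mutant-allele frequency at every locus (markers
#' plus the causal positions), then draws per-SNP depths as Poisson and
#' mutant-allele reads as binomial with the error-adjusted frequency.
#'
#' @param f2 the F2 \linkS4class{Population}.
#' @param gSpec,ySpec \code{\link{bulkSpec}} for the green and yellow bulks.
#' @param seed optional integer seed.
#' @return a \linkS4class{SnpCountTable} (ref = wild-parent allele,
#'   alt = mutant-parent allele).
#' @export
simulateBulkCounts <- function(f2, gSpec = bulkSpec("G-pool"),
                               ySpec = bulkSpec("Y-pool"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ph <- phenotypes(f2)
  gIdx <- which(ph == "green")
  yIdx <- which(ph == "yellow")
  if (length(gIdx) < gSpec$size)
    stop("insufficient green plants for the G-pool", call. = FALSE)
  if (length(yIdx) < ySpec$size)
    stop("insufficient yellow plants for the Y-pool", call. = FALSE)
  gSel <- sample(gIdx, gSpec$size)
  ySel <- sample(yIdx, ySpec$size)
  lo <- f2@genome@loci
  draw <- function(idx, spec) {
    f <- .poolFrequencies(f2, idx)
    fObs <- f * (1 - spec$errorRate) + (1 - f) * spec$errorRate
    depth <- stats::rpois(length(f), spec$meanDepth)
    alt <- stats::rbinom(length(f), depth, fObs)
    cbind(ref = depth - alt, alt = alt)
  }
  g <- draw(gSel, gSpec)
  y <- draw(ySel, ySpec)
  SnpCountTable(data.frame(
    chrom = lo$chrom, pos = lo$pos, ref = "A", alt = "G",
    ref_G = g[, "ref"], alt_G = g[, "alt"],
    ref_Y = y[, "ref"], alt_Y = y[, "alt"]))
}

#' Simulate pooled per-gene expression counts
#'
#' Generates a two-pool expression table over a gene annotation. Non-DE genes
#' have equal expected counts in both pools (log-normal baseline across
#' genes, Poisson sampling); configured DE genes have their yellow-pool rate
#' multiplied by the fold change. Causal genes are typically configured
#' downregulated in the yellow pool, mirroring the loss-of-function mutant.
#'
#' @param genes \code{GRanges} gene annotation (mcols \code{gene_id}).
#' @param deConfig data.frame with columns \code{gene_id} and
#'   \code{fold_change} (Y relative to G; must be > 0), and optionally
#'   \code{base_count} to pin a DE gene's expected G-pool count.
#' @param baseMeanLog,baseSdLog log-normal parameters of the per-gene baseline
#'   expected count.
#' @param seed optional integer seed.
#' @return an \linkS4class{ExpressionTable}.
#' @export
simulateExpressionCounts <- function(genes, deConfig = NULL,
                                     baseMeanLog = log(100), baseSdLog = 1,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(genes)
  ids <- S4Vectors::mcols(genes)$gene_id
  base <- stats::rlnorm(n, baseMeanLog, baseSdLog)
  fc <- rep(1, n)
  if (!is.null(deConfig) && nrow(deConfig)) {
    if (any(deConfig$fold_change <= 0))
      stop("fold changes must be positive", call. = FALSE)
    j <- match(deConfig$gene_id, ids)
    if (anyNA(j)) stop("deConfig names genes absent from the annotation",
                       call. = FALSE)
    fc[j] <- deConfig$fold_change
    if (!is.null(deConfig$base_count)) {
      has <- !is.na(deConfig$base_count)
      base[j[has]] <- deConfig$base_count[has]
    }
  }
  countG <- stats::rpois(n, base)
  countY <- stats::rpois(n, base * fc)
  et <- ExpressionTable(cbind(G = countG, Y = countY), genes)
  S4Vectors::metadata(et)$deConfig <- deConfig
  et
}
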