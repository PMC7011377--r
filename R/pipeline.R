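#' RunReport: results of one end-to-end pipeline run
#'
#' @slot segregation data.frame of per-generation segregation statistics.
#' @slot familyClasses data.frame of F2:3/F3:4 family classifications.
#' @slot regions data.frame of called candidate regions (Table-2 style).
#' @slot linkage named list (per causal locus) of linkage results and mapped
#'   intervals.
#' @slot degs data.frame of DEG calls.
#' @slot candidates data.frame of candidate genes (DEG x interval).
#' @slot provenance list: seed, config hash, package version, file paths.
#' @export
setClass("RunReport", slots = c(
  segregation = "data.frame",
  familyClasses = "data.frame",
  regions = "data.frame",
  linkage = "list",
  degs = "data.frame",
  candidates = "data.frame",
  provenance = "list"
))

setMethod("show", "RunReport", function(object) {
  cat("RunReport (seed ", object@provenance$seed, ")\n", sep = "")
  cat("Segregation:\n")
  print(object@segregation, row.names = FALSE)
  cat("\nCandidate regions:\n")
  print(object@regions, row.names = FALSE)
  cat("\nMapped intervals:\n")
  for (nm in names(object@linkage)) {
    iv <- object@linkage[[nm]]$interval
    cat(sprintf("  %s: %s:%s-%s (%d genes in interval)\n", nm, iv$chrom,
                format(iv$start, big.mark = ","),
                format(iv$end, big.mark = ","),
                length(object@linkage[[nm]]$genes)))
  }
  cat(sprintf("\nDEGs: %d (%d up, %d down); candidate genes: %s\n",
              sum(object@degs$is_deg),
              sum(object@degs$is_deg & object@degs$direction == "up"),
              sum(object@degs$is_deg & object@degs$direction == "down"),
              paste(object@candidates$gene_id, collapse = ", ")))
})

## Table-1 style segregation rows for the standard generations. Hypothesised
## ratios follow the k-locus recessive-epistasis model: F2 green:yellow =
## (4^k - 1):1, BC1-to-mutant = (2^k - 1):1 (k = 2 gives 15:1 and 3:1).
.segregationTable <- function(ds, critical = 3.84) {
  pops <- studyPopulations(ds)
  k <- nrow(genomeModel(ds)@causal)
  f2Ratio <- c(4^k - 1, 1)
  bc1Ratio <- c(2^k - 1, 1)
  row <- function(nm, ratio = NULL) {
    if (!nm %in% names(pops)) return(NULL)
    pc <- phenotypeCounts(pops[[nm]])
    if (nm %in% c("P1", "P2") &&
        paste0(nm, "_line") %in% names(pops))  # report the line, not the founder
      pc <- phenotypeCounts(pops[[paste0(nm, "_line")]])
    if (is.null(ratio) || pc$yellow == 0L) {
      data.frame(generation = nm, total = pc$total, green = pc$green,
                 yellow = pc$yellow, hypothesis = NA_character_,
                 observed_ratio = NA_real_, chi2 = NA_real_,
                 consistent = NA)
    } else {
      st <- segregationTest(pc$green, pc$yellow, ratio, critical = critical)
      data.frame(generation = nm, total = st$total, green = st$green,
                 yellow = st$yellow, hypothesis = st$hypothesis,
                 observed_ratio = st$observed_ratio, chi2 = st$chi2,
                 consistent = st$consistent)
    }
  }
  out <- rbind(row("P1"), row("P2"), row("F1_forward"), row("F1_reverse"),
               row("BC1_wild"), row("BC1_mutant", bc1Ratio),
               row("F2", f2Ratio))
  rownames(out) <- NULL
  out
}

## Does any F3:4 family segregate for this locus (parent heterozygous there,
## homozygous mutant at every other causal locus)?
.locusHasMappingFamily <- function(ds, locus) {
  ca <- genomeModel(ds)@causal
  li <- which(ca$locus == locus)
  f34 <- studyPopulation(ds, "F34")
  f23 <- studyPopulation(ds, "F23")
  dosF23 <- causalGenotypes(f23)
  fams <- unique(f34@info$family)
  for (fam in fams) {
    parentId <- f34@info$mother[match(fam, f34@info$family)]
    d <- dosF23[match(parentId, f23@info$id), ]
    if (d[li] == 1L && all(d[-li] == 2L)) return(TRUE)
  }
  FALSE
}

## Assemble the recessive-class mapping population for one causal locus.
## Among the F3:4 families whose parent is heterozygous at this locus (and
## homozygous mutant at the other causal locus), the one with the most
## yellow plants nominates its parent; a large mapping population is then
## grown from that parent (the study genotyped 1520 and 1860 yellow F3:4
## plants) and its yellow members are scored at the target chromosome's
## markers that are polymorphic in the parent. Only the target chromosome is
## simulated: the parent is homozygous mutant at the other causal locus, so
## the phenotype segregates with the target locus alone.
.mapLocus <- function(ds, locus, annotation, mappingYellow = 1500L) {
  genome <- genomeModel(ds)
  ca <- genome@causal
  li <- which(ca$locus == locus)
  tc <- ca$chrom[li]
  f34 <- studyPopulation(ds, "F34")
  f23 <- studyPopulation(ds, "F23")
  dosF23 <- causalGenotypes(f23)
  fams <- unique(f34@info$family)
  segFams <- character()
  for (fam in fams) {
    parentId <- f34@info$mother[match(fam, f34@info$family)]
    d <- dosF23[match(parentId, f23@info$id), ]
    if (d[li] == 1L && all(d[-li] == 2L)) segFams <- c(segFams, fam)
  }
  if (!length(segFams))
    stop("no F3:4 family segregates for ", locus, call. = FALSE)
  yCount <- vapply(segFams, function(fam)
    sum(f34@info$family == fam & phenotypes(f34) == "yellow"), integer(1L))
  fam <- segFams[which.max(yCount)]
  parentId <- f34@info$mother[match(fam, f34@info$family)]
  pi <- match(parentId, f23@info$id)
  lo <- genome@loci
  sel <- lo$chrom == tc
  cM <- lo$cM[sel]
  h1p <- f23@haps[[tc]]$h1[pi, ]
  h2p <- f23@haps[[tc]]$h2[pi, ]
  n <- 4L * mappingYellow  # ~1/4 of the family is yellow
  g1 <- .chromGametes(h1p, h2p, cM, n)
  g2 <- .chromGametes(h1p, h2p, cM, n)
  cidx <- which(lo$pos[sel] == ca$pos[li] & lo$causal[sel])
  yellow <- (g1[, cidx] + g2[, cidx]) == 2L
  ## polymorphism screen: markers heterozygous in the family parent
  mk <- genome@markers[genome@markers$chrom == tc, , drop = FALSE]
  midx <- match(mk$pos, lo$pos[sel])
  informative <- (h1p + h2p)[midx] == 1L
  mk <- mk[informative, , drop = FALSE]
  if (!nrow(mk))
    stop("no informative markers for ", locus, call. = FALSE)
  dosM <- g1[yellow, midx[informative], drop = FALSE] +
    g2[yellow, midx[informative], drop = FALSE]
  geno <- matrix(c("B", "H", "A")[dosM + 1L], nrow = nrow(dosM))
  mgt <- MarkerGenotypeTable(geno, mk)
  lt <- recombFractionRecessive(mgt)
  interval <- delimitInterval(lt)
  genes <- if (!interval$oneSided)
    genesInInterval(annotation, interval) else GenomicRanges::GRanges()
  list(locus = locus, family = fam, nIndividuals = sum(yellow),
       linkage = lt, interval = interval, genes = genes)
}

#' Run the simulate-analyse-report pipeline
#'
#' Orchestrates the full desk-scale study in the order of the original
#' analysis: breeding simulation, segregation tests and family
#' classification, pooled SNP simulation and the ED^5 bulked-segregant scan,
#' recessive-class fine mapping of each causal locus, and DEG calling
#' intersected with the mapped intervals. All stage outputs are written as
#' TSVs to \code{outDir}; the run is deterministic given the config seed.
#'
#' @param config configuration list from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @param outDir output directory.
#' @param verbose log stage progress and filter counts.
#' @return a \linkS4class{RunReport}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run"),
                        verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(outDir, "config.yaml")
  writePipelineConfig(config, cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  seed <- config$seed

  .msg(verbose, "[simulate] breeding design, seed ", seed)
  genome <- if (!is.null(config$genome$causal))
    makeGenomeModel(markersPerChrom = config$genome$markersPerChrom,
                    causal = as.data.frame(config$genome$causal))
  else makeGenomeModel(markersPerChrom = config$genome$markersPerChrom)
  ## The crossing design only supports fine mapping when the twenty selfed
  ## green F2 plants happen to include a single-locus heterozygote for each
  ## causal locus (the original study drew four usable families and covered
  ## both loci). Draws that miss a locus are discarded deterministically:
  ## attempt i re-simulates with a seed derived from the global seed.
  ds <- NULL
  for (attempt in seq_len(10L)) {
    dseed <- seed + (attempt - 1L) * 7919L
    design <- do.call(studyDesign, c(config$design, list(seed = dseed)))
    cand <- tryCatch(simulateStudy(design, genome), error = function(e) e)
    if (inherits(cand, "error")) {
      .msg(verbose, "[simulate] attempt ", attempt, ": ",
           conditionMessage(cand))
      next
    }
    if (all(vapply(genome@causal$locus, function(lc)
      .locusHasMappingFamily(cand, lc), logical(1L)))) {
      ds <- cand
      break
    }
    .msg(verbose, "[simulate] attempt ", attempt,
         ": realized F3:4 families do not cover both loci; re-drawing")
  }
  if (is.null(ds))
    stop("breeding design failed to realize mapping families for all loci",
         call. = FALSE)
  writeStudyDataset(ds, outDir, genotypes = FALSE)

  .msg(verbose, "[segtest] segregation statistics")
  crit <- config$segregation$critical
  seg <- .segregationTable(ds, crit)
  f23Cls <- classifyFamily(phenotypeCounts(studyPopulation(ds, "F23"),
                                           byFamily = TRUE), critical = crit)
  f34Cls <- classifyFamily(phenotypeCounts(studyPopulation(ds, "F34"),
                                           byFamily = TRUE), critical = crit)
  famCls <- rbind(cbind(generation = "F23", f23Cls),
                  cbind(generation = "F34", f34Cls))
  inheritance <- inferInheritanceMode(
    unlist(phenotypeCounts(studyPopulation(ds, "F1_forward"))[c("green", "yellow")]),
    unlist(phenotypeCounts(studyPopulation(ds, "F1_reverse"))[c("green", "yellow")]))
  utils::write.table(seg, file.path(outDir, "segregation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(famCls, file.path(outDir, "family_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  .msg(verbose, "[bsr] pooled SNP simulation and ED^5 scan")
  set.seed(.stageSeed(seed, 11L))
  sct <- simulateBulkCounts(
    studyPopulation(ds, "F2"),
    bulkSpec("G-pool", config$bulk$size, config$bulk$meanDepth,
             config$bulk$errorRate),
    bulkSpec("Y-pool", config$bulk$size, config$bulk$meanDepth,
             config$bulk$errorRate))
  writeSnpCountTable(sct, file.path(outDir, "snp_counts.tsv"))
  scan <- bsrScan(sct, minDepth = config$bsr$minDepth,
                  topFraction = config$bsr$topFraction,
                  maxGapBp = config$bsr$maxGapBp,
                  minLoci = config$bsr$minLoci)
  .msg(verbose, sprintf("[bsr] %d/%d SNPs pass depth screen; %d flagged; %d regions",
                        nrow(scan$track), nrow(snpCounts(sct)),
                        sum(scan$track$significant), length(scan$regions)))
  utils::write.table(scan$track, file.path(outDir, "ed_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(scan$regions)),
    start = GenomicRanges::start(scan$regions),
    end = GenomicRanges::end(scan$regions),
    n_loci = S4Vectors::mcols(scan$regions)$n_loci,
    length = S4Vectors::mcols(scan$regions)$length_bp)
  utils::write.table(regions, file.path(outDir, "regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grDevices::pdf(file.path(outDir, "ed_track.pdf"), width = 10, height = 4)
  plotEdTrack(scan$track, scan$threshold)
  grDevices::dev.off()

  .msg(verbose, "[map] recessive-class fine mapping")
  annotation <- makeGeneAnnotation(genome,
                                   genesPerChrom = config$genome$genesPerChrom)
  set.seed(.stageSeed(seed, 12L))
  linkage <- lapply(genome@causal$locus, function(lc)
    .mapLocus(ds, lc, annotation,
              mappingYellow = config$linkage$mappingYellow))
  names(linkage) <- genome@causal$locus
  linkTab <- do.call(rbind, lapply(linkage, function(l)
    cbind(locus = l$locus, l$linkage)))
  utils::write.table(linkTab, file.path(outDir, "linkage.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ivTab <- do.call(rbind, lapply(linkage, function(l)
    data.frame(locus = l$locus, family = l$family, n = l$nIndividuals,
               chrom = l$interval$chrom, start = l$interval$start,
               end = l$interval$end, n_genes = length(l$genes))))
  utils::write.table(ivTab, file.path(outDir, "intervals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  .msg(verbose, "[deg] expression simulation and DEG calling")
  set.seed(.stageSeed(seed, 13L))
  ids <- S4Vectors::mcols(annotation)$gene_id
  causalIds <- ids[S4Vectors::mcols(annotation)$causal]
  exCfg <- config$expression
  nDownRandom <- max(exCfg$nDownTotal - length(causalIds), 0L)
  pool <- setdiff(ids, causalIds)
  deUp <- sample(pool, exCfg$nUp)
  deDown <- sample(setdiff(pool, deUp), nDownRandom)
  deConfig <- data.frame(
    gene_id = c(deUp, deDown, causalIds),
    fold_change = c(rep(exCfg$foldUp, length(deUp)),
                    rep(exCfg$foldDown, length(deDown)),
                    rep(exCfg$causalFold, length(causalIds))),
    base_count = exCfg$baseCount)
  et <- simulateExpressionCounts(annotation, deConfig)
  writeExpressionTable(et, file.path(outDir, "expression.tsv"))
  degs <- callDegs(et, pseudocount = config$deg$pseudocount,
                   log2fcMin = config$deg$log2fcMin,
                   fdrMax = config$deg$fdrMax, rpkmMin = config$deg$rpkmMin)
  utils::write.table(degs, file.path(outDir, "degs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cand <- do.call(rbind, lapply(linkage, function(l) {
    if (l$interval$oneSided) return(NULL)
    cg <- candidateGenes(degs, l$interval, annotation)
    if (nrow(cg)) cbind(locus = l$locus, cg) else NULL
  }))
  if (is.null(cand))
    cand <- data.frame(locus = character(), gene_id = character())
  utils::write.table(cand, file.path(outDir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .msg(verbose, sprintf("[deg] %d DEGs; %d candidate gene(s)",
                        sum(degs$is_deg), nrow(cand)))

  report <- new("RunReport", segregation = seg, familyClasses = famCls,
                regions = regions, linkage = linkage, degs = degs,
                candidates = cand,
                provenance = list(seed = seed, configHash = cfgHash,
                                  version = as.character(
                                    utils::packageVersion("digenicBSR")),
                                  inheritance = inheritance,
                                  outDir = outDir))
  txt <- file.path(outDir, "report.txt")
  con <- file(txt, "w")
  sink(con)
  show(report)
  sink()
  close(con)
  report
}

#' Plot the ED^5 track across chromosomes
#'
#' Genome-wide per-SNP ED^5 values coloured by chromosome with the
#' significance threshold as a horizontal line.
#'
#' @param track data.frame from \code{\link{bsrScan}} (chrom, pos, ed5).
#' @param threshold ED^5 significance threshold to draw.
#' @return invisibly, the cumulative-position data.frame plotted.
#' @export
plotEdTrack <- function(track, threshold = NULL) {
  chroms <- unique(track$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(cc)
    max(track$pos[track$chrom == cc]), numeric(1L))))
  names(offsets) <- c(chroms, "end")
  x <- track$pos + offsets[track$chrom]
  col <- (match(track$chrom, chroms) %% 2L) + 1L
  plot(x, track$ed5, pch = 16, cex = 0.5,
       col = c("grey40", "steelblue")[col],
       xlab = "chromosome", ylab = expression(ED^5), xaxt = "n")
  mid <- offsets[seq_along(chroms)] + diff(offsets) / 2
  graphics::axis(1, at = mid, labels = chroms, las = 2, cex.axis = 0.8)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(data.frame(x = x, ed5 = track$ed5))
}
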