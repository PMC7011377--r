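## Rectangular TSV is the canonical interchange format; minimal VCF (allelic
## depths) and GFF3 adapters sit at the edges.

.checkColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

.badLines <- function(bad) paste(which(bad) + 1L, collapse = ", ")  # +1 header

#' Read a SNP count table from TSV
#'
#' Expected columns: chrom, pos (1-based), ref, alt, ref_G, alt_G, ref_Y,
#' alt_Y. Schema violations are reported with the offending column and line.
#'
#' @param path TSV file path.
#' @return a \linkS4class{SnpCountTable}.
#' @export
readSnpCountTable <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  .checkColumns(d, .SNP_COLS, path)
  for (cc in c("pos", "ref_G", "alt_G", "ref_Y", "alt_Y")) {
    v <- suppressWarnings(as.numeric(d[[cc]]))
    bad <- !is.finite(v) | v < 0
    if (any(bad))
      stop(sprintf("%s: column %s invalid at line(s) %s", path, cc,
                   .badLines(bad)), call. = FALSE)
  }
  SnpCountTable(d)
}

#' Write a SNP count table to TSV
#' @param x a \linkS4class{SnpCountTable}.
#' @param path output file.
#' @export
writeSnpCountTable <- function(x, path) {
  utils::write.table(snpCounts(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a SNP count table as minimal VCF
#'
#' Two samples (G, Y) with AD-format allelic depths, VCF 4.2.
#'
#' @param x a \linkS4class{SnpCountTable}.
#' @param path output .vcf file.
#' @export
snpCountsToVcf <- function(x, path) {
  d <- snpCounts(x)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=digenicBSR",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "G", "Y"), collapse = "\t"))
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD\t%d,%d\t%d,%d",
                  d$chrom, d$pos, d$ref, d$alt,
                  d$ref_G, d$alt_G, d$ref_Y, d$alt_Y)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read pooled allelic depths from a minimal VCF
#'
#' Uses \code{VariantAnnotation::readVcf}; expects two samples named G and Y
#' carrying AD allelic depths.
#'
#' @param path VCF file path.
#' @return a \linkS4class{SnpCountTable}.
#' @export
vcfToSnpCounts <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(v)$AD
  if (is.null(ad)) stop(path, ": VCF lacks AD genotype field", call. = FALSE)
  if (!all(c("G", "Y") %in% colnames(ad)))
    stop(path, ": VCF must have samples G and Y", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(v)
  adG <- do.call(rbind, ad[, "G"])
  adY <- do.call(rbind, ad[, "Y"])
  SnpCountTable(data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = vapply(VariantAnnotation::alt(v), function(a)
      as.character(a)[1L], character(1L)),
    ref_G = adG[, 1L], alt_G = adG[, 2L],
    ref_Y = adY[, 1L], alt_Y = adY[, 2L]))
}

#' Read a pooled expression table from TSV
#'
#' Expected columns: gene_id, chrom, start, end, length_bp, count_G, count_Y.
#'
#' @param path TSV file path.
#' @param libSize optional length-2 numeric (G, Y) total mapped reads;
#'   defaults to the count column sums.
#' @return an \linkS4class{ExpressionTable}.
#' @export
readExpressionTable <- function(path, libSize = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  .checkColumns(d, c("gene_id", "chrom", "start", "end", "length_bp",
                     "count_G", "count_Y"), path)
  bad <- d$start > d$end
  if (any(bad))
    stop(sprintf("%s: start > end at line(s) %s", path, .badLines(bad)),
         call. = FALSE)
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end))
  S4Vectors::mcols(gr)$gene_id <- d$gene_id
  S4Vectors::mcols(gr)$length_bp <- d$length_bp
  cnt <- cbind(G = d$count_G, Y = d$count_Y)
  if (is.null(libSize)) libSize <- colSums(cnt)
  ExpressionTable(cnt, gr, libSize)
}

#' Write a pooled expression table to TSV
#' @param x an \linkS4class{ExpressionTable}.
#' @param path output file.
#' @export
writeExpressionTable <- function(x, path) {
  gr <- SummarizedExperiment::rowRanges(x)
  cnt <- SummarizedExperiment::assay(x, "counts")
  utils::write.table(data.frame(
    gene_id = S4Vectors::mcols(gr)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    length_bp = geneLengths(x),
    count_G = cnt[, "G"], count_Y = cnt[, "Y"]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker genotype table
#'
#' @param genoPath TSV of individuals x markers; first column \code{id},
#'   remaining columns A/H/B/"-" calls.
#' @param markersPath TSV with columns id, chrom, pos (one row per marker).
#' @return a \linkS4class{MarkerGenotypeTable}.
#' @export
readMarkerGenotypeTable <- function(genoPath, markersPath) {
  g <- utils::read.table(genoPath, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  mk <- utils::read.table(markersPath, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .checkColumns(mk, c("id", "chrom", "pos"), markersPath)
  mat <- as.matrix(g[, -1L, drop = FALSE])
  mat[mat == "-"] <- NA
  if (!identical(colnames(mat), mk$id))
    stop("genotype columns do not match the marker table", call. = FALSE)
  MarkerGenotypeTable(mat, mk)
}

#' Write a marker genotype table
#' @param x a \linkS4class{MarkerGenotypeTable}.
#' @param genoPath,markersPath output TSV files.
#' @export
writeMarkerGenotypeTable <- function(x, genoPath, markersPath) {
  g <- genotypeMatrix(x)
  g[is.na(g)] <- "-"
  utils::write.table(data.frame(id = seq_len(nrow(g)), g,
                                check.names = FALSE),
                     genoPath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(markerInfo(x), markersPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(genoPath)
}

#' Read a gene annotation from GFF3
#'
#' Imports via \code{rtracklayer}; keeps \code{gene} features when a type
#' column is present. Records with start > end are rejected with their line
#' numbers.
#'
#' @param path GFF3 file.
#' @return \code{GRanges} with mcols \code{gene_id}.
#' @export
readGeneAnnotation <- function(path) {
  ln <- readLines(path)
  body <- !startsWith(ln, "#") & nzchar(ln)
  fields <- strsplit(ln[body], "\t", fixed = TRUE)
  st <- suppressWarnings(vapply(fields, function(f) as.numeric(f[4L]),
                                numeric(1L)))
  en <- suppressWarnings(vapply(fields, function(f) as.numeric(f[5L]),
                                numeric(1L)))
  bad <- is.finite(st) & is.finite(en) & st > en
  if (any(bad))
    stop(sprintf("%s: start > end at line(s) %s", path,
                 paste(which(body)[bad], collapse = ", ")), call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  gid <- if (!is.null(mc$gene_id)) mc$gene_id else
    if (!is.null(mc$ID)) mc$ID else as.character(seq_along(gr))
  S4Vectors::mcols(gr)$gene_id <- gid
  names(gr) <- gid
  sort(gr)
}

#' Write a gene annotation as GFF3
#' @param gr \code{GRanges} with mcols \code{gene_id}.
#' @param path output .gff3 file.
#' @export
writeGeneAnnotationGff3 <- function(gr, path) {
  out <- gr
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    type = "gene",
    ID = S4Vectors::mcols(gr)$gene_id,
    gene_id = S4Vectors::mcols(gr)$gene_id)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Export a StudyDataset as TSV files
#'
#' Writes \code{individuals.tsv} (id, generation, family, mother, father,
#' phenotype, optionally per-locus mutant-allele dosage) and
#' \code{families.tsv} (family, generation, parents, phenotype counts).
#'
#' @param ds a \linkS4class{StudyDataset}.
#' @param dir output directory (created if needed).
#' @param genotypes include per-locus dosage columns.
#' @return the directory, invisibly.
#' @export
writeStudyDataset <- function(ds, dir, genotypes = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pops <- studyPopulations(ds)
  ind <- do.call(rbind, lapply(pops, function(p) p@info))
  rownames(ind) <- NULL
  if (genotypes) {
    lo <- ds@genome@loci
    dos <- do.call(rbind, lapply(pops, function(p) {
      do.call(cbind, lapply(names(p@haps), function(cc)
        p@haps[[cc]]$h1 + p@haps[[cc]]$h2))
    }))
    colnames(dos) <- unlist(lapply(unique(lo$chrom), function(cc)
      lo$id[lo$chrom == cc]))
    ind <- cbind(ind, dos)
  }
  utils::write.table(ind, file.path(dir, "individuals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fam <- do.call(rbind, lapply(names(pops), function(nm) {
    p <- pops[[nm]]
    pc <- phenotypeCounts(p, byFamily = TRUE)
    pc$generation <- p@info$generation[match(pc$family, p@info$family)]
    pc$mother <- p@info$mother[match(pc$family, p@info$family)]
    pc$father <- p@info$father[match(pc$family, p@info$family)]
    pc
  }))
  utils::write.table(fam, file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load and validate analysis input tables
#'
#' Convenience loader for the analysis-side inputs: any subset of
#' \code{snp} (SNP count TSV), \code{vcf} (minimal VCF), \code{expression}
#' (expression TSV), \code{markers} (list of geno/markers TSV paths) and
#' \code{annotation} (GFF3).
#'
#' @param paths named list of file paths.
#' @return named list of validated domain objects.
#' @export
loadTables <- function(paths) {
  out <- list()
  if (!is.null(paths$snp)) out$snp <- readSnpCountTable(paths$snp)
  if (!is.null(paths$vcf)) out$snp <- vcfToSnpCounts(paths$vcf)
  if (!is.null(paths$expression))
    out$expression <- readExpressionTable(paths$expression)
  if (!is.null(paths$markers))
    out$markers <- readMarkerGenotypeTable(paths$markers$geno,
                                           paths$markers$markers)
  if (!is.null(paths$annotation))
    out$annotation <- readGeneAnnotation(paths$annotation)
  out
}

#' Default pipeline configuration
#'
#' All tunables of the simulate-analyse-report driver with the study's
#' conditions as defaults: the crossing design sizes, extreme bulks of 100
#' plants at 30x depth, the > 3x depth screen, the top-1% ED^5 rule with a
#' 2 Mb clustering gap, the 3.84 chi-square critical value, and the DEG
#' thresholds |log2FC| >= 1, FDR <= 0.05 with a synthetic DE scenario of 90
#' upregulated and 91 downregulated genes (the causal genes among the
#' downregulated).
#'
#' @param seed global seed; every stage seed is derived from it.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(markersPerChrom = 600L, genesPerChrom = 200L),
    design = list(p1Self = 92L, p2Self = 120L,
                  f1Forward = 258L, f1Reverse = 226L, f2 = 2376L,
                  bc1Wild = 669L, bc1Mutant = 720L,
                  f23Families = 20L, f23Size = 100L,
                  f34PerFamily = 8L, f34Size = 150L),
    linkage = list(mappingYellow = 1500L),
    bulk = list(size = 100L, meanDepth = 30, errorRate = 0.001),
    bsr = list(minDepth = 4L, topFraction = 0.01, maxGapBp = 2000000L,
               minLoci = 2L),
    segregation = list(critical = 3.84),
    deg = list(log2fcMin = 1, fdrMax = 0.05, rpkmMin = 0.1, pseudocount = 1),
    expression = list(nUp = 90L, nDownTotal = 91L, foldUp = 4,
                      foldDown = 0.25, causalFold = 0.25, baseCount = 300)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' \code{\link{pipelineConfig}}.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipelineConfig(seed = if (!is.null(user$seed)) user$seed else 1L)
  utils::modifyList(cfg, user)
}

#' Write a pipeline configuration to YAML
#' @param config configuration list.
#' @param path output file.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
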