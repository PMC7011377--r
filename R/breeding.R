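## Forward breeding simulator. Meiosis is a Poisson crossover process (no
## interference) on the cM axis: the number of crossovers between consecutive
## loci at genetic distance d Morgans is Poisson(d), so the recombination
## fraction between any two loci follows the Haldane transform
## r = (1 - exp(-2d)) / 2, which serves as the closed-form oracle in tests.

#' Phenotype from causal-locus genotypes
#'
#' The trait is digenic recessive epistatic: a plant is yellow (chlorophyll
#' deficient) if and only if it is homozygous for the mutant allele at every
#' causal locus; a single homozygous locus does not produce the phenotype.
#'
#' @param dosage mutant-allele dosage (0, 1 or 2) at each causal locus: a
#'   vector for one individual or a matrix (individuals x loci).
#' @return character vector "green"/"yellow".
#' @examples
#' phenotypeOf(c(2, 2))  # double homozygote -> yellow
#' phenotypeOf(c(1, 2))  # one locus heterozygous -> green
#' @export
phenotypeOf <- function(dosage) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1L)
  if (ncol(dosage) < 1L || anyNA(dosage))
    stop("malformed individual: missing causal genotype", call. = FALSE)
  if (!all(dosage %in% 0:2))
    stop("causal dosages must be 0, 1 or 2", call. = FALSE)
  ifelse(rowSums(dosage == 2L) == ncol(dosage), "yellow", "green")
}

## n gametes from one parent chromosome (h1, h2 allele vectors, loci at cM).
## Poisson crossover increments between consecutive loci; the strand at the
## first locus is chosen fairly.
.chromGametes <- function(h1, h2, cM, n) {
  m <- length(cM)
  start <- sample.int(2L, n, replace = TRUE) - 1L
  if (m == 1L) {
    phase <- matrix(start, n, 1L)
  } else {
    lam <- diff(cM) / 100
    inc <- matrix(stats::rpois(n * (m - 1L), rep(lam, each = n)), nrow = n)
    if (m > 2L) for (j in 2:(m - 1L)) inc[, j] <- inc[, j] + inc[, j - 1L]
    phase <- cbind(start, (start + inc) %% 2L)
  }
  g <- matrix(rep(as.integer(h1), each = n), nrow = n)
  alt <- matrix(rep(as.integer(h2), each = n), nrow = n)
  sel <- phase == 1L
  g[sel] <- alt[sel]
  g
}

#' Draw gametes from one individual
#'
#' Simulates meioses for a single parent: per chromosome, crossover counts are
#' Poisson in the genetic length (no interference), breakpoints fall between
#' loci according to their cM spacing, and the starting haplotype is chosen
#' fairly. Chromosomes assort independently.
#'
#' @param pop a \linkS4class{Population} containing the parent.
#' @param individual row index of the parent in \code{pop}.
#' @param n number of gametes.
#' @return named list (per chromosome) of n x loci 0/1 allele matrices.
#' @export
drawGametes <- function(pop, individual = 1L, n = 1L) {
  lo <- pop@genome@loci
  lapply(stats::setNames(nm = names(pop@haps)), function(cc) {
    hh <- pop@haps[[cc]]
    .chromGametes(hh$h1[individual, ], hh$h2[individual, ],
                  lo$cM[lo$chrom == cc], n)
  })
}

.newPopulation <- function(genome, haps, ids, generation, family = generation,
                           mother = NA_character_, father = NA_character_) {
  ca <- genome@causal
  lo <- genome@loci
  n <- length(ids)
  dos <- matrix(NA_integer_, n, nrow(ca))
  for (j in seq_len(nrow(ca))) {
    cc <- ca$chrom[j]
    idx <- which(lo$pos[lo$chrom == cc] == ca$pos[j] & lo$causal[lo$chrom == cc])
    dos[, j] <- haps[[cc]]$h1[, idx] + haps[[cc]]$h2[, idx]
  }
  info <- data.frame(id = ids, generation = generation,
                     family = rep_len(family, n),
                     mother = rep_len(mother, n), father = rep_len(father, n),
                     phenotype = phenotypeOf(dos))
  new("Population", genome = genome, info = info, haps = haps)
}

#' Create a founder line
#'
#' Fully homozygous (doubled-haploid) founders: the wild parent carries the
#' reference allele at every marker and the wild allele at the causal loci;
#' the mutant parent carries the alternate/mutant allele everywhere, so all
#' markers are informative in crosses between them.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param type \code{"wild"} or \code{"mutant"}.
#' @param id individual id.
#' @return a \linkS4class{Population} of one individual.
#' @export
makeFounder <- function(genome, type = c("wild", "mutant"), id = type) {
  type <- match.arg(type)
  allele <- if (type == "wild") 0L else 1L
  lo <- genome@loci
  haps <- lapply(stats::setNames(nm = unique(lo$chrom)), function(cc) {
    m <- sum(lo$chrom == cc)
    h <- matrix(allele, 1L, m)
    list(h1 = h, h2 = h)
  })
  .newPopulation(genome, haps, ids = id, generation = "P",
                 family = type)
}

#' Cross (or self) two parents
#'
#' Each offspring unites one independently drawn gamete from each parent;
#' selfing is the same operation with both parents equal. Phenotypes are
#' assigned from the causal-locus genotypes.
#'
#' @param mother,father \linkS4class{Population} objects holding the parents.
#' @param n number of offspring.
#' @param motherIndex,fatherIndex parent row indices.
#' @param generation generation label for the offspring.
#' @param family family label.
#' @param prefix id prefix (defaults to the family label).
#' @return a \linkS4class{Population} of \code{n} offspring.
#' @export
makeOffspring <- function(mother, father = mother, n,
                          motherIndex = 1L, fatherIndex = 1L,
                          generation = "F1", family = generation,
                          prefix = family) {
  stopifnot(n >= 1L)
  gm <- drawGametes(mother, motherIndex, n)
  gf <- drawGametes(father, fatherIndex, n)
  haps <- lapply(stats::setNames(nm = names(gm)), function(cc)
    list(h1 = gm[[cc]], h2 = gf[[cc]]))
  .newPopulation(mother@genome, haps,
                 ids = sprintf("%s_%04d", prefix, seq_len(n)),
                 generation = generation, family = family,
                 mother = mother@info$id[motherIndex],
                 father = father@info$id[fatherIndex])
}

## Row-bind populations (same genome/loci); used to assemble family sets.
.bindPopulations <- function(pops) {
  g <- pops[[1L]]@genome
  info <- do.call(rbind, lapply(pops, function(p) p@info))
  rownames(info) <- NULL
  haps <- lapply(stats::setNames(nm = names(pops[[1L]]@haps)), function(cc) {
    list(h1 = do.call(rbind, lapply(pops, function(p) p@haps[[cc]]$h1)),
         h2 = do.call(rbind, lapply(pops, function(p) p@haps[[cc]]$h2)))
  })
  new("Population", genome = g, info = info, haps = haps)
}

#' Default study design
#'
#' Family sizes follow the source study's generation totals: reciprocal F1 of
#' 258 and 226, an F2 of 2376, backcrosses of 669 (to the wild parent) and 720
#' (to the mutant), twenty F2:3 families from selfed green F2 plants, and
#' eight green plants selfed per 3:1-segregating F2:3 family to give F3:4
#' families. F2:3/F3:4 family sizes are simulation choices (the study does not
#' print them).
#'
#' @param p1Self,p2Self selfed-progeny sizes of the wild and mutant parent
#'   lines (phenotype-confirmation rows of the segregation table).
#' @param f1Forward,f1Reverse,f2,bc1Wild,bc1Mutant generation sizes.
#' @param f23Families number of green F2 plants selfed.
#' @param f23Size individuals per F2:3 family.
#' @param f34PerFamily green plants selfed per 3:1-segregating F2:3 family.
#' @param f34Size individuals per F3:4 family.
#' @param generations which generations to simulate (subsets speed up
#'   segregation-only experiments).
#' @param seed integer seed for the simulation.
#' @return a design list for \code{\link{simulateStudy}}.
#' @export
studyDesign <- function(p1Self = 92L, p2Self = 120L,
                        f1Forward = 258L, f1Reverse = 226L, f2 = 2376L,
                        bc1Wild = 669L, bc1Mutant = 720L,
                        f23Families = 20L, f23Size = 100L,
                        f34PerFamily = 8L, f34Size = 100L,
                        generations = c("F1", "F2", "BC1", "F23", "F34"),
                        seed = 1L) {
  list(p1Self = p1Self, p2Self = p2Self,
       f1Forward = f1Forward, f1Reverse = f1Reverse, f2 = f2,
       bc1Wild = bc1Wild, bc1Mutant = bc1Mutant,
       f23Families = f23Families, f23Size = f23Size,
       f34PerFamily = f34PerFamily, f34Size = f34Size,
       generations = generations, seed = seed)
}

#' Simulate the full crossing design
#'
#' Propagates the digenic recessive trait through the study's breeding
#' scheme: reciprocal F1s between the wild and mutant founders, an F2 from
#' selfed F1, backcrosses of the F1 to both parents, F2:3 families from
#' randomly chosen selfed green F2 plants, and F3:4 families from selfed green
#' plants of the F2:3 families that segregate 3:1 (classified from their
#' observed counts, as in the study).
#'
#' @param design list from \code{\link{studyDesign}}.
#' @param genome a \linkS4class{GenomeModel}.
#' @return a \linkS4class{StudyDataset}.
#' @examples
#' ds <- simulateStudy(studyDesign(f2 = 320, generations = c("F1", "F2"),
#'                                 seed = 7),
#'                     makeGenomeModel(markersPerChrom = 5))
#' phenotypeCounts(studyPopulation(ds, "F2"))
#' @export
simulateStudy <- function(design = studyDesign(), genome = makeGenomeModel()) {
  set.seed(.stageSeed(design$seed, 1L))
  gens <- design$generations
  pops <- list()
  p1 <- makeFounder(genome, "wild", id = "P1_wild")
  p2 <- makeFounder(genome, "mutant", id = "P2_mutant")
  pops$P1 <- p1
  pops$P2 <- p2
  pops$P1_line <- makeOffspring(p1, p1, n = design$p1Self,
                                generation = "P1_line", family = "P1_line")
  pops$P2_line <- makeOffspring(p2, p2, n = design$p2Self,
                                generation = "P2_line", family = "P2_line")
  f1f <- makeOffspring(p1, p2, n = max(design$f1Forward, 1L),
                       generation = "F1", family = "F1_forward")
  if ("F1" %in% gens) {
    pops$F1_forward <- f1f
    pops$F1_reverse <- makeOffspring(p2, p1, n = design$f1Reverse,
                                     generation = "F1", family = "F1_reverse")
  }
  if (any(c("F2", "F23", "F34") %in% gens)) {
    set.seed(.stageSeed(design$seed, 2L))
    f2 <- makeOffspring(f1f, f1f, n = design$f2, generation = "F2",
                        family = "F2")
    pops$F2 <- f2
  }
  if ("BC1" %in% gens) {
    set.seed(.stageSeed(design$seed, 3L))
    pops$BC1_wild <- makeOffspring(f1f, p1, n = design$bc1Wild,
                                   generation = "BC1", family = "BC1_wild")
    pops$BC1_mutant <- makeOffspring(f1f, p2, n = design$bc1Mutant,
                                     generation = "BC1", family = "BC1_mutant")
  }
  if (any(c("F23", "F34") %in% gens)) {
    set.seed(.stageSeed(design$seed, 4L))
    greenIdx <- which(phenotypes(pops$F2) == "green")
    if (length(greenIdx) < design$f23Families)
      stop("not enough green F2 plants for the requested F2:3 families",
           call. = FALSE)
    sel <- sample(greenIdx, design$f23Families)
    fams <- lapply(seq_along(sel), function(k)
      makeOffspring(pops$F2, pops$F2, n = design$f23Size,
                    motherIndex = sel[k], fatherIndex = sel[k],
                    generation = "F23", family = sprintf("F23_%02d", k)))
    pops$F23 <- .bindPopulations(fams)
  }
  if ("F34" %in% gens) {
    set.seed(.stageSeed(design$seed, 5L))
    cls <- classifyFamily(phenotypeCounts(pops$F23, byFamily = TRUE))
    segFams <- cls$family[cls$class == "seg_3_1"]
    if (!length(segFams))
      stop("no F2:3 family segregated 3:1; re-seed or enlarge the design",
           call. = FALSE)
    f34 <- list()
    k <- 0L
    for (fam in segFams) {
      inFam <- which(pops$F23@info$family == fam &
                       phenotypes(pops$F23) == "green")
      parents <- sample(inFam, min(design$f34PerFamily, length(inFam)))
      for (pi in parents) {
        k <- k + 1L
        f34[[k]] <- makeOffspring(pops$F23, pops$F23, n = design$f34Size,
                                  motherIndex = pi, fatherIndex = pi,
                                  generation = "F34",
                                  family = sprintf("F34_%02d", k))
      }
    }
    pops$F34 <- .bindPopulations(f34)
  }
  new("StudyDataset", genome = genome, populations = pops, design = design)
}
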