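## Segregation-ratio statistics for green/yellow counts, and the exact
## expectations of the digenic recessive model obtained by gamete
## enumeration (never hard-coded).

#' Observed phenotype ratio
#'
#' Green plants per one yellow plant, rounded half-up to two decimals as in
#' published segregation tables.
#'
#' @param green,yellow phenotype counts (vectors allowed).
#' @return numeric ratio(s).
#' @examples
#' phenotypeRatio(2243, 133)  # 16.86
#' @export
phenotypeRatio <- function(green, yellow) {
  if (any(yellow == 0))
    stop("ratio undefined for all-green families (no yellow plants)",
         call. = FALSE)
  roundHalfUp(green / yellow, 2L)
}

#' Chi-square goodness of fit to a phenotypic ratio
#'
#' One-degree-of-freedom goodness-of-fit chi-square of observed green/yellow
#' counts against a hypothesised ratio, with Yates continuity correction
#' (each deviation reduced by 0.5 and truncated at zero) by default. The
#' correction reproduces published digenic segregation statistics; it can be
#' disabled.
#'
#' @param green,yellow observed counts (vectors allowed).
#' @param ratio length-2 numeric, hypothesised green:yellow ratio.
#' @param correct apply the Yates continuity correction.
#' @return chi-square value(s), df = 1.
#' @examples
#' chiSquareYates(2243, 133, c(15, 1))  # 1.616...
#' chiSquareYates(551, 169, c(3, 1))    # 0.816...
#' @export
chiSquareYates <- function(green, yellow, ratio = c(15, 1), correct = TRUE) {
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  n <- green + yellow
  if (any(n <= 0)) stop("empty family", call. = FALSE)
  eG <- n * ratio[1L] / sum(ratio)
  eY <- n * ratio[2L] / sum(ratio)
  if (any(eG == 0) || any(eY == 0)) stop("zero expected count", call. = FALSE)
  dG <- abs(green - eG)
  dY <- abs(yellow - eY)
  if (correct) {
    dG <- pmax(dG - 0.5, 0)
    dY <- pmax(dY - 0.5, 0)
  }
  dG^2 / eG + dY^2 / eY
}

#' Segregation-ratio test report
#'
#' Convenience wrapper assembling the published-table row: observed ratio,
#' Yates chi-square against the hypothesis and the consistency call at the
#' df = 1 critical value.
#'
#' @inheritParams chiSquareYates
#' @param critical chi-square critical value (default 3.84, df = 1,
#'   alpha = 0.05).
#' @return data.frame with total, green, yellow, hypothesis, observed_ratio,
#'   chi2 and consistent columns.
#' @export
segregationTest <- function(green, yellow, ratio = c(15, 1), correct = TRUE,
                            critical = 3.84) {
  chi2 <- chiSquareYates(green, yellow, ratio, correct)
  data.frame(total = green + yellow, green = green, yellow = yellow,
             hypothesis = paste0(ratio[1L], ":", ratio[2L]),
             observed_ratio = ifelse(yellow > 0,
                                     roundHalfUp(green / yellow, 2L), NA_real_),
             chi2 = chi2, critical = critical, consistent = chi2 < critical)
}

#' Classify a family's segregation pattern
#'
#' A family with no yellow plants is \code{all_green}; otherwise it is tested
#' against the 3:1 and 15:1 hypotheses and assigned the one with chi-square
#' below the critical value (the smaller chi-square if both pass), or
#' \code{other} if neither fits.
#'
#' @param green counts vector, or a data.frame with \code{green} and
#'   \code{yellow} columns (and optionally \code{family}).
#' @param yellow counts vector (ignored when \code{green} is a data.frame).
#' @param critical chi-square critical value (df = 1).
#' @param correct apply Yates continuity correction.
#' @return data.frame with \code{class} in \{all_green, seg_3_1, seg_15_1,
#'   other\} and the supporting chi-square values.
#' @export
classifyFamily <- function(green, yellow = NULL, critical = 3.84,
                           correct = TRUE) {
  fam <- NULL
  if (is.data.frame(green)) {
    fam <- green$family
    yellow <- green$yellow
    green <- green$green
  }
  n <- length(green)
  chi31 <- chi151 <- rep(NA_real_, n)
  cls <- character(n)
  hasY <- yellow > 0
  cls[!hasY] <- "all_green"
  if (any(hasY)) {
    chi31[hasY] <- chiSquareYates(green[hasY], yellow[hasY], c(3, 1), correct)
    chi151[hasY] <- chiSquareYates(green[hasY], yellow[hasY], c(15, 1), correct)
    pass31 <- hasY & chi31 < critical
    pass151 <- hasY & chi151 < critical
    cls[pass31 & (!pass151 | chi31 <= chi151)] <- "seg_3_1"
    cls[pass151 & (!pass31 | chi151 < chi31)] <- "seg_15_1"
    cls[hasY & !pass31 & !pass151] <- "other"
  }
  out <- data.frame(green = green, yellow = yellow, chi2_3_1 = chi31,
                    chi2_15_1 = chi151, class = cls)
  if (!is.null(fam)) out <- cbind(family = fam, out)
  out
}

## ---- exact digenic enumeration -------------------------------------------

## Gamete distribution of one diploid genotype: matrix of gametes (rows,
## one column per causal locus, allele 0/1) with integer weights summing to
## 2^k. Exact integer arithmetic throughout.
.enumGametes <- function(dosage) {
  alleles <- lapply(dosage, function(d)
    switch(as.character(d),
           "0" = data.frame(a = 0L, w = 2L),
           "1" = data.frame(a = c(0L, 1L), w = c(1L, 1L)),
           "2" = data.frame(a = 1L, w = 2L)))
  grid <- expand.grid(lapply(alleles, function(x) seq_len(nrow(x))))
  g <- mapply(function(al, idx) al$a[idx], alleles, grid, SIMPLIFY = FALSE)
  wm <- mapply(function(al, idx) al$w[idx], alleles, grid, SIMPLIFY = FALSE)
  w <- Reduce(`*`, wm)
  list(gametes = matrix(as.integer(unlist(g)), ncol = length(dosage)),
       weights = as.integer(w))
}

## Offspring genotype distribution of a cross: data.frame of dosage columns
## plus an integer weight column (common denominator 4^k per cross).
.enumOffspring <- function(dosageMother, dosageFather = dosageMother) {
  gm <- .enumGametes(dosageMother)
  gf <- .enumGametes(dosageFather)
  k <- ncol(gm$gametes)
  rows <- list()
  for (i in seq_along(gm$weights)) {
    for (j in seq_along(gf$weights)) {
      rows[[length(rows) + 1L]] <- c(gm$gametes[i, ] + gf$gametes[j, ],
                                     gm$weights[i] * gf$weights[j])
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(tab[, k + 1L],
                          by = as.data.frame(tab[, seq_len(k), drop = FALSE]),
                          FUN = sum)
  names(agg) <- c(paste0("L", seq_len(k)), "weight")
  agg
}

## Probability (exact fraction as weight/total) that selfing a genotype gives
## a yellow offspring, and the implied family type.
.familyTypeOfGenotype <- function(dosage) {
  off <- .enumOffspring(dosage)
  k <- length(dosage)
  dos <- as.matrix(off[, seq_len(k), drop = FALSE])
  yellowW <- sum(off$weight[rowSums(dos == 2L) == k])
  totalW <- sum(off$weight)
  if (yellowW == 0L) return("all_green")
  ## exact dyadic fractions: compare to 1/4 and 1/16
  if (yellowW * 4L == totalW) return("seg_3_1")
  if (yellowW * 16L == totalW) return("seg_15_1")
  "other"
}

#' Exact expectations of the digenic recessive model
#'
#' Expected compositions computed by exhaustive enumeration of parental
#' gamete combinations (with exact integer weights), then conditioning as the
#' breeding design dictates:
#' \itemize{
#'   \item \code{F2_phenotypes}: green:yellow in the F2 of a double
#'     heterozygote self (15:1).
#'   \item \code{BC1_mutant_phenotypes}: green:yellow in the backcross of the
#'     F1 to the double mutant (3:1).
#'   \item \code{F23_family_types}: all_green : 3:1-segregating :
#'     15:1-segregating families among selfed green F2 plants (7:4:4).
#'   \item \code{F34_family_types}: 3:1-segregating : all_green families
#'     among selfed green plants of a 3:1 family (2:1).
#' }
#'
#' @param tag one of the four composition tags above.
#' @return named integer vector giving the expected ratio in lowest terms.
#' @examples
#' expectedComposition("F2_phenotypes")
#' expectedComposition("F23_family_types")
#' @export
expectedComposition <- function(tag = c("F2_phenotypes",
                                        "BC1_mutant_phenotypes",
                                        "F23_family_types",
                                        "F34_family_types")) {
  tag <- match.arg(tag)
  het <- c(1L, 1L)
  mut <- c(2L, 2L)
  if (tag == "F2_phenotypes") {
    off <- .enumOffspring(het)
    dos <- as.matrix(off[, 1:2])
    ph <- phenotypeOf(dos)
    w <- c(green = sum(off$weight[ph == "green"]),
           yellow = sum(off$weight[ph == "yellow"]))
    return(stats::setNames(.simplifyRatio(w), names(w)))
  }
  if (tag == "BC1_mutant_phenotypes") {
    off <- .enumOffspring(het, mut)
    dos <- as.matrix(off[, 1:2])
    ph <- phenotypeOf(dos)
    w <- c(green = sum(off$weight[ph == "green"]),
           yellow = sum(off$weight[ph == "yellow"]))
    return(stats::setNames(.simplifyRatio(w), names(w)))
  }
  if (tag == "F23_family_types") {
    f2 <- .enumOffspring(het)
    dos <- as.matrix(f2[, 1:2])
    green <- phenotypeOf(dos) == "green"
    types <- vapply(which(green), function(i) .familyTypeOfGenotype(dos[i, ]),
                    character(1L))
    w <- vapply(c("all_green", "seg_3_1", "seg_15_1"), function(tt)
      sum(f2$weight[green][types == tt]), integer(1L))
    return(stats::setNames(.simplifyRatio(w), names(w)))
  }
  ## F34_family_types: parent family segregates 3:1, i.e. heterozygous at one
  ## locus and homozygous mutant at the other; enumerate its selfed green
  ## offspring and type their own selfed families.
  fam <- .enumOffspring(c(1L, 2L))
  dos <- as.matrix(fam[, 1:2])
  green <- phenotypeOf(dos) == "green"
  types <- vapply(which(green), function(i) .familyTypeOfGenotype(dos[i, ]),
                  character(1L))
  w <- vapply(c("seg_3_1", "all_green"), function(tt)
    sum(fam$weight[green][types == tt]), integer(1L))
  stats::setNames(.simplifyRatio(w), names(w))
}

#' Infer nuclear vs cytoplasmic inheritance from reciprocal F1s
#'
#' Reciprocal F1 families with the same phenotype distribution indicate
#' nuclear inheritance; a phenotype tracking the maternal parent (the
#' reciprocal families differing) suggests cytoplasmic inheritance. The
#' comparison is a two-sided Fisher exact test of the two green/yellow
#' distributions.
#'
#' @param f1Forward,f1Reverse length-2 integer vectors
#'   \code{c(green, yellow)} for the two reciprocal F1 families.
#' @param alpha significance level for declaring the distributions different.
#' @return \code{"nuclear"} or \code{"cytoplasmic_suspected"}.
#' @examples
#' inferInheritanceMode(c(258, 0), c(226, 0))  # "nuclear"
#' @export
inferInheritanceMode <- function(f1Forward, f1Reverse, alpha = 0.05) {
  if (sum(f1Forward) == 0 || sum(f1Reverse) == 0)
    stop("empty reciprocal F1 family", call. = FALSE)
  tab <- rbind(f1Forward, f1Reverse)
  if (all(colSums(tab) > 0)) {
    p <- stats::fisher.test(tab)$p.value
  } else {
    p <- 1  # both families monomorphic for the same phenotype
  }
  if (p < alpha) "cytoplasmic_suspected" else "nuclear"
}
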