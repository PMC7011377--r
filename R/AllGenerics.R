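#' @export
setGeneric("genomeModel", function(x) standardGeneric("genomeModel"))

#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @export
setGeneric("phenotypeCounts", function(x, ...) standardGeneric("phenotypeCounts"))

#' @export
setGeneric("causalGenotypes", function(x) standardGeneric("causalGenotypes"))

#' @export
setGeneric("markerGenotypes", function(x, markers, ...) standardGeneric("markerGenotypes"))

#' @export
setGeneric("snpCounts", function(x) standardGeneric("snpCounts"))

#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))

#' @export
setGeneric("studyPopulations", function(x) standardGeneric("studyPopulations"))

#' @export
setGeneric("studyPopulation", function(x, name) standardGeneric("studyPopulation"))
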