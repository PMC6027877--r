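#' @rdname HSCohort-class
#' @param object,x an object
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname HSCohort-class
#' @export
setGeneric("markerPanel", function(x) standardGeneric("markerPanel"))

#' @rdname HSCohort-class
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' Number of informative meioses represented by a pedigree or cohort
#'
#' Two meioses (one per transmitting parent) are counted for every
#' final-generation offspring whose sire and dam are both genotyped.
#'
#' @param x a [Pedigree] or [HSCohort]
#' @return integer meiosis count
#' @export
setGeneric("meiosisCount", function(x) standardGeneric("meiosisCount"))

#' Chromosomes covered by an object
#' @param x an object with chromosome-structured content
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' Marker table of a genetic map
#' @param x a [GeneticMap]
#' @export
setGeneric("mapMarkers", function(x) standardGeneric("mapMarkers"))

#' Total genetic length per chromosome
#'
#' @param x a [GeneticMap] or [MapModel]
#' @param sex one of "avg", "male", "female"
#' @return named numeric, cM per chromosome
#' @export
setGeneric("totalLength", function(x, sex = "avg") standardGeneric("totalLength"))

#' @rdname MapModel-class
#' @param x a [MapModel]
#' @export
setGeneric("modelAnchors", function(x) standardGeneric("modelAnchors"))

#' Dosage accessor for an F2 cross
#' @rdname F2Cross-class
#' @export
setGeneric("crossGeno", function(x) standardGeneric("crossGeno"))

#' @rdname F2Cross-class
#' @export
setGeneric("crossPheno", function(x) standardGeneric("crossPheno"))

#' @rdname F2Cross-class
#' @export
setGeneric("crossMap", function(x) standardGeneric("crossMap"))

#' LOD grid of a QTL scan
#' @rdname QtlScan-class
#' @export
setGeneric("scanGrid", function(x) standardGeneric("scanGrid"))

#' @rdname QtlScan-class
#' @export
setGeneric("scanPeaks", function(x) standardGeneric("scanPeaks"))

#' @rdname QtlScan-class
#' @export
setGeneric("scanThresholds", function(x) standardGeneric("scanThresholds"))
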