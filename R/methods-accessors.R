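#' @rdname HSCohort-class
#' @export
setMethod("dosage", "HSCohort", function(x) assay(x, "dosage"))

#' @rdname HSCohort-class
#' @export
setMethod("markerPanel", "HSCohort", function(x) {
    gr <- rowRanges(x)
    new("MarkerPanel", gr)
})

#' @rdname HSCohort-class
#' @export
setMethod("pedigree", "HSCohort", function(x) {
    new("Pedigree", colData(x)[, c("id", "sire", "dam", "sex", "family", "generation")])
})

#' @rdname meiosisCount
#' @export
setMethod("meiosisCount", "Pedigree", function(x) {
    kids <- !is.na(x$sire) & !is.na(x$dam) &
        x$sire %in% x$id & x$dam %in% x$id
    2L * sum(kids)
})

#' @rdname meiosisCount
#' @export
setMethod("meiosisCount", "HSCohort", function(x) meiosisCount(pedigree(x)))

#' @rdname chromosomes
#' @export
setMethod("chromosomes", "MarkerPanel", function(x)
    unique(as.character(seqnames(x))))

#' @rdname chromosomes
#' @export
setMethod("chromosomes", "GeneticMap", function(x) unique(x@markers$chrom))

#' @rdname chromosomes
#' @export
setMethod("chromosomes", "MapModel", function(x) names(x@anchors))

#' @rdname chromosomes
#' @export
setMethod("chromosomes", "TrueRecombinationMap", function(x) x@chromosomes)

#' @rdname mapMarkers
#' @export
setMethod("mapMarkers", "GeneticMap", function(x) x@markers)

#' @rdname totalLength
#' @export
setMethod("totalLength", "GeneticMap", function(x, sex = "avg") {
    col <- paste0("cM_", match.arg(sex, c("avg", "male", "female")))
    vapply(split(x@markers[[col]], x@markers$chrom),
           function(v) if (length(v)) v[length(v)] else 0, numeric(1))
})

#' @rdname totalLength
#' @export
setMethod("totalLength", "MapModel", function(x, sex = "avg") {
    col <- paste0("cM_", match.arg(sex, c("avg", "male", "female")))
    vapply(x@anchors, function(a) a[[col]][nrow(a)], numeric(1))
})

#' @rdname modelAnchors
#' @export
setMethod("modelAnchors", "MapModel", function(x) x@anchors)

#' @rdname F2Cross-class
#' @export
setMethod("crossGeno", "F2Cross", function(x) x@geno)

#' @rdname F2Cross-class
#' @export
setMethod("crossPheno", "F2Cross", function(x) x@pheno)

#' @rdname F2Cross-class
#' @export
setMethod("crossMap", "F2Cross", function(x) x@map)

#' @rdname QtlScan-class
#' @export
setMethod("scanGrid", "QtlScan", function(x) x@grid)

#' @rdname QtlScan-class
#' @export
setMethod("scanPeaks", "QtlScan", function(x) x@peaks)

#' @rdname QtlScan-class
#' @export
setMethod("scanThresholds", "QtlScan", function(x) x@thresholds)

setMethod("show", "Pedigree", function(object) {
    cat(sprintf("Pedigree: %d individuals, %d families, %d meioses\n",
                nrow(object), length(unique(object$family)),
                meiosisCount(object)))
})

setMethod("show", "HSCohort", function(object) {
    cat(sprintf("HSCohort: %d markers x %d individuals (%d meioses)\n",
                nrow(object), ncol(object), meiosisCount(object)))
    cat(sprintf("  chromosomes: %s\n",
                paste(chromosomes(markerPanel(object)), collapse = ", ")))
    miss <- mean(is.na(assay(object, "dosage")))
    cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

setMethod("show", "GeneticMap", function(object) {
    m <- object@markers
    cat(sprintf("GeneticMap: %d markers on %d chromosome(s)\n",
                nrow(m), length(unique(m$chrom))))
    tot <- function(col) sum(vapply(split(m[[col]], m$chrom),
                             function(v) v[length(v)], numeric(1)))
    cat(sprintf("  total cM: male %.1f, female %.1f, averaged %.1f\n",
                tot("cM_male"), tot("cM_female"), tot("cM_avg")))
})

setMethod("show", "MapModel", function(object) {
    cat(sprintf("MapModel: monotone cubic cM(bp) on %d chromosome(s), %d anchors\n",
                length(object@anchors),
                sum(vapply(object@anchors, nrow, integer(1)))))
})

setMethod("show", "MeiosisSet", function(object) {
    cat(sprintf("MeiosisSet: %d meioses (%d paternal, %d maternal)\n",
                nrow(object@meioses),
                sum(object@meioses$parentSex == "male"),
                sum(object@meioses$parentSex == "female")))
    if (nrow(object@markerStats))
        cat(sprintf("  discordant markers: %d\n", sum(object@markerStats$discordant)))
})

setMethod("show", "F2Cross", function(object) {
    cat(sprintf("F2Cross: %d individuals, %d markers on %d chromosome(s)\n",
                nrow(object@geno), ncol(object@geno),
                length(unique(object@map$chrom))))
})

setMethod("show", "QtlScan", function(object) {
    cat(sprintf("QtlScan: %d grid points, max LOD %.2f\n",
                nrow(object@grid), suppressWarnings(max(object@grid$lod, na.rm = TRUE))))
    if (length(object@thresholds))
        cat("  thresholds:", paste(sprintf("%s=%.2f", names(object@thresholds),
                                           object@thresholds), collapse = ", "), "\n")
})

setMethod("show", "QtlComparison", function(object) {
    t <- object@table
    cat(sprintf("QtlComparison: %d QTL, %d detected in both, %d shifted > %g cM\n",
                nrow(t), sum(t$detected_in_both),
                sum(t$shifted, na.rm = TRUE), object@shiftThreshold))
})
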