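#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start width
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowRanges
NULL

#' MarkerPanel: a genotyping marker panel with physical coordinates
#'
#' A `MarkerPanel` is a [GenomicRanges::GRanges] of width-1 positions
#' (1-based bp) carrying the metadata columns `marker_id`, `allele1` and
#' `allele2`. Within each chromosome positions are strictly increasing and
#' marker identifiers are unique genome-wide.
#'
#' @slot .Data see [GenomicRanges::GRanges]
#' @export
setClass("MarkerPanel", contains = "GRanges")

setValidity("MarkerPanel", function(object) {
    mc <- mcols(object)
    need <- c("marker_id", "allele1", "allele2")
    if (!all(need %in% colnames(mc)))
        return(paste("missing mcols:", paste(setdiff(need, colnames(mc)), collapse = ", ")))
    if (anyDuplicated(mc$marker_id))
        return("marker_id values must be unique genome-wide")
    if (any(width(object) != 1L))
        return("markers must be width-1 positions")
    if (any(start(object) < 1L))
        return("positions must be >= 1 (1-based)")
    for (ch in unique(as.character(seqnames(object)))) {
        p <- start(object)[as.character(seqnames(object)) == ch]
        if (is.unsorted(p, strictly = TRUE))
            return(sprintf("positions on %s are not strictly increasing", ch))
    }
    TRUE
})

#' Pedigree of genotyped individuals
#'
#' Wraps a [S4Vectors::DataFrame] with columns `id`, `sire`, `dam`
#' (`NA` for founders), `sex` ("male"/"female"), `family` and `generation`.
#' Parents precede offspring in generation, sires are male, dams female,
#' and an individual has either both parents recorded or neither.
#'
#' @export
setClass("Pedigree", contains = "DFrame")

setValidity("Pedigree", function(object) {
    need <- c("id", "sire", "dam", "sex", "family", "generation")
    if (!all(need %in% colnames(object)))
        return(paste("missing columns:", paste(setdiff(need, colnames(object)), collapse = ", ")))
    if (anyDuplicated(object$id)) return("individual ids must be unique")
    if (!all(object$sex %in% c("male", "female")))
        return("sex must be 'male' or 'female'")
    if (any(xor(is.na(object$sire), is.na(object$dam))))
        return("individuals must have both parents or neither")
    gen <- setNames(object$generation, object$id)
    sx <- setNames(object$sex, object$id)
    kid <- !is.na(object$sire)
    if (any(kid)) {
        s <- object$sire[kid]; d <- object$dam[kid]
        if (!all(s %in% object$id) || !all(d %in% object$id))
            return("parents must be present in the pedigree")
        if (any(sx[s] != "male")) return("sires must be male")
        if (any(sx[d] != "female")) return("dams must be female")
        if (any(gen[s] >= object$generation[kid]) || any(gen[d] >= object$generation[kid]))
            return("parents must precede offspring in generation")
    }
    TRUE
})

#' True (generative) recombination map
#'
#' Per chromosome and sex, a piecewise-linear cM(bp) landscape given by
#' anchor points with cM(first) = 0. Used as simulation ground truth.
#'
#' @slot chromosomes chromosome labels
#' @slot lengthsBp named numeric, chromosome lengths in bp
#' @slot anchors named list of data.frames with columns `bp`, `cM_male`,
#'   `cM_female`
#' @export
setClass("TrueRecombinationMap", representation(
    chromosomes = "character",
    lengthsBp = "numeric",
    anchors = "list"
))

setValidity("TrueRecombinationMap", function(object) {
    if (!identical(object@chromosomes, names(object@anchors)))
        return("anchors must be named by chromosome")
    for (ch in object@chromosomes) {
        a <- object@anchors[[ch]]
        if (!all(c("bp", "cM_male", "cM_female") %in% colnames(a)))
            return("anchor tables need bp, cM_male, cM_female")
        if (a$cM_male[1] != 0 || a$cM_female[1] != 0)
            return("anchor cM must start at 0")
        if (is.unsorted(a$bp, strictly = TRUE)) return("anchor bp must increase")
        if (is.unsorted(a$cM_male) || is.unsorted(a$cM_female))
            return("anchor cM must be non-decreasing")
    }
    TRUE
})

#' Simulated cohort ground truth
#'
#' Records every simulated crossover (offspring meioses and the meioses that
#' formed parent haplotypes), the founder-strain blocks of every haplotype,
#' and every corrupted or masked genotype call.
#'
#' @export
setClass("CohortTruth", representation(
    crossovers = "data.frame",
    founderBlocks = "data.frame",
    corrupted = "data.frame",
    displaced = "character",
    gametes = "list",
    parentHaplotypes = "list"
))

#' HS cohort genotypes
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with a `"dosage"`
#' assay (markers x individuals, counts of `allele2` in 0:2, `NA` missing),
#' marker coordinates as `rowRanges` (a [MarkerPanel]) and pedigree columns
#' in `colData`.
#'
#' @export
setClass("HSCohort", contains = "RangedSummarizedExperiment")

setValidity("HSCohort", function(object) {
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        return("an HSCohort needs a 'dosage' assay")
    d <- assay(object, "dosage")
    if (!all(d[!is.na(d)] %in% 0:2)) return("dosage values must be 0, 1, 2 or NA")
    need <- c("id", "sire", "dam", "sex", "family", "generation")
    if (!all(need %in% colnames(colData(object))))
        return("colData must carry the pedigree columns")
    TRUE
})

#' Phased transmissions extracted from a cohort
#'
#' Per meiosis (offspring x transmitting parent) and chromosome, the indices
#' of informative markers and the transmitted-haplotype indicator (0/1) after
#' phasing, chain-segment labels, and per-marker discordance statistics.
#'
#' @export
setClass("MeiosisSet", representation(
    meioses = "data.frame",
    transmissions = "list",
    transmissionsRaw = "list",
    markerStats = "data.frame",
    params = "list"
))

#' Per-interval recombination estimates for one sex
#' @export
setClass("IntervalEstimate", representation(
    sex = "character",
    intervals = "data.frame",
    markerOffsets = "data.frame",
    mappingFunction = "character"
))

#' A sex-specific genetic map
#'
#' Ordered markers per chromosome with physical position and cumulative
#' `cM_male`, `cM_female` and `cM_avg` (the arithmetic mean of the sex
#' tracks). Raw estimated maps may contain errant markers that break
#' monotonicity; [residualFilter()] removes them.
#'
#' @export
setClass("GeneticMap", representation(markers = "data.frame"))

setValidity("GeneticMap", function(object) {
    m <- object@markers
    need <- c("chrom", "marker_id", "bp", "cM_male", "cM_female", "cM_avg")
    if (!all(need %in% colnames(m)))
        return(paste("missing columns:", paste(setdiff(need, colnames(m)), collapse = ", ")))
    if (anyDuplicated(m$marker_id)) return("marker_id must be unique")
    for (ch in unique(m$chrom)) {
        i <- m$chrom == ch
        if (is.unsorted(m$bp[i]))
            return(sprintf("bp not sorted on %s", ch))
    }
    TRUE
})

#' Residual-filter report for one cleaning pass
#' @export
setClass("CleaningReport", representation(
    table = "data.frame",
    span = "numeric",
    threshold = "numeric"
))

#' Monotone cM(bp) interpolation model
#'
#' Per chromosome, deduplicated and isotonically projected anchors through
#' which a Fritsch--Carlson monotone cubic interpolant passes exactly for
#' each track (`cM_male`, `cM_female`, `cM_avg`). The derivative is the
#' local recombination rate.
#'
#' @export
setClass("MapModel", representation(
    anchors = "list",
    lengthsBp = "numeric"
))

setValidity("MapModel", function(object) {
    for (ch in names(object@anchors)) {
        a <- object@anchors[[ch]]
        if (is.unsorted(a$bp, strictly = TRUE)) return("anchor bp must increase")
        for (tr in c("cM_male", "cM_female", "cM_avg"))
            if (is.unsorted(a[[tr]])) return(sprintf("%s not monotone on %s", tr, ch))
    }
    TRUE
})

#' An F2 intercross for QTL scanning
#'
#' @slot pheno data.frame of phenotypes/covariates, one row per individual
#' @slot geno integer matrix (individuals x markers) of allele-B dosages
#'   0/1/2 with NA missing
#' @slot map data.frame with columns `marker`, `chrom`, `cM`, sorted by cM
#'   within chromosome
#' @export
setClass("F2Cross", representation(
    pheno = "data.frame",
    geno = "matrix",
    map = "data.frame"
))

setValidity("F2Cross", function(object) {
    if (nrow(object@pheno) != nrow(object@geno))
        return("pheno and geno must agree on individuals")
    if (ncol(object@geno) != nrow(object@map))
        return("geno columns must match map rows")
    if (!all(object@geno[!is.na(object@geno)] %in% 0:2))
        return("genotypes must be 0/1/2/NA")
    for (ch in unique(object@map$chrom)) {
        if (is.unsorted(object@map$cM[object@map$chrom == ch]))
            return(sprintf("map not sorted by cM on %s", ch))
    }
    TRUE
})

#' A genome scan by multiple imputation
#' @export
setClass("QtlScan", representation(
    grid = "data.frame",
    thresholds = "numeric",
    peaks = "data.frame",
    params = "list"
))

setValidity("QtlScan", function(object) {
    g <- object@grid
    if (!all(c("chrom", "cM", "lod") %in% colnames(g)))
        return("grid needs chrom, cM, lod")
    if (any(g$lod[!is.na(g$lod)] < -1e-8)) return("LOD must be non-negative")
    TRUE
})

#' Old-map vs new-map QTL comparison
#' @export
setClass("QtlComparison", representation(
    table = "data.frame",
    shiftThreshold = "numeric"
))

#' Genotype-QC report
#' @export
setClass("QcReport", representation(
    mendelRate = "numeric",
    removedMonomorphic = "character",
    removedMendel = "character",
    retainedAfterThinning = "character",
    flaggedNoTrio = "character"
))
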