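#' Construct a true (generative) recombination landscape
#'
#' Builds the piecewise-linear cM(bp) ground truth used by the simulator.
#' `shape = "linear"` gives a uniform rate per chromosome; `shape = "sine"`
#' modulates the rate sinusoidally around its mean (useful for testing
#' local-rate recovery) while preserving each chromosome's total length.
#'
#' @param lengthsBp named numeric, chromosome lengths in bp
#' @param cMMale,cMFemale named numeric, total male/female cM per chromosome
#'   (names matching `lengthsBp`)
#' @param shape "linear" or "sine"
#' @param amplitude relative rate modulation in (0, 1) for `shape = "sine"`
#' @param periods number of sine periods per chromosome
#' @param nAnchors anchors per chromosome used to discretize the landscape
#' @return a [TrueRecombinationMap]
#' @export
trueRecombinationMap <- function(lengthsBp, cMMale, cMFemale,
                                 shape = c("linear", "sine"),
                                 amplitude = 0.5, periods = 3,
                                 nAnchors = 101L) {
    shape <- match.arg(shape)
    chrs <- names(lengthsBp)
    if (is.null(chrs)) stop("lengthsBp must be named by chromosome")
    stopifnot(all(chrs %in% names(cMMale)), all(chrs %in% names(cMFemale)))
    anchors <- lapply(chrs, function(ch) {
        L <- lengthsBp[[ch]]
        if (shape == "linear") {
            data.frame(bp = c(1, L),
                       cM_male = c(0, cMMale[[ch]]),
                       cM_female = c(0, cMFemale[[ch]]))
        } else {
            bp <- seq(1, L, length.out = nAnchors)
            x <- (bp - 1) / (L - 1)
            # integral of 1 + amplitude*sin(2*pi*periods*x), rescaled to total
            cum <- x + amplitude * (1 - cos(2 * pi * periods * x)) /
                (2 * pi * periods)
            cum <- (cum - cum[1]) / (cum[length(cum)] - cum[1])
            data.frame(bp = bp,
                       cM_male = cMMale[[ch]] * cum,
                       cM_female = cMFemale[[ch]] * cum)
        }
    })
    names(anchors) <- chrs
    new("TrueRecombinationMap", chromosomes = chrs,
        lengthsBp = setNames(as.numeric(lengthsBp), chrs), anchors = anchors)
}

#' Published rat chromosome landscape as simulation truth
#'
#' Uses the published revised rat genetic-map chromosome summaries
#' ([ratMapSummary()]): physical lengths (Mb, rn6) and sex-specific genetic
#' lengths per chromosome, with a linear (or sinusoidal) within-chromosome
#' landscape.
#'
#' @param chromosomes which chromosomes to include (default all 21)
#' @inheritParams trueRecombinationMap
#' @return a [TrueRecombinationMap]
#' @examples
#' tm <- ratTrueMap()
#' sum(vapply(tm@anchors, function(a) max(a$cM_female), numeric(1))) / 100
#' # ~18.3 expected crossovers per female meiosis genome-wide
#' @export
ratTrueMap <- function(chromosomes = NULL, shape = "linear",
                       amplitude = 0.5, periods = 3) {
    s <- ratMapSummary()
    if (!is.null(chromosomes)) s <- s[s$chrom %in% chromosomes, ]
    trueRecombinationMap(
        lengthsBp = setNames(s$mb * 1e6, s$chrom),
        cMMale = setNames(s$cM_male, s$chrom),
        cMFemale = setNames(s$cM_female, s$chrom),
        shape = shape, amplitude = amplitude, periods = periods)
}

#' Expected crossovers per meiosis under a truth landscape
#'
#' @param trueMap a [TrueRecombinationMap]
#' @param sex "male" or "female"
#' @return named numeric of per-chromosome Poisson means (total cM / 100)
#' @export
expectedCrossovers <- function(trueMap, sex = c("male", "female")) {
    sexcol <- paste0("cM_", match.arg(sex))
    vapply(trueMap@anchors, function(a) a[[sexcol]][nrow(a)] / 100, numeric(1))
}
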