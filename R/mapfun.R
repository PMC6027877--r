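#' Mapping functions between recombination fraction and genetic distance
#'
#' Haldane's function assumes no crossover interference
#' (d = -50 log(1 - 2r)); Kosambi's allows partial interference
#' (d = 25 log((1 + 2r) / (1 - 2r))). Both return 0 at r = 0 and are
#' strictly increasing on \[0, 0.5); r >= 0.5 has no finite distance.
#'
#' @param r recombination fraction(s) in \[0, 0.5)
#' @param mappingFunction "haldane" (default) or "kosambi"
#' @return genetic distance(s) in cM
#' @examples
#' mapDistance(0.1)                       # 11.157 cM
#' mapDistance(0.1, "kosambi")            # 10.137 cM
#' @export
mapDistance <- function(r, mappingFunction = c("haldane", "kosambi")) {
    mappingFunction <- match.arg(mappingFunction)
    if (any(r < 0 | r >= 0.5, na.rm = TRUE))
        stop("recombination fraction must lie in [0, 0.5) for a finite distance")
    switch(mappingFunction,
        haldane = -50 * log(1 - 2 * r),
        kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' @rdname mapDistance
#' @param d genetic distance(s) in cM
#' @export
recombinationFraction <- function(d, mappingFunction = c("haldane", "kosambi")) {
    mappingFunction <- match.arg(mappingFunction)
    if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
    switch(mappingFunction,
        haldane = 0.5 * (1 - exp(-d / 50)),
        kosambi = 0.5 * tanh(d / 50))
}

# Piecewise-linear interpolation of a truth landscape: cM at bp.
.truthCm <- function(anchor, bp, sexcol) {
    stats::approx(anchor$bp, anchor[[sexcol]], xout = bp, rule = 2)$y
}

# Inverse: bp at cM. Flat segments (zero recombination) map to their left
# edge; ties = "ordered" keeps approx() happy on non-strictly-increasing cM.
.truthBp <- function(anchor, cm, sexcol) {
    y <- anchor[[sexcol]]
    keep <- !duplicated(y)
    stats::approx(y[keep], anchor$bp[keep], xout = cm, rule = 2)$y
}

# Split helper preserving chromosome order of first appearance.
.splitKeepOrder <- function(x, f) {
    split(x, factor(f, levels = unique(f)))
}
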