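# Resource outputs: per-kb cM tables, cM annotation of marker lists, and
# chromosome/genome summaries in the published report conventions
# (cM to one decimal, rates to two decimals).

#' Genetic positions for every kilobase of the physical map
#'
#' Rows at bp = 1000*k, k = 1..floor(L/1000), per chromosome, with all
#' three cM tracks interpolated from the model. Columns are non-decreasing
#' down each chromosome.
#'
#' @param model a [MapModel]
#' @param lengthsBp optional named chromosome lengths in bp (defaults to
#'   the model's)
#' @return data.frame with columns `chrom`, `bp`, `cM_male`, `cM_female`,
#'   `cM_avg`
#' @export
kbGrid <- function(model, lengthsBp = NULL) {
    if (is.null(lengthsBp)) lengthsBp <- model@lengthsBp
    out <- lapply(names(model@anchors), function(ch) {
        L <- lengthsBp[[ch]]
        if (is.null(L) || is.na(L)) stop("no length for chromosome ", ch)
        bp <- seq(1000, floor(L / 1000) * 1000, by = 1000)
        if (!length(bp)) return(NULL)
        data.frame(chrom = ch, bp = bp,
                   cM_male = as.numeric(predictCm(model, ch, bp, "male")),
                   cM_female = as.numeric(predictCm(model, ch, bp, "female")),
                   cM_avg = as.numeric(predictCm(model, ch, bp, "avg")),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Annotate a marker list with interpolated genetic positions
#'
#' Markers listed with exactly one genomic position receive interpolated
#' cM on all three tracks; markers with no position, an unknown
#' chromosome, or multiple listed positions are flagged `unmapped` and get
#' no cM. Positions beyond the model range are annotated with the
#' terminal-slope extension and flagged `extrapolated`.
#'
#' @param model a [MapModel]
#' @param markers data.frame with columns `name`, `chrom`, `bp` (`chrom`
#'   or `bp` may be NA for unplaced markers; duplicated names mean
#'   multiple reported positions)
#' @return the input with added columns `cM_male`, `cM_female`, `cM_avg`,
#'   `unmapped`, `extrapolated`
#' @export
annotateMarkers <- function(model, markers) {
    out <- markers
    nr <- nrow(out)
    out$cM_male <- rep(NA_real_, nr); out$cM_female <- rep(NA_real_, nr)
    out$cM_avg <- rep(NA_real_, nr)
    out$unmapped <- rep(FALSE, nr); out$extrapolated <- rep(FALSE, nr)
    if (!nr) return(out)
    multi <- names(which(table(markers$name) > 1L))
    out$unmapped <- markers$name %in% multi | is.na(markers$chrom) |
        is.na(markers$bp) | !(markers$chrom %in% names(model@anchors))
    todo <- which(!out$unmapped)
    for (ch in unique(out$chrom[todo])) {
        i <- todo[out$chrom[todo] == ch]
        for (tr in c("male", "female", "avg")) {
            v <- predictCm(model, ch, out$bp[i], tr)
            out[[paste0("cM_", tr)]][i] <- as.numeric(v)
            out$extrapolated[i] <- out$extrapolated[i] | attr(v, "extrapolated")
        }
    }
    out
}

#' Chromosome and genome summaries of a genetic map
#'
#' Per chromosome: marker count, total male/female/averaged cM, physical
#' size and recombination rate (averaged cM / Mb). The genome row sums cM
#' and Mb; the headline genome-wide rate is the *unweighted mean* of the
#' per-chromosome rates (the convention that reproduces the published
#' genome figures), with the weighted alternative (total cM / total Mb)
#' also reported. Report columns are rounded (cM to 1 decimal, rates to
#' 2); full-precision columns carry the `_full` suffix.
#'
#' @param x a [GeneticMap] or [MapModel]
#' @param physicalLengthsBp named numeric chromosome lengths in bp; for a
#'   [MapModel] defaults to the model lengths
#' @param nMarkers optional named marker counts per chromosome (used for a
#'   [MapModel], where anchors need not equal genotyped markers)
#' @return list with `perChromosome` (data.frame) and `genome` (one-row
#'   data.frame with `cM_male`, `cM_female`, `cM_avg`, `mb`,
#'   `rate_unweighted`, `rate_weighted`, `n_markers`, `resolution_cM`)
#' @export
summarizeMap <- function(x, physicalLengthsBp = NULL, nMarkers = NULL) {
    if (is(x, "GeneticMap")) {
        chrs <- chromosomes(x)
        male <- totalLength(x, "male"); female <- totalLength(x, "female")
        avg <- totalLength(x, "avg")
        cnt <- vapply(.splitKeepOrder(x@markers$chrom, x@markers$chrom),
                      length, integer(1))
        if (is.null(physicalLengthsBp))
            physicalLengthsBp <- vapply(
                .splitKeepOrder(x@markers$bp, x@markers$chrom), max, numeric(1))
    } else if (is(x, "MapModel")) {
        chrs <- chromosomes(x)
        male <- totalLength(x, "male"); female <- totalLength(x, "female")
        avg <- totalLength(x, "avg")
        cnt <- if (is.null(nMarkers))
            vapply(x@anchors, nrow, integer(1)) else nMarkers[chrs]
        if (is.null(physicalLengthsBp)) physicalLengthsBp <- x@lengthsBp
    } else stop("x must be a GeneticMap or MapModel")
    mb <- as.numeric(physicalLengthsBp[chrs]) / 1e6
    rateFull <- ifelse(mb > 0, avg / mb, 0)
    per <- data.frame(
        chrom = chrs, n_markers = as.integer(cnt),
        cM_male = round(male, 1), cM_female = round(female, 1),
        cM_avg = round(avg, 1), mb = round(mb, 1),
        rate = round(rateFull, 2),
        cM_male_full = as.numeric(male), cM_female_full = as.numeric(female),
        cM_avg_full = as.numeric(avg), rate_full = as.numeric(rateFull),
        stringsAsFactors = FALSE, row.names = NULL)
    genome <- data.frame(
        n_markers = sum(per$n_markers),
        cM_male = round(sum(male), 0), cM_female = round(sum(female), 0),
        cM_avg = round(sum(avg), 0), mb = round(sum(mb), 0),
        rate_unweighted = round(mean(rateFull), 2),
        rate_weighted = round(sum(avg) / sum(mb), 2),
        resolution_cM = sum(avg) / sum(per$n_markers),
        cM_male_full = sum(male), cM_female_full = sum(female),
        cM_avg_full = sum(avg), mb_full = sum(mb),
        rate_unweighted_full = mean(rateFull),
        rate_weighted_full = sum(avg) / sum(mb))
    list(perChromosome = per, genome = genome)
}

#' Genome summary arithmetic on a published chromosome table
#'
#' Applies the genome-level summary conventions to a chromosome summary
#' table such as [ratMapSummary()]: totals by summation, headline rate as
#' the unweighted mean of per-chromosome rates, alternative rate as total
#' cM / total Mb, and average map resolution as total averaged cM divided
#' by the marker count.
#'
#' @param perChromosome data.frame with columns `cM_avg`, `mb`, `rate` and
#'   optionally `cM_male`, `cM_female`, `n_markers`
#' @return one-row data.frame of genome figures
#' @export
summarizeChromosomeTable <- function(perChromosome) {
    p <- perChromosome
    data.frame(
        n_markers = if ("n_markers" %in% names(p)) sum(p$n_markers) else NA,
        cM_male = if ("cM_male" %in% names(p)) sum(p$cM_male) else NA,
        cM_female = if ("cM_female" %in% names(p)) sum(p$cM_female) else NA,
        cM_avg = sum(p$cM_avg), mb = sum(p$mb),
        rate_unweighted = round(mean(p$rate), 2),
        rate_weighted = round(sum(p$cM_avg) / sum(p$mb), 2),
        resolution_cM = if ("n_markers" %in% names(p))
            sum(p$cM_avg) / sum(p$n_markers) else NA)
}
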