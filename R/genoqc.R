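# Genotype cleaning: monomorphic removal, cohort Mendelian-error filtering
# and MAF/window marker thinning.

#' Minor allele frequency per marker
#'
#' Computed from non-missing calls over all genotyped individuals (founders
#' included).
#'
#' @param cohort an [HSCohort]
#' @return numeric vector named by marker id (NaN where all calls missing)
#' @export
markerMaf <- function(cohort) {
    d <- dosage(cohort)
    f <- rowMeans(d, na.rm = TRUE) / 2
    pmin(f, 1 - f)
}

#' Remove monomorphic markers
#'
#' A marker is retained only if its non-missing calls show at least two
#' alleles. All-missing markers count as monomorphic and are removed.
#'
#' @param cohort an [HSCohort]
#' @return list with `cohort` (filtered) and `removed` (marker ids)
#' @export
dropMonomorphic <- function(cohort) {
    d <- dosage(cohort)
    hasHet <- rowSums(d == 1L, na.rm = TRUE) > 0L
    has0 <- rowSums(d == 0L, na.rm = TRUE) > 0L
    has2 <- rowSums(d == 2L, na.rm = TRUE) > 0L
    poly <- hasHet | (has0 & has2)
    list(cohort = new("HSCohort", cohort[poly, ]),
         removed = rownames(cohort)[!poly])
}

# Trio transmission legality: dosages code counts of allele2; a parent with
# dosage 0/1/2 can transmit {0}/{0,1}/{1}. Offspring dosage must be a sum
# of one gamete from each parent.
.mendelOK <- local({
    ok <- array(FALSE, c(3, 3, 3))
    gam <- list(0L, 0:1, 1L)
    for (s in 0:2) for (d in 0:2) for (o in 0:2)
        ok[s + 1, d + 1, o + 1] <- o %in% outer(gam[[s + 1]], gam[[d + 1]], "+")
    ok
})

# Per-marker Mendelian-error counts over complete trios. Returns a list of
# matrices: errors and complete-trio counts (markers x 1).
.mendelCounts <- function(d, ped) {
    kids <- which(!is.na(ped$sire) & !is.na(ped$dam))
    nm <- nrow(d)
    err <- integer(nm); tot <- integer(nm)
    for (i in kids) {
        s <- d[, ped$sire[i]]; m <- d[, ped$dam[i]]; o <- d[, ped$id[i]]
        comp <- !is.na(s) & !is.na(m) & !is.na(o)
        tot <- tot + comp
        lk <- .mendelOK[cbind(s + 1L, m + 1L, o + 1L)]
        err <- err + (comp & !(lk %in% TRUE))
    }
    list(errors = err, trios = tot)
}

#' Filter markers by cohort Mendelian-error rate
#'
#' The per-marker error rate is the fraction of trio-incompatible offspring
#' calls among trios with all three calls non-missing; a call counts as one
#' error regardless of how many Mendelian rules it violates. Markers with
#' rate strictly greater than `maxRate` are removed. Markers with no
#' complete trio have an undefined rate: they are retained and flagged.
#'
#' @param cohort an [HSCohort]
#' @param maxRate removal threshold on the error rate (strict `>`)
#' @return list with `cohort` (filtered), `report` (a [QcReport]) and
#'   `removed` (marker ids)
#' @export
mendelFilter <- function(cohort, maxRate = 0.02) {
    d <- dosage(cohort)
    ped <- pedigree(cohort)
    cnt <- .mendelCounts(d, ped)
    rate <- ifelse(cnt$trios > 0L, cnt$errors / cnt$trios, NA_real_)
    names(rate) <- rownames(cohort)
    drop <- !is.na(rate) & rate > maxRate
    rep <- new("QcReport",
               mendelRate = rate,
               removedMonomorphic = character(0),
               removedMendel = rownames(cohort)[drop],
               retainedAfterThinning = character(0),
               flaggedNoTrio = rownames(cohort)[cnt$trios == 0L])
    list(cohort = new("HSCohort", cohort[!drop, ]), report = rep,
         removed = rownames(cohort)[drop])
}

#' Thin markers to one per physical window
#'
#' Chromosomes are partitioned into fixed windows
#' `[k*windowBp + 1, (k+1)*windowBp]` anchored at bp 1; within each window
#' the lowest-bp marker with MAF strictly greater than `mafMin` is
#' retained. Windows without a qualifying marker contribute nothing.
#'
#' @param cohort an [HSCohort]
#' @param windowBp window width in bp
#' @param mafMin MAF gate (strict `>`)
#' @return character vector of retained marker ids, in panel order
#' @export
thinByWindow <- function(cohort, windowBp = 10000, mafMin = 0.05) {
    if (windowBp <= 0) stop("windowBp must be positive")
    panel <- markerPanel(cohort)
    maf <- markerMaf(cohort)
    ok <- !is.na(maf) & maf > mafMin
    if (!any(ok)) return(character(0))
    chrs <- as.character(seqnames(panel))[ok]
    pos <- start(panel)[ok]
    ids <- mcols(panel)$marker_id[ok]
    win <- (pos - 1L) %/% windowBp
    first <- !duplicated(paste(chrs, win))
    ids[first]
}

#' Subset a cohort to a marker set
#'
#' @param cohort an [HSCohort]
#' @param markerIds marker ids to keep (panel order is preserved)
#' @return an [HSCohort]
#' @export
selectMarkers <- function(cohort, markerIds) {
    new("HSCohort", cohort[rownames(cohort) %in% markerIds, ])
}

#' Run the full genotype-QC stage
#'
#' Monomorphic removal, Mendelian-error filtering (strict > `mendelMax`)
#' and MAF/window thinning, in that order.
#'
#' @param cohort an [HSCohort]
#' @param mendelMax Mendelian-error-rate threshold
#' @param windowBp thinning window in bp; `NULL` skips thinning
#' @param mafMin MAF gate for thinning
#' @return list with `cohort` (cleaned) and `report` (a [QcReport])
#' @export
runQc <- function(cohort, mendelMax = 0.02, windowBp = 10000, mafMin = 0.05) {
    mono <- dropMonomorphic(cohort)
    mf <- mendelFilter(mono$cohort, maxRate = mendelMax)
    out <- mf$cohort
    retained <- rownames(out)
    if (!is.null(windowBp)) {
        retained <- thinByWindow(out, windowBp = windowBp, mafMin = mafMin)
        out <- selectMarkers(out, retained)
    }
    rep <- mf$report
    rep@removedMonomorphic <- mono$removed
    rep@retainedAfterThinning <- retained
    list(cohort = out, report = rep)
}
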