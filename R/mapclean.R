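# Two-stage map cleaning: local-regression residual filtering of errant
# markers, then a monotone cubic interpolation model of cM vs bp whose
# derivative is the local recombination rate.

#' Remove errant markers by local-regression residuals
#'
#' Per chromosome and per sex track, a locally weighted linear regression
#' (tricube kernel with Tukey-biweight robustness iterations, so that the
#' errant markers being hunted cannot bend the reference curve) of cM on
#' bp is fitted; markers whose absolute residual strictly exceeds
#' `thresholdCm` in any requested track are removed from all tracks,
#' keeping the three tracks on one marker set. Chromosomes with fewer
#' than 10 markers are left unfiltered with a warning.
#'
#' @param map a [GeneticMap]
#' @param tracks which sex tracks to screen (default both sex-specific)
#' @param span local-regression span as a fraction of the chromosome's
#'   markers
#' @param thresholdCm residual threshold in cM (strict `>`)
#' @return list with `map` (filtered [GeneticMap]), `report` (a
#'   [CleaningReport]) and `removed` (marker ids)
#' @export
residualFilter <- function(map, tracks = c("male", "female"), span = 0.05,
                           thresholdCm = 1.0) {
    m <- mapMarkers(map)
    tracks <- match.arg(tracks, c("male", "female", "avg"), several.ok = TRUE)
    recs <- list()
    removed <- character(0)
    for (ch in unique(m$chrom)) {
        rows <- which(m$chrom == ch)
        if (length(rows) < 10L) {
            warning(sprintf("chromosome %s has < 10 markers; not filtered", ch))
            next
        }
        for (tr in tracks) {
            cm <- m[[paste0("cM_", tr)]][rows]
            bp <- m$bp[rows]
            # the local window must hold enough markers for a stable fit;
            # Mb units keep the local design well conditioned
            sp <- max(span, min(1, 25 / length(rows)))
            bpMb <- bp / 1e6
            # perfectly collinear stretches make the local solver grumble
            # about (pseudo)singular fits; those messages are expected on
            # zero-residual data and carry no information here
            fit <- withCallingHandlers(
                stats::loess(cm ~ bpMb, span = sp, degree = 1,
                             family = "symmetric",
                             control = stats::loess.control(surface = "direct")),
                warning = function(w) {
                    if (grepl(paste0("pseudoinverse|condition number|",
                                     "neighborhood radius|radius|",
                                     "boundary|singularities|^at "),
                              conditionMessage(w)))
                        invokeRestart("muffleWarning")
                })
            fitted <- stats::fitted(fit)
            res <- cm - fitted
            bad <- abs(res) > thresholdCm
            recs[[length(recs) + 1L]] <- data.frame(
                chrom = ch, marker_id = m$marker_id[rows], bp = bp,
                track = tr, fitted = fitted, residual = res,
                removed = bad, stringsAsFactors = FALSE)
            removed <- union(removed, m$marker_id[rows][bad])
        }
    }
    keep <- !(m$marker_id %in% removed)
    rep <- new("CleaningReport",
               table = if (length(recs)) do.call(rbind, recs) else data.frame(),
               span = span, threshold = thresholdCm)
    list(map = new("GeneticMap", markers = m[keep, , drop = FALSE]),
         report = rep, removed = removed)
}

#' Fit a monotone cM(bp) interpolation model
#'
#' Anchors sharing a bp position are collapsed to their mean cM; residual
#' non-monotonicities are resolved by isotonic (pool-adjacent-violators)
#' projection; a Fritsch--Carlson shape-preserving monotone cubic
#' interpolant then passes exactly through the (possibly projected)
#' anchors of each track. The derivative is continuous and non-negative.
#'
#' @param map a [GeneticMap] (typically residual-filtered)
#' @param lengthsBp optional named chromosome lengths (bp); defaults to the
#'   last marker position per chromosome
#' @return a [MapModel]
#' @export
fitMapModel <- function(map, lengthsBp = NULL) {
    m <- mapMarkers(map)
    anchors <- list()
    for (ch in unique(m$chrom)) {
        rows <- which(m$chrom == ch)
        if (length(rows) < 2L)
            stop(sprintf("chromosome %s has < 2 anchors", ch))
        a <- m[rows, c("bp", "cM_male", "cM_female", "cM_avg")]
        if (anyDuplicated(a$bp)) {
            a <- do.call(rbind, lapply(split(a, a$bp), function(g)
                data.frame(bp = g$bp[1], cM_male = mean(g$cM_male),
                           cM_female = mean(g$cM_female),
                           cM_avg = mean(g$cM_avg))))
            a <- a[order(a$bp), ]
        }
        for (tr in c("cM_male", "cM_female", "cM_avg"))
            if (is.unsorted(a[[tr]]))
                a[[tr]] <- stats::isoreg(a[[tr]])$yf
        rownames(a) <- NULL
        anchors[[ch]] <- a
    }
    if (is.null(lengthsBp))
        lengthsBp <- vapply(anchors, function(a) max(a$bp), numeric(1))
    new("MapModel", anchors = anchors,
        lengthsBp = setNames(as.numeric(lengthsBp[names(anchors)]),
                             names(anchors)))
}

# Evaluate a model track at arbitrary bp. Inside the anchor range the
# monotone cubic interpolant is used; outside, the terminal segment's slope
# extends linearly, clamped at cM >= 0.
.modelEval <- function(a, bp, track, deriv = 0L) {
    f <- stats::splinefun(a$bp, a[[track]], method = "monoH.FC")
    lo <- a$bp[1]; hi <- a$bp[nrow(a)]
    n <- nrow(a)
    sl1 <- (a[[track]][2] - a[[track]][1]) / (a$bp[2] - a$bp[1])
    sl2 <- (a[[track]][n] - a[[track]][n - 1]) / (a$bp[n] - a$bp[n - 1])
    out <- numeric(length(bp))
    inside <- bp >= lo & bp <= hi
    if (deriv == 0L) {
        out[inside] <- f(bp[inside])
        out[bp < lo] <- pmax(0, a[[track]][1] - sl1 * (lo - bp[bp < lo]))
        out[bp > hi] <- a[[track]][n] + sl2 * (bp[bp > hi] - hi)
    } else {
        out[inside] <- pmax(0, f(bp[inside], deriv = 1L))
        out[bp < lo] <- sl1
        out[bp > hi] <- sl2
    }
    attr(out, "extrapolated") <- !inside
    out
}

#' Interpolated genetic position(s) from a map model
#'
#' @param model a [MapModel]
#' @param chrom chromosome label (single)
#' @param bp physical position(s), 1-based bp
#' @param track "avg", "male" or "female"
#' @return cM values; positions outside the anchor range are linearly
#'   extended at the terminal slope (clamped at 0) and flagged in the
#'   `extrapolated` attribute
#' @export
predictCm <- function(model, chrom, bp, track = c("avg", "male", "female")) {
    track <- paste0("cM_", match.arg(track))
    a <- model@anchors[[chrom]]
    if (is.null(a)) stop("no model for chromosome ", chrom)
    .modelEval(a, bp, track, deriv = 0L)
}

#' Local recombination rate from a map model
#'
#' The derivative of the monotone interpolant, scaled to cM/Mb.
#' Out-of-range positions are clamped to the terminal segment's rate and
#' flagged in the `extrapolated` attribute.
#'
#' @inheritParams predictCm
#' @return rates in cM/Mb (>= 0)
#' @export
localRate <- function(model, chrom, bp, track = c("avg", "male", "female")) {
    track <- paste0("cM_", match.arg(track))
    a <- model@anchors[[chrom]]
    if (is.null(a)) stop("no model for chromosome ", chrom)
    out <- .modelEval(a, bp, track, deriv = 1L)
    flag <- attr(out, "extrapolated")
    out <- out * 1e6
    attr(out, "extrapolated") <- flag
    out
}

#' Run the full map-cleaning stage
#'
#' Residual filtering of both sex tracks followed by monotone-spline model
#' fitting on the retained markers.
#'
#' @inheritParams residualFilter
#' @param lengthsBp optional chromosome lengths for the model
#' @return list with `map` (cleaned [GeneticMap]), `model` (a [MapModel]),
#'   `report` (a [CleaningReport]) and `removed` (marker ids)
#' @export
cleanMap <- function(map, span = 0.05, thresholdCm = 1.0, lengthsBp = NULL) {
    rf <- residualFilter(map, span = span, thresholdCm = thresholdCm)
    model <- fitMapModel(rf$map, lengthsBp = lengthsBp)
    list(map = rf$map, model = model, report = rf$report,
         removed = rf$removed)
}
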