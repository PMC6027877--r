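# Single-locus F2 interval mapping by multiple imputation: genotype
# imputation on a cM grid, LOD scans, permutation thresholds, bayesint-style
# credible intervals and old-map vs new-map comparison.

# F2 transition matrix over ordered gamete-origin pairs {AA, AB, BA, BB}
# at recombination fraction r: each gamete switches independently.
.f2Trans <- function(r) {
    T1 <- matrix(c(1 - r, r, r, 1 - r), 2, 2)
    T1 %x% T1
}

.stateDosage <- c(0L, 1L, 1L, 2L)

# Build the scan grid for one chromosome: marker positions plus a fixed-step
# lattice from the first to the last marker.
.scanPositions <- function(cm, stepCm) {
    grid <- seq(min(cm), max(cm), by = stepCm)
    pos <- sort(unique(c(grid, cm)))
    list(pos = pos, isMarker = pos %in% cm)
}

#' Impute F2 genotypes on a cM grid
#'
#' For each imputation, full genotypes at all grid positions (a fixed-step
#' lattice united with the typed markers) are drawn from their joint
#' distribution given the observed flanking marker genotypes, under a
#' Markov model along the map with Haldane recombination probabilities and
#' no genotyping error. Observed genotypes are reproduced exactly.
#'
#' @param cross an [F2Cross]
#' @param stepCm grid step in cM (> 0)
#' @param nImputations number of imputations (>= 1)
#' @param seed integer seed (identical seeds give identical imputations)
#' @return list with `grid` (data.frame chrom, cM, marker) and `draws`
#'   (list per chromosome of integer arrays individuals x positions x
#'   imputations holding dosages)
#' @export
imputeGenotypes <- function(cross, stepCm = 2, nImputations = 128L,
                            seed = NULL) {
    if (stepCm <= 0) stop("stepCm must be positive")
    if (nImputations < 1) stop("need at least one imputation")
    map <- crossMap(cross)
    geno <- crossGeno(cross)
    n <- nrow(geno)
    .withSeed(seed, {
        draws <- list(); gridRows <- list()
        for (ch in unique(map$chrom)) {
            mi <- which(map$chrom == ch)
            if (!length(mi)) { warning("empty chromosome ", ch); next }
            sp <- .scanPositions(map$cM[mi], stepCm)
            S <- length(sp$pos)
            markerAt <- match(sp$pos, map$cM[mi])
            obs <- matrix(NA_integer_, n, S)
            obs[, !is.na(markerAt)] <- geno[, mi[markerAt[!is.na(markerAt)]]]
            Tm <- lapply(recombinationFraction(diff(sp$pos)), .f2Trans)
            # forward filtering (shared across imputations)
            Fm <- array(0, c(n, 4L, S))
            alpha <- matrix(0.25, n, 4L)
            for (s in seq_len(S)) {
                if (s > 1L) alpha <- alpha %*% Tm[[s - 1L]]
                o <- obs[, s]
                known <- !is.na(o)
                if (any(known)) {
                    em <- outer(o[known], .stateDosage, "==") * 1
                    alpha[known, ] <- alpha[known, ] * em
                }
                norm <- rowSums(alpha)
                if (any(norm == 0))
                    stop("impossible genotype configuration on ", ch)
                alpha <- alpha / norm
                Fm[, , s] <- alpha
            }
            arr <- array(NA_integer_, c(n, S, nImputations))
            for (b in seq_len(nImputations)) {
                st <- integer(n)
                p <- Fm[, , S, drop = FALSE]
                dim(p) <- c(n, 4L)
                st <- .sampleRows(p)
                arr[, S, b] <- .stateDosage[st]
                if (S > 1L) for (s in (S - 1L):1L) {
                    w <- Fm[, , s] * t(Tm[[s]])[st, , drop = FALSE]
                    st <- .sampleRows(w)
                    arr[, s, b] <- .stateDosage[st]
                }
            }
            draws[[ch]] <- arr
            gridRows[[ch]] <- data.frame(
                chrom = ch, cM = sp$pos,
                marker = ifelse(is.na(markerAt), NA_character_,
                                map$marker[mi][ifelse(is.na(markerAt), 1L,
                                                      markerAt)]),
                stringsAsFactors = FALSE)
        }
        list(grid = do.call(rbind, gridRows), draws = draws,
             stepCm = stepCm, nImputations = as.integer(nImputations))
    })
}

# Vectorized categorical sampling: one draw per row of a (non-negative)
# weight matrix.
.sampleRows <- function(w) {
    cw <- w / rowSums(w)
    cw <- t(apply(cw, 1L, cumsum))
    u <- stats::runif(nrow(w))
    1L + rowSums(u > cw[, -ncol(cw), drop = FALSE])
}

# RSS of y (vector or matrix of columns) under design X, via QR.
.rssQr <- function(qrX, Y) {
    Y <- as.matrix(Y)
    Q <- qr.Q(qrX)
    colSums(Y^2) - colSums((crossprod(Q, Y))^2)
}

#' LOD scan over imputed genotypes
#'
#' At each grid position the QTL model (covariates + additive + dominance
#' genotype terms) is compared with the null model (covariates only):
#' per imputation `LOD = (n/2) log10(RSS0/RSS1)`; imputations are combined
#' by `log10(mean(10^LOD))`. Individuals with missing phenotype or
#' covariates are dropped.
#'
#' @param imputations result of [imputeGenotypes()]
#' @param phenotype numeric phenotype vector (one per cross individual)
#' @param covariates optional numeric matrix/data.frame of additive
#'   covariates
#' @return a [QtlScan] (no thresholds or peaks yet; see [scanQtl()])
#' @export
lodScan <- function(imputations, phenotype, covariates = NULL) {
    grid <- imputations$grid
    y <- as.numeric(phenotype)
    C <- if (is.null(covariates)) NULL else as.matrix(covariates)
    keep <- !is.na(y)
    if (!is.null(C)) keep <- keep & stats::complete.cases(C)
    if (sum(keep) < 10L) stop("need at least 10 phenotyped individuals")
    y <- y[keep]
    C <- if (is.null(C)) NULL else C[keep, , drop = FALSE]
    n <- length(y)
    X0 <- cbind(rep(1, n), C)
    rss0 <- .rssQr(qr(X0), y)
    lod <- numeric(nrow(grid))
    row0 <- 0L
    for (ch in names(imputations$draws)) {
        arr <- imputations$draws[[ch]][keep, , , drop = FALSE]
        S <- dim(arr)[2]; B <- dim(arr)[3]
        for (s in seq_len(S)) {
            l <- numeric(B)
            for (b in seq_len(B)) {
                g <- arr[, s, b]
                X <- cbind(X0, g - 1, as.integer(g == 1L))
                qrX <- qr(X)
                rss1 <- .rssQr(qrX, y)
                l[b] <- if (qrX$rank < ncol(X))
                    NA_real_ else (n / 2) * log10(rss0 / rss1)
            }
            lod[row0 + s] <- if (all(is.na(l))) NA_real_
                else log10(mean(10^l[!is.na(l)]))
        }
        row0 <- row0 + S
    }
    grid$lod <- pmax(lod, 0)
    new("QtlScan", grid = grid, thresholds = numeric(0),
        peaks = data.frame(),
        params = list(n = n, nImputations = imputations$nImputations,
                      stepCm = imputations$stepCm))
}

#' Genome-wide permutation thresholds for a scan
#'
#' The phenotype (with covariate rows kept attached) is permuted against
#' the genotypes; the genome-wide maximum LOD of each permutation forms
#' the null distribution, and `threshold(alpha)` is its `1 - alpha`
#' quantile.
#'
#' @param cross an [F2Cross]
#' @param phenotype phenotype column name in `crossPheno(cross)`
#' @param covariates optional covariate column names
#' @param nPerm number of permutations (>= 100)
#' @param alphas genome-wide error rates (defaults 0.05 significant,
#'   0.63 suggestive)
#' @param stepCm grid step
#' @param nImputations imputations used for the permutation scans (the
#'   maximum statistic is insensitive to this; a modest number keeps the
#'   permutations tractable)
#' @param seed integer seed
#' @return named numeric thresholds (names = alpha values)
#' @export
permutationThresholds <- function(cross, phenotype = "pheno",
                                  covariates = NULL, nPerm = 1000L,
                                  alphas = c(0.05, 0.63), stepCm = 2,
                                  nImputations = 16L, seed = NULL) {
    if (nPerm < 100) stop("use at least 100 permutations")
    y <- crossPheno(cross)[[phenotype]]
    if (length(unique(y[!is.na(y)])) < 2L) stop("phenotype is constant")
    C <- if (is.null(covariates)) NULL
         else as.matrix(crossPheno(cross)[covariates])
    keep <- !is.na(y)
    if (!is.null(C)) keep <- keep & stats::complete.cases(C)
    .withSeed(seed, {
        imp <- imputeGenotypes(cross, stepCm = stepCm,
                               nImputations = nImputations)
        y <- y[keep]
        C <- if (is.null(C)) NULL else C[keep, , drop = FALSE]
        n <- length(y)
        perms <- vapply(seq_len(nPerm), function(i) sample(y),
                        numeric(n))
        X0 <- cbind(rep(1, n), C)
        rss0 <- .rssQr(qr(X0), perms)
        maxlod <- rep(0, nPerm)
        for (ch in names(imp$draws)) {
            arr <- imp$draws[[ch]][keep, , , drop = FALSE]
            S <- dim(arr)[2]; B <- dim(arr)[3]
            for (s in seq_len(S)) {
                acc <- matrix(0, nPerm, B)
                for (b in seq_len(B)) {
                    g <- arr[, s, b]
                    X <- cbind(X0, g - 1, as.integer(g == 1L))
                    rss1 <- .rssQr(qr(X), perms)
                    acc[, b] <- 10^((n / 2) * log10(rss0 / rss1))
                }
                lod <- log10(rowMeans(acc))
                maxlod <- pmax(maxlod, lod)
            }
        }
        setNames(as.numeric(stats::quantile(maxlod, 1 - alphas, type = 7)),
                 as.character(alphas))
    })
}

#' Bayes credible interval for a QTL peak
#'
#' Posterior mass proportional to `10^LOD` over the chromosome's grid
#' points; returns the smallest run of consecutive grid points that
#' contains the peak and accumulates at least `coverage` of the mass.
#'
#' @param scan a [QtlScan]
#' @param chrom chromosome label
#' @param coverage target posterior mass
#' @return numeric `c(lo, hi)` in cM
#' @export
bayesInterval <- function(scan, chrom, coverage = 0.95) {
    g <- scanGrid(scan)
    g <- g[g$chrom == chrom & !is.na(g$lod), , drop = FALSE]
    if (!nrow(g)) stop("no grid points on chromosome ", chrom)
    w <- 10^g$lod
    w <- w / sum(w)
    peak <- which.max(g$lod)          # ties -> lowest cM (first index)
    best <- NULL
    for (width in 0:(nrow(g) - 1L)) {
        for (lo in max(1L, peak - width):peak) {
            hi <- lo + width
            if (hi > nrow(g) || hi < peak) next
            if (sum(w[lo:hi]) >= coverage) { best <- c(lo, hi); break }
        }
        if (!is.null(best)) break
    }
    if (is.null(best)) best <- c(1L, nrow(g))
    c(g$cM[best[1]], g$cM[best[2]])
}

#' Full single-phenotype QTL scan
#'
#' Imputation, LOD scan, optional permutation thresholds, and per-
#' chromosome peaks with Bayes credible intervals. A chromosome's peak is
#' the grid argmax (ties to lowest cM); it is `detected` when its LOD
#' exceeds the suggestive threshold.
#'
#' @param cross an [F2Cross]
#' @param phenotype phenotype column name
#' @param covariates optional covariate column names
#' @param stepCm grid step in cM
#' @param nImputations imputations for the scan
#' @param nPerm permutations for thresholds (0 skips)
#' @param alphas genome-wide error rates (first = significant, second =
#'   suggestive)
#' @param coverage credible-interval coverage
#' @param seed integer seed
#' @return a [QtlScan]
#' @export
scanQtl <- function(cross, phenotype = "pheno", covariates = NULL,
                    stepCm = 2, nImputations = 128L, nPerm = 0L,
                    alphas = c(0.05, 0.63), coverage = 0.95, seed = NULL) {
    .withSeed(seed, {
        imp <- imputeGenotypes(cross, stepCm = stepCm,
                               nImputations = nImputations)
        y <- crossPheno(cross)[[phenotype]]
        C <- if (is.null(covariates)) NULL
             else as.matrix(crossPheno(cross)[covariates])
        scan <- lodScan(imp, y, C)
        thr <- numeric(0)
        if (nPerm > 0)
            thr <- permutationThresholds(cross, phenotype, covariates,
                                         nPerm = nPerm, alphas = alphas,
                                         stepCm = stepCm)
        scan@thresholds <- thr
        g <- scanGrid(scan)
        peaks <- do.call(rbind, lapply(unique(g$chrom), function(ch) {
            gc <- g[g$chrom == ch & !is.na(g$lod), ]
            if (!nrow(gc)) return(NULL)
            i <- which.max(gc$lod)
            ci <- bayesInterval(scan, ch, coverage)
            data.frame(chrom = ch, cM = gc$cM[i], lod = gc$lod[i],
                       ci_lo = ci[1], ci_hi = ci[2],
                       detected = if (length(thr) >= 2L)
                           gc$lod[i] > thr[[2L]] else NA,
                       stringsAsFactors = FALSE)
        }))
        scan@peaks <- peaks
        scan
    })
}

#' Apply the >10 cM peak-shift rule to a QTL comparison table
#'
#' For QTL detected in both scans the shift is `|new peak - old peak|`;
#' the `shifted` flag is strict (`shift > threshold`). QTL missing in one
#' scan are reported with `detected_in_both = FALSE`, excluded from shift
#' arithmetic but counted in the QTL total.
#'
#' @param table data.frame with columns `old_peak` and `new_peak` (NA
#'   where not detected); other columns are carried through
#' @param shiftThresholdCm shift threshold in cM
#' @return a [QtlComparison]
#' @export
applyShiftRule <- function(table, shiftThresholdCm = 10) {
    t <- table
    t$detected_in_both <- !is.na(t$old_peak) & !is.na(t$new_peak)
    t$shift <- ifelse(t$detected_in_both, abs(t$new_peak - t$old_peak),
                      NA_real_)
    t$shifted <- ifelse(t$detected_in_both, t$shift > shiftThresholdCm, NA)
    new("QtlComparison", table = t, shiftThreshold = shiftThresholdCm)
}

#' Compare QTL between scans under two genetic maps
#'
#' Scans are matched by name (e.g. `"phenotype.model"`); within each pair
#' QTL are matched by chromosome. A QTL exists on a chromosome if either
#' scan's peak exceeds its suggestive threshold there; peaks undetected in
#' one scan give `detected_in_both = FALSE`.
#'
#' @param old,new named lists of [QtlScan] objects (same names), scanned
#'   with the old and new marker positions respectively
#' @param shiftThresholdCm shift threshold in cM
#' @return a [QtlComparison]
#' @export
compareScans <- function(old, new, shiftThresholdCm = 10) {
    if (is(old, "QtlScan")) old <- list(scan = old)
    if (is(new, "QtlScan")) new <- list(scan = new)
    if (!identical(sort(names(old)), sort(names(new))))
        stop("old and new scan sets must share names")
    rows <- list()
    for (nmX in names(old)) {
        po <- scanPeaks(old[[nmX]]); pn <- scanPeaks(new[[nmX]])
        chs <- union(po$chrom[po$detected %in% TRUE],
                     pn$chrom[pn$detected %in% TRUE])
        for (ch in chs) {
            io <- which(po$chrom == ch & po$detected %in% TRUE)
            if (length(io) > 1L) stop("duplicate QTL match on ", ch)
            inw <- which(pn$chrom == ch & pn$detected %in% TRUE)
            if (length(inw) > 1L) stop("duplicate QTL match on ", ch)
            rows[[length(rows) + 1L]] <- data.frame(
                scan = nmX, chrom = ch,
                old_peak = if (length(io)) po$cM[io] else NA_real_,
                old_lod = if (length(io)) po$lod[io] else NA_real_,
                old_ci_lo = if (length(io)) po$ci_lo[io] else NA_real_,
                old_ci_hi = if (length(io)) po$ci_hi[io] else NA_real_,
                new_peak = if (length(inw)) pn$cM[inw] else NA_real_,
                new_lod = if (length(inw)) pn$lod[inw] else NA_real_,
                new_ci_lo = if (length(inw)) pn$ci_lo[inw] else NA_real_,
                new_ci_hi = if (length(inw)) pn$ci_hi[inw] else NA_real_,
                stringsAsFactors = FALSE)
        }
    }
    tab <- if (length(rows)) do.call(rbind, rows)
           else data.frame(scan = character(0), chrom = character(0),
                           old_peak = numeric(0), new_peak = numeric(0))
    applyShiftRule(tab, shiftThresholdCm)
}

#' @rdname QtlComparison-class
#' @param x a [QtlComparison]
#' @export
comparisonTable <- function(x) x@table
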