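grid2chr <- function(step = 10, len = 60) {
    data.frame(marker = paste0("m", seq_len(2 * (len / step + 1))),
               chrom = rep(c("1", "2"), each = len / step + 1),
               cM = rep(seq(0, len, by = step), 2))
}

test_that("cross files round-trip through the comma-separated format", {
    cross <- simulateF2Cross(30, grid2chr(), qtl = NULL, seed = 1,
                             missingRate = 0.1)
    f <- tempfile(fileext = ".csv")
    writeCross(cross, f)
    back <- readCross(f)
    expect_equal(crossGeno(back), crossGeno(cross))
    expect_equal(crossPheno(back)$pheno, crossPheno(cross)$pheno,
                 tolerance = 1e-6)
    expect_equal(crossMap(back), crossMap(cross))
    bad <- readLines(f)
    bad[5] <- sub("AA", "XX", bad[5])
    writeLines(bad, f)
    expect_error(readCross(f), "XX")
})

test_that("imputation reproduces observed genotypes and is seed-stable", {
    cross <- simulateF2Cross(40, grid2chr(), qtl = NULL, seed = 2)
    imp <- imputeGenotypes(cross, stepCm = 2, nImputations = 8, seed = 3)
    g <- crossGeno(cross)
    grid <- imp$grid
    for (ch in c("1", "2")) {
        mi <- which(crossMap(cross)$chrom == ch)
        gi <- which(grid$chrom == ch)
        at <- match(crossMap(cross)$cM[mi], grid$cM[gi])
        for (b in 1:8)
            expect_identical(imp$draws[[ch]][, at, b], unname(g[, mi]))
    }
    imp2 <- imputeGenotypes(cross, stepCm = 2, nImputations = 8, seed = 3)
    expect_identical(imp$draws, imp2$draws)
})

test_that("imputed genotypes follow the two-locus conditional distribution", {
    # single individual, flanks AA--AA 20 cM apart; the midpoint genotype
    # distribution has the closed form p(g) over one gamete squared
    map <- data.frame(marker = c("L", "R"), chrom = "1", cM = c(0, 20))
    cross <- F2Cross(data.frame(pheno = 0),
                     matrix(c(0L, 0L), 1, 2), map)
    imp <- imputeGenotypes(cross, stepCm = 10, nImputations = 4000, seed = 4)
    mid <- which(imp$grid$cM == 10)
    draws <- imp$draws[["1"]][1, mid, ]
    r <- recombinationFraction(10)
    R <- recombinationFraction(20)
    pA <- (1 - r)^2 / (1 - R)         # P(gamete A at mid | A,A flanks)
    pAA <- pA^2
    se <- sqrt(pAA * (1 - pAA) / 4000)
    expect_lt(abs(mean(draws == 0L) - pAA), 3 * se + 1e-9)
})

test_that("the imputation LOD at a typed marker equals the regression closed form", {
    map <- grid2chr()
    cross <- simulateF2Cross(120, map,
                             qtl = data.frame(chrom = "1", cM = 30,
                                              add = 0.8, dom = 0.2),
                             seed = 5)
    imp <- imputeGenotypes(cross, stepCm = 2, nImputations = 1, seed = 6)
    scan <- lodScan(imp, crossPheno(cross)$pheno)
    g <- scanGrid(scan)
    y <- crossPheno(cross)$pheno
    n <- length(y)
    for (mk in c("m4", "m11")) {
        gi <- which(!is.na(g$marker) & g$marker == mk)
        gm <- crossGeno(cross)[, mk]
        rss1 <- sum(resid(lm(y ~ I(gm - 1) + I(as.integer(gm == 1))))^2)
        rss0 <- sum(resid(lm(y ~ 1))^2)
        expect_equal(g$lod[gi], (n / 2) * log10(rss0 / rss1),
                     tolerance = 1e-9)
    }
    # affine phenotype rescaling leaves the LOD curve unchanged
    scan2 <- lodScan(imp, 3 * y + 2)
    expect_equal(scanGrid(scan2)$lod, g$lod, tolerance = 1e-9)
})

test_that("permutation thresholds are ordered quantiles of the null maximum", {
    cross <- simulateF2Cross(80, grid2chr(), qtl = NULL, seed = 7)
    thr <- permutationThresholds(cross, nPerm = 150, nImputations = 4,
                                 alphas = c(0.05, 0.63, 1), seed = 8)
    expect_gte(thr[["0.05"]], thr[["0.63"]])
    expect_gte(thr[["0.63"]], thr[["1"]])    # alpha = 1 -> permutation min
    expect_gt(thr[["0.05"]], 0.5)
    expect_error(permutationThresholds(cross, nPerm = 10), "100")
    const <- cross
    const@pheno$pheno <- 1
    expect_error(permutationThresholds(const, nPerm = 150), "constant")
})

test_that("Bayes intervals match brute-force enumeration on small grids", {
    mkScan <- function(lod, cm = seq(0, 20, by = 2)) {
        new("QtlScan", grid = data.frame(chrom = "1", cM = cm,
                                         marker = NA, lod = lod),
            thresholds = numeric(0), peaks = data.frame(), params = list())
    }
    # spike: interval collapses to the peak
    spike <- c(rep(0, 5), 12, rep(0, 5))
    expect_equal(bayesInterval(mkScan(spike), "1"), c(10, 10))
    # flat: the whole chromosome
    expect_equal(bayesInterval(mkScan(rep(1, 11)), "1"), c(0, 20))
    # triangular and random shapes vs exhaustive enumeration
    bruteInterval <- function(lod, cm, coverage = 0.95) {
        w <- 10^lod / sum(10^lod)
        peak <- which.max(lod)
        best <- NULL
        for (lo in seq_along(cm)) for (hi in lo:length(cm)) {
            if (peak < lo || peak > hi) next
            if (sum(w[lo:hi]) >= coverage &&
                (is.null(best) || hi - lo < best[2] - best[1]))
                best <- c(lo, hi)
        }
        cm[best]
    }
    set.seed(9)
    for (i in 1:20) {
        lod <- pmax(0, c(sort(runif(5, 0, 4)), sort(runif(6, 0, 4),
                                                    decreasing = TRUE)))
        cm <- seq(0, 20, by = 2)
        expect_equal(bayesInterval(mkScan(lod), "1"),
                     bruteInterval(lod, cm))
    }
})

test_that("peak shifts are flagged with the strict >10 cM rule", {
    tab <- data.frame(old_peak = c(10, 20, NA, 40),
                      new_peak = c(10, 35, 12, NA))
    cmp <- applyShiftRule(tab)
    t <- comparisonTable(cmp)
    expect_equal(t$detected_in_both, c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(t$shift, c(0, 15, NA, NA))
    expect_equal(t$shifted, c(FALSE, TRUE, NA, NA))
    # boundary: a shift of exactly 10 is not flagged
    exact <- applyShiftRule(data.frame(old_peak = 0, new_peak = 10))
    expect_false(comparisonTable(exact)$shifted)
})

test_that("scans under identical maps compare with zero shifts", {
    cross <- simulateF2Cross(100, grid2chr(),
                             qtl = data.frame(chrom = "1", cM = 30,
                                              add = 0.9, dom = 0),
                             seed = 10)
    scan <- scanQtl(cross, nImputations = 8, nPerm = 120, seed = 11)
    expect_true(any(scanPeaks(scan)$detected))
    cmp <- compareScans(list(a = scan), list(a = scan))
    t <- comparisonTable(cmp)
    expect_true(all(t$shift == 0))
    expect_false(any(t$shifted))
})
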