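test_that("marker panels respect bounds, order and the target spacing", {
    p <- makeMarkerPanel(c(chrA = 10000), spacingBp = 1000, seed = 1)
    pos <- start(p)
    expect_true(all(pos >= 1 & pos <= 10000))
    expect_false(is.unsorted(pos, strictly = TRUE))
    expect_gt(length(p), 3)
    # published median inter-SNP spacing on a chr1-sized chromosome
    p2 <- makeMarkerPanel(c(chr1 = 282.8e6), spacingBp = 3470, seed = 2)
    med <- median(diff(start(p2)))
    expect_lt(abs(med - 3470) / 3470, 0.10)
    expect_identical(makeMarkerPanel(c(chrA = 1e6), 5000, seed = 7),
                     makeMarkerPanel(c(chrA = 1e6), 5000, seed = 7))
    expect_error(makeMarkerPanel(c(chrA = -5), 10), "positive")
    expect_error(makeMarkerPanel(c(chrA = 100), 1000), "longer")
})

test_that("HS pedigrees produce the configured meiosis count", {
    ped <- buildHSPedigree(65, 870 / 2 / 65, seed = 1)
    expect_equal(meiosisCount(ped), 870L)
    expect_equal(meiosisCount(buildHSPedigree(1, 1, seed = 1)), 2L)
    sx <- setNames(ped$sex, ped$id)
    kids <- !is.na(ped$sire)
    expect_true(all(sx[ped$sire[kids]] == "male"))
    expect_true(all(sx[ped$dam[kids]] == "female"))
    expect_error(buildHSPedigree(0, 5), "empty")
})

test_that("founder haplotypes honour the polymorphic fraction", {
    p <- makeMarkerPanel(c(chrA = 2e6), 2000, seed = 3)
    nm <- length(p)
    h1 <- simulateFounderHaplotypes(p, 8, 1.0, seed = 4)
    cs <- colSums(h1)
    expect_true(all(cs > 0 & cs < 8))       # every marker polymorphic
    h <- simulateFounderHaplotypes(p, 8, 0.5, seed = 5)
    mono <- sum(colSums(h) %in% c(0L, 8L))
    expect_lt(abs(mono - 0.5 * nm), 4 * sqrt(nm * 0.25))
    expect_error(simulateFounderHaplotypes(p, 1), "two strains")
    expect_error(simulateFounderHaplotypes(p, 8, 0), "polymorphicFraction")
})

test_that("gamete crossover counts follow Poisson(total cM / 100)", {
    # flat map -> no crossovers, ever
    tmFlat <- trueRecombinationMap(c(chrA = 1e6), c(chrA = 0), c(chrA = 0))
    panel <- makeMarkerPanel(c(chrA = 1e6), 5e4, seed = 1)
    hap <- list(list(chrA = rep(0L, length(panel))),
                list(chrA = rep(1L, length(panel))))
    set.seed(11)
    g <- drawGamete(hap, panel, tmFlat, "male")
    expect_equal(nrow(g$crossovers), 0L)
    # 100 cM chromosome: mean crossover count 1 within 3 SE
    tm1 <- trueRecombinationMap(c(chrA = 1e6), c(chrA = 100), c(chrA = 100))
    set.seed(12)
    counts <- replicate(2000, nrow(drawGamete(hap, panel, tm1, "male")$crossovers))
    expect_lt(abs(mean(counts) - 1), 3 / sqrt(2000))
    # chi-square goodness of fit against Poisson(1), alpha = 0.01
    obs <- table(factor(pmin(counts, 4), levels = 0:4))
    pr <- c(dpois(0:3, 1), 1 - ppois(3, 1))
    expect_gt(chisq.test(obs, p = pr)$p.value, 0.01)
})

test_that("published chromosome lengths give the expected genome-wide crossover means", {
    tm <- ratTrueMap()
    # genome totals / 100: ~15.9 male, ~18.3 female expected crossovers
    expect_equal(sum(expectedCrossovers(tm, "male")), 15.89, tolerance = 0.01)
    expect_equal(sum(expectedCrossovers(tm, "female")), 18.26, tolerance = 0.01)
    # conservation: per-chromosome means sum exactly to the genome total
    expect_equal(sum(expectedCrossovers(tm, "male")) * 100,
                 sum(ratMapSummary()$cM_male))
})

test_that("faithful transmission leaves no Mendelian inconsistencies", {
    s <- smallSim(chromosomes = "chr20", nFamilies = 8, seed = 21)
    rep <- mendelFilter(s$cohort)$report
    expect_true(all(rep@mendelRate == 0, na.rm = TRUE))
})

test_that("missingness and planted bad markers behave as configured", {
    s <- smallSim(chromosomes = "chr20", nFamilies = 8, missingRate = 0.1,
                  seed = 22)
    d <- dosage(s$cohort)
    expect_lt(abs(mean(is.na(d)) - 0.1), 4 * sqrt(0.1 * 0.9 / length(d)))
    s2 <- smallSim(chromosomes = "chr20", nFamilies = 12,
                   mendelBadMarkerFraction = 0.05, seed = 23)
    bad <- mcols(rowRanges(s2$cohort))$bad_planted
    rate <- mendelFilter(s2$cohort)$report@mendelRate
    expect_gt(mean(rate[bad] > 0.02, na.rm = TRUE), 0.9)
})

test_that("cohorts are bit-identical under a fixed seed", {
    a <- smallSim(chromosomes = "chr20", nFamilies = 5, errorRate = 0.01,
                  missingRate = 0.05, seed = 30)
    b <- smallSim(chromosomes = "chr20", nFamilies = 5, errorRate = 0.01,
                  missingRate = 0.05, seed = 30)
    expect_identical(dosage(a$cohort), dosage(b$cohort))
    expect_identical(a$truth@crossovers, b$truth@crossovers)
})

test_that("marker displacement moves only the selected positions", {
    p <- makeMarkerPanel(c(chrA = 5e7), 5e5, seed = 5)
    id0 <- corruptMarkerPositions(p, 0, 1e6)
    expect_identical(start(id0$panel), start(p))
    expect_length(id0$displaced, 0L)
    cp <- corruptMarkerPositions(p, 0.05, 1e6, seed = 6)
    expect_equal(length(cp$displaced), round(0.05 * length(p)))
    old <- setNames(start(p), mcols(p)$marker_id)
    new <- setNames(start(cp$panel), mcols(cp$panel)$marker_id)
    moved <- abs(new[names(old)] - old)
    expect_true(all(moved[cp$displaced] >= 1e6))
    expect_true(all(moved[setdiff(names(old), cp$displaced)] == 0))
    expect_error(corruptMarkerPositions(p, 0.5, 1e6), "minority")
})
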