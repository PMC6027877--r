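test_that("monomorphic and all-missing markers are removed", {
    ped <- trioPed(2)
    dos <- rbind(
        c(0L, 0L, 0L, 0L),      # all AA -> removed
        c(0L, 0L, 1L, 0L),      # one AB -> retained
        c(NA, NA, NA, NA),      # all missing -> removed
        c(0L, 2L, 1L, 1L))      # clearly polymorphic
    res <- dropMonomorphic(makeCohort(dos, ped))
    expect_equal(nrow(res$cohort), 2L)
    expect_length(res$removed, 2L)
})

test_that("Mendelian-error rates use strict > and complete trios only", {
    # 100 trio families at one marker; plant 3 (then 2) impossible calls
    ped <- famPed(100)
    sire <- rep(0L, 100); dam <- rep(0L, 100)
    off3 <- rep(0L, 100); off3[1:3] <- 1L    # AAxAA -> AB impossible
    # columns in pedigree order (S, D, O per family)
    dos <- matrix(as.integer(as.vector(t(cbind(sire, dam, off3)))), nrow = 1)
    co <- makeCohort(dos, ped)
    mf <- mendelFilter(co)
    expect_equal(unname(mf$report@mendelRate[1]), 0.03)
    expect_length(mf$removed, 1L)             # 0.03 > 0.02 -> removed
    off2 <- off3; off2[3] <- 0L
    dos2 <- matrix(as.integer(as.vector(t(cbind(sire, dam, off2)))), nrow = 1)
    mf2 <- mendelFilter(makeCohort(dos2, ped))
    expect_equal(unname(mf2$report@mendelRate[1]), 0.02)
    expect_length(mf2$removed, 0L)            # exactly 2% -> retained
    # incomplete trios do not count; no complete trio -> flagged, retained
    dosNA <- matrix(c(NA_integer_, 0L, 1L), nrow = 1)
    mf3 <- mendelFilter(makeCohort(dosNA, trioPed(1)))
    expect_length(mf3$removed, 0L)
    expect_length(mf3$report@flaggedNoTrio, 1L)
})

test_that("window thinning keeps the first MAF-qualifying marker per 10 kb window", {
    ped <- trioPed(8)          # 10 individuals
    mkRow <- function(maf) {   # dosage vector of 10 with given allele-2 freq
        n1 <- round(maf * 20)
        v <- integer(10); i <- 1
        while (n1 >= 2) { v[i] <- 2L; n1 <- n1 - 2; i <- i + 1 }
        if (n1 == 1) { v[i] <- 1L }
        v
    }
    dos <- rbind(mkRow(0.3), mkRow(0.4), mkRow(0.2))
    co <- makeCohort(dos, ped, pos = c(1000, 4000, 12000))
    kept <- thinByWindow(co, windowBp = 10000, mafMin = 0.05)
    expect_equal(kept, c("chr1_0001000", "chr1_0012000"))
    dos2 <- rbind(mkRow(0.04), mkRow(0.3))
    co2 <- makeCohort(dos2, ped, pos = c(4000, 9000))
    expect_equal(thinByWindow(co2), "chr1_0009000")
    # MAF exactly at the gate is excluded (strict >)
    dos3 <- rbind(mkRow(0.05))
    expect_length(thinByWindow(makeCohort(dos3, ped, pos = 500)), 0L)
    # empty input
    co0 <- makeCohort(matrix(integer(0), 0, 10), ped)
    expect_length(thinByWindow(co0), 0L)
})

test_that("QC filters are idempotent and thinning keeps <= 1 marker per window", {
    s <- smallSim(chromosomes = "chr20", nFamilies = 10, errorRate = 0.01,
                  missingRate = 0.05, mendelBadMarkerFraction = 0.05,
                  seed = 31)
    q1 <- runQc(s$cohort, windowBp = 5e5)
    q2 <- runQc(q1$cohort, windowBp = 5e5)
    expect_identical(rownames(q1$cohort), rownames(q2$cohort))
    panel <- markerPanel(q1$cohort)
    win <- (start(panel) - 1) %/% 5e5
    expect_true(all(table(paste(seqnames(panel), win)) <= 1))
    maf <- markerMaf(q1$cohort)
    expect_true(all(maf > 0.05))
})

test_that("the Mendel filter separates planted bad markers from clean ones", {
    # at the study scale (65 families, ~435 trios) a single miscalled
    # parent (a half-sibship error burst) stays below the 2% threshold
    s <- smallSim(chromosomes = "chr20", nFamilies = 65,
                  offspringPerFamily = 870 / 2 / 65, spacingBp = 2e5,
                  errorRate = 0.002, missingRate = 0.02,
                  mendelBadMarkerFraction = 0.05, seed = 32)
    bad <- mcols(rowRanges(s$cohort))$bad_planted
    mf <- mendelFilter(s$cohort)
    badIds <- rownames(s$cohort)[bad]
    cleanIds <- rownames(s$cohort)[!bad]
    expect_gte(mean(badIds %in% mf$removed), 0.95)
    expect_lte(mean(cleanIds %in% mf$removed), 0.01)
})
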