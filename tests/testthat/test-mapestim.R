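test_that("parental calls are imputed only when logically forced", {
    # dam AA, sire missing, offspring {AA, AB}: sire must carry B; with
    # only A alleles seen in offspring, both AA and AB remain compatible
    ped <- trioPed(2)
    dos <- rbind(c(NA, 0L, 0L, 1L),   # forces sire het
                 c(NA, 0L, 0L, 0L),   # unresolved: stays missing
                 c(1L, 1L, 0L, 2L))   # complete: unchanged
    co <- callParents(makeCohort(dos, ped))
    d <- dosage(co)
    expect_equal(unname(d[1, 1]), 1L)
    expect_true(is.na(d[2, 1]))
    expect_identical(d[3, ], dosage(makeCohort(dos, ped))[3, ])
    # offspring BB with dam AA is impossible for every sire genotype
    dos2 <- rbind(c(NA, 0L, 1L, 2L))
    co2 <- callParents(makeCohort(dos2, ped))
    expect_true(mcols(rowRanges(co2))$parent_contradiction[1])
    expect_true(is.na(dosage(co2)[1, 1]))
})

test_that("segregation distortion is tested with Pearson chi-square", {
    # 100 AB x AB families, one offspring each
    ped <- famPed(100)
    mkDos <- function(offs) {
        matrix(as.integer(as.vector(t(cbind(rep(1L, 100), rep(1L, 100),
                                            offs)))), nrow = 1)
    }
    perfect <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
    dfP <- distortionFilter(makeCohort(mkDos(perfect), ped))
    expect_equal(dfP$stats$statistic[1], 0)
    expect_length(dfP$removed, 0L)
    skewed <- c(rep(0L, 80), rep(1L, 15), rep(2L, 5))
    dfS <- distortionFilter(makeCohort(mkDos(skewed), ped))
    # independent oracle: Pearson statistic from chisq.test
    oracle <- suppressWarnings(
        chisq.test(c(80, 15, 5), p = c(0.25, 0.5, 0.25)))
    expect_equal(dfS$stats$statistic[1], unname(oracle$statistic),
                 tolerance = 1e-10)
    expect_length(dfS$removed, 1L)
    # AA x AA families: uninformative, retained
    allhom <- matrix(0L, 1, 300)
    dfU <- distortionFilter(makeCohort(allhom, ped))
    expect_length(dfU$removed, 0L)
    expect_true(is.na(dfU$stats$p[1]))
})

test_that("phasing recovers transmissions and counts recombinants", {
    # parent het at two markers, mate homozygous; 10 offspring transmit
    # (A,A) or (B,B): phase resolves with 0 recombinants, then one
    # offspring transmitting (A,B) adds exactly one recombinant
    ped <- trioPed(10)
    tAll <- c(rep(0L, 5), rep(1L, 5))
    dos <- rbind(c(1L, 0L, tAll), c(1L, 0L, tAll))
    ms <- phaseAndExtract(makeCohort(dos, ped), trimSegmentEnds = FALSE)
    iv <- intervalRecFrac(ms, "male")@intervals
    expect_equal(iv$n, 10)
    expect_equal(iv$k, 0)
    tRec <- tAll; tRec[1] <- 1L
    dos2 <- rbind(c(1L, 0L, tAll), c(1L, 0L, tRec))
    ms2 <- phaseAndExtract(makeCohort(dos2, ped), trimSegmentEnds = FALSE)
    iv2 <- intervalRecFrac(ms2, "male")@intervals
    expect_equal(iv2$n, 10)
    expect_equal(iv2$k, 1)
    expect_equal(iv2$r, 0.1)
    # homozygous parent: nothing informative on the maternal side
    ivf <- intervalRecFrac(ms2, "female")@intervals
    expect_true(all(ivf$uninformative))
    expect_equal(ivf$cM, 0)
})

test_that("exact phasing equals brute-force minimum recombination", {
    # random small families (<= 4 offspring, <= 6 markers), mate
    # homozygous so transmissions are direct; total recombination events
    # must match exhaustive enumeration over all phase assignments
    set.seed(77)
    for (rep in 1:25) {
        nOff <- sample(2:4, 1); nMark <- sample(3:6, 1)
        ped <- trioPed(nOff)
        t <- matrix(sample(c(0L, 1L, NA), nMark * nOff, TRUE,
                           prob = c(.4, .4, .2)), nMark, nOff)
        dos <- cbind(rep(1L, nMark), rep(0L, nMark), t)
        dos[is.na(dos)] <- NA_integer_
        co <- makeCohort(dos, ped)
        ms <- phaseAndExtract(co, maskRun = 0L, repairClusters = FALSE,
                              trimSegmentEnds = FALSE)
        iv <- intervalRecFrac(ms, "male")@intervals
        # the op screens out unanimous >= 4-meiosis markers (presumptive
        # miscalled heterozygotes) before phasing; apply the same data
        # preprocessing before the independent exhaustive search
        kn <- rowSums(!is.na(t)); ones <- rowSums(t == 1L, na.rm = TRUE)
        t2 <- t
        t2[kn >= 4L & (ones == 0L | ones == kn), ] <- NA_integer_
        expect_equal(sum(iv$k), bruteMinRecombination(t2),
                     info = sprintf("case %d", rep))
    }
})

test_that("maps assemble cumulatively with an averaged track", {
    s <- smallSim(chromosomes = "chr20", nFamilies = 10, seed = 41)
    map <- estimateMap(runQc(s$cohort, windowBp = NULL)$cohort)
    m <- mapMarkers(map)
    expect_equal(m$cM_avg, (m$cM_male + m$cM_female) / 2)
    expect_equal(m$cM_male[1], 0)
    expect_false(is.unsorted(m$cM_male))      # clean sim: monotone
})

test_that("sex-specific maps separate paternal from maternal meioses", {
    # female truth three times longer than male: the estimated male map
    # must not absorb female recombination
    tm <- trueRecombinationMap(c(chrA = 5e7), cMMale = c(chrA = 30),
                               cMFemale = c(chrA = 90))
    panel <- makeMarkerPanel(c(chrA = 5e7), 2e5, seed = 51)
    ped <- buildHSPedigree(40, 7, seed = 52)
    fh <- simulateFounderHaplotypes(panel, 8, 1.0, seed = 53)
    sim <- simulateCohort(ped, fh, tm, panel, errorRate = 0, missingRate = 0,
                          mendelBadMarkerFraction = 0, seed = 54)
    map <- estimateMap(runQc(sim$cohort, windowBp = NULL)$cohort)
    expect_lt(abs(sum(totalLength(map, "male")) - 30), 10)
    expect_lt(abs(sum(totalLength(map, "female")) - 90), 18)
})

test_that("replicate consensus averages maps and re-enforces monotonicity", {
    mk <- function(shift) {
        new("GeneticMap", markers = data.frame(
            chrom = "chrA", marker_id = paste0("m", 1:5), bp = 1:5 * 1e6,
            cM_male = c(0, 1, 2, 3, 4) + shift,
            cM_female = c(0, 2, 4, 6, 8) + shift,
            cM_avg = c(0, 1.5, 3, 4.5, 6) + shift))
    }
    same <- replicateConsensus(replicate(10, mk(0)))
    expect_equal(mapMarkers(same)$cM_male, mapMarkers(mk(0))$cM_male)
    two <- replicateConsensus(list(mk(0), mk(1)))
    expect_equal(mapMarkers(two)$cM_male, c(0, 1, 2, 3, 4) + 0.5)
    bad <- mk(0); bad@markers$marker_id[1] <- "other"
    expect_error(replicateConsensus(list(mk(0), bad)), "identical")
})

test_that("family-bootstrap consensus tracks the single-run estimate", {
    s <- smallSim(chromosomes = "chr20", nFamilies = 12, seed = 61)
    qc <- runQc(s$cohort, windowBp = NULL)$cohort
    single <- estimateMap(qc)
    cons <- estimateMap(qc, replicates = 5L, seed = 62)
    expect_identical(mapMarkers(cons)$marker_id, mapMarkers(single)$marker_id)
    expect_false(is.unsorted(mapMarkers(cons)$cM_male))
    # consensus stays in the neighbourhood of the point estimate
    expect_lt(abs(sum(totalLength(cons, "avg")) -
                  sum(totalLength(single, "avg"))), 10)
})
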