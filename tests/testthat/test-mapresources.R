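twoPointModel <- function(LBp = 1e7, totalCm = 10) {
    fitMapModel(new("GeneticMap", markers = data.frame(
        chrom = "chrA", marker_id = c("a", "b"), bp = c(1, LBp),
        cM_male = c(0, totalCm), cM_female = c(0, totalCm),
        cM_avg = c(0, totalCm))), lengthsBp = c(chrA = LBp))
}

test_that("the per-kb grid has one row per kilobase with monotone columns", {
    model <- twoPointModel(1e4, 0.01)
    g <- kbGrid(model)
    expect_equal(nrow(g), 10L)
    expect_equal(g$bp, 1:10 * 1000)
    lin <- twoPointModel(1e6, 1)          # 1 cM/Mb
    g2 <- kbGrid(lin)
    expect_equal(g2$cM_avg[g2$bp == 5e5], 0.5, tolerance = 1e-5)
    for (col in c("cM_male", "cM_female", "cM_avg"))
        expect_false(is.unsorted(g2[[col]]))
})

test_that("marker annotation flags unmapped and extrapolated entries", {
    model <- twoPointModel(1e6, 1)
    mk <- data.frame(name = c("at_anchor", "dup", "dup", "noPos", "beyond"),
                     chrom = c("chrA", "chrA", "chrA", NA, "chrA"),
                     bp = c(1e6, 2e5, 8e5, NA, 2e6))
    ann <- annotateMarkers(model, mk)
    expect_equal(ann$cM_avg[1], 1, tolerance = 1e-9)   # anchor reproduced
    expect_true(all(ann$unmapped[2:4]))
    expect_true(all(is.na(ann$cM_avg[2:4])))
    expect_true(ann$extrapolated[5])
    expect_equal(nrow(annotateMarkers(model, mk[0, ])), 0L)
    # grid and annotation agree at shared positions
    g <- kbGrid(model)
    ann2 <- annotateMarkers(model, data.frame(name = "x", chrom = "chrA",
                                              bp = 500000))
    expect_equal(ann2$cM_avg, g$cM_avg[g$bp == 500000], tolerance = 1e-12)
})

test_that("chromosome summaries follow the published report conventions", {
    s <- ratMapSummary()
    # sex-averaging rule and chromosome-wide rate arithmetic
    expect_true(all(abs((s$cM_male + s$cM_female) / 2 - s$cM_avg) <= 0.0501))
    expect_true(all(abs(round(s$cM_avg / s$mb, 2) - s$rate) <= 0.0101))
    g <- summarizeChromosomeTable(s)
    expect_equal(g$rate_unweighted, 0.66)
    # the weighted convention does NOT reproduce the headline figure
    expect_false(isTRUE(all.equal(g$rate_weighted, g$rate_unweighted)))
    expect_lt(g$resolution_cM, 0.02)
    hist <- data.frame(cM_avg = s$cM_avg_hist, mb = s$mb_hist,
                       rate = s$rate_hist)
    expect_equal(summarizeChromosomeTable(hist)$rate_unweighted, 0.65)
})

test_that("summaries of estimated maps conserve totals", {
    s <- smallSim(chromosomes = c("chr19", "chr20"), nFamilies = 10,
                  seed = 71)
    map <- estimateMap(runQc(s$cohort, windowBp = NULL)$cohort)
    summ <- summarizeMap(map, physicalLengthsBp = s$trueMap@lengthsBp)
    expect_equal(sum(summ$perChromosome$cM_avg_full),
                 summ$genome$cM_avg_full)
    expect_equal(summ$genome$n_markers, nrow(mapMarkers(map)))
    expect_equal(summ$perChromosome$rate_full,
                 summ$perChromosome$cM_avg_full /
                     (as.numeric(s$trueMap@lengthsBp) / 1e6))
    flat <- new("GeneticMap", markers = data.frame(
        chrom = "chrA", marker_id = c("a", "b"), bp = c(1, 1e6),
        cM_male = 0, cM_female = 0, cM_avg = 0))
    expect_equal(summarizeMap(flat)$perChromosome$rate, 0)
})
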