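linearMap <- function(n = 200, ratePerMb = 0.5, chrom = "chrA") {
    bp <- seq_len(n) * 1e6
    cm <- (bp - bp[1]) / 1e6 * ratePerMb
    new("GeneticMap", markers = data.frame(
        chrom = chrom, marker_id = sprintf("%s_%03d", chrom, seq_len(n)),
        bp = bp, cM_male = cm, cM_female = cm, cM_avg = cm))
}

test_that("the residual filter removes displaced markers and nothing else", {
    lin <- linearMap()
    rf <- residualFilter(lin)
    expect_length(rf$removed, 0L)
    # one marker displaced +5 cM: exactly that marker is removed
    bad <- lin
    bad@markers$cM_male[100] <- bad@markers$cM_male[100] + 5
    rf2 <- residualFilter(bad)
    expect_equal(rf2$removed, "chrA_100")
    # removal flag is the strict |residual| > threshold rule
    tab <- rf2$report@table
    expect_identical(tab$removed, abs(tab$residual) > 1.0)
    # re-running on the filtered output removes nothing further
    rf3 <- residualFilter(rf2$map)
    expect_length(rf3$removed, 0L)
})

test_that("chromosomes with fewer than 10 markers are left unfiltered", {
    small <- linearMap(5)
    expect_warning(rf <- residualFilter(small), "< 10 markers")
    expect_equal(nrow(mapMarkers(rf$map)), 5L)
})

test_that("the monotone spline reproduces anchors and interpolates linearly", {
    two <- new("GeneticMap", markers = data.frame(
        chrom = "chrA", marker_id = c("a", "b"), bp = c(1, 1000001),
        cM_male = c(0, 1), cM_female = c(0, 1), cM_avg = c(0, 1)))
    model <- fitMapModel(two)
    expect_equal(as.numeric(predictCm(model, "chrA", 500001)), 0.5)
    expect_equal(as.numeric(localRate(model, "chrA", 500001)), 1.0)
    lin <- linearMap()
    model2 <- fitMapModel(lin)
    m <- mapMarkers(lin)
    expect_equal(as.numeric(predictCm(model2, "chrA", m$bp, "male")),
                 m$cM_male, tolerance = 1e-9)
    expect_error(fitMapModel(linearMap(1)), "< 2 anchors")
})

test_that("bp ties collapse to mean cM and non-monotone anchors are projected", {
    m <- data.frame(chrom = "chrA",
                    marker_id = paste0("m", 1:4),
                    bp = c(1e6, 2e6, 2e6, 3e6),
                    cM_male = c(0, 1, 2, 3), cM_female = c(0, 1, 2, 3),
                    cM_avg = c(0, 1, 2, 3))
    model <- fitMapModel(new("GeneticMap", markers = m))
    a <- modelAnchors(model)$chrA
    expect_equal(nrow(a), 3L)
    expect_equal(a$cM_male[2], 1.5)
    expect_true(all(diff(a$cM_avg) >= 0))
})

test_that("local rates recover a sinusoidal landscape and integrate to the total", {
    tm <- ratTrueMap(chromosomes = "chr12", shape = "sine",
                     amplitude = 0.5, periods = 3)
    a <- tm@anchors$chr12
    L <- tm@lengthsBp[["chr12"]]
    # anchors every 100 kb sampled from the true landscape
    bp <- seq(1, L, by = 1e5)
    cmM <- approx(a$bp, a$cM_male, bp)$y
    cmF <- approx(a$bp, a$cM_female, bp)$y
    map <- new("GeneticMap", markers = data.frame(
        chrom = "chr12", marker_id = sprintf("s%05d", seq_along(bp)),
        bp = bp, cM_male = cmM, cM_female = cmF,
        cM_avg = (cmM + cmF) / 2))
    model <- fitMapModel(map)
    grid <- seq(5e5, L - 5e5, by = 2e5)
    est <- as.numeric(localRate(model, "chr12", grid, "male"))
    tru <- approx((a$bp[-1] + a$bp[-nrow(a)]) / 2,
                  diff(a$cM_male) / diff(a$bp) * 1e6, grid, rule = 2)$y
    rmse <- sqrt(mean((est - tru)^2))
    expect_lt(rmse, 0.15 * mean(tru))
    # fundamental-theorem check over the anchored range: the integral of
    # the local rate equals the chromosome's genetic length
    fine <- seq(min(bp), max(bp), length.out = 20001)
    r <- as.numeric(localRate(model, "chr12", fine, "male")) / 1e6
    integral <- sum((r[-1] + r[-length(r)]) / 2 * diff(fine))
    expect_lt(abs(integral - max(cmM)) / max(cmM), 0.001)
})

test_that("out-of-range queries are clamped to the terminal slope and flagged", {
    model <- fitMapModel(linearMap(20, ratePerMb = 1))
    hi <- mapMarkers(linearMap(20))$bp[20]
    v <- predictCm(model, "chrA", c(hi + 1e6, 5e5))
    expect_true(all(attr(v, "extrapolated")))
    expect_equal(as.numeric(v[1]), 19 + 1, tolerance = 1e-8)
    expect_gte(as.numeric(v[2]), 0)
    flat <- linearMap(20, ratePerMb = 0)
    expect_equal(as.numeric(localRate(fitMapModel(flat), "chrA", 5e6)), 0)
})
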