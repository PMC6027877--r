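test_that("mapping functions match their closed forms", {
    expect_equal(mapDistance(0), 0)
    expect_equal(mapDistance(0, "kosambi"), 0)
    # closed forms: -50*log(0.8) and 25*log(1.2/0.8)
    expect_equal(mapDistance(0.1), 11.15718, tolerance = 1e-6)
    expect_equal(mapDistance(0.1, "kosambi"), 10.13663, tolerance = 1e-6)
    expect_error(mapDistance(0.5), "0.5")
    expect_error(mapDistance(-0.01))
    expect_error(recombinationFraction(-1))
})

test_that("mapping functions invert and order correctly", {
    r <- seq(0, 0.49, by = 0.01)
    for (mf in c("haldane", "kosambi")) {
        expect_equal(recombinationFraction(mapDistance(r, mf), mf), r,
                     tolerance = 1e-12)
    }
    pos <- r[r > 0]
    expect_true(all(mapDistance(pos, "kosambi") < mapDistance(pos, "haldane")))
    expect_true(all(diff(mapDistance(r)) > 0))
})
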