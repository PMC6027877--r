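test_that("PED/MAP round-trips losslessly with reference alleles", {
    s <- smallSim(chromosomes = "chr20", nFamilies = 5, missingRate = 0.05,
                  seed = 81)
    ped <- file.path(tempdir(), "c.ped"); map <- file.path(tempdir(), "c.map")
    writePedMap(s$cohort, ped, map)
    panel <- markerPanel(s$cohort)
    ref <- data.frame(marker_id = mcols(panel)$marker_id,
                      allele1 = mcols(panel)$allele1,
                      allele2 = mcols(panel)$allele2)
    back <- readPedMap(ped, map, refAlleles = ref)
    expect_identical(dosage(back), dosage(s$cohort))
    pb <- pedigree(back); p0 <- pedigree(s$cohort)
    expect_identical(as.data.frame(pb), as.data.frame(p0))
    expect_identical(start(markerPanel(back)), start(panel))
})

test_that("malformed PED input is rejected with the offending line", {
    s <- smallSim(chromosomes = "chr20", nFamilies = 2, spacingBp = 5e6,
                  seed = 82)
    ped <- file.path(tempdir(), "bad.ped"); map <- file.path(tempdir(), "bad.map")
    writePedMap(s$cohort, ped, map)
    lines <- readLines(ped)
    writeLines(c(lines, paste(strsplit(lines[1], "\t")[[1]][1:7],
                              collapse = "\t")), ped)
    expect_error(readPedMap(ped, map), "line")
    writeLines(sub("\t1\t0\t", "\t5\t0\t", lines), ped)
    expect_error(readPedMap(ped, map), "sex code")
})

test_that("genetic maps round-trip and strict reading flags non-monotone rows", {
    s <- smallSim(chromosomes = "chr20", nFamilies = 8, seed = 83)
    map <- estimateMap(runQc(s$cohort, windowBp = NULL)$cohort)
    f <- tempfile(fileext = ".tsv")
    writeGeneticMap(map, f)
    back <- readGeneticMap(f)
    expect_equal(mapMarkers(back)$cM_avg, mapMarkers(map)$cM_avg,
                 tolerance = 1e-9)
    t <- readTsv(f)
    t$cM_male[5] <- t$cM_male[4] - 1
    writeTsv(t, f)
    expect_error(readGeneticMap(f), t$marker_id[5])
    expect_silent(readGeneticMap(f, strict = FALSE))
    empty <- tempfile()
    writeTsv(t[0, ], empty)
    expect_warning(e <- readGeneticMap(empty), "empty")
    expect_equal(nrow(mapMarkers(e)), 0L)
})

test_that("map models serialize bit-exactly", {
    s <- smallSim(chromosomes = "chr20", nFamilies = 8, seed = 84)
    cl <- cleanMap(estimateMap(runQc(s$cohort, windowBp = NULL)$cohort),
                   lengthsBp = s$trueMap@lengthsBp)
    f <- tempfile(fileext = ".tsv")
    writeMapModel(cl$model, f)
    back <- readMapModel(f)
    bp <- seq(1e6, 5e7, by = 1e6)
    expect_identical(as.numeric(predictCm(back, "chr20", bp)),
                     as.numeric(predictCm(cl$model, "chr20", bp)))
})

test_that("the pipeline runs end to end, writes a manifest, and is deterministic", {
    out1 <- file.path(tempdir(), "run1"); out2 <- file.path(tempdir(), "run2")
    cfg <- list(seed = 5, outDir = out1,
                sim = list(chromosomes = "chr20", nFamilies = 8,
                           markersPerChromosome = 120))
    runPipeline(cfg)
    arts <- list.files(out1)
    expect_true(all(c("cohort.ped", "cohort.map", "map_raw.tsv",
                      "map_clean.tsv", "map_model.tsv", "summary.tsv",
                      "manifest.tsv") %in% arts))
    man <- readTsv(file.path(out1, "manifest.tsv"))
    expect_gte(length(unique(man$stage)), 5L)
    cfg$outDir <- out2
    runPipeline(cfg)
    expect_identical(readLines(file.path(out1, "map_clean.tsv")),
                     readLines(file.path(out2, "map_clean.tsv")))
    expect_error(runPipeline(list(seed = 1, outDir = out1, bogus = 2)),
                 "unknown config keys")
    expect_error(runPipeline(list(outDir = out1)), "seed")
})
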