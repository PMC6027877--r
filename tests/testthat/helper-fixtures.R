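# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no stored data.

suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# A cohort built directly from a dosage matrix (markers x individuals),
# for hand-crafted QC/estimation cases. `ped` is a data.frame with the
# pedigree columns; marker positions default to 1e5 * index on one
# chromosome.
makeCohort <- function(dos, ped, chrom = NULL, pos = NULL) {
    nm <- nrow(dos)
    if (is.null(chrom)) chrom <- rep("chr1", nm)
    if (is.null(pos)) pos <- seq_len(nm) * 1e5
    ids <- sprintf("%s_%07d", chrom, pos)
    dimnames(dos) <- list(ids, ped$id)
    gr <- GRanges(chrom, IRanges(pos, width = 1L))
    mcols(gr) <- DataFrame(marker_id = ids, allele1 = rep("A", nm),
                           allele2 = rep("B", nm))
    names(gr) <- ids
    cd <- DataFrame(ped); rownames(cd) <- ped$id
    new("HSCohort", SummarizedExperiment(
        assays = list(dosage = dos), rowRanges = gr, colData = cd))
}

# A minimal pedigree: one family, one sire/dam pair, n offspring.
trioPed <- function(n = 1L, fam = "F01") {
    data.frame(
        id = c(paste0(fam, "_S"), paste0(fam, "_D"),
               sprintf("%s_O%02d", fam, seq_len(n))),
        sire = c(NA, NA, rep(paste0(fam, "_S"), n)),
        dam = c(NA, NA, rep(paste0(fam, "_D"), n)),
        sex = c("male", "female", rep("male", n)),
        family = fam, generation = c(0L, 0L, rep(1L, n)),
        stringsAsFactors = FALSE)
}

# Pedigree with several independent trio families of n offspring each.
famPed <- function(nFam, n = 1L) {
    do.call(rbind, lapply(seq_len(nFam), function(i)
        trioPed(n, sprintf("F%02d", i))))
}

# A small simulated cohort on the given chromosomes (defaults to the two
# smallest rat chromosomes) with full truth tracking.
smallSim <- function(chromosomes = c("chr19", "chr20"), nFamilies = 15,
                     offspringPerFamily = 6, spacingBp = 3e5,
                     errorRate = 0, missingRate = 0,
                     mendelBadMarkerFraction = 0, seed = 1,
                     polymorphicFraction = 0.95, ...) {
    tm <- ratTrueMap(chromosomes = chromosomes)
    panel <- makeMarkerPanel(tm@lengthsBp, spacingBp, seed = seed)
    ped <- buildHSPedigree(nFamilies, offspringPerFamily, seed = seed + 1)
    fh <- simulateFounderHaplotypes(panel, 8, polymorphicFraction,
                                    seed = seed + 2)
    sim <- simulateCohort(ped, fh, tm, panel, errorRate = errorRate,
                          missingRate = missingRate,
                          mendelBadMarkerFraction = mendelBadMarkerFraction,
                          seed = seed + 3, ...)
    list(trueMap = tm, panel = panel, ped = ped, founders = fh,
         cohort = sim$cohort, truth = sim$truth)
}

# Independent brute-force minimum-recombination phasing for one parent:
# enumerate all phase assignments of the heterozygous markers and count
# events between consecutive informative markers of each meiosis.
bruteMinRecombination <- function(t) {
    nh <- nrow(t)
    if (nh < 2) return(0L)
    best <- Inf
    for (code in 0:(2^(nh - 1) - 1)) {
        fl <- as.integer(intToBits(code)[seq_len(nh - 1)])
        phi <- cumsum(c(0L, fl)) %% 2L
        cost <- 0L
        for (j in seq_len(ncol(t))) {
            k <- which(!is.na(t[, j]))
            if (length(k) < 2) next
            z <- (t[k, j] + phi[k]) %% 2L
            cost <- cost + sum(z[-1] != z[-length(z)])
        }
        if (cost < best) best <- cost
    }
    best
}
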