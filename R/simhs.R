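# Synthetic HS-cohort generator: every downstream stage of the pipeline is
# testable against the fully known crossover ground truth produced here.

.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

#' Generate a random marker panel
#'
#' Adjacent-marker gaps are drawn log-normally with median `spacingBp`
#' (sigma 0.6 on the log scale), so the median inter-marker distance of the
#' panel approximates `spacingBp` while gap sizes vary realistically.
#'
#' @param chromosomeLengthsBp named numeric vector of chromosome lengths (bp)
#' @param spacingBp target median adjacent-marker spacing in bp
#' @param seed integer seed (identical seeds give identical panels)
#' @return a [MarkerPanel]
#' @examples
#' panel <- makeMarkerPanel(c(chr1 = 1e6), spacingBp = 10000, seed = 1)
#' @export
makeMarkerPanel <- function(chromosomeLengthsBp, spacingBp, seed = NULL) {
    if (any(chromosomeLengthsBp <= 0) || spacingBp <= 0)
        stop("chromosome lengths and spacing must be positive")
    if (any(chromosomeLengthsBp <= spacingBp))
        stop("every chromosome must be longer than the marker spacing")
    if (is.null(names(chromosomeLengthsBp)))
        names(chromosomeLengthsBp) <- paste0("chr", seq_along(chromosomeLengthsBp))
    .withSeed(seed, {
        out <- lapply(names(chromosomeLengthsBp), function(ch) {
            L <- chromosomeLengthsBp[[ch]]
            n <- ceiling(1.6 * L / spacingBp) + 10L
            gaps <- spacingBp * exp(stats::rnorm(n, 0, 0.6))
            pos <- cumsum(gaps)
            pos <- unique(pmax(1, round(pos[pos <= L])))
            pos <- pos[!duplicated(pos)]
            data.frame(chrom = ch, pos = pos)
        })
        tab <- do.call(rbind, out)
        gr <- GRanges(tab$chrom, IRanges(tab$pos, width = 1L))
        mcols(gr)$marker_id <- sprintf("%s_%07d", tab$chrom, tab$pos)
        mcols(gr)$allele1 <- "A"
        mcols(gr)$allele2 <- "B"
        new("MarkerPanel", gr)
    })
}

#' Build a heterogeneous-stock breeding pedigree
#'
#' Each family has one sire and one dam (founders whose haplotypes are
#' later drawn as mosaics of the inbred founder strains) and a batch of
#' final-generation offspring. Every offspring with both parents genotyped
#' contributes exactly two meioses, so the meiosis count is
#' `2 * round(nFamilies * offspringPerFamily)`.
#'
#' @param nFamilies number of families (> 0)
#' @param offspringPerFamily mean offspring per family; the rounded total
#'   `round(nFamilies * offspringPerFamily)` is distributed as evenly as
#'   possible across families
#' @param nFounderStrains number of inbred founder strains (>= 2; HS rats
#'   descend from eight)
#' @param seed integer seed
#' @return a [Pedigree]
#' @examples
#' ped <- buildHSPedigree(65, 870 / 2 / 65, seed = 1)
#' meiosisCount(ped)   # 870
#' @export
buildHSPedigree <- function(nFamilies, offspringPerFamily,
                            nFounderStrains = 8L, seed = NULL) {
    if (nFamilies < 1) stop("cannot build an empty pedigree (nFamilies < 1)")
    if (nFounderStrains < 2) stop("at least two founder strains are required")
    total <- round(nFamilies * offspringPerFamily)
    if (total < 1) stop("offspringPerFamily too small: no offspring")
    .withSeed(seed, {
        base <- total %/% nFamilies
        counts <- rep(base, nFamilies)
        extra <- total - base * nFamilies
        if (extra > 0) counts[sample.int(nFamilies, extra)] <- base + 1L
        fam <- sprintf("F%03d", seq_len(nFamilies))
        sire <- paste0(fam, "_S"); dam <- paste0(fam, "_D")
        parents <- DataFrame(
            id = c(sire, dam),
            sire = NA_character_, dam = NA_character_,
            sex = rep(c("male", "female"), each = nFamilies),
            family = c(fam, fam), generation = 0L)
        kidfam <- rep(fam, counts)
        kids <- DataFrame(
            id = unlist(lapply(seq_len(nFamilies), function(i)
                sprintf("%s_O%02d", fam[i], seq_len(counts[i]))), use.names = FALSE),
            sire = paste0(kidfam, "_S"), dam = paste0(kidfam, "_D"),
            sex = sample(c("male", "female"), total, replace = TRUE),
            family = kidfam, generation = 1L)
        ped <- rbind(parents, kids)
        metadata(ped)$nFounderStrains <- as.integer(nFounderStrains)
        new("Pedigree", ped)
    })
}

#' Simulate inbred founder-strain haplotypes
#'
#' Each strain is fully inbred (its two haplotypes are identical), so one
#' haplotype row per strain suffices. A `polymorphicFraction` of markers
#' segregate (at least two alleles across strains, allele-1 frequency drawn
#' binomially); the remainder are monomorphic, which downstream QC must
#' remove.
#'
#' @param panel a [MarkerPanel]
#' @param nStrains number of inbred strains (>= 2)
#' @param polymorphicFraction fraction of markers polymorphic across strains
#' @param seed integer seed
#' @return integer matrix (strains x markers) of alleles coded 0/1, with
#'   `dimnames` strain/marker ids and attribute `polymorphic` (logical)
#' @export
simulateFounderHaplotypes <- function(panel, nStrains = 8L,
                                      polymorphicFraction = 0.9, seed = NULL) {
    if (nStrains < 2) stop("at least two strains are required")
    if (polymorphicFraction <= 0 || polymorphicFraction > 1)
        stop("polymorphicFraction must lie in (0, 1]")
    nm <- length(panel)
    .withSeed(seed, {
        poly <- stats::runif(nm) < polymorphicFraction
        H <- matrix(0L, nStrains, nm,
                    dimnames = list(sprintf("strain%d", seq_len(nStrains)),
                                    mcols(panel)$marker_id))
        npoly <- sum(poly)
        if (npoly) {
            Hp <- matrix(stats::rbinom(nStrains * npoly, 1L, 0.5), nStrains, npoly)
            cs <- colSums(Hp)
            fix <- which(cs == 0L | cs == nStrains)
            if (length(fix)) {
                flip <- sample.int(nStrains, length(fix), replace = TRUE)
                Hp[cbind(flip, fix)] <- 1L - Hp[cbind(flip, fix)]
            }
            H[, poly] <- Hp
        }
        if (any(!poly))
            H[, !poly] <- rep(stats::rbinom(sum(!poly), 1L, 0.5), each = nStrains)
        attr(H, "polymorphic") <- poly
        H
    })
}

# Crossover positions for one chromosome: Poisson count on the cM scale
# (no interference), uniform on cM, mapped to bp by inverting the truth
# landscape. Returns sorted bp positions (possibly empty).
.drawCrossoverBp <- function(anchor, sexcol) {
    L <- anchor[[sexcol]][nrow(anchor)]
    if (L <= 0) return(numeric(0))
    nxo <- stats::rpois(1L, L / 100)
    if (nxo == 0L) return(numeric(0))
    sort(.truthBp(anchor, sort(stats::runif(nxo, 0, L)), sexcol))
}

#' Draw one gamete from a pair of parental haplotypes
#'
#' Crossover counts per chromosome are Poisson(total cM / 100) (Haldane's
#' no-interference model); positions are uniform on the cM scale and mapped
#' to bp through the inverse of the truth landscape. The transmitted
#' haplotype alternates across crossovers, starting from a fair coin.
#'
#' @param haplotypes list of two haplotypes, each a named list per
#'   chromosome of 0/1 integer allele vectors in panel order
#' @param panel the [MarkerPanel] the haplotypes are indexed on
#' @param trueMap a [TrueRecombinationMap]
#' @param parentSex "male" or "female" (selects the sex-specific landscape)
#' @return list with `gamete` (per-chromosome allele vectors) and
#'   `crossovers` (data.frame chrom, bp)
#' @export
drawGamete <- function(haplotypes, panel, trueMap,
                       parentSex = c("male", "female")) {
    parentSex <- match.arg(parentSex)
    sexcol <- paste0("cM_", parentSex)
    pos <- .splitKeepOrder(start(panel), as.character(seqnames(panel)))
    gam <- list(); xo <- list()
    for (ch in names(pos)) {
        anchor <- trueMap@anchors[[ch]]
        if (is.null(anchor)) stop("true map not defined for chromosome ", ch)
        bp <- .drawCrossoverBp(anchor, sexcol)
        startHap <- sample.int(2L, 1L)
        seg <- findInterval(pos[[ch]], bp)
        use2 <- (seg + startHap) %% 2L == 0L
        g <- haplotypes[[1L]][[ch]]
        g[use2] <- haplotypes[[2L]][[ch]][use2]
        gam[[ch]] <- g
        if (length(bp)) xo[[ch]] <- data.frame(chrom = ch, bp = bp)
    }
    list(gamete = gam,
         crossovers = if (length(xo)) do.call(rbind, xo)
                      else data.frame(chrom = character(0), bp = numeric(0)))
}

# Build one parental haplotype as a two-strain mosaic: a single simulated
# meiosis over a random pair of distinct founder strains.
.strainMosaic <- function(founders, posByChr, trueMap, sexcol) {
    pair <- sample.int(nrow(founders), 2L)
    hap <- list(); blocks <- list()
    off <- 0L
    for (ch in names(posByChr)) {
        p <- posByChr[[ch]]
        bp <- .drawCrossoverBp(trueMap@anchors[[ch]], sexcol)
        startHap <- sample.int(2L, 1L)
        seg <- findInterval(p, bp)
        pick <- pair[1L + (seg + startHap) %% 2L]
        idx <- off + seq_along(p)
        h <- founders[cbind(pick, idx)]
        hap[[ch]] <- as.integer(h)
        blocks[[ch]] <- pick
        off <- off + length(p)
    }
    list(hap = hap, labels = blocks)
}

#' Simulate genotypes for a whole HS cohort
#'
#' Parent haplotypes are random two-strain mosaics of the founder strains;
#' offspring receive one recombinant gamete from each parent (sex-specific
#' landscapes). Genotyping error is a symmetric per-call allele flip at
#' `errorRate`; a `mendelBadMarkerFraction` of markers instead get
#' `badErrorRate`, planting the high-Mendelian-error markers that QC must
#' remove. Calls go missing independently at `missingRate`.
#'
#' @param ped a [Pedigree] (two generations: founder parents + offspring)
#' @param founders founder haplotype matrix from
#'   [simulateFounderHaplotypes()]
#' @param trueMap a [TrueRecombinationMap]
#' @param panel the [MarkerPanel]
#' @param errorRate per-call allele-flip probability
#' @param missingRate per-call missingness probability
#' @param mendelBadMarkerFraction fraction of markers planted with
#'   `badErrorRate` instead of `errorRate`
#' @param badErrorRate per-call error rate at planted bad markers
#' @param trackFounders if TRUE, store per-marker founder-strain labels of
#'   every parental haplotype in the truth object (memory heavy; offspring
#'   mosaics are compositions of these and the recorded crossovers)
#' @param trackGametes if TRUE, store every transmitted gamete and parent
#'   haplotype pair in the truth object (memory heavy; enables exact
#'   transmission-recovery checks in tests)
#' @param seed integer seed; identical seeds give bit-identical cohorts
#' @return list with `cohort` (an [HSCohort]) and `truth` (a [CohortTruth])
#' @export
simulateCohort <- function(ped, founders, trueMap, panel,
                           errorRate = 0.002, missingRate = 0.02,
                           mendelBadMarkerFraction = 0.01,
                           badErrorRate = 0.15,
                           trackFounders = FALSE, trackGametes = FALSE,
                           seed = NULL) {
    stopifnot(is(ped, "Pedigree"), is(trueMap, "TrueRecombinationMap"))
    for (r in c(errorRate, missingRate, mendelBadMarkerFraction, badErrorRate))
        if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
    if (nrow(founders) < 2) stop("founder haplotype set needs >= 2 strains")
    chrs <- as.character(seqnames(panel))
    posByChr <- .splitKeepOrder(start(panel), chrs)
    if (!all(names(posByChr) %in% chromosomes(trueMap)))
        stop("true map must cover every panel chromosome")
    nm <- length(panel); ids <- ped$id; ni <- length(ids)
    isKid <- !is.na(ped$sire)
    if (!all(ped$sire[isKid] %in% ids) || !all(ped$dam[isKid] %in% ids))
        stop("pedigree references unknown parents")
    .withSeed(seed, {
        haps <- vector("list", ni); names(haps) <- ids
        labels <- if (trackFounders) list() else NULL
        xoRecs <- list()
        # parent (founder) haplotypes: two independent strain mosaics,
        # maternal-side via the female landscape, paternal-side via the male
        for (i in which(!isKid)) {
            m1 <- .strainMosaic(founders, posByChr, trueMap, "cM_female")
            m2 <- .strainMosaic(founders, posByChr, trueMap, "cM_male")
            haps[[ids[i]]] <- list(m1$hap, m2$hap)
            if (trackFounders)
                labels[[ids[i]]] <- list(m1$labels, m2$labels)
        }
        # offspring gametes: the meioses the estimator will see
        gam <- if (trackGametes) list() else NULL
        for (i in which(isKid)) {
            gs <- drawGamete(haps[[ped$sire[i]]], panel, trueMap, "male")
            gd <- drawGamete(haps[[ped$dam[i]]], panel, trueMap, "female")
            haps[[ids[i]]] <- list(gd$gamete, gs$gamete)
            if (trackGametes) {
                gam[[paste0(ids[i], ".paternal")]] <- gs$gamete
                gam[[paste0(ids[i], ".maternal")]] <- gd$gamete
            }
            if (nrow(gs$crossovers))
                xoRecs[[length(xoRecs) + 1L]] <- cbind(
                    offspring = ids[i], parent = ped$sire[i],
                    parentSex = "male", gs$crossovers)
            if (nrow(gd$crossovers))
                xoRecs[[length(xoRecs) + 1L]] <- cbind(
                    offspring = ids[i], parent = ped$dam[i],
                    parentSex = "female", gd$crossovers)
        }
        dos <- matrix(NA_integer_, nm, ni,
                      dimnames = list(mcols(panel)$marker_id, ids))
        for (i in seq_len(ni)) {
            h <- haps[[ids[i]]]
            dos[, i] <- unlist(h[[1L]], use.names = FALSE) +
                        unlist(h[[2L]], use.names = FALSE)
        }
        # plant bad markers, then corrupt calls by symmetric allele flips
        nbad <- round(mendelBadMarkerFraction * nm)
        bad <- if (nbad) sort(sample.int(nm, nbad)) else integer(0)
        rate <- rep(errorRate, nm); rate[bad] <- badErrorRate
        err <- which(matrix(stats::runif(nm * ni), nm, ni) < rate)
        if (length(err)) {
            g <- dos[err]
            flipUp <- stats::runif(length(err)) < 0.5
            g <- ifelse(g == 0L, 1L, ifelse(g == 2L, 1L, ifelse(flipUp, 2L, 0L)))
            dos[err] <- as.integer(g)
        }
        miss <- which(matrix(stats::runif(nm * ni), nm, ni) < missingRate)
        if (length(miss)) dos[miss] <- NA_integer_
        corrupted <- data.frame(
            marker_id = rownames(dos)[c((err - 1L) %% nm + 1L, (miss - 1L) %% nm + 1L)],
            individual = ids[c((err - 1L) %/% nm + 1L, (miss - 1L) %/% nm + 1L)],
            type = rep(c("error", "missing"), c(length(err), length(miss))))
        gr <- GRanges(chrs, IRanges(start(panel), width = 1L))
        mcols(gr) <- mcols(panel)
        mcols(gr)$bad_planted <- seq_len(nm) %in% bad
        names(gr) <- mcols(panel)$marker_id
        cd <- as(ped, "DFrame")
        rownames(cd) <- cd$id
        cohort <- new("HSCohort", SummarizedExperiment(
            assays = list(dosage = dos), rowRanges = gr, colData = cd))
        xo <- if (length(xoRecs)) do.call(rbind, xoRecs)
              else data.frame(offspring = character(0), parent = character(0),
                              parentSex = character(0), chrom = character(0),
                              bp = numeric(0))
        fb <- if (trackFounders) {
            do.call(rbind, lapply(names(labels), function(id)
                do.call(rbind, lapply(1:2, function(hp)
                    do.call(rbind, lapply(names(labels[[id]][[hp]]), function(ch)
                        data.frame(individual = id, hap = hp, chrom = ch,
                                   marker_idx = seq_along(labels[[id]][[hp]][[ch]]),
                                   strain = labels[[id]][[hp]][[ch]])))))))
        } else data.frame()
        truth <- new("CohortTruth", crossovers = xo, founderBlocks = fb,
                     corrupted = corrupted, displaced = character(0),
                     gametes = if (trackGametes) gam else list(),
                     parentHaplotypes = if (trackGametes)
                         haps[!isKid] else list())
        list(cohort = cohort, truth = truth)
    })
}

#' Displace a fraction of marker physical positions
#'
#' Emulates assembly errors: selected markers are moved at least
#' `minShiftBp` away (uniformly over the admissible range of their
#' chromosome); genetic data are untouched, so the displaced markers become
#' "errant" -- their genetic position disagrees with the recorded physical
#' one, which the residual filter should catch.
#'
#' @param panel a [MarkerPanel]
#' @param fraction fraction of markers to displace (< 0.2: cleaning assumes
#'   errant markers are a minority)
#' @param minShiftBp minimum displacement in bp
#' @param seed integer seed
#' @return list with `panel` (re-sorted [MarkerPanel]) and `displaced`
#'   (character vector of displaced marker ids)
#' @export
corruptMarkerPositions <- function(panel, fraction, minShiftBp, seed = NULL) {
    if (fraction < 0 || fraction >= 0.2)
        stop("fraction must lie in [0, 0.2): errant markers must be a minority")
    if (fraction == 0) return(list(panel = panel, displaced = character(0)))
    .withSeed(seed, {
        chrs <- as.character(seqnames(panel))
        pos <- start(panel)
        bound <- tapply(pos, chrs, max)
        n <- length(panel)
        idx <- sort(sample.int(n, round(fraction * n)))
        newpos <- pos
        for (i in idx) {
            L <- bound[[chrs[i]]]
            repeat {
                cand <- round(stats::runif(1, 1, L))
                if (abs(cand - pos[i]) >= minShiftBp &&
                    !cand %in% newpos[chrs == chrs[i]]) break
                if (L <= 2 * minShiftBp && abs(cand - pos[i]) >= minShiftBp) break
            }
            newpos[i] <- cand
        }
        ord <- order(factor(chrs, levels = unique(chrs)), newpos)
        gr <- GRanges(chrs[ord], IRanges(newpos[ord], width = 1L))
        mcols(gr) <- mcols(panel)[ord, , drop = FALSE]
        names(gr) <- mcols(gr)$marker_id
        mcols(gr)$displaced <- mcols(panel)$marker_id[ord] %in%
            mcols(panel)$marker_id[idx]
        list(panel = new("MarkerPanel", gr),
             displaced = mcols(panel)$marker_id[idx])
    })
}

#' Apply a (re-ordered) marker panel to a cohort
#'
#' Reindexes the dosage rows of a cohort to follow a new panel (e.g. after
#' [corruptMarkerPositions()]); markers are matched by `marker_id`.
#'
#' @param cohort an [HSCohort]
#' @param panel the new [MarkerPanel] (same marker ids)
#' @return an [HSCohort] in the new panel order
#' @export
applyPanel <- function(cohort, panel) {
    ids <- mcols(panel)$marker_id
    if (!setequal(ids, rownames(cohort)))
        stop("panel and cohort must carry the same markers")
    se <- cohort[match(ids, rownames(cohort)), ]
    gr <- GRanges(as.character(seqnames(panel)), IRanges(start(panel), width = 1L))
    mcols(gr) <- mcols(panel)
    names(gr) <- ids
    SummarizedExperiment::rowRanges(se) <- gr
    new("HSCohort", se)
}
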