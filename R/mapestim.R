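# Sex-specific map estimation from pedigree genotypes with markers in fixed
# physical order: parental-genotype inference, segregation-distortion
# filtering, phasing/transmission extraction, per-interval recombination
# fractions and cumulative map assembly.

#' Infer missing parental genotypes from relatives
#'
#' A missing parental call is imputed only when it is logically forced by
#' the non-missing calls of the other parent and the offspring (e.g. an
#' offspring carrying an allele absent from the other parent forces the
#' missing parent to carry it; homozygosity is inferred only when a single
#' genotype is compatible with every informative relative). Calls that are
#' compatible with more than one genotype stay missing. A marker where no
#' parental genotype is compatible with some family is flagged
#' (`parent_contradiction` in the panel metadata), not imputed.
#'
#' @param cohort an [HSCohort]
#' @return an [HSCohort] with forced parental calls filled in
#' @export
callParents <- function(cohort) {
    d <- dosage(cohort)
    ped <- pedigree(cohort)
    contra <- logical(nrow(d))
    kids <- ped$id[!is.na(ped$sire)]
    fams <- .splitKeepOrder(kids, ped$family[match(kids, ped$id)])
    for (off in fams) {
        sire <- ped$sire[match(off[1], ped$id)]
        dam <- ped$dam[match(off[1], ped$id)]
        O <- d[, off, drop = FALSE]
        anyOff <- rowSums(!is.na(O)) > 0L
        for (side in 1:2) {
            p <- if (side == 1) sire else dam
            q <- if (side == 1) dam else sire
            fix <- which(is.na(d[, p]) & !is.na(d[, q]) & anyOff)
            if (!length(fix)) next
            qv <- d[fix, q]
            compat <- matrix(TRUE, length(fix), 3)
            for (cand in 0:2) {
                okAll <- rep(TRUE, length(fix))
                for (o in seq_len(ncol(O))) {
                    ov <- O[fix, o]
                    known <- !is.na(ov)
                    if (!any(known)) next
                    lk <- .mendelOK[cbind(rep(cand + 1L, sum(known)),
                                          qv[known] + 1L, ov[known] + 1L)]
                    okAll[known] <- okAll[known] & lk
                }
                compat[, cand + 1L] <- okAll
            }
            ncomp <- rowSums(compat)
            forced <- ncomp == 1L
            if (any(forced))
                d[cbind(fix[forced], match(p, colnames(d)))] <-
                    as.integer(compat[forced, , drop = FALSE] %*% (0:2))
            contra[fix[ncomp == 0L]] <- TRUE
        }
    }
    se <- cohort
    SummarizedExperiment::assay(se, "dosage") <- d
    rr <- rowRanges(se)
    mcols(rr)$parent_contradiction <- contra
    SummarizedExperiment::rowRanges(se) <- rr
    new("HSCohort", se)
}

# Mating-type codes for pooled segregation tests: expectation over offspring
# dosage given (unordered) parental dosages; deterministic types carry no
# degrees of freedom. Cells with expected count 0 are pooled with their
# neighbouring cell.
.matingExp <- list(
    `0_1` = list(groups = list(1L, 2:3), p = c(0.5, 0.5)),
    `1_1` = list(groups = list(1L, 2L, 3L), p = c(0.25, 0.5, 0.25)),
    `1_2` = list(groups = list(1:2, 3L), p = c(0.5, 0.5)))

#' Remove markers with segregation distortion
#'
#' Pooled offspring genotype counts (across families, grouped by parental
#' mating type) are tested against Mendelian expectations with a Pearson
#' chi-square statistic; zero-expectation cells are pooled with their
#' neighbour. Markers with p-value strictly below `pMin` are removed.
#' Markers with no informative mating type are retained.
#'
#' @param cohort an [HSCohort]
#' @param pMin removal threshold on the chi-square p-value
#' @return list with `cohort` (filtered), `removed` (marker ids), and
#'   `stats` (data.frame marker_id, statistic, df, p)
#' @export
distortionFilter <- function(cohort, pMin = 0.001) {
    d <- dosage(cohort)
    ped <- pedigree(cohort)
    nm <- nrow(d)
    counts <- array(0L, c(nm, 3L, 3L))  # marker x mating type x offspring geno
    kids <- which(!is.na(ped$sire))
    for (i in kids) {
        s <- d[, ped$sire[i]]; m <- d[, ped$dam[i]]; o <- d[, ped$id[i]]
        keep <- !is.na(s) & !is.na(m) & !is.na(o)
        if (!any(keep)) next
        lo <- pmin(s[keep], m[keep]); hi <- pmax(s[keep], m[keep])
        type <- ifelse(lo == 0L & hi == 1L, 1L,
                ifelse(lo == 1L & hi == 1L, 2L,
                ifelse(lo == 1L & hi == 2L, 3L, NA_integer_)))
        tk <- !is.na(type)
        if (!any(tk)) next
        idx <- cbind(which(keep)[tk], type[tk], o[keep][tk] + 1L)
        counts[idx] <- counts[idx] + 1L
    }
    stat <- numeric(nm); df <- integer(nm)
    for (t in 1:3) {
        spec <- .matingExp[[t]]
        obs <- vapply(spec$groups, function(g)
            rowSums(counts[, t, g, drop = FALSE], dims = 1), numeric(nm))
        if (is.null(dim(obs))) obs <- matrix(obs, nrow = nm)
        n <- rowSums(obs)
        use <- n > 0
        if (!any(use)) next
        E <- outer(n[use], spec$p)
        stat[use] <- stat[use] + rowSums((obs[use, , drop = FALSE] - E)^2 / E)
        df[use] <- df[use] + length(spec$p) - 1L
    }
    p <- ifelse(df > 0L, stats::pchisq(stat, df, lower.tail = FALSE), NA_real_)
    drop <- !is.na(p) & p < pMin
    list(cohort = new("HSCohort", cohort[!drop, ]),
         removed = rownames(cohort)[drop],
         stats = data.frame(marker_id = rownames(cohort),
                            statistic = stat, df = df, p = p))
}

# Transmitted-allele matrix for one parent on one chromosome:
# rows = heterozygous markers of the parent, cols = offspring;
# values 0/1 (allele2 transmitted?) or NA where ambiguous/impossible.
.transmissions <- function(het, pDos, qDos, O) {
    q <- qDos[het]
    Ov <- O[het, , drop = FALSE]
    t <- matrix(NA_integer_, length(het), ncol(Ov))
    q0 <- which(q %in% 0L); q2 <- which(q %in% 2L)
    qh <- which(is.na(q) | q == 1L)
    if (length(q0)) {
        v <- Ov[q0, , drop = FALSE]
        t[q0, ] <- ifelse(v == 2L, NA_integer_, v)
    }
    if (length(q2)) {
        v <- Ov[q2, , drop = FALSE]
        t[q2, ] <- ifelse(v == 0L, NA_integer_, v - 1L)
    }
    if (length(qh)) {
        v <- Ov[qh, , drop = FALSE]
        t[qh, ] <- ifelse(v == 0L, 0L, ifelse(v == 2L, 1L, NA_integer_))
    }
    t
}

# Haplotype flow of one meiosis: the indicator at a position is known when
# the nearest informative flanks (within one phase segment) agree; at
# informative positions it is the observed indicator itself.
.flowFill <- function(z, seg) {
    n <- length(z)
    known <- !is.na(z)
    out <- rep(NA_integer_, n)
    gap <- rep(NA_integer_, n)
    if (!any(known)) return(structure(out, gap = gap))
    idx <- seq_len(n)
    prev <- cummax(ifelse(known, idx, 0L))
    nxt <- rev(cummin(rev(ifelse(known, idx, n + 1L))))
    ok <- prev > 0L & nxt <= n &
        seg[pmax(prev, 1L)] == seg & seg[pmin(nxt, n)] == seg
    ok[ok] <- z[prev[ok]] == z[nxt[ok]]
    out[ok] <- z[prev[ok]]
    gap[ok] <- nxt[ok] - prev[ok]
    structure(out, gap = gap)
}


# Repair coherent switch clusters: independent meioses essentially never
# recombine in the same small marker window, so a window where most of a
# parent's meioses (and at least minCount) show a haplotype switch marks a
# phase/genotype artefact, not recombination. Each affected meiosis has its
# own switch removed (suffix flip); only within-meiosis switches carry
# recombination evidence, so per-meiosis flips are safe.
.repairCoherentSwitches <- function(z, minCount = 3L, minFrac = 0.6,
                                    radius = 2L) {
    nh <- nrow(z); noff <- ncol(z)
    if (nh < 3L) return(z)
    idx <- seq_len(nh)
    for (it in seq_len(25L)) {
        swM <- matrix(FALSE, nh, noff); covM <- matrix(FALSE, nh, noff)
        for (j in seq_len(noff)) {
            known <- !is.na(z[, j])
            if (sum(known) < 2L) next
            prevv <- cummax(ifelse(known, idx, 0L))
            nxt0 <- rev(cummin(rev(ifelse(known, idx, nh + 1L))))
            pB <- c(rep(0L, radius + 1L), prevv)[seq_len(nh)]
            nA <- c(nxt0[-seq_len(radius + 1L)], rep(nh + 1L, radius + 1L))
            ok <- pB > 0L & nA <= nh
            covM[ok, j] <- TRUE
            swM[ok, j] <- z[cbind(pB[ok], j)] != z[cbind(nA[ok], j)]
        }
        sw <- rowSums(swM); cov <- rowSums(covM)
        bad <- which(sw >= minCount & sw > minFrac * pmax(cov, 1))
        if (!length(bad)) break
        m <- bad[1L]
        changed <- FALSE
        for (j in which(swM[m, ])) {
            k <- which(!is.na(z[, j]))
            a <- k[-length(k)]; b <- k[-1L]
            inWin <- which(b >= m - radius & a <= m + radius &
                           z[cbind(a, j)] != z[cbind(b, j)])
            if (!length(inWin)) next
            bo <- b[inWin[1L]]
            z[bo:nh, j] <- 1L - z[bo:nh, j]
            changed <- TRUE
        }
        if (!changed) break
    }
    z
}


# First and last entry of every segment (all entries of segments shorter
# than three markers).
.segmentEnds <- function(seg) {
    first <- !duplicated(seg)
    last <- !duplicated(seg, fromLast = TRUE)
    first | last
}

# Interior runs of identical haplotype state with length <= maxRun, fully
# inside one phase segment and not touching discordant markers, are
# treated as genotyping errors and dropped from the meiosis track.
.maskShortRuns <- function(z, seg, maxRun, isDisc) {
    n <- length(z)
    drop <- logical(n)
    for (sg in unique(seg)) {
        ix <- which(seg == sg)
        if (length(ix) < 3L) next
        r <- rle(z[ix])
        if (length(r$lengths) < 3L) next
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        short <- which(r$lengths <= maxRun)
        short <- short[short > 1L & short < length(r$lengths)]
        for (q in short) {
            run <- ix[starts[q]:ends[q]]
            if (any(isDisc[run])) next
            drop[run] <- TRUE
        }
    }
    drop
}

# Total recombination events implied by a phase assignment: per meiosis,
# state changes between consecutive informative markers.
.phaseCost <- function(t, phi) {
    cost <- 0L
    for (j in seq_len(ncol(t))) {
        k <- which(!is.na(t[, j]))
        if (length(k) < 2L) next
        z <- (t[k, j] + phi[k]) %% 2L
        cost <- cost + sum(z[-1L] != z[-length(z)])
    }
    cost
}
# Segment labels: links crossed by no informative pair of any meiosis
# split the phase chain (relative phase across them is undetermined).
.chainSegments <- function(t) {
    nh <- nrow(t)
    if (nh <= 1L) return(rep(1L, nh))
    cover <- numeric(nh)
    for (j in seq_len(ncol(t))) {
        k <- which(!is.na(t[, j]))
        if (length(k) < 2L) next
        aa <- k[-length(k)]; bb <- k[-1L]
        cover[aa] <- cover[aa] + 1; cover[bb] <- cover[bb] - 1
    }
    covered <- cumsum(cover)[-nh] > 0
    cumsum(c(1L, as.integer(!covered)))
}

# Coordinate-descent fallback for parents with many genotyped offspring
# (link flips plus single-marker flips; monotone in the event count).
.phaseChainHeuristic <- function(t) {
    nh <- nrow(t)
    nL <- nh - 1L
    offPairs <- lapply(seq_len(ncol(t)), function(j) {
        k <- which(!is.na(t[, j]))
        if (length(k) < 2L) return(NULL)
        list(k = k, tv = t[k, j])
    })
    offPairs <- offPairs[!vapply(offPairs, is.null, logical(1))]
    a <- t[-nh, , drop = FALSE]; b <- t[-1L, , drop = FALSE]
    both <- !is.na(a) & !is.na(b)
    diffc <- rowSums(both & (a != b)); samec <- rowSums(both & (a == b))
    phi <- cumsum(c(0L, as.integer(diffc > samec))) %% 2L
    cost <- .phaseCost(t, phi)
    tryMove <- function(phi2) {
        c2 <- .phaseCost(t, phi2)
        if (c2 < cost) { phi <<- phi2; cost <<- c2; TRUE } else FALSE
    }
    for (it in seq_len(50L)) {
        D <- numeric(nL + 1L); S <- numeric(nL + 1L)
        Dm <- numeric(nh); Sm <- numeric(nh)
        for (op in offPairs) {
            z <- (op$tv + phi[op$k]) %% 2L
            mis <- z[-1L] != z[-length(z)]
            aa <- op$k[-length(op$k)]; bb <- op$k[-1L]
            D[aa[mis]] <- D[aa[mis]] + 1; D[bb[mis]] <- D[bb[mis]] - 1
            S[aa[!mis]] <- S[aa[!mis]] + 1; S[bb[!mis]] <- S[bb[!mis]] - 1
            Dm[aa[mis]] <- Dm[aa[mis]] + 1; Dm[bb[mis]] <- Dm[bb[mis]] + 1
            Sm[aa[!mis]] <- Sm[aa[!mis]] + 1; Sm[bb[!mis]] <- Sm[bb[!mis]] + 1
        }
        linkGain <- cumsum(D[seq_len(nL)]) - cumsum(S[seq_len(nL)])
        markGain <- Dm - Sm
        improved <- FALSE
        cand <- which(linkGain > 0)
        if (length(cand)) {
            phi2 <- phi
            phi2[-1L] <- (phi2[-1L] +
                cumsum(replace(integer(nL), cand, 1L))) %% 2L
            improved <- tryMove(phi2)
            if (!improved) {
                j <- cand[which.max(linkGain[cand])]
                phi2 <- phi
                phi2[(j + 1L):nh] <- 1L - phi2[(j + 1L):nh]
                improved <- tryMove(phi2)
            }
        }
        if (!improved) {
            candM <- which(markGain > 0)
            if (length(candM)) {
                phi2 <- phi; phi2[candM] <- 1L - phi2[candM]
                improved <- tryMove(phi2)
                if (!improved) {
                    m <- candM[which.max(markGain[candM])]
                    phi2 <- phi; phi2[m] <- 1L - phi2[m]
                    improved <- tryMove(phi2)
                }
            }
        }
        if (!improved) break
    }
    as.integer(phi)
}

# Phase one parent's heterozygous-marker chain; exact DP (compiled) when
# the number of meioses permits, heuristic refinement otherwise.
.phaseChain <- function(t, maxMeioses = 14L) {
    nh <- nrow(t)
    if (nh == 0L) return(list(phi = integer(0), seg = integer(0)))
    if (nh == 1L) return(list(phi = 0L, seg = 1L))
    phi <- if (ncol(t) <= maxMeioses) .phaseDPCpp(t)
           else .phaseChainHeuristic(t)
    list(phi = phi, seg = .chainSegments(t))
}

#' Extract phased transmissions (meioses) from a cohort
#'
#' For every heterozygous parent the relative phase of consecutive
#' heterozygous markers is chosen to minimize the total number of
#' recombination events across the parent's meioses (greedy chain; exact
#' for the pairwise recombination count, ties resolved toward the phase
#' consistent with the previous informative block). Each meiosis then
#' yields a transmitted-haplotype indicator along the chromosome.
#'
#' Two marker-hygiene rules are applied on top of the raw indicators:
#' an isolated flip (a haplotype state disagreeing with both informative
#' neighbours -- an apparent double crossover confined to a single marker)
#' is masked as a presumptive genotyping error, but only at markers whose
#' cohort-wide isolated-flip rate is at most `flipRateMax`; markers above
#' that rate are labelled *discordant* (their genetic behaviour disagrees
#' with their recorded physical position, as for physically misplaced
#' markers) and are kept unmasked but excluded from the map backbone, to be
#' positioned by their direct recombination distance to neighbours and
#' later judged by the residual filter.
#'
#' @param cohort an [HSCohort] (QC-cleaned, markers in physical order)
#' @param flipRateMax isolated-flip rate above which a marker is declared
#'   discordant rather than error-masked
#' @param minFlipInf minimum informative triples before a marker can be
#'   declared discordant
#' @param maskRun maximum length (in informative markers) of an interior
#'   haplotype run that is masked as a presumptive genotyping error
#'   (0 disables masking)
#' @param repairClusters repair coherent switch clusters (several meioses
#'   of one parent apparently recombining in the same small window --
#'   a phase or genotype artefact, not recombination)
#' @param trimSegmentEnds drop the first and last informative entry of
#'   every phase segment, whose calls cannot be error-screened
#' @return a [MeiosisSet]
#' @export
phaseAndExtract <- function(cohort, flipRateMax = 0.03, minFlipInf = 10L,
                            maskRun = 2L, repairClusters = TRUE,
                            trimSegmentEnds = TRUE) {
    d <- dosage(cohort)
    ped <- pedigree(cohort)
    panel <- markerPanel(cohort)
    chrs <- as.character(seqnames(panel))
    chrLevels <- unique(chrs)
    pos <- start(panel)
    kids <- which(!is.na(ped$sire) & !is.na(ped$dam))
    meio <- data.frame(
        offspring = rep(ped$id[kids], each = 2L),
        parent = as.vector(rbind(ped$sire[kids], ped$dam[kids])),
        parentSex = rep(c("male", "female"), length(kids)),
        family = rep(ped$family[kids], each = 2L),
        stringsAsFactors = FALSE)
    nmTotal <- nrow(d)
    flips <- numeric(nmTotal); inf3 <- numeric(nmTotal); hetn <- numeric(nmTotal)
    transRaw <- list()
    for (ch in chrLevels) {
        rows <- which(chrs == ch)
        chList <- .extractChromosome(d[rows, , drop = FALSE], ped, meio,
                                     exclude = integer(0),
                                     repairClusters = repairClusters)
        # isolated-flip statistics per marker (pooled over all meioses)
        for (tr in chList) {
            if (is.null(tr) || length(tr$idx) < 3L) next
            len <- length(tr$idx)
            mid <- 2:(len - 1L)
            use <- tr$seg[mid - 1L] == tr$seg[mid + 1L] &
                tr$z[mid - 1L] == tr$z[mid + 1L]
            if (!any(use)) next
            g <- rows[tr$idx[mid[use]]]
            isFlip <- tr$z[mid[use]] != tr$z[mid[use] - 1L]
            inf3[g] <- inf3[g] + 1
            flips[g] <- flips[g] + as.numeric(isFlip)
        }
        for (tr in chList) if (!is.null(tr)) hetn[rows[tr$idx]] <-
            hetn[rows[tr$idx]] + 1
        transRaw[[ch]] <- chList
    }
    rate <- ifelse(inf3 > 0, flips / inf3, 0)
    # a marker needs several independent apparent double crossovers before
    # it is declared discordant; one or two can be chance
    discordant <- inf3 >= minFlipInf & flips >= 3 & rate > flipRateMax
    # second extraction with discordant markers excluded entirely, so one
    # errant marker cannot distort phasing, double-heterozygote resolution
    # or the backbone; the raw tracks are kept for positioning the
    # discordant markers by their direct recombination distances
    trans <- list()
    for (ch in chrLevels) {
        rows <- which(chrs == ch)
        disc <- which(discordant[rows])
        chList <- if (length(disc))
            .extractChromosome(d[rows, , drop = FALSE], ped, meio,
                               exclude = disc,
                               repairClusters = repairClusters)
        else transRaw[[ch]]
        # mask short interior runs (presumptive genotyping errors) and trim
        # segment ends, whose entries cannot be error-screened
        clean <- function(lst, discSet) {
            for (k in seq_along(lst)) {
                tr <- lst[[k]]
                if (is.null(tr) || length(tr$idx) < 3L) next
                dropIt <- .maskShortRuns(tr$z, tr$seg, maskRun,
                                         tr$idx %in% discSet)
                if (trimSegmentEnds) dropIt <- dropIt | .segmentEnds(tr$seg)
                if (any(dropIt)) {
                    keep <- which(!dropIt)
                    lst[[k]] <- list(idx = tr$idx[keep], z = tr$z[keep],
                                     seg = tr$seg[keep])
                }
            }
            lst
        }
        trans[[ch]] <- clean(chList, integer(0))
        transRaw[[ch]] <- clean(transRaw[[ch]], disc)
    }
    stats <- data.frame(
        chrom = chrs, marker_id = mcols(panel)$marker_id, bp = pos,
        informative = hetn, flipInf = inf3, flipCount = flips,
        flipRate = rate, discordant = discordant,
        stringsAsFactors = FALSE)
    new("MeiosisSet", meioses = meio, transmissions = trans,
        transmissionsRaw = transRaw,
        markerStats = stats,
        params = list(flipRateMax = flipRateMax, minFlipInf = minFlipInf,
                      maskRun = maskRun))
}

# One chromosome's phased transmissions: pass A derives directly
# determined transmitted alleles per parent (screening out presumptive
# miscalled heterozygotes with unanimous transmissions); pass B resolves
# double-heterozygous transmissions through the mate's phased haplotype
# flow; pass C re-phases the augmented matrix and repairs coherent switch
# clusters. `exclude` removes markers (row indices) from every chain.
.extractChromosome <- function(dch, ped, meio, exclude = integer(0),
                               repairClusters = TRUE) {
    nMeio <- nrow(meio)
    chList <- vector("list", nMeio)
    parents <- unique(meio$parent)
    pdat <- vector("list", length(parents)); names(pdat) <- parents
    for (p in parents) {
        mIdx <- which(meio$parent == p)
        offs <- meio$offspring[mIdx]
        qcol <- if (meio$parentSex[mIdx[1]] == "male") "dam" else "sire"
        q <- ped[[qcol]][match(offs[1], ped$id)]
        pv <- dch[, p]
        het <- which(!is.na(pv) & pv == 1L)
        het <- setdiff(het, exclude)
        if (!length(het)) next
        t <- .transmissions(het, pv, dch[, q], dch[, offs, drop = FALSE])
        # a marker whose determinable transmissions are unanimous across
        # >= 4 meioses is most likely a miscalled heterozygote (a truly
        # heterozygous parent transmits both alleles with high
        # probability); treat it as uninformative for this parent so it
        # cannot distort the phase chain
        kn <- rowSums(!is.na(t))
        ones <- rowSums(t == 1L, na.rm = TRUE)
        fake <- kn >= 4L & (ones == 0L | ones == kn)
        if (any(fake)) t[fake, ] <- NA_integer_
        ph <- .phaseChain(t)
        pdat[[p]] <- list(mIdx = mIdx, offs = offs, mate = q, het = het,
                          t = t, phi = ph$phi, seg = ph$seg, fake = fake)
    }
    for (p in parents) {
        pd <- pdat[[p]]
        if (is.null(pd)) next
        qd <- pdat[[pd$mate]]
        if (is.null(qd)) next
        j <- match(pd$het, qd$het)
        for (cc in seq_along(pd$offs)) {
            o <- pd$offs[cc]
            qc <- match(o, qd$offs)
            if (is.na(qc)) next
            need <- which(is.na(pd$t[, cc]) & !is.na(j) & !pd$fake &
                          !qd$fake[j] %in% TRUE &
                          dch[pd$het, o] %in% 1L)
            if (!length(need)) next
            zq <- (qd$t[, qc] + qd$phi) %% 2L
            hap <- .flowFill(zq, qd$seg)
            # only trust the mate flow across short gaps: long gaps ride on
            # weakly supported stretches of the mate phase, where a local
            # phase error corrupts whole blocks of resolved transmissions
            gapOk <- attr(hap, "gap")[j[need]] <= 10L
            tq <- (hap[j[need]] + qd$phi[j[need]]) %% 2L
            tq[!gapOk %in% TRUE] <- NA_integer_
            pd$t[need, cc] <- ifelse(is.na(tq), NA_integer_, 1L - tq)
        }
        pdat[[p]] <- pd
    }
    for (p in parents) {
        pd <- pdat[[p]]
        if (is.null(pd)) next
        ph <- .phaseChain(pd$t)
        z <- (pd$t + ph$phi) %% 2L
        if (repairClusters) z <- .repairCoherentSwitches(z)
        for (jj in seq_along(pd$mIdx)) {
            known <- which(!is.na(z[, jj]))
            if (length(known))
                chList[[pd$mIdx[jj]]] <- list(idx = pd$het[known],
                                              z = z[known, jj],
                                              seg = ph$seg[known])
        }
    }
    chList
}

#' Per-interval recombination fractions for one transmitting-parent sex
#'
#' For every adjacent-marker interval, the recombination fraction is
#' `r = k / n` over the meioses of the given sex. With `spanning = TRUE`
#' (default) every consecutive pair of informative markers of a meiosis
#' contributes to all the intervals it spans: `n` increments on each
#' spanned interval and a recombination event is attributed fractionally
#' across the spanned intervals proportionally to their physical width.
#' With `spanning = FALSE` only pairs of physically adjacent markers count
#' (the meiosis must be informative at both flanking markers of the
#' interval). Intervals with `n = 0` are flagged uninformative and carry 0
#' cM. Discordant markers are excluded from the backbone; their direct
#' recombination distances to the nearest backbone neighbours are returned
#' separately.
#'
#' @param ms a [MeiosisSet]
#' @param sex transmitting-parent sex, "male" or "female"
#' @param mappingFunction "haldane" or "kosambi"
#' @param spanning use bracketing-pair attribution (see Details)
#' @param weights optional per-meiosis weights (e.g. family bootstrap)
#' @return an [IntervalEstimate]
#' @export
intervalRecFrac <- function(ms, sex = c("male", "female"),
                            mappingFunction = c("haldane", "kosambi"),
                            spanning = TRUE, weights = NULL) {
    sex <- match.arg(sex)
    mappingFunction <- match.arg(mappingFunction)
    sel <- which(ms@meioses$parentSex == sex)
    if (is.null(weights)) weights <- rep(1, nrow(ms@meioses))
    st <- ms@markerStats
    chrLevels <- unique(st$chrom)
    ints <- list(); offs <- list()
    for (ch in chrLevels) {
        rows <- which(st$chrom == ch)
        M <- length(rows)
        bp <- st$bp[rows]
        disc <- which(st$discordant[rows])
        nInt <- max(M - 1L, 0L)
        n <- numeric(nInt); k <- numeric(nInt)
        w_bp <- diff(bp)
        cumw <- cumsum(c(0, w_bp))
        # discordant-offset accumulators: left/right neighbour counts
        dn <- matrix(0, length(disc), 4,
                     dimnames = list(NULL, c("nL", "kL", "nR", "kR")))
        chList <- ms@transmissions[[ch]]
        rawList <- if (length(ms@transmissionsRaw)) ms@transmissionsRaw[[ch]]
                   else chList
        for (mi in sel) {
            tr <- chList[[mi]]
            if (is.null(tr) || length(tr$idx) < 2L) next
            w <- weights[mi]
            if (w == 0) next
            keep <- !(tr$idx %in% disc)
            idx <- tr$idx[keep]; z <- tr$z[keep]; seg <- tr$seg[keep]
            if (length(idx) >= 2L) {
                a <- idx[-length(idx)]; b <- idx[-1L]
                ok <- seg[-length(seg)] == seg[-1L]
                if (!spanning) ok <- ok & (b == a + 1L)
                a <- a[ok]; b <- b[ok]
                rec <- (z[-length(z)] != z[-1L])[ok]
                if (length(a)) {
                    delta <- numeric(nInt + 1L)
                    delta[a] <- delta[a] + w; delta[b] <- delta[b] - w
                    n <- n + cumsum(delta[seq_len(nInt)])
                    for (jj in which(rec)) {
                        span <- a[jj]:(b[jj] - 1L)
                        tot <- cumw[b[jj]] - cumw[a[jj]]
                        k[span] <- k[span] +
                            if (tot > 0) w * w_bp[span] / tot
                            else w / length(span)
                    }
                }
            }
            if (length(disc)) {
                tr <- rawList[[mi]]
                if (is.null(tr) || !length(tr$idx)) next
                dIn <- which(tr$idx %in% disc)
                for (jj in dIn) {
                    m <- tr$idx[jj]
                    di <- match(m, disc)
                    lo <- jj - 1L
                    while (lo >= 1L && (tr$idx[lo] %in% disc)) lo <- lo - 1L
                    if (lo >= 1L && tr$seg[lo] == tr$seg[jj]) {
                        dn[di, "nL"] <- dn[di, "nL"] + w
                        dn[di, "kL"] <- dn[di, "kL"] +
                            w * (tr$z[lo] != tr$z[jj])
                    }
                    hi <- jj + 1L
                    while (hi <= length(tr$idx) && (tr$idx[hi] %in% disc))
                        hi <- hi + 1L
                    if (hi <= length(tr$idx) && tr$seg[hi] == tr$seg[jj]) {
                        dn[di, "nR"] <- dn[di, "nR"] + w
                        dn[di, "kR"] <- dn[di, "kR"] +
                            w * (tr$z[hi] != tr$z[jj])
                    }
                }
            }
        }
        r <- ifelse(n > 0, k / n, 0)
        saturated <- r >= 0.5
        r <- pmin(r, 0.499)
        ints[[ch]] <- data.frame(
            chrom = ch,
            markerLeft = st$marker_id[rows[seq_len(nInt)]],
            markerRight = st$marker_id[rows[seq_len(nInt) + 1L]],
            bpLeft = bp[seq_len(nInt)], bpRight = bp[seq_len(nInt) + 1L],
            n = n, k = k, r = r,
            cM = mapDistance(r, mappingFunction),
            uninformative = n == 0, saturated = saturated,
            stringsAsFactors = FALSE)
        if (length(disc)) {
            rLeft <- ifelse(dn[, "nL"] > 0, dn[, "kL"] / dn[, "nL"], NA_real_)
            rRight <- ifelse(dn[, "nR"] > 0, dn[, "kR"] / dn[, "nR"], NA_real_)
            offs[[ch]] <- data.frame(
                chrom = ch, marker_id = st$marker_id[rows[disc]],
                bp = bp[disc],
                nL = dn[, "nL"], rL = pmin(rLeft, 0.45),
                nR = dn[, "nR"], rR = pmin(rRight, 0.45),
                stringsAsFactors = FALSE)
        }
    }
    new("IntervalEstimate", sex = sex,
        intervals = do.call(rbind, ints),
        markerOffsets = if (length(offs)) do.call(rbind, offs)
                        else data.frame(),
        mappingFunction = mappingFunction)
}

#' Assemble a sex-averaged genetic map from per-sex interval estimates
#'
#' Cumulative cM per sex from 0 at the first marker of each chromosome; the
#' averaged track is the arithmetic mean of the two sex tracks at every
#' marker. Discordant markers are positioned off the backbone at their
#' direct recombination distance from the nearest preceding backbone
#' marker (falling back to the following one), so that errant markers show
#' up as residual outliers instead of stepping the downstream map.
#'
#' @param male,female [IntervalEstimate] objects for the two sexes (same
#'   marker set)
#' @param panel the [MarkerPanel] (marker order of the estimates)
#' @return a [GeneticMap]
#' @export
assembleMap <- function(male, female, panel) {
    stopifnot(is(male, "IntervalEstimate"), is(female, "IntervalEstimate"))
    if (!identical(male@intervals$markerLeft, female@intervals$markerLeft))
        stop("male and female estimates must cover the same marker set")
    chrs <- as.character(seqnames(panel))
    ids <- mcols(panel)$marker_id
    pos <- start(panel)
    out <- list()
    for (ch in unique(chrs)) {
        rows <- which(chrs == ch)
        cum <- list()
        for (est in list(male, female)) {
            iv <- est@intervals[est@intervals$chrom == ch, , drop = FALSE]
            cm <- cumsum(c(0, iv$cM))
            backbone <- cm   # reference untouched by off-backbone placement
            mf <- est@mappingFunction
            if (nrow(est@markerOffsets)) {
                mo <- est@markerOffsets[est@markerOffsets$chrom == ch, ,
                                        drop = FALSE]
                for (j in seq_len(nrow(mo))) {
                    at <- match(mo$marker_id[j], ids[rows])
                    if (!is.na(mo$rL[j]) && mo$nL[j] > 0) {
                        prev <- if (at > 1L) backbone[at - 1L] else 0
                        cm[at] <- prev + mapDistance(mo$rL[j], mf)
                    } else if (!is.na(mo$rR[j]) && mo$nR[j] > 0) {
                        nxt <- if (at < length(backbone)) backbone[at + 1L]
                               else backbone[length(backbone)]
                        cm[at] <- nxt + mapDistance(mo$rR[j], mf)
                    }
                }
            }
            cum[[est@sex]] <- cm
        }
        out[[ch]] <- data.frame(
            chrom = ch, marker_id = ids[rows], bp = pos[rows],
            cM_male = cum$male, cM_female = cum$female,
            cM_avg = (cum$male + cum$female) / 2,
            stringsAsFactors = FALSE)
    }
    new("GeneticMap", markers = do.call(rbind, out))
}

#' Estimate a sex-specific genetic map from a cohort
#'
#' Orchestrates the estimation stage: parental-genotype inference,
#' segregation-distortion filtering, phasing/transmission extraction,
#' per-interval recombination fractions for each sex, and cumulative map
#' assembly. Optionally averages `replicates` family-bootstrap replicate
#' maps into a consensus via [replicateConsensus()].
#'
#' @param cohort an [HSCohort] (after genotype QC)
#' @param mappingFunction "haldane" (default, matches the simulator's
#'   no-interference crossover model) or "kosambi"
#' @param distortionP segregation-distortion p-value threshold
#' @param spanning see [intervalRecFrac()]
#' @param flipRateMax see [phaseAndExtract()]
#' @param replicates number of family-bootstrap replicates (0 = off)
#' @param seed integer seed (needed when `replicates > 0`)
#' @return a [GeneticMap]; the distortion-removed markers and the
#'   [MeiosisSet] are attached as attributes `removedDistortion` and
#'   `meioses`
#' @export
estimateMap <- function(cohort, mappingFunction = c("haldane", "kosambi"),
                        distortionP = 0.001, spanning = TRUE,
                        flipRateMax = 0.03, replicates = 0L, seed = NULL) {
    mappingFunction <- match.arg(mappingFunction)
    cohort <- callParents(cohort)
    df <- distortionFilter(cohort, pMin = distortionP)
    cohort <- df$cohort
    ms <- phaseAndExtract(cohort, flipRateMax = flipRateMax)
    panel <- markerPanel(cohort)
    buildOne <- function(w) {
        m <- intervalRecFrac(ms, "male", mappingFunction, spanning, weights = w)
        f <- intervalRecFrac(ms, "female", mappingFunction, spanning, weights = w)
        assembleMap(m, f, panel)
    }
    if (replicates > 0L) {
        map <- .withSeed(seed, {
            fams <- unique(ms@meioses$family)
            maps <- lapply(seq_len(replicates), function(b) {
                pick <- sample(fams, length(fams), replace = TRUE)
                mult <- table(factor(pick, levels = fams))
                w <- as.numeric(mult[ms@meioses$family])
                buildOne(w)
            })
            replicateConsensus(maps)
        })
    } else map <- buildOne(NULL)
    attr(map, "removedDistortion") <- df$removed
    attr(map, "meioses") <- ms
    map
}

#' Average replicate maps into a consensus
#'
#' Per-marker mean across replicates for each sex track, followed by an
#' isotonic (pool-adjacent-violators) pass per chromosome to re-enforce
#' monotonicity; the averaged track is recomputed as the mean of the two
#' consensus sex tracks.
#'
#' @param maps list of [GeneticMap] objects over identical marker sets
#' @return a [GeneticMap]
#' @export
replicateConsensus <- function(maps) {
    if (!length(maps)) stop("no maps supplied")
    ref <- mapMarkers(maps[[1]])
    for (m in maps[-1])
        if (!identical(mapMarkers(m)$marker_id, ref$marker_id))
            stop("replicate maps must cover identical marker sets")
    male <- rowMeans(vapply(maps, function(m) mapMarkers(m)$cM_male,
                            numeric(nrow(ref))))
    female <- rowMeans(vapply(maps, function(m) mapMarkers(m)$cM_female,
                              numeric(nrow(ref))))
    iso <- function(v, chrom) {
        unlist(lapply(.splitKeepOrder(v, chrom), function(x)
            if (length(x) > 1L) cummax(stats::isoreg(x)$yf) else x),
            use.names = FALSE)
    }
    male <- iso(male, ref$chrom); female <- iso(female, ref$chrom)
    out <- ref
    out$cM_male <- male; out$cM_female <- female
    out$cM_avg <- (male + female) / 2
    new("GeneticMap", markers = out)
}
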