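# F2 intercross container, comma-separated cross format IO, and an F2
# simulator with planted QTL for calibration tests.

#' Construct an F2 cross
#'
#' @param pheno data.frame of phenotypes and covariates (one row per
#'   individual)
#' @param geno integer matrix (individuals x markers), allele-B dosage
#'   0/1/2, NA missing
#' @param map data.frame with columns `marker`, `chrom`, `cM`
#' @return an [F2Cross]
#' @export
F2Cross <- function(pheno, geno, map) {
    ord <- order(factor(map$chrom, levels = unique(map$chrom)), map$cM)
    map <- map[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
    colnames(geno) <- map$marker
    rownames(map) <- NULL
    new("F2Cross", pheno = pheno, geno = geno, map = map)
}

#' Read an F2 cross from the comma-separated cross format
#'
#' Row 1 holds phenotype and marker names, row 2 chromosome labels (blank
#' for phenotype columns), row 3 cM positions, then one row per
#' individual; genotypes are coded `AA`/`AB`/`BB` and `-` (missing).
#'
#' @param path file path
#' @return an [F2Cross]
#' @export
readCross <- function(path) {
    raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (nrow(raw) < 4L) stop("cross file needs 3 header rows plus data")
    nm <- as.character(raw[1, ])
    chr <- trimws(as.character(raw[2, ]))
    cm <- trimws(as.character(raw[3, ]))
    isPheno <- chr == "" | is.na(chr)
    if (!any(isPheno)) stop("no phenotype columns (blank chromosome row)")
    dat <- raw[-(1:3), , drop = FALSE]
    pheno <- as.data.frame(lapply(dat[, isPheno, drop = FALSE], function(v) {
        num <- suppressWarnings(as.numeric(v))
        if (all(is.na(num) == (v %in% c("", "NA", "-")))) num else v
    }), stringsAsFactors = FALSE)
    names(pheno) <- nm[isPheno]
    code <- c(AA = 0L, AB = 1L, BB = 2L)
    gRaw <- as.matrix(dat[, !isPheno, drop = FALSE])
    bad <- !(gRaw %in% c(names(code), "-", "", "NA"))
    if (any(bad))
        stop("unrecognized genotype code(s): ",
             paste(unique(gRaw[bad]), collapse = ", "))
    geno <- matrix(code[gRaw], nrow(gRaw), ncol(gRaw))
    map <- data.frame(marker = nm[!isPheno], chrom = chr[!isPheno],
                      cM = as.numeric(cm[!isPheno]), stringsAsFactors = FALSE)
    F2Cross(pheno, geno, map)
}

#' Write an F2 cross in the comma-separated cross format
#'
#' @param cross an [F2Cross]
#' @param path file path
#' @export
writeCross <- function(cross, path) {
    map <- crossMap(cross); pheno <- crossPheno(cross)
    codes <- c("AA", "AB", "BB")
    g <- matrix("-", nrow(cross@geno), ncol(cross@geno))
    ok <- !is.na(cross@geno)
    g[ok] <- codes[cross@geno[ok] + 1L]
    head <- rbind(c(names(pheno), map$marker),
                  c(rep("", ncol(pheno)), map$chrom),
                  c(rep("", ncol(pheno)), format(map$cM, trim = TRUE)))
    body <- cbind(as.matrix(format(pheno, trim = TRUE)), g)
    utils::write.table(rbind(head, body), path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

# Simulate one F2 genotype chain (both gametes) at the given cM positions:
# each gamete is a Markov chain over parental origins with Haldane switch
# probabilities. Returns the dosage matrix (n x positions).
.simF2Dosage <- function(n, cm) {
    S <- length(cm)
    r <- recombinationFraction(diff(cm))
    g1 <- matrix(0L, n, S); g2 <- matrix(0L, n, S)
    g1[, 1] <- stats::rbinom(n, 1L, 0.5)
    g2[, 1] <- stats::rbinom(n, 1L, 0.5)
    for (s in seq_len(S - 1L)) {
        sw1 <- stats::rbinom(n, 1L, r[s]); sw2 <- stats::rbinom(n, 1L, r[s])
        g1[, s + 1L] <- (g1[, s] + sw1) %% 2L
        g2[, s + 1L] <- (g2[, s] + sw2) %% 2L
    }
    g1 + g2
}

#' Simulate an F2 intercross with planted QTL
#'
#' Gamete origins follow independent Markov chains along the cM map with
#' Haldane recombination probabilities (no interference). Phenotypes are
#' `sum(additive * (q - 1) + dominance * (q == 1)) + N(0, sigma^2)` over
#' the planted QTL genotypes `q`.
#'
#' @param n number of F2 individuals
#' @param map data.frame with columns `marker`, `chrom`, `cM`
#' @param qtl data.frame with columns `chrom`, `cM`, `add`, `dom` (may be
#'   empty for a null cross)
#' @param sigma residual standard deviation
#' @param missingRate per-call missing probability
#' @param seed integer seed
#' @return an [F2Cross]; true QTL genotypes are attached as attribute
#'   `qtlGeno`
#' @export
simulateF2Cross <- function(n, map, qtl = NULL, sigma = 1,
                            missingRate = 0, seed = NULL) {
    .withSeed(seed, {
        geno <- matrix(NA_integer_, n, nrow(map))
        qg <- NULL
        if (!is.null(qtl) && nrow(qtl)) qg <- matrix(NA_integer_, n, nrow(qtl))
        for (ch in unique(map$chrom)) {
            mi <- which(map$chrom == ch)
            qi <- if (is.null(qtl)) integer(0) else which(qtl$chrom == ch)
            pos <- c(map$cM[mi], if (length(qi)) qtl$cM[qi])
            ord <- order(pos)
            d <- .simF2Dosage(n, pos[ord])
            back <- match(seq_along(pos), ord)
            geno[, mi] <- d[, back[seq_along(mi)], drop = FALSE]
            if (length(qi))
                qg[, qi] <- d[, back[length(mi) + seq_along(qi)], drop = FALSE]
        }
        y <- stats::rnorm(n, 0, sigma)
        if (!is.null(qg))
            for (j in seq_len(ncol(qg)))
                y <- y + qtl$add[j] * (qg[, j] - 1) +
                    qtl$dom[j] * (qg[, j] == 1L)
        if (missingRate > 0) {
            miss <- matrix(stats::runif(length(geno)) < missingRate,
                           nrow(geno))
            geno[miss] <- NA_integer_
        }
        cross <- F2Cross(data.frame(pheno = y), geno, map)
        attr(cross, "qtlGeno") <- qg
        cross
    })
}
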