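# Shared readers/writers (PED/MAP, genetic-map and generic TSV), plus the
# pipeline umbrella tying the stages together.

#' Write a data.frame as a TSV with optional comment header
#' @param df data.frame
#' @param path file path
#' @param comments character vector written as "# " lines before the header
#' @export
writeTsv <- function(df, path, comments = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (cm in comments) writeLines(paste("#", cm), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a TSV written by [writeTsv()]
#' @param path file path
#' @return data.frame
#' @export
readTsv <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a cohort as PED/MAP (PLINK dialect)
#'
#' PED columns: family, individual, sire, dam, sex (1 = male, 2 = female),
#' phenotype (0), then two allele columns per marker with `0 0` for
#' missing. MAP columns: chromosome, marker id, cM, bp.
#'
#' @param cohort an [HSCohort]
#' @param pedPath,mapPath output paths
#' @param geneticMap optional [GeneticMap] supplying the MAP cM column
#'   (defaults to 0)
#' @export
writePedMap <- function(cohort, pedPath, mapPath, geneticMap = NULL) {
    panel <- markerPanel(cohort)
    ped <- pedigree(cohort)
    d <- dosage(cohort)
    a1 <- mcols(panel)$allele1; a2 <- mcols(panel)$allele2
    cm <- rep(0, length(panel))
    if (!is.null(geneticMap)) {
        mm <- mapMarkers(geneticMap)
        cm <- mm$cM_avg[match(mcols(panel)$marker_id, mm$marker_id)]
        cm[is.na(cm)] <- 0
    }
    mapDf <- data.frame(chrom = as.character(seqnames(panel)),
                        marker_id = mcols(panel)$marker_id,
                        cM = cm, bp = start(panel))
    utils::write.table(mapDf, mapPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    n <- ncol(d)
    lines <- character(n)
    for (i in seq_len(n)) {
        g <- d[, i]
        c1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a2, a1))
        c2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a2, a1))
        lines[i] <- paste(c(ped$family[i], ped$id[i],
                            ifelse(is.na(ped$sire[i]), "0", ped$sire[i]),
                            ifelse(is.na(ped$dam[i]), "0", ped$dam[i]),
                            ifelse(ped$sex[i] == "male", "1", "2"), "0",
                            rbind(c1, c2)), collapse = "\t")
    }
    writeLines(lines, pedPath)
    invisible(c(ped = pedPath, map = mapPath))
}

#' Read a PED/MAP pair into a cohort
#'
#' Missing genotypes (`0 0`) become NA. Allele identities are not part of
#' the PED/MAP dialect; supply `refAlleles` (data.frame `marker_id`,
#' `allele1`, `allele2`) for a lossless round-trip, otherwise the two
#' observed symbols per marker are assigned in sorted order.
#'
#' @param pedPath,mapPath input paths
#' @param refAlleles optional reference allele table
#' @return an [HSCohort]
#' @export
readPedMap <- function(pedPath, mapPath, refAlleles = NULL) {
    mapDf <- utils::read.delim(mapPath, header = FALSE,
                               stringsAsFactors = FALSE)
    names(mapDf) <- c("chrom", "marker_id", "cM", "bp")[seq_len(ncol(mapDf))]
    nm <- nrow(mapDf)
    rawLines <- readLines(pedPath)
    rawLines <- rawLines[nzchar(rawLines)]
    fields <- strsplit(rawLines, "[ \t]+")
    nf <- lengths(fields)
    expect <- 6L + 2L * nm
    badLen <- which(nf != expect)
    if (length(badLen))
        stop(sprintf("PED line %d has %d fields (expected %d)",
                     badLen[1], nf[badLen[1]], expect))
    M <- do.call(rbind, fields)
    sexCode <- M[, 5]
    if (!all(sexCode %in% c("1", "2")))
        stop("PED line ", which(!sexCode %in% c("1", "2"))[1],
             ": sex code outside {1,2}")
    aOdd <- M[, 6L + 2L * seq_len(nm) - 1L, drop = FALSE]
    aEven <- M[, 6L + 2L * seq_len(nm), drop = FALSE]
    n <- nrow(M)
    dos <- matrix(NA_integer_, nm, n)
    if (is.null(refAlleles)) {
        al <- t(vapply(seq_len(nm), function(j) {
            s <- setdiff(unique(c(aOdd[, j], aEven[, j])), "0")
            s <- sort(s)
            c(if (length(s) >= 1) s[1] else "A",
              if (length(s) >= 2) s[2] else "N")
        }, character(2)))
    } else {
        i <- match(mapDf$marker_id, refAlleles$marker_id)
        al <- cbind(refAlleles$allele1[i], refAlleles$allele2[i])
    }
    for (j in seq_len(nm)) {
        o <- aOdd[, j]; e <- aEven[, j]
        known <- o != "0" & e != "0"
        badSym <- known & !(o %in% al[j, ] & e %in% al[j, ])
        if (any(badSym))
            stop(sprintf("PED line %d: allele symbol outside panel at %s",
                         which(badSym)[1], mapDf$marker_id[j]))
        dos[j, known] <- (o[known] == al[j, 2]) + (e[known] == al[j, 2])
    }
    gr <- GRanges(mapDf$chrom, IRanges(mapDf$bp, width = 1L))
    mcols(gr)$marker_id <- mapDf$marker_id
    mcols(gr)$allele1 <- al[, 1]; mcols(gr)$allele2 <- al[, 2]
    names(gr) <- mapDf$marker_id
    sire <- ifelse(M[, 3] == "0", NA_character_, M[, 3])
    dam <- ifelse(M[, 4] == "0", NA_character_, M[, 4])
    ped <- DataFrame(id = M[, 2], sire = sire, dam = dam,
                     sex = ifelse(sexCode == "1", "male", "female"),
                     family = M[, 1],
                     generation = ifelse(is.na(sire), 0L, 1L),
                     row.names = M[, 2])
    dimnames(dos) <- list(mapDf$marker_id, M[, 2])
    new("HSCohort", SummarizedExperiment(
        assays = list(dosage = dos), rowRanges = gr, colData = ped))
}

#' Write a genetic map as TSV
#' @param map a [GeneticMap]
#' @param path file path
#' @export
writeGeneticMap <- function(map, path) {
    m <- mapMarkers(map)
    m <- m[, c("chrom", "marker_id", "bp", "cM_male", "cM_female", "cM_avg")]
    writeTsv(m, path)
}

#' Read a genetic map from TSV
#'
#' Columns: `chrom`, `marker_id`, `bp`, `cM_male`, `cM_female`, `cM_avg`.
#' With `strict = TRUE` (default) monotonicity of every cM track is
#' validated per chromosome and violations are reported by marker.
#'
#' @param path file path
#' @param strict validate cM monotonicity
#' @return a [GeneticMap]
#' @export
readGeneticMap <- function(path, strict = TRUE) {
    m <- readTsv(path)
    if (!nrow(m)) {
        warning("empty genetic-map file: ", path)
        m <- data.frame(chrom = character(0), marker_id = character(0),
                        bp = numeric(0), cM_male = numeric(0),
                        cM_female = numeric(0), cM_avg = numeric(0))
        return(new("GeneticMap", markers = m))
    }
    need <- c("chrom", "marker_id", "bp", "cM_male", "cM_female", "cM_avg")
    if (!all(need %in% names(m)))
        stop("genetic-map file must have columns: ",
             paste(need, collapse = ", "))
    if (strict) {
        offenders <- character(0)
        for (ch in unique(m$chrom)) {
            i <- which(m$chrom == ch)
            for (tr in c("cM_male", "cM_female", "cM_avg")) {
                v <- m[[tr]][i]
                badLoc <- which(diff(v) < 0)
                if (length(badLoc))
                    offenders <- c(offenders,
                                   paste0(m$marker_id[i][badLoc + 1L],
                                          " (", tr, ")"))
            }
        }
        if (length(offenders))
            stop("non-monotone cM at: ",
                 paste(unique(offenders), collapse = ", "))
    }
    new("GeneticMap", markers = m)
}

#' Serialize / restore a map model as an anchor TSV
#'
#' Anchors are written with 17 significant digits, enough to reconstruct
#' the interpolant bit-exactly.
#'
#' @param model a [MapModel]
#' @param path file path
#' @export
writeMapModel <- function(model, path) {
    rows <- do.call(rbind, lapply(names(model@anchors), function(ch) {
        a <- model@anchors[[ch]]
        data.frame(chrom = ch,
                   length_bp = sprintf("%.17g", model@lengthsBp[[ch]]),
                   bp = sprintf("%.17g", a$bp),
                   cM_male = sprintf("%.17g", a$cM_male),
                   cM_female = sprintf("%.17g", a$cM_female),
                   cM_avg = sprintf("%.17g", a$cM_avg))
    }))
    writeTsv(rows, path)
}

#' @rdname writeMapModel
#' @return [readMapModel()] returns a [MapModel]
#' @export
readMapModel <- function(path) {
    t <- readTsv(path)
    anchors <- lapply(.splitKeepOrder(seq_len(nrow(t)), t$chrom), function(i)
        data.frame(bp = as.numeric(t$bp[i]),
                   cM_male = as.numeric(t$cM_male[i]),
                   cM_female = as.numeric(t$cM_female[i]),
                   cM_avg = as.numeric(t$cM_avg[i])))
    lengths <- vapply(.splitKeepOrder(as.numeric(t$length_bp), t$chrom),
                      function(v) v[1], numeric(1))
    new("MapModel", anchors = anchors, lengthsBp = lengths)
}

#' Run the simulate -> qc -> estimate -> clean -> resources pipeline
#'
#' Every artifact is written under `outDir` together with a manifest
#' recording stage parameters, the seed and input-file digests, making the
#' run reproducible from its recorded configuration. Identical
#' configurations and seeds give byte-identical numeric outputs.
#'
#' @param config nested list with elements `seed`, `outDir`, and optional
#'   stage parameter lists `sim`, `qc`, `estimate`, `clean` (unknown keys
#'   are rejected); see the vignette for the full schema
#' @return invisible list of in-memory stage results
#' @export
runPipeline <- function(config) {
    allowed <- c("seed", "outDir", "sim", "qc", "estimate", "clean")
    unknown <- setdiff(names(config), allowed)
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    if (is.null(config$seed)) stop("config$seed is required")
    if (is.null(config$outDir)) stop("config$outDir is required")
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    getp <- function(stage, key, default) {
        v <- config[[stage]][[key]]
        if (is.null(v)) default else v
    }
    bad <- function(stage, keys) {
        u <- setdiff(names(config[[stage]]), keys)
        if (length(u)) stop("unknown ", stage, " keys: ",
                            paste(u, collapse = ", "))
    }
    bad("sim", c("nFamilies", "offspringPerFamily", "nStrains",
                 "markersPerChromosome", "chromosomes", "errorRate",
                 "missingRate", "mendelBadMarkerFraction",
                 "displacedFraction", "minShiftBp", "polymorphicFraction"))
    bad("qc", c("mendelMax", "windowBp", "mafMin"))
    bad("estimate", c("mappingFunction", "distortionP", "replicates"))
    bad("clean", c("span", "thresholdCm"))
    manifest <- list()
    note <- function(stage, key, value)
        manifest[[length(manifest) + 1L]] <<- data.frame(
            stage = stage, key = key, value = as.character(value))
    seed <- as.integer(config$seed)
    note("run", "seed", seed)

    # --- simulate -------------------------------------------------------
    chroms <- getp("sim", "chromosomes", NULL)
    tm <- ratTrueMap(chromosomes = chroms)
    mpc <- getp("sim", "markersPerChromosome", 2000)
    spacing <- round(mean(tm@lengthsBp) / mpc)
    panel <- makeMarkerPanel(tm@lengthsBp, spacing, seed = seed)
    ped <- buildHSPedigree(getp("sim", "nFamilies", 65),
                           getp("sim", "offspringPerFamily", 870 / 2 / 65),
                           getp("sim", "nStrains", 8), seed = seed + 1L)
    founders <- simulateFounderHaplotypes(
        panel, getp("sim", "nStrains", 8),
        getp("sim", "polymorphicFraction", 0.9), seed = seed + 2L)
    displacedFraction <- getp("sim", "displacedFraction", 0)
    displaced <- character(0)
    simres <- simulateCohort(
        ped, founders, tm, panel,
        errorRate = getp("sim", "errorRate", 0.002),
        missingRate = getp("sim", "missingRate", 0.02),
        mendelBadMarkerFraction = getp("sim", "mendelBadMarkerFraction", 0.01),
        seed = seed + 3L)
    cohort <- simres$cohort
    if (displacedFraction > 0) {
        cp <- corruptMarkerPositions(markerPanel(cohort), displacedFraction,
                                     getp("sim", "minShiftBp", 2e7),
                                     seed = seed + 4L)
        cohort <- applyPanel(cohort, cp$panel)
        displaced <- cp$displaced
    }
    writePedMap(cohort, file.path(config$outDir, "cohort.ped"),
                file.path(config$outDir, "cohort.map"))
    writeTsv(simres$truth@crossovers,
             file.path(config$outDir, "truth_crossovers.tsv"))
    tmTab <- do.call(rbind, lapply(names(tm@anchors), function(ch)
        cbind(chrom = ch, tm@anchors[[ch]])))
    writeTsv(tmTab, file.path(config$outDir, "true_map.tsv"))
    note("simulate", "nMarkers", nrow(cohort))
    note("simulate", "meioses", meiosisCount(cohort))
    note("simulate", "displaced", length(displaced))

    # --- qc -------------------------------------------------------------
    qc <- runQc(cohort, mendelMax = getp("qc", "mendelMax", 0.02),
                windowBp = getp("qc", "windowBp",
                                round(mean(tm@lengthsBp) / mpc)),
                mafMin = getp("qc", "mafMin", 0.05))
    note("qc", "markersRetained", nrow(qc$cohort))
    writeTsv(data.frame(marker_id = names(qc$report@mendelRate),
                        mendel_rate = qc$report@mendelRate),
             file.path(config$outDir, "qc_mendel.tsv"))

    # --- estimate -------------------------------------------------------
    rawMap <- estimateMap(
        qc$cohort,
        mappingFunction = getp("estimate", "mappingFunction", "haldane"),
        distortionP = getp("estimate", "distortionP", 0.001),
        replicates = getp("estimate", "replicates", 0L), seed = seed + 5L)
    writeGeneticMap(rawMap, file.path(config$outDir, "map_raw.tsv"))
    note("estimate", "markers", nrow(mapMarkers(rawMap)))

    # --- clean ----------------------------------------------------------
    cl <- cleanMap(rawMap, span = getp("clean", "span", 0.1),
                   thresholdCm = getp("clean", "thresholdCm", 1.0),
                   lengthsBp = tm@lengthsBp)
    writeGeneticMap(cl$map, file.path(config$outDir, "map_clean.tsv"))
    writeMapModel(cl$model, file.path(config$outDir, "map_model.tsv"))
    writeTsv(cl$report@table, file.path(config$outDir, "cleaning_report.tsv"))
    note("clean", "removed", length(cl$removed))

    # --- resources ------------------------------------------------------
    summ <- summarizeMap(cl$map, physicalLengthsBp = tm@lengthsBp)
    writeTsv(summ$perChromosome, file.path(config$outDir, "summary.tsv"))
    writeTsv(summ$genome, file.path(config$outDir, "summary_genome.tsv"))
    note("resources", "genome_cM_avg", round(summ$genome$cM_avg_full, 3))

    arts <- list.files(config$outDir, full.names = TRUE)
    arts <- arts[!grepl("manifest", arts)]
    dig <- tools::md5sum(arts)
    for (i in seq_along(dig))
        note("digest", basename(names(dig)[i]), unname(dig[i]))
    writeTsv(do.call(rbind, manifest),
             file.path(config$outDir, "manifest.tsv"))
    invisible(list(cohort = cohort, truth = simres$truth, displaced = displaced,
                   qc = qc, rawMap = rawMap, clean = cl, summary = summ))
}
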