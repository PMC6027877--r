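# Published chromosome-level and QTL-level tables for the rat. These are
# report-surface numbers (cM to 1 decimal, rates to 2 decimals) and serve as
# simulation truth and as inputs to the summary / comparison arithmetic.

#' Published rat genetic-map chromosome summary
#'
#' Chromosome-level summary of the revised sex-specific rat genetic map
#' (95,769 markers, RGSC 6.0/rn6 physical lengths) alongside the historical
#' Jensen-Seaman sex-averaged map (Baylor 3.4/rn4). Genetic lengths are in
#' cM, physical sizes in Mb, rates in cM/Mb as printed (cM to one decimal,
#' rates to two).
#'
#' @return data.frame with columns `chrom`, `n_markers`, `cM_male`,
#'   `cM_female`, `cM_avg`, `mb`, `rate` (revised map) and `cM_avg_hist`,
#'   `mb_hist`, `rate_hist` (historical map); one row per chromosome, no
#'   totals row (see [summarizeMap()] for the genome-level arithmetic)
#' @export
ratMapSummary <- function() {
    data.frame(
        chrom = c(paste0("chr", 1:20), "chrX"),
        n_markers = c(9098L, 10440L, 6142L, 6930L, 6859L, 5747L, 5157L, 4759L,
                      3761L, 4479L, 2788L, 2108L, 4869L, 4519L, 2991L, 3806L,
                      2679L, 3223L, 2360L, 1890L, 1165L),
        cM_male = c(134.4, 122.0, 95.4, 100.5, 99.3, 81.4, 91.6, 83.0, 72.8,
                    88.0, 56.0, 53.9, 59.6, 72.3, 64.4, 62.5, 61.2, 55.3,
                    51.2, 47.2, 37.1),
        cM_female = c(146.0, 135.5, 113.1, 110.7, 111.8, 94.9, 99.4, 99.6,
                      83.9, 94.3, 66.8, 52.4, 70.3, 74.1, 79.2, 61.0, 74.4,
                      63.1, 58.5, 54.7, 82.8),
        cM_avg = c(140.2, 128.8, 104.2, 105.6, 105.6, 88.1, 95.5, 91.3, 78.3,
                   91.1, 61.4, 53.2, 64.9, 73.2, 71.8, 61.8, 67.8, 59.2,
                   54.8, 51.0, 59.9),
        mb = c(282.8, 266.4, 177.7, 184.2, 173.7, 148.0, 145.7, 133.3, 122.1,
               112.6, 90.5, 52.7, 114.0, 115.5, 111.2, 90.7, 90.8, 88.2,
               62.3, 56.2, 160.0),
        rate = c(0.50, 0.48, 0.59, 0.57, 0.61, 0.60, 0.66, 0.68, 0.64, 0.81,
                 0.68, 1.01, 0.57, 0.63, 0.65, 0.68, 0.75, 0.67, 0.88, 0.91,
                 0.37),
        cM_avg_hist = c(149.3, 112.4, 91.5, 102.2, 105.7, 85.2, 88.5, 84.1,
                        78.3, 92.8, 39.0, 51.9, 43.9, 70.9, 63.8, 45.5, 43.9,
                        52.3, 48.1, 48.2, 44.6),
        mb_hist = c(267.4, 255.3, 166.0, 186.1, 171.6, 134.2, 141.6, 126.8,
                    109.5, 101.2, 73.6, 43.6, 75.1, 105.7, 106.1, 76.6, 91.0,
                    84.7, 56.4, 50.6, 130.8),
        rate_hist = c(0.56, 0.44, 0.55, 0.55, 0.62, 0.63, 0.62, 0.66, 0.71,
                      0.92, 0.53, 1.19, 0.58, 0.67, 0.60, 0.59, 0.48, 0.62,
                      0.85, 0.95, 0.34),
        stringsAsFactors = FALSE)
}

#' Published old-map vs new-map QTL comparison inputs
#'
#' Peak positions, LOD scores and 95% Bayes credible intervals of the
#' immobility and climbing QTL from the WKY x F344 F2 reciprocal cross,
#' rescanned with the historical ("old") and revised ("new") sex-averaged
#' rat genetic maps. One QTL was not detected with the new map (NA columns);
#' it still counts in the QTL total when the >10 cM shift rule is applied.
#' Significance codes: "sig" exceeds the 0.05 genome-wide threshold,
#' "sugg" the 0.63 threshold.
#'
#' @return data.frame, one row per QTL (phenotype, model, chrom, old/new
#'   peak cM, LOD, CI bounds, significance)
#' @seealso [compareScans()], [applyShiftRule()]
#' @export
ratQtlTable <- function() {
    tab <- rbind(
        c("Immobility", "A", "3", 52, 2.37, 32, 70, 66, 2.37, 34, 82),
        c("Immobility", "A", "5", 95, 3.38, 83, 105, 102, 3.64, 94, 105),
        c("Immobility", "A", "8", 20, 2.06, 8, 54, NA, NA, NA, NA),
        c("Immobility", "B", "5", 95, 4.32, 77, 105, 102, 4.72, 86, 105),
        c("Immobility", "B", "16", 26, 3.34, 6, 32, 53, 3.14, 23, 61),
        c("Immobility", "C", "5", 95, 3.92, 83, 105, 102, 4.08, 94, 105),
        c("Immobility", "C", "16", 6, 3.18, 6, 28, 15, 3.19, 15, 37),
        c("Immobility", "D", "5", 95, 4.78, 79, 105, 102, 5.12, 88, 105),
        c("Immobility", "D", "16", 6, 4.35, 6, 30, 15, 4.43, 15, 49),
        c("Climbing", "A", "1", 99, 4.30, 90, 106, 98, 4.17, 91, 103),
        c("Climbing", "A", "2", 58, 5.68, 54, 64, 78, 5.69, 74, 82),
        c("Climbing", "A", "3", 34, 2.89, 18, 54, 42, 2.97, 16, 60),
        c("Climbing", "A", "6", 1, 2.72, 1, 23, 7, 2.71, 7, 71),
        c("Climbing", "A", "9", 76, 2.29, 6, 76, 74, 2.29, 7, 74),
        c("Climbing", "B", "1", 99, 4.86, 88, 106, 95, 4.76, 89, 103),
        c("Climbing", "B", "2", 58, 6.12, 52, 64, 80, 6.23, 74, 84),
        c("Climbing", "B", "3", 34, 3.37, 18, 50, 42, 3.36, 20, 58),
        c("Climbing", "B", "6", 1, 3.06, 1, 22, 7, 3.02, 7, 69),
        c("Climbing", "B", "9", 76, 3.08, 34, 76, 74, 3.02, 27, 74),
        c("Climbing", "B", "13", 10, 3.32, 8, 16, 26, 3.17, 26, 32),
        c("Climbing", "B", "15", 2, 3.90, 2, 8, 6, 3.77, 6, 12),
        c("Climbing", "B", "16", 24, 5.36, 14, 28, 20, 5.14, 19, 43),
        c("Climbing", "B", "17", 42, 3.95, 35, 42, 58, 3.84, 45, 58),
        c("Climbing", "C", "1", 99, 5.31, 92, 102, 98, 5.21, 93, 101),
        c("Climbing", "C", "2", 58, 5.80, 52, 64, 78, 5.79, 74, 84),
        c("Climbing", "C", "3", 34, 4.34, 20, 46, 42, 4.44, 26, 50),
        c("Climbing", "C", "16", 22, 3.17, 12, 26, 21, 3.08, 19, 43),
        c("Climbing", "D", "1", 99, 5.86, 92, 104, 98, 5.75, 93, 103),
        c("Climbing", "D", "2", 58, 6.23, 52, 64, 80, 6.35, 74, 84),
        c("Climbing", "D", "3", 34, 4.83, 20, 44, 42, 4.87, 28, 52),
        c("Climbing", "D", "15", 2, 4.02, 2, 10, 6, 3.88, 6, 64),
        c("Climbing", "D", "16", 22, 6.82, 16, 26, 20, 6.72, 19, 35),
        c("Climbing", "D", "17", 42, 4.20, 35, 42, 58, 4.13, 45, 58))
    sig <- c(
        # immobility A3 A5 A8 B5 B16 C5 C16 D5 D16
        "sugg", "sig", "sugg", "sugg", "sugg", "sugg", "sugg", "sugg", "sugg",
        # climbing A1 A2 A3 A6 A9
        "sig", "sig", "sugg", "sugg", "sugg",
        # climbing B1 B2 B3 B6 B9 B13 B15 B16 B17
        "sig", "sig", "sugg", "sugg", "sugg", "sugg", "sugg", "sig", "sugg",
        # climbing C1 C2 C3 C16
        "sig", "sig", "sugg", "sugg",
        # climbing D1 D2 D3 D15 D16 D17
        "sig", "sig", "sugg", "sugg", "sig", "sugg")
    sigNew <- c(
        "sugg", "sig", NA, "sig", "sugg", "sugg", "sugg", "sugg", "sugg",
        "sig", "sig", "sugg", "sugg", "sugg",
        "sig", "sig", "sugg", "sugg", "sugg", "sugg", "sugg", "sig", "sugg",
        "sig", "sig", "sig", "sugg",
        "sig", "sig", "sugg", "sugg", "sig", "sugg")
    out <- data.frame(
        phenotype = tab[, 1], model = tab[, 2], chrom = tab[, 3],
        old_peak = as.numeric(tab[, 4]), old_lod = as.numeric(tab[, 5]),
        old_ci_lo = as.numeric(tab[, 6]), old_ci_hi = as.numeric(tab[, 7]),
        new_peak = as.numeric(tab[, 8]), new_lod = as.numeric(tab[, 9]),
        new_ci_lo = as.numeric(tab[, 10]), new_ci_hi = as.numeric(tab[, 11]),
        old_sig = sig, new_sig = sigNew, stringsAsFactors = FALSE)
    out
}
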