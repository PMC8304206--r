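## Assembly of the 64-dimensional coupling feature vector:
## {XS, XF, JD} x 8 pairs (24 entropy features), {MSCFm, MSCFsd} x 8 (16),
## {ICPSDm, ICPSDsd} x 8 (16), MI x 8 (8). Feature names follow the
## pair-measure convention, e.g. "TpeI-DTI-JD" is the JDistEn feature of
## the TpeI-DTI pair.

MEASURE_CODES <- c("XS", "XF", "JD", "MSCFm", "MSCFsd",
                   "ICPSDm", "ICPSDsd", "MI")

FEATURE_FAMILIES <- list(
    entropy = c("XS", "XF", "JD"),
    spectral = c("MSCFm", "MSCFsd", "ICPSDm", "ICPSDsd", "MI"),
    all = MEASURE_CODES
)

#' Canonical names of the 64 coupling features
#'
#' Ordered measure-major: for each measure code (XS, XF, JD, MSCFm,
#' MSCFsd, ICPSDm, ICPSDsd, MI) the eight pairs in canonical order.
#'
#' @param measures subset of measure codes (default all eight).
#' @return Character vector of `<electrical>-<mechanical>-<code>` names.
#' @examples
#' head(couplingFeatureNames())
#' @export
couplingFeatureNames <- function(measures = MEASURE_CODES) {
    cp <- canonicalPairs()
    pairNames <- paste(cp[, 1], cp[, 2], sep = "-")
    unlist(lapply(measures, function(mc) paste(pairNames, mc, sep = "-")),
           use.names = FALSE)
}

#' Feature-family membership of feature names
#'
#' @param featureNames canonical feature names.
#' @param family `"entropy"` (XSampEn/XFuzzyEn/JDistEn), `"spectral"`
#'   (MSCF/ICPSD/MI) or `"all"`.
#' @return Logical mask over `featureNames`.
#' @export
featureFamilyMask <- function(featureNames, family = c("entropy", "spectral",
                                                       "all")) {
    family <- match.arg(family)
    codes <- FEATURE_FAMILIES[[family]]
    sub(".*-", "", featureNames) %in% codes
}

#' Extract the 64 coupling features of one subject
#'
#' Builds the eight z-normalized pairs and applies all six coupling
#' measures. An undefined entropy (zero cross-matches in XSampEn) becomes
#' an `NA` feature with a warning; downstream stages impute missing
#' entropies with the cohort maximum of that feature (an undefined entropy
#' means "no matches", i.e. maximal irregularity).
#'
#' @param seriesSet a valid [IntervalSeriesSet-class].
#' @param entropy [entropyParams()] for XSampEn/XFuzzyEn (delay 1).
#' @param jdist [entropyParams()] for JDistEn (default m = 2, tau = 3).
#' @param spectral [spectralParams()].
#' @param mi [miParams()].
#' @param measures measure codes to compute (default all 8 -> 64
#'   features).
#' @return Named numeric vector (64 entries for the full measure set).
#' @export
extractFeatures <- function(seriesSet,
                            entropy = entropyParams(),
                            jdist = entropyParams(m = 2L, tau = 3L),
                            spectral = spectralParams(),
                            mi = miParams(),
                            measures = MEASURE_CODES) {
    measures <- match.arg(measures, MEASURE_CODES, several.ok = TRUE)
    pairs <- makePairs(seriesSet)
    out <- setNames(rep(NA_real_, length(measures) * length(pairs)),
                    couplingFeatureNames(measures))
    for (pn in names(pairs)) {
        p <- pairs[[pn]]
        if ("XS" %in% measures)
            out[paste(pn, "XS", sep = "-")] <- tryCatch(
                xSampEn(p, entropy),
                undefinedEntropyError = function(e) {
                    warning(sprintf("%s: %s", pn, conditionMessage(e)),
                            call. = FALSE)
                    NA_real_
                })
        if ("XF" %in% measures)
            out[paste(pn, "XF", sep = "-")] <- xFuzzyEn(p, entropy)
        if ("JD" %in% measures)
            out[paste(pn, "JD", sep = "-")] <- jDistEn(p, jdist)
        if (any(c("MSCFm", "MSCFsd") %in% measures)) {
            cs <- mscf(p, spectral)
            if ("MSCFm" %in% measures)
                out[paste(pn, "MSCFm", sep = "-")] <- cs$mean
            if ("MSCFsd" %in% measures)
                out[paste(pn, "MSCFsd", sep = "-")] <- cs$sd
        }
        if (any(c("ICPSDm", "ICPSDsd") %in% measures)) {
            ic <- icpsd(p, spectral)
            if ("ICPSDm" %in% measures)
                out[paste(pn, "ICPSDm", sep = "-")] <- ic$mean
            if ("ICPSDsd" %in% measures)
                out[paste(pn, "ICPSDsd", sep = "-")] <- ic$sd
        }
        if ("MI" %in% measures)
            out[paste(pn, "MI", sep = "-")] <- mutualInformation(p, mi)
    }
    out
}

#' Coupling feature matrix of a cohort as a SummarizedExperiment
#'
#' Applies [extractFeatures()] to every subject and assembles a
#' `SummarizedExperiment`: assay `"features"` (features x subjects),
#' `colData` with `subject_id`, `group` and (when available) the
#' ground-truth coupling `rho`.
#'
#' @param cohort a [SyntheticCohort-class], or a named list of
#'   [IntervalSeriesSet-class] objects with a `labels` data.frame.
#' @param labels data.frame `subject_id, group` (required for a plain
#'   list).
#' @param verbose print progress every 25 subjects.
#' @param ... passed to [extractFeatures()].
#' @return A [SummarizedExperiment::SummarizedExperiment-class].
#' @export
cohortFeatures <- function(cohort, labels = NULL, verbose = FALSE, ...) {
    if (is(cohort, "SyntheticCohort")) {
        sets <- lapply(cohort@subjects, `[[`, "series")
        labels <- cohort@labels
        rho <- vapply(cohort@subjects, `[[`, numeric(1), "rho")
    } else {
        sets <- cohort
        if (is.null(labels)) stop("labels required for a plain subject list")
        rho <- rep(NA_real_, length(sets))
    }
    stopifnot(identical(names(sets), labels$subject_id))
    feats <- vector("list", length(sets))
    for (i in seq_along(sets)) {
        feats[[i]] <- extractFeatures(sets[[i]], ...)
        if (verbose && i %% 25 == 0)
            message(sprintf("  features: %d / %d subjects", i, length(sets)))
    }
    mat <- do.call(cbind, feats)
    colnames(mat) <- labels$subject_id
    SummarizedExperiment(
        assays = list(features = mat),
        colData = S4Vectors::DataFrame(subject_id = labels$subject_id,
                                       group = labels$group, rho = rho,
                                       row.names = labels$subject_id))
}

#' Impute missing features with the cohort maximum
#'
#' An undefined cross entropy means no template matches were found, the
#' maximal-irregularity end of the scale, so missing entries are imputed
#' with the per-feature cohort maximum.
#'
#' @param se feature `SummarizedExperiment` from [cohortFeatures()] or a
#'   features x subjects matrix.
#' @return Same type as the input, with `NA`s imputed.
#' @export
imputeMissingFeatures <- function(se) {
    mat <- if (is(se, "SummarizedExperiment")) assay(se, "features") else se
    for (i in seq_len(nrow(mat))) {
        miss <- is.na(mat[i, ])
        if (any(miss) && !all(miss))
            mat[i, miss] <- max(mat[i, !miss])
    }
    if (is(se, "SummarizedExperiment")) {
        assay(se, "features") <- mat
        se
    } else mat
}

#' Write the cohort feature matrix as CSV
#'
#' One row per subject: `subject_id, group`, then the 64 canonical feature
#' columns; missing features are empty cells.
#'
#' @param se feature `SummarizedExperiment`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeFeatureCSV <- function(se, path) {
    mat <- t(assay(se, "features"))
    df <- data.frame(subject_id = colData(se)$subject_id,
                     group = colData(se)$group, mat, check.names = FALSE)
    write.csv(df, path, row.names = FALSE, na = "")
    invisible(path)
}
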