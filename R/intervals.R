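## Construction, validation and pairing of the six beat-interval series
## from ECG/PCG fiducial annotations.

ANNOTATION_COLUMNS <- c("beat_index", "r_peak_ms", "q_onset_ms", "t_peak_ms",
                        "t_offset_ms", "s1_offset_ms", "s2_onset_ms",
                        "s2_offset_ms", "next_s1_onset_ms")

#' Read a fiducial-annotation CSV
#'
#' One row per cardiac cycle with the eight landmark times in ms:
#' `r_peak_ms, q_onset_ms, t_peak_ms, t_offset_ms, s1_offset_ms,
#' s2_onset_ms, s2_offset_ms, next_s1_onset_ms` (plus `beat_index`).
#'
#' @param path CSV path.
#' @return The annotation data.frame.
#' @export
readAnnotations <- function(path) {
    ann <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(ANNOTATION_COLUMNS, names(ann))
    if (length(missing))
        stop("annotation file missing columns: ",
             paste(missing, collapse = ", "))
    ann
}

#' Bazett heart-rate correction of the QT interval
#'
#' `QTc = QT / sqrt(RR / 1000)` with QT and RR in ms (RR expressed in
#' seconds inside the square root, the Bazett convention).
#'
#' @param qt QT interval(s), ms.
#' @param rr RR interval(s), ms; must be positive.
#' @return QTc in ms.
#' @examples
#' bazettCorrect(400, 1000)  # 400
#' bazettCorrect(400, 640)   # 500
#' @export
bazettCorrect <- function(qt, rr) {
    if (any(rr <= 0)) stop("rr must be positive")
    qt / sqrt(rr / 1000)
}

#' Default physiologic bounds for anomaly screening
#'
#' Beat-interval plausibility ranges (ms): RRI 300-2000, STI 150-600,
#' DTI 100-1500, TpeI 20-200. These codify the anomalous-beat screening
#' that clinical over-reading would otherwise perform; they are
#' configurable.
#'
#' @return A named list of `c(lower, upper)` bounds.
#' @export
defaultBounds <- function() {
    list(RRI = c(300, 2000), STI = c(150, 600),
         DTI = c(100, 1500), TpeI = c(20, 200))
}

#' Flag anomalous beats
#'
#' A beat is flagged if any bounded series value falls outside its
#' physiologic range, or if any series value deviates more than
#' `k` x MAD from a rolling median (robust outlier rule; window
#' `window` beats, MAD taken over the rolling-median residuals of that
#' series).
#'
#' @param seriesSet an [IntervalSeriesSet-class] (or beats x 6 matrix).
#' @param bounds named list of `c(lower, upper)` physiologic bounds, see
#'   [defaultBounds()].
#' @param k MAD multiplier (default 5).
#' @param window rolling-median window in beats (odd; default 11).
#' @return Logical per-beat mask.
#' @export
detectAnomalousBeats <- function(seriesSet, bounds = defaultBounds(),
                                 k = 5, window = 11) {
    s <- if (is(seriesSet, "IntervalSeriesSet")) seriesSet@series
         else as.matrix(seriesSet)
    n <- nrow(s)
    mask <- rep(FALSE, n)
    for (nm in names(bounds)) {
        if (!nm %in% colnames(s)) next
        v <- s[, nm]
        mask <- mask | v < bounds[[nm]][1] | v > bounds[[nm]][2]
    }
    w <- min(window, if (n %% 2L == 1L) n else n - 1L)
    for (nm in colnames(s)) {
        v <- s[, nm]
        med <- runmed(v, w, endrule = "median")
        resid <- v - med
        sigma <- mad(resid)
        if (sigma > 0) mask <- mask | abs(resid) > k * sigma
    }
    mask
}

#' Construct the six interval series from fiducial annotations
#'
#' From n annotation rows: `RRI[i] = R[i+1] - R[i]` (length n - 1);
#' `QTI = t_offset - q_onset`; `TpeI = t_offset - t_peak`;
#' `TpeQTI = TpeI / QTI`; `STI = s2_onset - s1_offset`;
#' `DTI = next_s1_onset - s2_offset`; QTcI is the Bazett-corrected QTI.
#' The five within-beat series are truncated to the first n - 1 beats so
#' all six series have equal length. Beats violating the landmark-ordering
#' invariants are not dropped silently: they are flagged in the anomaly
#' mask, together with the beats flagged by [detectAnomalousBeats()], and
#' the subject validity flag follows the strict 10\% rule.
#'
#' @param ann annotation data.frame (schema of [readAnnotations()]).
#' @param bounds,k,window anomaly-screening settings, see
#'   [detectAnomalousBeats()].
#' @param minBeats minimum usable series length (default 30); fewer beats
#'   is an error (entropy estimates are unreliable below that).
#' @return An [IntervalSeriesSet-class].
#' @export
extractIntervalSeries <- function(ann, bounds = defaultBounds(), k = 5,
                                  window = 11, minBeats = 30) {
    missing <- setdiff(ANNOTATION_COLUMNS, names(ann))
    if (length(missing))
        stop("annotation table missing columns: ",
             paste(missing, collapse = ", "))
    n <- nrow(ann)
    if (n < minBeats + 1L)
        stop(sprintf("fewer than %d usable beats: invalid subject", minBeats))
    L <- n - 1L
    i <- seq_len(L)

    ordViolation <- with(ann, !(q_onset_ms < r_peak_ms &
                                r_peak_ms < t_peak_ms &
                                t_peak_ms < t_offset_ms &
                                s1_offset_ms < s2_onset_ms &
                                s2_onset_ms < s2_offset_ms &
                                s2_offset_ms < next_s1_onset_ms))[i]

    rri <- diff(ann$r_peak_ms)
    qti <- (ann$t_offset_ms - ann$q_onset_ms)[i]
    tpe <- (ann$t_offset_ms - ann$t_peak_ms)[i]
    sti <- (ann$s2_onset_ms - ann$s1_offset_ms)[i]
    dti <- (ann$next_s1_onset_ms - ann$s2_offset_ms)[i]

    bad <- ordViolation | rri <= 0
    ## neutralize unusable values so downstream arithmetic stays finite;
    ## these beats are flagged and removed before any analysis
    if (any(bad)) {
        rri[bad & rri <= 0] <- 1
        qti[qti <= 0] <- 1
    }
    series <- cbind(RRI = rri, QTcI = bazettCorrect(qti, rri), TpeI = tpe,
                    TpeQTI = tpe / qti, STI = sti, DTI = dti)
    mask <- bad | detectAnomalousBeats(series, bounds = bounds, k = k,
                                       window = window)
    if (sum(!mask) < minBeats)
        stop(sprintf("fewer than %d usable beats: invalid subject", minBeats))
    IntervalSeriesSet(series, anomalyMask = mask)
}

#' Apply the 10\% invalidation rule
#'
#' Recomputes (or accepts) the anomaly mask and sets the validity flag:
#' invalid iff the flagged fraction is strictly greater than 10\%.
#'
#' @param seriesSet an [IntervalSeriesSet-class].
#' @param mask optional logical mask overriding the stored one (e.g., from
#'   [detectAnomalousBeats()]).
#' @return The [IntervalSeriesSet-class] with mask and validity flag set.
#' @export
validateSubject <- function(seriesSet, mask = NULL) {
    stopifnot(is(seriesSet, "IntervalSeriesSet"))
    if (is.null(mask)) {
        mask <- seriesSet@anomalyMask
        if (!any(mask))
            mask <- detectAnomalousBeats(seriesSet)
    }
    IntervalSeriesSet(seriesSet@series, anomalyMask = mask,
                      meta = seriesSet@meta)
}

#' Remove flagged beats from all six series
#'
#' Deleting beat i deletes index i from every series, mirroring the rule
#' that a cardiac cycle deleted in one signal is deleted in the other.
#'
#' @param seriesSet a valid [IntervalSeriesSet-class].
#' @return An [IntervalSeriesSet-class] with flagged beats removed and an
#'   all-clear mask.
#' @export
dropAnomalousBeats <- function(seriesSet) {
    stopifnot(is(seriesSet, "IntervalSeriesSet"))
    keep <- !seriesSet@anomalyMask
    IntervalSeriesSet(seriesSet@series[keep, , drop = FALSE],
                      meta = seriesSet@meta)
}

#' Build the eight electrical-mechanical series pairs
#'
#' For a valid subject, removes flagged beats and returns the eight
#' z-normalized pairs in canonical order (RRI-STI, RRI-DTI, QTcI-STI,
#' QTcI-DTI, TpeI-STI, TpeI-DTI, TpeQTI-STI, TpeQTI-DTI).
#'
#' @param seriesSet an [IntervalSeriesSet-class]; must be valid under the
#'   10\% rule.
#' @return Named list of eight [SeriesPair-class] objects.
#' @export
makePairs <- function(seriesSet) {
    stopifnot(is(seriesSet, "IntervalSeriesSet"))
    if (!isValid(seriesSet))
        stop("invalid subject (anomaly fraction > 10%): cannot build pairs")
    clean <- dropAnomalousBeats(seriesSet)
    s <- clean@series
    if (nrow(s) < 30L)
        stop("fewer than 30 usable beats after anomaly removal")
    cp <- canonicalPairs()
    pairs <- vector("list", nrow(cp))
    names(pairs) <- paste(cp[, 1], cp[, 2], sep = "-")
    for (j in seq_len(nrow(cp)))
        pairs[[j]] <- SeriesPair(cp[j, 1], cp[j, 2],
                                 s[, cp[j, 1]], s[, cp[j, 2]])
    pairs
}

#' Write one subject's interval series as CSV
#'
#' @param seriesSet an [IntervalSeriesSet-class].
#' @param path output CSV (beat_index + six series columns + anomaly flag).
#' @return Invisibly, `path`.
#' @export
writeIntervalSeries <- function(seriesSet, path) {
    s <- seriesSet@series
    df <- data.frame(beat_index = seq_len(nrow(s)), s,
                     anomalous = seriesSet@anomalyMask)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}
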