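#' @import methods
#' @importFrom stats fft mad runmed sd var cov dnorm rnorm runif aov
#'   kruskal.test t.test wilcox.test p.adjust predict quantile setNames
#' @importFrom utils read.csv write.csv head
NULL

## Canonical series and pair vocabulary -------------------------------------

#' Canonical interval-series names
#'
#' The six beat-interval series: four electrical (ECG-derived) and two
#' mechanical (PCG-derived). `TpeQTI` is the dimensionless Tpe/QT ratio;
#' all others are in milliseconds.
#' @keywords internal
SERIES_NAMES <- c("RRI", "QTcI", "TpeI", "TpeQTI", "STI", "DTI")

ELECTRICAL_SERIES <- c("RRI", "QTcI", "TpeI", "TpeQTI")
MECHANICAL_SERIES <- c("STI", "DTI")

#' Canonical electrical-mechanical pair order
#'
#' The eight series pairs on which every coupling measure is computed, in
#' canonical order: RRI-STI, RRI-DTI, QTcI-STI, QTcI-DTI, TpeI-STI,
#' TpeI-DTI, TpeQTI-STI, TpeQTI-DTI.
#'
#' @return A two-column character matrix (electrical, mechanical).
#' @examples
#' canonicalPairs()
#' @export
canonicalPairs <- function() {
    el <- rep(ELECTRICAL_SERIES, each = 2L)
    me <- rep(MECHANICAL_SERIES, times = 4L)
    cbind(electrical = el, mechanical = me)
}

## IntervalSeriesSet ---------------------------------------------------------

#' IntervalSeriesSet: the six beat-interval series of one subject
#'
#' Holds the six named beat-interval series (columns of `series`), the
#' per-beat anomaly mask, and the subject validity flag. All six series have
#' equal length; the validity flag is `FALSE` iff the flagged anomaly
#' fraction exceeds 10\% (strict), the exclusion rule applied before any
#' coupling analysis.
#'
#' @slot series numeric matrix, one row per beat, columns
#'   `RRI, QTcI, TpeI, TpeQTI, STI, DTI`.
#' @slot anomalyMask logical vector, one entry per beat; `TRUE` marks an
#'   anomalous beat.
#' @slot valid scalar logical; `FALSE` iff `mean(anomalyMask) > 0.10`.
#' @slot meta list of provenance (ground-truth coupling, corrupted indices,
#'   generator parameters, ...).
#' @export
setClass("IntervalSeriesSet",
    representation(
        series = "matrix",
        anomalyMask = "logical",
        valid = "logical",
        meta = "list"
    )
)

setValidity("IntervalSeriesSet", function(object) {
    s <- object@series
    msgs <- character()
    if (!identical(colnames(s), SERIES_NAMES))
        msgs <- c(msgs, sprintf("series columns must be %s",
                                paste(SERIES_NAMES, collapse = ", ")))
    if (length(object@anomalyMask) != nrow(s))
        msgs <- c(msgs, "anomalyMask length must equal number of beats")
    if (length(object@valid) != 1L || is.na(object@valid))
        msgs <- c(msgs, "valid must be a scalar logical")
    if (anyNA(s) || any(!is.finite(s)))
        msgs <- c(msgs, "all series values must be finite")
    expectValid <- mean(object@anomalyMask) <= 0.10
    if (length(msgs) == 0L && object@valid != expectValid)
        msgs <- c(msgs, "valid flag inconsistent with 10% anomaly rule")
    if (length(msgs)) msgs else TRUE
})

#' Construct an IntervalSeriesSet
#'
#' @param series numeric matrix (beats x 6) with columns
#'   `RRI, QTcI, TpeI, TpeQTI, STI, DTI`, or a named list/data.frame of the
#'   six equal-length series.
#' @param anomalyMask logical per-beat mask (default: no anomalies).
#' @param meta list of provenance.
#' @return An [IntervalSeriesSet-class] object; the validity flag is derived
#'   from the mask via the strict 10\% rule.
#' @examples
#' s <- IntervalSeriesSet(cbind(RRI = rep(900, 50), QTcI = rep(400, 50),
#'     TpeI = rep(80, 50), TpeQTI = rep(0.2, 50),
#'     STI = rep(300, 50), DTI = rep(420, 50)))
#' isValid(s)
#' @export
IntervalSeriesSet <- function(series, anomalyMask = NULL, meta = list()) {
    if (is.list(series) && !is.data.frame(series))
        series <- do.call(cbind, series[SERIES_NAMES])
    series <- as.matrix(series)
    if (is.null(colnames(series)) && ncol(series) == 6L)
        colnames(series) <- SERIES_NAMES
    series <- series[, SERIES_NAMES, drop = FALSE]
    storage.mode(series) <- "double"
    if (is.null(anomalyMask)) anomalyMask <- rep(FALSE, nrow(series))
    valid <- mean(anomalyMask) <= 0.10
    new("IntervalSeriesSet", series = series, anomalyMask = anomalyMask,
        valid = valid, meta = meta)
}

#' @describeIn IntervalSeriesSet number of beats
#' @param x,object an `IntervalSeriesSet`
#' @export
setMethod("length", "IntervalSeriesSet", function(x) nrow(x@series))

#' Accessors for IntervalSeriesSet
#'
#' `intervalSeries` returns the beats x 6 series matrix (or one named
#' series); `anomalyMask` the per-beat logical mask; `isValid` the subject
#' validity flag under the strict 10\% anomaly rule; `anomalyFraction` the
#' flagged fraction.
#'
#' @param object an [IntervalSeriesSet-class]
#' @param name optional series name (one of `RRI, QTcI, TpeI, TpeQTI, STI,
#'   DTI`)
#' @return `intervalSeries`: numeric matrix or vector; `anomalyMask`:
#'   logical vector; `isValid`: logical scalar; `anomalyFraction`: numeric
#'   scalar.
#' @export
setGeneric("intervalSeries", function(object, name = NULL)
    standardGeneric("intervalSeries"))

#' @rdname intervalSeries
#' @export
setMethod("intervalSeries", "IntervalSeriesSet", function(object, name = NULL) {
    if (is.null(name)) return(object@series)
    name <- match.arg(name, SERIES_NAMES)
    object@series[, name]
})

#' @rdname intervalSeries
#' @export
setGeneric("anomalyMask", function(object) standardGeneric("anomalyMask"))

#' @rdname intervalSeries
#' @export
setMethod("anomalyMask", "IntervalSeriesSet", function(object) object@anomalyMask)

#' @rdname intervalSeries
#' @export
setGeneric("isValid", function(object) standardGeneric("isValid"))

#' @rdname intervalSeries
#' @export
setMethod("isValid", "IntervalSeriesSet", function(object) object@valid)

#' @rdname intervalSeries
#' @export
setGeneric("anomalyFraction", function(object) standardGeneric("anomalyFraction"))

#' @rdname intervalSeries
#' @export
setMethod("anomalyFraction", "IntervalSeriesSet",
          function(object) mean(object@anomalyMask))

setMethod("show", "IntervalSeriesSet", function(object) {
    cat(sprintf("IntervalSeriesSet: %d beats, %d series\n",
                nrow(object@series), ncol(object@series)))
    cat(sprintf("  anomalous: %d (%.1f%%) -> %s\n",
                sum(object@anomalyMask), 100 * mean(object@anomalyMask),
                if (object@valid) "valid" else "INVALID"))
    rng <- apply(object@series, 2, range)
    cat("  ranges:",
        paste(sprintf("%s [%.3g, %.3g]", colnames(object@series),
                      rng[1, ], rng[2, ]), collapse = ", "), "\n")
})

## SeriesPair ----------------------------------------------------------------

#' SeriesPair: one aligned, z-normalized electrical/mechanical pair
#'
#' The unit on which every coupling measure operates. Both vectors are
#' z-normalized (mean 0, SD 1) so that entropy tolerances are in SD units.
#'
#' @slot electrical,mechanical the series names.
#' @slot x,y equal-length z-normalized numeric vectors (x electrical,
#'   y mechanical).
#' @export
setClass("SeriesPair",
    representation(
        electrical = "character",
        mechanical = "character",
        x = "numeric",
        y = "numeric"
    )
)

setValidity("SeriesPair", function(object) {
    msgs <- character()
    if (!(object@electrical %in% ELECTRICAL_SERIES))
        msgs <- c(msgs, "electrical must be one of RRI, QTcI, TpeI, TpeQTI")
    if (!(object@mechanical %in% MECHANICAL_SERIES))
        msgs <- c(msgs, "mechanical must be STI or DTI")
    if (length(object@x) != length(object@y))
        msgs <- c(msgs, "x and y must have equal length")
    if (length(object@x) < 30L)
        msgs <- c(msgs, "pair length must be at least 30 beats")
    tol <- 1e-9
    if (abs(mean(object@x)) > tol || abs(sd(object@x) - 1) > tol ||
        abs(mean(object@y)) > tol || abs(sd(object@y) - 1) > tol)
        msgs <- c(msgs, "both vectors must be z-normalized (mean 0, SD 1)")
    if (length(msgs)) msgs else TRUE
})

#' Construct a SeriesPair from raw vectors
#'
#' Z-normalizes both inputs. A constant input (SD = 0) is a degenerate pair
#' and raises an error.
#'
#' @param electrical,mechanical series names.
#' @param x,y raw equal-length numeric vectors.
#' @return A [SeriesPair-class].
#' @export
SeriesPair <- function(electrical, mechanical, x, y) {
    new("SeriesPair", electrical = electrical, mechanical = mechanical,
        x = zNormalize(x), y = zNormalize(y))
}

#' @describeIn SeriesPair pair length N
#' @param x a `SeriesPair`
#' @export
setMethod("length", "SeriesPair", function(x) length(x@x))

setMethod("show", "SeriesPair", function(object) {
    cat(sprintf("SeriesPair %s-%s: N = %d (z-normalized)\n",
                object@electrical, object@mechanical, length(object@x)))
})

#' @rdname SeriesPair
#' @param object a `SeriesPair`
#' @export
setGeneric("pairName", function(object) standardGeneric("pairName"))

#' @rdname SeriesPair
#' @export
setMethod("pairName", "SeriesPair", function(object)
    paste(object@electrical, object@mechanical, sep = "-"))

#' Z-normalize a numeric vector
#'
#' @param x numeric vector.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zNormalize <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0)
        stop("cannot z-normalize a constant series (SD = 0)")
    (x - mean(x)) / s
}

## SyntheticCohort -----------------------------------------------------------

#' SyntheticCohort: labeled synthetic subjects
#'
#' @slot subjects list of per-subject records (`subjectId`, `group`, `rho`,
#'   `series` (IntervalSeriesSet), `annotation` (data.frame)).
#' @slot labels data.frame with columns `subject_id`, `group`.
#' @slot config the generating [syntheticCohortConfig()].
#' @export
setClass("SyntheticCohort",
    representation(subjects = "list", labels = "data.frame", config = "list"))

setMethod("show", "SyntheticCohort", function(object) {
    tab <- table(object@labels$group)
    cat(sprintf("SyntheticCohort: %d subjects (%s)\n",
                nrow(object@labels),
                paste(names(tab), tab, sep = "=", collapse = ", ")))
})

#' @describeIn SyntheticCohort number of subjects
#' @param x a `SyntheticCohort`
#' @export
setMethod("length", "SyntheticCohort", function(x) length(x@subjects))

#' Accessors for SyntheticCohort
#' @param object a [SyntheticCohort-class]
#' @return `cohortLabels`: the subject_id/group data.frame;
#'   `cohortSubjects`: the list of subject records.
#' @export
setGeneric("cohortLabels", function(object) standardGeneric("cohortLabels"))

#' @rdname cohortLabels
#' @export
setMethod("cohortLabels", "SyntheticCohort", function(object) object@labels)

#' @rdname cohortLabels
#' @export
setGeneric("cohortSubjects", function(object) standardGeneric("cohortSubjects"))

#' @rdname cohortLabels
#' @export
setMethod("cohortSubjects", "SyntheticCohort", function(object) object@subjects)
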