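## Synthetic cohorts of coupled ECG/PCG beat-interval series.
##
## The generator works in the beat domain: every series is an AR(1) process
## around a physiologic baseline, and the electrical-mechanical coupling is a
## shared-innovation convex mixture. The RR innovation e_rr drives the RRI
## series; every other series k is driven by
##     eps_k = (rho * e_rr + (1 - rho) * eta_k) / sqrt(rho^2 + (1 - rho)^2)
## with eta_k independent standard normal, so rho = 0 gives independent
## innovations and rho = 1 makes every innovation identical to e_rr. The
## group label acts only through rho and through the per-group dispersion /
## autocorrelation profile (no mean shift carries class signal on normalized
## series).

GROUPS <- c("severe", "mild-moderate", "CPNCA")

#' Default per-group generator profiles
#'
#' One row per stenosis-severity group. Coupling strength `couplingRho`
#' increases from severe CHD to the normal-angiography (CPNCA) group, the
#' direction in which cardiac mechano-electric coupling degrades with
#' disease severity. Dispersion/autocorrelation defaults encode the
#' qualitative series morphology of the three groups: stable RRI but
#' elevated, widely fluctuating TpeI in severe CHD; large dispersed RRI and
#' DTI fluctuation in mild-to-moderate CHD; concentrated TpeI (40-110 ms)
#' and Tpe/QT (0.15-0.25) in CPNCA.
#'
#' @return data.frame with columns `group, couplingRho, arCoeff, rrSD,
#'   qtiMean, qtiSD, tpeMean, tpeSD, stiSD, dtiSD` (SDs and means in ms).
#' @export
defaultGroupProfiles <- function() {
    data.frame(
        group       = GROUPS,
        couplingRho = c(0.2, 0.5, 0.8),
        arCoeff     = c(0.80, 0.30, 0.55),
        rrSD        = c(15, 50, 35),
        qtiMean     = c(430, 405, 390),
        qtiSD       = c(10, 8, 6),
        tpeMean     = c(120, 90, 75),
        tpeSD       = c(12, 7, 5),
        stiSD       = c(12, 15, 10),
        dtiSD       = c(20, 35, 18),
        stringsAsFactors = FALSE
    )
}

#' Configuration for a synthetic cohort
#'
#' @param nPerGroup named integer vector of subjects per group; the default
#'   mirrors the 114/37/40 severe / mild-to-moderate / CPNCA cohort
#'   structure.
#' @param nBeats beats per subject (default 300, about 5 min at RR 900 ms);
#'   must be >= 50.
#' @param meanRR mean RR interval in ms (default 900).
#' @param anomalyFraction fraction of beats replaced by out-of-range values
#'   (default 0).
#' @param seed integer seed; all generation is a pure function of
#'   (config, seed).
#' @param profiles per-group profile data.frame, see
#'   [defaultGroupProfiles()]. `couplingRho` values must be ordered
#'   severe < mild-moderate < CPNCA.
#' @return A validated config list of class `syntheticCohortConfig`.
#' @examples
#' cfg <- syntheticCohortConfig(nPerGroup = c(severe = 10,
#'     `mild-moderate` = 10, CPNCA = 10), seed = 1)
#' @export
syntheticCohortConfig <- function(nPerGroup = c(severe = 114L,
                                                `mild-moderate` = 37L,
                                                CPNCA = 40L),
                                  nBeats = 300L,
                                  meanRR = 900,
                                  anomalyFraction = 0,
                                  seed = 1L,
                                  profiles = defaultGroupProfiles()) {
    stopifnot(is.numeric(nPerGroup), all(nPerGroup >= 2))
    if (is.null(names(nPerGroup)) || !all(names(nPerGroup) %in% GROUPS))
        stop("nPerGroup must be named with groups: ",
             paste(GROUPS, collapse = ", "))
    if (nBeats < 50) stop("nBeats must be >= 50")
    if (meanRR <= 0) stop("meanRR must be positive")
    if (anomalyFraction < 0 || anomalyFraction > 1)
        stop("anomalyFraction must be in [0, 1]")
    stopifnot(all(GROUPS %in% profiles$group))
    rho <- profiles$couplingRho[match(GROUPS, profiles$group)]
    if (any(rho < 0 | rho > 1)) stop("couplingRho must be in [0, 1]")
    if (!(rho[1] < rho[2] && rho[2] < rho[3]))
        stop("couplingRho must be ordered severe < mild-moderate < CPNCA")
    sdCols <- c("rrSD", "qtiSD", "tpeSD", "stiSD", "dtiSD")
    if (any(as.matrix(profiles[, sdCols]) <= 0))
        stop("all profile SDs must be positive")
    structure(list(nPerGroup = nPerGroup, nBeats = as.integer(nBeats),
                   meanRR = meanRR, anomalyFraction = anomalyFraction,
                   seed = as.integer(seed), profiles = profiles),
              class = "syntheticCohortConfig")
}

## mean-reverting AR(1) deviation with unit-variance innovations
ar1Deviation <- function(innov, a, sdTarget) {
    n <- length(innov)
    d <- numeric(n)
    scale <- sqrt(1 - a^2) * sdTarget
    d[1] <- sdTarget * innov[1]
    for (i in seq_len(n)[-1]) d[i] <- a * d[i - 1] + scale * innov[i]
    d
}

## convex shared-innovation mixture, restandardized to unit variance
mixInnovations <- function(eShared, eta, rho) {
    if (rho == 1) return(eShared)
    (rho * eShared + (1 - rho) * eta) / sqrt(rho^2 + (1 - rho)^2)
}

#' Generate one subject's coupled interval series
#'
#' RRI is a mean-reverting AR(1) around `meanRR`. STI and DTI sit on
#' deterministic physiologic baselines (systole about RR/3; diastole the
#' remainder of the cycle net of the S1/S2 sound durations) and QTI/TpeI on
#' group-level baselines; each non-RRI series is an AR(1) driven by the
#' shared-innovation mixture with the group's coupling strength `rho`.
#' QTcI is the Bazett-corrected QTI and TpeQTI = TpeI/QTI element-wise.
#'
#' @param config a [syntheticCohortConfig()].
#' @param group group label (`severe`, `mild-moderate`, `CPNCA`).
#' @param seed integer seed for this subject.
#' @param rho optional coupling override in [0, 1] (defaults to the group
#'   profile value).
#' @return An [IntervalSeriesSet-class] with ground truth in `meta`
#'   (`rho`, `group`, `s1Duration`, `s2Duration`).
#' @examples
#' cfg <- syntheticCohortConfig(seed = 1)
#' s <- genIntervalSeries(cfg, "CPNCA", seed = 7)
#' @export
genIntervalSeries <- function(config, group, seed, rho = NULL) {
    stopifnot(inherits(config, "syntheticCohortConfig"))
    if (!(group %in% GROUPS))
        stop("invalid group label: ", group)
    prof <- config$profiles[config$profiles$group == group, , drop = FALSE]
    if (is.null(rho)) rho <- prof$couplingRho
    stopifnot(rho >= 0, rho <= 1)
    n <- config$nBeats
    set.seed(seed)

    eRR <- rnorm(n)
    rri <- config$meanRR + ar1Deviation(eRR, prof$arCoeff, prof$rrSD)

    mixed <- function(sdTarget) {
        eps <- mixInnovations(eRR, rnorm(n), rho)
        ar1Deviation(eps, prof$arCoeff, sdTarget)
    }
    s1Dur <- 100; s2Dur <- 80
    stiBase <- config$meanRR / 3
    dtiBase <- config$meanRR - s1Dur - stiBase - s2Dur
    sti <- stiBase + mixed(prof$stiSD)
    dti <- dtiBase + mixed(prof$dtiSD)
    qti <- prof$qtiMean + mixed(prof$qtiSD)
    tpe <- prof$tpeMean + mixed(prof$tpeSD)

    qtc <- bazettCorrect(qti, rri)
    series <- cbind(RRI = rri, QTcI = qtc, TpeI = tpe, TpeQTI = tpe / qti,
                    STI = sti, DTI = dti)
    iss <- IntervalSeriesSet(series,
        meta = list(rho = rho, group = group, seed = seed,
                    s1Duration = s1Dur, s2Duration = s2Dur))
    if (config$anomalyFraction > 0)
        iss <- injectAnomalies(iss, config$anomalyFraction,
                               seed = seed + 1L)
    iss
}

#' Emit fiducial annotations consistent with an interval-series set
#'
#' Produces one row per beat with landmark times (ms) whose pairwise
#' differences reproduce the input series exactly: consecutive R peaks give
#' RRI, S1 offset to S2 onset gives STI, S2 offset to next S1 onset gives
#' DTI, and the Q-onset/T-peak/T-offset landmarks encode QTI (inverse Bazett
#' from QTcI and RRI) and TpeI. A series set of length L yields L + 1
#' annotation rows (the last beat closes the final RR interval; its
#' within-beat intervals repeat the last series values).
#'
#' @param seriesSet an [IntervalSeriesSet-class].
#' @param t0 time of the first R peak (ms).
#' @return data.frame with columns `beat_index, r_peak_ms, q_onset_ms,
#'   t_peak_ms, t_offset_ms, s1_offset_ms, s2_onset_ms, s2_offset_ms,
#'   next_s1_onset_ms`.
#' @seealso [extractIntervalSeries()] for the inverse (round-trip identity).
#' @export
genAnnotations <- function(seriesSet, t0 = 1000) {
    stopifnot(is(seriesSet, "IntervalSeriesSet"))
    s <- seriesSet@series
    L <- nrow(s)
    meta <- seriesSet@meta
    s1Dur <- if (!is.null(meta$s1Duration)) meta$s1Duration else 100
    s2Dur <- if (!is.null(meta$s2Duration)) meta$s2Duration else 80

    ## beats 1..L carry the series values; beat L+1 repeats beat L's
    ## within-beat intervals (it exists to close RRI[L]).
    idx <- c(seq_len(L), L)
    rri <- s[, "RRI"]
    rPeak <- t0 + c(0, cumsum(rri))           # length L + 1
    rriOfBeat <- rri[idx]                     # RR used for inverse Bazett
    qtcI <- s[idx, "QTcI"]
    qti <- qtcI * sqrt(rriOfBeat / 1000)      # inverse Bazett
    tpeI <- s[idx, "TpeI"]
    stiI <- s[idx, "STI"]
    dtiI <- s[idx, "DTI"]

    qOnset <- rPeak - 25
    tOffset <- qOnset + qti
    tPeak <- tOffset - tpeI
    s1Offset <- rPeak + s1Dur
    s2Onset <- s1Offset + stiI
    s2Offset <- s2Onset + s2Dur
    nextS1 <- s2Offset + dtiI

    data.frame(beat_index = seq_len(L + 1L), r_peak_ms = rPeak,
               q_onset_ms = qOnset, t_peak_ms = tPeak, t_offset_ms = tOffset,
               s1_offset_ms = s1Offset, s2_onset_ms = s2Onset,
               s2_offset_ms = s2Offset, next_s1_onset_ms = nextS1)
}

#' Replace a fraction of beats with out-of-range values
#'
#' Replaces `ceiling(fraction * n)` randomly chosen beats' RRI with values
#' outside the physiologic range (below 300 ms or above 2000 ms), the kind
#' of corruption the 10\% invalidation rule screens for. Corrupted indices
#' are recorded in `meta$corrupted`; the anomaly mask itself is left to
#' [detectAnomalousBeats()], so detection recall can be measured.
#'
#' @param seriesSet an [IntervalSeriesSet-class].
#' @param fraction fraction of beats to corrupt, in [0, 1].
#' @param seed integer seed.
#' @return The corrupted [IntervalSeriesSet-class].
#' @export
injectAnomalies <- function(seriesSet, fraction, seed = 1L) {
    stopifnot(is(seriesSet, "IntervalSeriesSet"))
    if (fraction < 0 || fraction > 1)
        stop("fraction must be in [0, 1]")
    if (fraction == 0) return(seriesSet)
    n <- nrow(seriesSet@series)
    k <- ceiling(fraction * n)
    set.seed(seed)
    beats <- sort(sample.int(n, k))
    low <- runif(k) < 0.5
    vals <- ifelse(low, runif(k, 100, 250), runif(k, 2200, 3000))
    s <- seriesSet@series
    s[beats, "RRI"] <- vals
    meta <- seriesSet@meta
    meta$corrupted <- beats
    IntervalSeriesSet(s, anomalyMask = seriesSet@anomalyMask, meta = meta)
}

#' Generate a labeled synthetic cohort
#'
#' Deterministic under `config$seed`: per-subject seeds are derived from the
#' cohort seed, group index and subject index.
#'
#' @param config a [syntheticCohortConfig()].
#' @param annotations if `TRUE` (default) each subject also carries the
#'   fiducial-annotation table consistent with its series.
#' @return A [SyntheticCohort-class].
#' @examples
#' cfg <- syntheticCohortConfig(nPerGroup = c(severe = 3,
#'     `mild-moderate` = 3, CPNCA = 3), seed = 1)
#' genCohort(cfg)
#' @export
genCohort <- function(config, annotations = TRUE) {
    stopifnot(inherits(config, "syntheticCohortConfig"))
    subjects <- list()
    labels <- list()
    for (gi in seq_along(GROUPS)) {
        g <- GROUPS[gi]
        ng <- config$nPerGroup[[g]]
        if (is.na(ng)) next
        for (si in seq_len(ng)) {
            sid <- sprintf("%s_%03d", gsub("[^A-Za-z]", "", g), si)
            seed <- deriveSeed(config$seed, gi * 1000L + si)
            iss <- genIntervalSeries(config, g, seed = seed)
            rec <- list(subjectId = sid, group = g, rho = iss@meta$rho,
                        series = iss,
                        annotation = if (annotations) genAnnotations(iss)
                                     else NULL)
            subjects[[sid]] <- rec
            labels[[sid]] <- data.frame(subject_id = sid, group = g,
                                        stringsAsFactors = FALSE)
        }
    }
    new("SyntheticCohort", subjects = subjects,
        labels = do.call(rbind, c(labels, list(make.row.names = FALSE))),
        config = unclass(config))
}

#' Derive a stage/subject seed from a global seed
#'
#' Linear-congruential mixing kept below 2^31 so derived seeds remain valid
#' R integers.
#' @param seed global integer seed.
#' @param k stream index.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}

#' Write cohort annotation and label files
#'
#' One annotation CSV per subject (`<subject_id>.csv`, schema of
#' [genAnnotations()]) plus `labels.csv` (`subject_id, group`).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeCohortAnnotations <- function(cohort, dir) {
    stopifnot(is(cohort, "SyntheticCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (rec in cohort@subjects) {
        ann <- if (is.null(rec$annotation)) genAnnotations(rec$series)
               else rec$annotation
        f <- file.path(dir, paste0(rec$subjectId, ".csv"))
        write.csv(ann, f, row.names = FALSE)
        files <- c(files, f)
    }
    lf <- file.path(dir, "labels.csv")
    write.csv(cohort@labels, lf, row.names = FALSE)
    invisible(c(files, lf))
}
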