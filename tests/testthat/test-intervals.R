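makeAnn <- function(n = 40, rr = 900) {
    r <- 1000 + (0:(n - 1)) * rr
    data.frame(beat_index = 1:n, r_peak_ms = r, q_onset_ms = r - 25,
               t_peak_ms = r + 295, t_offset_ms = r + 375,
               s1_offset_ms = r + 100, s2_onset_ms = r + 400,
               s2_offset_ms = r + 480, next_s1_onset_ms = r + 900)
}

test_that("interval definitions follow the landmark arithmetic", {
    ann <- makeAnn()
    ## one beat with the worked textbook landmarks
    ann$s1_offset_ms[1] <- ann$r_peak_ms[1] + 100
    iss <- extractIntervalSeries(ann)
    expect_equal(unname(intervalSeries(iss, "RRI")), rep(900, 39))
    expect_equal(unname(intervalSeries(iss, "STI")), rep(300, 39))
    expect_equal(unname(intervalSeries(iss, "DTI")), rep(420, 39))
    expect_equal(unname(intervalSeries(iss, "TpeI")), rep(80, 39))
    ## QTI = 400, RR = 900 -> QTc = 400 / sqrt(0.9)
    expect_equal(unname(intervalSeries(iss, "QTcI")),
                 rep(400 / sqrt(0.9), 39))
    expect_equal(unname(intervalSeries(iss, "TpeQTI")), rep(0.2, 39))
})

test_that("STI/DTI worked example: S1 offset 100, S2 onset 400, S2 offset 500, next S1 900", {
    ann <- makeAnn(31)
    ann$s1_offset_ms[1] <- 100
    ann$s2_onset_ms[1] <- 400
    ann$s2_offset_ms[1] <- 500
    ann$next_s1_onset_ms[1] <- 900
    iss <- extractIntervalSeries(ann)
    expect_equal(unname(intervalSeries(iss, "STI")[1]), 300)
    expect_equal(unname(intervalSeries(iss, "DTI")[1]), 400)
})

test_that("Bazett correction matches its closed form and rejects bad RR", {
    expect_equal(bazettCorrect(400, 1000), 400)
    expect_equal(bazettCorrect(400, 640), 500)
    expect_equal(bazettCorrect(0, 900), 0)
    expect_error(bazettCorrect(400, 0), "positive")
    expect_error(bazettCorrect(400, -10), "positive")
})

test_that("anomalous beats are flagged by physiologic bounds", {
    ann <- makeAnn(60)
    iss <- extractIntervalSeries(ann)
    expect_false(any(anomalyMask(iss)))
    s <- intervalSeries(iss)
    s[10, "RRI"] <- 150   # below the 300 ms floor
    mask <- detectAnomalousBeats(s)
    expect_true(mask[10])
    expect_equal(sum(mask), 1L)
})

test_that("rolling-MAD rule catches in-range outliers and recall on injected anomalies is >= 0.95", {
    iss <- testSubject()
    recalls <- vapply(1:10, function(s) {
        bad <- injectAnomalies(iss, 0.08, seed = s)
        mask <- detectAnomalousBeats(bad)
        mean(bad@meta$corrupted %in% which(mask))
    }, numeric(1))
    expect_gte(min(recalls), 0.95)
})

test_that("the 10% rule is strict and monotone in the anomaly count", {
    base <- testSubject(nBeats = 280)
    n <- length(base)
    expect_equal(n, 280L)
    mask30 <- rep(FALSE, n); mask30[1:30] <- TRUE   # 10.7%
    mask28 <- rep(FALSE, n); mask28[1:28] <- TRUE   # 10.0% exactly
    expect_false(isValid(validateSubject(base, mask30)))
    expect_true(isValid(validateSubject(base, mask28)))
    expect_true(isValid(validateSubject(base, rep(FALSE, n))))
    ## monotonicity: once invalid, more anomalies can never restore validity
    valid <- vapply(seq(0, 60, by = 4), function(k) {
        m <- rep(FALSE, n); if (k > 0) m[seq_len(k)] <- TRUE
        isValid(validateSubject(base, m))
    }, logical(1))
    expect_true(all(diff(as.integer(valid)) <= 0))
})

test_that("beat deletion is synchronized across all six series", {
    iss <- testSubject()
    mask <- rep(FALSE, length(iss)); mask[c(3, 17, 40)] <- TRUE
    flagged <- validateSubject(iss, mask)
    clean <- dropAnomalousBeats(flagged)
    expect_equal(length(clean), length(iss) - 3L)
    expect_equal(intervalSeries(clean), intervalSeries(iss)[!mask, ])
})

test_that("makePairs returns the eight canonical z-normalized pairs", {
    pairs <- makePairs(testSubject())
    expect_named(pairs, c("RRI-STI", "RRI-DTI", "QTcI-STI", "QTcI-DTI",
                          "TpeI-STI", "TpeI-DTI", "TpeQTI-STI",
                          "TpeQTI-DTI"))
    for (p in pairs) {
        expect_lt(abs(mean(p@x)), 1e-9)
        expect_lt(abs(sd(p@x) - 1), 1e-9)
        expect_lt(abs(mean(p@y)), 1e-9)
        expect_lt(abs(sd(p@y) - 1), 1e-9)
    }
})

test_that("degenerate and invalid subjects are rejected by pairing", {
    iss <- testSubject()
    mask <- rep(FALSE, length(iss)); mask[1:45] <- TRUE  # 15%
    expect_error(makePairs(validateSubject(iss, mask)), "invalid subject")
    expect_error(zNormalize(rep(5, 100)), "constant")
    ## constant series inside a set: pairing must fail on normalization
    s <- intervalSeries(iss)
    s[, "STI"] <- 300
    expect_error(makePairs(IntervalSeriesSet(s)), "constant")
})

test_that("ordering violations are flagged, not silently dropped", {
    ann <- makeAnn(45)
    ann$t_peak_ms[5] <- ann$t_offset_ms[5] + 10  # T peak after T offset
    iss <- extractIntervalSeries(ann)
    expect_true(anomalyMask(iss)[5])
    expect_error(extractIntervalSeries(makeAnn(20)), "fewer than 30")
})
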