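test_that("degenerate mixture: rho = 1 with vanishing noise makes the mechanical series a function of RRI", {
    prof <- defaultGroupProfiles()
    prof$stiSD <- rep(1e-8, 3)  # noise floor -> deterministic baseline
    cfg <- syntheticCohortConfig(nPerGroup = c(severe = 2,
        `mild-moderate` = 2, CPNCA = 2), seed = 1, profiles = prof)
    s <- genIntervalSeries(cfg, "CPNCA", seed = 5, rho = 1)
    sti <- intervalSeries(s, "STI")
    rri <- intervalSeries(s, "RRI")
    ## with rho = 1 both series share the same innovation stream and the
    ## same AR filter, so they are affinely related
    expect_gt(abs(cor(sti, rri)), 0.999999)
})

test_that("rho = 0 gives uncoupled innovations (|corr| < 0.15 at n = 300 over 20 seeds)", {
    cfg <- smallConfig()
    innovCor <- function(iss) {
        ## strip the shared AR(1) filter: residual of s[i] on s[i-1]
        ## recovers each series' innovation stream
        r <- function(v) {
            n <- length(v)
            stats::resid(stats::lm(v[-1] ~ v[-n]))
        }
        cor(r(intervalSeries(iss, "RRI")), r(intervalSeries(iss, "STI")))
    }
    cors <- vapply(1:20, function(s) {
        innovCor(genIntervalSeries(cfg, "CPNCA", seed = deriveSeed(7, s),
                                   rho = 0))
    }, numeric(1))
    expect_lt(max(abs(cors)), 0.15)
    expect_lt(abs(mean(cors)), 0.05)
})

test_that("generation is a pure function of (config, seed)", {
    cfg <- smallConfig()
    a <- genIntervalSeries(cfg, "severe", seed = 42)
    b <- genIntervalSeries(cfg, "severe", seed = 42)
    expect_identical(intervalSeries(a), intervalSeries(b))
    c1 <- genCohort(cfg)
    c2 <- genCohort(cfg)
    expect_identical(
        lapply(cohortSubjects(c1), function(s) intervalSeries(s$series)),
        lapply(cohortSubjects(c2), function(s) intervalSeries(s$series)))
})

test_that("annotation round-trip reproduces every series exactly across seeds", {
    cfg <- smallConfig()
    for (s in 1:50) {
        g <- c("severe", "mild-moderate", "CPNCA")[(s %% 3) + 1]
        iss <- genIntervalSeries(cfg, g, seed = deriveSeed(123, s))
        ann <- genAnnotations(iss)
        back <- extractIntervalSeries(ann)
        expect_equal(nrow(ann), length(iss) + 1L)
        expect_lt(max(abs(intervalSeries(back) - intervalSeries(iss))), 1e-9)
    }
})

test_that("minimal annotation table yields a single RRI value", {
    iss <- testSubject()
    ann <- genAnnotations(iss)[1:2, ]
    rri <- diff(ann$r_peak_ms)
    expect_length(rri, 1L)
    expect_equal(rri, intervalSeries(iss, "RRI")[1])
})

test_that("innovation coupling is monotone in rho (RRI-STI, averaged over seeds)", {
    cfg <- smallConfig()
    rhoGrid <- c(0, 0.25, 0.5, 0.75, 1)
    meanCor <- vapply(rhoGrid, function(rho) {
        mean(vapply(1:20, function(s) {
            iss <- genIntervalSeries(cfg, "CPNCA",
                                     seed = deriveSeed(31, s), rho = rho)
            cor(intervalSeries(iss, "RRI"), intervalSeries(iss, "STI"))
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(meanCor) > 0))
    expect_gt(meanCor[5], 0.99)
})

test_that("per-group series land in their physiologic ranges", {
    cfg <- smallConfig()
    cp <- genIntervalSeries(cfg, "CPNCA", seed = 3)
    expect_true(all(intervalSeries(cp, "TpeI") > 40 &
                    intervalSeries(cp, "TpeI") < 110))
    expect_true(all(intervalSeries(cp, "TpeQTI") > 0.15 &
                    intervalSeries(cp, "TpeQTI") < 0.25))
    sv <- genIntervalSeries(cfg, "severe", seed = 3)
    expect_gt(mean(intervalSeries(sv, "TpeI")), 110)
    expect_gt(mean(intervalSeries(sv, "TpeQTI")), 0.25)
    ## TpeQTI consistency holds element-wise: TpeQTI = TpeI / QTI with
    ## QTI recovered from QTcI via inverse Bazett
    qti <- intervalSeries(cp, "QTcI") * sqrt(intervalSeries(cp, "RRI") / 1000)
    expect_equal(intervalSeries(cp, "TpeQTI"),
                 intervalSeries(cp, "TpeI") / qti, tolerance = 1e-12)
})

test_that("anomaly injection corrupts the requested number of beats", {
    iss <- testSubject()
    expect_identical(injectAnomalies(iss, 0), iss)
    out <- injectAnomalies(iss, 0.12, seed = 9)
    expect_length(out@meta$corrupted, ceiling(0.12 * length(iss)))
    vals <- intervalSeries(out, "RRI")[out@meta$corrupted]
    expect_true(all(vals < 300 | vals > 2000))
    expect_error(injectAnomalies(iss, 1.2), "fraction")
})

test_that("cohort structure, counts and labels are as configured", {
    cfg <- smallConfig(n = 10)
    cohort <- genCohort(cfg, annotations = FALSE)
    expect_length(cohort, 30L)
    expect_equal(as.integer(table(cohortLabels(cohort)$group)[
        c("severe", "mild-moderate", "CPNCA")]), c(10L, 10L, 10L))
    big <- syntheticCohortConfig(seed = 2)  # study-sized default counts
    expect_equal(sum(big$nPerGroup), 191)
    expect_error(syntheticCohortConfig(nPerGroup = c(severe = 1,
        `mild-moderate` = 5, CPNCA = 5)), "nPerGroup")
})

test_that("config validation enforces ordering and positivity invariants", {
    prof <- defaultGroupProfiles()
    prof$couplingRho <- c(0.9, 0.5, 0.2)  # wrong direction
    expect_error(syntheticCohortConfig(profiles = prof), "ordered")
    prof <- defaultGroupProfiles()
    prof$rrSD[1] <- -1
    expect_error(syntheticCohortConfig(profiles = prof), "positive")
    expect_error(syntheticCohortConfig(nBeats = 20), "nBeats")
    expect_error(genIntervalSeries(smallConfig(), "nonsense", 1),
                 "invalid group")
})
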