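test_that("XSampEn and XFuzzyEn match the literal-equation oracle to 1e-12", {
    for (s in 1:10) {
        set.seed(s)
        N <- sample(50:200, 1)
        x <- rnorm(N)
        y <- 0.5 * x + rnorm(N)
        p <- entropyParams(m = 2, r = 0.2)
        expect_equal(xSampEn(x, p, y = y), naiveXSampEn(x, y),
                     tolerance = 1e-12)
        expect_equal(xFuzzyEn(x, p, y = y), naiveXFuzzyEn(x, y),
                     tolerance = 1e-12)
    }
})

test_that("entropies vanish in the wide-tolerance limit", {
    set.seed(3)
    x <- rnorm(120); y <- rnorm(120)
    p <- entropyParams(r = 10)
    expect_equal(xSampEn(x, p, y = y), 0)
    expect_lt(abs(xFuzzyEn(x, p, y = y)), 0.01)
})

test_that("fuzzy membership is 1/2 exactly at d = r", {
    expect_equal(fuzzyMembership(0.2, 0.2), 0.5)
    expect_equal(fuzzyMembership(1, 1), 0.5)
    expect_equal(fuzzyMembership(0, 0.2), 1)
})

test_that("periodic signals are more cross-predictable than noise", {
    set.seed(11)
    t <- 1:200
    sine <- sin(2 * pi * t / 20)
    noise <- rnorm(200)
    p <- entropyParams()
    expect_lt(xSampEn(sine, p, y = sine), xSampEn(noise, p, y = rnorm(200)))
    expect_lt(xFuzzyEn(sine, p, y = sine), xFuzzyEn(noise, p, y = rnorm(200)))
})

test_that("undefined XSampEn raises a distinct condition, never an infinity", {
    ## two series far apart after disabling normalization: no cross matches
    x <- rnorm(60)
    y <- x + 100
    expect_error(xSampEn(x, entropyParams(), y = y, normalize = FALSE),
                 class = "undefinedEntropyError")
    expect_error(xSampEn(rnorm(3), y = rnorm(3)), "too short")
})

test_that("Doane's rule matches the textbook computation", {
    expect_equal(doaneBins(c(seq_len(512), -seq_len(512))), 11L)
    for (s in 1:20) {
        set.seed(s)
        v <- rexp(sample(30:500, 1))^sample(1:2, 1)
        expect_equal(doaneBins(v), naiveDoane(v))
    }
    expect_gte(doaneBins(rnorm(3)), 1L)
    expect_error(doaneBins(1:2), "at least 3")
})

test_that("JDistEn reduces to the single-series distribution entropy for identical series", {
    for (s in 1:5) {
        set.seed(s)
        u <- rnorm(150)
        expect_equal(jDistEn(u, y = u), naiveDistributionEntropy(u),
                     tolerance = 1e-12)
    }
})

test_that("JDistEn stays in [0, 1] and handles degenerate input", {
    for (s in 1:20) {
        set.seed(s)
        v <- jDistEn(rnorm(100), y = rnorm(100))
        expect_gte(v, 0)
        expect_lte(v, 1)
    }
    ## constant series: all embedded distances 0, defined as 0
    expect_equal(jDistEn(rep(1, 100), y = rnorm(100), normalize = FALSE), 0)
})

test_that("the printed-form flag changes the distance combination", {
    set.seed(4)
    x <- rnorm(120); y <- rnorm(120)
    a <- jDistEn(x, y = y, sqrtForm = TRUE)
    b <- jDistEn(x, y = y, sqrtForm = FALSE)
    expect_false(isTRUE(all.equal(a, b)))
    expect_true(b >= 0 && b <= 1)
})

test_that("JDistEn separates strongly coupled from uncoupled pairs with consistent sign", {
    cfg <- smallConfig()
    jd <- function(rho) vapply(1:20, function(s) {
        iss <- genIntervalSeries(cfg, "CPNCA", seed = deriveSeed(55, s),
                                 rho = rho)
        jDistEn(makePairs(validateSubject(iss))[["RRI-STI"]])
    }, numeric(1))
    lo <- jd(0); hi <- jd(0.9)
    ## direction recorded from the oracle run: coupling RAISES JDistEn on
    ## these AR pairs (the joint distance distribution spreads)
    expect_gt(mean(hi), mean(lo))
    expect_gt(abs(mean(hi) - mean(lo)) /
              sqrt((var(hi) + var(lo)) / 2), 1)
})
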