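# Independent reference implementations used as oracles. These follow the
# defining equations literally (explicit loop over templates i, per-template
# match averages), deliberately not sharing code with the package's
# vectorized implementations.

naiveCrossDistances <- function(x, y, m, n) {
    D <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
        xi <- x[i:(i + m - 1)]
        for (j in seq_len(n))
            D[i, j] <- max(abs(xi - y[j:(j + m - 1)]))
    }
    D
}

naiveXSampEn <- function(x, y, m = 2, r = 0.2) {
    x <- (x - mean(x)) / sd(x)
    y <- (y - mean(y)) / sd(y)
    n <- length(x) - m
    Dm <- naiveCrossDistances(x, y, m, n)
    Dm1 <- naiveCrossDistances(x, y, m + 1, n)
    Bi_m <- vapply(seq_len(n), function(i) mean(r - Dm[i, ] >= 0), 0)
    Bi_m1 <- vapply(seq_len(n), function(i) mean(r - Dm1[i, ] >= 0), 0)
    -log(mean(Bi_m1) / mean(Bi_m))
}

naiveXFuzzyEn <- function(x, y, m = 2, r = 0.2) {
    x <- (x - mean(x)) / sd(x)
    y <- (y - mean(y)) / sd(y)
    n <- length(x) - m
    Dm <- naiveCrossDistances(x, y, m, n)
    Dm1 <- naiveCrossDistances(x, y, m + 1, n)
    -log(mean(exp(-log(2) * (Dm1 / r)^2)) / mean(exp(-log(2) * (Dm / r)^2)))
}

# single-series distribution entropy of a normalized distance matrix:
# the value JDistEn must reduce to when the two series are identical
naiveDistributionEntropy <- function(u, m = 2, tau = 3) {
    u <- (u - mean(u)) / sd(u)
    n <- length(u) - m * tau
    emb <- sapply(0:(m - 1), function(k) u[(1:n) + k * tau])
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        D[i, j] <- max(abs(emb[i, ] - emb[j, ]))
    d <- D[upper.tri(D)] / max(D[upper.tri(D)])
    B <- doaneBins(d)
    if (B <= 1) return(0)
    p <- tabulate(pmin(pmax(ceiling(d * B), 1), B), nbins = B) / length(d)
    p <- p[p > 0]
    -sum(p * log2(p)) / log2(B)
}

# textbook Doane computation written out step by step
naiveDoane <- function(v) {
    n <- length(v)
    s <- sum((v - mean(v))^3) / n / (sum((v - mean(v))^2) / n)^(3 / 2)
    sigma <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
    round(1 + log(n, 2) + log(1 + abs(s) / sigma, 2))
}

# one clean valid synthetic subject for structural tests
testSubject <- function(seed = 101, group = "CPNCA", nBeats = 300) {
    cfg <- syntheticCohortConfig(
        nPerGroup = c(severe = 2, `mild-moderate` = 2, CPNCA = 2),
        nBeats = nBeats, seed = 1)
    validateSubject(genIntervalSeries(cfg, group, seed = seed))
}

# small all-group config used across tests
smallConfig <- function(n = 3, seed = 1, ...) {
    syntheticCohortConfig(
        nPerGroup = c(severe = n, `mild-moderate` = n, CPNCA = n),
        seed = seed, ...)
}
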