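## Cross-entropy coupling measures on z-normalized series pairs.
##
## All three measures consume the same z-normalized pair, so the tolerance
## r is in SD units. Template conventions: although embedded vectors exist
## for i = 1..N-m+1, matching probabilities average over the first N-m
## templates at BOTH lengths m and m+1 (the standard sample-entropy
## convention that keeps B^m and B^(m+1) comparable).

#' Parameters for the entropy-family measures
#'
#' @param m embedding dimension (default 2).
#' @param r tolerance in SD units (default 0.2).
#' @param tau embedding delay in beats (1 for XSampEn/XFuzzyEn; 3 for
#'   JDistEn).
#' @return A validated list of class `entropyParams`.
#' @export
entropyParams <- function(m = 2L, r = 0.2, tau = 1L) {
    stopifnot(m >= 1, r > 0, tau >= 1)
    structure(list(m = as.integer(m), r = r, tau = as.integer(tau)),
              class = "entropyParams")
}

## Chebyshev cross-distance matrix between length-m templates of x and y,
## using the first n starting indices of each series.
chebyshevCrossDist <- function(x, y, m, n) {
    D <- abs(outer(x[seq_len(n)], y[seq_len(n)], "-"))
    if (m > 1L)
        for (k in seq_len(m - 1L))
            D <- pmax(D, abs(outer(x[seq_len(n) + k], y[seq_len(n) + k], "-")))
    D
}

undefinedEntropy <- function(msg) {
    stop(structure(class = c("undefinedEntropyError", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

#' Cross sample entropy (XSampEn)
#'
#' Embeds both z-normalized series at lengths m and m+1, counts
#' cross-template matches under the Chebyshev (maximum-norm) distance and
#' hard threshold r (a match is d <= r), and returns
#' `-ln(B^(m+1) / B^m)` where `B^m` is the mean match indicator over the
#' (N-m)^2 template pairs.
#'
#' @param pair a [SeriesPair-class], or a numeric vector (then `y` must be
#'   supplied; both are z-normalized internally if `normalize = TRUE`).
#' @param params [entropyParams()] (tau is ignored; delay is 1).
#' @param y optional second series when `pair` is a vector.
#' @param normalize z-normalize raw vectors first (default TRUE; a
#'   `SeriesPair` is already normalized).
#' @return The XSampEn value. If no template pair matches at either length
#'   the entropy is undefined and an error of class
#'   `undefinedEntropyError` is raised (never a silent infinity).
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- rnorm(200)
#' xSampEn(x, y = y)
#' @export
xSampEn <- function(pair, params = entropyParams(), y = NULL,
                    normalize = TRUE) {
    xy <- resolvePair(pair, y, normalize)
    m <- params$m; r <- params$r
    N <- length(xy$x)
    if (N <= m + 1L) stop("series too short: need N > m + 1")
    n <- N - m
    Dm <- chebyshevCrossDist(xy$x, xy$y, m, n)
    Dm1 <- chebyshevCrossDist(xy$x, xy$y, m + 1L, n)
    Bm <- mean(Dm <= r)
    Bm1 <- mean(Dm1 <= r)
    if (Bm == 0 || Bm1 == 0)
        undefinedEntropy("no template matches within tolerance r: XSampEn undefined")
    -log(Bm1 / Bm)
}

#' Cross fuzzy entropy (XFuzzyEn)
#'
#' As [xSampEn()] but the hard Heaviside threshold is replaced by the
#' Gaussian fuzzy membership `A(d) = exp(-ln(2) * (d / r)^2)`, which equals
#' 1/2 exactly at d = r and is strictly positive for finite data, so the
#' match probabilities never vanish.
#'
#' @inheritParams xSampEn
#' @return The XFuzzyEn value.
#' @export
xFuzzyEn <- function(pair, params = entropyParams(), y = NULL,
                     normalize = TRUE) {
    xy <- resolvePair(pair, y, normalize)
    m <- params$m; r <- params$r
    N <- length(xy$x)
    if (N <= m + 1L) stop("series too short: need N > m + 1")
    n <- N - m
    Dm <- chebyshevCrossDist(xy$x, xy$y, m, n)
    Dm1 <- chebyshevCrossDist(xy$x, xy$y, m + 1L, n)
    Bm <- mean(fuzzyMembership(Dm, r))
    Bm1 <- mean(fuzzyMembership(Dm1, r))
    -log(Bm1 / Bm)
}

#' Gaussian fuzzy membership function
#'
#' `A(d) = exp(-ln(2) * (d / r)^2)`; `A(r) = 0.5` exactly.
#' @param d distances.
#' @param r tolerance.
#' @return Membership values in (0, 1].
#' @export
fuzzyMembership <- function(d, r) exp(-log(2) * (d / r)^2)

resolvePair <- function(pair, y, normalize) {
    if (is(pair, "SeriesPair")) return(list(x = pair@x, y = pair@y))
    if (is.null(y)) stop("supply a SeriesPair or both x and y vectors")
    if (normalize) list(x = zNormalize(pair), y = zNormalize(y))
    else list(x = pair, y = y)
}

#' Doane's histogram bin-count rule
#'
#' `B = round(1 + log2(n) + log2(1 + |g1| / sigma_g1))` with `g1` the
#' sample skewness (`m3 / m2^(3/2)`) and
#' `sigma_g1 = sqrt(6 (n-2) / ((n+1)(n+3)))`; at least one bin.
#'
#' @param values numeric vector, length >= 3.
#' @return Integer bin count B >= 1.
#' @examples
#' doaneBins(c(seq_len(512), -seq_len(512)))  # symmetric, n = 1024 -> 11
#' @export
doaneBins <- function(values) {
    n <- length(values)
    if (n < 3L) stop("Doane's rule needs at least 3 values")
    mu <- mean(values)
    m2 <- mean((values - mu)^2)
    if (m2 == 0) return(1L)
    g1 <- mean((values - mu)^3) / m2^1.5
    sg <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
    max(1L, as.integer(round(1 + log2(n) + log2(1 + abs(g1) / sg))))
}

## Chebyshev self-distance matrix of the (m, tau) embedding of u, using
## the first n starting indices.
embeddedSelfDist <- function(u, m, tau, n) {
    idx <- seq_len(n)
    D <- matrix(0, n, n)
    for (k in 0:(m - 1L)) {
        v <- u[idx + k * tau]
        D <- pmax(D, abs(outer(v, v, "-")))
    }
    D
}

#' Normalized distribution entropy of a distance-value sample
#'
#' Histogram over the fixed support [0, 1] with B = Doane bins; returns
#' `-(1 / log2 B) * sum p_t log2 p_t`, in [0, 1]. Empty bins contribute 0.
#' @param d values in [0, 1].
#' @return Normalized Shannon entropy.
#' @keywords internal
distributionEntropy01 <- function(d) {
    B <- doaneBins(d)
    if (B <= 1L) return(0)
    bins <- pmin(pmax(ceiling(d * B), 1L), B)
    p <- tabulate(bins, nbins = B) / length(d)
    p <- p[p > 0]
    -sum(p * log2(p)) / log2(B)
}

#' Joint distribution entropy (JDistEn)
#'
#' Embeds each z-normalized series with (m, tau) -- N - m*tau embedded
#' vectors per series -- and builds the per-series Chebyshev distance
#' matrices D1, D2, each rescaled to [0, 1] by its own maximum
#' off-diagonal entry. The joint distance matrix is the element-wise
#' `JD = J - sqrt((J - D1) * (J - D2))` (J the all-ones matrix); with
#' `sqrtForm = FALSE` the plain product `JD = J - (J - D1)(J - D2)` is used
#' instead. The value is the Doane-binned distribution entropy of JD's
#' off-diagonal upper-triangle entries, normalized by log2(B), hence in
#' [0, 1]. Identical series give D1 = D2 = D and JD = D, reducing JDistEn
#' to the single-series distribution entropy of D. A fully degenerate
#' distance matrix (all distances 0) returns 0.
#'
#' @inheritParams xSampEn
#' @param params [entropyParams()]; defaults for JDistEn are m = 2,
#'   tau = 3.
#' @param sqrtForm use the element-wise geometric-mean combination
#'   (default TRUE).
#' @return JDistEn in [0, 1].
#' @export
jDistEn <- function(pair, params = entropyParams(m = 2L, tau = 3L), y = NULL,
                    normalize = TRUE, sqrtForm = TRUE) {
    xy <- resolvePair(pair, y, normalize)
    m <- params$m; tau <- params$tau
    N <- length(xy$x)
    n <- N - m * tau
    if (n < 2L) stop("series too short for (m, tau) embedding")
    D1 <- embeddedSelfDist(xy$x, m, tau, n)
    D2 <- embeddedSelfDist(xy$y, m, tau, n)
    off <- upper.tri(D1)
    m1 <- max(D1[off]); m2 <- max(D2[off])
    if (m1 == 0 || m2 == 0) return(0)
    D1 <- D1 / m1; D2 <- D2 / m2
    jd <- if (sqrtForm) 1 - sqrt((1 - D1[off]) * (1 - D2[off]))
          else 1 - (1 - D1[off]) * (1 - D2[off])
    distributionEntropy01(jd)
}
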