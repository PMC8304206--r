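## Frequency-domain coupling measures on beat-indexed series.
##
## Interval series are treated as evenly sampled in the beat domain, so
## frequencies are in cycles/beat on (0, 0.5]. Spectra are Welch-style
## segment-averaged periodograms; with a single segment the magnitude-
## squared coherence is identically 1 (degenerate), so at least two
## averaging segments are required.

#' Parameters for the spectral coupling measures
#'
#' @param segLength segment length in beats (default 128; when estimating
#'   it is capped so that at least two overlapping segments fit the
#'   series, i.e. `segLength * (2 - overlap) <= N`).
#' @param overlap overlap fraction in [0, 1) (default 0.5).
#' @param taper window name: `"hamming"`, `"hann"` or `"boxcar"`.
#' @return A validated list of class `spectralParams`.
#' @export
spectralParams <- function(segLength = 128L, overlap = 0.5,
                           taper = c("hamming", "hann", "boxcar")) {
    stopifnot(segLength >= 8, overlap >= 0, overlap < 1)
    taper <- match.arg(taper)
    structure(list(segLength = as.integer(segLength), overlap = overlap,
                   taper = taper), class = "spectralParams")
}

taperWindow <- function(name, n) {
    k <- seq_len(n) - 1L
    switch(name,
        hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
        hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
        boxcar = rep(1, n),
        stop("unknown taper: ", name))
}

#' Welch-averaged auto- and cross-spectra of a series pair
#'
#' Splits both series into overlapping demeaned, tapered segments,
#' averages the per-segment auto- and cross-periodograms, and returns the
#' spectra on the beat-frequency grid k/segLength, k = 1..segLength/2
#' (DC excluded).
#'
#' @param x,y equal-length numeric vectors.
#' @param params a [spectralParams()].
#' @return List with `freq` (cycles/beat), `Pxx`, `Pyy` (real), `Pxy`
#'   (complex), and `nSegments`.
#' @export
welchCrossSpectra <- function(x, y, params = spectralParams()) {
    stopifnot(length(x) == length(y))
    N <- length(x)
    ## cap the segment length so at least two overlapping segments fit:
    ## seg * (2 - overlap) <= N
    seg <- min(params$segLength, as.integer(floor(N / (2 - params$overlap))))
    if (seg < 8L)
        stop("fewer than 2 averaging segments: coherence would be degenerate")
    step <- max(1L, as.integer(floor(seg * (1 - params$overlap))))
    starts <- seq(1L, N - seg + 1L, by = step)
    L <- length(starts)
    w <- taperWindow(params$taper, seg)
    U <- sum(w^2)
    half <- seg %/% 2L
    keep <- 2L:(half + 1L)            # exclude DC; keep up to Nyquist
    Pxx <- Pyy <- numeric(half)
    Pxy <- complex(half)
    for (s0 in starts) {
        xs <- x[s0:(s0 + seg - 1L)]; ys <- y[s0:(s0 + seg - 1L)]
        X <- fft(w * (xs - mean(xs)))[keep]
        Y <- fft(w * (ys - mean(ys)))[keep]
        Pxx <- Pxx + Re(X * Conj(X)) / U
        Pyy <- Pyy + Re(Y * Conj(Y)) / U
        Pxy <- Pxy + X * Conj(Y) / U
    }
    list(freq = (seq_len(half)) / seg, Pxx = Pxx / L, Pyy = Pyy / L,
         Pxy = Pxy / L, nSegments = L)
}

#' Magnitude-squared coherence (MSCF)
#'
#' `C(f) = |Pxy(f)|^2 / (Pxx(f) Pyy(f))` on the beat-frequency grid, with
#' Welch-averaged spectra; by Cauchy-Schwarz C is in [0, 1] (tiny
#' floating-point overshoot is clamped). The summary statistics are the
#' mean and SD of the coherence over the grid (DC excluded by
#' construction).
#'
#' @param pair a [SeriesPair-class] or numeric vector (with `y`).
#' @param params a [spectralParams()].
#' @param y second series when `pair` is a vector.
#' @return List with `freq`, `coherence`, `mean`, `sd`, `nSegments`.
#' @examples
#' set.seed(1)
#' x <- rnorm(256)
#' mscf(x, y = x)$mean  # identically 1
#' @export
mscf <- function(pair, params = spectralParams(), y = NULL) {
    xy <- resolvePair(pair, y, normalize = FALSE)
    sp <- welchCrossSpectra(xy$x, xy$y, params)
    C <- Mod(sp$Pxy)^2 / (sp$Pxx * sp$Pyy)
    C <- pmin(pmax(C, 0), 1)
    list(freq = sp$freq, coherence = C, mean = mean(C), sd = sd(C),
         nSegments = sp$nSegments)
}

#' Imaginary cross power spectral density (ICPSD)
#'
#' `ICPSD(f) = |Im(Sxy(f))| = Ax Ay |sin(delta-phi)|`: the phase-lagged
#' covariation between the two series, insensitive to zero-lag (in-phase
#' or anti-phase) coupling. Summary statistics are the mean and SD over
#' the beat-frequency grid.
#'
#' @inheritParams mscf
#' @return List with `freq`, `icpsd`, `mean`, `sd`, `nSegments`.
#' @export
icpsd <- function(pair, params = spectralParams(), y = NULL) {
    xy <- resolvePair(pair, y, normalize = FALSE)
    sp <- welchCrossSpectra(xy$x, xy$y, params)
    v <- abs(Im(sp$Pxy))
    list(freq = sp$freq, icpsd = v, mean = mean(v), sd = sd(v),
         nSegments = sp$nSegments)
}
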