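#' Wavelet transform parameters
#'
#' The decomposition depth sets the neighbor scale: with `nLevels = J - M`
#' levels, the high-frequency signal measures differences from neighbors
#' up to `2^nLevels` bins.  At 100 bp bins the defaults (`J = 25`,
#' `M = 10`, i.e. 15 levels, about 3 MB) target focal alterations; `C`
#' scales the universal hard threshold and defaults to 2.0.
#'
#' Either give `J` and `M` (genome-scale convention) or `nLevels`
#' directly; for signals shorter than `2^J`, `J` is derived from the
#' extended signal length and only the depth matters.
#'
#' @param J signal-length exponent (optional).
#' @param M coarsest retained level (optional).
#' @param C threshold multiplier, `>= 0`.
#' @param nLevels decomposition depth; default `J - M` when both given,
#'   otherwise 15.
#' @return A [WaveletParams-class].
#' @examples
#' waveletParams(J = 25, M = 10)        # 15 levels, ~3 MB neighbor scale
#' waveletParams(nLevels = 15, C = 1.5)
#' @export
waveletParams <- function(J = NA, M = NA, C = 2.0, nLevels = NA) {
    J <- as.integer(J); M <- as.integer(M); nLevels <- as.integer(nLevels)
    if (!is.na(J) && !is.na(M)) {
        if (!is.na(nLevels) && nLevels != J - M)
            stop("nLevels inconsistent with J - M")
        nLevels <- J - M
    } else if (is.na(nLevels)) {
        nLevels <- 15L
    }
    # assign C by slot: a named `C` argument to new() would partially
    # match its `Class` parameter
    p <- new("WaveletParams", J = J, M = M, nLevels = nLevels)
    p@C <- C
    validObject(p)
    p
}

setMethod("show", "WaveletParams", function(object) {
    cat("WaveletParams: nLevels =", object@nLevels,
        if (!is.na(object@J)) paste0("(J = ", object@J, ", M = ", object@M, ")"),
        ", C =", object@C, "\n")
})

#' Decomposition depth for a neighbor scale, and the coarsest level
#'
#' `levelsForScale()` gives the number of Haar levels needed so the
#' high-frequency signal spans neighbor differences up to `neighborBins`
#' bins (e.g. 30,000 bins = 3 MB at 100 bp needs 15 levels);
#' `coarsestLevel()` subtracts it from the signal-length exponent `J`
#' (J = 25 and a 3 MB scale give M = 10).
#'
#' @param neighborBins neighbor scale in bins.
#' @param J signal-length exponent.
#' @return integer.
#' @examples
#' levelsForScale(30000)    # 15
#' coarsestLevel(25, 30000) # 10
#' @export
levelsForScale <- function(neighborBins) as.integer(ceiling(log2(neighborBins)))

#' @rdname levelsForScale
#' @export
coarsestLevel <- function(J, neighborBins) as.integer(J) - levelsForScale(neighborBins)

#' Symmetric extension to a power-of-two length
#'
#' Mirror-reflected copies of the signal are concatenated until the target
#' length is reached, which avoids boundary artifacts of the circular
#' transform.  The original occupies positions `1..length(x)`, so cropping
#' after reconstruction is exact.
#'
#' @param x numeric signal.
#' @param targetLength power of two `>= length(x)`; default: the next
#'   power of two.
#' @return numeric of length `targetLength`, original values first.
#' @examples
#' symmetricExtend(c(1, 2, 3), 8)  # 1 2 3 3 2 1 1 2
#' @export
symmetricExtend <- function(x, targetLength = NULL) {
    n <- length(x)
    if (is.null(targetLength)) targetLength <- 2^ceiling(log2(max(n, 2)))
    if (targetLength < n) stop("targetLength must be >= length(x)")
    if (abs(log2(targetLength) - round(log2(targetLength))) > 1e-9)
        stop("targetLength must be a power of two")
    if (targetLength == n) return(x)
    period <- c(x, rev(x))
    rep_len(period, targetLength)
}

#' Stationary Haar wavelet decomposition
#'
#' Undecimated (a-trous) Haar analysis of a circular signal whose length
#' is a power of two.  At step `t` with dilation `h = 2^(t-1)`:
#' `s_t[i] = (s_{t-1}[i] + s_{t-1}[i+h]) / 2` (scaling, the neighbor
#' average) and `w_t[i] = (s_{t-1}[i] - s_{t-1}[i+h]) / 2` (detail, the
#' neighbor half-difference), indices circular.  Every level keeps one
#' coefficient per position, so the transform is shift-covariant.
#'
#' @param x numeric signal, length a power of two `>= 2^nLevels`.
#' @param nLevels number of decomposition steps.
#' @return list with `scaling` (coarsest `s`), `detail` (list of `w` per
#'   level, finest first), and `n` (signal length).
#' @export
haarSWT <- function(x, nLevels) {
    n <- length(x)
    if (n < 2 || bitwAnd(n, n - 1L) != 0)
        stop("signal length must be a power of two")
    if (nLevels < 1 || 2^nLevels > n)
        stop("too many levels for this signal length")
    s <- x
    detail <- vector("list", nLevels)
    for (t in seq_len(nLevels)) {
        h <- 2^(t - 1)
        idx <- c((h + 1):n, 1:h)       # circular left shift by h
        s2 <- s[idx]
        detail[[t]] <- (s - s2) / 2
        s <- (s + s2) / 2
    }
    list(scaling = s, detail = detail, n = n)
}

#' Inverse stationary Haar transform
#'
#' Shift-corrected (branch-averaged) a-trous synthesis: at each level both
#' reconstruction branches — `s + w` and the `h`-shifted `s - w` — are
#' averaged.  With unmodified coefficients this reproduces the input to
#' machine precision.
#'
#' @param coeffs list as returned by [haarSWT()] (`scaling`, `detail`).
#' @return numeric signal of the original length.
#' @export
inverseHaarSWT <- function(coeffs) {
    n <- coeffs$n
    s <- coeffs$scaling
    for (t in rev(seq_along(coeffs$detail))) {
        h <- 2^(t - 1)
        w <- coeffs$detail[[t]]
        a <- s + w
        b <- s - w
        idx <- c((n - h + 1):n, 1:(n - h))  # circular right shift by h
        s <- (a + b[idx]) / 2
    }
    s
}

#' Level-wise universal hard threshold
#'
#' `lambda_j = C * sigma_j * sqrt(2 log n_j)` with the robust noise scale
#' `sigma_j = median(|w_j|) / 0.6745` and `n_j` the number of coefficients
#' in the level (constant across levels for the stationary transform).
#' An all-zero level yields `lambda_j = 0`.
#'
#' @param w numeric detail coefficients of one level.
#' @param C threshold multiplier (`lambda` is exactly linear in `C`).
#' @return numeric scalar `lambda_j`.
#' @export
levelThreshold <- function(w, C) {
    stopifnot(length(w) >= 1)
    sigma <- stats::median(abs(w)) / 0.6745
    C * sigma * sqrt(2 * log(length(w)))
}

#' Hard thresholding
#'
#' Coefficients with `|w| <= lambda` are set to zero (non-strict, so
#' `lambda = 0` only removes exact zeros); others pass unchanged.
#'
#' @param w numeric coefficients.
#' @param lambda threshold `>= 0`.
#' @return numeric, same length.
#' @export
hardThreshold <- function(w, lambda) {
    stopifnot(lambda >= 0)
    ifelse(abs(w) <= lambda, 0, w)
}

#' High-frequency reconstruction from thresholded details
#'
#' The inverse stationary transform is applied with all coarsest-level
#' scaling coefficients set to zero and the (thresholded) details
#' retained, then cropped to the original signal range.  The result,
#' `y_HIGH`, measures a position's difference from its neighborhood up to
#' `2^nLevels` positions; a step edge produces paired opposite-signed
#' lobes flanking it.
#'
#' @param coeffs list from [haarSWT()] whose `detail` has been
#'   thresholded; `originalLength` positions are kept from the front.
#' @param originalLength length to crop to (default: full length).
#' @return numeric `y_HIGH`.
#' @export
reconstructYHigh <- function(coeffs, originalLength = coeffs$n) {
    coeffs$scaling <- numeric(coeffs$n)
    inverseHaarSWT(coeffs)[seq_len(originalLength)]
}

#' Sign-consistency filter
#'
#' The high-frequency reconstruction places opposite-signed regions next
#' to a true change.  Each maximal same-sign region of `yHigh` is
#' compared with the log2 ratio over that region (the sign of its sum):
#' regions whose sign disagrees — the transform artifacts — are set to
#' zero whole; agreeing regions pass unchanged.  A length-one region
#' reduces to the pointwise rule.
#'
#' @param yHigh numeric high-frequency signal.
#' @param log2Ratio numeric log2-ratio values, same length.
#' @return numeric filtered signal.
#' @export
signFilter <- function(yHigh, log2Ratio) {
    stopifnot(length(yHigh) == length(log2Ratio))
    r <- rle(sign(yHigh))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cs <- cumsum(log2Ratio)
    regionSum <- cs[ends] - cs[starts] + log2Ratio[starts]
    drop <- r$values == 0 | sign(regionSum) != r$values
    out <- yHigh
    if (any(drop))
        out[sequence(r$lengths[drop], from = starts[drop])] <- 0
    out
}

# resolve the decomposition depth against an extended signal length
resolveLevels <- function(params, extLength) {
    nl <- params@nLevels
    if (2^nl > extLength)
        stop("decomposition depth ", nl,
             " too large for extended signal length ", extLength)
    nl
}

#' Per-patient high-frequency CNA signal
#'
#' Orchestrates the single-patient transform: concatenate the unmasked
#' bins, extend symmetrically to a power of two, decompose with the
#' stationary Haar transform, hard-threshold every level at its universal
#' threshold, reconstruct the high-frequency signal, crop, and apply the
#' sign filter against the log2 ratio.  Invalid bins enter the transform
#' as zeros and can never pass the sign filter.
#'
#' @param track a [CopyRatioTrack-class].
#' @param layout the [GenomeLayout-class] (masks final for this pass).
#' @param params a [WaveletParams-class].
#' @param engine `"cpp"` (fast path) or `"r"` (reference implementation);
#'   both produce identical signals.
#' @return A [HighFreqSignal-class] in concatenated coordinates.
#' @export
computeSampleSignal <- function(track, layout = track@layout,
                                params = waveletParams(),
                                engine = c("cpp", "r")) {
    engine <- match.arg(engine)
    ms <- concatenateUnmasked(track, layout)
    x <- ms@values
    ext <- symmetricExtend(x)
    nLevels <- resolveLevels(params, length(ext))
    if (engine == "cpp") {
        yh <- cpp_swt_yhigh(ext, nLevels, params@C)[seq_along(x)]
    } else {
        co <- haarSWT(ext, nLevels)
        co$detail <- lapply(co$detail, function(w)
            hardThreshold(w, levelThreshold(w, params@C)))
        yh <- reconstructYHigh(co, length(x))
        # same numerical zero-snap as the fast path
        if (any(yh != 0))
            yh[abs(yh) < 1e-9 * max(abs(yh))] <- 0
    }
    new("HighFreqSignal", sampleId = track@sampleId,
        values = signFilter(yh, x), yHigh = yh, ratio = x,
        origin = ms@origin, junctions = ms@junctions, layout = layout,
        params = params)
}

#' @describeIn computeSampleSignal Sign-filtered high-frequency values.
#' @param x a `HighFreqSignal` (or any `MaskedSignal`).
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname computeSampleSignal
#' @export
setMethod("signalValues", "MaskedSignal", function(x) x@values)

#' @rdname computeSampleSignal
#' @export
setMethod("sampleId", "HighFreqSignal", function(x) x@sampleId)

setMethod("show", "HighFreqSignal", function(object) {
    cat("HighFreqSignal '", object@sampleId, "': ",
        format(length(object@values), big.mark = ","), " positions, ",
        sum(object@values != 0), " nonzero after sign filter\n", sep = "")
})
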