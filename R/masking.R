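#' Concatenate a track over its unmasked bins
#'
#' Bins overlapping reference N gaps or the low-mapping mask are excluded;
#' the remaining bins are concatenated genome-wide so the wavelet
#' transform never sees the gaps.  Values are copied exactly (no
#' interpolation); invalid bins contribute 0.  Junction indices record
#' where adjacent concatenated positions are not genomically adjacent.
#'
#' @param track a [CopyRatioTrack-class] (or a [BinnedCoverage-class],
#'   whose counts are concatenated unchanged).
#' @param layout the [GenomeLayout-class] whose masks to apply (defaults
#'   to the track's own).
#' @return A [MaskedSignal-class].
#' @export
concatenateUnmasked <- function(track, layout = track@layout) {
    keep <- !maskedBins(layout)
    if (!any(keep)) stop("all bins are masked")
    if (is(track, "CopyRatioTrack")) {
        v <- track@log2Ratio
        v[!track@valid] <- 0
    } else if (is(track, "BinnedCoverage")) {
        v <- track@counts
    } else stop("unsupported track class: ", class(track))
    origin <- which(keep)
    vals <- v[origin]
    ch <- chromOfBin(layout, origin)
    jump <- which(diff(origin) != 1L | diff(ch) != 0L) + 1L
    new("MaskedSignal", values = vals, origin = as.integer(origin),
        junctions = as.integer(jump), layout = layout)
}

#' Map concatenated positions back to genomic intervals
#'
#' @param signal a [MaskedSignal-class].
#' @param from,to concatenated positions (1-based, inclusive).
#' @return data.frame with `chrom`, `start`, `end` of the genomic span
#'   from the first to the last underlying bin (1-based inclusive bp).
#' @export
concatenatedSpan <- function(signal, from, to) {
    stopifnot(length(from) == length(to), all(from <= to))
    layout <- signal@layout
    a <- binToGenome(layout, signal@origin[from])
    b <- binToGenome(layout, signal@origin[to])
    if (any(a$chrom != b$chrom))
        stop("span crosses a chromosome boundary")
    data.frame(chrom = a$chrom, start = a$start, end = b$end)
}

#' Detect low-mapping segments from a normal sample
#'
#' Sparse-mapping stretches of the reference produce artifactual copy
#' number signal.  The normal-sample count track is put through the same
#' high-frequency wavelet procedure as the main analysis; maximal runs of
#' nonzero thresholded signal delimit candidate segments.  For each
#' segment, the mean number of normal reads per bp is computed; this
#' feature is usually bimodal (sparse-mapping segments vs. segments of
#' ordinary depth), so 1-D `k`(=2)-means — initialized at the feature
#' minimum and maximum for determinism — separates them.  Segments in the
#' lower-mean class at least `minLen` bp long are returned.
#'
#' @param normal a [BinnedCoverage-class] normal track.
#' @param layout the [GenomeLayout-class] (N-gap mask applied).
#' @param params [WaveletParams-class]; the main-analysis parameters
#'   unless overridden.
#' @param k number of clusters (2).
#' @param minLen minimum segment length in bp to remove (default 3000).
#' @return `GRanges` of segments to mask (possibly empty).
#' @export
detectLowMappingSegments <- function(normal, layout = normal@layout,
                                     params = waveletParams(), k = 2,
                                     minLen = 3000) {
    ms <- concatenateUnmasked(normal, layout)
    ext <- symmetricExtend(ms@values)
    nLevels <- resolveLevels(params, length(ext))
    yh <- cpp_swt_yhigh(ext, nLevels, params@C)[seq_along(ms@values)]
    nz <- rle(yh != 0)
    ends <- cumsum(nz$lengths)
    starts <- ends - nz$lengths + 1L
    segs <- data.frame(start = starts[nz$values], end = ends[nz$values])
    if (nrow(segs) == 0L) return(GenomicRanges::GRanges())
    # genomic span + mean normal reads per bp of each segment
    spans <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
        s <- segs$start[i]; e <- segs$end[i]
        ch <- chromOfBin(ms@layout, ms@origin[c(s, e)])
        if (ch[1] != ch[2]) {       # split at the chromosome boundary
            br <- which(chromOfBin(ms@layout, ms@origin[s:e]) != ch[1])[1]
            return(rbind(
                data.frame(start = s, end = s + br - 2L),
                data.frame(start = s + br - 1L, end = e)))
        }
        data.frame(start = s, end = e)
    }))
    gspan <- concatenatedSpan(ms, spans$start, spans$end)
    reads <- vapply(seq_len(nrow(spans)), function(i)
        sum(ms@values[spans$start[i]:spans$end[i]]), numeric(1))
    feature <- reads / (gspan$end - gspan$start + 1)
    if (length(unique(feature)) < k) {
        warning("no bimodal separation of segment read densities; ",
                "no low-mapping segments removed")
        return(GenomicRanges::GRanges())
    }
    ctr <- c(min(feature), max(feature))
    if (length(feature) == k) {
        # n == k: nearest-center assignment is the exact solution
        assign <- vapply(feature, function(f)
            which.min(abs(f - ctr)), integer(1))
        centers <- vapply(seq_len(k), function(c)
            mean(feature[assign == c]), numeric(1))
    } else {
        km <- stats::kmeans(feature, centers = matrix(ctr))
        assign <- km$cluster
        centers <- km$centers
    }
    low <- which.min(centers)
    sel <- assign == low &
           (gspan$end - gspan$start + 1) >= minLen
    if (!any(sel)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(gspan$chrom[sel],
                           IRanges::IRanges(gspan$start[sel],
                                            gspan$end[sel]))
}

#' Two-pass masking of a single patient
#'
#' Pass 1 detects low-mapping segments on the normal track; the layout
#' mask is extended (masking is monotone — no bin is ever unmasked) and
#' the cleaned signal is re-concatenated for pass 2, after which the
#' caller re-runs the wavelet transform.
#'
#' @param track a [CopyRatioTrack-class].
#' @param normal the matched [BinnedCoverage-class] normal track.
#' @param layout the starting [GenomeLayout-class].
#' @param params [WaveletParams-class] for the detection pass.
#' @param minLen minimum segment length in bp (default 3000).
#' @return list with `layout` (mask updated), `signal` (pass-2
#'   [MaskedSignal-class]), and `segments` (the `GRanges` removed).
#' @export
twoPassMask <- function(track, normal, layout = track@layout,
                        params = waveletParams(), minLen = 3000) {
    segs <- detectLowMappingSegments(normal, layout, params,
                                     minLen = minLen)
    layout2 <- addLowMapMask(layout, segs)
    list(layout = layout2,
         signal = concatenateUnmasked(track, layout2),
         segments = segs)
}

setMethod("show", "MaskedSignal", function(object) {
    cat("MaskedSignal:", format(length(object@values), big.mark = ","),
        "positions,", length(object@junctions), "junctions\n")
})
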