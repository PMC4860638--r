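#' Run the full recurrent-focal-CNA pipeline on a cohort
#'
#' Per patient: chromosome-normalized log2 ratio, then (optionally) the
#' low-mapping detection pass on the normal track; detected segments from
#' all patients are unioned into the layout mask before the second,
#' definitive wavelet pass.  The sign-filtered high-frequency signals are
#' summed, partitioned into clusters with distances `d` and `r`, and
#' assessed against the permutation null with all five FDC schemes.
#'
#' @param patients list of per-patient lists with `tumor` and `normal`
#'   [BinnedCoverage-class] tracks (as produced by [simulateCohort()]).
#' @param layout the [GenomeLayout-class].
#' @param params a [WaveletParams-class].
#' @param d,r grouping distances in bp (defaults 3e5).
#' @param B permutations for the null (default 1000; set 0 to skip).
#' @param seed RNG seed for the null.
#' @param maskLowMapping run the two-pass low-mapping masking (default
#'   TRUE).
#' @param minMaskLen minimum low-mapping segment length in bp (3000).
#' @return list with `clusters` (`GRanges` with `p.FDC1`..`p.FDC5`
#'   columns, sorted by |score|), `sum` ([SumSignal-class]), `signals`,
#'   `null` ([NullDistribution-class] or NULL), `layout` (mask updated),
#'   and `lowMapSegments`.
#' @export
runCohortPipeline <- function(patients, layout, params = waveletParams(),
                              d = 3e5, r = 3e5, B = 1000L, seed = 1L,
                              maskLowMapping = TRUE, minMaskLen = 3000) {
    tracks <- lapply(patients, function(p)
        computeLog2Ratio(p$tumor, p$normal))
    segs <- GenomicRanges::GRanges()
    if (maskLowMapping) {
        detected <- lapply(patients, function(p)
            detectLowMappingSegments(p$normal, layout, params,
                                     minLen = minMaskLen))
        segs <- normalizeMask(do.call(c, detected))
        layout <- addLowMapMask(layout, segs)
    }
    signals <- lapply(tracks, computeSampleSignal, layout = layout,
                      params = params)
    total <- sumSamples(signals)
    clusters <- groupAndCluster(total, d = d, r = r)
    null <- NULL
    if (B > 0 && length(clusters)) {
        null <- buildNull(signals, d = d, r = r, B = B, seed = seed)
        for (m in 1:5)
            S4Vectors::mcols(clusters)[[paste0("p.FDC", m)]] <-
                suppressWarnings(fdcPvalue(clusters, null, m))
    }
    list(clusters = clusters, sum = total, signals = signals,
         null = null, layout = layout, lowMapSegments = segs)
}
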