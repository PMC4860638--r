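#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics counts start end width strand
#' @importFrom GenomeInfoDb seqnames
#' @importFrom stats median rnbinom rlnorm runif setNames quantile lm coef
#' @importFrom stats predict residuals kmeans
#' @importFrom utils read.table write.table head
#' @useDynLib focalWave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' GenomeLayout: bins, masks, and the genome/analysis coordinate bijection
#'
#' A `GenomeLayout` fixes the coordinate system for an analysis: an ordered
#' set of chromosomes, a bin size (default 100 bp), intervals of reference
#' `N` bases (assembly gaps), and intervals flagged as low-mapping by the
#' masking pass.  Bins tile each chromosome left to right; a trailing
#' partial bin is kept.  The layout also defines the bijection between the
#' global bin index and `(chromosome, bin start)` used throughout.
#'
#' @slot chromLengths named numeric, chromosome lengths in bp (order kept).
#' @slot binSize integer bin width in bp.
#' @slot nGaps [GenomicRanges::GRanges] of reference N gaps.
#' @slot lowMapMask [GenomicRanges::GRanges] of low-mapping intervals.
#'
#' @seealso [genomeLayout()], [totalBins()], [maskedBins()]
#' @export
setClass("GenomeLayout",
    representation(chromLengths = "numeric", binSize = "integer",
                   nGaps = "GRanges", lowMapMask = "GRanges"))

setValidity("GenomeLayout", function(object) {
    msg <- character()
    if (is.null(names(object@chromLengths)) ||
        anyDuplicated(names(object@chromLengths)))
        msg <- c(msg, "chromosome lengths must have unique names")
    if (any(object@chromLengths <= 0))
        msg <- c(msg, "every chromosome length must be > 0")
    if (object@binSize < 1L)
        msg <- c(msg, "binSize must be >= 1")
    for (slot in c("nGaps", "lowMapMask")) {
        gr <- slot(object, slot)
        if (length(gr) &&
            !all(as.character(GenomeInfoDb::seqnames(gr)) %in%
                 names(object@chromLengths)))
            msg <- c(msg, paste(slot, "uses unknown chromosome names"))
    }
    if (length(msg)) msg else TRUE
})

#' BinnedCoverage: per-bin read counts for one sample
#'
#' Nonnegative per-bin read counts for a tumor or matched-normal sample,
#' aligned to a [GenomeLayout].
#'
#' @slot sampleId character scalar.
#' @slot role `"tumor"` or `"normal"`.
#' @slot counts numeric vector, one nonnegative count per layout bin.
#' @slot layout the [GenomeLayout] the counts are aligned to.
#' @export
setClass("BinnedCoverage",
    representation(sampleId = "character", role = "character",
                   counts = "numeric", layout = "GenomeLayout"))

setValidity("BinnedCoverage", function(object) {
    msg <- character()
    if (!object@role %in% c("tumor", "normal"))
        msg <- c(msg, "role must be 'tumor' or 'normal'")
    if (length(object@counts) != totalBins(object@layout))
        msg <- c(msg, "counts length must equal the layout's bin count")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' CopyRatioTrack: per-bin log2 tumor/normal copy-ratio signal
#'
#' The observed per-bin signal `y_i`: the log2 ratio of chromosome-
#' normalized tumor depth over normal depth.  Bins where the ratio is
#' undefined (zero tumor or normal count, reference gaps) carry
#' `valid = FALSE` and a placeholder value of 0.
#'
#' @slot sampleId character scalar.
#' @slot log2Ratio numeric per-bin values (0 where invalid).
#' @slot valid logical per-bin mask; ratio finite wherever `TRUE`.
#' @slot layout the [GenomeLayout].
#' @export
setClass("CopyRatioTrack",
    representation(sampleId = "character", log2Ratio = "numeric",
                   valid = "logical", layout = "GenomeLayout"))

setValidity("CopyRatioTrack", function(object) {
    msg <- character()
    if (length(object@log2Ratio) != totalBins(object@layout))
        msg <- c(msg, "log2Ratio length must equal the layout's bin count")
    if (length(object@valid) != length(object@log2Ratio))
        msg <- c(msg, "valid mask length mismatch")
    if (any(!is.finite(object@log2Ratio[object@valid])))
        msg <- c(msg, "log2Ratio must be finite wherever valid")
    if (length(msg)) msg else TRUE
})

#' MaskedSignal: a genome signal concatenated over unmasked bins
#'
#' Values over the unmasked bins only, concatenated in genome order.
#' `origin` maps each concatenated position back to its global bin index in
#' the layout; `junctions` records concatenated positions whose left
#' neighbor is not genomically adjacent (mask joints and chromosome
#' boundaries), so downstream reports can flag clusters spanning a joint.
#'
#' @slot values numeric, the concatenated signal.
#' @slot origin integer, global layout bin index of each position.
#' @slot junctions integer, concatenated indices that start a new block.
#' @slot layout the [GenomeLayout].
#' @export
setClass("MaskedSignal",
    representation(values = "numeric", origin = "integer",
                   junctions = "integer", layout = "GenomeLayout"))

setValidity("MaskedSignal", function(object) {
    msg <- character()
    if (length(object@values) != length(object@origin))
        msg <- c(msg, "values and origin must have equal length")
    if (is.unsorted(object@origin, strictly = TRUE))
        msg <- c(msg, "origin must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' WaveletParams: stationary Haar transform parameters
#'
#' `J` is the signal-length exponent (2^J must cover the concatenated
#' genome; 25 for a 3.2 Gbp genome at 100 bp bins), `M` the coarsest
#' retained level, and `C` the threshold multiplier.  The number of
#' decomposition levels is `J - M`; the transform then measures differences
#' from neighbors up to `2^(J-M)` bins (about 3 MB at the defaults).  When
#' `J`/`M` are not given, `nLevels` is used directly so small genomes keep
#' the same neighbor scale.
#'
#' @slot J integer or NA (derived from the signal when NA).
#' @slot M integer or NA.
#' @slot C numeric threshold multiplier (>= 0).
#' @slot nLevels integer decomposition depth.
#' @export
setClass("WaveletParams",
    representation(J = "integer", M = "integer", C = "numeric",
                   nLevels = "integer"),
    prototype(J = NA_integer_, M = NA_integer_, C = 2.0, nLevels = 15L))

setValidity("WaveletParams", function(object) {
    msg <- character()
    if (object@C < 0) msg <- c(msg, "C must be >= 0")
    if (object@nLevels < 1L) msg <- c(msg, "nLevels must be >= 1")
    if (!is.na(object@J) && !is.na(object@M) && object@J <= object@M)
        msg <- c(msg, "J must exceed M")
    if (length(msg)) msg else TRUE
})

#' HighFreqSignal: one patient's thresholded high-frequency signal
#'
#' Holds both the raw high-frequency reconstruction `yHigh` and the
#' sign-filtered signal (in `values`): positions whose `yHigh` sign
#' disagrees with the local log2 ratio are zeroed, removing the
#' opposite-signed lobes the reconstruction places next to true changes.
#' Coordinates are concatenated (see [MaskedSignal]).
#'
#' @slot sampleId character scalar.
#' @slot yHigh numeric, unfiltered high-frequency reconstruction.
#' @slot ratio numeric, the concatenated log2-ratio signal the sign filter
#'   compared against.
#' @slot params the [WaveletParams] used.
#' @export
setClass("HighFreqSignal", contains = "MaskedSignal",
    representation(sampleId = "character", yHigh = "numeric",
                   ratio = "numeric", params = "WaveletParams"))

#' SumSignal: the cohort recurrence signal
#'
#' Element-wise sum of the patients' sign-filtered high-frequency signals,
#' with the per-position count of patients contributing a nonzero value.
#'
#' @slot support integer per-position patient support.
#' @slot nSamples integer number of summed patients.
#' @export
setClass("SumSignal", contains = "MaskedSignal",
    representation(support = "integer", nSamples = "integer"))

setValidity("SumSignal", function(object) {
    if (any(object@support > object@nSamples))
        "support cannot exceed the number of samples" else TRUE
})

#' NullDistribution: the permutation null for cluster significance
#'
#' Random clusters obtained by independently reallocating every patient's
#' nonzero runs within their chromosome and re-running the aggregation and
#' clustering with the same `d`/`r`.  A pure function of
#' `(signals, d, r, B, seed)`.
#'
#' @slot B integer number of permutations.
#' @slot clusters data.frame with columns `perm`, `score`, `lengthBp`,
#'   `nPatients`, `sign`.
#' @slot d,r numeric grouping distances (bp) the null was built with.
#' @slot seed integer RNG seed.
#' @slot binSize integer bin size of the underlying layout.
#' @export
setClass("NullDistribution",
    representation(B = "integer", clusters = "data.frame", d = "numeric",
                   r = "numeric", seed = "integer", binSize = "integer"))

#' SimulationSpec: a synthetic tumor/normal WGS cohort description
#'
#' Describes a multi-patient cohort of binned tumor/normal read counts with
#' planted copy-number events and the read-depth pathologies of real WGS:
#' reference N gaps, sparse-mapping stretches, and "fractured" excessive
#' read-depth noise.  See [simulationSpec()] for field semantics.
#'
#' @export
setClass("SimulationSpec",
    representation(chromLengths = "numeric", binSize = "integer",
                   nGaps = "GRanges", sparseRegions = "GRanges",
                   events = "data.frame", germlineEvents = "data.frameOrNULL",
                   nPatients = "integer", tumorCoverage = "numeric",
                   normalCoverage = "numeric", dispersion = "numeric",
                   fracturedFraction = "numeric", fractureScaleBp = "numeric",
                   fractureSdLog = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
    if (object@tumorCoverage <= 0 || object@normalCoverage <= 0)
        msg <- c(msg, "coverages must be positive")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be positive")
    if (object@fracturedFraction < 0 || object@fracturedFraction > 1)
        msg <- c(msg, "fracturedFraction must be in [0, 1]")
    ev <- object@events
    if (nrow(ev)) {
        if (!all(ev$chrom %in% names(object@chromLengths)))
            msg <- c(msg, "event on unknown chromosome")
        else {
            len <- object@chromLengths[ev$chrom]
            if (any(ev$start < 1 | ev$end > len | ev$start > ev$end))
                msg <- c(msg, "event interval outside its chromosome")
            w <- ev$end - ev$start + 1
            if (any(ev$kind == "focal" & w > 3e6))
                msg <- c(msg, "focal events must be <= 3 MB")
            if (any(ev$kind == "broad" & w <= 0.25 * len))
                msg <- c(msg, "broad events must exceed 25% of their chromosome")
            bad <- vapply(ev$carriers, function(p)
                any(p < 1 | p > object@nPatients), logical(1))
            if (any(bad)) msg <- c(msg, "event carriers outside 1..nPatients")
        }
    }
    if (length(msg)) msg else TRUE
})
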