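#' Count aligned reads per base from a BAM file
#'
#' Each mapped read increments exactly one position: its leftmost mapped
#' base.  Unmapped, secondary, supplementary, and duplicate-flagged reads
#' are skipped (a tally is reported via `message`).  A simple,
#' deterministic depth-of-coverage proxy.
#'
#' @param bam path to an indexed BAM file.
#' @param layout a [GenomeLayout-class]; its chromosomes must cover every
#'   reference name used by mapped reads.
#' @return named list of per-base numeric count vectors, one per layout
#'   chromosome.
#' @export
countReadsPerBase <- function(bam, layout) {
    cl <- chromLengths(layout)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isDuplicate = FALSE)
    keepParam <- Rsamtools::ScanBamParam(flag = flag,
                                         what = c("rname", "pos"))
    res <- Rsamtools::scanBam(bam, param = keepParam)[[1]]
    allParam <- Rsamtools::ScanBamParam(what = "rname")
    nAll <- length(Rsamtools::scanBam(bam, param = allParam)[[1]]$rname)
    nSkipped <- nAll - length(res$pos)
    if (nSkipped > 0)
        message(nSkipped,
                " unmapped/secondary/supplementary/duplicate reads skipped")
    rn <- as.character(res$rname)
    unknown <- setdiff(unique(rn), names(cl))
    if (length(unknown))
        stop("reference name(s) not in layout: ",
             paste(unknown, collapse = ", "))
    out <- lapply(cl, function(L) numeric(L))
    for (ch in unique(rn)) {
        sel <- rn == ch
        tab <- tabulate(res$pos[sel], nbins = cl[[ch]])
        out[[ch]] <- as.numeric(tab)
    }
    out
}

#' Winsorize read-depth outliers in a sliding window
#'
#' Each position whose count exceeds the empirical `quantile` of its
#' centered `window`-bp neighborhood is capped at that quantile (an order
#' statistic of the window, so the cap is always an observed value).
#' Capping is repeated until a fixed point is reached — capping a spike
#' can lower a neighboring window's quantile, so a single pass is not
#' idempotent, while the fixed point is by construction.  Values are
#' replaced, never removed: track length is preserved and no count
#' increases.
#'
#' @param counts per-base numeric vector, or a named list of them
#'   (one per chromosome).
#' @param window sliding window width in bp (default 200).
#' @param quantile the winsorization quantile (default 0.95).
#' @param maxIter passes allowed to reach the fixed point (typically 2-3
#'   are needed).
#' @return Same shape as `counts`.
#' @examples
#' x <- c(rep(1, 300), 1000, rep(1, 300))
#' max(removeOutliers(x))  # the spike is capped at the window quantile
#' @export
removeOutliers <- function(counts, window = 200L, quantile = 0.95,
                           maxIter = 50L) {
    stopifnot(window >= 2, quantile > 0, quantile < 1)
    if (is.list(counts))
        return(lapply(counts, removeOutliers, window = window,
                      quantile = quantile, maxIter = maxIter))
    if (window > length(counts)) {
        warning("window longer than sequence; using a single window")
        window <- length(counts)
    }
    x <- as.numeric(counts)
    for (i in seq_len(maxIter)) {
        capped <- cpp_window_winsorize(x, as.integer(window), quantile)
        if (identical(capped, x)) break
        x <- capped
    }
    x
}

#' Aggregate per-base counts into layout bins
#'
#' Each bin's count is the exact sum of its constituent per-base counts
#' (mass is conserved per chromosome); per-chromosome totals are then
#' recomputable from the binned track.
#'
#' @param perBase named list of per-base numeric vectors (as returned by
#'   [countReadsPerBase()]), matching the layout chromosomes and lengths.
#' @param layout a [GenomeLayout-class].
#' @param sampleId,role metadata for the returned track.
#' @return A [BinnedCoverage-class].
#' @export
binCounts <- function(perBase, layout, sampleId = "sample",
                      role = c("tumor", "normal")) {
    role <- match.arg(role)
    cl <- chromLengths(layout)
    if (!identical(sort(names(perBase)), sort(names(cl))))
        stop("per-base chromosomes do not match the layout")
    bs <- binSize(layout)
    binned <- lapply(names(cl), function(ch) {
        v <- perBase[[ch]]
        if (length(v) != cl[[ch]])
            stop("per-base length mismatch on ", ch)
        idx <- ((seq_along(v) - 1) %/% bs) + 1
        as.numeric(rowsum(v, idx, reorder = TRUE))
    })
    new("BinnedCoverage", sampleId = sampleId, role = role,
        counts = unlist(binned, use.names = FALSE), layout = layout)
}

#' Build a BinnedCoverage directly from per-bin counts
#'
#' @param counts numeric vector over all layout bins.
#' @inheritParams binCounts
#' @return A [BinnedCoverage-class].
#' @export
binnedCoverage <- function(counts, layout, sampleId = "sample",
                           role = c("tumor", "normal")) {
    new("BinnedCoverage", sampleId = sampleId, role = match.arg(role),
        counts = as.numeric(counts), layout = layout)
}

#' @describeIn binnedCoverage Per-bin counts of a track.
#' @param object a `BinnedCoverage`.
#' @export
setMethod("counts", "BinnedCoverage", function(object) object@counts)

#' @describeIn binnedCoverage Sample identifier.
#' @param x a `BinnedCoverage`.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname binnedCoverage
#' @export
setMethod("sampleId", "BinnedCoverage", function(x) x@sampleId)

#' Per-chromosome total read counts of a binned track
#'
#' @param x a [BinnedCoverage-class].
#' @return named numeric vector, one total per chromosome.
#' @export
perChromosomeTotals <- function(x) {
    layout <- x@layout
    npc <- binsPerChrom(layout)
    off <- binOffsets(layout)
    vapply(seq_along(npc), function(c)
        sum(x@counts[(off[c] + 1):(off[c] + npc[c])]), numeric(1)) |>
        stats::setNames(names(chromLengths(layout)))
}

setMethod("show", "BinnedCoverage", function(object) {
    cat("BinnedCoverage '", object@sampleId, "' (", object@role, "): ",
        format(length(object@counts), big.mark = ","), " bins, mean ",
        round(mean(object@counts), 2), " reads/bin\n", sep = "")
})

#' Chromosome-normalized log2 copy-ratio track
#'
#' For bin `i` on chromosome `c` the ratio is
#' `log2((Tumor_i / Tumor_c) / (Normal_i / Normal_c))`, where the `_c`
#' terms are the chromosome's total aligned reads.  The per-chromosome
#' normalization makes the ratio invariant to library size, per
#' chromosome.  Bins with a zero tumor or normal count are marked invalid
#' (no pseudocounts: persistent sparse regions are the masking module's
#' job, and pseudocounts would fabricate deletions).
#'
#' @param tumor,normal [BinnedCoverage-class] tracks on the same layout.
#' @return A [CopyRatioTrack-class] for the tumor sample.
#' @export
computeLog2Ratio <- function(tumor, normal) {
    if (!identical(chromLengths(tumor@layout), chromLengths(normal@layout)) ||
        binSize(tumor@layout) != binSize(normal@layout))
        stop("tumor and normal must share the same layout")
    layout <- tumor@layout
    tc <- perChromosomeTotals(tumor)
    nc <- perChromosomeTotals(normal)
    zeroChrom <- tc == 0 | nc == 0
    if (any(zeroChrom))
        warning("chromosome(s) with zero total reads marked invalid: ",
                paste(names(tc)[zeroChrom], collapse = ", "))
    npc <- binsPerChrom(layout)
    res <- cpp_log2_ratio(tumor@counts, normal@counts,
                          rep(tc, npc), rep(nc, npc))
    new("CopyRatioTrack", sampleId = tumor@sampleId,
        log2Ratio = res$ratio, valid = res$valid, layout = layout)
}

#' @describeIn computeLog2Ratio Per-bin log2-ratio values (0 where invalid).
#' @param x a `CopyRatioTrack`.
#' @export
setGeneric("log2Ratio", function(x) standardGeneric("log2Ratio"))

#' @rdname computeLog2Ratio
#' @export
setMethod("log2Ratio", "CopyRatioTrack", function(x) x@log2Ratio)

#' @describeIn computeLog2Ratio Logical validity mask.
#' @export
setGeneric("validBins", function(x) standardGeneric("validBins"))

#' @rdname computeLog2Ratio
#' @export
setMethod("validBins", "CopyRatioTrack", function(x) x@valid)

setMethod("show", "CopyRatioTrack", function(object) {
    cat("CopyRatioTrack '", object@sampleId, "': ",
        format(length(object@log2Ratio), big.mark = ","), " bins, ",
        sum(!object@valid), " invalid\n", sep = "")
})
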