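#' Construct a GenomeLayout
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp,
#'   in the order the genome should be traversed.
#' @param binSize bin width in bp (default 100).
#' @param nGaps `GRanges` of reference N-gap intervals (optional).
#' @param lowMapMask `GRanges` of low-mapping intervals (optional; normally
#'   filled by [detectLowMappingSegments()]).
#' @return A [GenomeLayout-class] object.
#' @examples
#' genomeLayout(c(chr1 = 3e6, chr2 = 2e6))
#' @export
genomeLayout <- function(chromLengths, binSize = 100L,
                         nGaps = GenomicRanges::GRanges(),
                         lowMapMask = GenomicRanges::GRanges()) {
    new("GenomeLayout", chromLengths = chromLengths,
        binSize = as.integer(binSize),
        nGaps = normalizeMask(nGaps), lowMapMask = normalizeMask(lowMapMask))
}

# reduce() so masked intervals never overlap after normalization
normalizeMask <- function(gr) {
    if (length(gr) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(gr)
}

#' @rdname genomeLayout
#' @param object,x a `GenomeLayout`.
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname genomeLayout
#' @export
setMethod("chromLengths", "GenomeLayout", function(x) x@chromLengths)

#' @rdname genomeLayout
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname genomeLayout
#' @export
setMethod("binSize", "GenomeLayout", function(x) x@binSize)

#' @rdname genomeLayout
#' @export
setGeneric("lowMapMask", function(x) standardGeneric("lowMapMask"))

#' @rdname genomeLayout
#' @export
setMethod("lowMapMask", "GenomeLayout", function(x) x@lowMapMask)

#' @rdname genomeLayout
#' @export
setGeneric("nGaps", function(x) standardGeneric("nGaps"))

#' @rdname genomeLayout
#' @export
setMethod("nGaps", "GenomeLayout", function(x) x@nGaps)

#' Bin bookkeeping for a GenomeLayout
#'
#' `binsPerChrom()` gives the number of bins tiling each chromosome (the
#' trailing partial bin is kept); `totalBins()` their sum; `binOffsets()`
#' the cumulative offset preceding each chromosome.
#'
#' @param layout a [GenomeLayout-class].
#' @return integer vector / scalar.
#' @examples
#' totalBins(genomeLayout(c(chr1 = 3.2e9 / 32), binSize = 100))
#' @export
binsPerChrom <- function(layout) {
    n <- ceiling(chromLengths(layout) / binSize(layout))
    storage.mode(n) <- "double"
    n
}

#' @rdname binsPerChrom
#' @export
totalBins <- function(layout) sum(binsPerChrom(layout))

#' @rdname binsPerChrom
#' @export
binOffsets <- function(layout) {
    n <- binsPerChrom(layout)
    stats::setNames(cumsum(c(0, n[-length(n)])), names(n))
}

#' Map global bin indices to genomic coordinates and back
#'
#' The layout defines a bijection between the global bin index and
#' `(chromosome, start)`: `binToGenome()` returns the genomic interval of
#' each bin (1-based inclusive), `genomeToBin()` the global index of the
#' bin containing a position.  Round-trips are exact.
#'
#' @param layout a [GenomeLayout-class].
#' @param index integer vector of global bin indices.
#' @return `binToGenome()`: data.frame with `chrom`, `start`, `end`;
#'   `genomeToBin()`: integer vector.
#' @export
binToGenome <- function(layout, index) {
    off <- binOffsets(layout)
    npc <- binsPerChrom(layout)
    ci <- findInterval(index - 0.5, cumsum(c(0, npc))) # chromosome id
    if (any(ci < 1 | ci > length(npc)))
        stop("bin index out of range")
    within <- index - off[ci]
    bs <- binSize(layout)
    start <- (within - 1) * bs + 1
    end <- pmin(within * bs, chromLengths(layout)[ci])
    data.frame(chrom = names(chromLengths(layout))[ci],
               start = start, end = end, row.names = NULL)
}

#' @rdname binToGenome
#' @param chrom chromosome names.
#' @param pos genomic positions (1-based).
#' @export
genomeToBin <- function(layout, chrom, pos) {
    cl <- chromLengths(layout)
    m <- match(chrom, names(cl))
    if (anyNA(m)) stop("unknown chromosome: ",
                       paste(unique(chrom[is.na(m)]), collapse = ", "))
    if (any(pos < 1 | pos > cl[m])) stop("position outside chromosome")
    as.integer(binOffsets(layout)[m] + (pos - 1) %/% binSize(layout) + 1)
}

#' Chromosome id (1-based, layout order) of each global bin index
#' @keywords internal
chromOfBin <- function(layout, index) {
    npc <- binsPerChrom(layout)
    as.integer(findInterval(index - 0.5, cumsum(c(0, npc))))
}

#' Which bins are masked?
#'
#' A bin is masked when it overlaps a reference N gap or a low-mapping
#' interval by at least one bp.
#'
#' @param layout a [GenomeLayout-class].
#' @return logical vector over all bins.
#' @export
maskedBins <- function(layout) {
    out <- logical(totalBins(layout))
    off <- binOffsets(layout)
    bs <- binSize(layout)
    npc <- binsPerChrom(layout)
    mark <- function(gr) {
        if (length(gr) == 0L) return()
        ch <- as.character(GenomeInfoDb::seqnames(gr))
        s <- BiocGenerics::start(gr); e <- BiocGenerics::end(gr)
        for (i in seq_along(gr)) {
            o <- off[ch[i]]
            b1 <- max(1, (s[i] - 1) %/% bs + 1)
            b2 <- min(npc[ch[i]], (e[i] - 1) %/% bs + 1)
            if (b2 >= b1) out[(o + b1):(o + b2)] <<- TRUE
        }
    }
    mark(nGaps(layout))
    mark(lowMapMask(layout))
    out
}

#' Add low-mapping intervals to a layout's mask
#'
#' Masking is monotone: new intervals are unioned with the existing mask;
#' no bin is ever unmasked.
#'
#' @param layout a [GenomeLayout-class].
#' @param intervals `GRanges` to add.
#' @return The updated layout.
#' @export
addLowMapMask <- function(layout, intervals) {
    if (length(intervals) == 0L) return(layout)
    layout@lowMapMask <- normalizeMask(c(layout@lowMapMask, intervals))
    validObject(layout)
    layout
}

#' Read a two-column chrom-sizes file into a GenomeLayout
#'
#' @param path tab- or space-separated file with chromosome name and length.
#' @param binSize bin width in bp.
#' @param gapsBed optional BED file of N-gap intervals.
#' @return A [GenomeLayout-class].
#' @export
readChromSizes <- function(path, binSize = 100L, gapsBed = NULL) {
    tab <- utils::read.table(path, header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "numeric"))
    gaps <- if (is.null(gapsBed)) GenomicRanges::GRanges()
            else rtracklayer::import(gapsBed, format = "BED")
    genomeLayout(stats::setNames(tab$length, tab$chrom), binSize,
                 nGaps = gaps)
}

setMethod("show", "GenomeLayout", function(object) {
    cat("GenomeLayout:", length(object@chromLengths), "chromosomes,",
        format(sum(object@chromLengths), big.mark = ","), "bp,",
        "bin", object@binSize, "bp,",
        format(totalBins(object), big.mark = ","), "bins\n")
    if (length(object@nGaps))
        cat("  N gaps:", length(object@nGaps), "intervals\n")
    if (length(object@lowMapMask))
        cat("  low-mapping mask:", length(object@lowMapMask), "intervals\n")
})
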