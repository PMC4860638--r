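#' Flag altered segments under the silver-standard filter
#'
#' A segmentation call counts as an altered (focal) region when its
#' absolute mean log2 ratio is at least `minAbsLog2` (default 0.4) and
#' its length is at most `maxArmFraction` (default 25%) of the
#' chromosome arm it sits on.  Segments whose arm length is unknown are
#' skipped with a warning (flag `NA`).
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `meanLog2`,
#'   `arm` (`"p"`/`"q"`).
#' @param armLengths data.frame with `chrom`, `arm`, `length` (bp).
#' @param minAbsLog2 amplitude threshold.
#' @param maxArmFraction broad/focal boundary as a fraction of the arm.
#' @return logical vector (`NA` where the arm length is missing).
#' @export
classifyAlteredSegments <- function(segments, armLengths,
                                    minAbsLog2 = 0.4,
                                    maxArmFraction = 0.25) {
    key <- paste(segments$chrom, segments$arm)
    akey <- paste(armLengths$chrom, armLengths$arm)
    armLen <- armLengths$length[match(key, akey)]
    if (anyNA(armLen))
        warning(sum(is.na(armLen)),
                " segment(s) skipped: missing arm length")
    len <- segments$end - segments$start + 1
    ifelse(is.na(armLen), NA,
           abs(segments$meanLog2) >= minAbsLog2 &
           len <= maxArmFraction * armLen)
}

#' Cumulative inspection-length curve
#'
#' Walking down the regions in decreasing |score| (for score-ranked
#' output) or decreasing |mean log2| (manual-inspection mode), region
#' lengths are accumulated and the cumulative bp at which each target
#' gene is first overlapped (>= 1 bp) is recorded.  Duplicate genes count
#' once; the curve is nondecreasing in both axes.
#'
#' @param regions `GRanges` with a `score` metadata column.
#' @param targets `GRanges` of target genes with a `name` column.
#' @return data.frame with `gene`, `genesFound`, `cumulativeBp` (empty
#'   when no region overlaps any target).
#' @export
inspectionLengthCurve <- function(regions, targets) {
    if (is.null(regions$score)) stop("regions must carry scores")
    if (is.null(targets$name)) stop("targets must carry names")
    ord <- order(-abs(regions$score))
    found <- character(); cum <- 0
    rows <- list()
    for (i in ord) {
        cum <- cum + BiocGenerics::width(regions)[i]
        hits <- GenomicRanges::findOverlaps(regions[i], targets)
        new <- setdiff(unique(targets$name[S4Vectors::subjectHits(hits)]),
                       found)
        for (g in new) {
            found <- c(found, g)
            rows[[length(rows) + 1L]] <- data.frame(
                gene = g, genesFound = length(found), cumulativeBp = cum)
        }
    }
    if (!length(rows))
        return(data.frame(gene = character(), genesFound = integer(),
                          cumulativeBp = numeric()))
    do.call(rbind, rows)
}
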