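# genomic coordinates as plain integers (never scientific notation)
.coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a bedGraph track into layout bins
#'
#' Accepts 4-column bedGraph (`chrom`, `start`, `end`, `count`; 0-based
#' half-open).  When every interval aligns exactly with one layout bin
#' (the format written by [writeBedGraphTrack()]), values are taken as
#' per-bin totals; otherwise values are treated as per-position counts
#' and a bin's count is the sum of `count * overlap_width` over the
#' intervals it intersects.
#'
#' @param path bedGraph file.
#' @param layout a [GenomeLayout-class].
#' @param sampleId,role track metadata.
#' @return A [BinnedCoverage-class].
#' @export
readBedGraphTrack <- function(path, layout, sampleId = "sample",
                              role = c("tumor", "normal")) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    cl <- chromLengths(layout)
    unknown <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gr))),
                       names(cl))
    if (length(unknown))
        stop("unknown chromosome(s) in bedGraph: ",
             paste(unknown, collapse = ", "))
    countsVec <- numeric(totalBins(layout))
    bs <- binSize(layout)
    ch <- as.character(GenomeInfoDb::seqnames(gr))
    s <- BiocGenerics::start(gr); e <- BiocGenerics::end(gr)
    val <- gr$score
    off <- binOffsets(layout)
    endsOk <- e %% bs == 0 | e == cl[ch]
    aligned <- all((s - 1) %% bs == 0 & endsOk & e - s + 1 <= bs)
    if (aligned) {
        countsVec[off[ch] + (s - 1) %/% bs + 1] <- val
    } else {
        for (i in seq_along(gr)) {
            b1 <- (s[i] - 1) %/% bs + 1
            b2 <- (e[i] - 1) %/% bs + 1
            for (b in b1:b2) {
                lo <- max(s[i], (b - 1) * bs + 1)
                hi <- min(e[i], b * bs)
                countsVec[off[ch[i]] + b] <- countsVec[off[ch[i]] + b] +
                    val[i] * (hi - lo + 1)
            }
        }
    }
    binnedCoverage(countsVec, layout, sampleId, match.arg(role))
}

#' Write a per-bin track as bedGraph
#'
#' Emitted intervals are 0-based half-open, one per bin; zero bins are
#' skipped.  `values` defaults to the track's counts; a numeric vector
#' over all bins (e.g. a log2-ratio) may be given instead.
#'
#' @param x a [BinnedCoverage-class] or [CopyRatioTrack-class].
#' @param path output file.
#' @param values optional numeric vector overriding the track values.
#' @return `path`, invisibly.
#' @export
writeBedGraphTrack <- function(x, path, values = NULL) {
    layout <- x@layout
    v <- if (!is.null(values)) values
         else if (is(x, "CopyRatioTrack")) ifelse(x@valid, x@log2Ratio, 0)
         else x@counts
    keep <- which(v != 0)
    g <- binToGenome(layout, keep)
    df <- data.frame(chrom = g$chrom,
                     start = .coord(g$start - 1), end = .coord(g$end),
                     value = v[keep])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write the cluster report
#'
#' Tab-separated report mirroring the standard presentation: 1-based
#' inclusive coordinates, clusters ordered by |score| descending, with
#' per-FDC p-values and overlapping genes when present.
#'
#' @param clusters annotated `GRanges` from [runCohortPipeline()] /
#'   [annotateClusters()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeClusterReport <- function(clusters, path) {
    ord <- order(-abs(clusters$score))
    cl <- clusters[ord]
    df <- data.frame(Chr = as.character(GenomeInfoDb::seqnames(cl)),
                     Start = .coord(BiocGenerics::start(cl)),
                     End = .coord(BiocGenerics::end(cl)),
                     Score = round(cl$score, 2),
                     Patients = cl$nPatients)
    for (m in 1:5) {
        col <- paste0("p.FDC", m)
        if (!is.null(S4Vectors::mcols(cl)[[col]]))
            df[[col]] <- S4Vectors::mcols(cl)[[col]]
    }
    df$Genes <- if (!is.null(cl$genes)) cl$genes else ""
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export clusters as BED9 with sign-colored entries
#'
#' Gains are colored red (`255,0,0`), losses blue (`0,0,255`);
#' coordinates follow BED's 0-based half-open convention.
#'
#' @param clusters `GRanges` with `score` and `sign` columns.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
clustersToBed <- function(clusters, path) {
    ord <- order(-abs(clusters$score))
    cl <- clusters[ord]
    df <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(cl)),
        start = .coord(BiocGenerics::start(cl) - 1),
        end = .coord(BiocGenerics::end(cl)),
        name = sprintf("cluster%03d", seq_along(cl)),
        score = pmin(1000L, as.integer(abs(cl$score))),
        strand = ".",
        thickStart = .coord(BiocGenerics::start(cl) - 1),
        thickEnd = .coord(BiocGenerics::end(cl)),
        rgb = ifelse(cl$sign > 0, "255,0,0", "0,0,255"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
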