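#' Describe a synthetic tumor/normal WGS cohort
#'
#' Builds a validated [SimulationSpec-class].  Per patient, normal bin
#' counts are drawn from a negative binomial around `normalCoverage`
#' reads/bin (WGS depth is overdispersed, so Poisson would make the
#' noise-threshold machinery trivial); tumor counts use
#' `tumorCoverage * 2^dLog2` over events the patient carries.  Reference
#' N-gap bins are zeroed in both tracks.  Sparse-mapping stretches model
#' reference regions where alignment largely fails, with unequal retention
#' of tumor vs normal reads (`tumorRate`/`normalRate` metadata columns,
#' defaults 0.04 / 0.15) — the mechanism behind artifactual deletion
#' signal.  Germline events multiply both tracks (germline CNVs).
#' "Fractured" patients receive piecewise-constant multiplicative tumor
#' depth jitter, resampled every `fractureScaleBp`, log-normal with
#' `fractureSdLog` — emulating the excessive read-depth changes seen in a
#' subset of real tumor WGS.
#'
#' @param chromLengths named numeric chromosome lengths (bp).
#' @param binSize bin width in bp (default 100).
#' @param nPatients cohort size.
#' @param tumorCoverage,normalCoverage mean reads per bin (defaults 49.6
#'   and 43.7, typical tumor/normal WGS depths).
#' @param events data.frame with `chrom`, `start`, `end`, `dLog2`,
#'   `kind` (`"focal"` <= 3 Mb, `"broad"` > 25% of the chromosome) and a
#'   `carriers` list column of patient indices.
#' @param nGaps,sparseRegions `GRanges` (sparseRegions may carry
#'   `tumorRate`/`normalRate` columns).
#' @param germlineEvents optional data.frame `chrom`, `start`, `end`,
#'   `multiplier` applied to both tracks of every patient.
#' @param dispersion negative-binomial size parameter (default 20).
#' @param fracturedFraction share of patients fractured (default 0).
#' @param fractureScaleBp,fractureSdLog jitter scale (default 5e4 bp) and
#'   log-sd (default 0.25).
#' @param seed RNG seed stored with the spec.
#' @return A [SimulationSpec-class].
#' @export
simulationSpec <- function(chromLengths, binSize = 100L, nPatients = 10L,
                           tumorCoverage = 49.6, normalCoverage = 43.7,
                           events = NULL,
                           nGaps = GenomicRanges::GRanges(),
                           sparseRegions = GenomicRanges::GRanges(),
                           germlineEvents = NULL, dispersion = 20,
                           fracturedFraction = 0, fractureScaleBp = 5e4,
                           fractureSdLog = 0.25, seed = 1L) {
    if (is.null(events))
        events <- data.frame(chrom = character(), start = numeric(),
                             end = numeric(), dLog2 = numeric(),
                             kind = character(),
                             carriers = I(list()))
    if (length(sparseRegions) && is.null(sparseRegions$tumorRate)) {
        sparseRegions$tumorRate <- 0.04
        sparseRegions$normalRate <- 0.15
    }
    new("SimulationSpec", chromLengths = chromLengths,
        binSize = as.integer(binSize), nGaps = normalizeMask(nGaps),
        sparseRegions = sparseRegions, events = events,
        germlineEvents = germlineEvents, nPatients = as.integer(nPatients),
        tumorCoverage = tumorCoverage, normalCoverage = normalCoverage,
        dispersion = dispersion, fracturedFraction = fracturedFraction,
        fractureScaleBp = fractureScaleBp, fractureSdLog = fractureSdLog,
        seed = as.integer(seed))
}

#' Default focal-within-broad cohort
#'
#' A compact 3 chromosome x 30 Mb cohort of 20 patients emulating the
#' canonical detection scenario: a 20 Mb broad gain (dLog2 0.3) on chr1
#' with a 1 Mb focal amplification (dLog2 1.0) nested inside it, both
#' carried by patients 1..6.  Coverages default to 49.6 (tumor) and 43.7
#' (normal) reads per 100 bp bin, the tumor:normal depth ratio of typical
#' tumor/normal WGS cohorts.
#'
#' @param nPatients cohort size (default 20).
#' @param seed RNG seed.
#' @param carriers patient indices carrying the planted events.
#' @param fracturedFraction share of fractured patients (default 0).
#' @return A [SimulationSpec-class].
#' @export
wgsCohortSpec <- function(nPatients = 20L, seed = 1L, carriers = 1:6,
                          fracturedFraction = 0) {
    events <- data.frame(
        chrom = c("chr1", "chr1"),
        start = c(5e6 + 1, 1e7 + 1),
        end = c(2.5e7, 1.1e7),
        dLog2 = c(0.3, 1.0),
        kind = c("broad", "focal"))
    events$carriers <- list(carriers, carriers)
    simulationSpec(c(chr1 = 3e7, chr2 = 3e7, chr3 = 3e7),
                   nPatients = nPatients, events = events, seed = seed,
                   fracturedFraction = fracturedFraction)
}

# patient-independent per-bin depth multipliers (germline CNVs and
# sparse-mapping suppression)
.baseMultipliers <- function(spec, layout) {
    n <- totalBins(layout)
    tMul <- rep(1, n); nMul <- rep(1, n)
    binsOf <- function(chrom, start, end)
        genomeToBin(layout, chrom, start):genomeToBin(layout, chrom, end)
    ge <- spec@germlineEvents
    if (!is.null(ge)) for (i in seq_len(nrow(ge))) {
        b <- binsOf(ge$chrom[i], ge$start[i], ge$end[i])
        tMul[b] <- tMul[b] * ge$multiplier[i]
        nMul[b] <- nMul[b] * ge$multiplier[i]
    }
    sp <- spec@sparseRegions
    if (length(sp)) for (i in seq_along(sp)) {
        b <- binsOf(as.character(GenomeInfoDb::seqnames(sp))[i],
                    BiocGenerics::start(sp)[i], BiocGenerics::end(sp)[i])
        tMul[b] <- tMul[b] * sp$tumorRate[i]
        nMul[b] <- nMul[b] * sp$normalRate[i]
    }
    list(tumor = tMul, normal = nMul, binsOf = binsOf)
}

#' Simulate a tumor/normal cohort with known truth
#'
#' Fully reproducible from the spec's seed (or the `seed` argument).
#'
#' @param spec a [SimulationSpec-class].
#' @param seed overrides `spec@seed` when given.
#' @return list with `layout` (a [GenomeLayout-class] carrying the N
#'   gaps), `patients` (per patient, a list with `tumor` and `normal`
#'   [BinnedCoverage-class] tracks), `truth` (the planted event table),
#'   and `fractured` (logical per patient).
#' @export
simulateCohort <- function(spec, seed = NULL) {
    validObject(spec)
    set.seed(if (is.null(seed)) spec@seed else seed)
    layout <- genomeLayout(spec@chromLengths, spec@binSize,
                           nGaps = spec@nGaps)
    n <- totalBins(layout)
    # partial trailing bins see proportionally fewer reads
    widths <- rep(1, n)
    npc <- binsPerChrom(layout); off <- binOffsets(layout)
    last <- off + npc
    widths[last] <- (spec@chromLengths - (npc - 1) * spec@binSize) /
        spec@binSize
    gapped <- maskedBins(layout)
    fractured <- runif(spec@nPatients) < spec@fracturedFraction
    binsPerSeg <- max(1, round(spec@fractureScaleBp / spec@binSize))
    base <- .baseMultipliers(spec, layout)
    tMuBase <- spec@tumorCoverage * widths * base$tumor
    nMuBase <- spec@normalCoverage * widths * base$normal
    nMuBase[gapped] <- 0
    ev <- spec@events
    patients <- vector("list", spec@nPatients)
    for (p in seq_len(spec@nPatients)) {
        tMu <- tMuBase
        nMu <- nMuBase
        if (nrow(ev)) for (i in seq_len(nrow(ev))) {
            if (!p %in% ev$carriers[[i]]) next
            b <- base$binsOf(ev$chrom[i], ev$start[i], ev$end[i])
            tMu[b] <- tMu[b] * 2^ev$dLog2[i]
        }
        if (fractured[p]) {
            nSeg <- ceiling(n / binsPerSeg)
            fac <- rep(rlnorm(nSeg, 0, spec@fractureSdLog),
                       each = binsPerSeg)[seq_len(n)]
            tMu <- tMu * fac
        }
        tMu[gapped] <- 0
        tCounts <- cpp_rnbinom_mu(tMu, spec@dispersion)
        nCounts <- cpp_rnbinom_mu(nMu, spec@dispersion)
        patients[[p]] <- list(
            tumor = binnedCoverage(tCounts, layout,
                                   sampleId = sprintf("patient%02d", p),
                                   role = "tumor"),
            normal = binnedCoverage(nCounts, layout,
                                    sampleId = sprintf("patient%02d", p),
                                    role = "normal"))
    }
    list(layout = layout, patients = patients, truth = spec@events,
         fractured = fractured)
}

setMethod("show", "SimulationSpec", function(object) {
    cat("SimulationSpec:", object@nPatients, "patients,",
        length(object@chromLengths), "chromosomes,",
        nrow(object@events), "planted events, coverage",
        object@tumorCoverage, "/", object@normalCoverage, "reads/bin\n")
})
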