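#' @include AllGenerics.R
NULL

#' GenotypeExperiment: diploid SNP dosages with sample populations
#'
#' Container for a biallelic SNP genotype matrix. Extends
#' [SummarizedExperiment::RangedSummarizedExperiment-class]: rows are SNP
#' sites (a `GRanges` with metadata columns `ref`, `alt` and `snpId`),
#' columns are samples, and the single assay `"dosage"` holds the per-site
#' per-sample alternate-allele count (0, 1, 2 or `NA` for a missing call).
#' The population label of every sample lives in `colData(x)$population`.
#'
#' Sites are kept sorted by (chromosome, position) and must be biallelic;
#' the validity method enforces both, together with the 0/1/2/NA dosage
#' domain.
#'
#' @aliases GenotypeExperiment-class
#' @export
setClass("GenotypeExperiment",
    contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        bad <- !is.na(d) & !(d %in% c(0, 1, 2))
        if (any(bad))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA (ploidy 2)")
    }
    if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'population' column")
    rr <- SummarizedExperiment::rowRanges(object)
    need <- c("ref", "alt", "snpId")
    miss <- setdiff(need, colnames(S4Vectors::mcols(rr)))
    if (length(miss))
        msg <- c(msg, paste0("rowRanges metadata missing: ",
                             paste(miss, collapse = ", ")))
    if (length(rr) > 1L) {
        o <- order(as.integer(GenomeInfoDb::seqnames(rr)),
                   GenomicRanges::start(rr))
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param dosage integer/numeric matrix, sites x samples, values 0/1/2/NA.
#' @param rowRanges `GRanges` of SNP sites (width-1), with metadata columns
#'   `ref`, `alt`, `snpId`. Re-sorted by (chrom, pos) together with `dosage`
#'   if needed.
#' @param population character vector of population labels, one per sample
#'   (column of `dosage`).
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'     ref = c("A", "C"), alt = c("G", "T"), snpId = c("s1", "s2"))
#' d <- matrix(c(0L, 1L, 2L, 1L), nrow = 2,
#'     dimnames = list(NULL, c("i1", "i2")))
#' ge <- GenotypeExperiment(d, gr, population = c("P1", "P2"))
#' @export
GenotypeExperiment <- function(dosage, rowRanges, population) {
    dosage <- as.matrix(dosage)
    if (nrow(dosage) != length(rowRanges))
        stop("nrow(dosage) must equal length(rowRanges)")
    if (ncol(dosage) != length(population))
        stop("one population label per sample is required")
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("sample%03d", seq_len(ncol(dosage)))
    o <- order(as.integer(GenomeInfoDb::seqnames(rowRanges)),
               GenomicRanges::start(rowRanges))
    rowRanges <- rowRanges[o]
    dosage <- dosage[o, , drop = FALSE]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage),
        rowRanges = rowRanges,
        colData = S4Vectors::DataFrame(population = as.character(population),
                                       row.names = colnames(dosage)))
    methods::new("GenotypeExperiment", se)
}

#' @describeIn GenotypeExperiment the dosage matrix (sites x samples).
#' @param x a `GenotypeExperiment`.
#' @export
setMethod("dosages", "GenotypeExperiment", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @describeIn GenotypeExperiment per-sample population labels.
#' @export
setMethod("populations", "GenotypeExperiment", function(x)
    SummarizedExperiment::colData(x)$population)

#' @describeIn GenotypeExperiment SNP identifiers, in site order.
#' @export
setMethod("snpIds", "GenotypeExperiment", function(x)
    S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$snpId)

setMethod("show", "GenotypeExperiment", function(object) {
    cat("GenotypeExperiment:", nrow(object), "sites x", ncol(object),
        "samples\n")
    pops <- table(populations(object))
    cat("populations:",
        paste(sprintf("%s(%d)", names(pops), pops), collapse = " "), "\n")
    cat("chromosomes:",
        paste(GenomeInfoDb::seqlevels(SummarizedExperiment::rowRanges(object)),
              collapse = " "), "\n")
})

#' AlleleCounts: per-site, per-population allele tallies
#'
#' Holds, for every SNP site and every population: the number of called
#' alleles (2 x non-missing diploid samples), the alternate-allele count and
#' the observed heterozygote count. These are the sufficient statistics for
#' the allele-frequency F_ST estimators.
#'
#' @slot sites `GRanges` of the SNP sites (metadata `ref`, `alt`, `snpId`).
#' @slot populations character vector of population labels (column order of
#'   the matrices).
#' @slot nAlleles,altCount,hetCount numeric matrices, sites x populations.
#' @aliases AlleleCounts-class
#' @export
setClass("AlleleCounts", representation(
    sites = "GRanges",
    populations = "character",
    nAlleles = "matrix",
    altCount = "matrix",
    hetCount = "matrix"))

setValidity("AlleleCounts", function(object) {
    msg <- character()
    n <- length(object@sites)
    k <- length(object@populations)
    for (s in c("nAlleles", "altCount", "hetCount")) {
        m <- methods::slot(object, s)
        if (!identical(dim(m), c(n, k)))
            msg <- c(msg, paste0(s, " must be sites x populations"))
    }
    if (!length(msg)) {
        if (any(object@altCount > object@nAlleles))
            msg <- c(msg, "altCount must not exceed nAlleles")
        if (any(object@hetCount * 2 > object@nAlleles))
            msg <- c(msg, "hetCount must not exceed non-missing samples")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "AlleleCounts", function(object) {
    cat("AlleleCounts:", length(object@sites), "sites x",
        length(object@populations), "populations (",
        paste(object@populations, collapse = ", "), ")\n")
})

#' @describeIn AlleleCounts sample alternate-allele frequency matrix
#'   (sites x populations); `NaN` where a population has no called alleles.
#' @param x an `AlleleCounts`.
#' @export
setMethod("alleleFreq", "AlleleCounts", function(x)
    x@altCount / x@nAlleles)

#' @describeIn AlleleCounts SNP identifiers.
#' @export
setMethod("snpIds", "AlleleCounts", function(x)
    S4Vectors::mcols(x@sites)$snpId)

#' FstScan: per-SNP pairwise F_ST scores and pdSNP calls
#'
#' Result of [fstScan()]: one F_ST score per SNP per unordered population
#' pair, the per-pair top-percentile threshold, and the pdSNP membership
#' flags. `NA` scores mark sites not scorable for a pair (a population with
#' no called alleles, or the pair pooled-monomorphic).
#'
#' @slot sites `GRanges` of the scored SNP sites.
#' @slot pairs data.frame with columns `popA`, `popB`, `label`.
#' @slot fst numeric matrix, sites x pairs (per-site estimates).
#' @slot pd logical matrix, sites x pairs (top-percentile membership).
#' @slot threshold numeric per-pair percentile cut value.
#' @slot nScored integer per-pair count of scorable sites.
#' @slot fstMultilocus numeric per-pair genome-wide F_ST (ratio of summed
#'   variance components).
#' @slot topFraction the fraction used to call pdSNPs (default 0.01).
#' @slot estimator "wc" or "hudson".
#' @aliases FstScan-class
#' @export
setClass("FstScan", representation(
    sites = "GRanges",
    pairs = "data.frame",
    fst = "matrix",
    pd = "matrix",
    threshold = "numeric",
    nScored = "integer",
    fstMultilocus = "numeric",
    topFraction = "numeric",
    estimator = "character"))

setValidity("FstScan", function(object) {
    msg <- character()
    n <- length(object@sites)
    k <- nrow(object@pairs)
    if (!identical(dim(object@fst), c(n, k)))
        msg <- c(msg, "fst must be sites x pairs")
    if (!identical(dim(object@pd), dim(object@fst)))
        msg <- c(msg, "pd must match fst in shape")
    if (length(object@threshold) != k || length(object@nScored) != k)
        msg <- c(msg, "one threshold and nScored per pair required")
    if (length(msg)) msg else TRUE
})

setMethod("show", "FstScan", function(object) {
    cat("FstScan:", length(object@sites), "sites,", nrow(object@pairs),
        "population pairs, estimator:", object@estimator, "\n")
    cat("top fraction:", object@topFraction,
        "| pdSNP union size:", nrow(pdUnion(object)), "\n")
})

#' @describeIn FstScan SNP identifiers of the scored sites.
#' @param x an `FstScan`.
#' @export
setMethod("snpIds", "FstScan", function(x) S4Vectors::mcols(x@sites)$snpId)
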