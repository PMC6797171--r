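#' Per-population allele counts
#'
#' Derives, for every site and population, the number of called alleles
#' (twice the non-missing diploid samples), the alternate-allele count and
#' the observed heterozygote count — the sufficient statistics for the
#' allele-frequency F_ST estimators. Missing genotypes are excluded from
#' the counts, not imputed. A population with zero called alleles at a site
#' leaves that site uncallable for pairs involving it (`nAlleles` 0).
#'
#' @param ge a [GenotypeExperiment-class].
#' @return An [AlleleCounts-class] object.
#' @examples
#' sim <- simulateGenotypes(simulationConfig(2, 5, 20, c(chr1 = 1e5),
#'     seed = 1))
#' ac <- alleleCounts(sim$genotypes)
#' head(alleleFreq(ac))
#' @export
alleleCounts <- function(ge) {
    stopifnot(methods::is(ge, "GenotypeExperiment"))
    d <- dosages(ge)
    pop <- populations(ge)
    pops <- unique(pop)
    n <- nrow(d)
    mk <- function(f) vapply(pops, function(p)
        f(d[, pop == p, drop = FALSE]), numeric(n))
    asMat <- function(m) matrix(m, nrow = n, ncol = length(pops),
                                dimnames = list(NULL, pops))
    nAll <- asMat(mk(function(x) 2 * rowSums(!is.na(x))))
    alt <- asMat(mk(function(x) rowSums(x, na.rm = TRUE)))
    het <- asMat(mk(function(x) rowSums(x == 1L, na.rm = TRUE)))
    methods::new("AlleleCounts",
                 sites = SummarizedExperiment::rowRanges(ge),
                 populations = pops,
                 nAlleles = nAll, altCount = alt, hetCount = het)
}

#' Filter monomorphic sites
#'
#' Returns a logical keep-mask over sites. Mode `"pooled"` (default) drops
#' sites monomorphic across all populations combined; mode `"any-pop"`
#' drops sites monomorphic (or uncallable) within at least one population.
#' The pooled mode retains fixed differences between populations — the
#' highest-F_ST sites a differentiation scan targets — whereas `"any-pop"`
#' discards them; both readings of "monomorphic in any population" are
#' offered.
#'
#' @param counts an [AlleleCounts-class].
#' @param mode `"pooled"` or `"any-pop"`.
#' @return logical vector, `TRUE` for sites to keep.
#' @export
filterMonomorphic <- function(counts, mode = c("pooled", "any-pop")) {
    mode <- match.arg(mode)
    stopifnot(methods::is(counts, "AlleleCounts"))
    if (mode == "pooled") {
        tAlt <- rowSums(counts@altCount)
        tAll <- rowSums(counts@nAlleles)
        tAlt > 0 & tAlt < tAll
    } else {
        mono <- counts@nAlleles == 0 |
            counts@altCount == 0 |
            counts@altCount == counts@nAlleles
        rowSums(mono) == 0
    }
}

#' Subset an AlleleCounts by a site mask
#'
#' @param counts an [AlleleCounts-class].
#' @param keep logical or integer site index.
#' @return The subsetted [AlleleCounts-class].
#' @export
subsetSites <- function(counts, keep) {
    methods::new("AlleleCounts",
                 sites = counts@sites[keep],
                 populations = counts@populations,
                 nAlleles = counts@nAlleles[keep, , drop = FALSE],
                 altCount = counts@altCount[keep, , drop = FALSE],
                 hetCount = counts@hetCount[keep, , drop = FALSE])
}
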