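#' Two-deme Weir-Cockerham F_ST variance components
#'
#' Computes the classic variance-components estimator for a pair of
#' populations at biallelic sites, from diploid sample sizes, sample
#' alternate-allele frequencies and observed heterozygote proportions.
#' `wcFst` returns the per-site ratio estimate theta-hat = a/(a+b+c);
#' `wcFstComponents` exposes the between-population component `a` and the
#' total `a+b+c` so multi-locus estimates can be formed as
#' `sum(a)/sum(a+b+c)` — the standard way to combine loci, and the one
#' that recovers the simulation's divergence parameter (a mean of per-site
#' ratios is biased downward by Jensen's inequality at low-information
#' sites).
#'
#' Per-site theta-hat may be negative from sampling noise; values are not
#' clamped, so that percentile ranking is not distorted by mass ties at 0.
#'
#' @param nA,nB diploid sample sizes (non-missing individuals) per site.
#' @param pA,pB sample alternate-allele frequencies per site.
#' @param hA,hB observed heterozygote proportions per site
#'   (heterozygotes / non-missing individuals).
#' @return `wcFst`: numeric vector of per-site theta-hat.
#'   `wcFstComponents`: list with components `a` and `total`.
#' @examples
#' wcFst(50, 0, 0, 50, 1, 0)  # fixed difference: 1
#' @export
wcFst <- function(nA, pA, hA, nB, pB, hB) {
    cmp <- wcFstComponents(nA, pA, hA, nB, pB, hB)
    cmp$a / cmp$total
}

#' @rdname wcFst
#' @export
wcFstComponents <- function(nA, pA, hA, nB, pB, hB) {
    r <- 2
    nbar <- (nA + nB) / 2
    nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
    pbar <- (nA * pA + nB * pB) / (r * nbar)
    s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
    hbar <- (nA * hA + nB * hB) / (r * nbar)
    a <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    list(a = a, total = a + b + cc)
}

#' Hudson's F_ST estimator
#'
#' Closed-form allele-frequency estimator used as an independent
#' cross-check of the Weir-Cockerham implementation: numerator
#' `(pA-pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)`, denominator
#' `pA(1-pB) + pB(1-pA)`. Sample sizes are in alleles (2x diploids).
#' Undefined (NaN) when both populations are monomorphic for the same
#' allele.
#'
#' @param pA,pB sample alternate-allele frequencies.
#' @param nA,nB allele counts (>= 2).
#' @return numeric vector of per-site estimates.
#' @examples
#' hudsonFst(1, 0, 100, 100)            # 1
#' round(hudsonFst(0.2, 0.8, 20, 20), 4)  # 0.5046
#' @export
hudsonFst <- function(pA, pB, nA, nB) {
    if (any(nA < 2) || any(nB < 2)) stop("allele counts must be >= 2")
    num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
    den <- pA * (1 - pB) + pB * (1 - pA)
    num / den
}

#' Enumerate unordered population pairs
#'
#' @param pops character vector of population labels.
#' @return data.frame with columns `popA`, `popB`, `label`
#'   ("popA-popB"); `choose(K, 2)` rows.
#' @examples
#' nrow(populationPairs(sprintf("P%d", 1:14)))  # 91
#' @export
populationPairs <- function(pops) {
    if (length(pops) < 2) stop("need at least two populations")
    cmb <- utils::combn(pops, 2)
    data.frame(popA = cmb[1, ], popB = cmb[2, ],
               label = paste(cmb[1, ], cmb[2, ], sep = "-"),
               stringsAsFactors = FALSE)
}

#' Call top-percentile (pd) SNPs from a score vector
#'
#' Selects the `ceiling(q * n)` highest finite scores; every score tied
#' with the boundary order statistic is included, making the rule
#' deterministic and permutation-invariant. Non-finite scores are never
#' selected.
#'
#' @param scores numeric scores (NA/NaN allowed; excluded from ranking).
#' @param topFraction top fraction q (default 0.01).
#' @return list with `threshold` (the cut value) and `selected` (logical
#'   over `scores`).
#' @export
callPdSnps <- function(scores, topFraction = 0.01) {
    fin <- is.finite(scores)
    n <- sum(fin)
    if (n == 0L) stop("no finite scores to rank")
    if (topFraction <= 0 || topFraction > 1)
        stop("topFraction must lie in (0, 1]")
    k <- ceiling(topFraction * n)
    thr <- sort(scores[fin], decreasing = TRUE)[k]
    list(threshold = thr, selected = fin & scores >= thr)
}

#' Pairwise F_ST scan with top-percentile pdSNP calling
#'
#' Scores every site for every unordered population pair and calls pdSNPs
#' per pair by the top-fraction rule (default top 1%). Sites uncallable
#' for a pair (a population with no called alleles) or pooled-monomorphic
#' within the pair get `NA` and are excluded from that pair's ranking.
#' Genome-wide sites monomorphic across all populations should be removed
#' beforehand with [filterMonomorphic()].
#'
#' @param counts an [AlleleCounts-class].
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @param topFraction top fraction for the pdSNP call (default 0.01).
#' @return An [FstScan-class] object.
#' @export
fstScan <- function(counts, estimator = c("wc", "hudson"),
                    topFraction = 0.01) {
    estimator <- match.arg(estimator)
    stopifnot(methods::is(counts, "AlleleCounts"))
    pairs <- populationPairs(counts@populations)
    n <- length(counts@sites)
    k <- nrow(pairs)
    fst <- matrix(NA_real_, n, k, dimnames = list(NULL, pairs$label))
    pd <- matrix(FALSE, n, k, dimnames = list(NULL, pairs$label))
    thr <- numeric(k)
    nSc <- integer(k)
    multi <- numeric(k)
    for (i in seq_len(k)) {
        A <- pairs$popA[i]; B <- pairs$popB[i]
        nAllA <- counts@nAlleles[, A]; nAllB <- counts@nAlleles[, B]
        altA <- counts@altCount[, A]; altB <- counts@altCount[, B]
        callable <- nAllA > 0 & nAllB > 0
        poly <- (altA + altB) > 0 & (altA + altB) < (nAllA + nAllB)
        ok <- callable & poly
        pA <- altA[ok] / nAllA[ok]; pB <- altB[ok] / nAllB[ok]
        if (estimator == "wc") {
            nA <- nAllA[ok] / 2; nB <- nAllB[ok] / 2
            hA <- counts@hetCount[ok, A] / nA
            hB <- counts@hetCount[ok, B] / nB
            cmp <- wcFstComponents(nA, pA, hA, nB, pB, hB)
            fst[ok, i] <- cmp$a / cmp$total
            multi[i] <- sum(cmp$a) / sum(cmp$total)
        } else {
            num <- (pA - pB)^2 - pA * (1 - pA) / (nAllA[ok] - 1) -
                pB * (1 - pB) / (nAllB[ok] - 1)
            den <- pA * (1 - pB) + pB * (1 - pA)
            fst[ok, i] <- num / den
            multi[i] <- sum(num) / sum(den)
        }
        call <- callPdSnps(fst[, i], topFraction)
        pd[, i] <- call$selected
        thr[i] <- call$threshold
        nSc[i] <- sum(is.finite(fst[, i]))
    }
    methods::new("FstScan", sites = counts@sites, pairs = pairs,
                 fst = fst, pd = pd, threshold = thr, nScored = nSc,
                 fstMultilocus = multi, topFraction = topFraction,
                 estimator = estimator)
}

#' @describeIn fstScan per-pair summary: sites scored, top-percentile
#'   threshold, pdSNP count, mean F_ST over that pair's pdSNPs, and the
#'   genome-wide multi-locus F_ST.
#' @param x an [FstScan-class].
#' @export
setMethod("pairSummary", "FstScan", function(x) {
    meanPd <- vapply(seq_len(nrow(x@pairs)), function(i)
        mean(x@fst[x@pd[, i], i]), numeric(1))
    data.frame(x@pairs,
               nScored = x@nScored,
               threshold = x@threshold,
               nPd = colSums(x@pd),
               meanPdFst = meanPd,
               fstMultilocus = x@fstMultilocus,
               stringsAsFactors = FALSE, row.names = NULL)
})

#' @describeIn fstScan union of the per-pair pdSNP sets, with the number
#'   of pairs selecting each SNP.
#' @export
setMethod("pdUnion", "FstScan", function(x) {
    nPairs <- rowSums(x@pd)
    sel <- nPairs > 0
    data.frame(snpId = snpIds(x)[sel],
               nPairs = as.integer(nPairs[sel]),
               stringsAsFactors = FALSE)
})

#' @describeIn fstScan symmetric distance matrix over populations whose
#'   entries are each pair's mean F_ST over its own pdSNPs (zero
#'   diagonal); errors if a pair is absent.
#' @param union use the global pdSNP union instead of each pair's own top
#'   set when averaging.
#' @export
setMethod("meanPdFstMatrix", "FstScan", function(x, union = FALSE) {
    pops <- unique(c(x@pairs$popA, x@pairs$popB))
    need <- populationPairs(pops)
    missing <- setdiff(need$label, x@pairs$label)
    if (length(missing))
        stop("missing population pair(s): ",
             paste(missing, collapse = ", "))
    m <- matrix(0, length(pops), length(pops),
                dimnames = list(pops, pops))
    inUnion <- rowSums(x@pd) > 0
    for (i in seq_len(nrow(x@pairs))) {
        sel <- if (union) inUnion & is.finite(x@fst[, i]) else x@pd[, i]
        v <- mean(x@fst[sel, i])
        m[x@pairs$popA[i], x@pairs$popB[i]] <- v
        m[x@pairs$popB[i], x@pairs$popA[i]] <- v
    }
    m
})
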