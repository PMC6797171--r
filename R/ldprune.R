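#' Squared Pearson correlation of genotype dosages
#'
#' r-squared between two dosage vectors over jointly non-missing samples
#' — the conventional unphased-genotype meaning of LD r-squared. A vector
#' with zero variance (monomorphic among the compared samples) has no
#' defined correlation; for pruning purposes that is treated as r² = 0,
#' and this function returns 0 there.
#'
#' @param x,y numeric dosage vectors of equal length (NA = missing).
#' @return squared Pearson correlation in `[0, 1]`.
#' @examples
#' pairwiseR2(c(0, 1, 2, 1), c(0, 1, 2, 1))  # 1
#' pairwiseR2(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0
#' @export
pairwiseR2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) stop("need >= 2 jointly non-missing samples")
    x <- x[ok]; y <- y[ok]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
    stats::cor(x, y)^2
}

#' Greedy windowed LD pruning
#'
#' Thins a SNP set left-to-right along each chromosome: a SNP is kept iff
#' its dosage r-squared with every already-kept SNP within `windowBp`
#' upstream is at most `r2Max`. The output therefore satisfies the
#' verifiable guarantee that no retained pair within the window exceeds
#' the ceiling (auditable with [ldAudit()]). The default parameters are a
#' 1 Mb window with an r-squared ceiling of 0.8. With
#' `victim = "lower-maf"`, when a pair exceeds the ceiling the SNP with
#' the lower minor-allele frequency is removed instead of the later one.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param snps optional character vector restricting pruning to a SNP
#'   subset (default: all sites).
#' @param windowBp window size in bp (default 1e6).
#' @param r2Max r-squared ceiling (default 0.8).
#' @param victim `"first"` (keep earlier SNP, default) or `"lower-maf"`.
#' @param population optional population label; r-squared is then
#'   computed in that population's samples only.
#' @return list with `kept` (character vector of retained SNP ids) and
#'   `report` (data.frame `snpId`, `kept`, `reason`).
#' @export
ldPrune <- function(ge, snps = NULL, windowBp = 1e6, r2Max = 0.8,
                    victim = c("first", "lower-maf"), population = NULL) {
    victim <- match.arg(victim)
    d <- dosages(ge)
    if (!is.null(population))
        d <- d[, populations(ge) == population, drop = FALSE]
    rr <- SummarizedExperiment::rowRanges(ge)
    ids <- snpIds(ge)
    use <- if (is.null(snps)) seq_along(ids) else which(ids %in% snps)
    chrom <- as.character(GenomeInfoDb::seqnames(rr))[use]
    pos <- GenomicRanges::start(rr)[use]
    keptFlag <- rep(TRUE, length(use))
    reason <- rep("kept", length(use))
    maf <- function(v) {
        f <- mean(v, na.rm = TRUE) / 2
        min(f, 1 - f)
    }
    for (chr in unique(chrom)) {
        ci <- which(chrom == chr)      # already in position order
        keptIdx <- integer()
        for (t in ci) {
            lo <- pos[t] - windowBp
            inWin <- keptIdx[pos[keptIdx] >= lo]
            conflict <- NA_integer_
            for (s in rev(inWin)) {
                r2 <- pairwiseR2(d[use[t], ], d[use[s], ])
                if (r2 > r2Max) { conflict <- s; break }
            }
            if (is.na(conflict)) {
                keptIdx <- c(keptIdx, t)
            } else if (victim == "first") {
                keptFlag[t] <- FALSE
                reason[t] <- sprintf("r2>%g with %s", r2Max,
                                     ids[use[conflict]])
            } else {
                if (maf(d[use[t], ]) >= maf(d[use[conflict], ])) {
                    keptFlag[conflict] <- FALSE
                    reason[conflict] <- sprintf("r2>%g with %s (lower maf)",
                                                r2Max, ids[use[t]])
                    keptIdx <- setdiff(keptIdx, conflict)
                    # re-test t against remaining kept SNPs in window
                    inWin2 <- keptIdx[pos[keptIdx] >= lo]
                    ok <- all(vapply(inWin2, function(s2)
                        pairwiseR2(d[use[t], ], d[use[s2], ]) <= r2Max,
                        logical(1)))
                    if (ok) keptIdx <- c(keptIdx, t)
                    else { keptFlag[t] <- FALSE; reason[t] <- "r2 conflict" }
                } else {
                    keptFlag[t] <- FALSE
                    reason[t] <- sprintf("r2>%g with %s (lower maf)", r2Max,
                                         ids[use[conflict]])
                }
            }
        }
    }
    list(kept = ids[use][keptFlag],
         report = data.frame(snpId = ids[use], kept = keptFlag,
                             reason = reason, stringsAsFactors = FALSE))
}

#' Exhaustive post-pruning LD audit
#'
#' Scans every pair of retained SNPs within `windowBp` on the same
#' chromosome and reports the maximum r-squared and the number of pairs
#' above a ceiling — the pruned-set check that no high-LD pair remains.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param kept character vector of retained SNP ids.
#' @param windowBp window size in bp.
#' @param r2Max ceiling used for the violation count.
#' @param population optional population restriction (as in [ldPrune()]).
#' @return list with `maxR2`, `nPairs` (pairs examined) and `nViolations`
#'   (pairs with r-squared above `r2Max`).
#' @export
ldAudit <- function(ge, kept, windowBp = 1e6, r2Max = 0.8,
                    population = NULL) {
    d <- dosages(ge)
    if (!is.null(population))
        d <- d[, populations(ge) == population, drop = FALSE]
    rr <- SummarizedExperiment::rowRanges(ge)
    ids <- snpIds(ge)
    use <- which(ids %in% kept)
    chrom <- as.character(GenomeInfoDb::seqnames(rr))[use]
    pos <- GenomicRanges::start(rr)[use]
    maxR2 <- 0; nPairs <- 0L; nViol <- 0L
    for (chr in unique(chrom)) {
        ci <- which(chrom == chr)
        if (length(ci) < 2) next
        for (a in 2:length(ci)) {
            for (b in seq_len(a - 1)) {
                i <- ci[a]; j <- ci[b]
                if (pos[i] - pos[j] > windowBp) next
                r2 <- pairwiseR2(d[use[i], ], d[use[j], ])
                nPairs <- nPairs + 1L
                maxR2 <- max(maxR2, r2)
                if (r2 > r2Max) nViol <- nViol + 1L
            }
        }
    }
    list(maxR2 = maxR2, nPairs = nPairs, nViolations = nViol)
}
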