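# Fixture builders shared across test files.

# A hand-built GenotypeExperiment from a dosage matrix; positions default to
# 100, 200, ... on one chromosome.
makeGe <- function(dosage, population, chrom = "chr1", pos = NULL,
                   chromLen = 1e6) {
    dosage <- as.matrix(dosage)
    n <- nrow(dosage)
    if (is.null(pos)) pos <- seq_len(n) * 100L
    if (is.null(colnames(dosage)))
        colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
    cl <- stats::setNames(rep(chromLen, length(unique(chrom))),
                          unique(chrom))
    gr <- GenomicRanges::GRanges(
        rep(chrom, length.out = n), IRanges::IRanges(pos, width = 1),
        seqinfo = GenomeInfoDb::Seqinfo(names(cl), unname(cl)))
    S4Vectors::mcols(gr)$ref <- rep("A", n)
    S4Vectors::mcols(gr)$alt <- rep("G", n)
    S4Vectors::mcols(gr)$snpId <- sprintf("s%04d", seq_len(n))
    GenotypeExperiment(dosage, gr, population)
}

# A single gene model (mRNA + exons + CDS) as a feature GRanges.
makeGene <- function(geneId, chrom, strand, txStart, txEnd,
                     exons = NULL, cds = NULL, chromLen = 1e6) {
    if (is.null(exons)) exons <- list(c(txStart, txEnd))
    starts <- c(txStart, vapply(exons, `[`, numeric(1), 1))
    ends <- c(txEnd, vapply(exons, `[`, numeric(1), 2))
    types <- c("mRNA", rep("exon", length(exons)))
    if (!is.null(cds)) {
        starts <- c(starts, vapply(cds, `[`, numeric(1), 1))
        ends <- c(ends, vapply(cds, `[`, numeric(1), 2))
        types <- c(types, rep("CDS", length(cds)))
    }
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(starts, ends), strand = strand,
        seqinfo = GenomeInfoDb::Seqinfo(chrom, chromLen))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        type = types, geneId = geneId,
        ID = paste0(geneId, ".", seq_along(types)),
        Parent = c(NA_character_, rep(paste0(geneId, ".1"),
                                      length(types) - 1L)))
    gr
}

combineGenes <- function(...) {
    suppressWarnings(do.call(c, list(...)))
}

# Weir-Cockerham two-deme theta-hat transcribed independently of the
# package implementation (scalar, follows the published variance-component
# formulas term by term). Serves as the oracle for wcFst.
oracleWcTheta <- function(n1, p1, h1, n2, p2, h2) {
    r <- 2
    nbar <- (n1 + n2) / 2
    CV2num <- (n1 - nbar)^2 + (n2 - nbar)^2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
        ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
}

# Exhaustive two-sided Fisher p by direct enumeration of the
# hypergeometric support with log-binomial coefficients (independent of
# stats::dhyper inside the implementation path).
oracleFisherP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    x <- lo:hi
    lp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
    pObs <- exp(lchoose(m, a) + lchoose(n, c) - lchoose(m + n, k))
    min(1, sum(exp(lp)[exp(lp) <= pObs * (1 + 1e-7)]))
}
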