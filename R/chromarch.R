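#' Per-chromosome differentiation architecture statistics
#'
#' Counts, per chromosome: SNPs, pdSNPs, pf-pdSNPs, genes, pdGenes and
#' pf-pdGenes, with within-chromosome proportions (pdSNPs over that
#' chromosome's SNPs; pdGenes over that chromosome's genes). A
#' chromosome with zero SNPs gets `NA` SNP proportions.
#'
#' @param annotations output of [assignRegions()] (provides each SNP's
#'   chromosome).
#' @param pdIds pdSNP ids (global union).
#' @param pfIds potentially-functional SNP ids; pf-pdSNPs are
#'   `intersect(pdIds, pfIds)`.
#' @param tallies output of [tallyGenes()] (provides gene chromosomes and
#'   pdGene flags); may be `NULL` when no gene models exist.
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @return data.frame, one row per chromosome in `chromLengths` order:
#'   `chrom`, `lengthBp`, `nSnps`, `nPd`, `nPfPd`, `nGenes`, `nPdGenes`,
#'   `nPfPdGenes`, `propPd`, `propPfPd`, `propPdGenes`, `propPfPdGenes`.
#' @export
perChromosomeStats <- function(annotations, pdIds, pfIds, tallies,
                               chromLengths) {
    chroms <- names(chromLengths)
    pfpdIds <- intersect(pdIds, pfIds)
    cnt <- function(ids) {
        sub <- annotations[annotations$snpId %in% ids, , drop = FALSE]
        table(factor(sub$chrom, levels = chroms))
    }
    nSnps <- table(factor(annotations$chrom, levels = chroms))
    nPd <- cnt(pdIds)
    nPfPd <- cnt(pfpdIds)
    if (!is.null(tallies) && nrow(tallies)) {
        nGenes <- table(factor(tallies$chrom, levels = chroms))
        nPdG <- table(factor(tallies$chrom[tallies$pdGene],
                             levels = chroms))
        nPfPdG <- table(factor(tallies$chrom[tallies$pfPdGene],
                               levels = chroms))
    } else {
        nGenes <- nPdG <- nPfPdG <- table(factor(character(),
                                                 levels = chroms))
    }
    div <- function(a, b) ifelse(b > 0, as.numeric(a) / as.numeric(b),
                                 NA_real_)
    data.frame(chrom = chroms,
               lengthBp = as.numeric(chromLengths),
               nSnps = as.integer(nSnps),
               nPd = as.integer(nPd),
               nPfPd = as.integer(nPfPd),
               nGenes = as.integer(nGenes),
               nPdGenes = as.integer(nPdG),
               nPfPdGenes = as.integer(nPfPdG),
               propPd = div(nPd, nSnps),
               propPfPd = div(nPfPd, nSnps),
               propPdGenes = div(nPdG, nGenes),
               propPfPdGenes = div(nPfPdG, nGenes),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Ordinary least-squares fit with slope test
#'
#' Simple linear regression of `y` on `x` via `stats::lm`: returns the
#' slope, intercept, coefficient of determination and the slope t-test
#' p-value (n - 2 df). Requires at least 3 points and non-constant `x`.
#'
#' @param x,y numeric vectors of equal length.
#' @return list `slope`, `intercept`, `rSquared`, `pValue`, `n`.
#' @examples
#' olsFit(1:3, c(2, 4, 6))$rSquared  # 1
#' @export
olsFit <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 points")
    if (stats::var(x) == 0) stop("x must not be constant")
    if (stats::var(y) == 0)   # flat response: zero-slope fit, R^2 = 0 by the
        return(list(slope = 0, intercept = mean(y), rSquared = 0,
                    pValue = 1, n = length(x)))  # SS_tot convention
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         rSquared = sm$r.squared,
         pValue = unname(sm$coefficients[2, 4]),
         n = length(x))
}

#' Chromosome-architecture regression report
#'
#' The six regressions relating differentiation to chromosome
#' architecture: pdSNP and pf-pdSNP proportions against chromosome
#' length; pdGene and pf-pdGene proportions against chromosome length;
#' and pdGene and pf-pdGene proportions against the gene count per
#' chromosome. Each row reports slope, R-squared and the slope p-value
#' at full precision.
#'
#' @param stats output of [perChromosomeStats()]; may be the pruned or
#'   unpruned SNP set — the table structure is identical.
#' @return data.frame `response`, `predictor`, `slope`, `intercept`,
#'   `rSquared`, `pValue`, `n`.
#' @export
architectureReport <- function(stats) {
    specs <- list(
        c("propPd", "lengthBp"),
        c("propPfPd", "lengthBp"),
        c("propPdGenes", "lengthBp"),
        c("propPfPdGenes", "lengthBp"),
        c("propPdGenes", "nGenes"),
        c("propPfPdGenes", "nGenes"))
    rows <- lapply(specs, function(sp) {
        fit <- tryCatch(olsFit(stats[[sp[2]]], stats[[sp[1]]]),
                        error = function(e)
                            list(slope = NA_real_, intercept = NA_real_,
                                 rSquared = NA_real_, pValue = NA_real_,
                                 n = sum(is.finite(stats[[sp[1]]]))))
        data.frame(response = sp[1], predictor = sp[2],
                   slope = fit$slope, intercept = fit$intercept,
                   rSquared = fit$rSquared, pValue = fit$pValue,
                   n = fit$n, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
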