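#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: with margins fixed,
#' sum the hypergeometric probabilities of every table whose point
#' probability does not exceed the observed one (within a relative
#' tolerance of 1e-7 for floating-point ties). The reported effect is the
#' sample (cross-product) odds ratio `a*d / (b*c)`, with the
#' Haldane-Anscombe +0.5 correction applied to all four cells iff any
#' cell is zero — matching how printed odds ratios are conventionally
#' formed, rather than the conditional-MLE odds ratio.
#'
#' @param a,b,c,d non-negative counts: rows are the two SNP categories,
#'   columns in-region vs out-of-region.
#' @return list with `oddsRatio` and `pValue`.
#' @examples
#' fisherTest2x2(5, 5, 5, 5)  # OR 1, p 1
#' @export
fisherTest2x2 <- function(a, b, c, d) {
    if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
        stop("all margins of the 2x2 table must be positive")
    m <- a + b          # row 1 total
    n <- c + d          # row 2 total
    k <- a + c          # column 1 total
    lo <- max(0L, k - n); hi <- min(k, m)
    x <- lo:hi
    probs <- stats::dhyper(x, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
    orr <- if (a == 0 || b == 0 || c == 0 || d == 0)
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    else (a * d) / (b * c)
    list(oddsRatio = orr, pValue = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values (delegates to
#' `stats::p.adjust(method = "BH")`); input order is preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, elementwise >= the raw values.
#' @export
bhAdjust <- function(p) {
    .assertProb(p, "p")
    stats::p.adjust(p, method = "BH")
}

#' Region odds-ratio battery
#'
#' For each genic region and each requested contrast of two SNP
#' categories, builds the 2x2 table of in-region / out-of-region counts
#' and runs [fisherTest2x2()]. The special category `"genome"` is the
#' region nucleotide composition (bp shares) scaled to the total SNP
#' count of the reference category, so "SNP share vs genomic share"
#' contrasts can be tested with the same machinery. P-values are
#' BH-adjusted across the battery.
#'
#' @param composition output of [compositionTable()] (counts per
#'   category and region).
#' @param contrasts list of 2-element character vectors
#'   `c(category1, category2)`; e.g. `list(c("pd", "all"))`. Category
#'   names must appear in `composition` (or be `"genome"`).
#' @param genomeComposition optional output of [regionComposition()],
#'   required when a contrast uses `"genome"`.
#' @param regions region labels to test (default: the five genic labels
#'   plus intergenic).
#' @return data.frame `contrast`, `region`, `a`, `b`, `c`, `d`,
#'   `oddsRatio`, `pRaw`, `pAdjusted`.
#' @export
regionOrBattery <- function(composition, contrasts,
                            genomeComposition = NULL,
                            regions = c(.REGION_LABELS, "intergenic")) {
    getCounts <- function(cat, total) {
        if (cat == "genome") {
            if (is.null(genomeComposition))
                stop("contrast uses 'genome' but no genomeComposition given")
            stats::setNames(
                round(genomeComposition$proportion * total),
                genomeComposition$region)
        } else {
            sub <- composition[composition$category == cat, , drop = FALSE]
            if (!nrow(sub)) stop("unknown category: ", cat)
            stats::setNames(sub$count, sub$region)
        }
    }
    rows <- list()
    for (ct in contrasts) {
        tot1 <- sum(composition$count[composition$category == ct[1]])
        if (tot1 == 0 && ct[1] != "genome") {
            warning("category '", ct[1], "' empty; contrast skipped")
            next
        }
        ref <- if (ct[2] == "genome") tot1 else
            sum(composition$count[composition$category == ct[2]])
        if (ref == 0) {
            warning("category '", ct[2], "' empty; contrast skipped")
            next
        }
        c1 <- getCounts(ct[1], tot1)
        c2 <- getCounts(ct[2], ref)
        for (rg in regions) {
            a <- unname(c1[rg]); b <- sum(c1) - a
            cc <- unname(c2[rg]); dd <- sum(c2) - cc
            ft <- tryCatch(fisherTest2x2(a, b, cc, dd),
                           error = function(e) list(oddsRatio = NA_real_,
                                                    pValue = NA_real_))
            rows[[length(rows) + 1L]] <- data.frame(
                contrast = paste(ct, collapse = "_vs_"), region = rg,
                a = a, b = b, c = cc, d = dd,
                oddsRatio = ft$oddsRatio, pRaw = ft$pValue,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$pAdjusted <- NA_real_
    ok <- !is.na(out$pRaw)
    out$pAdjusted[ok] <- bhAdjust(out$pRaw[ok])
    out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per term: the probability of observing
#' at least the seen overlap when drawing `|query|` genes without
#' replacement from the universe. Term gene lists are intersected with
#' the universe; the query must be a subset of the universe. P-values are
#' BH-adjusted across terms; `significant` flags adjusted p < `alpha`.
#'
#' @param query character vector of query gene ids (e.g. enriched
#'   pdGenes).
#' @param termSets named list of gene id vectors (e.g. from
#'   [readGmt()]).
#' @param universe character vector of all eligible gene ids.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame `term`, `overlap`, `termSize`, `querySize`,
#'   `universeSize`, `geneRatio` (overlap/querySize), `fold`
#'   (observed/expected overlap), `pRaw`, `pAdjusted`, `significant`,
#'   ordered by `pAdjusted` then `pRaw`.
#' @examples
#' u <- sprintf("g%02d", 1:20)
#' hypergeomEnrich(u[1:5], list(t1 = u[1:5]), u)$pRaw  # 1/choose(20,5)
#' @export
hypergeomEnrich <- function(query, termSets, universe, alpha = 0.05) {
    if (!length(universe)) stop("universe must be non-empty")
    universe <- unique(universe)
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query genes must be a subset of the universe")
    N <- length(universe)
    nQ <- length(query)
    rows <- lapply(names(termSets), function(tm) {
        tg <- intersect(unique(termSets[[tm]]), universe)
        K <- length(tg)
        k <- length(intersect(tg, query))
        p <- if (K == 0 || nQ == 0) 1 else
            stats::phyper(k - 1, K, N - K, nQ, lower.tail = FALSE)
        data.frame(term = tm, overlap = k, termSize = K, querySize = nQ,
                   universeSize = N,
                   geneRatio = if (nQ > 0) k / nQ else 0,
                   fold = if (K > 0 && nQ > 0) (k / nQ) / (K / N)
                          else NA_real_,
                   pRaw = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$pAdjusted <- bhAdjust(out$pRaw)
    out$significant <- out$pAdjusted < alpha
    out[order(out$pAdjusted, out$pRaw, out$term), , drop = FALSE]
}

#' Per-chromosome gene-set enrichment comparison
#'
#' Runs [hypergeomEnrich()] separately with each chromosome's query genes
#' (e.g. its enriched pd-/pf-pdGenes) against the same term map and
#' universe, and stacks the results into one long-format grid
#' (term x chromosome) ready for dot-plot display. Chromosomes with an
#' empty query yield no rows rather than an error. Significance is
#' adjusted p < `alpha` within each chromosome's term battery.
#'
#' @param queriesByChrom named list: chromosome -> query gene ids.
#' @param termSets named list of gene id vectors.
#' @param universe character vector of all eligible gene ids.
#' @param alpha significance level (default 0.05).
#' @return data.frame as [hypergeomEnrich()] plus a `chrom` column.
#' @export
compareByChromosome <- function(queriesByChrom, termSets, universe,
                                alpha = 0.05) {
    rows <- lapply(names(queriesByChrom), function(chr) {
        q <- intersect(queriesByChrom[[chr]], universe)
        if (!length(q)) return(NULL)
        res <- hypergeomEnrich(q, termSets, universe, alpha = alpha)
        cbind(chrom = chr, res, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(chrom = character(), term = character(),
                          overlap = integer(), termSize = integer(),
                          querySize = integer(), universeSize = integer(),
                          geneRatio = numeric(), fold = numeric(),
                          pRaw = numeric(), pAdjusted = numeric(),
                          significant = logical(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
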