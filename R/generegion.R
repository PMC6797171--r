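#' Region labels in decreasing assignment precedence
#' @keywords internal
.REGION_LABELS <- c("coding", "utr5", "utr3", "promoter", "intron")

#' Derive labeled genic intervals from gene models
#'
#' Expands gene-model features (`mRNA`/`exon`/`CDS` rows with a `geneId`)
#' into labeled interval sets per gene: `coding` (CDS), `utr5`/`utr3`
#' (exonic bases outside the CDS span, sides resolved by strand),
#' `intron` (transcript span minus exons) and `promoter` (the
#' `promoterBp` bases immediately upstream of the transcription start
#' site on the gene's strand; for a minus-strand gene these are the bases
#' with coordinates greater than the TSS). Promoters are truncated at
#' chromosome edges. Multiple transcripts of one gene are merged by
#' union of like intervals, so assignment is gene-keyed.
#'
#' @param models `GRanges` of gene-model features (see
#'   [simulateGeneModels()] / [readGeneModelsGff3()]).
#' @param promoterBp promoter length in bp upstream of the TSS
#'   (default 5000).
#' @return `GRanges` with metadata columns `region` and `geneId`.
#' @export
deriveGeneIntervals <- function(models, promoterBp = 5000) {
    mc <- S4Vectors::mcols(models)
    stopifnot(all(c("type", "geneId") %in% colnames(mc)))
    out <- list()
    for (gid in unique(mc$geneId)) {
        g <- models[mc$geneId == gid]
        gmc <- S4Vectors::mcols(g)
        ex <- GenomicRanges::reduce(g[gmc$type == "exon"])
        tx <- GenomicRanges::reduce(g[gmc$type == "mRNA"])
        if (!length(ex)) ex <- tx
        if (!length(tx)) tx <- range(ex)
        span <- range(c(GenomicRanges::granges(tx),
                        GenomicRanges::granges(ex)))
        if (!all(IRanges::overlapsAny(ex, span)) ||
            min(GenomicRanges::start(ex)) < GenomicRanges::start(span) ||
            max(GenomicRanges::end(ex)) > GenomicRanges::end(span))
            stop("gene ", gid, ": exons outside the transcript span")
        strand <- as.character(GenomicRanges::strand(g))[1]
        cds <- GenomicRanges::reduce(g[gmc$type == "CDS"])
        pieces <- list()
        add <- function(gr, label) {
            if (!length(gr)) return()
            gr <- GenomicRanges::granges(gr)
            S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
                region = label, geneId = gid)
            pieces[[length(pieces) + 1L]] <<- gr
        }
        if (length(cds)) {
            add(cds, "coding")
            cdsLo <- min(GenomicRanges::start(cds))
            cdsHi <- max(GenomicRanges::end(cds))
            left <- GenomicRanges::restrict(ex, end = cdsLo - 1L)
            right <- GenomicRanges::restrict(ex, start = cdsHi + 1L)
            if (strand == "-") { tmp <- left; left <- right; right <- tmp }
            add(left, "utr5")
            add(right, "utr3")
        }
        add(GenomicRanges::setdiff(span, GenomicRanges::granges(ex),
                                   ignore.strand = TRUE), "intron")
        spanStranded <- span
        GenomicRanges::strand(spanStranded) <- strand
        prom <- suppressWarnings(
            GenomicRanges::promoters(spanStranded,
                                     upstream = promoterBp,
                                     downstream = 0))
        prom <- GenomicRanges::trim(
            GenomicRanges::restrict(prom, start = 1L))
        GenomicRanges::strand(prom) <- "*"
        add(prom, "promoter")
        out[[length(out) + 1L]] <- do.call(c, pieces)
    }
    if (!length(out)) {
        g <- GenomicRanges::GRanges(
            seqinfo = GenomeInfoDb::seqinfo(models))
        S4Vectors::mcols(g) <- S4Vectors::DataFrame(
            region = character(), geneId = character())
        return(g)
    }
    res <- do.call(c, out)
    GenomicRanges::strand(res) <- "*"
    GenomicRanges::sort(res, ignore.strand = TRUE)
}

#' Assign one region label per SNP
#'
#' Overlaps SNP sites with labeled genic intervals and resolves each SNP
#' to exactly one label. When a SNP overlaps several labels (overlapping
#' genes or features), a fixed precedence decides — by default
#' `coding > utr5 > utr3 > promoter > intron`; remaining ties go to the
#' lexicographically smallest gene id. SNPs overlapping nothing are
#' `intergenic` with no gene.
#'
#' @param sites a [GenotypeExperiment-class] or a `GRanges` with a
#'   `snpId` metadata column.
#' @param intervals labeled intervals from [deriveGeneIntervals()].
#' @param precedence character vector ordering the genic labels.
#' @return data.frame `snpId`, `chrom`, `pos`, `region`, `geneId`
#'   (`NA` for intergenic), one row per SNP, in site order.
#' @export
assignRegions <- function(sites, intervals,
                          precedence = .REGION_LABELS) {
    if (methods::is(sites, "GenotypeExperiment"))
        sites <- SummarizedExperiment::rowRanges(sites)
    stopifnot(setequal(precedence, .REGION_LABELS))
    ids <- S4Vectors::mcols(sites)$snpId
    region <- rep("intergenic", length(sites))
    gene <- rep(NA_character_, length(sites))
    if (length(intervals)) {
        ov <- GenomicRanges::findOverlaps(sites, intervals,
                                          ignore.strand = TRUE)
        if (length(ov)) {
            qh <- S4Vectors::queryHits(ov)
            sh <- S4Vectors::subjectHits(ov)
            rk <- match(S4Vectors::mcols(intervals)$region[sh], precedence)
            gid <- S4Vectors::mcols(intervals)$geneId[sh]
            o <- order(qh, rk, gid)
            first <- !duplicated(qh[o])
            qf <- qh[o][first]
            region[qf] <- precedence[rk[o][first]]
            gene[qf] <- gid[o][first]
        }
    }
    data.frame(snpId = ids,
               chrom = as.character(GenomeInfoDb::seqnames(sites)),
               pos = GenomicRanges::start(sites),
               region = region, geneId = gene,
               stringsAsFactors = FALSE)
}

#' Gene-level pdSNP tallies and pdGene flags
#'
#' Counts, per gene, the genic SNPs that are population-differentiated
#' (pdSNPs) and those that are both differentiated and potentially
#' functional (pf-pdSNPs), and sets the derived flags: a pdGene carries at
#' least one pdSNP, an enriched pdGene at least three (analogously for
#' pf-pdGenes). Intergenic SNPs never count toward a gene.
#'
#' @param annotations output of [assignRegions()].
#' @param pdIds character vector of pdSNP ids.
#' @param pfIds character vector of potentially-functional SNP ids.
#' @param enrichedMin pdSNP count that makes a gene "enriched"
#'   (default 3).
#' @return data.frame per gene: `geneId`, `chrom`, `nSnps`, `nPd`,
#'   `nPfPd`, `pdGene`, `pfPdGene`, `enrichedPdGene`, `enrichedPfPdGene`.
#' @export
tallyGenes <- function(annotations, pdIds, pfIds = character(),
                       enrichedMin = 3L) {
    genic <- annotations[!is.na(annotations$geneId), , drop = FALSE]
    if (!nrow(genic))
        return(data.frame(geneId = character(), chrom = character(),
                          nSnps = integer(), nPd = integer(),
                          nPfPd = integer(), pdGene = logical(),
                          pfPdGene = logical(), enrichedPdGene = logical(),
                          enrichedPfPdGene = logical(),
                          stringsAsFactors = FALSE))
    df <- data.frame(geneId = genic$geneId, chrom = genic$chrom,
                     nSnps = 1L,
                     nPd = as.integer(genic$snpId %in% pdIds),
                     stringsAsFactors = FALSE)
    df$nPfPd <- as.integer(df$nPd == 1L & genic$snpId %in% pfIds)
    agg <- stats::aggregate(cbind(nSnps, nPd, nPfPd) ~ geneId + chrom,
                            data = df, FUN = sum)
    agg <- agg[order(agg$geneId), , drop = FALSE]
    rownames(agg) <- NULL
    agg$pdGene <- agg$nPd >= 1L
    agg$pfPdGene <- agg$nPfPd >= 1L
    agg$enrichedPdGene <- agg$nPd >= enrichedMin
    agg$enrichedPfPdGene <- agg$nPfPd >= enrichedMin
    agg
}

#' Region composition of SNP categories
#'
#' Tabulates, for each SNP category (e.g. all SNPs, pdSNPs, pf-pdSNPs),
#' how many SNPs fall in each region label, with proportions summing to 1
#' within a category. Empty categories produce a zero row-set with a
#' warning.
#'
#' @param annotations output of [assignRegions()].
#' @param categories named list of SNP id vectors; `NULL` entries mean
#'   "all annotated SNPs".
#' @return data.frame `category`, `region`, `count`, `proportion`.
#' @export
compositionTable <- function(annotations,
                             categories = list(all = NULL)) {
    labels <- c(.REGION_LABELS, "intergenic")
    out <- lapply(names(categories), function(nm) {
        ids <- categories[[nm]]
        sub <- if (is.null(ids)) annotations else
            annotations[annotations$snpId %in% ids, , drop = FALSE]
        if (!nrow(sub))
            warning("category '", nm, "' is empty")
        cnt <- table(factor(sub$region, levels = labels))
        tot <- sum(cnt)
        data.frame(category = nm, region = labels,
                   count = as.integer(cnt),
                   proportion = if (tot > 0) as.numeric(cnt) / tot
                                else rep(0, length(labels)),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Nucleotide (bp) composition of region labels
#'
#' Shares of the genome occupied by each region label, resolving overlaps
#' with the same precedence as [assignRegions()] so that SNP shares and
#' bp shares are directly comparable: under uniform SNP placement each
#' region's SNP share converges to its bp share — the null that the
#' region odds-ratio battery tests against.
#'
#' @param intervals labeled intervals from [deriveGeneIntervals()].
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param precedence label precedence for overlap resolution.
#' @return data.frame `region`, `bp`, `proportion` (over the genome).
#' @export
regionComposition <- function(intervals, chromLengths,
                              precedence = .REGION_LABELS) {
    total <- sum(chromLengths)
    covered <- GenomicRanges::GRanges()
    bp <- stats::setNames(numeric(length(precedence) + 1L),
                          c(precedence, "intergenic"))
    for (lab in precedence) {
        gr <- GenomicRanges::reduce(
            intervals[S4Vectors::mcols(intervals)$region == lab])
        gr <- GenomicRanges::setdiff(gr, covered, ignore.strand = TRUE)
        bp[lab] <- sum(GenomicRanges::width(gr))
        covered <- GenomicRanges::reduce(
            c(covered, gr), ignore.strand = TRUE)
    }
    bp["intergenic"] <- total - sum(bp[precedence])
    data.frame(region = names(bp), bp = as.numeric(bp),
               proportion = as.numeric(bp) / total,
               stringsAsFactors = FALSE)
}
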