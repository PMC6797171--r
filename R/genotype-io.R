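#' Write a GenotypeExperiment as VCF 4.2
#'
#' Serializes the sites and diploid GT calls (unphased, `0/0`/`0/1`/`1/1`,
#' missing as `./.`) with contig header lines carrying chromosome lengths.
#' Output is deterministic: the same object always yields byte-identical
#' files.
#'
#' @param ge a [GenotypeExperiment-class].
#' @param path output file path (plain text `.vcf`).
#' @param source optional string recorded in a `##source=` header line
#'   (e.g. the simulation seed).
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(ge, path, source = NULL) {
    rr <- SummarizedExperiment::rowRanges(ge)
    mc <- S4Vectors::mcols(rr)
    sl <- GenomeInfoDb::seqlengths(rr)
    hdr <- c("##fileformat=VCFv4.2",
             if (!is.null(source)) paste0("##source=", source),
             sprintf("##contig=<ID=%s,length=%d>", names(sl), sl),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(ge)), collapse = "\t"))
    d <- dosages(ge)
    gtMap <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(d), ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gtMap[d[ok] + 1L]
    body <- paste(as.character(GenomeInfoDb::seqnames(rr)),
                  GenomicRanges::start(rr), mc$snpId, mc$ref, mc$alt,
                  ".", ".", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(hdr, body), con, sep = "\n")
    invisible(path)
}

#' Read a VCF into a GenotypeExperiment
#'
#' Reads via `VariantAnnotation::readVcf`. Only biallelic SNVs are kept;
#' multi-allelic records are skipped and their count reported in a message.
#' Missing genotypes are preserved as `NA`. Phased and unphased diploid GT
#' calls are both accepted.
#'
#' @param path VCF file.
#' @param panel data.frame mapping `sample` to `population` (see
#'   [readPanel()]).
#' @param unmatched what to do with VCF samples absent from the panel:
#'   `"error"` (default) or `"drop"`.
#' @return A [GenotypeExperiment-class].
#' @export
readGenotypeVcf <- function(path, panel, unmatched = c("error", "drop")) {
    unmatched <- match.arg(unmatched)
    if (!file.exists(path)) stop("no such VCF file: ", path)
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    altL <- VariantAnnotation::alt(vcf)
    refC <- as.character(VariantAnnotation::ref(vcf))
    biallelic <- S4Vectors::elementNROWS(altL) == 1L
    altC <- rep(NA_character_, length(altL))
    altC[biallelic] <- as.character(unlist(altL[biallelic]))
    snv <- biallelic & nchar(refC) == 1L & !is.na(altC) & nchar(altC) == 1L
    nSkipped <- sum(!snv)
    if (nSkipped > 0)
        message("skipped ", nSkipped, " non-biallelic/non-SNV record(s)")
    vcf <- vcf[snv]
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field")
    lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
             "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_)
    bad <- !(gt %in% names(lut))
    if (any(bad))
        stop("unparseable GT value(s): ",
             paste(utils::head(unique(gt[bad]), 3), collapse = ", "))
    d <- matrix(lut[gt], nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
    samp <- colnames(d)
    known <- samp %in% panel$sample
    if (!all(known)) {
        if (unmatched == "error")
            stop("sample(s) absent from panel: ",
                 paste(utils::head(samp[!known], 5), collapse = ", "))
        d <- d[, known, drop = FALSE]
        samp <- samp[known]
    }
    pop <- panel$population[match(samp, panel$sample)]
    rr <- SummarizedExperiment::rowRanges(vcf)
    sites <- GenomicRanges::granges(rr)
    S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
        ref = refC[snv], alt = altC[snv], snpId = names(rr))
    names(sites) <- NULL
    GenotypeExperiment(d, sites, pop)
}

#' Read / write a sample-to-population panel
#'
#' Two-column headerless TSV (`sample<TAB>population`), the layout
#' distributed with large resequencing-project panels.
#'
#' @param path file path.
#' @return `readPanel`: data.frame `sample`, `population`.
#' @export
readPanel <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("sample", "population"))
    df
}

#' @rdname readPanel
#' @param panel data.frame `sample`, `population`.
#' @export
writePanel <- function(panel, path) {
    utils::write.table(panel[, c("sample", "population")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' Read / write a potentially-functional SNP table
#'
#' Two-column TSV with a header (`snpId<TAB>tag`) mapping SNP ids to
#' functional annotation tags.
#'
#' @param path file path.
#' @return `readPfTable`: data.frame `snpId`, `tag`.
#' @export
readPfTable <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}

#' @rdname readPfTable
#' @param pf data.frame `snpId`, `tag`.
#' @export
writePfTable <- function(pf, path) {
    utils::write.table(pf[, c("snpId", "tag")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write GMT gene-set files
#'
#' `readGmt` delegates to `fgsea::gmtPathways`. `writeGmt` writes one set
#' per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return `readGmt`: named list of gene id vectors.
#' @export
readGmt <- function(path) {
    fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @param sets named list of gene id vectors.
#' @param description description field (recycled).
#' @export
writeGmt <- function(sets, path, description = "na") {
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
        character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    invisible(path)
}

#' Read / write gene models as GFF3
#'
#' Gene models are a flat `GRanges` of `mRNA`, `exon` and `CDS` features
#' with a `geneId` metadata column (the layout produced by
#' [simulateGeneModels()]). I/O goes through `rtracklayer`; GFF3 uses
#' 1-based inclusive coordinates, matching the package's internal
#' convention.
#'
#' @param path file path.
#' @return `readGeneModelsGff3`: a `GRanges` with metadata `type`,
#'   `geneId`, `ID`, `Parent`.
#' @export
readGeneModelsGff3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    keep <- as.character(mc$type) %in% c("mRNA", "exon", "CDS")
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
    par <- if (is.null(mc$Parent)) rep(NA_character_, length(gr)) else
        vapply(as.list(mc$Parent), function(p)
            if (length(p)) p[[1]] else NA_character_, character(1))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        type = as.character(mc$type),
        geneId = as.character(mc$geneId),
        ID = if (is.null(mc$ID)) NA_character_ else as.character(mc$ID),
        Parent = par)
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname readGeneModelsGff3
#' @param models `GRanges` of gene-model features (`type`, `geneId`, `ID`,
#'   `Parent` metadata).
#' @export
writeGeneModelsGff3 <- function(models, path) {
    mc <- S4Vectors::mcols(models)
    if (is.null(mc$phase)) {
        ph <- rep(NA_integer_, length(models))
        ph[mc$type == "CDS"] <- 0L
        S4Vectors::mcols(models)$phase <- ph
    }
    rtracklayer::export(models, path, format = "gff3")
    invisible(path)
}
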