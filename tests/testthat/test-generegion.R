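test_that("promoters are the 5 kb immediately upstream of the TSS, strand-aware", {
    plus <- makeGene("gp", "chr1", "+", 10001, 12000,
                     exons = list(c(10001, 12000)),
                     cds = list(c(10101, 11900)), chromLen = 1e6)
    iv <- deriveGeneIntervals(plus)
    prom <- iv[S4Vectors::mcols(iv)$region == "promoter"]
    expect_identical(GenomicRanges::start(prom), 5001L)
    expect_identical(GenomicRanges::end(prom), 10000L)

    minus <- makeGene("gm", "chr1", "-", 8000, 10000,
                      exons = list(c(8000, 10000)),
                      cds = list(c(8100, 9900)), chromLen = 1e6)
    iv <- deriveGeneIntervals(minus)
    prom <- iv[S4Vectors::mcols(iv)$region == "promoter"]
    expect_identical(GenomicRanges::start(prom), 10001L)
    expect_identical(GenomicRanges::end(prom), 15000L)

    # truncation at the chromosome start
    near <- makeGene("gn", "chr1", "+", 2001, 4000,
                     exons = list(c(2001, 4000)),
                     cds = list(c(2101, 3900)), chromLen = 1e6)
    prom <- deriveGeneIntervals(near)
    prom <- prom[S4Vectors::mcols(prom)$region == "promoter"]
    expect_identical(GenomicRanges::start(prom), 1L)
    expect_identical(GenomicRanges::end(prom), 2000L)
})

test_that("UTR sides follow strand and single-exon genes have no introns", {
    g <- makeGene("g1", "chr1", "-", 1000, 2000,
                  exons = list(c(1000, 1400), c(1600, 2000)),
                  cds = list(c(1200, 1400), c(1600, 1800)))
    iv <- deriveGeneIntervals(g)
    reg <- S4Vectors::mcols(iv)$region
    # on the minus strand the 5' UTR sits at higher coordinates
    utr5 <- iv[reg == "utr5"]; utr3 <- iv[reg == "utr3"]
    expect_true(all(GenomicRanges::start(utr5) > 1800))
    expect_true(all(GenomicRanges::end(utr3) < 1200))
    intr <- iv[reg == "intron"]
    expect_identical(GenomicRanges::start(intr), 1401L)
    expect_identical(GenomicRanges::end(intr), 1599L)

    single <- makeGene("g2", "chr1", "+", 5000, 6000,
                       exons = list(c(5000, 6000)),
                       cds = list(c(5100, 5900)))
    iv <- deriveGeneIntervals(single)
    expect_identical(sum(S4Vectors::mcols(iv)$region == "intron"), 0L)
})

test_that("promoter intervals never overlap their own transcript span", {
    models <- simulateGeneModels(c(chr1 = 3e6, chr2 = 2e6), 30, seed = 71)
    iv <- deriveGeneIntervals(models)
    mc <- S4Vectors::mcols(iv)
    mmc <- S4Vectors::mcols(models)
    for (gid in unique(mc$geneId)) {
        prom <- iv[mc$region == "promoter" & mc$geneId == gid]
        tx <- models[mmc$type == "mRNA" & mmc$geneId == gid]
        expect_identical(
            length(GenomicRanges::intersect(
                GenomicRanges::granges(prom), GenomicRanges::granges(tx),
                ignore.strand = TRUE)), 0L)
    }
})

test_that("region assignment applies the documented precedence", {
    # gene X: intron covers 2000-2999; gene Y overlapping with CDS there
    gx <- makeGene("gX", "chr1", "+", 1000, 4000,
                   exons = list(c(1000, 1999), c(3000, 4000)),
                   cds = list(c(1100, 1999), c(3000, 3900)))
    gy <- makeGene("gY", "chr1", "+", 1800, 2600,
                   exons = list(c(1800, 2600)),
                   cds = list(c(1900, 2500)))
    iv <- deriveGeneIntervals(combineGenes(gx, gy))
    sites <- makeGe(matrix(0:1, 2, 2), population = c("A", "B"),
                    pos = c(2200L, 9000L))
    ann <- assignRegions(sites, iv)
    expect_identical(ann$region[1], "coding")
    expect_identical(ann$geneId[1], "gY")
    # 6000 bp upstream of the only gene: outside the 5 kb promoter
    expect_identical(ann$region[2], "intergenic")
    expect_true(is.na(ann$geneId[2]))
})

test_that("assignment matches a brute-force all-overlaps scan", {
    models <- simulateGeneModels(c(chr1 = 1e6), 25, seed = 73)
    iv <- deriveGeneIntervals(models)
    set.seed(74)
    pos <- sort(sample.int(1e6, 400))
    sites <- makeGe(matrix(0L, 400, 2), population = c("A", "B"),
                    pos = pos)
    ann <- assignRegions(sites, iv)
    prec <- c("coding", "utr5", "utr3", "promoter", "intron")
    for (i in sample(400, 60)) {
        hits <- which(GenomicRanges::start(iv) <= pos[i] &
                          GenomicRanges::end(iv) >= pos[i])
        if (!length(hits)) {
            expect_identical(ann$region[i], "intergenic")
        } else {
            rk <- match(S4Vectors::mcols(iv)$region[hits], prec)
            best <- hits[rk == min(rk)]
            expect_identical(ann$region[i], prec[min(rk)])
            expect_identical(ann$geneId[i],
                             min(S4Vectors::mcols(iv)$geneId[best]))
        }
    }
    # conservation: every SNP gets exactly one label
    expect_identical(nrow(ann), 400L)
    expect_identical(sum(table(ann$region)), 400L)
})

test_that("gene tallies implement the >=1 and >=3 thresholds", {
    ann <- data.frame(
        snpId = sprintf("s%d", 1:8),
        chrom = "chr1", pos = 1:8,
        region = c(rep("coding", 5), "intron", "promoter", "intergenic"),
        geneId = c(rep("gA", 5), "gB", "gB", NA),
        stringsAsFactors = FALSE)
    pd <- c("s1", "s2", "s3", "s6", "s8")
    pf <- c("s1", "s2", "s6", "s8")
    tal <- tallyGenes(ann, pd, pf)
    a <- tal[tal$geneId == "gA", ]
    expect_identical(a$nPd, 3L)
    expect_identical(a$nPfPd, 2L)
    expect_true(a$pdGene && a$enrichedPdGene && a$pfPdGene)
    expect_false(a$enrichedPfPdGene)
    b <- tal[tal$geneId == "gB", ]
    expect_identical(b$nPd, 1L)
    expect_true(b$pdGene && !b$enrichedPdGene)
    # intergenic pdSNP s8 counts toward no gene
    expect_identical(sum(tal$nPd), 4L)
})

test_that("tallies equal a naive per-gene recount on simulated data", {
    models <- simulateGeneModels(c(chr1 = 5e5), 15, seed = 79)
    iv <- deriveGeneIntervals(models)
    set.seed(80)
    pos <- sort(sample.int(5e5, 300))
    sites <- makeGe(matrix(0L, 300, 2), population = c("A", "B"),
                    pos = pos, chromLen = 5e5)
    ann <- assignRegions(sites, iv)
    pd <- sample(ann$snpId, 80)
    pf <- sample(ann$snpId, 50)
    tal <- tallyGenes(ann, pd, pf)
    for (gid in tal$geneId) {
        sub <- ann[!is.na(ann$geneId) & ann$geneId == gid, ]
        expect_identical(tal$nPd[tal$geneId == gid],
                         sum(sub$snpId %in% pd))
        expect_identical(tal$nPfPd[tal$geneId == gid],
                         sum(sub$snpId %in% pd & sub$snpId %in% pf))
    }
})

test_that("composition tables count and normalize per category", {
    ann <- data.frame(
        snpId = sprintf("s%d", 1:12),
        chrom = "chr1", pos = 1:12,
        region = c("coding", "coding", "utr5", "utr3", "utr3", "promoter",
                   "intron", "intron", "intron", "intergenic",
                   "intergenic", "intergenic"),
        geneId = c(rep("g1", 9), NA, NA, NA),
        stringsAsFactors = FALSE)
    pd <- c("s1", "s4", "s10")
    comp <- compositionTable(ann, list(all = NULL, pd = pd))
    allRows <- comp[comp$category == "all", ]
    expect_identical(sum(allRows$count), 12L)
    expect_equal(sum(allRows$proportion), 1)
    expect_identical(allRows$count[allRows$region == "intron"], 3L)
    pdRows <- comp[comp$category == "pd", ]
    expect_identical(pdRows$count[pdRows$region == "coding"], 1L)
    expect_identical(pdRows$count[pdRows$region == "utr3"], 1L)
    expect_identical(pdRows$count[pdRows$region == "intergenic"], 1L)
    expect_equal(sum(pdRows$proportion), 1)
    expect_warning(compositionTable(ann, list(none = "absent")), "empty")

    # all-intergenic input: genic fraction zero
    ann2 <- ann; ann2$region <- "intergenic"; ann2$geneId <- NA
    comp2 <- compositionTable(ann2)
    expect_identical(comp2$count[comp2$region == "intergenic"], 12L)
    expect_equal(comp2$proportion[comp2$region == "intergenic"], 1)
})

test_that("under uniform placement each region's SNP share matches its bp share", {
    models <- simulateGeneModels(c(chr1 = 2e6, chr2 = 1e6), 40, seed = 83)
    iv <- deriveGeneIntervals(models)
    cl <- c(chr1 = 2e6, chr2 = 1e6)
    bp <- regionComposition(iv, cl)
    set.seed(84)
    n <- 50000
    chrom <- sample(names(cl), n, replace = TRUE, prob = cl / sum(cl))
    pos <- vapply(chrom, function(ch) sample.int(cl[[ch]], 1), numeric(1))
    o <- order(match(chrom, names(cl)), pos)
    sites <- GenomicRanges::GRanges(
        chrom[o], IRanges::IRanges(pos[o], width = 1),
        seqinfo = GenomeInfoDb::Seqinfo(names(cl), unname(cl)))
    S4Vectors::mcols(sites)$snpId <- sprintf("u%05d", seq_len(n))
    S4Vectors::mcols(sites)$ref <- "A"; S4Vectors::mcols(sites)$alt <- "G"
    ann <- assignRegions(sites, iv)
    comp <- compositionTable(ann)
    for (rg in bp$region) {
        share <- bp$proportion[bp$region == rg]
        snpShare <- comp$proportion[comp$region == rg]
        tol <- 5 * sqrt(share * (1 - share) / n) + 1e-4
        expect_lt(abs(snpShare - share), max(tol, 0.01))
    }
})
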