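test_that("Balding-Nichols draws have the right degenerate case, mean and spread", {
    expect_equal(drawBaldingNicholsFreqs(0.3, 0, 4), rep(0.3, 4))
    expect_error(drawBaldingNicholsFreqs(0, 0.1, 2), "strictly in")
    expect_error(drawBaldingNicholsFreqs(1, 0.1, 2), "strictly in")
    expect_error(drawBaldingNicholsFreqs(0.5, 1, 2), "F must")

    set.seed(11)
    draws <- drawBaldingNicholsFreqs(rep(0.5, 20000), 0.1, 2)
    expect_true(all(draws >= 0 & draws <= 1))
    expect_equal(mean(draws), 0.5, tolerance = 0.01)

    # parametric differentiation of independent pairs recovers F; the
    # per-locus ratios are combined as sum(num)/sum(den), the standard
    # multi-locus convention
    set.seed(12)
    p <- drawBaldingNicholsFreqs(rep(0.5, 10000), 0.2, 2)
    num <- (p[, 1] - p[, 2])^2
    den <- p[, 1] * (1 - p[, 2]) + p[, 2] * (1 - p[, 1])
    expect_equal(sum(num) / sum(den), 0.2, tolerance = 0.02)
})

test_that("genotype simulation is seed-deterministic down to the VCF bytes", {
    cfg <- simulationConfig(nPops = 2, samplesPerPop = 5, nSnps = 60,
                            chromLengths = c(chr1 = 5e5, chr2 = 3e5),
                            fstTarget = 0.1, seed = 42)
    f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
    writeGenotypeVcf(simulateGenotypes(cfg)$genotypes, f1, source = "s42")
    writeGenotypeVcf(simulateGenotypes(cfg)$genotypes, f2, source = "s42")
    expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
    unlink(c(f1, f2))
})

test_that("zero requested SNPs yields empty but valid outputs", {
    cfg <- simulationConfig(nPops = 2, samplesPerPop = 3, nSnps = 0,
                            chromLengths = c(chr1 = 1e5), seed = 1)
    sim <- simulateGenotypes(cfg)
    expect_s4_class(sim$genotypes, "GenotypeExperiment")
    expect_identical(nrow(sim$genotypes), 0L)
    expect_identical(nrow(sim$panel), 6L)
})

test_that("undifferentiated populations give near-zero genome-wide F_ST", {
    cfg <- simulationConfig(nPops = 2, samplesPerPop = 50, nSnps = 10000,
                            chromLengths = c(chr1 = 5e7), fstTarget = 0,
                            seed = 7)
    sim <- simulateGenotypes(cfg)
    ac <- alleleCounts(sim$genotypes)
    sc <- fstScan(subsetSites(ac, filterMonomorphic(ac)))
    expect_lt(abs(pairSummary(sc)$fstMultilocus), 0.01)
})

test_that("population sample frequencies converge to the planted truth", {
    cfg <- simulationConfig(nPops = 2, samplesPerPop = 500, nSnps = 400,
                            chromLengths = c(chr1 = 1e6), fstTarget = 0.1,
                            seed = 5)
    sim <- simulateGenotypes(cfg)
    f <- alleleFreq(alleleCounts(sim$genotypes))
    err <- abs(f - sim$truth$popFreq)
    # binomial noise at 1000 alleles: nearly all sites inside +-0.05
    expect_gte(mean(err < 0.05), 0.99)
    expect_lt(mean(err), 0.02)
})

test_that("LD blocks produce high within-block and low between-block r2", {
    cfg <- simulationConfig(nPops = 1, samplesPerPop = 60, nSnps = 200,
                            chromLengths = c(chr1 = 1e7),
                            ldBlockSize = 10, seed = 9)
    sim <- simulateGenotypes(cfg)
    d <- dosages(sim$genotypes)
    blk <- sim$truth$blockId
    within <- between <- numeric()
    for (i in seq_len(nrow(d) - 1)) {
        r2 <- tryCatch(pairwiseR2(d[i, ], d[i + 1, ]), error = function(e) NA)
        if (is.na(r2)) next
        if (blk[i] == blk[i + 1]) within <- c(within, r2)
        else between <- c(between, r2)
    }
    expect_gt(mean(within), mean(between))
    expect_gt(mean(within), 0.5)
    expect_lt(mean(between), 0.2)
})

test_that("simulated gene models are structurally sound and round-trip", {
    expect_length(simulateGeneModels(c(chr1 = 1e4), 0), 0)

    models <- simulateGeneModels(c(chr1 = 2e6, chr2 = 1e6), 5, seed = 21)
    mc <- S4Vectors::mcols(models)
    expect_identical(length(unique(mc$geneId)), 5L)
    for (gid in unique(mc$geneId)) {
        g <- models[mc$geneId == gid]
        tx <- g[S4Vectors::mcols(g)$type == "mRNA"]
        cds <- g[S4Vectors::mcols(g)$type == "CDS"]
        ex <- g[S4Vectors::mcols(g)$type == "exon"]
        expect_length(tx, 1)
        expect_gte(length(ex), 1)
        # CDS and exons inside the transcript span
        expect_true(all(GenomicRanges::start(cds) >=
                            GenomicRanges::start(tx)))
        expect_true(all(GenomicRanges::end(cds) <= GenomicRanges::end(tx)))
        # exons do not overlap each other
        expect_identical(length(GenomicRanges::reduce(ex)), length(ex))
    }
    path <- tempfile(fileext = ".gff3")
    suppressWarnings(writeGeneModelsGff3(models, path))
    back <- readGeneModelsGff3(path)
    expect_identical(length(back), length(models))
    expect_identical(GenomicRanges::start(back), GenomicRanges::start(models))
    expect_identical(GenomicRanges::end(back), GenomicRanges::end(models))
    expect_identical(S4Vectors::mcols(back)$geneId,
                     S4Vectors::mcols(models)$geneId)
    expect_identical(as.character(GenomicRanges::strand(back)),
                     as.character(GenomicRanges::strand(models)))
    unlink(path)
})

test_that("a gene that cannot fit on its chromosome is skipped with a warning", {
    w <- capture_warnings(
        models <- simulateGeneModels(c(tiny = 500), 3,
                                     geneLengthRange = c(2000, 3000),
                                     seed = 2))
    expect_length(w, 3)
    expect_true(all(grepl("too short", w)))
    expect_length(models, 0)
})

test_that("pf annotation covers the requested fraction deterministically", {
    ids <- sprintf("snp%05d", 1:1000)
    pf <- simulatePfAnnotation(ids, fraction = 0.1, seed = 3)
    expect_identical(nrow(pf), 100L)
    expect_true(all(pf$snpId %in% ids))
    expect_identical(pf, simulatePfAnnotation(ids, fraction = 0.1, seed = 3))
})

test_that("gene-set simulation plants an enriched set and is seed-stable", {
    u <- sprintf("g%03d", 1:200)
    diff <- u[1:40]
    gs <- simulateGeneSets(u, diff, nSets = 10, plantedFraction = 0.8,
                           plantedSize = 20, seed = 4)
    expect_identical(gs$planted, "set001")
    expect_gte(length(intersect(gs$sets$set001, diff)), 15)
    gs2 <- simulateGeneSets(u, diff, nSets = 10, plantedFraction = 0.8,
                            plantedSize = 20, seed = 4)
    expect_identical(gs, gs2)
    none <- simulateGeneSets(u, diff, nSets = 10, plantedFraction = 0,
                             seed = 4)
    expect_true(is.na(none$planted))
})
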