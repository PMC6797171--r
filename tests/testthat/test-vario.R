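writeFixtureVcf <- function(lines, path = tempfile(fileext = ".vcf")) {
    writeLines(c("##fileformat=VCFv4.2",
                 "##contig=<ID=chr1,length=100000>",
                 paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                        "Description=\"Genotype\">"),
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT",
                         "i1", "i2", "i3", "i4"), collapse = "\t"),
                 lines), path)
    path
}

fixturePanel <- data.frame(sample = c("i1", "i2", "i3", "i4"),
                           population = c("A", "A", "B", "B"),
                           stringsAsFactors = FALSE)

test_that("a small VCF reads into the expected matrix", {
    path <- writeFixtureVcf(c(
        "chr1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1\t./.",
        "chr1\t200\trs2\tC\tT\t.\t.\t.\tGT\t0|1\t1|1\t0|0\t0/0",
        "chr1\t300\trs3\tG\tA\t.\t.\t.\tGT\t0/0\t0/0\t0/1\t1/1"))
    ge <- readGenotypeVcf(path, fixturePanel)
    expect_identical(dim(ge), c(3L, 4L))
    expect_identical(unname(dosages(ge)[1, ]), c(0L, 1L, 2L, NA))
    expect_identical(unname(dosages(ge)[2, ]), c(1L, 2L, 0L, 0L))
    expect_identical(snpIds(ge), c("rs1", "rs2", "rs3"))
    expect_identical(populations(ge), c("A", "A", "B", "B"))
    unlink(path)
})

test_that("multi-allelic records are skipped and counted", {
    path <- writeFixtureVcf(c(
        "chr1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1\t0/0",
        "chr1\t200\trs2\tC\tT,G\t.\t.\t.\tGT\t0/1\t1/2\t0/0\t0/0",
        "chr1\t300\trs3\tG\tA\t.\t.\t.\tGT\t0/0\t0/0\t0/1\t1/1"))
    expect_message(ge <- readGenotypeVcf(path, fixturePanel),
                   "skipped 1")
    expect_identical(nrow(ge), 2L)
    expect_identical(snpIds(ge), c("rs1", "rs3"))
    unlink(path)
})

test_that("samples missing from the panel error or drop as configured", {
    path <- writeFixtureVcf(
        "chr1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1\t0/0")
    partial <- fixturePanel[1:3, ]
    expect_error(readGenotypeVcf(path, partial), "absent from panel")
    ge <- readGenotypeVcf(path, partial, unmatched = "drop")
    expect_identical(ncol(ge), 3L)
    unlink(path)
})

test_that("VCF write -> read is the identity on dosages and sites", {
    cfg <- simulationConfig(nPops = 2, samplesPerPop = 6, nSnps = 80,
                            chromLengths = c(chr1 = 4e5, chr2 = 2e5),
                            fstTarget = 0.15, seed = 13)
    sim <- simulateGenotypes(cfg)
    path <- tempfile(fileext = ".vcf")
    writeGenotypeVcf(sim$genotypes, path)
    back <- readGenotypeVcf(path, sim$panel)
    expect_identical(unname(dosages(back)), unname(dosages(sim$genotypes)))
    expect_identical(snpIds(back), snpIds(sim$genotypes))
    rr1 <- SummarizedExperiment::rowRanges(back)
    rr2 <- SummarizedExperiment::rowRanges(sim$genotypes)
    expect_identical(GenomicRanges::start(rr1), GenomicRanges::start(rr2))
    expect_identical(S4Vectors::mcols(rr1)$ref, S4Vectors::mcols(rr2)$ref)
    expect_identical(S4Vectors::mcols(rr1)$alt, S4Vectors::mcols(rr2)$alt)
    unlink(path)
})

test_that("allele counts tally alleles, alts and heterozygotes per population", {
    ge <- makeGe(rbind(c(0, 1, 2, 1), c(NA, NA, NA, 1)),
                 population = c("A", "A", "A", "B"))
    ac <- alleleCounts(ge)
    expect_identical(unname(ac@nAlleles[1, ]), c(6, 2))
    expect_identical(unname(ac@altCount[1, ]), c(3, 1))
    expect_identical(unname(ac@hetCount[1, ]), c(1, 1))
    # all-missing population at site 2 -> uncallable (zero alleles)
    expect_identical(unname(ac@nAlleles[2, ]), c(0, 2))
})

test_that("allele totals are conserved across populations", {
    cfg <- simulationConfig(nPops = 3, samplesPerPop = 7, nSnps = 50,
                            chromLengths = c(chr1 = 1e5), seed = 17)
    sim <- simulateGenotypes(cfg)
    d <- dosages(sim$genotypes)
    d[sample(length(d), 30)] <- NA   # inject missingness
    ge <- GenotypeExperiment(
        d, SummarizedExperiment::rowRanges(sim$genotypes),
        populations(sim$genotypes))
    ac <- alleleCounts(ge)
    expect_equal(unname(rowSums(ac@nAlleles)), 2 * rowSums(!is.na(d)))
})

test_that("monomorphic filtering distinguishes pooled and any-pop modes", {
    # site 1: all ref everywhere; site 2: fixed alt in A, segregating in B;
    # site 3: segregating in both
    ge <- makeGe(rbind(c(0, 0, 0, 0),
                       c(2, 2, 0, 1),
                       c(0, 1, 1, 2)),
                 population = c("A", "A", "B", "B"))
    ac <- alleleCounts(ge)
    expect_identical(unname(filterMonomorphic(ac, "pooled")),
                     c(FALSE, TRUE, TRUE))
    expect_identical(unname(filterMonomorphic(ac, "any-pop")),
                     c(FALSE, FALSE, TRUE))
})

test_that("kept-site counts match a brute-force dosage scan", {
    cfg <- simulationConfig(nPops = 2, samplesPerPop = 10, nSnps = 300,
                            chromLengths = c(chr1 = 1e6),
                            ancFreqRange = c(0.02, 0.98),
                            fstTarget = 0.3, seed = 19)
    sim <- simulateGenotypes(cfg)
    ac <- alleleCounts(sim$genotypes)
    d <- dosages(sim$genotypes)
    tot <- rowSums(d)
    bruteKeep <- tot > 0 & tot < 2 * ncol(d)
    expect_identical(unname(filterMonomorphic(ac, "pooled")), bruteKeep)
    pop <- populations(sim$genotypes)
    bruteAny <- vapply(seq_len(nrow(d)), function(i) {
        all(vapply(unique(pop), function(p) {
            v <- d[i, pop == p]
            s <- sum(v)
            s > 0 && s < 2 * length(v)
        }, logical(1)))
    }, logical(1))
    expect_identical(unname(filterMonomorphic(ac, "any-pop")), bruteAny)
})

test_that("simulated sample frequencies track the ground truth", {
    cfg <- simulationConfig(nPops = 2, samplesPerPop = 60, nSnps = 1000,
                            chromLengths = c(chr1 = 1e7), fstTarget = 0.1,
                            seed = 23)
    sim <- simulateGenotypes(cfg)
    f <- alleleFreq(alleleCounts(sim$genotypes))
    # binomial sampling error at n = 120 alleles: bound by 5 sd
    se <- sqrt(sim$truth$popFreq * (1 - sim$truth$popFreq) / 120)
    expect_true(all(abs(f - sim$truth$popFreq) <= pmax(5 * se, 0.08)))
})

test_that("panel and pf tables round-trip", {
    p <- tempfile(); f <- tempfile()
    writePanel(fixturePanel, p)
    expect_identical(readPanel(p), fixturePanel)
    pf <- data.frame(snpId = c("rs1", "rs9"), tag = c("TFBS", "nsSNP"),
                     stringsAsFactors = FALSE)
    writePfTable(pf, f)
    expect_identical(readPfTable(f), pf)
    unlink(c(p, f))
})
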