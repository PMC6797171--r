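#' Run the full population-differentiation pipeline
#'
#' Orchestrates every stage end-to-end and writes all outputs into one run
#' directory: simulate (or read) genotypes, panel, gene models, functional
#' annotation and gene sets; derive allele counts and drop pooled-
#' monomorphic sites; score all population pairs and call pdSNPs;
#' annotate SNPs to genic regions and tally pdGenes; LD-prune the pdSNP
#' union and audit the result; run the region odds-ratio battery and the
#' per-chromosome gene-set enrichment; and fit the chromosome-architecture
#' regressions. A manifest records the package version, seed, parameters
#' and input checksums. Any stage failure aborts with the stage name.
#'
#' @param outDir run directory (created if absent).
#' @param simConfig a [simulationConfig()]; when given, inputs are
#'   simulated and written. Otherwise `vcf`, `panel` and `genes` paths
#'   must name existing files.
#' @param vcf,panel,genes,pf,gmt input file paths (VCF, panel TSV, GFF3
#'   gene models, pf-annotation TSV, GMT gene sets) used when
#'   `simConfig` is `NULL`; `pf` and `gmt` are optional.
#' @param nGenes,pfFraction,nGeneSets simulation-only knobs for the gene
#'   models, pf-annotation coverage and gene sets.
#' @param topFraction pdSNP top fraction (default 0.01).
#' @param promoterBp promoter length (default 5000).
#' @param windowBp,r2Max LD-pruning parameters (defaults 1e6 and 0.8).
#' @param monomorphicMode `"pooled"` or `"any-pop"` site filter.
#' @return invisibly, a list with every stage's in-memory result
#'   (`genotypes`, `counts`, `scan`, `annotations`, `tallies`,
#'   `composition`, `pruned`, `audit`, `regionOr`, `enrichment`,
#'   `byChromosome`, `chromStats`, `regressions`, `tree`, `manifest`).
#' @export
runAll <- function(outDir,
                   simConfig = NULL,
                   vcf = NULL, panel = NULL, genes = NULL,
                   pf = NULL, gmt = NULL,
                   nGenes = 40, pfFraction = 0.05, nGeneSets = 30,
                   topFraction = 0.01, promoterBp = 5000,
                   windowBp = 1e6, r2Max = 0.8,
                   monomorphicMode = "pooled") {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    inputs <- character()

    if (!is.null(simConfig)) {
        sim <- stage("simdata", {
            s <- simulateGenotypes(simConfig)
            models <- simulateGeneModels(simConfig$chromLengths, nGenes,
                                         seed = simConfig$seed + 1L)
            pfTab <- simulatePfAnnotation(snpIds(s$genotypes), pfFraction,
                                          seed = simConfig$seed + 2L)
            list(s = s, models = models, pfTab = pfTab)
        })
        ge <- sim$s$genotypes
        models <- sim$models
        pfTab <- sim$pfTab
        stage("write-inputs", {
            writeGenotypeVcf(ge, file.path(outDir, "genotypes.vcf"),
                             source = paste0("PopDiffScan-sim seed=",
                                             simConfig$seed))
            writePanel(sim$s$panel, file.path(outDir, "panel.tsv"))
            writeGeneModelsGff3(models, file.path(outDir, "genes.gff3"))
            writePfTable(pfTab, file.path(outDir, "pf.tsv"))
            truth <- data.frame(snpId = names(sim$s$truth$ancFreq),
                                ancFreq = unname(sim$s$truth$ancFreq),
                                fst = unname(sim$s$truth$fst),
                                blockId = unname(sim$s$truth$blockId))
            utils::write.table(truth,
                               file.path(outDir, "ground_truth.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        })
        inputs <- file.path(outDir, c("genotypes.vcf", "panel.tsv",
                                      "genes.gff3", "pf.tsv"))
        chromLengths <- simConfig$chromLengths
    } else {
        if (is.null(vcf) || is.null(panel) || is.null(genes))
            stop("without simConfig, vcf, panel and genes are required")
        panelDf <- stage("vario", readPanel(panel))
        ge <- stage("vario", readGenotypeVcf(vcf, panelDf))
        models <- stage("generegion",
                        if (!file.exists(genes))
                            stop("gene-model file not found: ", genes)
                        else readGeneModelsGff3(genes))
        pfTab <- if (!is.null(pf)) stage("vario", readPfTable(pf)) else
            data.frame(snpId = character(), tag = character())
        inputs <- c(vcf, panel, genes, pf)
        sl <- GenomeInfoDb::seqlengths(
            SummarizedExperiment::rowRanges(ge))
        if (any(is.na(sl)))
            sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(ch) {
                rr <- SummarizedExperiment::rowRanges(ge)
                max(GenomicRanges::end(
                    rr[GenomeInfoDb::seqnames(rr) == ch]))
            }, numeric(1))
        chromLengths <- sl
    }

    counts <- stage("vario", {
        ac <- alleleCounts(ge)
        keep <- filterMonomorphic(ac, monomorphicMode)
        subsetSites(ac, keep)
    })

    scan <- stage("fstscan", fstScan(counts, topFraction = topFraction))
    pd <- pdUnion(scan)
    tree <- stage("fstscan", {
        tr <- buildPopulationTree(meanPdFstMatrix(scan))
        ape::write.tree(tr, file.path(outDir, "population_tree.nwk"))
        tr
    })

    ann <- stage("generegion", {
        iv <- deriveGeneIntervals(models, promoterBp = promoterBp)
        assignRegions(counts@sites, iv)
    })
    tal <- stage("generegion",
                 tallyGenes(ann, pd$snpId, pfTab$snpId))
    comp <- stage("generegion", compositionTable(ann, list(
        all = NULL, pd = pd$snpId,
        pfpd = intersect(pd$snpId, pfTab$snpId))))

    pruned <- stage("ldprune",
                    ldPrune(ge, snps = pd$snpId, windowBp = windowBp,
                            r2Max = r2Max))
    audit <- stage("ldprune",
                   ldAudit(ge, pruned$kept, windowBp = windowBp,
                           r2Max = r2Max))

    universe <- tal$geneId
    sets <- stage("enrich", {
        if (!is.null(gmt)) readGmt(gmt)
        else if (!is.null(simConfig) && length(universe) >= 5) {
            gs <- simulateGeneSets(
                universe,
                diffGenes = tal$geneId[tal$enrichedPdGene],
                nSets = nGeneSets,
                setSizeRange = c(3, max(4, length(universe) %/% 3)),
                plantedSize = min(10, max(3, length(universe) %/% 4)),
                seed = simConfig$seed + 3L)
            writeGmt(gs$sets, file.path(outDir, "genesets.gmt"))
            gs$sets
        } else NULL
    })
    regionOr <- stage("enrich", regionOrBattery(
        comp, contrasts = list(c("pd", "all"), c("pfpd", "pd"))))
    enr <- byChrom <- NULL
    if (!is.null(sets) && length(universe)) {
        enr <- stage("enrich", hypergeomEnrich(
            tal$geneId[tal$enrichedPdGene], sets, universe))
        byChrom <- stage("enrich", compareByChromosome(
            split(tal$geneId[tal$enrichedPdGene],
                  tal$chrom[tal$enrichedPdGene]),
            sets, universe))
    }

    chromStats <- stage("chromarch", perChromosomeStats(
        ann, pd$snpId, pfTab$snpId, tal, chromLengths))
    regr <- stage("chromarch", architectureReport(chromStats))

    stage("write-outputs", {
        wt <- function(x, f) utils::write.table(
            x, file.path(outDir, f), sep = "\t", quote = FALSE,
            row.names = FALSE)
        wt(pairSummary(scan), "pair_summary.tsv")
        wt(pd, "pdsnps.tsv")
        dm <- meanPdFstMatrix(scan)
        utils::write.table(dm, file.path(outDir, "distance_matrix.tsv"),
                           sep = "\t", quote = FALSE)
        wt(ann, "annotation.tsv")
        wt(tal, "gene_tallies.tsv")
        wt(comp, "composition.tsv")
        writeLines(pruned$kept, file.path(outDir, "pruned_snps.txt"))
        wt(pruned$report, "prune_report.tsv")
        wt(regionOr, "region_odds_ratios.tsv")
        if (!is.null(enr)) wt(enr, "enrichment.tsv")
        if (!is.null(byChrom)) wt(byChrom, "enrichment_by_chrom.tsv")
        wt(chromStats, "chrom_stats.tsv")
        wt(regr, "regressions.tsv")
    })

    manifest <- list(
        package = "PopDiffScan",
        version = as.character(utils::packageVersion("PopDiffScan")),
        seed = if (!is.null(simConfig)) simConfig$seed else NA,
        parameters = list(topFraction = topFraction,
                          promoterBp = promoterBp, windowBp = windowBp,
                          r2Max = r2Max,
                          monomorphicMode = monomorphicMode),
        inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
        ldAudit = audit)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    invisible(list(genotypes = ge, counts = counts, scan = scan,
                   tree = tree, annotations = ann, tallies = tal,
                   composition = comp, pruned = pruned, audit = audit,
                   regionOr = regionOr, enrichment = enr,
                   byChromosome = byChrom, chromStats = chromStats,
                   regressions = regr, manifest = manifest))
}
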