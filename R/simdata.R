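#' Simulation configuration for multi-population genotype data
#'
#' Bundles and validates the parameters of the Balding-Nichols genotype
#' simulator. Per-population allele frequencies are drawn from a Beta
#' distribution around a uniform ancestral frequency so that the expected
#' differentiation equals `fstTarget`; diploid genotypes are then drawn
#' under Hardy-Weinberg equilibrium.
#'
#' @param nPops number of populations (>= 1).
#' @param samplesPerPop diploid samples per population (>= 2).
#' @param nSnps number of SNPs to simulate.
#' @param chromLengths named numeric vector of chromosome lengths in bp;
#'   SNPs are allocated proportionally to length and placed uniformly.
#' @param ancFreqRange range (min, max) within (0,1) for the uniform
#'   ancestral allele frequency; the default (0.05, 0.95) avoids
#'   near-monomorphic draws.
#' @param fstTarget Balding-Nichols divergence F in `[0, 1)`. Either a single
#'   value, or a named per-chromosome vector (names matching
#'   `chromLengths`) to plant chromosome-specific divergence.
#' @param ldBlockSize SNPs per LD block (1 = independent sites). Within a
#'   block, SNPs share one underlying frequency draw and haplotypes are
#'   copied from the previous site with probability `ldCopyProb`, so
#'   adjacent dosage r-squared is high within blocks.
#' @param ldCopyProb haplotype copy probability within a block (default
#'   0.95, giving adjacent haplotype correlation of about 0.95).
#' @param treeSpec optional hierarchical population structure:
#'   `list(groups = list(<character vectors partitioning the populations>),
#'   fstBetween =, fstWithin =)`. Group frequencies diverge from the
#'   ancestral frequency at `fstBetween`; populations diverge from their
#'   group at `fstWithin`. Overrides `fstTarget`.
#' @param popNames population labels (default "P1".."PK").
#' @param seed integer seed; all randomness in [simulateGenotypes()] derives
#'   from it and outputs are reproducible byte-for-byte.
#' @return A validated list of class `"SimulationConfig"`.
#' @examples
#' cfg <- simulationConfig(nPops = 2, samplesPerPop = 10, nSnps = 100,
#'     chromLengths = c(chr1 = 1e6), fstTarget = 0.1, seed = 1)
#' @export
simulationConfig <- function(nPops, samplesPerPop, nSnps, chromLengths,
                             ancFreqRange = c(0.05, 0.95),
                             fstTarget = 0.1,
                             ldBlockSize = 1L,
                             ldCopyProb = 0.95,
                             treeSpec = NULL,
                             popNames = NULL,
                             seed = 1L) {
    if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
        stop("chromLengths must be a named vector")
    if (any(chromLengths <= 0)) stop("chromLengths must all be > 0")
    if (samplesPerPop < 2) stop("samplesPerPop must be >= 2")
    if (length(ancFreqRange) != 2 || ancFreqRange[1] <= 0 ||
        ancFreqRange[2] >= 1 || ancFreqRange[1] > ancFreqRange[2])
        stop("ancFreqRange must lie within (0, 1)")
    if (any(fstTarget < 0) || any(fstTarget >= 1))
        stop("fstTarget must lie in [0, 1)")
    if (length(fstTarget) > 1 &&
        !setequal(names(fstTarget), names(chromLengths)))
        stop("per-chromosome fstTarget must be named like chromLengths")
    if (is.null(popNames))
        popNames <- sprintf("P%d", seq_len(nPops))
    if (length(popNames) != nPops) stop("need one name per population")
    if (!is.null(treeSpec)) {
        if (!all(c("groups", "fstBetween", "fstWithin") %in% names(treeSpec)))
            stop("treeSpec needs fields groups, fstBetween, fstWithin")
        if (!setequal(unlist(treeSpec$groups), popNames))
            stop("treeSpec groups must partition the population names")
    }
    structure(list(nPops = as.integer(nPops),
                   samplesPerPop = as.integer(samplesPerPop),
                   nSnps = as.integer(nSnps),
                   chromLengths = chromLengths,
                   ancFreqRange = ancFreqRange,
                   fstTarget = fstTarget,
                   ldBlockSize = as.integer(ldBlockSize),
                   ldCopyProb = ldCopyProb,
                   treeSpec = treeSpec,
                   popNames = popNames,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Draw population allele frequencies under the Balding-Nichols model
#'
#' Each population's frequency is drawn independently from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is `p` and whose expected
#' pairwise differentiation between two draws equals `F`. `F = 0` is the
#' degenerate no-divergence case: all populations get exactly `p`.
#'
#' @param pAnc ancestral frequency (scalar or vector), strictly in (0, 1).
#' @param F divergence parameter in `[0, 1)`.
#' @param nPops number of populations to draw.
#' @return For scalar `pAnc`, a numeric vector of length `nPops`; otherwise
#'   a `length(pAnc) x nPops` matrix.
#' @examples
#' drawBaldingNicholsFreqs(0.3, 0, 4)   # c(0.3, 0.3, 0.3, 0.3)
#' @export
drawBaldingNicholsFreqs <- function(pAnc, F, nPops) {
    if (any(pAnc <= 0) || any(pAnc >= 1))
        stop("pAnc must lie strictly in (0, 1)")
    if (F < 0 || F >= 1) stop("F must lie in [0, 1)")
    n <- length(pAnc)
    if (F == 0) {
        out <- matrix(rep(pAnc, nPops), nrow = n)
    } else {
        a <- pAnc * (1 - F) / F
        b <- (1 - pAnc) * (1 - F) / F
        out <- matrix(stats::rbeta(n * nPops, rep(a, nPops), rep(b, nPops)),
                      nrow = n)
    }
    if (n == 1L) drop(out) else out
}

# Vectorised per-row F: beta draw with row-specific F (F may be 0 for some rows)
.bnDrawRowwise <- function(pAnc, F, nPops) {
    n <- length(pAnc)
    F <- rep_len(F, n)
    out <- matrix(rep(pAnc, nPops), nrow = n)
    idx <- which(F > 0)
    if (length(idx)) {
        a <- pAnc[idx] * (1 - F[idx]) / F[idx]
        b <- (1 - pAnc[idx]) * (1 - F[idx]) / F[idx]
        out[idx, ] <- matrix(
            stats::rbeta(length(idx) * nPops, rep(a, nPops), rep(b, nPops)),
            nrow = length(idx))
    }
    out
}

#' Simulate diploid genotypes for K populations
#'
#' Generates SNP positions uniformly along the configured chromosomes, draws
#' ancestral and per-population allele frequencies (Balding-Nichols, flat or
#' hierarchical per `treeSpec`), and samples Hardy-Weinberg diploid dosages.
#' With `ldBlockSize > 1`, consecutive SNPs on a chromosome form blocks that
#' share one frequency draw and copy haplotypes site-to-site, producing high
#' within-block dosage r-squared for the pruning stage to remove.
#'
#' @param config a [simulationConfig()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{genotypes}{a [GenotypeExperiment-class].}
#'     \item{panel}{data.frame `sample`, `population`.}
#'     \item{truth}{ground truth: per-SNP ancestral frequency (`ancFreq`),
#'       per-population frequency matrix (`popFreq`), per-SNP divergence
#'       (`fst`), LD block ids (`blockId`) and the seed.}
#'   }
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed, {
        cl <- config$chromLengths
        n <- config$nSnps
        K <- config$nPops
        m <- config$samplesPerPop
        if (n == 0L) {
            sites <- GenomicRanges::GRanges(seqinfo = .seqinfoFrom(cl))
            S4Vectors::mcols(sites)$ref <- character()
            S4Vectors::mcols(sites)$alt <- character()
            S4Vectors::mcols(sites)$snpId <- character()
            samples <- paste0(rep(config$popNames, each = m), "_",
                              sprintf("%03d", seq_len(m)))
            d <- matrix(integer(), 0, K * m,
                        dimnames = list(NULL, samples))
            ge <- GenotypeExperiment(d, sites,
                                     rep(config$popNames, each = m))
            panel <- data.frame(sample = samples,
                                population = rep(config$popNames, each = m),
                                stringsAsFactors = FALSE)
            return(list(genotypes = ge, panel = panel,
                        truth = list(ancFreq = numeric(),
                                     popFreq = matrix(0, 0, K),
                                     fst = numeric(), blockId = integer(),
                                     seed = config$seed)))
        }
        # allocate SNPs to chromosomes proportionally to length
        frac <- cl / sum(cl)
        ni <- floor(frac * n)
        rem <- n - sum(ni)
        if (rem > 0) {
            extra <- order(frac * n - ni, decreasing = TRUE)[seq_len(rem)]
            ni[extra] <- ni[extra] + 1L
        }
        chrom <- rep(names(cl), ni)
        pos <- unlist(lapply(seq_along(cl), function(i) {
            if (ni[i] == 0L) return(integer())
            sort(sample.int(as.integer(cl[i]), ni[i]))
        }), use.names = FALSE)

        # LD blocks: consecutive runs within a chromosome
        b <- config$ldBlockSize
        withinIdx <- unlist(lapply(ni, seq_len), use.names = FALSE)
        blockWithin <- (withinIdx - 1L) %/% b
        blockId <- if (n == 1L) 1L else
            cumsum(c(1L, diff(blockWithin) != 0 | chrom[-1] != chrom[-n]))
        nBlocks <- max(blockId)

        # ancestral + population frequencies (one draw per block)
        pAncB <- stats::runif(nBlocks, config$ancFreqRange[1],
                              config$ancFreqRange[2])
        firstOfBlock <- match(seq_len(nBlocks), blockId)
        if (!is.null(config$treeSpec)) {
            ts <- config$treeSpec
            popFreqB <- matrix(NA_real_, nBlocks, K,
                               dimnames = list(NULL, config$popNames))
            for (g in ts$groups) {
                gFreq <- .bnDrawRowwise(pAncB, ts$fstBetween, 1)[, 1]
                gFreq <- pmin(pmax(gFreq, 1e-9), 1 - 1e-9)
                popFreqB[, g] <- .bnDrawRowwise(gFreq, ts$fstWithin,
                                                length(g))
            }
            fPerSnp <- rep(ts$fstBetween + ts$fstWithin, n)
        } else {
            Fb <- if (length(config$fstTarget) > 1)
                unname(config$fstTarget[chrom[firstOfBlock]])
            else rep(config$fstTarget, nBlocks)
            popFreqB <- .bnDrawRowwise(pAncB, Fb, K)
            colnames(popFreqB) <- config$popNames
            fPerSnp <- Fb[blockId]
        }
        popFreq <- popFreqB[blockId, , drop = FALSE]

        # alleles and ids (site order = sorted by chrom, pos already)
        bases <- c("A", "C", "G", "T")
        ref <- sample(bases, n, replace = TRUE)
        alt <- bases[(match(ref, bases) - 1L +
                      sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
        snpId <- sprintf("snp%06d", seq_len(n))

        # genotypes
        samples <- paste0(rep(config$popNames, each = m), "_",
                          sprintf("%03d", seq_len(m)))
        d <- matrix(NA_integer_, n, K * m, dimnames = list(NULL, samples))
        for (j in seq_len(K)) {
            colsJ <- (j - 1L) * m + seq_len(m)
            pj <- popFreq[, j]
            if (b == 1L) {
                d[, colsJ] <- stats::rbinom(n * m, 2L, rep(pj, m))
            } else {
                H <- matrix(0L, 2L * m, n)
                newBlock <- c(TRUE, diff(blockId) != 0)
                for (t in seq_len(n)) {
                    if (newBlock[t]) {
                        H[, t] <- stats::rbinom(2L * m, 1L, pj[t])
                    } else {
                        cp <- stats::runif(2L * m) < config$ldCopyProb
                        fresh <- stats::rbinom(2L * m, 1L, pj[t])
                        H[, t] <- ifelse(cp, H[, t - 1L], fresh)
                    }
                }
                d[, colsJ] <- t(H[seq(1L, 2L * m, by = 2L), , drop = FALSE] +
                                H[seq(2L, 2L * m, by = 2L), , drop = FALSE])
            }
        }

        sites <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(pos, width = 1),
            seqinfo = .seqinfoFrom(cl))
        S4Vectors::mcols(sites)$ref <- ref
        S4Vectors::mcols(sites)$alt <- alt
        S4Vectors::mcols(sites)$snpId <- snpId
        ge <- GenotypeExperiment(d, sites, rep(config$popNames, each = m))
        panel <- data.frame(sample = samples,
                            population = rep(config$popNames, each = m),
                            stringsAsFactors = FALSE)
        rownames(popFreq) <- snpId
        list(genotypes = ge, panel = panel,
             truth = list(ancFreq = stats::setNames(pAncB[blockId], snpId),
                          popFreq = popFreq,
                          fst = stats::setNames(fPerSnp, snpId),
                          blockId = stats::setNames(blockId, snpId),
                          seed = config$seed))
    })
}

#' Simulate strand-aware gene models
#'
#' Places multi-exon protein-coding transcripts on the given chromosomes
#' (one transcript per gene), with exon/intron structure and a CDS leaving
#' 5' and 3' UTR bases where the exonic span allows. Genes that do not fit
#' on their chromosome are skipped with a warning. Both genic and
#' intergenic space are left by construction as long as gene lengths are
#' small relative to the chromosomes.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param nGenes number of genes to place.
#' @param geneLengthRange min/max transcript length in bp.
#' @param nExonRange min/max exon count per transcript.
#' @param seed optional integer seed.
#' @return A `GRanges` of features with metadata columns `type`
#'   ("mRNA", "exon", "CDS"), `geneId`, `ID` and `Parent`, suitable for
#'   [writeGeneModelsGff3()] and [deriveGeneIntervals()].
#' @export
simulateGeneModels <- function(chromLengths, nGenes,
                               geneLengthRange = c(2000, 20000),
                               nExonRange = c(1, 6),
                               seed = NULL) {
    si <- .seqinfoFrom(chromLengths)
    empty <- GenomicRanges::GRanges(seqinfo = si)
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
        type = character(), geneId = character(), ID = character(),
        Parent = character())
    if (nGenes == 0L) return(empty)
    .withSeed(seed, {
        recs <- list()
        for (i in seq_len(nGenes)) {
            gid <- sprintf("gene%04d", i)
            chr <- sample(names(chromLengths), 1,
                          prob = chromLengths / sum(chromLengths))
            L <- as.integer(chromLengths[chr])
            len <- sample(seq(geneLengthRange[1], geneLengthRange[2]), 1)
            if (L < len) {
                warning("chromosome ", chr, " too short for ", gid,
                        "; gene skipped")
                next
            }
            start <- sample.int(L - len + 1L, 1)
            end <- start + len - 1L
            strand <- sample(c("+", "-"), 1)
            k <- sample(seq(nExonRange[1], nExonRange[2]), 1)
            k <- min(k, (len + 1L) %/% 2L)
            if (k > 1L) {
                cuts <- sort(sample.int(len - 1L, 2L * k - 2L))
                seg <- diff(c(0L, cuts, len))
            } else seg <- len
            segStart <- start + c(0L, cumsum(seg))[seq_along(seg)]
            exIdx <- seq(1L, 2L * k - 1L, by = 2L)
            exStart <- segStart[exIdx]
            exEnd <- exStart + seg[exIdx] - 1L
            # CDS over exonic bases, leaving UTR bases at both ends if possible
            exonicPos <- unlist(mapply(seq, exStart, exEnd,
                                       SIMPLIFY = FALSE))
            E <- length(exonicPos)
            if (E >= 3L) {
                ci <- sample(2:(E - 1L), 1)
                cj <- if (ci < E - 1L) sample(ci:(E - 1L), 1) else ci
                cdsLo <- exonicPos[ci]; cdsHi <- exonicPos[cj]
            } else { cdsLo <- exonicPos[1]; cdsHi <- exonicPos[E] }
            cdsS <- pmax(exStart, cdsLo); cdsE <- pmin(exEnd, cdsHi)
            keep <- cdsS <= cdsE
            recs[[length(recs) + 1L]] <- data.frame(
                chrom = chr, start = c(start, exStart, cdsS[keep]),
                end = c(end, exEnd, cdsE[keep]), strand = strand,
                type = c("mRNA", rep("exon", k), rep("CDS", sum(keep))),
                geneId = gid, stringsAsFactors = FALSE)
        }
        if (!length(recs)) return(empty)
        df <- do.call(rbind, recs)
        nE <- stats::ave(seq_len(nrow(df)), df$geneId, df$type,
                         FUN = seq_along)
        gr <- GenomicRanges::GRanges(
            df$chrom, IRanges::IRanges(df$start, df$end),
            strand = df$strand, seqinfo = si)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            type = df$type, geneId = df$geneId,
            ID = ifelse(df$type == "mRNA", paste0(df$geneId, ".t1"),
                        paste0(df$geneId, ".", tolower(df$type), nE)),
            Parent = ifelse(df$type == "mRNA", NA_character_,
                            paste0(df$geneId, ".t1")))
        GenomicRanges::sort(gr, ignore.strand = TRUE)
    })
}

#' Simulate a potentially-functional SNP annotation table
#'
#' Flags a chosen fraction of SNPs as "potentially functional" with a tag
#' drawn from a small vocabulary, emulating an external functional-SNP
#' annotation resource.
#'
#' @param snpIds character vector of SNP identifiers.
#' @param fraction fraction of SNPs to flag (default 0.05).
#' @param seed optional integer seed.
#' @return data.frame with columns `snpId`, `tag`.
#' @export
simulatePfAnnotation <- function(snpIds, fraction = 0.05, seed = NULL) {
    .withSeed(seed, {
        nPf <- round(fraction * length(snpIds))
        ids <- sort(sample(snpIds, nPf))
        tags <- c("TFBS", "miRNA_site", "splice_reg", "nsSNP", "stop_gain")
        data.frame(snpId = ids,
                   tag = sample(tags, nPf, replace = TRUE),
                   stringsAsFactors = FALSE)
    })
}

#' Simulate gene sets with one optionally planted enriched set
#'
#' Draws `nSets` gene sets uniformly from the universe; when
#' `plantedFraction > 0` and differentiated genes are supplied, the first
#' set ("set001") is planted: `plantedFraction` of its members come from
#' `diffGenes`, so a downstream hypergeometric enrichment of the
#' differentiated genes should rank it first.
#'
#' @param universe character vector of all gene ids.
#' @param diffGenes genes the genotype simulation made highly
#'   differentiated (candidate planted members).
#' @param nSets number of gene sets (>= 1).
#' @param setSizeRange min/max size of the uniformly drawn sets.
#' @param plantedSize size of the planted set.
#' @param plantedFraction fraction of the planted set drawn from
#'   `diffGenes`; 0 disables planting.
#' @param seed optional integer seed.
#' @return list with `sets` (named list of gene id vectors, GMT-ready) and
#'   `planted` (name of the planted set, or `NA`).
#' @export
simulateGeneSets <- function(universe, diffGenes = character(),
                             nSets = 50, setSizeRange = c(10, 40),
                             plantedSize = 25, plantedFraction = 0.8,
                             seed = NULL) {
    stopifnot(nSets >= 1)
    .withSeed(seed, {
        sets <- vector("list", nSets)
        names(sets) <- sprintf("set%03d", seq_len(nSets))
        planted <- NA_character_
        start <- 1L
        if (plantedFraction > 0 && length(diffGenes)) {
            nIn <- min(round(plantedFraction * plantedSize),
                       length(diffGenes))
            memb <- sample(diffGenes, nIn)
            rest <- sample(setdiff(universe, memb), plantedSize - nIn)
            sets[[1L]] <- sort(c(memb, rest))
            planted <- names(sets)[1L]
            start <- 2L
        }
        for (i in seq(start, nSets)) {
            sz <- sample(seq(setSizeRange[1], setSizeRange[2]), 1)
            sets[[i]] <- sort(sample(universe, sz))
        }
        list(sets = sets, planted = planted)
    })
}
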