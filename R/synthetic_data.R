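#' @include data_model.R
NULL

# Evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All generators route through this so a fixed
# (config, seed) pair is fully deterministic with no global side effects.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

#' Default tissue panel
#'
#' Fourteen bovine tissues; the first three are the adipose tissues
#' (visceral, subcutaneous, intramuscular) used as the adipose group.
#'
#' @param n number of tissues wanted (panel is extended with numbered labels
#'   beyond 14).
#' @return character vector of tissue labels.
#' @export
tissuePanel <- function(n = 14L) {
    base <- c("visceral_adipose", "subcutaneous_adipose",
              "intramuscular_adipose", "muscle", "liver", "brain", "heart",
              "kidney", "spleen", "lung", "skin", "small_intestine",
              "cerebellum", "pituitary_gland")
    if (n <= length(base)) base[seq_len(n)]
    else c(base, sprintf("tissue%02d", seq_len(n - length(base)) + 14L))
}

#' Adipose tissue labels of the default panel
#' @return character vector of the three adipose tissue labels.
#' @export
adiposeTissues <- function() tissuePanel(3L)

#' Build a synthetic-study configuration
#'
#' Defaults emulate the study design the package targets: 14 tissues with
#' 2-11 replicates each, 5\% of genes planted as single-tissue specific, a
#' 23-gene program shared by the three adipose tissues, a genome-wide biotype
#' mix of roughly 59\% protein-coding / 15\% lncRNA / 2\% miRNA / 23\% other,
#' a 50-fold home-tissue boost for planted genes, negative-binomial counts
#' with dispersion 0.1 and planted 4-fold adipose differences.
#'
#' @param nGenes number of genes (default 2000, desk scale).
#' @param nTissues number of tissues (default 14).
#' @param repRange inclusive range replicates per tissue are drawn from.
#' @param fractionSpecific total fraction of genes planted single-tissue
#'   specific.
#' @param nSharedAdipose genes planted specific in all three adipose tissues.
#' @param biotypeMix proportions over protein_coding, lncRNA, miRNA, other;
#'   normalised to sum to 1.
#' @param baselineLogFpkmMean,baselineLogFpkmSd natural-log parameters of the
#'   background FPKM log-normal.
#' @param tissueEffectSd,replicateNoiseSd log-scale SDs of tissue-level and
#'   replicate-level variation.
#' @param specificBoost home-tissue multiplicative fold for planted genes.
#' @param nbDispersion NB dispersion of simulated counts.
#' @param deFoldChange planted adipose-vs-rest fold change.
#' @param deFraction fraction of genes planted differentially expressed.
#' @param seed RNG seed.
#' @return a validated [SimConfig].
#' @export
simConfig <- function(nGenes = 2000L, nTissues = 14L, repRange = c(2L, 11L),
                      fractionSpecific = 0.05, nSharedAdipose = 23L,
                      biotypeMix = c(58.87, 14.73, 2.27, 23.14),
                      baselineLogFpkmMean = 0.5, baselineLogFpkmSd = 1.5,
                      tissueEffectSd = 0.35, replicateNoiseSd = 0.3,
                      specificBoost = 50, nbDispersion = 0.1,
                      deFoldChange = 4, deFraction = 0.1, seed = 1L) {
    new("SimConfig", nTissues = as.integer(nTissues),
        repRange = as.integer(repRange), nGenes = as.integer(nGenes),
        fractionSpecific = fractionSpecific,
        nSharedAdipose = as.integer(nSharedAdipose),
        biotypeMix = biotypeMix / sum(biotypeMix),
        baselineLogFpkmMean = baselineLogFpkmMean,
        baselineLogFpkmSd = baselineLogFpkmSd,
        tissueEffectSd = tissueEffectSd,
        replicateNoiseSd = replicateNoiseSd,
        specificBoost = specificBoost, nbDispersion = nbDispersion,
        deFoldChange = deFoldChange, deFraction = deFraction,
        seed = as.integer(seed))
}

# Planted tissue-specific genes sit in a low baseline stratum: a gene that is
# specific to one tissue is, by definition, near-silent elsewhere, so its
# off-home FPKM is drawn around 0.15 and only the boosted home tissue(s)
# clear the expression floor.
.plantedBaseMeanlog <- log(0.15)
.plantedBaseSdlog <- 0.5

#' Simulate a multi-tissue FPKM experiment with planted specific genes
#'
#' Background genes draw a per-gene baseline from a log-normal, a per-tissue
#' multiplicative effect, and per-replicate log-normal noise. Planted genes
#' (single-tissue plus the shared adipose program) draw a low baseline and
#' are multiplied by `specificBoost` in their home tissue(s). Planted genes'
#' biotypes are drawn from a lncRNA-enriched mix (doubled lncRNA share),
#' background genes from the genome-wide mix.
#'
#' @param cfg a [SimConfig].
#' @return list with elements `expr` (a [TissueExpressionSet]), `annotation`
#'   (data.frame gene_id, biotype) and `truth` (data.frame gene_id,
#'   homeTissues -- comma-separated, "" if none -- and biotype).
#' @export
simulateExpression <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    .withSeed(cfg@seed, {
        tissues <- tissuePanel(cfg@nTissues)
        reps <- sample(seq(cfg@repRange[1L], cfg@repRange[2L]),
                       cfg@nTissues, replace = TRUE)
        sampleTissue <- rep(tissues, reps)
        sampleIds <- unlist(lapply(seq_along(tissues), function(i)
            sprintf("%s_rep%02d", tissues[i], seq_len(reps[i]))))
        genes <- sprintf("gene%05d", seq_len(cfg@nGenes))

        nSingle <- round(cfg@fractionSpecific * cfg@nGenes)
        plantedSingle <- seq_len(nSingle)
        plantedShared <- seq_len(cfg@nSharedAdipose) + nSingle
        homes <- vector("list", cfg@nGenes)
        if (nSingle > 0)
            homes[plantedSingle] <- as.list(
                tissues[(seq_len(nSingle) - 1L) %% cfg@nTissues + 1L])
        homes[plantedShared] <- list(adiposeTissues())
        planted <- c(plantedSingle, plantedShared)

        base <- exp(rnorm(cfg@nGenes, cfg@baselineLogFpkmMean,
                          cfg@baselineLogFpkmSd))
        base[planted] <- exp(rnorm(length(planted), .plantedBaseMeanlog,
                                   .plantedBaseSdlog))
        tissueMu <- base * exp(matrix(
            rnorm(cfg@nGenes * cfg@nTissues, 0, cfg@tissueEffectSd),
            cfg@nGenes, cfg@nTissues))
        dimnames(tissueMu) <- list(genes, tissues)
        for (g in planted)
            tissueMu[g, homes[[g]]] <- tissueMu[g, homes[[g]]] * cfg@specificBoost

        m <- tissueMu[, sampleTissue, drop = FALSE] *
            exp(matrix(rnorm(cfg@nGenes * length(sampleIds), 0,
                             cfg@replicateNoiseSd),
                       cfg@nGenes, length(sampleIds)))
        colnames(m) <- sampleIds

        mix <- cfg@biotypeMix
        lncMix <- c(mix[1L], 2 * mix[2L], mix[3L], mix[4L])
        lncMix <- lncMix / sum(lncMix)
        biotype <- character(cfg@nGenes)
        biotype[-planted] <- sample(biotypeClasses(),
                                    cfg@nGenes - length(planted),
                                    replace = TRUE, prob = mix)
        if (length(planted))
            biotype[planted] <- sample(biotypeClasses(), length(planted),
                                       replace = TRUE, prob = lncMix)

        truth <- data.frame(
            gene_id = genes,
            homeTissues = vapply(homes, function(h)
                if (is.null(h)) "" else paste(h, collapse = ","),
                character(1)),
            biotype = biotype)
        list(expr = TissueExpressionSet(m, tissue = structure(sampleTissue,
                                                              names = sampleIds)),
             annotation = data.frame(gene_id = genes,
                                     biotype = collapseBiotype(biotype)),
             truth = truth)
    })
}

#' Expand the comma-separated home tissues of a truth table to a list
#'
#' @param truth truth data.frame from [simulateExpression()].
#' @return named list, gene id -> character vector of home tissues (possibly
#'   empty).
#' @export
homeTissueList <- function(truth) {
    out <- lapply(strsplit(truth$homeTissues, ","), function(h)
        h[nzchar(h)])
    names(out) <- truth$gene_id
    out
}

#' Simulate a two-group negative-binomial count experiment
#'
#' Samples split into an adipose group and a non-adipose group; per-gene NB
#' means from a log-normal, per-sample library size factors, and a planted
#' fold change (half up, half down) in the adipose group for the flagged
#' `deFraction` of genes. With `deFoldChange = 1` no gene is flagged.
#'
#' @param cfg a [SimConfig].
#' @param nAdipose,nOther samples per group (default 6 and 6).
#' @return list with `counts` (a [TissueCountSet]) and `truth` (data.frame
#'   gene_id, isDE, log2fc).
#' @export
simulateCounts <- function(cfg, nAdipose = 6L, nOther = 6L) {
    stopifnot(is(cfg, "SimConfig"), nAdipose >= 2L, nOther >= 2L)
    validObject(cfg)
    .withSeed(cfg@seed, {
        adi <- adiposeTissues()
        oth <- setdiff(tissuePanel(max(cfg@nTissues, 6L)), adi)
        tissue <- c(adi[(seq_len(nAdipose) - 1L) %% 3L + 1L],
                    oth[(seq_len(nOther) - 1L) %% length(oth) + 1L])
        grp <- rep(c("adipose", "other"), c(nAdipose, nOther))
        sampleIds <- sprintf("%s_s%02d", tissue, seq_along(tissue))
        genes <- sprintf("gene%05d", seq_len(cfg@nGenes))

        nDE <- if (cfg@deFoldChange > 1)
            round(cfg@deFraction * cfg@nGenes) else 0L
        lfc <- numeric(cfg@nGenes)
        if (nDE > 0) {
            # the shared adipose program (same gene indices as in
            # simulateExpression) is up-regulated in the adipose group by
            # construction; remaining flags fill up around it
            nSingle <- round(cfg@fractionSpecific * cfg@nGenes)
            shared <- seq_len(min(cfg@nSharedAdipose, ceiling(nDE / 2))) +
                nSingle
            rest <- setdiff(seq_len(cfg@nGenes), shared)
            nUp <- ceiling(nDE / 2)
            up <- c(shared, rest[seq_len(nUp - length(shared))])
            down <- setdiff(rest, up)[seq_len(nDE - nUp)]
            lfc[up] <- log2(cfg@deFoldChange)
            lfc[down] <- -log2(cfg@deFoldChange)
            # the adipose-specific core is near-silent outside adipose, so
            # its count fold is the specificity boost, not the generic DE
            # effect size
            lfc[shared] <- log2(cfg@specificBoost)
        }
        mu <- exp(rnorm(cfg@nGenes, 4, 1.5))
        sf <- exp(rnorm(length(sampleIds), 0, 0.2))
        sf <- sf / exp(mean(log(sf)))

        muMat <- outer(mu, sf)
        muMat[, grp == "adipose"] <- muMat[, grp == "adipose"] * 2^lfc
        k <- matrix(rnbinom(length(muMat), mu = muMat,
                            size = 1 / cfg@nbDispersion),
                    cfg@nGenes, length(sampleIds),
                    dimnames = list(genes, sampleIds))
        list(counts = TissueCountSet(k, tissue = structure(tissue,
                                                           names = sampleIds)),
             truth = data.frame(gene_id = genes, isDE = lfc != 0,
                                log2fc = lfc))
    })
}

#' Simulate biallelic indel genotypes for one population
#'
#' Genotype probabilities follow Hardy-Weinberg with an inbreeding-like
#' deviation f: (p^2 + f p q, 2 p q (1 - f), q^2 + f p q) for (DD, ID, II),
#' truncated at zero and renormalised, then drawn multinomially.
#'
#' @param p frequency of the D (deletion) allele, in (0, 1).
#' @param n number of individuals.
#' @param f deviation from Hardy-Weinberg in \[-1, 1\]; 0 = equilibrium,
#'   1 = no heterozygotes.
#' @param population population label.
#' @param seed RNG seed.
#' @return list with `table` (a one-population [GenotypeTable]) and
#'   `genotypes` (character vector of per-individual genotypes, shuffled).
#' @export
simulateGenotypes <- function(p, n, f = 0, population = "sim", seed = 1L) {
    if (!is.numeric(p) || p <= 0 || p >= 1)
        stop("allele frequency p must lie strictly in (0, 1)")
    if (!is.numeric(f) || f < -1 || f > 1)
        stop("f must lie in [-1, 1]")
    stopifnot(n >= 1)
    q <- 1 - p
    pr <- c(DD = p^2 + f * p * q, ID = 2 * p * q * (1 - f),
            II = q^2 + f * p * q)
    pr <- pmax(pr, 0)
    pr <- pr / sum(pr)
    .withSeed(seed, {
        cnt <- as.vector(rmultinom(1L, n, pr))
        geno <- sample(rep(c("DD", "ID", "II"), cnt))
        list(table = GenotypeTable(population, cnt[1L], cnt[2L], cnt[3L]),
             genotypes = geno)
    })
}

#' Simulate trait values with genotype-dependent means
#'
#' value = base + effect\[genotype\] + Normal(0, sd).
#'
#' @param genotypes character vector of per-individual genotypes (DD/ID/II).
#' @param effects named numeric vector of mean shifts, one entry per genotype
#'   present in `genotypes` (an absent genotype is an error).
#' @param sd positive residual SD (trait units).
#' @param base baseline trait mean.
#' @param trait trait name.
#' @param sex single label or per-individual vector.
#' @param seed RNG seed.
#' @return long-format data.frame: individual_id, sex, genotype, trait,
#'   value.
#' @export
simulateTraits <- function(genotypes, effects, sd, base = 10,
                           trait = "trait", sex = "pooled", seed = 1L) {
    stopifnot(sd > 0)
    missing <- setdiff(unique(genotypes), names(effects))
    if (length(missing))
        stop("no effect specified for genotype(s): ",
             paste(missing, collapse = ", "))
    n <- length(genotypes)
    if (length(sex) == 1L) sex <- rep(sex, n)
    .withSeed(seed, data.frame(
        individual_id = sprintf("ind%04d", seq_len(n)),
        sex = sex,
        genotype = genotypes,
        trait = trait,
        value = base + unname(effects[genotypes]) + rnorm(n, 0, sd)))
}
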