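#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom BiocGenerics counts
NULL

#' TissueExpressionSet: genes x samples FPKM with a sample-to-tissue map
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] carrying one assay,
#' `"fpkm"`, of non-negative expression values (fragments per kilobase of
#' transcript per million mapped fragments) and a mandatory `tissue` column in
#' `colData`. It is the entry object of the tissue-specificity pipeline.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [TissueExpressionSet()] for the constructor,
#'   [readExpressionMatrix()] for the TSV reader, [tissueMeans()].
#' @export
setClass("TissueExpressionSet", contains = "SummarizedExperiment")

setValidity("TissueExpressionSet", function(object) {
    msg <- character()
    if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'fpkm' is required")
    else {
        x <- assay(object, "fpkm")
        if (any(!is.finite(x)))
            msg <- c(msg, "FPKM values must be finite")
        else if (any(x < 0)) {
            bad <- which(x < 0, arr.ind = TRUE)[1L, ]
            msg <- c(msg, sprintf("negative FPKM for gene '%s' in sample '%s'",
                                  rownames(object)[bad[1L]],
                                  colnames(object)[bad[2L]]))
        }
    }
    if (!"tissue" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'tissue' column")
    else {
        tis <- as.character(colData(object)$tissue)
        if (anyNA(tis) || any(!nzchar(tis)))
            msg <- c(msg, "every sample needs a non-empty tissue label")
    }
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene (row) and sample (column) names are required")
    if (length(msg)) msg else TRUE
})

#' TissueCountSet: genes x samples read counts with a sample-to-tissue map
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay, `"counts"`,
#' of non-negative integral read counts and a `tissue` column in `colData`.
#' Substrate of the differential-expression stage.
#'
#' @seealso [TissueCountSet()], [morSizeFactors()], [nbTwoGroupTest()].
#' @export
setClass("TissueCountSet", contains = "SummarizedExperiment")

setValidity("TissueCountSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        x <- assay(object, "counts")
        if (any(!is.finite(x)) || any(x < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        else if (any(abs(x - round(x)) > 1e-8))
            msg <- c(msg, "counts must be integral")
    }
    if (!"tissue" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'tissue' column")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "gene (row) and sample (column) names are required")
    if (length(msg)) msg else TRUE
})

#' TissueProfiles: genes x tissues mean-expression matrix
#'
#' Per-tissue mean FPKM profiles, the substrate for the tau specificity index
#' and the tissue-specific-gene caller. Produced by [tissueMeans()].
#'
#' @slot means non-negative numeric matrix, genes in rows, tissues in columns
#'   (at least two tissues).
#' @export
setClass("TissueProfiles", representation(means = "matrix"))

setValidity("TissueProfiles", function(object) {
    m <- object@means
    msg <- character()
    if (ncol(m) < 2L)
        msg <- c(msg, "at least two tissues are required")
    if (any(!is.finite(m)) || any(m < 0))
        msg <- c(msg, "tissue means must be finite and non-negative")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "gene and tissue names are required")
    if (length(msg)) msg else TRUE
})

#' GenotypeTable: per-population biallelic indel genotype counts
#'
#' Counts of the three genotypes of a biallelic insertion/deletion
#' polymorphism (DD, ID, II) for one or more populations. Substrate for
#' [alleleFrequencies()], [diversityStats()] and [hweChiSquare()].
#'
#' @slot population character vector of population labels.
#' @slot nDD,nID,nII non-negative integer vectors, one entry per population.
#' @export
setClass("GenotypeTable",
         representation(population = "character",
                        nDD = "integer", nID = "integer", nII = "integer"))

setValidity("GenotypeTable", function(object) {
    k <- length(object@population)
    msg <- character()
    if (any(lengths(list(object@nDD, object@nID, object@nII)) != k))
        msg <- c(msg, "count vectors must match the number of populations")
    cnt <- cbind(object@nDD, object@nID, object@nII)
    if (anyNA(cnt) || any(cnt < 0))
        msg <- c(msg, "genotype counts must be non-negative")
    else if (any(rowSums(cnt) < 1))
        msg <- c(msg, "every population needs at least one individual")
    if (anyDuplicated(object@population))
        msg <- c(msg, "population labels must be unique")
    if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic-data generators
#'
#' Holds every knob of the desk-scale study emulation: number of tissues and
#' replicates, fraction of planted tissue-specific genes, the shared adipose
#' program, biotype mix, expression and count model parameters, and the seed.
#' Build one with [simConfig()], which supplies the study defaults.
#'
#' @slot nTissues integer, number of tissues (first three are the adipose
#'   tissues).
#' @slot repRange integer length-2, inclusive range replicates per tissue are
#'   drawn from.
#' @slot nGenes integer, number of genes.
#' @slot fractionSpecific numeric, total fraction of genes planted as
#'   single-tissue specific (spread uniformly over tissues).
#' @slot nSharedAdipose integer, genes planted specific in all three adipose
#'   tissues.
#' @slot biotypeMix numeric length-4 proportions over protein_coding, lncRNA,
#'   miRNA, other (sums to 1).
#' @slot baselineLogFpkmMean,baselineLogFpkmSd baseline log-normal FPKM
#'   parameters (natural-log scale).
#' @slot tissueEffectSd,replicateNoiseSd log-scale SDs of tissue-level and
#'   replicate-level variation.
#' @slot specificBoost multiplicative fold applied in a planted gene's home
#'   tissue(s); > 1.
#' @slot nbDispersion negative-binomial dispersion of simulated counts; > 0.
#' @slot deFoldChange planted adipose-vs-rest fold change for flagged genes;
#'   >= 1.
#' @slot deFraction fraction of genes flagged as differentially expressed.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
         representation(nTissues = "integer", repRange = "integer",
                        nGenes = "integer", fractionSpecific = "numeric",
                        nSharedAdipose = "integer", biotypeMix = "numeric",
                        baselineLogFpkmMean = "numeric",
                        baselineLogFpkmSd = "numeric",
                        tissueEffectSd = "numeric",
                        replicateNoiseSd = "numeric",
                        specificBoost = "numeric", nbDispersion = "numeric",
                        deFoldChange = "numeric", deFraction = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nTissues < 4L)
        msg <- c(msg, "need at least 4 tissues (3 adipose + 1 other)")
    if (length(object@repRange) != 2L || object@repRange[1L] < 1L ||
        diff(object@repRange) < 0L)
        msg <- c(msg, "repRange must be an increasing pair of positive integers")
    if (object@fractionSpecific < 0 || object@fractionSpecific > 0.5)
        msg <- c(msg, "fractionSpecific must lie in [0, 0.5]")
    if (length(object@biotypeMix) != 4L ||
        abs(sum(object@biotypeMix) - 1) > 1e-6 || any(object@biotypeMix < 0))
        msg <- c(msg, "biotypeMix must be 4 non-negative proportions summing to 1")
    if (object@specificBoost <= 1)
        msg <- c(msg, "specificBoost must exceed 1")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be positive")
    if (object@deFoldChange < 1)
        msg <- c(msg, "deFoldChange must be >= 1")
    nPlanted <- round(object@fractionSpecific * object@nGenes) +
        object@nSharedAdipose
    if (nPlanted > object@nGenes)
        msg <- c(msg, "more planted genes than nGenes")
    if (length(msg)) msg else TRUE
})

#' SetReport: gene-set intersection report
#'
#' All 2^k - 1 disjoint region cardinalities of k named gene sets (the Venn
#' regions), plus the union, produced by [intersectSets()]. Region counts are
#' exact and satisfy inclusion-exclusion by construction.
#'
#' @slot sets the input named list of character gene sets.
#' @slot regions data.frame with one logical membership column per set and a
#'   `count` column for the disjoint region.
#' @export
setClass("SetReport",
         representation(sets = "list", regions = "data.frame"))

setValidity("SetReport", function(object) {
    if (length(object@sets) < 2L)
        return("at least two sets are required")
    if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
        return("sets must be named")
    TRUE
})
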