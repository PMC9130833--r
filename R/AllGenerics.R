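#' @include AllClasses.R
NULL

#' Sample-to-tissue map of an expression or count set
#'
#' @param x a [TissueExpressionSet] or [TissueCountSet].
#' @return named character vector, sample id -> tissue label.
#' @export
setGeneric("sampleTissues", function(x) standardGeneric("sampleTissues"))

#' FPKM assay accessor
#'
#' @param x a [TissueExpressionSet].
#' @return numeric matrix of FPKM values, genes x samples.
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' Per-tissue mean expression profiles
#'
#' Averages replicate samples within each tissue (arithmetic mean on the raw
#' FPKM scale) to one column per tissue.
#'
#' @param x a [TissueExpressionSet].
#' @return a [TissueProfiles] object, genes x tissues.
#' @export
setGeneric("tissueMeans", function(x) standardGeneric("tissueMeans"))

#' Tissue-mean matrix accessor
#'
#' @param x a [TissueProfiles].
#' @return numeric matrix, genes x tissues.
#' @export
setGeneric("profileMeans", function(x) standardGeneric("profileMeans"))

#' Tissue specificity index tau
#'
#' For a per-tissue mean expression profile x over N tissues,
#' tau = sum_i (1 - x_i / max_j x_j) / (N - 1). tau lies in \[0, 1\]: 0 for a
#' uniform profile, 1 when expression is confined to a single tissue. An
#' all-zero profile has no defined specificity and yields `NA`.
#'
#' @param x numeric profile vector, or a [TissueProfiles] (one tau per gene).
#' @param ... further arguments; `log2p1 = TRUE` computes tau on
#'   log2(x + 1)-transformed means (off by default).
#' @return numeric scalar, or named numeric vector for [TissueProfiles].
#' @examples
#' tauIndex(c(10, 0, 0, 0))  # 1
#' tauIndex(c(5, 5, 5, 5))   # 0
#' tauIndex(c(8, 4, 2, 2))   # 2/3
#' @export
setGeneric("tauIndex", function(x, ...) standardGeneric("tauIndex"))

#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: each sample's factor is the median,
#' over genes with a positive geometric mean across samples, of the ratio of
#' the sample's count to that geometric mean. Equalises depth/composition
#' across libraries before differential expression.
#'
#' @param x count matrix (genes x samples) or a [TissueCountSet].
#' @return named positive numeric vector of size factors.
#' @export
setGeneric("morSizeFactors", function(x) standardGeneric("morSizeFactors"))

#' Elementwise log2(x + 1) transform
#'
#' @param x non-negative numeric matrix or [TissueProfiles].
#' @return object of the same shape, transformed.
#' @export
setGeneric("log2p1", function(x) standardGeneric("log2p1"))

#' Allele frequencies of a biallelic indel
#'
#' p_D = (2 n_DD + n_ID) / (2n), p_I = 1 - p_D, per population.
#'
#' @param x a [GenotypeTable].
#' @return data.frame with columns population, pD, pI.
#' @export
setGeneric("alleleFrequencies", function(x) standardGeneric("alleleFrequencies"))

#' Diversity statistics of a biallelic indel locus
#'
#' Per population: allele frequencies, homozygosity (sum of squared allele
#' frequencies), expected heterozygosity, effective allele number, Botstein
#' polymorphism information content, and the Hardy-Weinberg chi-square test.
#' See [diversityStats()] methods for the formulas.
#'
#' @param x a [GenotypeTable].
#' @return a data.frame, one row per population.
#' @export
setGeneric("diversityStats", function(x) standardGeneric("diversityStats"))

#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' Expected genotype counts (n p^2, 2 n p q, n q^2) from the observed allele
#' frequencies; chi-square with 1 degree of freedom (3 classes - 1 - 1
#' estimated allele frequency).
#'
#' @param x a [GenotypeTable].
#' @return data.frame with columns population, chi2, df, p and a `lowCount`
#'   flag set when any expected class falls below 1.
#' @export
setGeneric("hweChiSquare", function(x) standardGeneric("hweChiSquare"))
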