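#' @include data_model.R
NULL

#' @describeIn morSizeFactors median-of-ratios factors of a count matrix
#' @export
setMethod("morSizeFactors", "matrix", function(x) {
    if (any(x < 0)) stop("counts must be non-negative")
    logGeo <- rowMeans(log(x))
    usable <- is.finite(logGeo)
    if (!any(usable))
        stop("no gene has nonzero counts in every sample; ",
             "size factors are undefined (filter samples or genes first)")
    sf <- apply(x, 2L, function(k)
        exp(stats::median(log(k[usable]) - logGeo[usable])))
    names(sf) <- colnames(x)
    sf
})

#' @describeIn morSizeFactors factors of a TissueCountSet
#' @export
setMethod("morSizeFactors", "TissueCountSet", function(x) {
    morSizeFactors(counts(x))
})

#' Two-group negative-binomial Wald test on counts
#'
#' Tests, gene by gene, for a difference in mean normalised counts between an
#' adipose and a non-adipose sample group under a negative-binomial model.
#' Counts are normalised by median-of-ratios size factors; the gene-wise
#' dispersion is a method-of-moments estimate pooled within groups (floored
#' at 1e-8); the Wald statistic on the log-mean difference is referred to a
#' t distribution with n1 + n2 - 2 degrees of freedom (a small-sample
#' correction for the estimated dispersion). The log2 fold change uses a
#' pseudo-count of 0.5 on the normalised group means. No exact agreement
#' with any published large-scale DE tool is claimed; the test is calibrated
#' on simulated null data instead (see the package vignette).
#'
#' @param x a [TissueCountSet] or count matrix.
#' @param group "adipose"/"other" factor per sample. When `x` is a
#'   [TissueCountSet] and `group` is `NULL`, samples whose tissue is in
#'   `adiposeLabels` form the adipose group.
#' @param sizeFactors optional precomputed size factors (default:
#'   [morSizeFactors()]).
#' @param adiposeLabels tissue labels defining the adipose group.
#' @return data.frame, one row per gene: `gene_id`, `baseMean`,
#'   `log2FoldChange` (adipose over non-adipose), `pvalue`, `padj` (BH),
#'   `direction` in higher/lower/ns at alpha = 0.05.
#' @export
nbTwoGroupTest <- function(x, group = NULL, sizeFactors = NULL,
                           adiposeLabels = adiposeTissues()) {
    k <- if (is(x, "TissueCountSet")) counts(x) else as.matrix(x)
    if (is.null(group)) {
        if (!is(x, "TissueCountSet"))
            stop("supply `group` when x is a plain matrix")
        group <- ifelse(sampleTissues(x) %in% adiposeLabels,
                        "adipose", "other")
    }
    group <- as.character(group)
    stopifnot(length(group) == ncol(k), all(group %in% c("adipose", "other")))
    n1 <- sum(group == "adipose"); n2 <- sum(group == "other")
    if (n1 < 2L || n2 < 2L)
        stop("need at least two samples per group")
    if (is.null(sizeFactors)) sizeFactors <- morSizeFactors(k)
    q <- sweep(k, 2L, sizeFactors, "/")
    a <- group == "adipose"
    m1 <- rowMeans(q[, a, drop = FALSE])
    m2 <- rowMeans(q[, !a, drop = FALSE])
    v1 <- apply(q[, a, drop = FALSE], 1L, stats::var)
    v2 <- apply(q[, !a, drop = FALSE], 1L, stats::var)
    inv1 <- mean(1 / sizeFactors[a]); inv2 <- mean(1 / sizeFactors[!a])

    # method-of-moments dispersion pooled over the two groups:
    # Var(K/s) ~ mu * E[1/s] + alpha * mu^2
    num <- (n1 - 1) * (v1 - m1 * inv1) + (n2 - 1) * (v2 - m2 * inv2)
    den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
    alphaHat <- pmax(ifelse(den > 0, num / den, 0), 1e-8)

    seLog2 <- function(m, nG, invS, alpha)
        (m * invS / nG + alpha * m^2 / nG) / (m + 0.5)^2
    se <- sqrt(seLog2(m1, n1, inv1, alphaHat) +
               seLog2(m2, n2, inv2, alphaHat))
    lfc <- log2((m1 + 0.5) / (m2 + 0.5))
    wald <- ifelse(se > 0, (log(m1 + 0.5) - log(m2 + 0.5)) / se, 0)
    p <- 2 * stats::pt(-abs(wald), df = n1 + n2 - 2)
    allZero <- m1 == 0 & m2 == 0
    p[allZero] <- 1; lfc[allZero] <- 0
    padj <- bhAdjust(p)
    data.frame(gene_id = rownames(k), baseMean = rowMeans(q),
               log2FoldChange = lfc, pvalue = p, padj = padj,
               direction = ifelse(padj < 0.05 & lfc > 0, "higher",
                           ifelse(padj < 0.05 & lfc < 0, "lower", "ns")))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]); output is elementwise >= input and clipped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call significantly higher / lower expressed genes
#'
#' @param results data.frame from [nbTwoGroupTest()].
#' @param alpha adjusted-p threshold, default 0.05.
#' @return list with `higher` (padj < alpha and log2FC > 0) and `lower`
#'   (padj < alpha and log2FC < 0) gene-id vectors.
#' @export
callHeg <- function(results, alpha = 0.05) {
    sig <- results$padj < alpha
    list(higher = results$gene_id[sig & results$log2FoldChange > 0],
         lower = results$gene_id[sig & results$log2FoldChange < 0])
}

#' Intersect tissue-specific gene sets with higher-expressed genes
#'
#' @param tsg named list of per-tissue TSG sets (e.g. the three adipose
#'   tissues from [tsgSets()]).
#' @param heg character vector of higher-expressed genes ([callHeg()]
#'   `higher`).
#' @return a [SetReport] over the TSG sets plus a `HEG` set.
#' @export
intersectTsgHeg <- function(tsg, heg) {
    intersectSets(c(tsg, list(HEG = heg)))
}
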