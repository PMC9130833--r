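#' @include data_model.R
NULL

#' @describeIn log2p1 transform a numeric matrix
#' @export
setMethod("log2p1", "matrix", function(x) {
    if (any(x < 0)) stop("log2p1 requires non-negative values")
    log2(x + 1)
})

#' @describeIn log2p1 transform the means of a TissueProfiles (returns a
#'   plain matrix)
#' @export
setMethod("log2p1", "TissueProfiles", function(x) log2p1(profileMeans(x)))

#' Pairwise Pearson correlations between tissue profiles
#'
#' Correlates tissue columns over a gene subset, conventionally on the
#' log2(FPKM + 1) scale. Two-sided p-values come from the exact t transform
#' t = r sqrt((n - 2) / (1 - r^2)) with n - 2 degrees of freedom. A
#' zero-variance tissue profile yields `NA` correlations.
#'
#' @param x a [TissueProfiles] (transformed internally when `transform`) or
#'   an already-transformed numeric matrix, genes x tissues.
#' @param genes optional gene subset (>= 3 genes).
#' @param tissues optional tissue subset.
#' @param transform apply [log2p1()] first (default `TRUE` for
#'   [TissueProfiles] input, `FALSE` for matrices, which are assumed
#'   transformed).
#' @return list with symmetric matrices `r` and `p` (unit / empty diagonal)
#'   and `n`, the number of genes used.
#' @export
tissueCorrelations <- function(x, genes = NULL, tissues = NULL,
                               transform = is(x, "TissueProfiles")) {
    m <- if (is(x, "TissueProfiles")) profileMeans(x) else as.matrix(x)
    if (transform) m <- log2p1(m)
    if (!is.null(genes)) m <- m[genes, , drop = FALSE]
    if (!is.null(tissues)) m <- m[, tissues, drop = FALSE]
    if (nrow(m) < 3L) stop("need at least 3 genes for correlation")
    n <- nrow(m)
    sdz <- apply(m, 2L, stats::sd)
    r <- suppressWarnings(stats::cor(m))
    r[sdz == 0, ] <- NA; r[, sdz == 0] <- NA
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1] <- 0
    diag(r) <- 1; diag(p) <- NA
    list(r = r, p = p, n = n)
}

#' PCA-based outlier screen for replicate samples
#'
#' Projects log2(FPKM + 1) samples onto the first two principal components
#' (genes centred) and flags samples whose Euclidean distance to their
#' tissue centroid exceeds median + `kMads` * MAD of all within-tissue
#' distances. The centroid is the componentwise median, so that with the
#' few replicates typical per tissue an outlier cannot drag the centroid
#' toward itself and mask the screen. A tissue with a single sample is
#' never flagged.
#'
#' @param x a [TissueExpressionSet] with >= 3 samples.
#' @param kMads rule multiplier (default 3); `Inf` flags nothing.
#' @return data.frame: sample, tissue, PC1, PC2, dist, flagged.
#' @export
pcaOutlierScreen <- function(x, kMads = 3) {
    stopifnot(is(x, "TissueExpressionSet"), ncol(x) >= 3L)
    m <- log2p1(fpkm(x))
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE, rank. = 2L)
    sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
    if (ncol(sc) < 2L) sc <- cbind(sc, 0)
    tis <- sampleTissues(x)
    # order-invariant: centroids and distances depend only on tissue labels
    cent <- apply(sc, 2L, function(col) tapply(col, tis, stats::median))
    if (is.null(dim(cent))) cent <- matrix(cent, nrow = 1L,
                                           dimnames = list(unique(tis), NULL))
    d <- sqrt(rowSums((sc - cent[tis, , drop = FALSE])^2))
    multi <- table(tis)[tis] > 1L
    if (is.finite(kMads)) {
        thr <- stats::median(d[multi]) + kMads * stats::mad(d[multi])
        flagged <- multi & d > thr
    } else flagged <- rep(FALSE, length(d))
    out <- data.frame(sample = colnames(x), tissue = unname(tis),
                      PC1 = sc[, 1L], PC2 = sc[, 2L], dist = unname(d),
                      flagged = unname(flagged))
    rownames(out) <- NULL
    out
}

#' Agglomerative clustering of tissue expression profiles
#'
#' Average-linkage clustering on the correlation distance 1 - Pearson r of
#' log2(FPKM + 1) tissue profiles, optionally restricted to a gene set
#' (typically the tissue-specific genes).
#'
#' @param x a [TissueProfiles] or transformed matrix (see
#'   [tissueCorrelations()]).
#' @param genes optional gene subset.
#' @param transform apply [log2p1()] first (defaults as in
#'   [tissueCorrelations()]).
#' @return an [stats::hclust] tree over tissues.
#' @export
clusterTissues <- function(x, genes = NULL,
                           transform = is(x, "TissueProfiles")) {
    m <- if (is(x, "TissueProfiles")) profileMeans(x) else as.matrix(x)
    if (transform) m <- log2p1(m)
    if (!is.null(genes)) m <- m[genes, , drop = FALSE]
    stopifnot(ncol(m) >= 2L)
    d <- stats::as.dist(1 - stats::cor(m))
    stats::hclust(d, method = "average")
}

#' Do the given tissues form a clade of the cluster tree?
#'
#' @param hc an [stats::hclust] tree from [clusterTissues()].
#' @param tissues tissue labels to test (>= 2, a strict subset of the
#'   leaves).
#' @return `TRUE` iff the tissues form an exact monophyletic group.
#' @export
formsClade <- function(hc, tissues) {
    stopifnot(inherits(hc, "hclust"), length(tissues) >= 2L,
              all(tissues %in% hc$labels))
    phy <- ape::as.phylo(hc)
    ape::is.monophyletic(phy, tissues)
}

#' Newick string of a tissue cluster tree
#'
#' @param hc an [stats::hclust] tree.
#' @return single-element character, Newick format.
#' @export
clusterNewick <- function(hc) {
    ape::write.tree(ape::as.phylo(hc))
}
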