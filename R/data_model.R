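#' @include AllGenerics.R
NULL

#' Construct a TissueExpressionSet
#'
#' @param fpkm numeric matrix of non-negative FPKM values, genes in rows
#'   (rownames = gene ids), samples in columns (colnames = sample ids).
#' @param tissue character vector of tissue labels, one per sample, or a
#'   named vector keyed by sample id.
#' @return a validated [TissueExpressionSet].
#' @examples
#' m <- matrix(c(1, 0, 5, 2, 0.5, 4), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' tes <- TissueExpressionSet(m, tissue = c("liver", "brain"))
#' sampleTissues(tes)
#' @export
TissueExpressionSet <- function(fpkm, tissue) {
    fpkm <- as.matrix(fpkm)
    tissue <- .alignTissue(tissue, colnames(fpkm))
    new("TissueExpressionSet",
        SummarizedExperiment(assays = list(fpkm = fpkm),
                             colData = DataFrame(tissue = tissue,
                                                 row.names = colnames(fpkm))))
}

#' Construct a TissueCountSet
#'
#' @param counts non-negative integral matrix, genes x samples.
#' @param tissue tissue labels as in [TissueExpressionSet()].
#' @return a validated [TissueCountSet].
#' @export
TissueCountSet <- function(counts, tissue) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    tissue <- .alignTissue(tissue, colnames(counts))
    new("TissueCountSet",
        SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(tissue = tissue,
                                                 row.names = colnames(counts))))
}

.alignTissue <- function(tissue, samples) {
    labels <- names(tissue)
    tissue <- as.character(tissue)
    names(tissue) <- labels
    if (!is.null(names(tissue)) && !is.null(samples)) {
        missing <- setdiff(samples, names(tissue))
        if (length(missing))
            stop("no tissue label for sample(s): ",
                 paste(missing, collapse = ", "))
        tissue <- tissue[samples]
    }
    if (length(tissue) != length(samples))
        stop("need exactly one tissue label per sample (",
             length(samples), " samples, ", length(tissue), " labels)")
    unname(tissue)
}

#' @describeIn sampleTissues sample-to-tissue map of an expression set
#' @export
setMethod("sampleTissues", "SummarizedExperiment", function(x) {
    structure(as.character(colData(x)$tissue), names = colnames(x))
})

#' @describeIn fpkm FPKM assay of a TissueExpressionSet
#' @export
setMethod("fpkm", "TissueExpressionSet", function(x) assay(x, "fpkm"))

#' @describeIn TissueCountSet counts assay accessor
#' @param object a [TissueCountSet].
#' @export
setMethod("counts", "TissueCountSet", function(object) assay(object, "counts"))

setMethod("show", "TissueProfiles", function(object) {
    m <- object@means
    cat("TissueProfiles:", nrow(m), "genes x", ncol(m), "tissues\n")
    cat("tissues:", paste(utils::head(colnames(m), 6), collapse = ", "),
        if (ncol(m) > 6) "...\n" else "\n")
})

#' @describeIn profileMeans matrix accessor
#' @export
setMethod("profileMeans", "TissueProfiles", function(x) x@means)

#' Read an expression matrix and sample map from TSV
#'
#' The matrix TSV has a header row of sample ids and gene ids in the first
#' column; the sample map is a two-column TSV (sample_id, tissue), headered
#' or not. Row and column order of the matrix are preserved.
#'
#' @param path path to the FPKM matrix TSV.
#' @param sampleMap path to the sample-to-tissue map TSV.
#' @return a validated [TissueExpressionSet].
#' @export
readExpressionMatrix <- function(path, sampleMap) {
    m <- .readMatrixTsv(path)
    TissueExpressionSet(m, tissue = .readSampleMap(sampleMap))
}

#' Read a count matrix and sample map from TSV
#'
#' @inheritParams readExpressionMatrix
#' @return a validated [TissueCountSet].
#' @export
readCountMatrix <- function(path, sampleMap) {
    m <- .readMatrixTsv(path)
    TissueCountSet(m, tissue = .readSampleMap(sampleMap))
}

.readMatrixTsv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    as.matrix(df)
}

.readSampleMap <- function(path) {
    df <- utils::read.delim(path, header = FALSE, check.names = FALSE,
                            col.names = c("sample_id", "tissue"))
    # tolerate a header row
    if (identical(tolower(df$sample_id[1L]), "sample_id"))
        df <- df[-1L, , drop = FALSE]
    structure(as.character(df$tissue), names = as.character(df$sample_id))
}

#' Write an expression or count set to TSV
#'
#' Inverse of [readExpressionMatrix()] / [readCountMatrix()]; writing then
#' reading reproduces the object exactly.
#'
#' @param x a [TissueExpressionSet] or [TissueCountSet].
#' @param path matrix TSV path.
#' @param sampleMap sample-map TSV path.
#' @return invisibly, `path`.
#' @export
writeExpressionMatrix <- function(x, path, sampleMap) {
    m <- if (is(x, "TissueExpressionSet")) fpkm(x) else counts(x)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    st <- sampleTissues(x)
    utils::write.table(data.frame(sample_id = names(st), tissue = unname(st)),
                       sampleMap, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read gene biotypes from a GFF3 annotation
#'
#' Extracts `gene` features and collapses their `gene_biotype` (fallback
#' `biotype`) attribute to four classes: `protein_coding`, `lncRNA`
#' (accepting the `lnc_RNA` synonym), `miRNA`, and `other` for everything
#' else (pseudogenes, tRNA, ...). A gene feature without the attribute is
#' classed `other` with a warning, not an error.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene_id`, `biotype` (factor with the
#'   four levels above).
#' @export
readGeneAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else gr$ID
    raw <- if ("gene_biotype" %in% colnames(S4Vectors::mcols(gr)))
        gr$gene_biotype
    else if ("biotype" %in% colnames(S4Vectors::mcols(gr)))
        gr$biotype
    else rep(NA_character_, length(gr))
    if (anyNA(raw))
        warning(sum(is.na(raw)),
                " gene(s) without a biotype attribute classed as 'other'")
    data.frame(gene_id = as.character(ids),
               biotype = collapseBiotype(raw))
}

#' Collapse raw biotype strings to the four analysis classes
#'
#' @param x character vector of raw biotypes (NA allowed).
#' @return factor with levels protein_coding, lncRNA, miRNA, other.
#' @export
collapseBiotype <- function(x) {
    cls <- rep("other", length(x))
    cls[x %in% "protein_coding"] <- "protein_coding"
    cls[x %in% c("lncRNA", "lnc_RNA")] <- "lncRNA"
    cls[x %in% "miRNA"] <- "miRNA"
    factor(cls, levels = biotypeClasses())
}

#' The four biotype classes
#' @return character vector of class labels in canonical order.
#' @export
biotypeClasses <- function() c("protein_coding", "lncRNA", "miRNA", "other")

#' @describeIn tissueMeans replicate-averaged tissue profiles
#' @export
setMethod("tissueMeans", "TissueExpressionSet", function(x) {
    m <- fpkm(x)
    tis <- sampleTissues(x)
    levels <- unique(unname(tis))
    means <- vapply(levels, function(t)
        rowMeans(m[, tis == t, drop = FALSE]), numeric(nrow(m)))
    if (nrow(m) == 1L) means <- matrix(means, nrow = 1L,
                                       dimnames = list(rownames(m), levels))
    new("TissueProfiles", means = means)
})

#' Remove genes below an expression floor in every tissue
#'
#' Retains exactly the genes whose maximum tissue mean is at or above
#' `threshold` (i.e. removes genes strictly below it in all tissues),
#' preserving order. Idempotent, and monotone in the threshold.
#'
#' @param tp a [TissueProfiles].
#' @param threshold positive expression floor (FPKM), default 1.
#' @return filtered [TissueProfiles]; an empty result is allowed (with a
#'   message).
#' @export
filterLowExpression <- function(tp, threshold = 1) {
    stopifnot(is(tp, "TissueProfiles"), threshold > 0)
    m <- profileMeans(tp)
    keep <- apply(m, 1L, max) >= threshold
    if (!any(keep))
        message("filterLowExpression: no gene reaches ", threshold,
                " in any tissue")
    new("TissueProfiles", means = m[keep, , drop = FALSE])
}
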