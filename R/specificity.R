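#' @include data_model.R
NULL

#' @describeIn tauIndex tau of a single per-tissue profile vector
#' @export
setMethod("tauIndex", "numeric", function(x, ...) {
    if (length(x) < 2L)
        stop("tau needs at least two tissues")
    if (any(!is.finite(x)) || any(x < 0))
        stop("tau requires finite, non-negative expression values")
    mx <- max(x)
    if (mx == 0)
        return(NA_real_)  # all-zero profile: specificity undefined
    sum(1 - x / mx) / (length(x) - 1L)
})

#' @describeIn tauIndex per-gene tau over a TissueProfiles matrix; pass
#'   `log2p1 = TRUE` to compute tau on log2(mean + 1) profiles
#' @param log2p1 logical; transform means with log2(x + 1) first (default
#'   `FALSE`: tau is computed on the raw FPKM scale).
#' @export
setMethod("tauIndex", "TissueProfiles", function(x, log2p1 = FALSE, ...) {
    m <- profileMeans(x)
    if (log2p1) m <- log2(m + 1)
    mx <- apply(m, 1L, max)
    tau <- ifelse(mx > 0, rowSums(1 - m / pmax(mx, .Machine$double.xmin)) /
                      (ncol(m) - 1L), NA_real_)
    names(tau) <- rownames(m)
    tau
})

#' Select candidate tissue-specific genes by tau quantile
#'
#' Takes the `ceiling(topFraction * G)` genes of highest tau among the G
#' genes of the (already expression-filtered) profile matrix. Ties at the
#' boundary tau are resolved deterministically: genes strictly above the
#' boundary enter first, remaining slots are filled in lexicographic gene-id
#' order among the tied genes. Genes with undefined tau (all-zero profile)
#' are excluded before the cut.
#'
#' @param tp a [TissueProfiles], normally the output of
#'   [filterLowExpression()].
#' @param topFraction fraction of genes to keep, in (0, 1\]; default 0.20.
#' @param tau optional precomputed tau vector (named by gene) to avoid
#'   recomputation.
#' @return character vector of candidate gene ids.
#' @export
candidatesByTau <- function(tp, topFraction = 0.20, tau = NULL) {
    stopifnot(is(tp, "TissueProfiles"),
              topFraction > 0, topFraction <= 1)
    if (is.null(tau)) tau <- tauIndex(tp)
    tau <- tau[!is.na(tau)]
    ids <- names(tau)
    size <- ceiling(topFraction * length(tau))
    ids[order(-tau, ids)][seq_len(size)]
}

#' Call tissue-specific genes from candidates
#'
#' A candidate gene is specific to tissue t iff its mean FPKM in t exceeds
#' `fpkmMin` (strictly) and t ranks within the top `rankK` tissues of the
#' gene's profile. Ranks are dense and descending, so tissues tied at rank
#' `rankK` are all admitted; a gene can be specific to up to `rankK`
#' tissues (more under ties). Non-candidates are never called.
#'
#' @param tp a [TissueProfiles] containing all candidates.
#' @param candidates character vector of candidate gene ids (from
#'   [candidatesByTau()]).
#' @param fpkmMin expression floor (strict), default 1.
#' @param rankK maximum admissible dense rank, default 3.
#' @return data.frame with one row per gene of `tp`: `gene_id`, `tau`,
#'   `candidate`, and `specificTissues` (comma-separated, "" when the gene
#'   is not called).
#' @export
callTissueSpecific <- function(tp, candidates, fpkmMin = 1, rankK = 3L) {
    stopifnot(is(tp, "TissueProfiles"))
    m <- profileMeans(tp)
    if (length(setdiff(candidates, rownames(m))))
        stop("candidates must be a subset of the profile genes")
    tau <- tauIndex(tp)
    tissues <- colnames(m)
    spec <- character(nrow(m))
    for (g in match(candidates, rownames(m))) {
        x <- m[g, ]
        denseRank <- match(x, sort(unique(x), decreasing = TRUE))
        hit <- x > fpkmMin & denseRank <= rankK
        spec[g] <- paste(tissues[hit], collapse = ",")
    }
    data.frame(gene_id = rownames(m), tau = unname(tau),
               candidate = rownames(m) %in% candidates,
               specificTissues = spec)
}

#' Per-tissue gene sets from TSG calls
#'
#' @param calls data.frame from [callTissueSpecific()].
#' @return named list, tissue -> character vector of genes called specific
#'   there.
#' @export
tsgSets <- function(calls) {
    pairs <- strsplit(calls$specificTissues, ",")
    genes <- rep(calls$gene_id, lengths(pairs))
    tissue <- unlist(pairs)
    keep <- nzchar(tissue)
    split(genes[keep], tissue[keep])
}

#' Precision and recall of planted home-tissue recovery
#'
#' Compares TSG calls with the generator's truth labels, restricted to the
#' planted genes: recall is the fraction of planted (gene, home-tissue)
#' pairs the caller recovered, and precision is the fraction of tissue calls
#' made for planted genes that are true home tissues. (Candidate selection
#' by a fixed top quantile necessarily also admits non-planted genes, so
#' overall call counts are reported separately in `nCallsOther`.)
#'
#' @param calls data.frame from [callTissueSpecific()].
#' @param truth truth data.frame from [simulateExpression()].
#' @return list with `precision`, `recall`, `nPlantedPairs`, `nCallsPlanted`,
#'   `nCallsOther`.
#' @export
tsgRecovery <- function(calls, truth) {
    homes <- homeTissueList(truth)
    planted <- names(homes)[lengths(homes) > 0]
    called <- homeTissueList(data.frame(gene_id = calls$gene_id,
                                        homeTissues = calls$specificTissues))
    tp <- sum(vapply(planted, function(g)
        length(intersect(homes[[g]], called[[g]])), numeric(1)))
    nPlantedPairs <- sum(lengths(homes))
    nCallsPlanted <- sum(lengths(called[planted]))
    nCallsOther <- sum(lengths(called)) - nCallsPlanted
    list(precision = if (nCallsPlanted > 0) tp / nCallsPlanted else NA_real_,
         recall = tp / nPlantedPairs,
         nPlantedPairs = nPlantedPairs,
         nCallsPlanted = nCallsPlanted,
         nCallsOther = nCallsOther)
}

#' Biotype composition of a gene set
#'
#' @param genes non-empty character vector of gene ids.
#' @param annotation data.frame with `gene_id` and `biotype` columns (from
#'   [readGeneAnnotation()] or the simulator); must cover all `genes`.
#' @return named numeric vector of proportions over the four biotype
#'   classes, summing to 1.
#' @export
biotypeComposition <- function(genes, annotation) {
    if (length(genes) == 0L)
        stop("cannot compute the biotype composition of an empty gene set")
    idx <- match(genes, annotation$gene_id)
    if (anyNA(idx))
        stop("gene(s) missing from the annotation: ",
             paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
    b <- factor(as.character(annotation$biotype[idx]),
                levels = biotypeClasses())
    tab <- prop.table(table(b))
    structure(as.numeric(tab), names = names(tab))[biotypeClasses()]
}

#' Intersect named gene sets into a region report
#'
#' Computes the cardinality of every disjoint membership region (the
#' 2^k - 1 Venn regions) of k >= 2 named gene sets.
#'
#' @param sets named list of >= 2 character gene sets.
#' @return a [SetReport].
#' @examples
#' sr <- intersectSets(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
#' intersectionCount(sr, c("A", "B"))  # 2
#' unionCount(sr)                      # 4
#' @export
intersectSets <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 2L)
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("sets must be named")
    sets <- lapply(sets, unique)
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L)
        member <- matrix(member, nrow = 1L, dimnames = list(NULL, names(sets)))
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
    names(patterns) <- names(sets)
    patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
    key <- apply(member, 1L, paste, collapse = "|")
    pkey <- apply(patterns, 1L, paste, collapse = "|")
    patterns$count <- as.vector(table(factor(key, levels = pkey)))
    rownames(patterns) <- NULL
    new("SetReport", sets = sets, regions = patterns)
}

#' Disjoint region counts of a SetReport
#' @param x a [SetReport].
#' @return data.frame of membership patterns and counts.
#' @export
regionCounts <- function(x) {
    stopifnot(is(x, "SetReport"))
    x@regions
}

#' Cardinality of the intersection of the named sets
#'
#' The plain k-wise intersection |A1 n ... n Ak| (not the disjoint region),
#' i.e. the sum of all regions inside every named set.
#'
#' @param x a [SetReport].
#' @param which character vector of set names (default: all sets).
#' @return integer cardinality.
#' @export
intersectionCount <- function(x, which = names(x@sets)) {
    stopifnot(is(x, "SetReport"), all(which %in% names(x@sets)))
    r <- x@regions
    inside <- rowSums(as.matrix(r[which])) == length(which)
    sum(r$count[inside])
}

#' Union cardinality of all sets in a SetReport
#' @param x a [SetReport].
#' @return integer cardinality of the union.
#' @export
unionCount <- function(x) sum(regionCounts(x)$count)

setMethod("show", "SetReport", function(object) {
    cat("SetReport:", length(object@sets), "sets (",
        paste(names(object@sets), collapse = ", "), "), union",
        unionCount(object), "genes\n")
    print(object@regions)
})
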