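#' @include data_model.R
NULL

#' Read a long-format qPCR Ct table
#'
#' Expects a headered TSV with columns `sample`, `tissue`, `gene`,
#' `replicate`, `ct` (threshold cycles).
#'
#' @param path TSV path.
#' @return data.frame with those columns; Ct values must be finite.
#' @export
readCtTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    need <- c("sample", "tissue", "gene", "replicate", "ct")
    if (!all(need %in% names(df)))
        stop("Ct table needs columns: ", paste(need, collapse = ", "))
    if (any(!is.finite(df$ct))) stop("Ct values must be finite")
    df
}

#' Relative expression by the 2^-ddCt method
#'
#' Per tissue, technical replicates are averaged on the Ct scale, then
#' dCt = mean Ct(target) - mean Ct(reference); ddCt subtracts the calibrator
#' tissue's dCt, and relative expression is 2^-ddCt (so the calibrator's
#' fold is exactly 1, and one cycle of ddCt is a two-fold change; the
#' amplification efficiency is fixed at 2).
#'
#' @param ct Ct data.frame with at least `tissue`, `gene`, `ct` columns (see
#'   [readCtTable()]).
#' @param target target gene name.
#' @param reference internal-control gene name (e.g. GAPDH).
#' @param calibrator calibrator tissue; must carry both genes.
#' @return data.frame, one row per tissue with a target measurement:
#'   `tissue`, `dCt`, `ddCt`, `fold`. A tissue lacking the reference gene is
#'   reported with `NA` values (with a warning), not dropped silently.
#' @export
deltaDeltaCt <- function(ct, target, reference, calibrator) {
    stopifnot(all(c("tissue", "gene", "ct") %in% names(ct)))
    tgt <- ct[ct$gene == target, ]
    ref <- ct[ct$gene == reference, ]
    if (nrow(tgt) == 0L) stop("no Ct rows for target gene '", target, "'")
    meanCt <- function(df) tapply(df$ct, df$tissue, mean)
    mt <- meanCt(tgt)
    mr <- meanCt(ref)
    tissues <- names(mt)
    dCt <- mt - mr[tissues]
    if (anyNA(dCt))
        warning("reference gene '", reference, "' missing for tissue(s): ",
                paste(tissues[is.na(dCt)], collapse = ", "))
    if (!calibrator %in% tissues || is.na(dCt[calibrator]))
        stop("calibrator tissue '", calibrator,
             "' lacks target or reference measurements")
    ddCt <- dCt - dCt[calibrator]
    data.frame(tissue = tissues, dCt = unname(dCt), ddCt = unname(ddCt),
               fold = unname(2^-ddCt))
}

#' Simulate a small qPCR Ct table
#'
#' Desk-scale fixture generator: a reference gene around 15 cycles in every
#' tissue and a target gene whose Ct decreases by log2(fold) cycles in
#' tissues where it is planted higher, plus replicate noise.
#'
#' @param tissues tissue labels (default 4 tissues of the panel).
#' @param target,reference gene names.
#' @param folds named numeric vector of true fold changes relative to the
#'   first tissue (default 1 everywhere).
#' @param replicates technical replicates per (tissue, gene).
#' @param noiseSd replicate Ct noise, cycles.
#' @param seed RNG seed.
#' @return long-format Ct data.frame as read by [readCtTable()].
#' @export
simulateCtTable <- function(tissues = tissuePanel(4L), target = "TARGET",
                            reference = "GAPDH", folds = NULL,
                            replicates = 3L, noiseSd = 0.1, seed = 1L) {
    if (is.null(folds)) folds <- structure(rep(1, length(tissues)),
                                           names = tissues)
    .withSeed(seed, {
        rows <- do.call(rbind, lapply(tissues, function(t) {
            refCt <- 15 + rnorm(replicates, 0, noiseSd)
            tgtCt <- 22 - log2(folds[[t]]) + rnorm(replicates, 0, noiseSd)
            data.frame(sample = sprintf("%s_q%d", t, seq_len(replicates)),
                       tissue = t,
                       gene = rep(c(reference, target), each = replicates),
                       replicate = rep(seq_len(replicates), 2L),
                       ct = c(refCt, tgtCt))
        }))
        rownames(rows) <- NULL
        rows
    })
}
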