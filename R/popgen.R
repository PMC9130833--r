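#' @include data_model.R
NULL

#' Construct a GenotypeTable
#'
#' @param population character vector of population labels.
#' @param nDD,nID,nII genotype counts (same length as `population`).
#' @return a validated [GenotypeTable].
#' @examples
#' gt <- GenotypeTable("Luxi", 24, 29, 6)
#' alleleFrequencies(gt)
#' @export
GenotypeTable <- function(population, nDD, nID, nII) {
    new("GenotypeTable", population = as.character(population),
        nDD = as.integer(nDD), nID = as.integer(nID), nII = as.integer(nII))
}

setMethod("show", "GenotypeTable", function(object) {
    cat("GenotypeTable:", length(object@population), "population(s)\n")
    print(as.data.frame(object))
})

#' @describeIn GenotypeTable coerce to data.frame (population, nDD, nID,
#'   nII, n)
#' @param x a [GenotypeTable].
#' @param ... ignored.
#' @export
as.data.frame.GenotypeTable <- function(x, ...) {
    data.frame(population = x@population, nDD = x@nDD, nID = x@nID,
               nII = x@nII, n = x@nDD + x@nID + x@nII)
}

#' Read genotype counts from TSV
#'
#' Headered TSV with columns population, nDD, nID, nII.
#'
#' @param path TSV path.
#' @return a [GenotypeTable].
#' @export
readGenotypeTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    need <- c("population", "nDD", "nID", "nII")
    if (!all(need %in% names(df)))
        stop("genotype table needs columns: ", paste(need, collapse = ", "))
    GenotypeTable(df$population, df$nDD, df$nID, df$nII)
}

#' Read a long-format trait table from TSV
#'
#' Headered TSV with columns individual_id, sex, genotype, trait, value.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readTraitTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    need <- c("individual_id", "sex", "genotype", "trait", "value")
    if (!all(need %in% names(df)))
        stop("trait table needs columns: ", paste(need, collapse = ", "))
    if (any(!is.finite(df$value))) stop("trait values must be finite")
    if (any(!df$genotype %in% c("DD", "ID", "II")))
        stop("genotypes must be DD, ID or II")
    df
}

#' Reconstruct integer genotype counts from printed frequencies
#'
#' Published genotype tables print frequencies and a sample size; exact
#' statistics need the integer counts back. Counts are `round(freq * n)`;
#' if the rounded counts do not sum to n, the class with the largest
#' rounding remainder is adjusted by the (at most one) missing unit.
#'
#' @param freqs numeric length-3 genotype frequencies (DD, ID, II), summing
#'   to 1 within 0.01.
#' @param n sample size.
#' @param population population label.
#' @return a one-population [GenotypeTable].
#' @examples
#' countsFromFrequencies(c(0.407, 0.492, 0.102), 59)   # 24, 29, 6
#' countsFromFrequencies(c(0.833, 0.161, 0.006), 516)  # 430, 83, 3
#' @export
countsFromFrequencies <- function(freqs, n, population = "pop") {
    stopifnot(length(freqs) == 3L, n >= 1)
    if (any(freqs < 0) || abs(sum(freqs) - 1) > 0.01)
        stop("frequencies must be non-negative and sum to 1 within 0.01")
    raw <- freqs * n
    cnt <- round(raw)
    diff <- n - sum(cnt)
    if (abs(diff) > 1)
        stop("frequencies irreconcilable with n (off by ", abs(diff),
             " after rounding)")
    if (diff != 0) {
        rem <- raw - floor(raw)
        idx <- if (diff > 0) which.max(ifelse(cnt == floor(raw), rem, -Inf))
               else which.max(ifelse(cnt > floor(raw), 1 - rem, -Inf))
        cnt[idx] <- cnt[idx] + diff
    }
    GenotypeTable(population, cnt[1L], cnt[2L], cnt[3L])
}

.alleleFreqD <- function(x) (2 * x@nDD + x@nID) / (2 * (x@nDD + x@nID + x@nII))

#' @describeIn alleleFrequencies frequencies from genotype counts
#' @export
setMethod("alleleFrequencies", "GenotypeTable", function(x) {
    pD <- .alleleFreqD(x)
    data.frame(population = x@population, pD = pD, pI = 1 - pD)
})

#' @describeIn hweChiSquare chi-square test per population
#' @export
setMethod("hweChiSquare", "GenotypeTable", function(x) {
    p <- .alleleFreqD(x)
    q <- 1 - p
    n <- x@nDD + x@nID + x@nII
    obs <- cbind(x@nDD, x@nID, x@nII)
    expd <- cbind(n * p^2, 2 * n * p * q, n * q^2)
    chi2 <- vapply(seq_along(n), function(i) {
        e <- expd[i, ]; o <- obs[i, ]
        sum(((o - e)^2 / e)[e > 0])
    }, numeric(1))
    data.frame(population = x@population, chi2 = chi2, df = 1L,
               p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
               lowCount = apply(expd, 1L, function(e) any(e > 0 & e < 1)))
})

#' @describeIn diversityStats diversity parameters per population
#'
#' Columns: allele frequencies `pD`/`pI`; `hom` = p^2 + q^2, the sum of
#' squared allele frequencies (homozygosity -- printed as "Ho" in the
#' breed-diversity tables this reproduces); `het` = 1 - hom (expected
#' heterozygosity); `ne` = 1/hom, the effective allele number (printed as
#' "Ne"); `pic` = 1 - (p^2 + q^2) - 2 p^2 q^2, the biallelic Botstein
#' polymorphism information content; and the Hardy-Weinberg chi-square
#' columns of [hweChiSquare()]. A monomorphic locus degenerates to hom = 1,
#' ne = 1, pic = 0.
#' @export
setMethod("diversityStats", "GenotypeTable", function(x) {
    p <- .alleleFreqD(x)
    q <- 1 - p
    hom <- p^2 + q^2
    hwe <- hweChiSquare(x)
    data.frame(population = x@population, n = x@nDD + x@nID + x@nII,
               pD = p, pI = q, hom = hom, het = 1 - hom, ne = 1 / hom,
               pic = 1 - hom - 2 * p^2 * q^2,
               hweChi2 = hwe$chi2, hweDf = hwe$df, hweP = hwe$p)
})

#' Levene's test with mean centring
#'
#' One-way ANOVA on absolute deviations from group means; the variance-
#' equality gate used to choose between the pooled and Welch t-test.
#'
#' @param values numeric trait values.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @return two-sided p-value; exactly 1 when every group has zero spread.
#' @export
leveneCenterMean <- function(values, groups) {
    groups <- factor(groups)
    stopifnot(nlevels(groups) >= 2L, all(table(groups) >= 2L))
    dev <- abs(values - stats::ave(values, groups))
    # constant deviations (e.g. both groups identical, or zero spread
    # everywhere) carry no variance signal
    if (stats::var(dev) == 0) return(1)
    fit <- stats::aov(dev ~ groups)
    summary(fit)[[1L]][["Pr(>F)"]][1L]
}

#' Independent two-sample t-test from summary statistics
#'
#' Reconstructs the t-test from printed (mean, SE, n) pairs. The pooled
#' variant uses s^2 = ((n1-1) n1 se1^2 + (n2-1) n2 se2^2) / (n1+n2-2) with
#' df = n1+n2-2; the Welch variant uses t = dmean / sqrt(se1^2 + se2^2) with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,se1,n1 first group's mean, standard error and size.
#' @param mean2,se2,n2 second group's.
#' @param variant "pooled" or "welch".
#' @return list with `t`, `df`, `p` (two-sided).
#' @examples
#' ttestFromSummary(11.66, 0.94, 25, 14.6, 0.57, 4, "welch")$p   # ~0.014
#' ttestFromSummary(7.69, 0.17, 54, 9.00, 0.41, 10, "pooled")$p  # ~0.004
#' @export
ttestFromSummary <- function(mean1, se1, n1, mean2, se2, n2,
                             variant = c("pooled", "welch")) {
    variant <- match.arg(variant)
    stopifnot(n1 >= 2, n2 >= 2)
    if (!is.finite(se1) || !is.finite(se2) || se1 <= 0 || se2 <= 0)
        stop("standard errors must be positive and finite")
    d <- mean1 - mean2
    if (variant == "pooled") {
        df <- n1 + n2 - 2
        s2 <- ((n1 - 1) * n1 * se1^2 + (n2 - 1) * n2 * se2^2) / df
        t <- d / sqrt(s2 * (1 / n1 + 1 / n2))
    } else {
        v1 <- se1^2; v2 <- se2^2
        t <- d / sqrt(v1 + v2)
        df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    }
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Genotype-trait association with group-size and variance gating
#'
#' Per sex stratum and trait: genotype groups with fewer than `minN`
#' individuals are excluded; each remaining genotype pair is tested with an
#' independent two-sample t-test, pooled when the mean-centred Levene test
#' does not reject variance equality at 0.05 and Welch otherwise.
#'
#' @param traits long-format trait data.frame (see [readTraitTable()] /
#'   [simulateTraits()]).
#' @param minN minimum group size, default 3.
#' @param stratifyBySex analyse each sex separately (default `TRUE`).
#' @return data.frame, one row per (sex, trait, genotype pair): group means,
#'   SEs and sizes, `leveneP`, the `variant` used, `t`, `df`, `p`. Strata
#'   with fewer than two eligible groups are skipped with a message.
#' @export
associate <- function(traits, minN = 3L, stratifyBySex = TRUE) {
    if (!stratifyBySex) traits$sex <- "all"
    out <- list()
    for (sx in unique(traits$sex)) for (tr in unique(traits$trait)) {
        d <- traits[traits$sex == sx & traits$trait == tr, ]
        if (nrow(d) == 0L) next
        sizes <- table(d$genotype)
        ok <- names(sizes)[sizes >= minN]
        if (length(ok) < 2L) {
            message("associate: ", sx, "/", tr,
                    " skipped (fewer than two genotype groups with n >= ",
                    minN, ")")
            next
        }
        for (i in seq_len(length(ok) - 1L)) for (j in seq(i + 1L, length(ok))) {
            g1 <- d$value[d$genotype == ok[i]]
            g2 <- d$value[d$genotype == ok[j]]
            lev <- leveneCenterMean(c(g1, g2),
                                    rep(c("a", "b"), c(length(g1), length(g2))))
            variant <- if (lev >= 0.05) "pooled" else "welch"
            tt <- ttestFromSummary(mean(g1), stats::sd(g1) / sqrt(length(g1)),
                                   length(g1),
                                   mean(g2), stats::sd(g2) / sqrt(length(g2)),
                                   length(g2), variant)
            out[[length(out) + 1L]] <- data.frame(
                sex = sx, trait = tr, genotype1 = ok[i], genotype2 = ok[j],
                mean1 = mean(g1), se1 = stats::sd(g1) / sqrt(length(g1)),
                n1 = length(g1),
                mean2 = mean(g2), se2 = stats::sd(g2) / sqrt(length(g2)),
                n2 = length(g2),
                leveneP = lev, variant = variant,
                t = tt$t, df = tt$df, p = tt$p)
        }
    }
    if (length(out) == 0L) return(data.frame())
    do.call(rbind, out)
}
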