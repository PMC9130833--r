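test_that("printed genotype frequencies reconstruct to integer counts", {
    luxi <- as.data.frame(countsFromFrequencies(c(0.407, 0.492, 0.102), 59))
    expect_identical(c(luxi$nDD, luxi$nID, luxi$nII), c(24L, 29L, 6L))
    sh <- as.data.frame(countsFromFrequencies(c(0.833, 0.161, 0.006), 516))
    expect_identical(c(sh$nDD, sh$nID, sh$nII), c(430L, 83L, 3L))
    mono <- as.data.frame(countsFromFrequencies(c(1, 0, 0), 10))
    expect_identical(c(mono$nDD, mono$nID, mono$nII), c(10L, 0L, 0L))
    expect_error(countsFromFrequencies(c(0.5, 0.3, 0.1), 50), "sum to 1")
})

test_that("allele frequencies follow the gene-counting formula", {
    expect_equal(alleleFrequencies(GenotypeTable("sh", 430, 83, 3))$pD,
                 943 / 1032)
    expect_equal(alleleFrequencies(GenotypeTable("m", 10, 0, 0))$pD, 1)
    expect_equal(alleleFrequencies(GenotypeTable("h", 0, 10, 0))$pD, 0.5)
})

test_that("diversity statistics match closed forms and printed breed values", {
    # p = q = 0.5 closed forms
    ds <- diversityStats(GenotypeTable("sym", 25, 50, 25))
    expect_equal(ds$hom, 0.5)
    expect_equal(ds$ne, 2)
    expect_equal(ds$pic, 0.375)
    # published breed rows, 3-decimal agreement
    rows <- list(list(c(0.833, 0.161, 0.006), 516, c(0.914, 0.842, 1.187, 0.145)),
                 list(c(0.407, 0.492, 0.102), 59, c(0.653, 0.547, 1.830, 0.351)),
                 list(c(0.600, 0.400, 0.000), 60, c(0.800, 0.680, 1.471, 0.269)),
                 list(c(0.811, 0.189, 0.000), 37, c(0.905, 0.829, 1.207, 0.157)))
    for (r in rows) {
        ds <- diversityStats(countsFromFrequencies(r[[1]], r[[2]]))
        expect_equal(round(c(ds$pD, ds$hom, ds$ne, ds$pic), 3), r[[3]])
    }
    # monomorphic locus degenerates cleanly
    mono <- diversityStats(GenotypeTable("m", 12, 0, 0))
    expect_equal(c(mono$hom, mono$ne, mono$pic), c(1, 1, 0))
})

test_that("diversity identities hold over random genotype tables", {
    set.seed(41)
    for (i in 1:200) {
        cnt <- as.vector(rmultinom(1, sample(10:500, 1), runif(3, 0.05, 1)))
        gt <- GenotypeTable("r", cnt[1], cnt[2], cnt[3])
        ds <- diversityStats(gt)
        expect_equal(ds$het + ds$hom, 1)
        expect_equal(ds$ne * ds$hom, 1)
        expect_lte(ds$pic, ds$het)
        expect_lt(ds$het, 1)
        expect_gte(ds$ne, 1); expect_lte(ds$ne, 2)
        expect_true(ds$hweP > 0 && ds$hweP <= 1)
    }
})

test_that("the HWE chi-square matches its closed forms and chisq.test", {
    perfect <- hweChiSquare(GenotypeTable("hw", 25, 50, 25))
    expect_equal(perfect$chi2, 0)
    expect_equal(perfect$p, 1)
    extreme <- hweChiSquare(GenotypeTable("x", 50, 0, 50))
    expect_equal(extreme$chi2, 100)  # equals n for the all-homozygote extreme
    expect_lt(extreme$p, 0.001)
    # oracle: chisq.test against expected HW proportions, df corrected to 1
    obs <- c(24, 29, 6)
    p <- (2 * 24 + 29) / (2 * 59); q <- 1 - p
    ref <- suppressWarnings(chisq.test(obs, p = c(p^2, 2 * p * q, q^2)))
    luxi <- hweChiSquare(GenotypeTable("luxi", 24, 29, 6))
    expect_equal(luxi$chi2, unname(ref$statistic))
    expect_equal(luxi$p, pchisq(unname(ref$statistic), 1, lower.tail = FALSE))
})

test_that("mean-centred Levene gates variance equality", {
    g <- rep(c("a", "b"), each = 50)
    expect_equal(leveneCenterMean(rep(c(1, 2), 50), g), 1)
    set.seed(43)
    unequal <- c(rnorm(50, sd = 1), rnorm(50, sd = 10))
    expect_lt(leveneCenterMean(unequal, g), 0.05)
    # calibration: equal variances keep the rejection rate near alpha
    rej <- vapply(1:400, function(i) {
        leveneCenterMean(rnorm(60), rep(c("a", "b"), each = 30)) < 0.05
    }, logical(1))
    expect_gt(mean(rej), 0.01); expect_lt(mean(rej), 0.10)
})

test_that("summary t-tests reproduce published associations and raw-data tests", {
    cerv <- ttestFromSummary(11.66, 0.94, 25, 14.6, 0.57, 4, "welch")
    expect_equal(cerv$p, 0.014, tolerance = 0.003 / 0.014)
    rsi <- ttestFromSummary(7.69, 0.17, 54, 9.00, 0.41, 10, "pooled")
    expect_equal(rsi$p, 0.004, tolerance = 0.003 / 0.004)
    eq <- ttestFromSummary(5, 0.2, 10, 5, 0.3, 12, "pooled")
    expect_equal(eq$t, 0); expect_equal(eq$p, 1)
    expect_error(ttestFromSummary(1, 0, 5, 2, 0.1, 5), "positive")
    # oracle: t.test on raw data whose summary stats match
    set.seed(47)
    x <- rnorm(20, 10, 2); y <- rnorm(15, 12, 2)
    mine <- ttestFromSummary(mean(x), sd(x) / sqrt(20), 20,
                             mean(y), sd(y) / sqrt(15), 15, "pooled")
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value)
    minw <- ttestFromSummary(mean(x), sd(x) / sqrt(20), 20,
                             mean(y), sd(y) / sqrt(15), 15, "welch")
    refw <- t.test(x, y)
    expect_equal(minw$df, unname(refw$parameter))
    expect_equal(minw$p, refw$p.value)
})

test_that("association drops small groups and finds planted effects", {
    g <- c(rep("DD", 50), rep("ID", 50), rep("II", 2))
    tr <- simulateTraits(g, c(DD = 0, ID = 3, II = 6), sd = 1, seed = 51)
    res <- associate(tr, minN = 3)
    expect_false(any(res$genotype1 == "II" | res$genotype2 == "II"))
    expect_identical(nrow(res), 1L)  # only DD vs ID eligible
    expect_lt(res$p, 0.05)
    # fewer than two eligible groups: skipped with a message, empty result
    small <- simulateTraits(c("DD", "DD", "DD", "ID", "ID"),
                            c(DD = 0, ID = 1), sd = 1, seed = 52)
    expect_message(empty <- associate(small, minN = 3), "skipped")
    expect_identical(nrow(empty), 0L)
})

test_that("association keeps its type-I error near alpha under the null", {
    rej <- vapply(1:1000, function(i) {
        tr <- simulateTraits(rep(c("DD", "ID"), each = 20),
                             c(DD = 0, ID = 0), sd = 1, seed = 1000 + i)
        associate(tr, minN = 3)$p < 0.05
    }, logical(1))
    expect_gt(mean(rej), 0.03); expect_lt(mean(rej), 0.08)
})
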