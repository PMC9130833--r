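test_that("expression matrix TSV round-trips identically", {
    tes <- toyExpressionSet()
    mPath <- withr::local_tempfile(fileext = ".tsv")
    sPath <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionMatrix(tes, mPath, sPath)
    back <- readExpressionMatrix(mPath, sPath)
    expect_identical(dim(back), c(3L, 4L))
    expect_equal(fpkm(back), fpkm(tes))
    expect_identical(sampleTissues(back), sampleTissues(tes))
    # count sets round-trip through the same writer
    tcs <- TissueCountSet(matrix(0:5, 2, 3,
                                 dimnames = list(c("g1", "g2"),
                                                 c("a", "b", "c"))),
                          tissue = c("x", "x", "y"))
    writeExpressionMatrix(tcs, mPath, sPath)
    expect_equal(counts(readCountMatrix(mPath, sPath)), counts(tcs))
})

test_that("validation names the offending gene and sample", {
    m <- toyFpkm()
    m["gB", "brain_1"] <- -0.2
    expect_error(TissueExpressionSet(m, tissue = c("l", "l", "b", "b")),
                 "gB.*brain_1")
    expect_error(TissueExpressionSet(toyFpkm(),
                                     tissue = c(liver_1 = "l", liver_2 = "l",
                                                brain_1 = "b")),
                 "brain_2")
    expect_error(TissueCountSet(matrix(c(1.5, 2), 1, 2,
                                       dimnames = list("g", c("a", "b"))),
                                tissue = c("x", "y")),
                 "integral")
})

test_that("GFF3 biotypes collapse to the four classes", {
    gff <- writeToyGff3(withr::local_tempfile(fileext = ".gff3"))
    ann <- readGeneAnnotation(gff)
    expect_setequal(ann$gene_id, paste0("g", 1:4))
    expect_identical(as.character(ann$biotype[match(paste0("g", 1:4),
                                                    ann$gene_id)]),
                     c("protein_coding", "lncRNA", "miRNA", "other"))
    comp <- biotypeComposition(ann$gene_id, ann)
    expect_equal(unname(comp), rep(0.25, 4))
    # lnc_RNA synonym and a missing attribute
    expect_identical(as.character(collapseBiotype(c("lnc_RNA", NA))),
                     c("lncRNA", "other"))
})

test_that("tissue means average replicates and respect sample order", {
    tes <- toyExpressionSet()
    tp <- tissueMeans(tes)
    expect_equal(profileMeans(tp)["gA", "liver"], 11)  # mean(10, 12)
    expect_equal(profileMeans(tp)["gC", "brain"], 8.5)
    # single-replicate tissue is copied unchanged
    one <- TissueExpressionSet(toyFpkm()[, 1:3],
                               tissue = c("liver", "liver", "brain"))
    expect_equal(profileMeans(tissueMeans(one))[, "brain"],
                 toyFpkm()[, "brain_1"])
    # permutation of samples within tissues leaves the means unchanged
    perm <- c(2, 4, 1, 3)
    tes2 <- TissueExpressionSet(toyFpkm()[, perm],
                                tissue = c("liver", "brain",
                                           "liver", "brain"))
    expect_equal(profileMeans(tissueMeans(tes2))[, c("liver", "brain")],
                 profileMeans(tp)[, c("liver", "brain")])
})

test_that("low-expression filter keeps genes reaching the floor anywhere", {
    m <- rbind(low1 = c(0.5, 0.9, 0.2), edge = c(1.0, 0, 0),
               hi = c(5, 0.1, 0.1))
    tp <- toyProfiles(m)
    kept <- rownames(profileMeans(filterLowExpression(tp)))
    expect_identical(kept, c("edge", "hi"))  # boundary value is retained

    set.seed(42)
    m10 <- matrix(runif(40, 1.2, 9), 10, 4)
    m10[c(2, 5, 7, 9), ] <- runif(16, 0, 0.95)
    tp10 <- toyProfiles(m10)
    f <- filterLowExpression(tp10)
    expect_identical(nrow(profileMeans(f)), 6L)
    # idempotent
    expect_equal(profileMeans(filterLowExpression(f)), profileMeans(f))
    # monotone: a higher threshold retains a subset
    f3 <- filterLowExpression(tp10, threshold = 3)
    expect_true(all(rownames(profileMeans(f3)) %in%
                    rownames(profileMeans(f))))
})

test_that("a 14-tissue simulated matrix yields 14 profile columns", {
    sim <- simulateExpression(simConfig(nGenes = 100L, seed = 5))
    tp <- tissueMeans(sim$expr)
    expect_identical(dim(profileMeans(tp)), c(100L, 14L))
    expect_identical(colnames(profileMeans(tp)), tissuePanel(14L))
})
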