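test_that("tau matches its defining formula on worked profiles", {
    expect_equal(tauIndex(c(10, 0, 0, 0)), 1)
    expect_equal(tauIndex(c(5, 5, 5, 5)), 0)
    expect_equal(tauIndex(c(8, 4, 2, 2)), 2 / 3)
    expect_equal(tauIndex(c(8, 4, 2, 2)), bruteTau(c(8, 4, 2, 2)))
    expect_true(is.na(tauIndex(c(0, 0, 0))))
    expect_error(tauIndex(c(-1, 2, 3)), "non-negative")
    expect_error(tauIndex(5), "two tissues")
})

test_that("tau is bounded, scale- and permutation-invariant on random profiles", {
    set.seed(101)
    for (i in seq_len(1000)) {
        n <- sample(2:20, 1)
        x <- rexp(n) * 10^runif(1, -2, 3)
        tau <- tauIndex(x)
        expect_gte(tau, 0); expect_lte(tau, 1)
        expect_equal(tau, bruteTau(x))
        expect_equal(tauIndex(x * runif(1, 0.01, 100)), tau)
        expect_equal(tauIndex(sample(x)), tau)
    }
    # tau = 0 iff constant; tau = 1 iff a single nonzero tissue
    expect_equal(tauIndex(rep(3.7, 9)), 0)
    expect_gt(tauIndex(c(rep(2, 8), 2.5)), 0)
    expect_equal(tauIndex(c(0, 0, 6, 0)), 1)
    expect_lt(tauIndex(c(0.01, 0, 6, 0)), 1)
})

test_that("tau on TissueProfiles matches per-row evaluation and log option", {
    m <- rbind(a = c(8, 4, 2, 2), b = c(5, 5, 5, 5), c = c(10, 0, 0, 0))
    tp <- toyProfiles(m)
    expect_equal(unname(tauIndex(tp)), c(2 / 3, 0, 1))
    expect_equal(unname(tauIndex(tp, log2p1 = TRUE))[1],
                 bruteTau(log2(c(8, 4, 2, 2) + 1)))
})

test_that("top-fraction candidate selection is sized and tie-stable", {
    m <- matrix(1, 10, 3)
    m[, 1] <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1.01)
    rownames(m) <- sprintf("g%02d", 1:10); colnames(m) <- c("t1", "t2", "t3")
    tp <- toyProfiles(m)
    tau <- tauIndex(tp)
    expect_identical(candidatesByTau(tp, 0.2),
                     names(sort(tau, decreasing = TRUE))[1:2])
    expect_setequal(candidatesByTau(tp, 1), rownames(m))
    # ties at the boundary resolve lexicographically
    mt <- rbind(aa = c(4, 1), bb = c(4, 1), cc = c(4, 1), dd = c(9, 1))
    colnames(mt) <- c("t1", "t2")
    expect_identical(sort(candidatesByTau(toyProfiles(mt), 0.5)),
                     c("aa", "dd"))
})

test_that("the three-rule caller applies the FPKM floor and top-k rank", {
    m <- rbind(cand = c(50, 3, 0.5, 0.2), low = c(0.9, 0.8, 0.5, 0.2),
               other = c(40, 30, 20, 10))
    colnames(m) <- c("fat", "muscle", "liver", "brain")
    tp <- toyProfiles(m)
    calls <- callTissueSpecific(tp, candidates = c("cand", "low"))
    get <- function(g) strsplit(
        calls$specificTissues[calls$gene_id == g], ",")[[1]]
    expect_setequal(get("cand"), c("fat", "muscle"))  # 0.5 fails FPKM > 1
    expect_length(get("low"), 0)                      # nothing above 1
    expect_length(get("other"), 0)                    # never called: not a candidate
    expect_error(callTissueSpecific(tp, "missing"), "subset")
    # a tie at rank k admits all tied tissues
    mt <- rbind(g = c(9, 5, 5, 5, 2))
    colnames(mt) <- paste0("t", 1:5)
    ct <- callTissueSpecific(toyProfiles(mt), "g", rankK = 2)
    expect_setequal(strsplit(ct$specificTissues, ",")[[1]],
                    c("t1", "t2", "t3", "t4"))
})

test_that("raising the floor or lowering the rank never adds a call", {
    set.seed(77)
    m <- matrix(rexp(200, rate = 0.3), 20, 10)
    rownames(m) <- sprintf("g%02d", 1:20)
    colnames(m) <- sprintf("t%02d", 1:10)
    tp <- toyProfiles(m)
    cand <- rownames(m)
    pairs <- function(calls) {
        s <- strsplit(calls$specificTissues, ",")
        paste(rep(calls$gene_id, lengths(s)), unlist(s))
    }
    base <- pairs(callTissueSpecific(tp, cand, fpkmMin = 1, rankK = 3))
    expect_true(all(pairs(callTissueSpecific(tp, cand, 2, 3)) %in% base))
    expect_true(all(pairs(callTissueSpecific(tp, cand, 1, 2)) %in% base))
})

test_that("biotype composition sums to one and flags bad input", {
    ann <- data.frame(gene_id = paste0("g", 1:4),
                      biotype = factor(biotypeClasses(),
                                       levels = biotypeClasses()))
    expect_equal(unname(biotypeComposition(paste0("g", 1:4), ann)),
                 rep(0.25, 4))
    expect_equal(unname(biotypeComposition("g1", ann)), c(1, 0, 0, 0))
    expect_error(biotypeComposition(character(), ann), "empty")
    expect_error(biotypeComposition("gX", ann), "missing")
})

test_that("planted lncRNA enrichment surfaces in the called TSG set", {
    sim <- simulateExpression(simConfig(seed = 7))
    tp <- filterLowExpression(tissueMeans(sim$expr))
    calls <- callTissueSpecific(tp, candidatesByTau(tp))
    tsg <- unique(unlist(tsgSets(calls)))
    genomeWide <- biotypeComposition(sim$annotation$gene_id, sim$annotation)
    inTsg <- biotypeComposition(tsg, sim$annotation)
    expect_gt(inTsg["lncRNA"], genomeWide["lncRNA"])
})

test_that("set reports satisfy inclusion-exclusion exactly", {
    sr <- intersectSets(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
    expect_identical(intersectionCount(sr, c("A", "B")), 2L)
    expect_identical(unionCount(sr), 4L)
    dj <- intersectSets(list(A = "a", B = "b", C = "c"))
    expect_identical(intersectionCount(dj, c("A", "B")), 0L)
    expect_identical(intersectionCount(dj, c("A", "B", "C")), 0L)
    expect_identical(unionCount(dj), 3L)
    set.seed(11)
    for (i in 1:20) {
        sets <- list(A = sample(letters, 10), B = sample(letters, 12),
                     C = sample(letters, 5))
        sr <- intersectSets(sets)
        # union by inclusion-exclusion from plain set ops
        ie <- length(unique(unlist(sets)))
        expect_identical(unionCount(sr), ie)
        expect_identical(intersectionCount(sr, c("A", "C")),
                         length(intersect(sets$A, sets$C)))
        expect_identical(sum(regionCounts(sr)$count[regionCounts(sr)$A]),
                         length(unique(sets$A)))
    }
    expect_error(intersectSets(list(A = "x")), "2")
    expect_error(intersectSets(list("x", "y")), "named")
})
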