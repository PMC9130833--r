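# Small in-code fixtures shared across test files.

toyFpkm <- function() {
    matrix(c(10, 0.5, 2,
             12, 0.7, 2,
             1,  0.9, 8,
             0,  0.8, 9),
           nrow = 3,
           dimnames = list(c("gA", "gB", "gC"),
                           c("liver_1", "liver_2", "brain_1", "brain_2")))
}

toyExpressionSet <- function() {
    TissueExpressionSet(toyFpkm(),
                        tissue = c("liver", "liver", "brain", "brain"))
}

toyProfiles <- function(m) {
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("t%02d", seq_len(ncol(m)))
    new("TissueProfiles", means = m)
}

# 4-gene GFF3 with one gene of each biotype class
writeToyGff3 <- function(path) {
    writeLines(c(
        "##gff-version 3",
        "chr1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=g1;gene_id=g1;gene_biotype=protein_coding",
        "chr1\ttest\tgene\t3000\t4000\t.\t+\t.\tID=g2;gene_id=g2;gene_biotype=lncRNA",
        "chr1\ttest\tgene\t5000\t6000\t.\t-\t.\tID=g3;gene_id=g3;gene_biotype=miRNA",
        "chr1\ttest\tgene\t7000\t8000\t.\t-\t.\tID=g4;gene_id=g4;gene_biotype=pseudogene"),
        path)
    path
}

# independent brute-force evaluation of the specificity index, written as a
# plain loop over the definition
bruteTau <- function(x) {
    xhat <- x / max(x)
    acc <- 0
    for (i in seq_along(x)) acc <- acc + (1 - xhat[i])
    acc / (length(x) - 1)
}

# independent step-up FDR oracle
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in rev(seq_len(m))) {
        prev <- min(prev, p[o[i]] * m / i)
        adj[o[i]] <- prev
    }
    adj
}
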