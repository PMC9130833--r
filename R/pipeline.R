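#' @include synthetic_data.R specificity.R diffexpr.R profiles.R qpcr.R popgen.R
NULL

#' Default pipeline configuration
#'
#' Thresholds default to the screen's published settings: expression floor
#' FPKM 1, top-20\% tau candidates, top-3 rank rule, adjusted-p 0.05,
#' minimum association group size 3, and a 3-MAD outlier rule.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving every stage.
#' @param stages character vector of stages to run, in dependency order, a
#'   subset of simulate, tsg, de, profiles, qpcr, popgen.
#' @param fpkmMin,topFraction,rankK,alpha,minN,kMads stage thresholds.
#' @param sim named list of overrides passed to [simConfig()].
#' @return configuration list.
#' @export
pipelineConfig <- function(outDir, seed = 1L,
                           stages = c("simulate", "tsg", "de", "profiles",
                                      "qpcr", "popgen"),
                           fpkmMin = 1, topFraction = 0.20, rankK = 3L,
                           alpha = 0.05, minN = 3L, kMads = 3,
                           sim = list()) {
    list(outDir = outDir, seed = as.integer(seed), stages = stages,
         fpkmMin = fpkmMin, topFraction = topFraction, rankK = rankK,
         alpha = alpha, minN = minN, kMads = kMads, sim = sim)
}

.pipePath <- function(cfg, file) file.path(cfg$outDir, file)

.needInputs <- function(cfg, stage, files) {
    missing <- files[!file.exists(vapply(files, .pipePath, "", cfg = cfg))]
    if (length(missing))
        stop("stage '", stage, "' needs missing input(s): ",
             paste(missing, collapse = ", "),
             " (did an upstream stage run?)")
}

.writeTsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

.writeAnnotationGff3 <- function(annotation, path) {
    gr <- GenomicRanges::GRanges(
        seqnames = "chr1",
        ranges = IRanges::IRanges(start = seq_len(nrow(annotation)) * 1000L,
                                  width = 500L),
        type = "gene",
        ID = annotation$gene_id,
        gene_id = annotation$gene_id,
        gene_biotype = as.character(annotation$biotype))
    rtracklayer::export(gr, path, format = "gff3")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order
#' (simulate -> tsg -> de -> profiles -> qpcr -> popgen), writing TSV/GFF3
#' outputs under `outDir` and a `manifest.json` listing parameters, per-file
#' MD5 checksums and the seed. Identical configuration and seed reproduce
#' byte-identical outputs. Stage-by-stage gene counts (genes in, filtered,
#' candidates, called) are logged with [message()].
#'
#' @param config a list from [pipelineConfig()] or the path of a YAML file
#'   with the same fields (a list in the file overrides the defaults).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        user <- yaml::read_yaml(config)
        config <- utils::modifyList(
            pipelineConfig(outDir = user$outDir %||% "."), user)
    }
    cfg <- config
    stopifnot(!is.null(cfg$outDir))
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    known <- c("simulate", "tsg", "de", "profiles", "qpcr", "popgen")
    stages <- known[known %in% cfg$stages]

    if ("simulate" %in% stages) {
        sc <- do.call(simConfig, utils::modifyList(list(seed = cfg$seed),
                                                   as.list(cfg$sim)))
        sim <- simulateExpression(sc)
        writeExpressionMatrix(sim$expr, .pipePath(cfg, "fpkm.tsv"),
                              .pipePath(cfg, "sample_map.tsv"))
        .writeAnnotationGff3(sim$annotation,
                             .pipePath(cfg, "annotation.gff3"))
        .writeTsv(sim$truth, .pipePath(cfg, "truth_expression.tsv"))
        cnt <- simulateCounts(sc)
        writeExpressionMatrix(cnt$counts, .pipePath(cfg, "counts.tsv"),
                              .pipePath(cfg, "counts_sample_map.tsv"))
        .writeTsv(cnt$truth, .pipePath(cfg, "truth_counts.tsv"))
        gt <- simulateGenotypes(p = 0.8, n = 120, f = 0,
                                population = "simulated",
                                seed = cfg$seed)
        .writeTsv(as.data.frame(gt$table), .pipePath(cfg, "genotypes.tsv"))
        traits <- simulateTraits(gt$genotypes,
                                 effects = c(DD = 0, ID = 1.5, II = 3),
                                 sd = 1, base = 10, trait = "carcass_weight",
                                 sex = "pooled", seed = cfg$seed)
        .writeTsv(traits, .pipePath(cfg, "traits.tsv"))
        ctTab <- simulateCtTable(seed = cfg$seed,
                                 folds = structure(c(1, 8, 2, 0.5),
                                                   names = tissuePanel(4L)))
        .writeTsv(ctTab, .pipePath(cfg, "ct.tsv"))
        message("simulate: ", nrow(sim$truth), " genes, ",
                ncol(sim$expr), " samples")
    }

    tsgCalls <- NULL
    if ("tsg" %in% stages) {
        .needInputs(cfg, "tsg", c("fpkm.tsv", "sample_map.tsv"))
        em <- readExpressionMatrix(.pipePath(cfg, "fpkm.tsv"),
                                   .pipePath(cfg, "sample_map.tsv"))
        tp <- tissueMeans(em)
        tpf <- filterLowExpression(tp, cfg$fpkmMin)
        message("tsg: ", nrow(profileMeans(tp)), " genes in, ",
                nrow(profileMeans(tpf)), " past the FPKM filter")
        tau <- tauIndex(tpf)
        .writeTsv(data.frame(gene_id = names(tau), tau = unname(tau)),
                  .pipePath(cfg, "tau.tsv"))
        cand <- candidatesByTau(tpf, cfg$topFraction, tau = tau)
        calls <- callTissueSpecific(tpf, cand, cfg$fpkmMin, cfg$rankK)
        message("tsg: ", length(cand), " candidates, ",
                sum(nzchar(calls$specificTissues)), " genes called specific")
        .writeTsv(calls, .pipePath(cfg, "tsg_calls.tsv"))
        sets <- tsgSets(calls)
        adi <- intersect(adiposeTissues(), names(sets))
        if (length(adi) >= 2L) {
            sr <- intersectSets(sets[adi])
            .writeTsv(regionCounts(sr), .pipePath(cfg, "tsg_set_report.tsv"))
        }
        tsgCalls <- calls
    }

    deRes <- NULL
    if ("de" %in% stages) {
        .needInputs(cfg, "de", c("counts.tsv", "counts_sample_map.tsv"))
        cm <- readCountMatrix(.pipePath(cfg, "counts.tsv"),
                              .pipePath(cfg, "counts_sample_map.tsv"))
        deRes <- nbTwoGroupTest(cm)
        .writeTsv(deRes, .pipePath(cfg, "de_results.tsv"))
        heg <- callHeg(deRes, cfg$alpha)
        message("de: ", length(heg$higher), " higher, ",
                length(heg$lower), " lower at padj < ", cfg$alpha)
        if (!is.null(tsgCalls)) {
            sets <- tsgSets(tsgCalls)
            adi <- intersect(adiposeTissues(), names(sets))
            if (length(adi) >= 1L) {
                sr <- intersectTsgHeg(sets[adi], heg$higher)
                .writeTsv(regionCounts(sr),
                          .pipePath(cfg, "tsg_heg_report.tsv"))
            }
        }
    }

    if ("profiles" %in% stages) {
        .needInputs(cfg, "profiles", c("fpkm.tsv", "sample_map.tsv"))
        em <- readExpressionMatrix(.pipePath(cfg, "fpkm.tsv"),
                                   .pipePath(cfg, "sample_map.tsv"))
        tp <- filterLowExpression(tissueMeans(em), cfg$fpkmMin)
        cr <- tissueCorrelations(tp)
        pairs <- which(upper.tri(cr$r), arr.ind = TRUE)
        .writeTsv(data.frame(tissue1 = rownames(cr$r)[pairs[, 1L]],
                             tissue2 = colnames(cr$r)[pairs[, 2L]],
                             r = cr$r[pairs], p = cr$p[pairs], n = cr$n),
                  .pipePath(cfg, "correlations.tsv"))
        .writeTsv(pcaOutlierScreen(em, cfg$kMads),
                  .pipePath(cfg, "outliers.tsv"))
        writeLines(clusterNewick(clusterTissues(tp)),
                   .pipePath(cfg, "tissue_clusters.nwk"))
    }

    if ("qpcr" %in% stages) {
        .needInputs(cfg, "qpcr", "ct.tsv")
        ctTab <- readCtTable(.pipePath(cfg, "ct.tsv"))
        calib <- ctTab$tissue[1L]
        .writeTsv(deltaDeltaCt(ctTab, target = "TARGET",
                               reference = "GAPDH", calibrator = calib),
                  .pipePath(cfg, "qpcr_folds.tsv"))
    }

    if ("popgen" %in% stages) {
        .needInputs(cfg, "popgen", c("genotypes.tsv", "traits.tsv"))
        gt <- readGenotypeTable(.pipePath(cfg, "genotypes.tsv"))
        .writeTsv(diversityStats(gt), .pipePath(cfg, "diversity.tsv"))
        assoc <- associate(readTraitTable(.pipePath(cfg, "traits.tsv")),
                           minN = cfg$minN)
        .writeTsv(assoc, .pipePath(cfg, "association.tsv"))
    }

    outputs <- setdiff(list.files(cfg$outDir), "manifest.json")
    manifest <- list(
        package = "adipospec",
        version = as.character(utils::packageVersion("adipospec")),
        seed = cfg$seed,
        parameters = cfg[c("fpkmMin", "topFraction", "rankK", "alpha",
                           "minN", "kMads")],
        stages = stages,
        outputs = as.list(tools::md5sum(
            vapply(sort(outputs), .pipePath, "", cfg = cfg))))
    names(manifest$outputs) <- sort(outputs)
    jsonlite::write_json(manifest, .pipePath(cfg, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
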