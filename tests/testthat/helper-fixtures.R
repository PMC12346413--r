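# In-code fixtures: small matrices and files built at test time.

makeExpr <- function(vals, timepoint, scale = "log2cpm", ps = 1) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = vals),
        colData = S4Vectors::DataFrame(timepoint = timepoint,
                                       row.names = colnames(vals)))
    S4Vectors::metadata(se)$scale <- scale
    if (scale != "cpm") S4Vectors::metadata(se)$pseudocount <- ps
    methods::new("MuscleExpression", se)
}

writeToyCounts <- function(counts, design, dir = withr::local_tempdir(
                               .local_envir = parent.frame())) {
    cpath <- file.path(dir, "counts.tsv")
    dpath <- file.path(dir, "design.tsv")
    writeLines(c(paste(c("gene", colnames(counts)), collapse = "\t"),
                 vapply(rownames(counts), function(g)
                     paste(c(g, counts[g, ]), collapse = "\t"),
                     character(1))), cpath)
    utils::write.table(design, dpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(counts = cpath, design = dpath)
}

# Adjusted Rand index between two labelings (independent of any package
# clustering code); mclust::adjustedRandIndex is used as a cross-check
# where available.
ariOracle <- function(a, b) {
    tab <- table(a, b)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    np <- choose(sum(tab), 2)
    expected <- ai * bj / np
    (sumij - expected) / ((ai + bj) / 2 - expected)
}
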