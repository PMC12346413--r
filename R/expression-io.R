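#' Read a raw count matrix and its sample design
#'
#' The counts file is a delimited table with genes as rows, a header row of
#' sample IDs and gene IDs in the first column; tab-delimited by default,
#' comma-delimited when the extension is \code{.csv}. The design file is a
#' TSV with columns \code{sample}, \code{timepoint} and optionally
#' \code{replicate}. Samples present in the counts file must all appear in
#' the design; row and column order is preserved from the counts file.
#'
#' @param path counts file.
#' @param designPath design file.
#' @return a \linkS4class{MuscleCounts}.
#' @export
readCounts <- function(path, designPath) {
    if (!file.exists(path)) stop("counts file not found: ", path)
    if (!file.exists(designPath)) stop("design file not found: ", designPath)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    genes <- tab[[1L]]
    dup <- genes[duplicated(genes)]
    if (length(dup))
        stop("duplicate gene identifier(s): ",
             paste(unique(dup), collapse = ", "))
    raw <- as.matrix(tab[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                   dimnames = list(genes, colnames(raw))))
    bad <- which(is.na(num) | num < 0 | abs(num - round(num)) > 1e-8,
                 arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "non-integer or negative count at gene '%s', sample '%s' (value '%s')",
            genes[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]],
            raw[bad[1L, 1L], bad[1L, 2L]]))
    design <- utils::read.table(designPath, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    req <- c("sample", "timepoint")
    if (!all(req %in% colnames(design)))
        stop("design file needs columns: ", paste(req, collapse = ", "))
    missing <- setdiff(colnames(num), design$sample)
    if (length(missing))
        stop("sample(s) missing from design: ",
             paste(missing, collapse = ", "))
    design <- design[match(colnames(num), design$sample), , drop = FALSE]
    MuscleCounts(num, timepoint = design$timepoint,
                 replicate = if ("replicate" %in% colnames(design))
                     design$replicate else NULL)
}

#' Write a count matrix (and design) back to disk
#'
#' Inverse of [readCounts()]: \code{readCounts(writeCounts(x, ...))} is the
#' identity on a \linkS4class{MuscleCounts}.
#'
#' @param x a \code{MuscleCounts}.
#' @param path counts output file (TSV; gene IDs in column \code{gene}).
#' @param designPath optional design output file.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(x, path, designPath = NULL) {
    stopifnot(methods::is(x, "MuscleCounts"))
    cts <- SummarizedExperiment::assay(x, "counts")
    df <- data.frame(gene = rownames(cts), cts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(designPath)) {
        cd <- SummarizedExperiment::colData(x)
        utils::write.table(
            data.frame(sample = rownames(cd),
                       timepoint = cd$timepoint,
                       replicate = cd$replicate),
            designPath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a one-gene-per-line list (housekeeping panel, candidate list)
#'
#' Lines may optionally carry a second tab-separated column (a functional
#' category label for candidates); blank lines and \code{#} comments are
#' skipped.
#'
#' @param path text file.
#' @return character vector of gene IDs; if category labels are present they
#'   are attached as the \code{names()}-free attribute \code{"category"}.
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("gene list not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    genes <- vapply(parts, `[`, character(1L), 1L)
    cats <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                   character(1L))
    if (any(!is.na(cats))) attr(genes, "category") <- cats
    genes
}

#' Counts-per-million normalization
#'
#' Scales each sample column to reads per million:
#' \eqn{CPM(g, s) = counts(g, s) / \sum_g counts(g, s) \times 10^6}. With no
#' gene filtering each sample column of the result sums to exactly 1e6.
#'
#' @param x a \linkS4class{MuscleCounts}.
#' @return a \linkS4class{MuscleExpression} on the \code{"cpm"} scale.
#' @export
setGeneric("computeCPM", function(x) standardGeneric("computeCPM"))

#' @rdname computeCPM
#' @export
setMethod("computeCPM", "MuscleCounts", function(x) {
    cts <- SummarizedExperiment::assay(x, "counts")
    libsize <- colSums(cts)
    zero <- names(libsize)[libsize == 0]
    if (length(zero))
        stop("zero library size for sample(s): ",
             paste(zero, collapse = ", "))
    cpm <- sweep(cts, 2L, libsize, "/") * 1e6
    .newExpression(cpm, x, scale = "cpm")
})

#' Log2 transform of a CPM matrix
#'
#' \eqn{value' = \log_2(CPM + pseudocount)}. The pseudocount (default 1,
#' giving 0 for absent genes) is recorded in the object's metadata.
#'
#' @param x a \linkS4class{MuscleExpression} on the \code{"cpm"} scale.
#' @param pseudocount positive offset added before taking logs.
#' @return a \code{MuscleExpression} on the \code{"log2cpm"} scale.
#' @export
setGeneric("log2Transform",
           function(x, pseudocount = 1) standardGeneric("log2Transform"))

#' @rdname log2Transform
#' @export
setMethod("log2Transform", "MuscleExpression", function(x, pseudocount = 1) {
    if (exprScale(x) != "cpm")
        stop("log2Transform expects scale 'cpm', got '", exprScale(x), "'")
    if (!is.numeric(pseudocount) || pseudocount <= 0)
        stop("pseudocount must be > 0")
    vals <- log2(SummarizedExperiment::assay(x, "exprs") + pseudocount)
    .newExpression(vals, x, scale = "log2cpm", pseudocount = pseudocount)
})

#' Remove genes below an expression floor
#'
#' Retains genes with value >= \code{minValue} in at least \code{minSamples}
#' samples; the default emulates the common "CPM >= 1 in at least the
#' smallest group" convention. Removed gene IDs and before/after counts are
#' attached to the result's metadata (\code{removedGenes},
#' \code{filterCounts}).
#'
#' @param x a \linkS4class{MuscleCounts} or \linkS4class{MuscleExpression}.
#' @param minValue expression floor (counts or CPM, matching \code{x}).
#' @param minSamples minimum number of samples at or above the floor;
#'   defaults to the smallest timepoint group.
#' @return an object of the same class as \code{x}.
#' @export
setGeneric("filterLowExpression",
           function(x, minValue = 1, minSamples = NULL)
               standardGeneric("filterLowExpression"))

.filterLow <- function(x, assayName, minValue, minSamples) {
    if (is.null(minSamples)) {
        tp <- SummarizedExperiment::colData(x)$timepoint
        minSamples <- if (is.null(tp)) 1L else min(table(tp))
    }
    if (minSamples > ncol(x))
        stop("minSamples exceeds the number of samples")
    vals <- SummarizedExperiment::assay(x, assayName)
    keep <- rowSums(vals >= minValue) >= minSamples
    out <- x[keep, ]
    md <- S4Vectors::metadata(out)
    md$removedGenes <- rownames(x)[!keep]
    md$filterCounts <- c(before = nrow(x), after = sum(keep))
    S4Vectors::metadata(out) <- md
    out
}

#' @rdname filterLowExpression
#' @export
setMethod("filterLowExpression", "MuscleCounts",
          function(x, minValue = 1, minSamples = NULL)
              .filterLow(x, "counts", minValue, minSamples))

#' @rdname filterLowExpression
#' @export
setMethod("filterLowExpression", "MuscleExpression",
          function(x, minValue = 1, minSamples = NULL)
              .filterLow(x, "exprs", minValue, minSamples))

#' Center expression on a housekeeping panel
#'
#' Normalizes each sample to the mean expression of the housekeeping panel:
#' on the log2CPM scale the per-sample panel mean is subtracted from every
#' gene (equivalently, CPM is divided by the panel's geometric mean). The
#' per-sample panel means are retained in metadata and the scale tag becomes
#' \code{"log2cpm_hk_centered"}. After centering, the panel genes average
#' exactly zero within every sample.
#'
#' @param x a \linkS4class{MuscleExpression} on the \code{"log2cpm"} or
#'   already-centered scale (centering an already-centered matrix with the
#'   same panel is a no-op).
#' @param panel character vector of housekeeping gene IDs (>= 2), all
#'   present in \code{x}; defaults to [defaultHkPanel()].
#' @return a centered \code{MuscleExpression}.
#' @export
setGeneric("hkCenter",
           function(x, panel = defaultHkPanel()) standardGeneric("hkCenter"))

#' @rdname hkCenter
#' @export
setMethod("hkCenter", "MuscleExpression", function(x, panel = defaultHkPanel()) {
    if (!exprScale(x) %in% c("log2cpm", "log2cpm_hk_centered"))
        stop("hkCenter expects scale 'log2cpm', got '", exprScale(x), "'")
    panel <- unique(as.character(panel))
    if (length(panel) < 2L)
        stop("housekeeping panel must contain at least 2 genes")
    missing <- setdiff(panel, rownames(x))
    if (length(missing))
        stop("housekeeping panel gene(s) absent from matrix: ",
             paste(missing, collapse = ", "))
    vals <- SummarizedExperiment::assay(x, "exprs")
    hkMeans <- colMeans(vals[panel, , drop = FALSE])
    centered <- sweep(vals, 2L, hkMeans, "-")
    .newExpression(centered, x, scale = "log2cpm_hk_centered",
                   pseudocount = pseudocount(x), hkMeans = hkMeans,
                   hkPanel = panel)
})
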