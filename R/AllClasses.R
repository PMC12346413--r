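#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.EXPR_SCALES <- c("cpm", "log2cpm", "log2cpm_hk_centered")

#' Raw count container for a timepoint-design experiment
#'
#' A \linkS4class{SummarizedExperiment} holding one integer assay
#' \code{"counts"} (genes x samples) and per-sample design columns
#' \code{timepoint} and \code{replicate}. Every sample carries exactly one
#' timepoint label; gene and sample identifiers are unique.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [MuscleCounts()] for construction, [computeCPM()] for
#'   normalization.
#' @export
setClass("MuscleCounts", contains = "SummarizedExperiment")

setValidity("MuscleCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(cts)))
            msg <- c(msg, "counts contain NA")
        else {
            if (any(cts < 0))
                msg <- c(msg, "counts must be non-negative")
            if (any(abs(cts - round(cts)) > 1e-8))
                msg <- c(msg, "counts must be integral")
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"timepoint" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'timepoint' column")
    else if (any(is.na(cd$timepoint)))
        msg <- c(msg, "every sample needs a timepoint label")
    if (length(msg)) msg else TRUE
})

#' Normalized expression container with a recorded scale
#'
#' A \linkS4class{SummarizedExperiment} with one real-valued assay
#' \code{"exprs"} and a scale tag in \code{metadata()$scale}, one of
#' \code{"cpm"}, \code{"log2cpm"} or \code{"log2cpm_hk_centered"}. For log
#' scales the pseudocount of the transform is recorded; for the
#' housekeeping-centered scale the per-sample panel means are retained.
#'
#' @seealso [computeCPM()], [log2Transform()], [hkCenter()], [exprScale()].
#' @export
setClass("MuscleExpression", contains = "SummarizedExperiment")

setValidity("MuscleExpression", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    sc <- S4Vectors::metadata(object)$scale
    if (is.null(sc) || !sc %in% .EXPR_SCALES)
        msg <- c(msg, sprintf("metadata()$scale must be one of %s",
                              paste(.EXPR_SCALES, collapse = ", ")))
    else if (sc != "cpm") {
        ps <- S4Vectors::metadata(object)$pseudocount
        if (is.null(ps) || !is.numeric(ps) || ps <= 0)
            msg <- c(msg, "log scales require a positive recorded pseudocount")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' Local gene-set annotation with a defined universe
#'
#' Maps term identifiers to non-empty gene sets (as read from a GMT file or
#' simulated), together with human-readable term names and the gene universe
#' used as the over-representation background. Every annotated gene belongs
#' to the universe.
#'
#' @slot terms named list of character vectors (term id -> member genes).
#' @slot termNames character vector parallel to \code{terms}.
#' @slot universe character vector of background genes.
#' @seealso [readGmt()], [ora()], [geneTermProfiles()].
#' @export
setClass("TermAnnotation",
    representation(terms = "list", termNames = "character",
                   universe = "character"))

setValidity("TermAnnotation", function(object) {
    msg <- character()
    if (length(object@terms)) {
        if (is.null(names(object@terms)) || anyDuplicated(names(object@terms)))
            msg <- c(msg, "terms must be uniquely named")
        sizes <- lengths(object@terms)
        if (any(sizes == 0L))
            msg <- c(msg, "term gene sets must be non-empty")
        allg <- unique(unlist(object@terms, use.names = FALSE))
        out <- setdiff(allg, object@universe)
        if (length(out))
            msg <- c(msg, sprintf("annotated genes outside universe: %s",
                                  paste(utils::head(out, 5), collapse = ", ")))
    }
    if (length(object@termNames) != length(object@terms))
        msg <- c(msg, "termNames must parallel terms")
    if (anyDuplicated(object@universe))
        msg <- c(msg, "universe genes must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a MuscleCounts object
#'
#' @param counts integer matrix, genes x samples, with rownames (gene IDs)
#'   and colnames (sample IDs).
#' @param timepoint character/factor of per-sample timepoint labels
#'   (e.g. \code{"T0"}, \code{"T30"}, \code{"T60"}).
#' @param replicate optional per-sample replicate index; defaults to a
#'   within-timepoint counter.
#' @return a \linkS4class{MuscleCounts}.
#' @examples
#' cts <- matrix(rpois(12, 50), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' MuscleCounts(cts, timepoint = c("T0", "T0", "T30", "T30"))
#' @export
MuscleCounts <- function(counts, timepoint, replicate = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene rownames and sample colnames")
    timepoint <- as.character(timepoint)
    if (length(timepoint) != ncol(counts))
        stop("one timepoint label per sample is required")
    if (is.null(replicate))
        replicate <- stats::ave(seq_along(timepoint), timepoint,
                                FUN = seq_along)
    cd <- S4Vectors::DataFrame(timepoint = timepoint,
                               replicate = replicate,
                               row.names = colnames(counts))
    methods::new("MuscleCounts",
                 SummarizedExperiment::SummarizedExperiment(
                     assays = list(counts = counts), colData = cd))
}

.newExpression <- function(values, template, scale, pseudocount = NULL,
                           hkMeans = NULL, hkPanel = NULL) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = SummarizedExperiment::colData(template))
    md <- S4Vectors::metadata(template)
    md$scale <- scale
    if (!is.null(pseudocount)) md$pseudocount <- pseudocount
    if (!is.null(hkMeans)) md$hkMeans <- hkMeans
    if (!is.null(hkPanel)) md$hkPanel <- hkPanel
    S4Vectors::metadata(se) <- md
    methods::new("MuscleExpression", se)
}

#' Construct a TermAnnotation object
#'
#' @param terms named list, term id -> character vector of member genes.
#' @param termNames optional character vector of descriptions (defaults to
#'   the term ids).
#' @param universe background gene set; defaults to the union of all term
#'   members.
#' @return a \linkS4class{TermAnnotation}.
#' @export
TermAnnotation <- function(terms, termNames = NULL, universe = NULL) {
    terms <- lapply(terms, function(g) unique(as.character(g)))
    if (is.null(universe))
        universe <- sort(unique(unlist(terms, use.names = FALSE)))
    if (is.null(termNames)) termNames <- names(terms)
    methods::new("TermAnnotation", terms = terms,
                 termNames = as.character(termNames),
                 universe = unique(as.character(universe)))
}

#' @describeIn MuscleExpression-class the recorded scale tag.
#' @param x a \code{MuscleExpression}.
#' @export
exprScale <- function(x) S4Vectors::metadata(x)$scale

#' @describeIn MuscleExpression-class the pseudocount used by the log2
#'   transform (NULL on the cpm scale).
#' @export
pseudocount <- function(x) S4Vectors::metadata(x)$pseudocount

#' @describeIn MuscleExpression-class per-sample housekeeping-panel means
#'   retained by [hkCenter()].
#' @export
hkPanelMeans <- function(x) S4Vectors::metadata(x)$hkMeans

#' @describeIn TermAnnotation-class term id -> gene set list.
#' @param x a \code{TermAnnotation}.
#' @export
annTerms <- function(x) x@terms

#' @describeIn TermAnnotation-class the background gene universe.
#' @export
annUniverse <- function(x) x@universe

#' @describeIn TermAnnotation-class term descriptions, named by term id.
#' @export
annTermNames <- function(x) stats::setNames(x@termNames, names(x@terms))

setMethod("show", "MuscleCounts", function(object) {
    tp <- table(SummarizedExperiment::colData(object)$timepoint)
    cat(sprintf("MuscleCounts: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    cat("  timepoints:",
        paste(sprintf("%s (n=%d)", names(tp), tp), collapse = ", "), "\n")
})

setMethod("show", "MuscleExpression", function(object) {
    cat(sprintf("MuscleExpression: %d genes x %d samples [scale: %s]\n",
                nrow(object), ncol(object), exprScale(object)))
    ps <- pseudocount(object)
    if (!is.null(ps)) cat(sprintf("  pseudocount: %g\n", ps))
})

setMethod("show", "TermAnnotation", function(object) {
    cat(sprintf("TermAnnotation: %d terms, %d-gene universe\n",
                length(object@terms), length(object@universe)))
})

#' The 13-gene housekeeping panel used as the empirical-null reference
#'
#' Genes assumed transcriptionally stable across glucose-stimulation
#' conditions; their delta-log2CPM distribution defines the null against
#' which candidate-gene shifts are standardized.
#'
#' @return character vector of 13 gene symbols.
#' @export
defaultHkPanel <- function() {
    c("Actb", "Gusb", "Hprt1", "Ipo8", "Ppia", "Rpl13a", "Rpl19",
      "Rps13", "Rps18", "Rps23", "Tbp", "Tubb", "Ywhag")
}
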