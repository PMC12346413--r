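#' Paired t-test on per-individual values
#'
#' Classical paired t on the per-individual differences d = x - y:
#' \eqn{t = \bar{d} / (s_d / \sqrt{n})}, two-sided p from the t distribution
#' with n - 1 df. The median difference is reported alongside (medians, not
#' means, are what fiber-type expression plots mark). Zero-variance
#' differences leave t undefined; the error suggests an exact sign test.
#'
#' @param x,y equal-length numeric vectors (n >= 2), paired per individual.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_diff},
#'   \code{median_diff}.
#' @export
pairedT <- function(x, y) {
    n <- length(x)
    if (length(y) != n || n < 2L)
        stop("x and y must have equal length >= 2")
    d <- x - y
    s <- stats::sd(d)
    if (s == 0)
        stop("zero-variance differences: paired t undefined; ",
             "consider an exact sign test")
    t <- mean(d) / (s / sqrt(n))
    list(t = t, df = n - 1L,
         p = 2 * stats::pt(abs(t), df = n - 1L, lower.tail = FALSE),
         mean_diff = mean(d), median_diff = stats::median(d))
}

#' Default fast/slow fiber-type paralog pairs
#'
#' Marker paralog pairs contrasting fast-twitch and slow-twitch programs:
#' myosin heavy and light chains, calsequestrins, SERCA calcium ATPases and
#' troponin T. Fully overridable via the \code{pairs} argument of
#' [fiberProfile()] or a pairs TSV.
#'
#' @return data.frame with \code{fast_gene}, \code{slow_gene},
#'   \code{family}.
#' @export
defaultParalogPairs <- function() {
    data.frame(
        fast_gene = c("Myh1", "Myh4", "Myl1", "Casq1", "Atp2a1", "Tnnt3"),
        slow_gene = c("Myh7", "Myh7", "Myl3", "Casq2", "Atp2a2", "Tnnt1"),
        family = c("myosin heavy chain", "myosin heavy chain",
                   "myosin light chain", "calsequestrin",
                   "calcium ATPase", "troponin T"))
}

#' Read a paralog-pair table
#'
#' @param path TSV with columns \code{fast_gene}, \code{slow_gene},
#'   \code{family}.
#' @return data.frame.
#' @export
readParalogPairs <- function(path) {
    if (!file.exists(path)) stop("pairs file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    req <- c("fast_gene", "slow_gene")
    if (!all(req %in% colnames(tab)))
        stop("pairs file needs columns: ", paste(req, collapse = ", "))
    if (!"family" %in% colnames(tab)) tab$family <- NA_character_
    bad <- tab$fast_gene == tab$slow_gene
    if (any(bad))
        stop("fast and slow paralog identical in pair(s): ",
             paste(tab$fast_gene[bad], collapse = ", "))
    tab
}

#' Fast-versus-slow paralog expression profile
#'
#' For each fast/slow paralog pair, runs a paired t-test across individuals
#' on log2CPM, reports per-paralog medians and calls the dominant paralog
#' (the one with the larger median). A paralog whose CPM never exceeds
#' \code{detectionCpm} in any sample is reported as \code{"not detected"}
#' rather than tested (e.g. a slow myosin absent from a fast-twitch
#' muscle). The composition call lists the dominant paralogs of pairs with
#' p < alpha.
#'
#' @param x a \linkS4class{MuscleExpression} on the \code{"log2cpm"} scale.
#' @param pairs data.frame of paralog pairs (default
#'   [defaultParalogPairs()]).
#' @param alpha significance level for the composition call (default 0.05).
#' @param detectionCpm CPM at or below which a gene counts as not detected
#'   (default 0: zero counts in every sample).
#' @return list with \code{report} (per-pair data.frame: t, df, p, medians,
#'   dominant, status) and \code{composition} (character vector of dominant
#'   paralogs at p < alpha).
#' @export
fiberProfile <- function(x, pairs = defaultParalogPairs(), alpha = 0.05,
                         detectionCpm = 0) {
    stopifnot(methods::is(x, "MuscleExpression"))
    if (exprScale(x) != "log2cpm")
        stop("fiberProfile expects scale 'log2cpm', got '", exprScale(x), "'")
    ps <- pseudocount(x)
    vals <- SummarizedExperiment::assay(x, "exprs")
    floorVal <- log2(detectionCpm + ps)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
        fg <- pairs$fast_gene[i]; sg <- pairs$slow_gene[i]
        row <- data.frame(fast_gene = fg, slow_gene = sg,
                          family = pairs$family[i], t = NA_real_,
                          df = NA_integer_, p = NA_real_,
                          median_fast = NA_real_, median_slow = NA_real_,
                          dominant = NA_character_, status = "ok",
                          row.names = NULL)
        present <- c(fg, sg) %in% rownames(vals)
        detected <- vapply(c(fg, sg), function(g)
            g %in% rownames(vals) &&
                any(vals[g, ] > floorVal + 1e-12), logical(1L))
        if (!any(present)) {
            row$status <- "both absent"
            return(row)
        }
        miss <- c(fg, sg)[!detected]
        if (length(miss)) {
            row$status <- paste0("not detected: ", paste(miss, collapse = ", "))
            for (g in c(fg, sg)[detected]) {
                med <- stats::median(vals[g, ])
                if (g == fg) row$median_fast <- med else row$median_slow <- med
            }
            if (sum(detected) == 1L)
                row$dominant <- c(fg, sg)[detected]
            return(row)
        }
        row$median_fast <- stats::median(vals[fg, ])
        row$median_slow <- stats::median(vals[sg, ])
        tt <- tryCatch(pairedT(vals[fg, ], vals[sg, ]), error = function(e) e)
        if (inherits(tt, "error")) {
            row$status <- "degenerate variance"
            return(row)
        }
        row$t <- tt$t; row$df <- tt$df; row$p <- tt$p
        if (row$median_fast != row$median_slow)
            row$dominant <- if (row$median_fast > row$median_slow) fg else sg
        row
    })
    report <- do.call(rbind, rows)
    sig <- !is.na(report$p) & report$p < alpha & !is.na(report$dominant)
    list(report = report, composition = report$dominant[sig])
}
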