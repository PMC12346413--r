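#' Group-mean expression change from baseline
#'
#' For every gene and post-stimulation timepoint, computes
#' \eqn{\Delta(g, t) = \bar{x}_{g,t} - \bar{x}_{g,baseline}} on the log2CPM
#' scale, where the bars are means over the samples of each timepoint group.
#' The design is cross-sectional (different animals at each timepoint), so
#' the change is defined on group means, not per-animal pairs; the baseline
#' timepoint never appears as a row (its delta is identically zero).
#'
#' @param x a \linkS4class{MuscleExpression} on a log2 scale.
#' @param baseline baseline timepoint label (default \code{"T0"}).
#' @param timepoints post-stimulation labels; default: all non-baseline
#'   labels in the design, in design order.
#' @return data.frame with columns \code{gene}, \code{timepoint},
#'   \code{delta_log2cpm}.
#' @export
groupMeanDelta <- function(x, baseline = "T0", timepoints = NULL) {
    stopifnot(methods::is(x, "MuscleExpression"))
    if (!exprScale(x) %in% c("log2cpm", "log2cpm_hk_centered"))
        stop("groupMeanDelta expects a log2 scale, got '", exprScale(x), "'")
    tp <- as.character(SummarizedExperiment::colData(x)$timepoint)
    if (is.null(timepoints)) timepoints <- setdiff(unique(tp), baseline)
    for (lab in c(baseline, timepoints))
        if (!any(tp == lab))
            stop("timepoint '", lab, "' has no samples")
    vals <- SummarizedExperiment::assay(x, "exprs")
    baseMean <- rowMeans(vals[, tp == baseline, drop = FALSE])
    out <- do.call(rbind, lapply(timepoints, function(lab) {
        data.frame(gene = rownames(vals), timepoint = lab,
                   delta_log2cpm = rowMeans(vals[, tp == lab, drop = FALSE]) -
                       baseMean,
                   row.names = NULL)
    }))
    out
}

#' Empirical-null summary from housekeeping deltas
#'
#' The housekeeping panel's delta-log2CPM values at one timepoint define the
#' empirical null for candidate shifts: \code{mu_hk} is their mean and
#' \code{sigma_hk} their sample standard deviation (n - 1 denominator; with
#' a 13-gene panel the denominator choice is material and is recorded).
#'
#' @param delta a delta table from [groupMeanDelta()].
#' @param panel housekeeping gene IDs (>= 2 present at the timepoint).
#' @param timepoint which timepoint's null to summarize.
#' @return list with \code{timepoint}, \code{mu_hk}, \code{sigma_hk},
#'   \code{n_hk}.
#' @export
nullSummary <- function(delta, panel, timepoint) {
    d <- delta$delta_log2cpm[delta$timepoint == timepoint &
                             delta$gene %in% panel]
    if (length(d) < 2L)
        stop("need >= 2 housekeeping genes at timepoint '", timepoint,
             "', found ", length(d))
    s <- stats::sd(d)
    if (s == 0)
        stop("degenerate null: all housekeeping deltas identical at '",
             timepoint, "'")
    list(timepoint = timepoint, mu_hk = mean(d), sigma_hk = s,
         n_hk = length(d))
}

#' Housekeeping-anchored z-score
#'
#' Standardizes a candidate's delta against the housekeeping null:
#' \eqn{z = (\Delta_{candidate} - \mu_{HK}) / \sigma_{HK}}.
#'
#' @param delta candidate delta-log2CPM (vectorized).
#' @param null a null summary from [nullSummary()].
#' @return numeric z-score(s).
#' @export
empiricalZ <- function(delta, null) {
    if (!is.numeric(null$sigma_hk) || null$sigma_hk <= 0)
        stop("null summary must have sigma_hk > 0")
    (delta - null$mu_hk) / null$sigma_hk
}

#' Two-tailed p-value for an empirical-null z-score
#'
#' \eqn{p = 2(1 - \Phi(|z|))} under the standard normal reference. With a
#' small housekeeping panel the z statistic has heavier-than-normal tails
#' (the null mean and sd are themselves estimates); a Student-t reference
#' with \code{df} degrees of freedom is available as an opt-in.
#'
#' @param z numeric z-score(s), finite.
#' @param df if non-NULL, use a t reference with this df (e.g.
#'   \code{n_hk - 1}) instead of the normal.
#' @return p-value(s) in (0, 1].
#' @export
twoTailedP <- function(z, df = NULL) {
    if (any(!is.finite(z))) stop("z must be finite")
    p <- if (is.null(df)) 2 * stats::pnorm(abs(z), lower.tail = FALSE)
         else 2 * stats::pt(abs(z), df = df, lower.tail = FALSE)
    pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (sort ascending, \eqn{q_i = \min_{j \ge i}
#' p_j n / j}, mapped back to input order, capped at 1), delegated to
#' \code{stats::p.adjust(method = "BH")} after validating the input domain.
#'
#' @param p p-values in (0, 1].
#' @return adjusted values, same order as input.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

# Exact null distribution of the positive-rank sum W+ over all 2^n sign
# assignments, with midranks. Ranks are doubled so midranks (multiples of
# 0.5) become integers; returns P(W2 = 0..sum(r2)) where W2 = 2*W+.
.signedRankDist <- function(r2) {
    probs <- 1
    for (r in r2) {
        nxt <- c(probs, numeric(r)) / 2
        nxt[(r + 1L):(r + length(probs))] <-
            nxt[(r + 1L):(r + length(probs))] + probs / 2
        probs <- nxt
    }
    probs
}

#' Wilcoxon signed-rank test with exact small-sample enumeration
#'
#' Paired one-sample signed-rank test of \code{x} against \code{y} (here:
#' a candidate's per-sample log2CPM against the per-sample housekeeping
#' mean). Zero differences are dropped (Wilcoxon's convention) and tied
#' absolute differences receive midranks. For \code{n_effective <=
#' exactThreshold} the two-sided p is exact, from the full distribution of
#' the positive-rank sum over all \eqn{2^n} sign assignments
#' (\eqn{p = \min(1, 2\min(P(W \le w), P(W \ge w)))}); above the threshold a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y equal-length numeric vectors, paired per sample.
#' @param exactThreshold largest effective n for the exact distribution
#'   (default 25).
#' @return list with \code{statistic} (W, the positive-rank sum), \code{p},
#'   \code{n_effective}, \code{median_diff} (median of all paired
#'   differences, zeros included) and \code{method}. If every difference is
#'   zero, \code{W = 0}, \code{p = 1}, \code{n_effective = 0}.
#' @export
wilcoxonSignedRank <- function(x, y, exactThreshold = 25L) {
    if (length(x) != length(y) || length(x) < 1L)
        stop("x and y must have equal length >= 1")
    d <- x - y
    medDiff <- stats::median(d)
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
        return(list(statistic = 0, p = 1, n_effective = 0L,
                    median_diff = medDiff, method = "degenerate"))
    rk <- rank(abs(d))
    W <- sum(rk[d > 0])
    if (n <= exactThreshold) {
        r2 <- as.integer(round(2 * rk))
        probs <- .signedRankDist(r2)
        w2 <- as.integer(round(2 * W))
        pLe <- sum(probs[seq_len(w2 + 1L)])
        pGe <- sum(probs[(w2 + 1L):length(probs)])
        p <- min(1, 2 * min(pLe, pGe))
        method <- "exact"
    } else {
        mu <- sum(rk) / 2
        sigma <- sqrt(sum(rk^2) / 4)
        zNum <- max(abs(W - mu) - 0.5, 0)
        p <- min(1, 2 * stats::pnorm(zNum / sigma, lower.tail = FALSE))
        method <- "normal_approx"
    }
    list(statistic = W, p = p, n_effective = n, median_diff = medDiff,
         method = method)
}

#' Score candidate genes for glucose responsiveness
#'
#' The full housekeeping-anchored procedure: group-mean delta-log2CPM per
#' timepoint, empirical null (mean/sd of housekeeping deltas), z-score and
#' two-tailed p per candidate x timepoint, Benjamini-Hochberg FDR across the
#' whole family (jointly over candidates and timepoints by default), and a
#' responsive call at \code{q < alpha}. Alongside, a per-candidate baseline
#' comparison against the housekeeping mean: an exact Wilcoxon signed-rank
#' test pairing each candidate's per-sample log2CPM with the per-sample
#' panel mean; \code{elevated} requires both \code{p < alpha} and a positive
#' median paired difference.
#'
#' @param x a \linkS4class{MuscleExpression} on a log2 scale (centered or
#'   not; which was used is recorded in the metadata of the result).
#' @param panel housekeeping gene IDs; disjoint from \code{candidates}.
#' @param candidates candidate gene IDs, all present in \code{x}.
#' @param baseline baseline timepoint label.
#' @param timepoints post-stimulation labels (default: all others).
#' @param alpha FDR threshold for the responsive call (default 0.05).
#' @param family \code{"joint"} (default) adjusts across all candidate x
#'   timepoint tests; \code{"per_timepoint"} adjusts within each timepoint.
#' @param reference \code{"normal"} (default) or \code{"t"} (t with
#'   \code{n_hk - 1} df, for small panels).
#' @param baselineSamples samples used for the baseline Wilcoxon test;
#'   default all samples.
#' @return list with \code{responsiveness} (gene, timepoint,
#'   delta_log2cpm, z, p, q, responsive), \code{baseline} (gene, statistic,
#'   p, n_effective, median_diff, elevated), \code{nulls} (per-timepoint
#'   mu_hk/sigma_hk/n_hk) and \code{metadata}.
#' @export
scoreCandidates <- function(x, panel = defaultHkPanel(), candidates,
                            baseline = "T0", timepoints = NULL,
                            alpha = 0.05,
                            family = c("joint", "per_timepoint"),
                            reference = c("normal", "t"),
                            baselineSamples = NULL) {
    family <- match.arg(family)
    reference <- match.arg(reference)
    panel <- unique(as.character(panel))
    candidates <- unique(as.character(candidates))
    overlap <- intersect(panel, candidates)
    if (length(overlap))
        stop("candidates and housekeeping panel must be disjoint: ",
             paste(overlap, collapse = ", "))
    missing <- setdiff(c(panel, candidates), rownames(x))
    if (length(missing))
        stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
    delta <- groupMeanDelta(x, baseline = baseline, timepoints = timepoints)
    timepoints <- unique(delta$timepoint)

    nulls <- lapply(timepoints, function(tpt) nullSummary(delta, panel, tpt))
    names(nulls) <- timepoints
    res <- do.call(rbind, lapply(timepoints, function(tpt) {
        nl <- nulls[[tpt]]
        sub <- delta[delta$timepoint == tpt & delta$gene %in% candidates, ]
        z <- empiricalZ(sub$delta_log2cpm, nl)
        p <- twoTailedP(z, df = if (reference == "t") nl$n_hk - 1L else NULL)
        data.frame(gene = sub$gene, timepoint = tpt,
                   delta_log2cpm = sub$delta_log2cpm, z = z, p = p,
                   row.names = NULL)
    }))
    if (family == "joint") {
        res$q <- bhAdjust(res$p)
    } else {
        res$q <- NA_real_
        for (tpt in timepoints) {
            i <- res$timepoint == tpt
            res$q[i] <- bhAdjust(res$p[i])
        }
    }
    res$responsive <- res$q < alpha

    vals <- SummarizedExperiment::assay(x, "exprs")
    if (is.null(baselineSamples)) baselineSamples <- colnames(x)
    vals <- vals[, baselineSamples, drop = FALSE]
    hkMean <- colMeans(vals[panel, , drop = FALSE])
    base <- do.call(rbind, lapply(candidates, function(g) {
        w <- wilcoxonSignedRank(vals[g, ], hkMean)
        data.frame(gene = g, statistic = w$statistic, p = w$p,
                   n_effective = w$n_effective, median_diff = w$median_diff,
                   elevated = w$p < alpha & w$median_diff > 0,
                   row.names = NULL)
    }))

    nullDf <- do.call(rbind, lapply(nulls, function(nl)
        data.frame(timepoint = nl$timepoint, mu_hk = nl$mu_hk,
                   sigma_hk = nl$sigma_hk, n_hk = nl$n_hk,
                   row.names = NULL)))
    list(responsiveness = res, baseline = base, nulls = nullDf,
         metadata = list(panel = panel, baseline = baseline,
                         alpha = alpha, family = family,
                         reference = reference, scale = exprScale(x),
                         pseudocount = pseudocount(x),
                         sigma_denominator = "n-1"))
}

#' Write responsiveness results with a JSON run-metadata block
#'
#' @param scored result of [scoreCandidates()].
#' @param path output TSV (gene, timepoint, delta_log2cpm, z, p, q,
#'   responsive); metadata (panel, per-timepoint null parameters,
#'   pseudocount, BH family) goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeResponsiveness <- function(scored, path) {
    utils::write.table(scored$responsiveness, path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    meta <- scored$metadata
    meta$nulls <- scored$nulls
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
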