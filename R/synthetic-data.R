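#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator, which emulates the
#' count structure of a glucose-stimulation flight-muscle experiment:
#' negative-binomial counts over three timepoint groups (default n = 4
#' baseline, 3 at 30 min, 5 at 60 min), a stable low-variance housekeeping
#' panel, candidate genes with planted time-dependent log2 effects,
#' block-structured term annotation with planted module membership, and a
#' truth-tagged DEG table standing in for upstream differential-expression
#' output.
#'
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the seed.
#' @param nGenes total genes in the count matrix.
#' @param nHk housekeeping genes (>= 2); when 13, they take the default
#'   panel's names so the panel applies directly.
#' @param nCandidates candidate genes.
#' @param groupSizes named integer vector of samples per timepoint.
#' @param baselineLog2MeanRange range of baseline log2 relative abundance.
#' @param nbDispersion NB dispersion (size); variance = mu + mu^2 /
#'   dispersion, so larger is closer to Poisson.
#' @param hkDispersionFactor housekeeping stability: panel genes use
#'   dispersion \code{nbDispersion * hkDispersionFactor}.
#' @param libsizeRange library sizes are drawn log-uniformly over this
#'   range (default 5e5-2e6), so CPM normalization matters.
#' @param plantedEffects data.frame (\code{gene}, \code{timepoint},
#'   \code{delta}) of planted log2 effects; NULL for none.
#' @param nTerms,nModules,nModuleGenes annotation block structure.
#' @param withinModuleP,backgroundP probability a module gene is annotated
#'   to a term of its own module vs any other term.
#' @param degNoiseSd sd of Gaussian noise added to planted log2fc in the
#'   simulated DEG table.
#' @param degAltQ adjusted p assigned to planted (alternative) DEG rows;
#'   null rows draw q ~ Uniform(0, 1).
#' @param baselineTimepoint label of the baseline group.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, nGenes = 2000L, nHk = 13L,
                      nCandidates = 20L,
                      groupSizes = c(T0 = 4L, T30 = 3L, T60 = 5L),
                      baselineLog2MeanRange = c(2, 9),
                      nbDispersion = 20, hkDispersionFactor = 10,
                      libsizeRange = c(5e5, 2e6),
                      plantedEffects = NULL,
                      nTerms = 40L, nModules = 4L, nModuleGenes = 40L,
                      withinModuleP = 0.8, backgroundP = 0.05,
                      degNoiseSd = 0.1, degAltQ = 1e-3,
                      baselineTimepoint = "T0") {
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                nHk = as.integer(nHk), nCandidates = as.integer(nCandidates),
                groupSizes = groupSizes,
                baselineLog2MeanRange = baselineLog2MeanRange,
                nbDispersion = nbDispersion,
                hkDispersionFactor = hkDispersionFactor,
                libsizeRange = libsizeRange,
                plantedEffects = plantedEffects,
                nTerms = as.integer(nTerms), nModules = as.integer(nModules),
                nModuleGenes = as.integer(nModuleGenes),
                withinModuleP = withinModuleP, backgroundP = backgroundP,
                degNoiseSd = degNoiseSd, degAltQ = degAltQ,
                baselineTimepoint = baselineTimepoint)
    if (cfg$nHk < 2L) stop("nHk must be >= 2")
    if (any(cfg$groupSizes < 1L)) stop("group sizes must be >= 1")
    if (is.null(names(cfg$groupSizes)))
        stop("groupSizes must be named by timepoint label")
    if (cfg$nbDispersion <= 0) stop("nbDispersion must be > 0")
    for (p in c(cfg$withinModuleP, cfg$backgroundP))
        if (p < 0 || p > 1) stop("annotation probabilities must lie in [0, 1]")
    if (cfg$nHk + cfg$nCandidates > cfg$nGenes)
        stop("nGenes must cover housekeeping and candidate genes")
    class(cfg) <- "SimConfig"
    cfg
}

.simGeneNames <- function(cfg) {
    hk <- if (cfg$nHk == 13L) defaultHkPanel()
          else sprintf("HK%03d", seq_len(cfg$nHk))
    cand <- sprintf("Cand%03d", seq_len(cfg$nCandidates))
    nOther <- cfg$nGenes - cfg$nHk - cfg$nCandidates
    other <- sprintf("G%05d", seq_len(nOther))
    list(hk = hk, cand = cand, other = other,
         all = c(hk, cand, other))
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Per gene g and sample s at timepoint t, counts are drawn as
#' NB(mean = libsize_s * f(g, t), size = dispersion_g), where f(g, t) is
#' the gene's relative abundance \eqn{2^{\mu_g + \Delta_{g,t}}} normalized
#' over genes so that expected library composition is a proper fraction.
#' Housekeeping genes have zero planted delta at all timepoints and an
#' inflated size parameter (reduced dispersion), emulating their stability.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{counts} (a \linkS4class{MuscleCounts}) and
#'   \code{truth} (per-gene data.frame: is_hk, is_candidate, planted delta
#'   per non-baseline timepoint).
#' @export
simulateCounts <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    nm <- .simGeneNames(cfg)
    G <- cfg$nGenes
    tps <- names(cfg$groupSizes)
    stopifnot(cfg$baselineTimepoint %in% tps)
    mu <- stats::runif(G, cfg$baselineLog2MeanRange[1L],
                       cfg$baselineLog2MeanRange[2L])
    names(mu) <- nm$all

    deltas <- matrix(0, G, length(tps), dimnames = list(nm$all, tps))
    if (!is.null(cfg$plantedEffects)) {
        pe <- cfg$plantedEffects
        for (i in seq_len(nrow(pe))) {
            if (pe$gene[i] %in% nm$hk)
                stop("cannot plant an effect on housekeeping gene ",
                     pe$gene[i])
            deltas[pe$gene[i], pe$timepoint[i]] <- pe$delta[i]
        }
    }

    size <- rep(cfg$nbDispersion, G)
    size[seq_len(cfg$nHk)] <- cfg$nbDispersion * cfg$hkDispersionFactor

    samples <- unlist(lapply(tps, function(t)
        sprintf("%s_r%d", t, seq_len(cfg$groupSizes[[t]]))),
        use.names = FALSE)
    tpOfSample <- rep(tps, cfg$groupSizes)
    libsize <- exp(stats::runif(length(samples), log(cfg$libsizeRange[1L]),
                                log(cfg$libsizeRange[2L])))

    counts <- matrix(0L, G, length(samples),
                     dimnames = list(nm$all, samples))
    for (j in seq_along(samples)) {
        rel <- 2^(mu + deltas[, tpOfSample[j]])
        mean_j <- libsize[j] * rel / sum(rel)
        counts[, j] <- stats::rnbinom(G, mu = mean_j, size = size)
    }

    truth <- data.frame(gene = nm$all,
                        is_hk = nm$all %in% nm$hk,
                        is_candidate = nm$all %in% nm$cand,
                        row.names = NULL)
    for (t in setdiff(tps, cfg$baselineTimepoint))
        truth[[paste0("delta_", t)]] <- deltas[, t]

    list(counts = MuscleCounts(counts, timepoint = tpOfSample),
         truth = truth)
}

#' Simulate block-structured term annotation with planted modules
#'
#' Terms are partitioned evenly into \code{nModules} blocks; each of
#' \code{nModuleGenes} genes belongs to one true module (round-robin) and
#' is annotated to each term of its module with probability
#' \code{withinModuleP} and to every other term with \code{backgroundP}.
#' Terms that end up with no genes are dropped (the annotation container
#' forbids empty sets). The annotated genes are the first
#' \code{nModuleGenes} non-housekeeping genes of the count simulation
#' (candidates first), so DEG output and annotation share a namespace; the
#' universe is the annotated gene set.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{annotation} (a \linkS4class{TermAnnotation}) and
#'   \code{truth} (gene -> true module id).
#' @export
simulateAnnotation <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed + 1L)
    nm <- .simGeneNames(cfg)
    if (cfg$nModuleGenes > cfg$nCandidates + length(nm$other))
        stop("nModuleGenes exceeds available non-housekeeping genes")
    genes <- c(nm$cand, nm$other)[seq_len(cfg$nModuleGenes)]
    geneModule <- rep(seq_len(cfg$nModules), length.out = cfg$nModuleGenes)
    termModule <- rep(seq_len(cfg$nModules), length.out = cfg$nTerms)
    termIds <- sprintf("TERM%03d", seq_len(cfg$nTerms))
    incidence <- matrix(FALSE, cfg$nModuleGenes, cfg$nTerms,
                        dimnames = list(genes, termIds))
    for (i in seq_len(cfg$nModuleGenes)) {
        pr <- ifelse(termModule == geneModule[i],
                     cfg$withinModuleP, cfg$backgroundP)
        incidence[i, ] <- stats::runif(cfg$nTerms) < pr
    }
    sets <- lapply(seq_len(cfg$nTerms),
                   function(j) genes[incidence[, j]])
    names(sets) <- termIds
    keep <- lengths(sets) > 0L
    ann <- TermAnnotation(sets[keep],
                          termNames = sprintf("simulated term %d (module %d)",
                                              which(keep), termModule[keep]),
                          universe = genes)
    list(annotation = ann,
         truth = data.frame(gene = genes, module = geneModule,
                            row.names = NULL))
}

#' Simulate a truth-tagged DEG table
#'
#' Stands in for upstream differential-expression output: per gene and
#' contrast, log2fc = planted delta + Gaussian noise
#' (\code{degNoiseSd}); planted (alternative) rows receive adjusted p
#' \code{degAltQ}, null rows draw q ~ Uniform(0, 1); raw p is drawn below
#' q. True direction (sign of the planted delta) is recorded.
#'
#' @param cfg a [simConfig()]; planted effects come from
#'   \code{cfg$plantedEffects} (contrast label =
#'   \code{<timepoint>_vs_<baseline>}).
#' @param contrasts contrast labels to emit; default one per non-baseline
#'   timepoint.
#' @return list with \code{deg} (gene, contrast, log2fc, p, q, direction)
#'   and \code{truth} (per row: planted delta, true direction, is_null).
#' @export
simulateDegTable <- function(cfg, contrasts = NULL) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed + 2L)
    nm <- .simGeneNames(cfg)
    tps <- setdiff(names(cfg$groupSizes), cfg$baselineTimepoint)
    if (is.null(contrasts))
        contrasts <- paste0(tps, "_vs_", cfg$baselineTimepoint)
    planted <- cfg$plantedEffects
    out <- lapply(seq_along(contrasts), function(ci) {
        tp <- tps[ci]
        delta <- stats::setNames(rep(0, cfg$nGenes), nm$all)
        if (!is.null(planted)) {
            sel <- planted$timepoint == tp
            delta[planted$gene[sel]] <- planted$delta[sel]
        }
        isNull <- delta == 0
        log2fc <- delta + stats::rnorm(cfg$nGenes, 0, cfg$degNoiseSd)
        q <- ifelse(isNull, stats::runif(cfg$nGenes), cfg$degAltQ)
        p <- q * stats::runif(cfg$nGenes)
        list(deg = data.frame(gene = nm$all, contrast = contrasts[ci],
                              log2fc = log2fc, p = pmax(p, 1e-300), q = q,
                              row.names = NULL),
             truth = data.frame(gene = nm$all, contrast = contrasts[ci],
                                planted_delta = unname(delta),
                                true_direction = ifelse(delta > 0, "up",
                                    ifelse(delta < 0, "down", "none")),
                                is_null = unname(isNull), row.names = NULL))
    })
    deg <- do.call(rbind, lapply(out, `[[`, "deg"))
    deg$direction <- ifelse(deg$log2fc > 0, "up", "down")
    list(deg = deg, truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Write a full simulated study to a directory
#'
#' Generates every pipeline input under one seed: counts TSV, design TSV,
#' housekeeping panel list, candidate list, GMT annotation, DEG table and
#' a JSON truth file. Unless \code{cfg$plantedEffects} is supplied, half
#' the candidates receive planted effects (+2 at the first post-baseline
#' timepoint, alternating sign at the second) so recovery is testable out
#' of the box.
#'
#' @param cfg a [simConfig()].
#' @param dir output directory (created if needed).
#' @return invisible named list of written paths.
#' @export
simulateStudy <- function(cfg, dir) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    nm <- .simGeneNames(cfg)
    tps <- setdiff(names(cfg$groupSizes), cfg$baselineTimepoint)
    if (is.null(cfg$plantedEffects)) {
        half <- nm$cand[seq_len(ceiling(cfg$nCandidates / 2))]
        cfg$plantedEffects <- do.call(rbind, lapply(seq_along(tps),
            function(i) data.frame(
                gene = half, timepoint = tps[i],
                delta = if (i == 1L) 2 else 2 * (-1)^seq_along(half))))
    }
    sim <- simulateCounts(cfg)
    ann <- simulateAnnotation(cfg)
    deg <- simulateDegTable(cfg)
    paths <- list(
        counts = file.path(dir, "counts.tsv"),
        design = file.path(dir, "design.tsv"),
        panel = file.path(dir, "hk_panel.txt"),
        candidates = file.path(dir, "candidates.txt"),
        gmt = file.path(dir, "annotation.gmt"),
        deg = file.path(dir, "deg_table.tsv"),
        truth = file.path(dir, "truth.json"))
    writeCounts(sim$counts, paths$counts, paths$design)
    writeLines(nm$hk, paths$panel)
    writeLines(nm$cand, paths$candidates)
    writeGmt(ann$annotation, paths$gmt)
    writeDegTable(deg$deg, paths$deg)
    jsonlite::write_json(
        list(seed = cfg$seed,
             counts_truth = sim$truth,
             module_truth = ann$truth,
             deg_truth = deg$truth,
             planted_effects = cfg$plantedEffects),
        paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(paths)
}
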