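#' Default pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults, plus input
#' paths (NULL = stage skipped). Unknown keys and out-of-domain values are
#' rejected by [validateRunConfig()].
#'
#' @return named list.
#' @export
defaultRunConfig <- function() {
    list(
        counts = NULL, design = NULL, panel = NULL, candidates = NULL,
        gmt = NULL, deg = NULL, pairs = NULL, growth = NULL,
        seed = 1L,
        pseudocount = 1,
        filter_min_cpm = 1, filter_min_samples = NULL,
        center_on_hk = TRUE,
        baseline = "T0",
        alpha = 0.05,
        bh_family = "joint",
        reference = "normal",
        deg_min_abs_log2fc = 1.5, deg_max_q = 0.01,
        ora_min_term_size = 2L, ora_max_term_size = 500L,
        ora_alpha = 0.05,
        profiles_enriched_only = TRUE,
        k_modules = 4L, linkage = "average", secondary_threshold = 0.2,
        fiber_alpha = 0.05)
}

.configDomains <- list(
    pseudocount = function(v) is.numeric(v) && v > 0,
    alpha = function(v) is.numeric(v) && v > 0 && v < 1,
    ora_alpha = function(v) is.numeric(v) && v > 0 && v < 1,
    fiber_alpha = function(v) is.numeric(v) && v > 0 && v < 1,
    deg_max_q = function(v) is.numeric(v) && v > 0 && v <= 1,
    deg_min_abs_log2fc = function(v) is.numeric(v) && v > 0,
    filter_min_cpm = function(v) is.numeric(v) && v >= 0,
    secondary_threshold = function(v) is.numeric(v) && v >= 0 && v <= 1,
    k_modules = function(v) is.numeric(v) && v >= 1,
    bh_family = function(v) v %in% c("joint", "per_timepoint"),
    reference = function(v) v %in% c("normal", "t"),
    linkage = function(v) v %in% c("average", "complete", "single",
                                   "ward.D2"))

#' Validate a pipeline configuration
#'
#' Merges user keys over [defaultRunConfig()], rejecting unknown keys and
#' values outside their documented domains. Failures signal a condition of
#' class \code{"muscleTx_config_error"} naming the offending field.
#'
#' @param config named list (or path to a YAML file) of overrides.
#' @return the merged, validated config list.
#' @export
validateRunConfig <- function(config = list()) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    base <- defaultRunConfig()
    unknown <- setdiff(names(config), names(base))
    if (length(unknown))
        stop(structure(class = c("muscleTx_config_error", "error",
                                 "condition"),
                       list(message = paste0("unknown config key(s): ",
                                             paste(unknown, collapse = ", ")),
                            call = NULL)))
    cfg <- utils::modifyList(base, config, keep.null = TRUE)
    for (field in names(.configDomains)) {
        v <- cfg[[field]]
        if (!is.null(v) && !.configDomains[[field]](v))
            stop(structure(class = c("muscleTx_config_error", "error",
                                     "condition"),
                           list(message = sprintf(
                                    "config field '%s' out of domain (value: %s)",
                                    field, paste(v, collapse = ", ")),
                                call = NULL)))
    }
    cfg
}

.provenance <- function(outPath, stage, cfg) {
    keep <- cfg[!vapply(cfg, is.null, logical(1L))]
    jsonlite::write_json(
        list(stage = stage, package = "muscleTx",
             version = as.character(utils::packageVersion("muscleTx")),
             r_version = paste(R.version$major, R.version$minor, sep = "."),
             seed = cfg$seed, config = keep),
        paste0(outPath, ".json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — read counts/design, CPM and
#' log2 normalization, low-expression filtering, housekeeping centering,
#' candidate responsiveness scoring, DEG threshold filtering,
#' cross-contrast overlap, over-representation analysis, Jaccard module
#' clustering and Venn, fiber-type paralog comparison, growth kinetics —
#' skipping any stage whose inputs are not configured. Every output TSV is
#' accompanied by a \code{.json} provenance block (stage, package version,
#' seed, full config) sufficient to re-run it; outputs are byte-identical
#' across runs with the same config and seed. Stage failures signal a
#' condition of class \code{"muscleTx_stage_error"} naming the stage.
#'
#' @param config named list or YAML path, validated by
#'   [validateRunConfig()].
#' @param outdir output directory (created if needed).
#' @return invisible named list of output paths.
#' @export
runPipeline <- function(config = list(), outdir) {
    cfg <- validateRunConfig(config)
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    set.seed(cfg$seed)
    outputs <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(structure(class = c("muscleTx_stage_error", "error",
                                     "condition"),
                           list(message = sprintf("stage '%s' failed: %s",
                                                  name, conditionMessage(e)),
                                call = NULL))))
    }

    expr <- NULL
    if (!is.null(cfg$counts)) {
        message("[io] reading counts")
        counts <- stage("io", readCounts(cfg$counts, cfg$design))
        message("[normalize] CPM + log2(+", cfg$pseudocount, ")")
        expr <- stage("normalize", {
            filtered <- filterLowExpression(computeCPM(counts),
                                            minValue = cfg$filter_min_cpm,
                                            minSamples = cfg$filter_min_samples)
            log2Transform(filtered, pseudocount = cfg$pseudocount)
        })
        if (!is.null(cfg$panel) && !is.null(cfg$candidates)) {
            message("[candidates] responsiveness scoring")
            panel <- readGeneList(cfg$panel)
            cand <- readGeneList(cfg$candidates)
            scoringMatrix <- if (cfg$center_on_hk)
                stage("candidates", hkCenter(expr, panel)) else expr
            scored <- stage("candidates",
                scoreCandidates(scoringMatrix, panel = panel,
                                candidates = intersect(cand, rownames(expr)),
                                baseline = cfg$baseline, alpha = cfg$alpha,
                                family = cfg$bh_family,
                                reference = cfg$reference))
            outputs$responsiveness <- file.path(outdir, "responsiveness.tsv")
            writeResponsiveness(scored, outputs$responsiveness)
            outputs$baseline <- file.path(outdir, "baseline_wilcoxon.tsv")
            utils::write.table(scored$baseline, outputs$baseline, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            .provenance(outputs$baseline, "candidates", cfg)
        }
    }

    degSets <- NULL
    if (!is.null(cfg$deg)) {
        message("[degs] threshold filtering")
        deg <- stage("degs", readDegTable(cfg$deg))
        surv <- stage("degs", filterDegs(deg,
                                         minAbsLog2fc = cfg$deg_min_abs_log2fc,
                                         maxQ = cfg$deg_max_q))
        outputs$degs <- file.path(outdir, "deg_filtered.tsv")
        writeDegTable(surv, outputs$degs)
        .provenance(outputs$degs, "degs", cfg)
        degSets <- split(surv$gene, surv$contrast)
        if (length(degSets) >= 2L) {
            ov <- contrastOverlap(degSets[[1L]], degSets[[2L]])
            outputs$overlap <- file.path(outdir, "contrast_overlap.tsv")
            utils::write.table(
                data.frame(region = c(names(degSets)[1L], "both",
                                      names(degSets)[2L]),
                           count = ov$counts,
                           genes = vapply(ov[c("only_a", "both", "only_b")],
                                          paste, character(1L),
                                          collapse = ";")),
                outputs$overlap, sep = "\t", quote = FALSE,
                row.names = FALSE)
            .provenance(outputs$overlap, "overlap", cfg)
        }
        if (!is.null(cfg$gmt)) {
            message("[ora] over-representation + modules")
            ann <- stage("ora", readGmt(cfg$gmt))
            study <- intersect(unique(surv$gene), annUniverse(ann))
            enr <- stage("ora", ora(study, ann,
                                    minTermSize = cfg$ora_min_term_size,
                                    maxTermSize = cfg$ora_max_term_size))
            outputs$enrichment <- file.path(outdir, "enrichment.tsv")
            utils::write.table(enr, outputs$enrichment, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            .provenance(outputs$enrichment, "ora", cfg)
            enrTerms <- if (cfg$profiles_enriched_only)
                enr$term_id[enr$q < cfg$ora_alpha] else NULL
            if (!is.null(enrTerms) && length(enrTerms) == 0L) {
                message("[modules] no enriched terms at q < ", cfg$ora_alpha,
                        "; profiling against full annotation")
                enrTerms <- NULL
            }
            profiles <- geneTermProfiles(study, ann, enriched = enrTerms)
            nonEmpty <- sum(lengths(profiles) > 0L)
            if (nonEmpty >= cfg$k_modules) {
                mods <- stage("modules",
                    clusterModules(profiles, k = cfg$k_modules,
                                   linkage = cfg$linkage,
                                   secondaryThreshold =
                                       cfg$secondary_threshold))
                outputs$modules <- file.path(outdir, "modules.tsv")
                utils::write.table(mods, outputs$modules, sep = "\t",
                                   quote = FALSE, row.names = FALSE)
                .provenance(outputs$modules, "modules", cfg)
                venn <- moduleVenn(mods)
                outputs$module_venn <- file.path(outdir, "module_venn.tsv")
                utils::write.table(
                    data.frame(region = names(venn), count = venn),
                    outputs$module_venn, sep = "\t", quote = FALSE,
                    row.names = FALSE)
                .provenance(outputs$module_venn, "modules", cfg)
            } else {
                message("[modules] skipped: only ", nonEmpty,
                        " non-empty profiles for k = ", cfg$k_modules)
            }
        }
    }

    if (!is.null(expr) && !is.null(cfg$pairs)) {
        message("[fiber] paralog comparison")
        pairs <- readParalogPairs(cfg$pairs)
        fib <- stage("fiber", fiberProfile(expr, pairs,
                                           alpha = cfg$fiber_alpha))
        outputs$fiber <- file.path(outdir, "fiber_profile.tsv")
        utils::write.table(fib$report, outputs$fiber, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        .provenance(outputs$fiber, "fiber", cfg)
    }

    if (!is.null(cfg$growth)) {
        message("[growth] doubling-time fits")
        gr <- stage("growth", growthReport(cfg$growth))
        outputs$growth <- file.path(outdir, "growth_kinetics.tsv")
        utils::write.table(gr, outputs$growth, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        .provenance(outputs$growth, "growth", cfg)
    }

    invisible(outputs)
}
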