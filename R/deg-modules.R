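#' Read / write a differential-expression table
#'
#' TSV with columns \code{gene}, \code{contrast}, \code{log2fc}, \code{p},
#' \code{q}. (gene, contrast) pairs must be unique. A \code{direction}
#' column (\code{up}/\code{down} from the sign of log2fc) is derived on
#' read.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readDegTable <- function(path) {
    if (!file.exists(path)) stop("DEG table not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    .validateDegTable(tab)
}

.validateDegTable <- function(tab) {
    req <- c("gene", "contrast", "log2fc", "p", "q")
    miss <- setdiff(req, colnames(tab))
    if (length(miss))
        stop("DEG table needs columns: ", paste(miss, collapse = ", "))
    key <- paste(tab$gene, tab$contrast)
    if (anyDuplicated(key))
        stop("duplicate (gene, contrast) row(s): ",
             paste(utils::head(unique(key[duplicated(key)]), 3),
                   collapse = "; "))
    tab$direction <- ifelse(tab$log2fc > 0, "up", "down")
    tab
}

#' @rdname readDegTable
#' @param tab a DEG table data.frame.
#' @export
writeDegTable <- function(tab, path) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Threshold-filter a DEG table
#'
#' Retains rows with \code{|log2fc| > minAbsLog2fc} and \code{q < maxQ}
#' (strict inequalities, matching the "<" / ">" convention of edgeR-style
#' DEG calls such as q < 0.05 with |log2FC| > 1, or the stricter
#' q < 0.01 with |log2FC| > 1.5). Per-contrast up/down survivor counts are
#' attached as \code{attr(, "summary")}.
#'
#' @param tab DEG table (see [readDegTable()]).
#' @param minAbsLog2fc positive fold-change threshold.
#' @param maxQ positive adjusted-p threshold.
#' @return the filtered table.
#' @export
filterDegs <- function(tab, minAbsLog2fc = 1, maxQ = 0.05) {
    if (minAbsLog2fc <= 0 || maxQ <= 0) stop("thresholds must be > 0")
    tab <- .validateDegTable(tab)
    keep <- abs(tab$log2fc) > minAbsLog2fc & tab$q < maxQ
    out <- tab[keep, , drop = FALSE]
    smry <- if (nrow(out)) {
        agg <- table(out$contrast,
                     factor(out$direction, levels = c("up", "down")))
        data.frame(contrast = rownames(agg),
                   up = as.integer(agg[, "up"]),
                   down = as.integer(agg[, "down"]),
                   row.names = NULL)
    } else data.frame(contrast = character(), up = integer(),
                      down = integer())
    attr(out, "summary") <- smry
    out
}

#' Overlap partition of two gene sets
#'
#' Exact three-region partition of two DEG sets (e.g. T30-vs-T0 and
#' T60-vs-T0), as drawn in a two-set Venn diagram:
#' \code{|only_a| + |only_b| + |both| = |a U b|}.
#'
#' @param a,b character vectors of gene IDs.
#' @return list with \code{only_a}, \code{only_b}, \code{both} (sorted
#'   character vectors) and \code{counts}.
#' @export
contrastOverlap <- function(a, b) {
    a <- unique(as.character(a)); b <- unique(as.character(b))
    res <- list(only_a = sort(setdiff(a, b)),
                only_b = sort(setdiff(b, a)),
                both = sort(intersect(a, b)))
    res$counts <- vapply(res[c("only_a", "both", "only_b")], length,
                         integer(1L))
    res
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: term id, term description, then member genes. Multiple
#' sources (KEGG, Reactome, ...) can be merged by reading each file and
#' concatenating; keep source-prefixed term ids to avoid collisions.
#'
#' @param path GMT file.
#' @param universe optional background gene set; defaults to the union of
#'   all term members.
#' @return a \linkS4class{TermAnnotation}.
#' @export
readGmt <- function(path, universe = NULL) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(parts, length, integer(1L)) < 3L
    if (any(short))
        stop("malformed GMT line(s) (need id, name, >=1 gene): line ",
             paste(which(short), collapse = ", "))
    ids <- vapply(parts, `[`, character(1L), 1L)
    nms <- vapply(parts, `[`, character(1L), 2L)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- ids
    TermAnnotation(sets, termNames = nms, universe = universe)
}

#' @rdname readGmt
#' @param ann a \code{TermAnnotation} to write.
#' @export
writeGmt <- function(ann, path) {
    nms <- annTermNames(ann)
    lines <- vapply(names(annTerms(ann)), function(id)
        paste(c(id, nms[[id]], annTerms(ann)[[id]]), collapse = "\t"),
        character(1L))
    writeLines(lines, path)
    invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term of size K within [minTermSize, maxTermSize],
#' tests whether the study set (size n, drawn from a universe of size N) is
#' enriched: \eqn{p = P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n),
#' where k is the observed overlap. p-values are BH-adjusted across the
#' reported terms. The background is the annotation's universe.
#'
#' @param study character vector of study genes, a subset of the universe.
#' @param ann a \linkS4class{TermAnnotation}.
#' @param minTermSize,maxTermSize term-size window (defaults 1, Inf).
#' @return data.frame with \code{term_id}, \code{term_name}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{p}, \code{q}, ordered by p.
#' @export
ora <- function(study, ann, minTermSize = 1L, maxTermSize = Inf) {
    stopifnot(methods::is(ann, "TermAnnotation"))
    study <- unique(as.character(study))
    out <- setdiff(study, annUniverse(ann))
    if (length(out))
        stop("study gene(s) outside universe: ",
             paste(utils::head(out, 10), collapse = ", "))
    N <- length(annUniverse(ann))
    n <- length(study)
    terms <- annTerms(ann)
    Ks <- lengths(terms)
    keep <- Ks >= minTermSize & Ks <= maxTermSize
    terms <- terms[keep]
    if (!length(terms))
        return(data.frame(term_id = character(), term_name = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric(), q = numeric()))
    ks <- vapply(terms, function(g) length(intersect(g, study)), integer(1L))
    Ks <- lengths(terms)
    p <- stats::phyper(ks - 1L, Ks, N - Ks, n, lower.tail = FALSE)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    res <- data.frame(term_id = names(terms),
                      term_name = unname(annTermNames(ann)[names(terms)]),
                      k = ks, K = Ks, n = n, N = N, p = p,
                      q = bhAdjust(p), row.names = NULL)
    res[order(res$p, res$term_id), , drop = FALSE]
}

#' Per-gene enrichment-term profiles
#'
#' Maps each gene to the set of terms containing it — either all annotated
#' terms, or only the enriched ones when an [ora()] result is supplied
#' (pass the rows you consider enriched, e.g. \code{q < 0.05}). Genes with
#' empty profiles are reported in \code{attr(, "unassignable")}; they cannot
#' be clustered.
#'
#' @param genes character vector of gene IDs.
#' @param ann a \linkS4class{TermAnnotation}.
#' @param enriched optional character vector of term ids to restrict to
#'   (e.g. \code{result$term_id[result$q < 0.05]}).
#' @return named list gene -> character vector of term ids.
#' @export
geneTermProfiles <- function(genes, ann, enriched = NULL) {
    stopifnot(methods::is(ann, "TermAnnotation"))
    genes <- unique(as.character(genes))
    terms <- annTerms(ann)
    if (!is.null(enriched)) terms <- terms[names(terms) %in% enriched]
    profiles <- lapply(genes, function(g)
        sort(names(terms)[vapply(terms, function(set) g %in% set,
                                 logical(1L))]))
    names(profiles) <- genes
    attr(profiles, "unassignable") <- genes[lengths(profiles) == 0L]
    profiles
}

#' Jaccard similarity of two sets
#'
#' \eqn{J(a, b) = |a \cap b| / |a \cup b|}; 1 iff the sets are equal,
#' 0 iff disjoint. Undefined (error) when both sets are empty — genes with
#' empty term profiles are excluded upstream.
#'
#' @param a,b character vectors.
#' @return similarity in [0, 1].
#' @export
jaccardIndex <- function(a, b) {
    a <- unique(a); b <- unique(b)
    u <- length(union(a, b))
    if (u == 0L) stop("Jaccard similarity undefined: both sets empty")
    length(intersect(a, b)) / u
}

# genes x genes Jaccard similarity via the binary gene x term incidence.
.jaccardMatrix <- function(profiles) {
    allTerms <- sort(unique(unlist(profiles, use.names = FALSE)))
    M <- vapply(profiles, function(p) as.numeric(allTerms %in% p),
                numeric(length(allTerms)))
    M <- t(M)  # genes x terms
    inter <- M %*% t(M)
    sizes <- rowSums(M)
    un <- outer(sizes, sizes, "+") - inter
    J <- inter / un
    dimnames(J) <- list(names(profiles), names(profiles))
    J
}

#' Cluster genes into functional modules by shared enrichment profiles
#'
#' Genes are clustered on the Jaccard distance (1 - similarity) between
#' their term profiles, by agglomerative hierarchical clustering cut at
#' \code{k} clusters; the cut clusters are the primary modules. A gene is
#' additionally given a secondary membership in module m (marking genes
#' shared between modules) when the Jaccard similarity between its profile
#' and the union of m's member-term profiles reaches
#' \code{secondaryThreshold}. Genes are processed in lexicographic ID order
#' and modules are numbered by their lexicographically smallest member, so
#' the assignment is invariant to input order.
#'
#' @param profiles named list gene -> term set (see [geneTermProfiles()]);
#'   genes with empty profiles are dropped with a message.
#' @param k number of modules (default 4).
#' @param linkage hclust agglomeration method (default \code{"average"}).
#' @param secondaryThreshold Jaccard cutoff for secondary membership
#'   (default 0.2).
#' @param moduleNames optional character vector of length \code{k} of
#'   caller-supplied labels (e.g. "lipid handling").
#' @return data.frame with \code{gene}, \code{primary_module},
#'   \code{secondary_modules} (semicolon-joined, possibly empty),
#'   \code{module_name}; module term-unions in \code{attr(, "moduleTerms")}.
#' @export
clusterModules <- function(profiles, k = 4L, linkage = "average",
                           secondaryThreshold = 0.2, moduleNames = NULL) {
    if (k < 1L) stop("k must be >= 1")
    profiles <- profiles[order(names(profiles))]
    empty <- lengths(profiles) == 0L
    if (any(empty)) {
        message(sum(empty), " gene(s) with empty profiles dropped")
        profiles <- profiles[!empty]
    }
    if (length(profiles) < k)
        stop("fewer genes with non-empty profiles (", length(profiles),
             ") than modules requested (", k, ")")
    if (length(profiles) == k) {
        cl <- stats::setNames(seq_len(k), names(profiles))
    } else {
        J <- .jaccardMatrix(profiles)
        d <- stats::as.dist(1 - J)
        cl <- stats::cutree(stats::hclust(d, method = linkage), k = k)
    }
    # renumber modules by lexicographically smallest member gene
    first <- vapply(split(names(cl), cl), min, character(1L))
    relabel <- match(names(sort(first)), names(first))
    cl <- stats::setNames(match(cl, relabel), names(cl))

    moduleTerms <- lapply(seq_len(k), function(m)
        sort(unique(unlist(profiles[names(cl)[cl == m]],
                           use.names = FALSE))))
    if (is.null(moduleNames)) moduleNames <- paste0("module", seq_len(k))
    if (length(moduleNames) != k)
        stop("moduleNames must have length k")

    secondary <- vapply(names(cl), function(g) {
        others <- setdiff(seq_len(k), cl[[g]])
        hits <- others[vapply(others, function(m)
            jaccardIndex(profiles[[g]], moduleTerms[[m]]) >=
                secondaryThreshold, logical(1L))]
        paste(hits, collapse = ";")
    }, character(1L))

    out <- data.frame(gene = names(cl),
                      primary_module = unname(cl),
                      secondary_modules = unname(secondary),
                      module_name = moduleNames[cl],
                      row.names = NULL)
    attr(out, "moduleTerms") <- moduleTerms
    out
}

#' Region counts of the module-membership Venn diagram
#'
#' Classifies every gene by its full membership set (primary plus secondary
#' modules, restricted to \code{modules}) and counts genes per exclusive
#' Venn region. With no secondary memberships the regions are exactly the
#' primary-module partition. Region counts conserve cardinality: summing
#' the regions containing a module recovers that module's total membership.
#'
#' @param assignments a [clusterModules()] result.
#' @param modules integer module labels to include (default: all primary
#'   labels present).
#' @return named integer vector over all non-empty-region labels (module
#'   ids joined by \code{"&"}), including zero counts.
#' @export
moduleVenn <- function(assignments, modules = NULL) {
    prim <- assignments$primary_module
    if (is.null(modules)) modules <- sort(unique(prim))
    if (!all(modules %in% prim))
        stop("module label(s) not assigned: ",
             paste(setdiff(modules, prim), collapse = ", "))
    membership <- lapply(seq_len(nrow(assignments)), function(i) {
        sec <- assignments$secondary_modules[i]
        mem <- c(prim[i],
                 if (nzchar(sec)) as.integer(strsplit(sec, ";")[[1L]]))
        sort(intersect(mem, modules))
    })
    regions <- unlist(lapply(seq_along(modules), function(r)
        utils::combn(sort(modules), r, paste, collapse = "&",
                     simplify = FALSE)), use.names = FALSE)
    counts <- stats::setNames(integer(length(regions)), regions)
    for (mem in membership) {
        if (!length(mem)) next
        key <- paste(mem, collapse = "&")
        counts[key] <- counts[key] + 1L
    }
    counts
}
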