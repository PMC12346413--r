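degToy <- function() {
    data.frame(gene = paste0("g", 1:5), contrast = "T30_vs_T0",
               log2fc = c(2.0, 1.2, 1.8, -1.7, 0.5),
               p = c(1e-4, 1e-4, 0.1, 4e-4, 0.3),
               q = c(0.001, 0.001, 0.2, 0.004, 0.5))
}

test_that("filterDegs applies strict thresholds and counts directions", {
    out <- filterDegs(degToy(), minAbsLog2fc = 1.5, maxQ = 0.01)
    expect_setequal(out$gene, c("g1", "g4"))
    smry <- attr(out, "summary")
    expect_equal(smry$up, 1L)
    expect_equal(smry$down, 1L)
    # boundary values are excluded (strict < and >)
    edge <- data.frame(gene = "e", contrast = "c", log2fc = 1.5,
                       p = 0.005, q = 0.01)
    expect_identical(nrow(filterDegs(edge, 1.5, 0.01)), 0L)
    # empty in, empty out
    expect_identical(nrow(filterDegs(degToy()[0, ], 1, 0.05)), 0L)
    expect_error(filterDegs(degToy(), 0, 0.05), "> 0")
})

test_that("filterDegs survivors are monotone in both thresholds", {
    set.seed(12)
    tab <- data.frame(gene = sprintf("g%03d", 1:200), contrast = "c",
                      log2fc = rnorm(200, 0, 2), p = runif(200),
                      q = runif(200))
    fcs <- c(0.5, 1, 1.5, 2); qs <- c(0.2, 0.1, 0.05, 0.01)
    n <- sapply(fcs, function(f) sapply(qs, function(q)
        nrow(filterDegs(tab, f, q))))
    expect_true(all(apply(n, 1, diff) <= 0))  # tighter fc -> fewer
    expect_true(all(apply(n, 2, diff) <= 0))  # tighter q -> fewer
})

test_that("contrastOverlap partitions exactly", {
    ov <- contrastOverlap(c("x", "y"), c("y", "z"))
    expect_identical(ov$only_a, "x")
    expect_identical(ov$both, "y")
    expect_identical(ov$only_b, "z")
    same <- contrastOverlap(c("a", "b"), c("b", "a"))
    expect_identical(same$counts,
                     c(only_a = 0L, both = 2L, only_b = 0L))
    set.seed(8)
    pool <- sprintf("g%04d", 1:400)
    a <- sample(pool, 100); b <- sample(pool, 100)
    ov <- contrastOverlap(a, b)
    # brute-force membership scan
    expect_identical(sort(ov$both), sort(pool[pool %in% a & pool %in% b]))
    expect_identical(sum(ov$counts), length(union(a, b)))
})

test_that("ora matches the combinatorial closed form", {
    universe <- paste0("u", 1:10)
    ann <- TermAnnotation(list(t1 = universe[1:5], all = universe),
                          universe = universe)
    res <- ora(universe[2:5], ann)
    # k=4 of K=5 drawn n=4 from N=10: C(5,4)C(5,0)/C(10,4) = 5/210
    expect_equal(res$p[res$term_id == "t1"], 5 / 210, tolerance = 1e-12)
    # term == universe: the overlap is certain
    expect_equal(res$p[res$term_id == "all"], 1)
    expect_equal(res$k[res$term_id == "all"], 4L)
    expect_error(ora(c("u1", "ghost"), ann), "ghost")
})

test_that("ora p-values equal enumeration on random small instances", {
    set.seed(64)
    for (i in 1:40) {
        N <- sample(8:30, 1)
        universe <- sprintf("u%02d", 1:N)
        K <- sample(2:(N - 1), 1)
        n <- sample(2:(N - 1), 1)
        term <- sample(universe, K)
        study <- sample(universe, n)
        ann <- TermAnnotation(list(t = term), universe = universe)
        p <- ora(study, ann)$p
        k <- length(intersect(term, study))
        expect_equal(p, hyperChooseOracle(k, K, n, N), tolerance = 1e-12,
                     info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
    # literal enumeration of every possible draw on tiny universes
    for (i in 1:5) {
        N <- sample(7:11, 1)
        universe <- sprintf("u%02d", 1:N)
        term <- sample(universe, sample(2:4, 1))
        study <- sample(universe, sample(2:4, 1))
        ann <- TermAnnotation(list(t = term), universe = universe)
        expect_equal(ora(study, ann)$p,
                     hyperEnumOracle(term, study, universe),
                     tolerance = 1e-12)
    }
})

test_that("geneTermProfiles transposes the incidence structure", {
    terms <- list(A = c("g1", "g2", "g5"), B = c("g2", "g3"),
                  C = c("g4", "g5"), D = c("g1", "g2", "g3", "g4"))
    ann <- TermAnnotation(terms, universe = paste0("g", 1:6))
    prof <- geneTermProfiles(paste0("g", 1:6), ann)
    # verify against a per-gene scan of the incidence
    for (g in paste0("g", 1:6))
        expect_identical(prof[[g]],
                         sort(names(terms)[vapply(terms, function(s)
                             g %in% s, logical(1))]))
    expect_identical(attr(prof, "unassignable"), "g6")
    # enriched-only restriction
    profAB <- geneTermProfiles(paste0("g", 1:6), ann,
                               enriched = c("A", "B"))
    expect_identical(profAB[["g4"]], character(0))
    expect_identical(profAB[["g2"]], c("A", "B"))
})

test_that("jaccardIndex: bounds, symmetry, identity, disjointness", {
    expect_equal(jaccardIndex(c("A", "B", "C"), c("B", "C", "D")), 0.5)
    expect_equal(jaccardIndex(c("A", "B"), c("B", "A")), 1)
    expect_equal(jaccardIndex("A", "B"), 0)
    expect_error(jaccardIndex(character(0), character(0)), "empty")
    set.seed(2)
    for (i in 1:30) {
        a <- sample(LETTERS, sample(1:10, 1))
        b <- sample(LETTERS, sample(1:10, 1))
        j <- jaccardIndex(a, b)
        expect_equal(j, jaccardIndex(b, a))
        expect_true(j >= 0 && j <= 1)
        expect_identical(j == 1, setequal(a, b))
        expect_identical(j == 0, length(intersect(a, b)) == 0L)
    }
})

test_that("clusterModules recovers separable blocks and handles k = 1", {
    profiles <- list(g1 = c("A", "B"), g2 = c("A", "B"),
                     g3 = c("C", "D"), g4 = c("C", "D"))
    out <- clusterModules(profiles, k = 2)
    expect_identical(out$primary_module[out$gene %in% c("g1", "g2")],
                     c(1L, 1L))
    expect_identical(out$primary_module[out$gene %in% c("g3", "g4")],
                     c(2L, 2L))
    expect_true(all(out$secondary_modules == ""))
    one <- clusterModules(profiles, k = 1)
    expect_true(all(one$primary_module == 1L))
    expect_error(clusterModules(profiles, k = 5), "fewer genes")
})

test_that("clusterModules is invariant to gene input order", {
    set.seed(14)
    cfg <- simConfig(seed = 14)
    sim <- simulateAnnotation(cfg)
    prof <- geneTermProfiles(annUniverse(sim$annotation), sim$annotation)
    prof <- prof[lengths(prof) > 0]
    a <- clusterModules(prof, k = 4)
    b <- clusterModules(prof[sample(names(prof))], k = 4)
    expect_identical(a[order(a$gene), ], b[order(b$gene), ])
})

test_that("secondary memberships mark genes shared between modules", {
    profiles <- list(g1 = c("A", "B"), g2 = c("A", "B"),
                     g3 = c("C", "D"), g4 = c("C", "D"),
                     g5 = c("A", "B", "C", "D"))
    out <- clusterModules(profiles, k = 2, secondaryThreshold = 0.4)
    shared <- out[out$gene == "g5", ]
    expect_true(nzchar(shared$secondary_modules))
    # a gene's primary module never reappears among its secondaries
    for (i in seq_len(nrow(out))) {
        sec <- out$secondary_modules[i]
        if (nzchar(sec))
            expect_false(out$primary_module[i] %in%
                             as.integer(strsplit(sec, ";")[[1]]))
    }
})

test_that("moduleVenn counts exclusive regions and conserves totals", {
    asn <- data.frame(gene = paste0("g", 1:5),
                      primary_module = c(1L, 1L, 2L, 2L, 1L),
                      secondary_modules = c("", "", "", "", "2"),
                      module_name = "m")
    venn <- moduleVenn(asn)
    expect_equal(venn[["1"]], 2L)
    expect_equal(venn[["2"]], 2L)
    expect_equal(venn[["1&2"]], 1L)
    # with no secondaries the regions are the primary partition
    asn0 <- transform(asn, secondary_modules = "")
    v0 <- moduleVenn(asn0)
    expect_equal(v0[["1"]], 3L); expect_equal(v0[["2"]], 2L)
    expect_equal(v0[["1&2"]], 0L)
    # random fixture: per-gene brute-force region classification
    set.seed(4)
    n <- 30
    rnd <- data.frame(
        gene = sprintf("g%02d", 1:n),
        primary_module = sample(1:3, n, replace = TRUE),
        secondary_modules = replicate(n, paste(
            sample(1:3, sample(0:2, 1)), collapse = ";")),
        module_name = "m")
    v <- moduleVenn(rnd)
    memb <- lapply(seq_len(n), function(i) sort(unique(c(
        rnd$primary_module[i],
        if (nzchar(rnd$secondary_modules[i]))
            as.integer(strsplit(rnd$secondary_modules[i], ";")[[1]])))))
    brute <- table(vapply(memb, paste, character(1), collapse = "&"))
    for (r in names(brute))
        expect_equal(v[[r]], unname(brute[[r]]))
    # region sums containing module m equal m's total membership
    for (m in 1:3) {
        inRegion <- vapply(strsplit(names(v), "&", fixed = TRUE),
                           function(s) as.character(m) %in% s, logical(1))
        expect_equal(sum(v[inRegion]),
                     sum(vapply(memb, function(x) m %in% x, logical(1))))
    }
})

test_that("GMT round trip preserves terms, names and universe", {
    ann <- TermAnnotation(list("KEGG:1" = c("a", "b"),
                               "REAC:2" = c("b", "c", "d")),
                          termNames = c("glycolysis", "beta oxidation"),
                          universe = letters[1:6])
    dir <- withr::local_tempdir()
    path <- file.path(dir, "sets.gmt")
    writeGmt(ann, path)
    back <- readGmt(path, universe = letters[1:6])
    expect_identical(annTerms(back), annTerms(ann))
    expect_identical(unname(annTermNames(back)),
                     c("glycolysis", "beta oxidation"))
    expect_error(readGmt(file.path(dir, "nope.gmt")), "not found")
    bad <- file.path(dir, "bad.gmt")
    writeLines("onlyid\tname", bad)
    expect_error(readGmt(bad), "malformed")
})
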