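test_that("groupMeanDelta subtracts baseline group means", {
    vals <- matrix(c(2, 4, 5, 7, 9,     # delta = 7 - 3 = 4
                     1, 1, 1, 1, 1,     # identical -> 0
                     0, 2, 3, 1, 2,     # 2 - 1 = 1
                     5, 3, 0, 4, 2,     # 2 - 4 = -2
                     8, 8, 9, 7, 8),    # 8 - 8 = 0
                   5, 5, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3", "g4", "g5"),
                                   c("a", "b", "c", "d", "e")))
    m <- makeExpr(vals, timepoint = c("T0", "T0", "T30", "T30", "T30"))
    d <- groupMeanDelta(m, baseline = "T0")
    expect_identical(unique(d$timepoint), "T30")  # baseline never a row
    expect_equal(d$delta_log2cpm[match(c("g1", "g2", "g3", "g4", "g5"),
                                       d$gene)],
                 c(4, 0, 1, -2, 0))
    expect_error(groupMeanDelta(m, baseline = "T0", timepoints = "T60"),
                 "T60.*no samples")
})

test_that("nullSummary gives mean and n-1 sd of housekeeping deltas", {
    d <- data.frame(gene = paste0("hk", 1:5), timepoint = "T30",
                    delta_log2cpm = c(0, 0.2, -0.2, 0.1, -0.1))
    nl <- nullSummary(d, paste0("hk", 1:5), "T30")
    expect_equal(nl$mu_hk, 0)
    expect_equal(nl$sigma_hk, sqrt(0.025), tolerance = 1e-12)
    expect_identical(nl$n_hk, 5L)
    dFlat <- transform(d, delta_log2cpm = 0.3)
    expect_error(nullSummary(dFlat, paste0("hk", 1:5), "T30"),
                 "degenerate")
    expect_error(nullSummary(d[1, ], "hk1", "T30"), ">= 2")
})

test_that("empiricalZ standardizes against the housekeeping null", {
    nl <- list(mu_hk = 0.05, sigma_hk = 0.2, n_hk = 13L)
    expect_equal(empiricalZ(0.05, nl), 0)
    expect_equal(empiricalZ(0.25, nl), 1)
    nl2 <- nullSummary(
        data.frame(gene = paste0("hk", 1:5), timepoint = "T30",
                   delta_log2cpm = c(0, 0.2, -0.2, 0.1, -0.1)),
        paste0("hk", 1:5), "T30")
    expect_equal(empiricalZ(1, nl2), 1 / sqrt(0.025), tolerance = 1e-9)
    expect_error(empiricalZ(1, list(mu_hk = 0, sigma_hk = 0)), "sigma")
})

test_that("twoTailedP is the two-sided normal tail, monotone in |z|", {
    expect_equal(twoTailedP(0), 1)
    expect_equal(twoTailedP(1.959964), 0.05, tolerance = 1e-5)
    expect_equal(twoTailedP(-1.959964), twoTailedP(1.959964))
    zs <- seq(0, 8, by = 0.25)
    expect_true(all(diff(twoTailedP(zs)) < 0))
    # |z| strictly increasing in |delta - mu| for a fixed null
    nl <- list(mu_hk = 0.1, sigma_hk = 0.3)
    deltas <- seq(0.1, 3, by = 0.1)
    expect_true(all(diff(abs(empiricalZ(deltas, nl))) > 0))
    expect_error(twoTailedP(Inf), "finite")
})

test_that("bhAdjust matches worked example and brute-force oracle", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
    expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
    set.seed(42)
    for (i in 1:250) {
        p <- runif(sample(1:50, 1))
        expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
    }
})

test_that("BH preserves p-value order and stays in (0, 1]", {
    set.seed(7)
    for (i in 1:20) {
        p <- runif(30)
        q <- bhAdjust(p)
        expect_true(all(q > 0 & q <= 1))
        expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
})

test_that("wilcoxonSignedRank: degenerate, all-positive, and tie handling", {
    w0 <- wilcoxonSignedRank(1:4, 1:4)
    expect_equal(w0$p, 1)
    expect_identical(w0$n_effective, 0L)
    expect_equal(w0$statistic, 0)

    w <- wilcoxonSignedRank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
    expect_equal(w$statistic, 15)
    expect_equal(w$p, 2 / 32)  # all 5 positive, distinct ranks

    # zeros are dropped: effective n shrinks
    wz <- wilcoxonSignedRank(c(5, 5, 7, 9), c(5, 5, 3, 4))
    expect_identical(wz$n_effective, 2L)
})

test_that("exact signed-rank p equals full 2^n enumeration for n <= 10", {
    set.seed(99)
    for (n in 1:10) {
        for (rep in 1:6) {
            x <- sample(seq(0.5, 6, by = 0.5), n, replace = TRUE)
            y <- sample(seq(0.5, 6, by = 0.5), n, replace = TRUE)
            got <- wilcoxonSignedRank(x, y)
            want <- wilcoxonEnumOracle(x, y)
            expect_equal(got$statistic, want$statistic,
                         info = sprintf("n=%d rep=%d", n, rep))
            expect_equal(got$p, want$p, tolerance = 1e-12,
                         info = sprintf("n=%d rep=%d", n, rep))
        }
    }
})

test_that("large-n normal approximation agrees with wilcox.test", {
    set.seed(5)
    x <- rnorm(40, 0.4); y <- rnorm(40)
    got <- wilcoxonSignedRank(x, y)
    expect_identical(got$method, "normal_approx")
    ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$statistic, unname(ref$statistic))
})

test_that("scoreCandidates composes the full responsiveness procedure", {
    set.seed(21)
    hk <- paste0("hk", 1:13)
    cands <- paste0("cand", 1:6)
    nSamp <- c(T0 = 4, T30 = 3, T60 = 5)
    tp <- rep(names(nSamp), nSamp)
    vals <- rbind(
        matrix(rnorm(13 * 12, mean = 8, sd = 0.1), 13, 12),
        matrix(rnorm(6 * 12, mean = 5, sd = 0.1), 6, 12))
    dimnames(vals) <- list(c(hk, cands), paste0("s", 1:12))
    # plant a strong shift in cand1 at T30 only
    vals["cand1", tp == "T30"] <- vals["cand1", tp == "T30"] + 5
    m <- makeExpr(vals, timepoint = tp)
    sc <- scoreCandidates(m, panel = hk, candidates = cands,
                          baseline = "T0")
    res <- sc$responsiveness
    expect_setequal(unique(res$timepoint), c("T30", "T60"))
    expect_true(res$responsive[res$gene == "cand1" &
                               res$timepoint == "T30"])
    expect_false(any(res$responsive[res$gene != "cand1"]))
    expect_true(all(res$responsive == (res$q < 0.05)))
    # null parameters exposed per timepoint
    expect_setequal(sc$nulls$timepoint, c("T30", "T60"))
    expect_true(all(sc$nulls$n_hk == 13))
    # candidates sit ~3 log2 units below the housekeeping mean: not elevated
    expect_true(all(!sc$baseline$elevated))
    expect_true(all(sc$baseline$median_diff < 0))
    expect_error(scoreCandidates(m, panel = hk, candidates = c("hk1", "x")),
                 "disjoint")
    expect_error(scoreCandidates(m, panel = hk, candidates = "ghost"),
                 "absent")
})

test_that("housekeeping self-standardization: z has mean 0, sd 1 exactly", {
    set.seed(31)
    hk <- paste0("hk", 1:13)
    vals <- matrix(rnorm(13 * 7, 8, 0.5), 13, 7,
                   dimnames = list(hk, paste0("s", 1:7)))
    m <- makeExpr(vals, timepoint = c(rep("T0", 4), rep("T30", 3)))
    d <- groupMeanDelta(m, baseline = "T0")
    nl <- nullSummary(d, hk, "T30")
    z <- empiricalZ(d$delta_log2cpm[d$timepoint == "T30"], nl)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("per-timepoint BH family adjusts within each timepoint", {
    set.seed(77)
    hk <- paste0("hk", 1:13)
    cands <- paste0("cand", 1:5)
    tp <- rep(c("T0", "T30", "T60"), c(4, 3, 5))
    vals <- matrix(rnorm(18 * 12, 7, 0.2), 18, 12,
                   dimnames = list(c(hk, cands), paste0("s", 1:12)))
    m <- makeExpr(vals, timepoint = tp)
    joint <- scoreCandidates(m, hk, cands, family = "joint")$responsiveness
    per <- scoreCandidates(m, hk, cands,
                           family = "per_timepoint")$responsiveness
    for (t in c("T30", "T60")) {
        i <- per$timepoint == t
        expect_equal(per$q[i], bhAdjust(per$p[i]))
    }
    expect_equal(joint$q, bhAdjust(joint$p))
})
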