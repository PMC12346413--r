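# Independent brute-force oracles; deliberately naive, never shared with
# the implementation paths they check.

# BH step-up by the literal definition: q_i = min over j with p_j >= p_i
# of p_j * n / rank_j, computed O(n^2) without sorting tricks.
bhOracle <- function(p) {
    n <- length(p)
    ord <- order(p)
    q <- numeric(n)
    for (i in seq_len(n)) {
        ri <- which(ord == i)  # rank of p[i]
        tails <- vapply(ri:n, function(j) p[ord[j]] * n / j, numeric(1))
        q[i] <- min(1, min(tails))
    }
    q
}

# Exact two-sided signed-rank p by literal enumeration of all 2^n sign
# assignments (midranks, zeros dropped beforehand by the caller's data).
wilcoxonEnumOracle <- function(x, y) {
    d <- (x - y)
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) return(list(statistic = 0, p = 1))
    rk <- rank(abs(d))
    W <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.numeric(signs %*% rk)
    pLe <- mean(Ws <= W + 1e-9)
    pGe <- mean(Ws >= W - 1e-9)
    list(statistic = W, p = min(1, 2 * min(pLe, pGe)))
}

# Hypergeometric upper tail from first principles (binomial coefficients).
hyperChooseOracle <- function(k, K, n, N) {
    js <- k:min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Full enumeration of every size-n draw from a size-N universe (tiny N).
hyperEnumOracle <- function(term, study, universe) {
    draws <- utils::combn(universe, length(study), simplify = FALSE)
    k <- length(intersect(term, study))
    mean(vapply(draws, function(d) length(intersect(term, d)) >= k,
                logical(1)))
}

# Paired t from the textbook formula, no shared code with pairedT().
pairedTOracle <- function(x, y) {
    d <- x - y
    n <- length(d)
    t <- mean(d) / sqrt(stats::var(d) / n)
    list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}
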