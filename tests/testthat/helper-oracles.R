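# Independent brute-force oracles. Every oracle works from first principles
# (pair enumeration, explicit loops, dense arithmetic) and never calls the
# package's own computational path.

# Pair-counting statistics by explicit enumeration of all C(n,2) object
# pairs. u, z: group vectors over the same cells.
oraclePairCounting <- function(u, z) {
    u <- as.character(u); z <- as.character(z)
    n <- length(u)
    N <- n * (n - 1) / 2
    sameU <- outer(u, u, "==")
    sameZ <- outer(z, z, "==")
    up <- upper.tri(sameU)
    a <- sum(sameU & sameZ & up)     # pairs joined in both
    su <- sum(sameU & up)            # pairs joined in U  (P)
    sz <- sum(sameZ & up)            # pairs joined in Z  (Q)
    adjust <- function(S, ES) if (is.nan(S) || ES == 1) NA_real_ else (S - ES) / (1 - ES)
    AW <- if (su == 0) NA_real_ else adjust(a / su, sz / N)
    AV <- if (sz == 0) NA_real_ else adjust(a / sz, su / N)
    AWi <- vapply(sort(unique(u)), function(cl) {
        sel <- sameU & up & outer(u == cl, u == cl)
        pairsIn <- sum(sel)
        if (pairsIn == 0) return(NA_real_)
        adjust(sum(sel & sameZ) / pairsIn, sz / N)
    }, numeric(1))
    AVj <- vapply(sort(unique(z)), function(cl) {
        sel <- sameZ & up & outer(z == cl, z == cl)
        pairsIn <- sum(sel)
        if (pairsIn == 0) return(NA_real_)
        adjust(sum(sel & sameU) / pairsIn, su / N)
    }, numeric(1))
    den <- (su + sz) / 2 - su * sz / N
    ARI <- if (den == 0) NA_real_ else (a - su * sz / N) / den
    AWp <- mean(AWi, na.rm = TRUE)
    AVp <- mean(AVj, na.rm = TRUE)
    ARI2 <- if (AWp + AVp == 0) NA_real_ else 2 * AWp * AVp / (AWp + AVp)
    list(AW = AW, AV = AV, AWi = AWi, AVj = AVj, ARI = ARI, ARI2 = ARI2)
}

# Silhouette widths by direct per-cell loops over a dense distance matrix.
oracleSilhouette <- function(co, g) {
    g <- as.character(g)
    D <- as.matrix(dist(co))
    n <- nrow(co)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- which(g == g[i])
        if (length(own) == 1L) { s[i] <- 0; next }
        a <- mean(D[i, setdiff(own, i)])
        b <- min(vapply(setdiff(unique(g), g[i]), function(cl)
            mean(D[i, g == cl]), numeric(1)))
        s[i] <- (b - a) / max(a, b)
    }
    s
}

# Per-class proportion of weakly connected cells by explicit degree loops.
oraclePwc <- function(A, g, weighted = FALSE) {
    A <- as.matrix(A)
    if (!weighted) A <- (A > 0) * 1
    g <- as.character(g)
    classes <- sort(unique(g))
    vapply(classes, function(cl) {
        members <- which(g == cl)
        weak <- vapply(members, function(i) {
            kin <- sum(A[i, g == cl])
            kout <- sum(A[i, g != cl])
            kin < kout
        }, logical(1))
        mean(weak)
    }, numeric(1))
}

# Exhaustive kNN lists with ties broken by ascending index.
oracleKnn <- function(co, k) {
    n <- nrow(co)
    m <- vapply(seq_len(n), function(i) {
        d <- sqrt(colSums((t(co) - co[i, ])^2))
        d[i] <- Inf
        order(d, seq_len(n))[seq_len(k)]
    }, integer(k))
    if (k == 1) matrix(m, ncol = 1) else t(m)
}

# Geary's C from dense double sums.
oracleGeary <- function(A, x) {
    A <- as.matrix(A)
    n <- length(x)
    num <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
        num <- num + A[i, j] * (x[i] - x[j])^2
    (n - 1) * num / (2 * sum(A) * sum((x - mean(x))^2))
}

# Small random labelled embedding for property-style loops.
randomInstance <- function(n, K, d = 3, seed = 1) {
    set.seed(seed)
    ids <- sprintf("c%03d", seq_len(n))
    co <- matrix(rnorm(n * d), n, d, dimnames = list(ids, NULL))
    list(embedding = EmbeddingMatrix(co),
         labels = LabelVector(ids, sample(paste0("k", seq_len(K)), n,
                                          replace = TRUE)))
}
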