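test_that("a depth-driven dimension is flagged with correlation 1", {
    set.seed(14)
    n <- 300
    ids <- sprintf("c%03d", 1:n)
    counts <- round(rlnorm(n, log(5000), 0.6))
    co <- cbind(sqrt(counts), matrix(rnorm(n * 3), n, 3))
    rownames(co) <- ids
    emb <- EmbeddingMatrix(co)
    lv <- LabelVector(ids, rep(c("A", "B", "C"), each = 100))
    ls <- LibrarySizeVector(ids, counts)
    res <- librarySizeCorrelation(emb, lv, ls, dims = 4)
    expect_equal(unname(res$perDimension[1]), 1, tolerance = 1e-12)
    expect_lt(max(res$perDimension[-1]), 0.3)
    expect_equal(res$summary, mean(res$perDimension[1:4]))
})

test_that("opposite-sign within-class correlations average by magnitude", {
    set.seed(15)
    n <- 400
    ids <- sprintf("c%03d", 1:n)
    counts <- round(rlnorm(n, log(5000), 0.5))
    s <- sqrt(counts)
    cls <- rep(c("A", "B"), each = 200)
    rho <- 0.8
    mk <- function(sel, sign) {
        z <- scale(s[sel])[, 1]
        sign * (rho * z + sqrt(1 - rho^2) * rnorm(sum(sel)))
    }
    dim1 <- numeric(n)
    dim1[cls == "A"] <- mk(cls == "A", +1)
    dim1[cls == "B"] <- mk(cls == "B", -1)
    emb <- EmbeddingMatrix(cbind(dim1, rnorm(n)), cellIds = ids)
    res <- librarySizeCorrelation(emb, LabelVector(ids, cls),
                                  LibrarySizeVector(ids, counts))
    expect_equal(unname(res$perDimension[1]), 0.8, tolerance = 0.07)
})

test_that("bias correlation is invariant to affine rescaling", {
    sim <- simulateEmbedding(simConfig(nCells = 200, biasLoading = 0.5,
                                       seed = 4))
    r1 <- librarySizeCorrelation(sim$embedding, sim$labels, sim$libsize)
    co <- sweep(coords(sim$embedding), 2,
                runif(ncol(coords(sim$embedding)), 0.5, 3), "*") + 11
    r2 <- librarySizeCorrelation(EmbeddingMatrix(co), sim$labels,
                                 sim$libsize)
    expect_equal(r1$perDimension, r2$perDimension, tolerance = 1e-10)
    ls2 <- LibrarySizeVector(cellIds(sim$libsize), libSizes(sim$libsize) * 4)
    r3 <- librarySizeCorrelation(sim$embedding, sim$labels, ls2)
    expect_equal(r1$perDimension, r3$perDimension, tolerance = 1e-10)
})

test_that("component filtering removes depth components at the 0.75 rule", {
    set.seed(16)
    n <- 250
    ids <- sprintf("c%03d", 1:n)
    counts <- round(rlnorm(n, log(8000), 0.5))
    co <- cbind(counts + rnorm(n, sd = 1), matrix(rnorm(n * 4), n, 4))
    emb <- EmbeddingMatrix(co, cellIds = ids)
    ls <- LibrarySizeVector(ids, counts)
    res <- componentFilter(emb, ls)
    expect_equal(res$removed, 1L)
    expect_equal(res$kept, 2:5)

    # orthogonal random components: all kept
    emb0 <- EmbeddingMatrix(matrix(rnorm(n * 5), n, 5), cellIds = ids)
    expect_length(componentFilter(emb0, ls)$removed, 0)

    # threshold 1 removes nothing short of exact collinearity
    expect_length(componentFilter(emb, ls, threshold = 1)$removed, 0)
    expect_error(componentFilter(emb, ls, threshold = 1.5), "threshold")

    # everything removed is an error
    emb1 <- EmbeddingMatrix(cbind(counts, 2 * counts), cellIds = ids)
    expect_error(componentFilter(emb1, ls), "no informative components")
})

test_that("Geary's C matches the dense-sum oracle and its anchors", {
    # path graph 1-2-3, x = (0,1,2): standard statistic gives 0.5
    A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
    g <- NeighborGraph(Matrix::Matrix(A, sparse = TRUE), kind = "knn",
                       cellIds = c("a", "b", "c"))
    expect_equal(gearysC(g, c(0, 1, 2)), 0.5)
    expect_equal(gearysC(g, c(0, 1, 2)), oracleGeary(A, c(0, 1, 2)))

    # smooth signal on separate components: numerator 0
    A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
    g <- NeighborGraph(Matrix::Matrix(A, sparse = TRUE), kind = "knn",
                       cellIds = letters[1:4])
    expect_equal(gearysC(g, c(5, 5, -2, -2)), 0)

    # random weighted graphs against the oracle
    set.seed(17)
    for (rep in 1:5) {
        n <- 25
        A <- matrix(0, n, n)
        A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.2) * runif(n * (n - 1) / 2)
        A <- A + t(A)
        x <- rnorm(n)
        g <- NeighborGraph(Matrix::Matrix(A, sparse = TRUE), kind = "knn",
                           cellIds = sprintf("c%02d", 1:n))
        expect_equal(gearysC(g, x), oracleGeary(A, x), tolerance = 1e-12)
    }

    expect_error(gearysC(g, rep(2, 25)), "zero variance")
})

test_that("Geary's C is near 1 for i.i.d. values on a kNN graph", {
    sim <- simulateEmbedding(simConfig(nCells = 600, seed = 18))
    g <- buildKnn(sim$embedding, k = 20)
    set.seed(18)
    x <- rnorm(600)
    expect_lt(abs(gearysC(g, x) - 1), 0.05)
})

test_that("Geary's C is invariant to affine x and uniform weight scaling", {
    set.seed(19)
    n <- 40
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.2)
    A <- A + t(A)
    x <- rnorm(n)
    g1 <- NeighborGraph(Matrix::Matrix(A, sparse = TRUE), kind = "knn",
                        cellIds = sprintf("c%02d", 1:n))
    g2 <- NeighborGraph(Matrix::Matrix(A * 3.7, sparse = TRUE), kind = "knn",
                        cellIds = sprintf("c%02d", 1:n))
    base <- gearysC(g1, x)
    expect_equal(gearysC(g1, 5 - 2 * x), base, tolerance = 1e-12)
    expect_equal(gearysC(g2, x), base, tolerance = 1e-12)
    expect_gte(base, 0)
})
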