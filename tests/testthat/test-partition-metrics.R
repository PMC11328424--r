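.pp <- function(u, z) {
    ids <- sprintf("c%03d", seq_along(u))
    list(labels = LabelVector(ids, u), partition = Partition(ids, z))
}

test_that("contingency tables carry exact pair counts", {
    p <- .pp(c("A", "A", "B", "B"), c(1, 1, 2, 2))
    ct <- contingencyTable(p$labels, p$partition)
    pc <- pairCounts(ct)
    expect_equal(unname(ct@table), matrix(c(2, 0, 0, 2), 2, 2))
    expect_equal(pc$N, 6)
    expect_equal(pc$P, 2)
    expect_equal(pc$Q, 2)

    p <- .pp(c("A", "A", "B", "B"), c(1, 2, 1, 2))
    pc <- pairCounts(contingencyTable(p$labels, p$partition))
    expect_equal(pc$sumCij, 0)

    # one cluster: Q = N
    p <- .pp(c("A", "A", "B"), c(1, 1, 1))
    pc <- pairCounts(contingencyTable(p$labels, p$partition))
    expect_equal(pc$Q, pc$N)
})

test_that("adjusted Wallace indices hit their closed-form anchors", {
    # identical partitions: everything 1
    p <- .pp(rep(c("A", "B", "C"), c(5, 4, 3)), rep(1:3, c(5, 4, 3)))
    w <- wallaceAdjusted(contingencyTable(p$labels, p$partition))
    expect_equal(w$AW, 1)
    expect_equal(w$AV, 1)
    expect_equal(unname(w$AWi), rep(1, 3))
    expect_equal(unname(w$AVj), rep(1, 3))

    # crossed 2x2 design: AW = AV = -0.5
    p <- .pp(c("A", "A", "B", "B"), c(1, 2, 1, 2))
    ct <- contingencyTable(p$labels, p$partition)
    w <- wallaceAdjusted(ct)
    expect_equal(w$AW, -0.5)
    expect_equal(w$AV, -0.5)
    expect_equal(ari(ct)$ARI, -0.5)
    expect_equal(suppressWarnings(ari2(ct))$ARI2, -0.5)

    # trivial single cluster: AW undefined (flagged NA, no error)
    p <- .pp(c("A", "A", "B", "B"), rep(1, 4))
    w <- wallaceAdjusted(contingencyTable(p$labels, p$partition))
    expect_true(is.na(w$AW))
    expect_false(is.na(w$AV))
})

test_that("chance level is zero for independent random partitions", {
    set.seed(7)
    aws <- replicate(300, {
        u <- sample(3, 100, replace = TRUE)
        z <- sample(4, 100, replace = TRUE)
        p <- .pp(u, z)
        wallaceAdjusted(contingencyTable(p$labels, p$partition))$AW
    })
    expect_lt(abs(mean(aws)), 0.02)
})

test_that("ARI routes agree with each other and with pair enumeration", {
    # anchor frozen from explicit enumeration of the 6 object pairs:
    # 1 pair joined in both, 3 joined in U, 2 in Z -> (1 - 1)/(2.5 - 1) = 0
    p <- .pp(c("A", "A", "A", "B"), c(1, 1, 2, 2))
    a <- ari(contingencyTable(p$labels, p$partition))
    expect_equal(a$ARI, oraclePairCounting(c("A", "A", "A", "B"),
                                           c(1, 1, 2, 2))$ARI)
    expect_equal(a$ARI, 0)

    set.seed(123)
    for (rep in 1:40) {
        n <- sample(10:100, 1)
        u <- sample(sample(2:5, 1), n, replace = TRUE)
        z <- sample(sample(2:5, 1), n, replace = TRUE)
        p <- .pp(paste0("u", u), paste0("z", z))
        a <- ari(contingencyTable(p$labels, p$partition))
        if (!is.na(a$harmonic)) {
            expect_equal(a$harmonic, a$ARI, tolerance = 1e-12)
            expect_equal(a$decomposed, a$ARI, tolerance = 1e-12)
        }
    }
})

test_that("ARI2 upweights errors in rare classes", {
    # large classes recovered perfectly, one rare class over-clustered into
    # two shards: the weighted ARI barely notices, the unweighted ARI2 does
    u <- rep(c("A", "B", "C", "D"), c(40, 40, 10, 10))
    z <- c(rep(c("A", "B", "C"), c(40, 40, 10)), rep(c("D1", "D2"), each = 5))
    p <- .pp(u, z)
    ct <- contingencyTable(p$labels, p$partition)
    a <- ari(ct)$ARI
    a2 <- ari2(ct)$ARI2
    expect_lt(a2, a)
    expect_gt(a, 0.95)   # the weighted index stays near perfect

    # symmetric case keeps ARI2 = ARI
    p <- .pp(c("A", "A", "B", "B"), c(1, 2, 1, 2))
    ct <- contingencyTable(p$labels, p$partition)
    expect_equal(suppressWarnings(ari2(ct))$ARI2, -0.5)

    # singleton classes are excluded with a warning
    p <- .pp(c("A", "A", "B"), c(1, 1, 2))
    expect_warning(ari2(contingencyTable(p$labels, p$partition)),
                   "singleton")
})

test_that("MI and VI satisfy their entropy identities", {
    # identical balanced 2-class partitions
    p <- .pp(rep(c("A", "B"), each = 5), rep(1:2, each = 5))
    mv <- miVi(contingencyTable(p$labels, p$partition))
    expect_equal(mv$MI, log(2), tolerance = 1e-12)
    expect_equal(mv$VI, 0, tolerance = 1e-12)

    # crossed (product-table) partitions: MI = 0, VI = H(U) + H(Z)
    p <- .pp(rep(c("A", "B"), each = 4), rep(rep(1:2, each = 2), 2))
    mv <- miVi(contingencyTable(p$labels, p$partition))
    expect_equal(mv$MI, 0, tolerance = 1e-12)
    expect_equal(mv$VI, mv$HU + mv$HZ, tolerance = 1e-12)

    # random partitions: identities Eq routes, symmetry, bounds
    set.seed(5)
    for (rep in 1:25) {
        n <- sample(8:60, 1)
        u <- paste0("u", sample(3, n, replace = TRUE))
        z <- paste0("z", sample(4, n, replace = TRUE))
        p <- .pp(u, z)
        ct <- contingencyTable(p$labels, p$partition)
        mv <- miVi(ct)
        expect_equal(mv$MI, mv$HZ - mv$HZgivenU, tolerance = 1e-12)
        expect_equal(mv$VI, mv$HU + mv$HZ - 2 * mv$MI, tolerance = 1e-12)
        expect_gte(mv$MI, -1e-12)
        expect_gte(mv$VI, -1e-12)
        expect_lte(mv$MI, min(mv$HU, mv$HZ) + 1e-12)
        # symmetry under swapping U and Z
        q <- .pp(z, u)
        mv2 <- miVi(contingencyTable(q$labels, q$partition))
        expect_equal(mv2$MI, mv$MI, tolerance = 1e-12)
        expect_equal(mv2$VI, mv$VI, tolerance = 1e-12)
        w <- wallaceAdjusted(ct)
        w2 <- wallaceAdjusted(contingencyTable(q$labels, q$partition))
        expect_equal(w2$AW, w$AV, tolerance = 1e-12)
        expect_equal(w2$AV, w$AW, tolerance = 1e-12)
    }
})

test_that("evenness spans [1/K, 1] with its closed-form anchors", {
    ids <- sprintf("c%03d", 1:8)
    expect_equal(evenness(LabelVector(ids, rep(c("A", "B"), each = 4))), 1)
    expect_equal(evenness(LabelVector(ids, rep("A", 8))), 1)  # K = 1
    expect_equal(evenness(LabelVector(ids, rep(c("A", "B"), c(6, 2)))),
                 exp(-(0.75 * log(0.75) + 0.25 * log(0.25))) / 2,
                 tolerance = 1e-12)
    set.seed(31)
    for (rep in 1:30) {
        n <- sample(5:50, 1)
        K <- sample(1:5, 1)
        lv <- LabelVector(sprintf("c%03d", 1:n),
                          sample(paste0("k", 1:K), n, replace = TRUE))
        E <- evenness(lv)
        expect_gte(E, 1 / nGroups(lv) - 1e-12)
        expect_lte(E, 1 + 1e-12)
    }
})

test_that("partitionScores bundles all metrics consistently", {
    p <- .pp(rep(c("A", "B", "C"), c(5, 4, 3)), rep(1:3, c(5, 4, 3)))
    ps <- partitionScores(p$labels, p$partition)
    expect_equal(unname(ps$scores[c("AW", "AV", "ARI", "ARI2")]),
                 rep(1, 4))
    expect_equal(unname(ps$scores["VI"]), 0, tolerance = 1e-12)
    expect_equal(names(ps$AWi), c("A", "B", "C"))
})
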