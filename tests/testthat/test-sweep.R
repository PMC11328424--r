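.makeGrid <- function(labels, partitionList) {
    runSweep(labels, partitions = partitionList)
}

.toyLabels <- function(n = 60, K = 3, seed = 1) {
    set.seed(seed)
    LabelVector(sprintf("c%03d", 1:n),
                sample(paste0("k", 1:K), n, replace = TRUE))
}

test_that("runSweep scores every supplied partition", {
    lv <- .toyLabels()
    parts <- list()
    for (r in c(0.5, 1.0)) for (s in c(0, 42)) {
        parts[[length(parts) + 1]] <- list(
            resolution = r, seed = s,
            partition = perturbPartition(lv, "relabel", fraction = r / 2,
                                         seed = s + r * 100))
    }
    grid <- .makeGrid(lv, parts)
    expect_length(grid@entries, 4)
    expect_true(all(vapply(grid@entries, function(e)
        all(c("ari", "vi") %in% names(e$metrics)), logical(1))))

    # a partition identical to the labels scores ARI 1
    parts[[5]] <- list(resolution = 2, seed = 0,
                       partition = Partition(cellIds(lv), groups(lv)))
    grid <- .makeGrid(lv, parts)
    expect_equal(grid@entries[[5]]$metrics[["ari"]], 1)

    expect_error(runSweep(lv, partitions = list()), "no partitions")
})

test_that("a failing clustering callback is recorded, not fatal", {
    lv <- .toyLabels()
    fun <- function(r, s) {
        if (r > 1) stop("resolution too high")
        perturbPartition(lv, "relabel", fraction = 0.2, seed = s)
    }
    grid <- runSweep(lv, resolutions = c(0.5, 1.5), seeds = c(0, 2),
                     clusterFun = fun)
    expect_length(grid@entries, 2)
    expect_length(grid@failures, 2)
    expect_match(grid@failures[[1]]$message, "too high")
})

test_that("normalized AUC reproduces rectangle and triangle areas", {
    lv <- .toyLabels(n = 40, K = 2)
    mkPart <- function(J, seed) perturbPartition(
        lv, "split", class = "k1", parts = J, seed = seed)
    # constant metric 0.5 across cluster numbers -> AUC = 0.5 exactly
    parts <- lapply(1:5, function(j)
        list(resolution = j / 10, seed = 0, partition = mkPart(j + 1, j)))
    grid <- .makeGrid(lv, parts)
    for (e in seq_along(grid@entries))
        grid@entries[[e]]$metrics["ari"] <- 0.5
    res <- aucCurve(grid, "ari")
    expect_equal(res$auc, 0.5, tolerance = 1e-12)

    # linear 0 -> 1 over the range -> trapezoid gives 0.5
    ks <- vapply(grid@entries, function(e) e$nClusters, numeric(1))
    for (e in seq_along(grid@entries))
        grid@entries[[e]]$metrics["ari"] <-
            (ks[e] - min(ks)) / (max(ks) - min(ks))
    expect_equal(aucCurve(grid, "ari")$auc, 0.5, tolerance = 1e-12)

    # VI at its empirical max everywhere -> score 1 - 1 = 0
    for (e in seq_along(grid@entries))
        grid@entries[[e]]$metrics["vi"] <- 2.7
    expect_equal(aucCurve(grid, "vi")$auc, 0, tolerance = 1e-12)

    # degenerate range errors
    one <- .makeGrid(lv, list(
        list(resolution = 0.1, seed = 0, partition = mkPart(2, 1)),
        list(resolution = 0.2, seed = 0, partition = mkPart(2, 2))))
    expect_error(aucCurve(one, "ari"), "degenerate")
})

test_that("duplicating an entry does not move the AUC", {
    lv <- .toyLabels(n = 50, K = 3)
    parts <- lapply(1:4, function(j)
        list(resolution = j / 10, seed = 0,
             partition = perturbPartition(lv, "split", class = "k1",
                                          parts = j + 1, seed = j)))
    grid <- .makeGrid(lv, parts)
    base <- aucCurve(grid, "ari")$auc
    grid2 <- .makeGrid(lv, c(parts, parts[2]))
    expect_equal(aucCurve(grid2, "ari")$auc, base, tolerance = 1e-12)
})

test_that("heatmap transform centers columns and scales by the matrix MAD", {
    B <- heatmapTransform(matrix(c(1, 2, 3), 3, 1))
    expect_equal(as.vector(B), c(-1, 0, 1))

    expect_warning(B0 <- heatmapTransform(matrix(5, 3, 2)), "degenerate")
    expect_equal(as.vector(B0), rep(0, 6))

    set.seed(8)
    A <- matrix(rnorm(30), 6, 5)
    B <- heatmapTransform(A)
    expect_equal(apply(B, 2, median), rep(0, 5), tolerance = 1e-9)
    # invariant to adding a constant to one column
    A2 <- A; A2[, 3] <- A2[, 3] + 17
    expect_equal(heatmapTransform(A2), B, tolerance = 1e-12)
})

test_that("stability measures seed disagreement via pairwise ARI", {
    lv <- .toyLabels(n = 50, K = 3)
    ident <- function(seed) Partition(cellIds(lv), groups(lv))
    parts <- list()
    for (r in c(0.5, 1)) for (s in 1:3)
        parts[[length(parts) + 1]] <-
            list(resolution = r, seed = s, partition = ident(s))
    grid <- .makeGrid(lv, parts)
    st <- stability(grid)
    expect_equal(st$overall, 0)
    expect_equal(unname(st$perResolution), c(0, 0))

    # independent random partitions: deviation near 1
    set.seed(9)
    parts <- list()
    for (s in 1:4)
        parts[[length(parts) + 1]] <- list(
            resolution = 1, seed = s,
            partition = Partition(cellIds(lv),
                                  sample(4, 50, replace = TRUE)))
    st <- stability(.makeGrid(lv, parts))
    expect_lt(abs(st$overall - 1), 0.15)

    # two identical + one independent: mean of the 3 pairs
    p1 <- ident(1)
    pr <- Partition(cellIds(lv), sample(4, 50, replace = TRUE))
    grid <- .makeGrid(lv, list(
        list(resolution = 1, seed = 1, partition = p1),
        list(resolution = 1, seed = 2, partition = p1),
        list(resolution = 1, seed = 3, partition = pr)))
    st <- stability(grid)
    ctd <- contingencyTable(LabelVector(cellIds(p1), groups(p1)), pr)
    d <- 1 - ari(ctd)$ARI
    expect_equal(st$overall, (0 + d + d) / 3, tolerance = 1e-12)

    # single seed per resolution: undefined, excluded
    grid <- .makeGrid(lv, list(
        list(resolution = 0.5, seed = 1, partition = p1),
        list(resolution = 1, seed = 1, partition = p1),
        list(resolution = 1, seed = 2, partition = pr)))
    st <- stability(grid)
    expect_true(is.na(st$perResolution[["0.5"]]))
    expect_false(is.na(st$overall))
})
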