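.sweepMetricFuns <- function(metrics) {
    known <- c("ari", "ari2", "aw", "av", "mi", "vi")
    bad <- setdiff(metrics, known)
    if (length(bad))
        stop(sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")))
    metrics
}

.scorePartition <- function(labels, partition, metrics) {
    ct <- contingencyTable(labels, partition)
    w <- wallaceAdjusted(ct)
    vals <- c(ari = ari(ct)$ARI,
              ari2 = suppressWarnings(ari2(ct))$ARI2,
              aw = w$AW, av = w$AV,
              mi = miVi(ct)$MI, vi = miVi(ct)$VI)
    vals[metrics]
}

#' Score a grid of clustering solutions against one ground truth
#'
#' Partitions are supplied either precomputed (as a list with per-entry
#' resolution and seed) or generated on the fly through a pluggable
#' clustering callback — typically a Leiden run over an SNN graph; the
#' package deliberately embeds no community-detection algorithm. A callback
#' that raises is recorded as a failure and its entry skipped.
#'
#' @param labels the ground-truth \linkS4class{LabelVector}.
#' @param partitions list of entries, each a list with \code{resolution},
#'   \code{seed} and \code{partition} (a \linkS4class{Partition} aligned to
#'   \code{labels}); or \code{NULL} when using \code{clusterFun}.
#' @param resolutions,seeds numeric grids for the callback route. The
#'   default seeds (0, 2, 5, 42, 123) and resolution grid 0.1–2.0 in steps
#'   of 0.1 match common sweep practice; both should be adapted per dataset.
#' @param clusterFun \code{function(resolution, seed) -> Partition}.
#' @param metrics metric names among \code{ari}, \code{ari2}, \code{aw},
#'   \code{av}, \code{mi}, \code{vi}.
#' @return a \linkS4class{SweepGrid}.
#' @export
runSweep <- function(labels, partitions = NULL,
                     resolutions = seq(0.1, 2.0, by = 0.1),
                     seeds = c(0, 2, 5, 42, 123),
                     clusterFun = NULL,
                     metrics = c("ari", "ari2", "aw", "av", "mi", "vi")) {
    metrics <- .sweepMetricFuns(metrics)
    failures <- list()
    if (is.null(partitions)) {
        if (is.null(clusterFun))
            stop("supply either `partitions` or `clusterFun`")
        partitions <- list()
        for (r in resolutions) for (s in seeds) {
            p <- tryCatch(clusterFun(r, s), error = function(e) e)
            if (inherits(p, "error")) {
                failures[[length(failures) + 1L]] <-
                    list(resolution = r, seed = s,
                         message = conditionMessage(p))
            } else {
                partitions[[length(partitions) + 1L]] <-
                    list(resolution = r, seed = s, partition = p)
            }
        }
    }
    if (!length(partitions)) stop("no partitions to score")
    entries <- lapply(partitions, function(e) {
        stopifnot(all(c("resolution", "seed", "partition") %in% names(e)))
        list(resolution = e$resolution, seed = e$seed,
             partition = e$partition,
             nClusters = nGroups(e$partition),
             metrics = .scorePartition(labels, e$partition, metrics))
    })
    new("SweepGrid", entries = entries, labels = labels, failures = failures)
}

#' Metric-versus-cluster-number curve and its normalized AUC
#'
#' Metric values are averaged at each observed cluster number; the area
#' under that mean curve over the observed cluster-number range is computed
#' by the trapezoidal rule and normalized by (upper bound of the metric) x
#' (range width). ARI, ARI2, AW and AV have upper bound 1; MI and VI use
#' their empirical maximum over the sweep. VI being a "smaller is better"
#' distance, its reported score is 1 minus the normalized AUC.
#'
#' @param grid a \linkS4class{SweepGrid}.
#' @param metric one metric name present in the grid entries.
#' @param upperBound a positive number, or \code{"empirical"} for the
#'   maximum value observed in the sweep; defaults to 1 for
#'   ari/ari2/aw/av and \code{"empirical"} for mi/vi.
#' @return a list with \code{curve} (data.frame: \code{nClusters},
#'   \code{mean}) and \code{auc} (the normalized area, inverted for VI).
#' @export
aucCurve <- function(grid, metric, upperBound = NULL) {
    vals <- vapply(grid@entries, function(e) e$metrics[[metric]], numeric(1))
    ks <- vapply(grid@entries, function(e) e$nClusters, numeric(1))
    if (is.null(upperBound))
        upperBound <- if (metric %in% c("mi", "vi")) "empirical" else 1
    keep <- !is.na(vals)
    vals <- vals[keep]; ks <- ks[keep]
    if (length(unique(ks)) < 2L)
        stop("degenerate range: need >= 2 distinct cluster numbers")
    curve <- vapply(split(vals, ks), mean, numeric(1))
    kk <- as.numeric(names(curve))
    o <- order(kk)
    kk <- kk[o]; curve <- curve[o]
    if (identical(upperBound, "empirical")) upperBound <- max(vals)
    if (!is.numeric(upperBound) || upperBound <= 0)
        stop("upper bound must be positive")
    area <- sum(diff(kk) * (utils::head(curve, -1) + utils::tail(curve, -1)) / 2)
    auc <- area / (upperBound * (max(kk) - min(kk)))
    if (metric == "vi") auc <- 1 - auc
    list(curve = data.frame(nClusters = kk, mean = unname(curve)), auc = auc)
}

#' Robust heatmap transform of an AUC matrix
#'
#' Centers each column (metric) of a methods-by-metrics AUC matrix at its
#' median and scales all deviations by the single matrix-wise median
#' absolute deviation: \eqn{B_{ij} = (A_{ij} - \mathrm{median}(A_{+j})) /
#' \mathrm{median}(|M|)} with \eqn{M} the column-centered matrix. The
#' resulting scores share one scale across datasets and are robust to
#' outliers. A constant matrix (zero scale) maps to the zero matrix with a
#' warning.
#'
#' @param A numeric matrix, methods in rows, metrics in columns.
#' @return the transformed matrix B, same shape; column medians of B are 0.
#' @export
heatmapTransform <- function(A) {
    A <- as.matrix(A)
    if (nrow(A) < 2L) stop("need >= 2 rows")
    if (any(!is.finite(A))) stop("A must be finite")
    M <- sweep(A, 2L, apply(A, 2L, stats::median))
    s <- stats::median(abs(M))
    if (s == 0) {
        warning("degenerate scale (median absolute deviation 0); returning zeros")
        return(M * 0)
    }
    M / s
}

#' Seed stability of a clustering sweep
#'
#' For each resolution, every pair of seeds is compared by the ARI between
#' the two predicted partitions (ground truth plays no role); the deviation
#' of that ARI from 1 measures instability (0 = identical solutions up to
#' relabeling, about 1 = unrelated solutions). Deviations are averaged over
#' seed pairs within each resolution, then over resolutions. Resolutions
#' with a single seed are undefined and excluded from the overall mean.
#'
#' @param grid a \linkS4class{SweepGrid}.
#' @return a list with \code{perResolution} (named numeric) and
#'   \code{overall}.
#' @export
stability <- function(grid) {
    res <- vapply(grid@entries, function(e) e$resolution, numeric(1))
    byRes <- split(grid@entries, res)
    perRes <- vapply(byRes, function(entries) {
        if (length(entries) < 2L) return(NA_real_)
        devs <- c()
        for (a in seq_along(entries)[-length(entries)])
            for (b in seq(a + 1L, length(entries))) {
                pa <- entries[[a]]$partition
                pb <- entries[[b]]$partition
                ct <- contingencyTable(
                    LabelVector(cellIds(pa), groups(pa)), pb)
                devs <- c(devs, 1 - ari(ct)$ARI)
            }
        mean(devs)
    }, numeric(1))
    list(perResolution = perRes, overall = .meanDefined(perRes))
}
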