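#' Silhouette widths, ASW and FNS per class
#'
#' For each cell, the silhouette width
#' \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))} compares the mean distance
#' to the cell's own class (\eqn{a}) with the smallest mean distance to any
#' other class (\eqn{b}); cells in singleton classes get \eqn{s = 0} by the
#' usual convention. The average silhouette width (ASW) summarizes
#' compactness and separation in [-1, 1]. Because ASW is not invariant to
#' rescaling of the space, the fraction of negative silhouettes (FNS) — the
#' per-class proportion of cells with \eqn{s(i) < 0} — is reported alongside
#' it; FNS depends only on the sign of \eqn{s(i)} and is therefore robust to
#' positive linear scaling. Class-level values are aggregated as unweighted
#' means over classes.
#'
#' @param embedding an \linkS4class{EmbeddingMatrix}.
#' @param labels a \linkS4class{LabelVector} aligned to the embedding
#'   (>= 2 classes).
#' @param metric distance metric; Euclidean only (apply cosine by
#'   row-normalizing the embedding first).
#' @return a list with \code{perCell} (named numeric in [-1, 1]),
#'   \code{aswPerClass}, \code{fnsPerClass}, \code{aswMean}, \code{fnsMean}.
#' @examples
#' sim <- simulateEmbedding(simConfig(nCells = 120, separation = 12, seed = 1))
#' sil <- silhouetteMetrics(sim$embedding, sim$labels)
#' sil$aswMean
#' @export
silhouetteMetrics <- function(embedding, labels, metric = "euclidean") {
    metric <- match.arg(metric, "euclidean")
    .checkAligned(embedding, labels)
    g <- groups(labels)
    if (nlevels(g) < 2L)
        stop("silhouette undefined for a single class")
    d <- stats::dist(coords(embedding))
    sil <- cluster::silhouette(as.integer(g), dist = d)
    s <- sil[, "sil_width"]
    names(s) <- cellIds(embedding)
    aswPerClass <- vapply(split(s, g), mean, numeric(1))
    fnsPerClass <- vapply(split(s, g), function(v) mean(v < 0), numeric(1))
    list(perCell = s,
         aswPerClass = aswPerClass,
         fnsPerClass = fnsPerClass,
         aswMean = mean(aswPerClass),
         fnsMean = mean(fnsPerClass))
}

#' Cluster-level Local Inverse Simpson Index (cLISI)
#'
#' For each cell, kernel weights \eqn{w_j \propto \exp(-\beta d_j)} over its
#' k nearest neighbors are calibrated by bisection on the precision
#' \eqn{\beta} so that the weight distribution's entropy equals
#' \eqn{\log(\mathrm{perplexity})} (the convention of the reference LISI
#' implementation, which applies the kernel to raw neighbor distances);
#' class probabilities are the summed weights per class, and the cell's
#' score is the inverse Simpson index \eqn{1 / \sum_c p(c)^2}. The score is
#' the effective number of classes in the cell's neighborhood: 1 means a
#' pure neighborhood, K means complete mixing of all K classes. Note that
#' the kernel's effective sample is bounded by the perplexity, so even under
#' complete mixing the expected value sits somewhat below K.
#'
#' @param embedding an \linkS4class{EmbeddingMatrix}.
#' @param labels a \linkS4class{LabelVector} aligned to the embedding.
#' @param perplexity effective neighborhood size for the kernel calibration
#'   (default 30).
#' @param kNeighbors neighbors per cell (default 90, three times the
#'   perplexity, the convention of the reference implementation).
#' @return a list with \code{perCell} (named numeric in [1, K]),
#'   \code{mean}, \code{perplexity}, \code{kNeighbors}.
#' @examples
#' sim <- simulateEmbedding(simConfig(nCells = 200, separation = 40, seed = 1))
#' clisi(sim$embedding, sim$labels, perplexity = 10, kNeighbors = 30)$mean
#' @export
clisi <- function(embedding, labels, perplexity = 30, kNeighbors = 90) {
    .checkAligned(embedding, labels)
    n <- nCells(embedding)
    if (kNeighbors >= n) stop("kNeighbors must be < n")
    if (perplexity >= kNeighbors) stop("perplexity must be < kNeighbors")
    g <- as.integer(groups(labels))
    K <- nGroups(labels)
    nn <- knnNeighbors(embedding, kNeighbors)
    Dnn <- attr(nn, "distances")
    target <- log(perplexity)
    perCell <- numeric(n)
    fellBack <- 0L
    for (i in seq_len(n)) {
        w <- .perplexityWeights(Dnn[i, ], target)
        if (is.null(w)) {
            fellBack <- fellBack + 1L
            w <- rep(1 / kNeighbors, kNeighbors)
        }
        p <- vapply(seq_len(K), function(cl) sum(w[g[nn[i, ]] == cl]),
                    numeric(1))
        perCell[i] <- 1 / sum(p^2)
    }
    if (fellBack > 0L)
        warning(sprintf(
            "kernel calibration did not converge for %d cell(s); uniform weights used",
            fellBack))
    names(perCell) <- cellIds(embedding)
    list(perCell = perCell, mean = mean(perCell),
         perplexity = perplexity, kNeighbors = kNeighbors)
}

# Exponential-kernel weights over neighbor distances with entropy
# log(perplexity), solved for the precision beta by bisection. Returns NULL
# on non-convergence (the caller falls back to uniform weights).
.perplexityWeights <- function(d2, target, maxIter = 100L, tol = 1e-5) {
    d2 <- d2 - min(d2)      # normalization-invariant; guards exp underflow
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in seq_len(maxIter)) {
        w <- exp(-beta * d2)
        sw <- sum(w)
        if (sw == 0) { hi <- beta; beta <- beta / 2; next }
        w <- w / sw
        h <- -sum(ifelse(w > 0, w * log(w), 0))
        if (abs(h - target) < tol) return(w)
        if (h > target) {       # too flat: increase precision
            lo <- beta
            beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2
        } else {
            hi <- beta
            beta <- if (is.finite(lo)) (lo + hi) / 2 else beta / 2
        }
    }
    NULL
}
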