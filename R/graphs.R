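#' Exact k-nearest-neighbor lists
#'
#' Exhaustive (non-approximate) neighbor search. Ties in distance are broken
#' by ascending cell index, so results are fully reproducible; duplicated
#' coordinate rows are allowed (each duplicate picks the other at distance
#' zero). Cosine neighbors are found as Euclidean neighbors of the
#' row-normalized coordinates, which induces the same ordering.
#'
#' @param embedding an \linkS4class{EmbeddingMatrix}.
#' @param k neighbors per cell, \code{1 <= k < n}.
#' @param metric \code{"euclidean"} or \code{"cosine"}.
#' @return integer matrix, \code{n} rows by \code{k} columns; row \code{i}
#'   holds the indices of the k nearest other cells in increasing distance;
#'   attribute \code{"distances"} carries the matching distances.
#' @export
knnNeighbors <- function(embedding, k, metric = c("euclidean", "cosine")) {
    metric <- match.arg(metric)
    co <- coords(embedding)
    n <- nrow(co)
    if (k < 1L || k >= n) stop("need 1 <= k < n")
    if (metric == "cosine") {
        nrm <- sqrt(rowSums(co^2))
        if (any(nrm == 0)) stop("all-zero row: cosine undefined")
        co <- co / nrm
    }
    D <- as.matrix(stats::dist(co))
    idx <- matrix(0L, n, k)
    dst <- matrix(0, n, k)
    for (i in seq_len(n)) {
        d <- D[i, ]
        d[i] <- Inf                        # exclude self
        o <- order(d, seq_len(n))[seq_len(k)]   # ties by ascending index
        idx[i, ] <- o
        dst[i, ] <- d[o]
    }
    attr(idx, "distances") <- dst
    idx
}

#' Build a k-nearest-neighbor graph
#'
#' Directed k-neighbor lists are symmetrized by union; every retained edge
#' has weight 1 (the unweighted view used by the graph-level metrics).
#'
#' @inheritParams knnNeighbors
#' @return a \linkS4class{NeighborGraph} with \code{kind = "knn"}.
#' @seealso \code{\link{knnNeighbors}} for the raw (directed) lists.
#' @export
buildKnn <- function(embedding, k = 20, metric = c("euclidean", "cosine")) {
    nn <- knnNeighbors(embedding, k, metric)
    n <- nrow(nn)
    A <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn)),
                              j = as.vector(nn), x = 1,
                              dims = c(n, n))
    A <- .symmetrizeMax(A)                 # union of directed edges
    dimnames(A) <- list(cellIds(embedding), cellIds(embedding))
    NeighborGraph(A, kind = "knn")
}

#' Build a shared-nearest-neighbor (SNN) graph
#'
#' The SNN weight between cells i and j is the Jaccard overlap of their
#' neighbor sets, \eqn{|N(i) \cap N(j)| / |N(i) \cup N(j)|}, where
#' \eqn{N(\cdot)} is the set of k nearest neighbors plus the cell itself
#' (so \eqn{|N| = k + 1}); weights at or below \code{prune} are removed.
#' These are the documented conventions of the widely used single-cell
#' implementation this graph emulates.
#'
#' @inheritParams knnNeighbors
#' @param k neighbors per cell (default 20).
#' @param prune Jaccard cutoff in [0, 1); weights \code{<= prune} are set to
#'   zero (default 1/15).
#' @return a \linkS4class{NeighborGraph} with \code{kind = "snn"}.
#' @export
buildSnn <- function(embedding, k = 20, prune = 1/15,
                     metric = c("euclidean", "cosine")) {
    if (prune >= 1) stop("prune must be < 1")
    if (prune < 0) stop("prune must be >= 0")
    nn <- knnNeighbors(embedding, k, metric)
    n <- nrow(nn)
    # indicator of membership: row i marks N(i) = {i} union k neighbors
    M <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn) + 1L),
                              j = c(as.vector(nn), seq_len(n)), x = 1,
                              dims = c(n, n))
    # |N(i) & N(j)|; general storage so both triangles are materialized
    inter <- as(as(Matrix::tcrossprod(M), "generalMatrix"), "CsparseMatrix")
    setSize <- k + 1
    tr <- Matrix::summary(inter)
    jac <- tr$x / (2 * setSize - tr$x)     # |union| = 2(k+1) - |inter|
    keep <- jac > prune & tr$i != tr$j
    A <- Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = jac[keep],
                              dims = c(n, n),
                              dimnames = list(cellIds(embedding),
                                              cellIds(embedding)))
    NeighborGraph(A, kind = "snn")
}
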