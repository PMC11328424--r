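#' Within-class library-size correlation of latent dimensions
#'
#' Quantifies how much each latent dimension is driven by sequencing depth
#' rather than biology. Depth differences \emph{between} cell types can be
#' biological, so the correlation is taken \emph{within} each class: for
#' latent dimension \eqn{l},
#' \deqn{r_l = \frac{1}{K}\sum_k \left|\,\mathrm{cor}\!\left(\sqrt{c_k},\,
#'   x_{k,l}\right)\right|,}
#' the absolute Pearson correlation between the square root of the per-cell
#' library size and the dimension's coordinates, averaged over classes.
#' Classes with fewer than 3 cells, or zero variance in either vector, are
#' skipped with a warning. The summary value averages \eqn{r_l} over the
#' first \code{min(dims, 5)} dimensions.
#'
#' @param embedding an \linkS4class{EmbeddingMatrix}.
#' @param labels a \linkS4class{LabelVector} aligned to the embedding.
#' @param libsize a \linkS4class{LibrarySizeVector} aligned to the embedding.
#' @param dims number of leading latent dimensions to assess (default: all).
#' @return a list with \code{perDimension} (named numeric in [0, 1]),
#'   \code{summary} (mean over the first \code{min(dims, 5)} dimensions) and
#'   \code{skipped} (classes skipped per dimension).
#' @export
librarySizeCorrelation <- function(embedding, labels, libsize, dims = NULL) {
    .checkAligned(embedding, labels, libsize)
    co <- coords(embedding)
    if (is.null(dims)) dims <- ncol(co)
    dims <- min(dims, ncol(co))
    g <- groups(labels)
    sqrtCounts <- sqrt(libSizes(libsize))
    perDim <- numeric(dims)
    skipped <- vector("list", dims)
    for (l in seq_len(dims)) {
        rs <- c(); sk <- c()
        for (cl in levels(g)) {
            sel <- g == cl
            if (sum(sel) < 3L ||
                stats::sd(sqrtCounts[sel]) == 0 ||
                stats::sd(co[sel, l]) == 0) {
                sk <- c(sk, cl)
                next
            }
            rs <- c(rs, abs(stats::cor(sqrtCounts[sel], co[sel, l])))
        }
        perDim[l] <- if (length(rs)) mean(rs) else NA_real_
        skipped[[l]] <- sk
    }
    if (length(unlist(skipped)))
        warning(sprintf("%d class/dimension combination(s) skipped (size < 3 or zero variance)",
                        length(unlist(skipped))))
    names(perDim) <- colnames(co)[seq_len(dims)]
    list(perDimension = perDim,
         summary = .meanDefined(perDim[seq_len(min(dims, 5L))]),
         skipped = skipped)
}

#' Filter latent components correlated with library size
#'
#' A latent dimension is removed when the absolute Pearson correlation,
#' across all cells, between its coordinates and the raw total counts
#' exceeds \code{threshold} (default 0.75, the filtering rule commonly
#' applied to LSI embeddings, where the first component typically tracks
#' depth). The order of kept dimensions is preserved.
#'
#' @param embedding an \linkS4class{EmbeddingMatrix}.
#' @param libsize a \linkS4class{LibrarySizeVector} aligned to the embedding.
#' @param threshold correlation cutoff in (0, 1].
#' @return a list with integer vectors \code{kept} and \code{removed}, plus
#'   \code{correlations} (the per-dimension |r|).
#' @export
componentFilter <- function(embedding, libsize, threshold = 0.75) {
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    .checkAligned(embedding, libsize)
    co <- coords(embedding)
    counts <- libSizes(libsize)
    r <- abs(apply(co, 2L, function(v)
        if (stats::sd(v) == 0 || stats::sd(counts) == 0) 0
        else stats::cor(v, counts)))
    removed <- which(r > threshold)
    kept <- setdiff(seq_len(ncol(co)), removed)
    if (!length(kept)) stop("no informative components: all dimensions removed")
    list(kept = kept, removed = as.integer(removed), correlations = r)
}

#' Geary's C spatial autocorrelation on a neighbor graph
#'
#' \deqn{C = \frac{(N-1)\sum_i\sum_j w_{ij}(x_i - x_j)^2}
#'            {2 S_0 \sum_i (x_i - \bar x)^2},}
#' with \eqn{S_0} the sum of all weights (both directions of each symmetric
#' edge, matching the double sum in the numerator). Values near 1 indicate
#' no autocorrelation; values below 1 indicate a signal that varies smoothly
#' over the graph — applied to log library sizes, a small C means depth
#' structures the embedding. When scoring library sizes use
#' \code{log1p}-transformed counts so zero-count cells are tolerated.
#'
#' @param graph a \linkS4class{NeighborGraph} (typically kNN with k = 20).
#' @param x numeric per-cell values aligned to the graph (nonzero variance).
#' @return the Geary's C statistic (non-negative scalar).
#' @export
gearysC <- function(graph, x) {
    A <- adjacency(graph)
    if (length(x) != nCells(graph))
        stop("x must have one value per cell")
    xc <- x - mean(x)
    ss <- sum(xc^2)
    if (ss == 0) stop("zero variance: Geary's C undefined")
    tr <- Matrix::summary(A)
    num <- sum(tr$x * (x[tr$i] - x[tr$j])^2)
    S0 <- sum(tr$x)
    if (S0 == 0) stop("empty graph")
    (nCells(graph) - 1) * num / (2 * S0 * ss)
}
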