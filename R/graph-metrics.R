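#' Proportion of Weakly Connected cells (PWC)
#'
#' Treats each ground-truth class as a candidate community in the graph and
#' asks, cell by cell, whether it is held more strongly inside or outside
#' its class. Splitting the degree of cell \eqn{i} in class \eqn{V} into
#' \eqn{k_i^{in}(V)} (edges into \eqn{V}) and \eqn{k_i^{out}(V)} (edges to
#' the rest of the graph), a cell is \emph{weak} when
#' \eqn{k_i^{in} < k_i^{out}} (strict; a community in the strong sense has
#' \eqn{k_i^{in} > k_i^{out}} for every member). PWC of a class is the
#' fraction of its cells that are weak; isolated cells (degree 0) are never
#' weak. The overall value is the unweighted mean over classes.
#'
#' @param graph a \linkS4class{NeighborGraph} aligned to \code{labels}.
#' @param labels a \linkS4class{LabelVector}.
#' @param weighted if \code{FALSE} (default) degrees count edges; if
#'   \code{TRUE} they sum edge weights (honoring SNN Jaccard weights).
#' @return a list with \code{perClass} (named numeric in [0, 1]),
#'   \code{mean}, and \code{weakCells} (per-class character vectors of weak
#'   cell ids).
#' @export
pwc <- function(graph, labels, weighted = FALSE) {
    .checkAligned(graph, labels)
    A <- Matrix::drop0(adjacency(graph))
    if (!weighted && length(A@x)) A@x[] <- 1
    g <- groups(labels)
    onehot <- Matrix::sparseMatrix(i = seq_along(g), j = as.integer(g), x = 1,
                                   dims = c(length(g), nlevels(g)))
    within <- as.matrix(A %*% onehot)      # cell x class degree split
    deg <- Matrix::rowSums(A)
    kin <- within[cbind(seq_along(g), as.integer(g))]
    kout <- deg - kin
    weak <- kin < kout                     # degree-0 cells: 0 < 0 is FALSE
    perClass <- vapply(split(weak, g), mean, numeric(1))
    ids <- cellIds(graph)
    weakCells <- lapply(split(seq_along(g)[weak], g[weak]), function(ix) ids[ix])
    weakCells <- weakCells[levels(g)[levels(g) %in% names(weakCells)]]
    list(perClass = perClass, mean = mean(perClass), weakCells = weakCells)
}
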