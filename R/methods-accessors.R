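#' @describeIn EmbeddingMatrix-class cell identifiers (row names).
#' @export
setMethod("cellIds", "EmbeddingMatrix", function(x) rownames(x@coords))

#' @describeIn EmbeddingMatrix-class number of cells.
#' @export
setMethod("nCells", "EmbeddingMatrix", function(x) nrow(x@coords))

#' @describeIn EmbeddingMatrix-class the coordinate matrix.
#' @export
setMethod("coords", "EmbeddingMatrix", function(x) x@coords)

#' @describeIn EmbeddingMatrix-class restrict/reorder to \code{ids}.
#' @export
setMethod("subsetCells", "EmbeddingMatrix", function(x, ids) {
    .checkSubsetIds(cellIds(x), ids)
    EmbeddingMatrix(x@coords[ids, , drop = FALSE])
})

setMethod("cellIds", "CellGrouping", function(x) x@cellIds)
setMethod("nCells", "CellGrouping", function(x) length(x@cellIds))
setMethod("groups", "CellGrouping", function(x) {
    g <- x@groups
    names(g) <- x@cellIds
    g
})
setMethod("nGroups", "CellGrouping", function(x) nlevels(x@groups))
setMethod("subsetCells", "CellGrouping", function(x, ids) {
    .checkSubsetIds(x@cellIds, ids)
    idx <- match(ids, x@cellIds)
    initialize(x, cellIds = x@cellIds[idx],
               groups = droplevels(x@groups[idx]))
})

#' @describeIn NeighborGraph-class cell identifiers.
#' @export
setMethod("cellIds", "NeighborGraph", function(x) rownames(x@adjacency))

#' @describeIn NeighborGraph-class number of cells.
#' @export
setMethod("nCells", "NeighborGraph", function(x) nrow(x@adjacency))

#' @describeIn NeighborGraph-class the sparse adjacency matrix.
#' @export
setMethod("adjacency", "NeighborGraph", function(x) x@adjacency)

#' @describeIn NeighborGraph-class the graph kind flag.
#' @export
setMethod("graphKind", "NeighborGraph", function(x) x@kind)

#' @describeIn NeighborGraph-class restrict/reorder to \code{ids}.
#' @export
setMethod("subsetCells", "NeighborGraph", function(x, ids) {
    .checkSubsetIds(cellIds(x), ids)
    NeighborGraph(x@adjacency[ids, ids, drop = FALSE], kind = x@kind)
})

#' @describeIn LibrarySizeVector-class cell identifiers.
#' @export
setMethod("cellIds", "LibrarySizeVector", function(x) x@cellIds)

#' @describeIn LibrarySizeVector-class number of cells.
#' @export
setMethod("nCells", "LibrarySizeVector", function(x) length(x@cellIds))

#' @describeIn LibrarySizeVector-class the counts, named by cell.
#' @export
setMethod("libSizes", "LibrarySizeVector", function(x) {
    ct <- x@counts
    names(ct) <- x@cellIds
    ct
})

#' @describeIn LibrarySizeVector-class restrict/reorder to \code{ids}.
#' @export
setMethod("subsetCells", "LibrarySizeVector", function(x, ids) {
    .checkSubsetIds(x@cellIds, ids)
    idx <- match(ids, x@cellIds)
    LibrarySizeVector(x@cellIds[idx], x@counts[idx])
})

#' @describeIn PairedEmbeddings-class cell identifiers (may be NULL).
#' @export
setMethod("cellIds", "PairedEmbeddings", function(x) rownames(x@X1))

#' @describeIn PairedEmbeddings-class number of cells.
#' @export
setMethod("nCells", "PairedEmbeddings", function(x) nrow(x@X1))

.checkSubsetIds <- function(have, want) {
    missing <- setdiff(want, have)
    if (length(missing))
        stop(sprintf("unknown cell id(s): %s",
                     paste(utils::head(missing, 3), collapse = ", ")))
    if (anyDuplicated(want)) stop("duplicated ids in subset")
    invisible(TRUE)
}

setMethod("show", "EmbeddingMatrix", function(object) {
    cat(sprintf("EmbeddingMatrix: %d cells x %d latent dimensions\n",
                nCells(object), ncol(object@coords)))
})

setMethod("show", "CellGrouping", function(object) {
    tab <- table(object@groups)
    cat(sprintf("%s: %d cells in %d groups\n", class(object),
                nCells(object), nGroups(object)))
    cat("  sizes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "NeighborGraph", function(object) {
    nEdges <- length(object@adjacency@x) / 2
    cat(sprintf("NeighborGraph (%s): %d cells, %d undirected edges\n",
                object@kind, nCells(object), round(nEdges)))
})

setMethod("show", "LibrarySizeVector", function(object) {
    cat(sprintf("LibrarySizeVector: %d cells, median %d fragments\n",
                nCells(object), round(stats::median(object@counts))))
})

setMethod("show", "Contingency", function(object) {
    cat(sprintf("Contingency: %d classes x %d clusters, n = %d cells\n",
                nrow(object@table), ncol(object@table), sum(object@table)))
})

setMethod("show", "MetricReport", function(object) {
    cat(sprintf("MetricReport [%s level]\n", object@level))
    for (nm in names(object@values))
        cat(sprintf("  %-12s %s\n", nm,
                    ifelse(is.na(object@values[[nm]]), "undefined",
                           format(object@values[[nm]], digits = 4))))
})

setMethod("show", "SweepGrid", function(object) {
    res <- unique(vapply(object@entries, `[[`, numeric(1), "resolution"))
    cat(sprintf("SweepGrid: %d entries over %d resolutions (%d failures)\n",
                length(object@entries), length(res), length(object@failures)))
})
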