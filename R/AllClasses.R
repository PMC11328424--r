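#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

.checkCellIds <- function(ids) {
    if (anyNA(ids) || any(!nzchar(ids)))
        return("cell identifiers must be non-missing, non-empty strings")
    if (anyDuplicated(ids))
        return(sprintf("duplicated cell identifier(s): %s",
                       paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
                             collapse = ", ")))
    NULL
}

#' EmbeddingMatrix: per-cell latent coordinates
#'
#' A cells-by-latent-dimensions real matrix with unique cell identifiers as
#' row names. This is the object all embedding-level metrics consume.
#'
#' @slot coords numeric matrix, \code{n} cells by \code{d} latent dimensions;
#'   row names are the cell identifiers.
#' @export
setClass("EmbeddingMatrix", slots = c(coords = "matrix"))

setValidity("EmbeddingMatrix", function(object) {
    x <- object@coords
    if (!is.numeric(x)) return("coords must be a numeric matrix")
    if (nrow(x) < 2L) return("need at least 2 cells")
    if (ncol(x) < 1L) return("need at least 1 latent dimension")
    if (is.null(rownames(x))) return("coords must carry cell identifiers as row names")
    msg <- .checkCellIds(rownames(x))
    if (!is.null(msg)) return(msg)
    if (any(!is.finite(x))) return("coords contain non-finite entries")
    TRUE
})

#' @param coords numeric matrix of latent coordinates.
#' @param cellIds optional character vector of cell identifiers; defaults to
#'   the row names of \code{coords}.
#' @rdname EmbeddingMatrix-class
#' @export
EmbeddingMatrix <- function(coords, cellIds = rownames(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (is.null(cellIds))
        stop("cell identifiers are required (row names or `cellIds`)")
    rownames(coords) <- as.character(cellIds)
    if (is.null(colnames(coords)))
        colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
    new("EmbeddingMatrix", coords = coords)
}

# Shared machinery for the two label-like classes: a grouping of cells into
# named categories, kept as a factor aligned to the cell identifiers.
setClass("CellGrouping",
         slots = c(cellIds = "character", groups = "factor"),
         contains = "VIRTUAL")

setValidity("CellGrouping", function(object) {
    if (length(object@cellIds) != length(object@groups))
        return("cellIds and groups differ in length")
    if (length(object@cellIds) < 1L) return("no cells")
    msg <- .checkCellIds(object@cellIds)
    if (!is.null(msg)) return(msg)
    if (anyNA(object@groups)) return("every cell must be assigned a group")
    if (nlevels(object@groups) < 1L) return("need at least one group")
    TRUE
})

#' LabelVector: ground-truth class assignments
#'
#' Cell-type (or other ground-truth) labels over a set of cells. The number
#' of distinct classes \code{K} is available via \code{\link{nGroups}}.
#'
#' @slot cellIds character vector of unique cell identifiers.
#' @slot groups factor of class labels aligned to \code{cellIds}.
#' @export
setClass("LabelVector", contains = "CellGrouping")

#' @param cellIds character vector of cell identifiers.
#' @param labels vector of class labels, one per cell.
#' @rdname LabelVector-class
#' @export
LabelVector <- function(cellIds, labels) {
    new("LabelVector", cellIds = as.character(cellIds),
        groups = droplevels(as.factor(labels)))
}

#' Partition: predicted cluster assignments
#'
#' A clustering prediction over a set of cells; structurally identical to
#' \linkS4class{LabelVector} but kept as a distinct type so the asymmetric
#' scores (class completeness vs cluster homogeneity) cannot be confused.
#'
#' @slot cellIds character vector of unique cell identifiers.
#' @slot groups factor of cluster identifiers aligned to \code{cellIds}.
#' @export
setClass("Partition", contains = "CellGrouping")

#' @param cellIds character vector of cell identifiers.
#' @param clusters vector of cluster identifiers, one per cell.
#' @rdname Partition-class
#' @export
Partition <- function(cellIds, clusters) {
    new("Partition", cellIds = as.character(cellIds),
        groups = droplevels(as.factor(clusters)))
}

#' NeighborGraph: sparse symmetric graph over cells
#'
#' A weighted undirected graph over cells, typically a k-nearest-neighbor
#' (kNN) or shared-nearest-neighbor (SNN) graph built from an embedding.
#' Stored as a general sparse matrix with both triangles present, zero
#' diagonal, and non-negative weights.
#'
#' @slot adjacency \code{dgCMatrix} adjacency with cell identifiers as
#'   dimnames.
#' @slot kind character, either \code{"knn"} or \code{"snn"}.
#' @export
setClass("NeighborGraph",
         slots = c(adjacency = "dgCMatrix", kind = "character"))

setValidity("NeighborGraph", function(object) {
    A <- object@adjacency
    if (nrow(A) != ncol(A)) return("adjacency must be square")
    if (is.null(rownames(A))) return("adjacency must carry cell identifiers as dimnames")
    msg <- .checkCellIds(rownames(A))
    if (!is.null(msg)) return(msg)
    if (!identical(rownames(A), colnames(A))) return("row and column ids differ")
    if (length(A@x) && any(A@x < 0)) return("edge weights must be non-negative")
    if (any(Matrix::diag(A) != 0)) return("diagonal must be zero")
    asym <- max(abs(A - Matrix::t(A)))
    if (asym > 1e-9)
        return(sprintf("adjacency not symmetric (max asymmetry %.3g)", asym))
    if (!object@kind %in% c("knn", "snn"))
        return("kind must be 'knn' or 'snn'")
    TRUE
})

#' @param adjacency square sparse (or dense) symmetric matrix of edge weights.
#' @param kind \code{"knn"} or \code{"snn"}.
#' @param cellIds optional cell identifiers; defaults to the dimnames.
#' @rdname NeighborGraph-class
#' @export
NeighborGraph <- function(adjacency, kind = c("knn", "snn"),
                          cellIds = rownames(adjacency)) {
    kind <- match.arg(kind)
    A <- as(as(as(adjacency, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (is.null(cellIds))
        cellIds <- sprintf("cell%d", seq_len(nrow(A)))
    dimnames(A) <- list(as.character(cellIds), as.character(cellIds))
    A <- Matrix::drop0(A)
    new("NeighborGraph", adjacency = A, kind = kind)
}

#' LibrarySizeVector: unique-fragment counts per cell
#'
#' Total unique fragments per cell, the technical covariate whose leakage
#' into latent spaces the bias metrics quantify.
#'
#' @slot cellIds character vector of unique cell identifiers.
#' @slot counts non-negative numeric vector of fragment counts.
#' @export
setClass("LibrarySizeVector",
         slots = c(cellIds = "character", counts = "numeric"))

setValidity("LibrarySizeVector", function(object) {
    if (length(object@cellIds) != length(object@counts))
        return("cellIds and counts differ in length")
    msg <- .checkCellIds(object@cellIds)
    if (!is.null(msg)) return(msg)
    if (anyNA(object@counts) || any(object@counts < 0))
        return("counts must be non-negative")
    TRUE
})

#' @param cellIds character vector of cell identifiers.
#' @param counts non-negative counts, one per cell.
#' @rdname LibrarySizeVector-class
#' @export
LibrarySizeVector <- function(cellIds, counts) {
    new("LibrarySizeVector", cellIds = as.character(cellIds),
        counts = as.numeric(counts))
}

#' PairedEmbeddings: aligned cross-modality embeddings
#'
#' Two embeddings of the same cells in a common latent space (for instance
#' RNA and ATAC coordinates after integration), with rows aligned so that
#' row \code{i} of each matrix is the same cell.
#'
#' @slot X1,X2 numeric matrices of equal shape; rows are cells.
#' @export
setClass("PairedEmbeddings", slots = c(X1 = "matrix", X2 = "matrix"))

setValidity("PairedEmbeddings", function(object) {
    if (!identical(dim(object@X1), dim(object@X2)))
        return("X1 and X2 must have identical shape")
    if (nrow(object@X1) < 2L) return("need at least 2 cells")
    if (any(!is.finite(object@X1)) || any(!is.finite(object@X2)))
        return("non-finite coordinates")
    if (any(rowSums(object@X1 != 0) == 0) || any(rowSums(object@X2 != 0) == 0))
        return("all-zero rows: cosine distance undefined")
    TRUE
})

#' @param X1,X2 numeric matrices, cells by dimensions, rows aligned.
#' @param cellIds optional cell identifiers.
#' @rdname PairedEmbeddings-class
#' @export
PairedEmbeddings <- function(X1, X2, cellIds = rownames(X1)) {
    X1 <- as.matrix(X1); X2 <- as.matrix(X2)
    storage.mode(X1) <- "double"; storage.mode(X2) <- "double"
    if (!is.null(cellIds)) {
        rownames(X1) <- cellIds
        rownames(X2) <- cellIds
    }
    new("PairedEmbeddings", X1 = X1, X2 = X2)
}

#' Contingency: cross-tabulation of two partitions
#'
#' The I-by-J contingency table between ground-truth classes and predicted
#' clusters, with all pair-counting quantities derived from it available via
#' \code{\link{pairCounts}}.
#'
#' @slot table integer matrix of co-occurrence counts; rows are classes,
#'   columns are clusters.
#' @export
setClass("Contingency", slots = c(table = "matrix"))

setValidity("Contingency", function(object) {
    tab <- object@table
    if (!is.numeric(tab) || any(tab < 0) || any(tab != round(tab)))
        return("table must hold non-negative integers")
    if (sum(tab) < 2) return("need at least 2 cells (no object pairs)")
    TRUE
})

#' MetricReport: named metric values at one evaluation level
#'
#' A lightweight container pairing scalar metric values with optional
#' per-class or per-cluster decompositions, serializable to JSON or TSV.
#' Undefined values are carried as \code{NA} and written as JSON
#' \code{null}.
#'
#' @slot level one of \code{"embedding"}, \code{"graph"}, \code{"partition"},
#'   \code{"sweep"}, \code{"bias"}, \code{"integration"}.
#' @slot values named numeric vector of metric values.
#' @slot perGroup named list of named numeric vectors (per-class or
#'   per-cluster values).
#' @export
setClass("MetricReport",
         slots = c(level = "character", values = "numeric", perGroup = "list"))

setValidity("MetricReport", function(object) {
    ok <- c("embedding", "graph", "partition", "sweep", "bias", "integration")
    if (length(object@level) != 1L || !object@level %in% ok)
        return(sprintf("level must be one of %s", paste(ok, collapse = ", ")))
    if (length(object@values) && is.null(names(object@values)))
        return("values must be named")
    TRUE
})

#' @param level evaluation level flag.
#' @param values named numeric vector.
#' @param perGroup named list of named numeric vectors.
#' @rdname MetricReport-class
#' @export
MetricReport <- function(level, values, perGroup = list()) {
    new("MetricReport", level = level, values = values, perGroup = perGroup)
}

#' SweepGrid: scored partitions from a resolution/seed sweep
#'
#' Clustering solutions indexed by (resolution, seed), each carrying its
#' cluster count and the partition-level metric values computed against one
#' fixed ground truth. Input to \code{\link{aucCurve}} and
#' \code{\link{stability}}.
#'
#' @slot entries list; each element has \code{resolution}, \code{seed},
#'   \code{partition} (a \linkS4class{Partition}), \code{nClusters} and
#'   \code{metrics} (named numeric).
#' @slot labels the \linkS4class{LabelVector} every entry was scored against.
#' @slot failures list of (resolution, seed, message) for callback failures.
#' @export
setClass("SweepGrid",
         slots = c(entries = "list", labels = "LabelVector", failures = "list"))

setValidity("SweepGrid", function(object) {
    for (e in object@entries) {
        need <- c("resolution", "seed", "partition", "nClusters", "metrics")
        if (!all(need %in% names(e)))
            return("each entry needs resolution, seed, partition, nClusters, metrics")
        if (e$nClusters != nGroups(e$partition))
            return("nClusters inconsistent with the partition")
    }
    TRUE
})
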