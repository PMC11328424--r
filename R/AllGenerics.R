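#' Cell identifiers of an object
#'
#' @param x an object carrying cells.
#' @return character vector of cell identifiers, in storage order.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' Number of cells in an object
#'
#' @param x an object carrying cells.
#' @return integer count of cells.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Restrict an object to a subset of cells, in the given order
#'
#' @param x an object carrying cells.
#' @param ids character vector of cell identifiers to keep; the result is
#'   reordered to match.
#' @return an object of the same class restricted to \code{ids}.
#' @export
setGeneric("subsetCells", function(x, ids) standardGeneric("subsetCells"))

#' Latent coordinates of an embedding
#'
#' @param x an \linkS4class{EmbeddingMatrix}.
#' @return the numeric coordinate matrix (cells by dimensions).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Group assignments of a label vector or partition
#'
#' @param x a \linkS4class{LabelVector} or \linkS4class{Partition}.
#' @return factor of group assignments aligned to \code{cellIds(x)}.
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' Number of distinct groups (classes K or clusters J)
#'
#' @param x a \linkS4class{LabelVector} or \linkS4class{Partition}.
#' @return integer count of distinct groups.
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' Adjacency matrix of a neighbor graph
#'
#' @param x a \linkS4class{NeighborGraph}.
#' @return sparse symmetric \code{dgCMatrix} of edge weights.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Graph kind (knn or snn)
#'
#' @param x a \linkS4class{NeighborGraph}.
#' @return \code{"knn"} or \code{"snn"}.
#' @export
setGeneric("graphKind", function(x) standardGeneric("graphKind"))

#' Library-size counts
#'
#' @param x a \linkS4class{LibrarySizeVector}.
#' @return numeric vector of counts aligned to \code{cellIds(x)}.
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))
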