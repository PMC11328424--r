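#' Read a cell embedding from delimited text
#'
#' Expects one row per cell: the cell identifier in the first column followed
#' by numeric latent coordinates. A header row is detected automatically
#' (any non-numeric entry beyond the first column in the first row). The
#' delimiter is auto-detected between comma and tab unless given.
#'
#' @param path path to a CSV/TSV file.
#' @param delimiter \code{","}, \code{"\t"}, or \code{NULL} to auto-detect.
#' @return an \linkS4class{EmbeddingMatrix}, row order preserved.
#' @export
readEmbedding <- function(path, delimiter = NULL) {
    if (!file.exists(path)) stop(sprintf("'%s': no such file", path))
    if (is.null(delimiter)) delimiter <- .detectDelim(path)
    df <- utils::read.table(path, sep = delimiter, header = FALSE,
                            colClasses = "character", quote = "\"",
                            comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop(sprintf("'%s': need a cell-id column plus >= 1 coordinate column", path))
    firstVals <- suppressWarnings(as.numeric(df[1, -1]))
    if (anyNA(firstVals)) df <- df[-1, , drop = FALSE]   # header row
    if (!nrow(df)) stop(sprintf("'%s': no records", path))
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop(sprintf("'%s': duplicated cell id '%s'", path,
                     ids[duplicated(ids)][1]))
    co <- suppressWarnings(
        vapply(df[-1], as.numeric, numeric(nrow(df))))
    co <- matrix(co, nrow = nrow(df))
    if (anyNA(co)) {
        bad <- which(is.na(co), arr.ind = TRUE)[1, ]
        stop(sprintf("'%s': non-numeric coordinate at row %d, column %d",
                     path, bad[1], bad[2] + 1L))
    }
    EmbeddingMatrix(co, cellIds = ids)
}

#' Write a cell embedding to delimited text
#'
#' Values are written with full double precision so that
#' \code{readEmbedding(writeEmbedding(x))} round-trips to 1e-12 or better.
#'
#' @param x an \linkS4class{EmbeddingMatrix}.
#' @param path output file.
#' @param delimiter field delimiter.
#' @return \code{path}, invisibly.
#' @export
writeEmbedding <- function(x, path, delimiter = "\t") {
    co <- coords(x)
    lines <- paste(cellIds(x),
                   apply(co, 1L, function(r)
                       paste(sprintf("%.17g", r), collapse = delimiter)),
                   sep = delimiter)
    writeLines(lines, path)
    invisible(path)
}

.readTwoColumn <- function(path, delimiter) {
    if (!file.exists(path)) stop(sprintf("'%s': no such file", path))
    if (is.null(delimiter)) delimiter <- .detectDelim(path)
    df <- utils::read.table(path, sep = delimiter, header = FALSE,
                            colClasses = "character", quote = "\"",
                            comment.char = "", stringsAsFactors = FALSE)
    if (!nrow(df)) stop(sprintf("'%s': no records", path))
    if (ncol(df) < 2L) stop(sprintf("'%s': expected two columns", path))
    # header detection: common id-column names only, since labels are
    # legitimately non-numeric
    if (tolower(df[1, 1]) %in% c("cell", "cell_id", "cellid", "barcode", "id"))
        df <- df[-1, , drop = FALSE]
    if (!nrow(df)) stop(sprintf("'%s': no records", path))
    df
}

#' Read ground-truth labels or a predicted partition
#'
#' Two-column delimited text: cell identifier, label. Alignment with a
#' companion embedding is not checked here; use \code{\link{alignCells}}.
#'
#' @param path path to a CSV/TSV file.
#' @param delimiter \code{","}, \code{"\t"}, or \code{NULL} to auto-detect.
#' @return a \linkS4class{LabelVector} (\code{readLabels}) or
#'   \linkS4class{Partition} (\code{readPartition}).
#' @export
readLabels <- function(path, delimiter = NULL) {
    df <- .readTwoColumn(path, delimiter)
    LabelVector(df[[1]], df[[2]])
}

#' @rdname readLabels
#' @export
readPartition <- function(path, delimiter = NULL) {
    df <- .readTwoColumn(path, delimiter)
    Partition(df[[1]], df[[2]])
}

#' @param x a \linkS4class{LabelVector} or \linkS4class{Partition}.
#' @rdname readLabels
#' @export
writeLabels <- function(x, path, delimiter = "\t") {
    writeLines(paste(cellIds(x), as.character(groups(x)), sep = delimiter),
               path)
    invisible(path)
}

#' Read per-cell library sizes
#'
#' Two-column delimited text: cell identifier, unique-fragment count.
#'
#' @inheritParams readLabels
#' @return a \linkS4class{LibrarySizeVector}.
#' @export
readLibrarySizes <- function(path, delimiter = NULL) {
    df <- .readTwoColumn(path, delimiter)
    ct <- suppressWarnings(as.numeric(df[[2]]))
    if (anyNA(ct))
        stop(sprintf("'%s': non-numeric count at row %d", path,
                     which(is.na(ct))[1]))
    LibrarySizeVector(df[[1]], ct)
}

#' @param x a \linkS4class{LibrarySizeVector}.
#' @rdname readLibrarySizes
#' @export
writeLibrarySizes <- function(x, path, delimiter = "\t") {
    writeLines(paste(cellIds(x), sprintf("%.17g", libSizes(x)),
                     sep = delimiter), path)
    invisible(path)
}

#' Read a neighbor graph from MatrixMarket or edge-list text
#'
#' MatrixMarket input may be coordinate real general or symmetric; an
#' edge list is 3-column delimited text (cell id, cell id, weight). In both
#' cases the adjacency is symmetrized by the elementwise maximum of the
#' (i,j) and (j,i) entries, and diagonal entries are dropped with a warning.
#'
#' @param path input file.
#' @param format \code{"mtx"} or \code{"edgelist"}; defaults from the file
#'   extension.
#' @param kind graph kind flag, \code{"knn"} or \code{"snn"}.
#' @param cellIds for MTX input, the cell identifiers of the matrix rows
#'   (read from \code{<path>.ids} if present, otherwise generated); for edge
#'   lists, the reference universe of ids (optional — defaults to the ids
#'   seen, in order of first appearance; any edge id outside a supplied
#'   universe is a format error).
#' @return a \linkS4class{NeighborGraph}.
#' @export
readGraph <- function(path, format = NULL, kind = c("snn", "knn"),
                      cellIds = NULL) {
    kind <- match.arg(kind)
    if (!file.exists(path)) stop(sprintf("'%s': no such file", path))
    if (is.null(format))
        format <- if (grepl("\\.mtx$", path)) "mtx" else "edgelist"
    format <- match.arg(format, c("mtx", "edgelist"))
    if (format == "mtx") {
        A <- as(as(Matrix::readMM(path), "generalMatrix"), "CsparseMatrix")
        if (is.null(cellIds)) {
            idsFile <- paste0(path, ".ids")
            cellIds <- if (file.exists(idsFile)) readLines(idsFile)
                       else sprintf("cell%d", seq_len(nrow(A)))
        }
        if (length(cellIds) != nrow(A))
            stop(sprintf("'%s': %d ids for a %d-cell matrix", path,
                         length(cellIds), nrow(A)))
        dimnames(A) <- list(cellIds, cellIds)
    } else {
        df <- utils::read.table(path, sep = .detectDelim(path), header = FALSE,
                                colClasses = "character",
                                stringsAsFactors = FALSE)
        if (ncol(df) < 3L)
            stop(sprintf("'%s': edge list needs 3 columns (id, id, weight)", path))
        w <- suppressWarnings(as.numeric(df[[3]]))
        if (anyNA(w))
            stop(sprintf("'%s': non-numeric weight at row %d", path,
                         which(is.na(w))[1]))
        if (is.null(cellIds)) {
            cellIds <- unique(c(rbind(df[[1]], df[[2]])))
        } else {
            unknown <- setdiff(c(df[[1]], df[[2]]), cellIds)
            if (length(unknown))
                stop(sprintf("'%s': unknown cell id '%s' in edge list",
                             path, unknown[1]))
        }
        i <- match(df[[1]], cellIds)
        j <- match(df[[2]], cellIds)
        A <- Matrix::sparseMatrix(i = i, j = j, x = w,
                                  dims = c(length(cellIds), length(cellIds)),
                                  dimnames = list(cellIds, cellIds))
    }
    if (length(A@x) && any(A@x < 0))
        stop(sprintf("'%s': negative edge weight", path))
    if (any(Matrix::diag(A) != 0)) {
        warning(sprintf("'%s': nonzero diagonal entries dropped", path))
        Matrix::diag(A) <- 0
    }
    A <- .symmetrizeMax(A)
    NeighborGraph(A, kind = kind)
}

# elementwise max of A and t(A); idempotent on symmetric inputs
.symmetrizeMax <- function(A) {
    At <- Matrix::t(A)
    (A + At + abs(A - At)) / 2
}

#' Write a neighbor graph
#'
#' MatrixMarket output writes the full symmetric adjacency plus a
#' \code{<path>.ids} sidecar with one cell identifier per line, so that
#' \code{readGraph} round-trips identifiers exactly.
#'
#' @param x a \linkS4class{NeighborGraph}.
#' @param path output file.
#' @param format \code{"mtx"} or \code{"edgelist"}.
#' @return \code{path}, invisibly.
#' @export
writeGraph <- function(x, path, format = c("mtx", "edgelist")) {
    format <- match.arg(format)
    A <- adjacency(x)
    if (format == "mtx") {
        Matrix::writeMM(A, path)
        writeLines(cellIds(x), paste0(path, ".ids"))
    } else {
        tr <- Matrix::summary(A)
        tr <- tr[tr$i < tr$j, , drop = FALSE]   # one line per undirected edge
        ids <- cellIds(x)
        writeLines(paste(ids[tr$i], ids[tr$j], sprintf("%.17g", tr$x),
                         sep = "\t"), path)
    }
    invisible(path)
}

#' Align cell-carrying objects to their common cells
#'
#' Restricts every object to the intersection of their cell-identifier sets
#' and reorders all of them to the order of the first object. Matching is
#' exact, case-sensitive string equality (barcodes are case-significant).
#'
#' @param ... two or more objects with \code{\link{cellIds}} methods.
#' @return a list of the restricted objects (named as supplied), with
#'   attribute \code{"dropped"} giving the per-object count of cells removed.
#' @export
alignCells <- function(...) {
    objs <- list(...)
    if (length(objs) < 2L) stop("need at least 2 objects to align")
    idSets <- lapply(objs, cellIds)
    common <- Reduce(intersect, idSets[-1], idSets[[1]])
    if (length(common) < 2L)
        stop(sprintf("only %d cell(s) shared across inputs", length(common)))
    out <- lapply(objs, subsetCells, ids = common)
    attr(out, "dropped") <- vapply(idSets, function(s)
        length(s) - length(common), integer(1))
    out
}
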