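# Run expr with a private RNG state seeded by `seed`; the caller's global
# RNG stream is restored on exit, so generators have no side effects.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Delimiter auto-detection between comma and tab: whichever occurs in the
# first non-empty line; tab wins ties (TSV headers often contain commas in
# free-text columns, the reverse is rare).
.detectDelim <- function(path) {
    ln <- readLines(path, n = 50L, warn = FALSE)
    ln <- ln[nzchar(ln)]
    if (!length(ln)) stop(sprintf("'%s': no records", path))
    first <- ln[[1]]
    nTab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
    nCom <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
    if (nTab == 0 && nCom == 0)
        stop(sprintf("'%s': neither tab nor comma delimiter found", path))
    if (nTab >= nCom) "\t" else ","
}

# Require that two cell-carrying objects are already aligned (same ids, same
# order); metric functions call this instead of silently reordering.
.checkAligned <- function(...) {
    objs <- list(...)
    ref <- cellIds(objs[[1]])
    for (o in objs[-1]) {
        if (!identical(cellIds(o), ref))
            stop("inputs are not aligned to the same cells in the same order; ",
                 "use alignCells() first")
    }
    invisible(ref)
}

# Unweighted mean over the defined entries of a per-group vector.
.meanDefined <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    mean(x)
}
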