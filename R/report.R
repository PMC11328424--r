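#' Serialize a MetricReport to JSON or TSV
#'
#' JSON output carries undefined values as \code{null} (never the text
#' "NaN"), with per-group decompositions nested under \code{per_group}. TSV
#' output is long format: \code{section}, \code{name}, \code{value}, with
#' undefined values as empty fields.
#'
#' @param report a \linkS4class{MetricReport}.
#' @param path output file.
#' @param format \code{"json"} or \code{"tsv"}; defaults from the file
#'   extension.
#' @return \code{path}, invisibly.
#' @export
writeMetricReport <- function(report, path, format = NULL) {
    if (is.null(format))
        format <- if (grepl("\\.tsv$", path)) "tsv" else "json"
    format <- match.arg(format, c("json", "tsv"))
    if (format == "json") {
        payload <- list(level = report@level,
                        values = as.list(report@values),
                        per_group = lapply(report@perGroup, as.list))
        jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                             na = "null", pretty = TRUE)
    } else {
        rows <- c(sprintf("values\t%s\t%s", names(report@values),
                          ifelse(is.na(report@values), "",
                                 sprintf("%.17g", report@values))))
        for (grp in names(report@perGroup)) {
            v <- report@perGroup[[grp]]
            rows <- c(rows, sprintf("%s\t%s\t%s", grp, names(v),
                                    ifelse(is.na(v), "", sprintf("%.17g", v))))
        }
        writeLines(c("section\tname\tvalue", rows), path)
    }
    invisible(path)
}
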