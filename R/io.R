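#' Read an OTU table from a tab-separated file
#'
#' Expects the common amplicon-table dialect: first column OTU id, header row
#' of sample ids (a leading `#` on the header line is tolerated, as written
#' by several OTU-picking tools), integer counts. Files with samples as rows
#' can be read with `transpose = TRUE`.
#'
#' @param path path to a TSV file.
#' @param transpose logical; if `TRUE` the file stores samples as rows and
#'   OTUs as columns and is transposed on read.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  header <- sub("^#\\s*", "", header)
  fields <- strsplit(header, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 2L) {
    stop("OTU table must have at least one id column and one count column",
         call. = FALSE)
  }
  body <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
  if (ncol(body) != length(fields)) {
    stop("ragged table: header has ", length(fields), " fields but rows have ",
         ncol(body), call. = FALSE)
  }
  row_ids <- body[[1]]
  cells <- as.matrix(body[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", cells[bad[1], bad[2]], "' at row '",
         row_ids[bad[1]], "'", call. = FALSE)
  }
  tab <- otu_table(num, otu_ids = row_ids, sample_ids = fields[-1])
  if (transpose) {
    tab <- otu_table(t(unclass(tab)))
  }
  tab
}

#' Write an OTU table to a tab-separated file
#'
#' @param table an [otu_table].
#' @param path output path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(OTU_ID = otu_ids(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from a tab-separated file
#'
#' Two required columns: `sample_id` and `group` (extra columns are ignored).
#'
#' @param path path to a TSV file with a header row.
#' @return A [sample_metadata] data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_metadata(df$sample_id, df$group)
}

#' Write sample metadata to a tab-separated file
#'
#' @param metadata a [sample_metadata] data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable JSON report
#'
#' Serializes any of the pipeline's result objects (network topology, ANOSIM
#' results, alpha-diversity tables, or plain named lists) to one JSON
#' document, preserving full numeric precision so a seeded re-run produces a
#' byte-identical payload.
#'
#' @param results a result object or named list of result objects.
#' @param path output path.
#' @export
write_report <- function(results, path) {
  payload <- as_report(results)
  con <- try(file(path, open = "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot write report to: ", path, call. = FALSE)
  }
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null", null = "null"),
             con)
  invisible(path)
}

# Convert pipeline result objects to plain lists for JSON serialization.
as_report <- function(x) UseMethod("as_report")

#' @export
as_report.default <- function(x) {
  if (is.list(x) && !is.data.frame(x)) lapply(x, as_report) else x
}

#' @export
as_report.network_topology <- function(x) {
  unclass(x)
}

#' @export
as_report.anosim_result <- function(x) unclass(x)

#' @export
as_report.data.frame <- function(x) x

#' @export
as_report.cooccurrence_network <- function(x) {
  list(nodes = length(network_nodes(x)),
       edges = nrow(network_edges(x)),
       rho_min = x$rho_min, p_max = x$p_max)
}
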