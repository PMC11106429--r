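#' OTU count table
#'
#' Construct and validate an OTU-by-sample count table, the universal input of
#' the pipeline. Rows are OTUs (97%-similarity sequence clusters or any other
#' taxon proxy), columns are samples, cells are non-negative integer read
#' counts.
#'
#' @param counts numeric matrix of non-negative integer counts; rows = OTUs,
#'   columns = samples.
#' @param otu_ids character vector of unique OTU identifiers; defaults to
#'   `rownames(counts)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(counts)`.
#' @return A matrix of class `otu_table` with OTU ids as rownames and sample
#'   ids as colnames.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
#' tab <- otu_table(m)
#' @export
otu_table <- function(counts, otu_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("OTU table is empty (", nrow(counts), " OTUs x ", ncol(counts),
         " samples)", call. = FALSE)
  }
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(counts)))
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != nrow(counts)) {
    stop("length of otu_ids (", length(otu_ids),
         ") does not match number of rows (", nrow(counts), ")", call. = FALSE)
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("length of sample_ids (", length(sample_ids),
         ") does not match number of columns (", ncol(counts), ")",
         call. = FALSE)
  }
  dup <- unique(otu_ids[duplicated(otu_ids)])
  if (length(dup)) {
    stop("duplicate OTU id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts) || !is.numeric(counts)) {
    stop("counts must be numeric with no missing values", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("counts must be integers; found ", counts[bad[1], bad[2]],
         " at OTU '", otu_ids[bad[1]], "', sample '", sample_ids[bad[2]], "'",
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(otu_ids, sample_ids)
  class(counts) <- c("otu_table", class(matrix()))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table: ", nrow(x), " OTUs x ", ncol(x), " samples, ",
      sum(x), " total reads\n", sep = "")
  invisible(x)
}

otu_ids <- function(table) rownames(table)
sample_ids <- function(table) colnames(table)

#' Sample metadata
#'
#' A minimal sample-to-group mapping: one row per sample with a non-empty
#' group label (e.g. the irrigation treatments FP, DI, MF of a three-arm
#' field design).
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character vector of non-empty group labels, recycled to the
#'   length of `sample_id` if of compatible length.
#' @return A data.frame of class `sample_metadata` with columns `sample_id`
#'   and `group`.
#' @export
sample_metadata <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(group) != length(sample_id)) {
    stop("sample_id and group must have the same length", call. = FALSE)
  }
  dup <- unique(sample_id[duplicated(sample_id)])
  if (length(dup)) {
    stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(group) | !nzchar(group))) {
    stop("group labels must be non-empty", call. = FALSE)
  }
  out <- data.frame(sample_id = sample_id, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_metadata", class(out))
  out
}

# Look up group labels for a table's samples, erroring on samples the
# metadata does not cover.
match_groups <- function(table, metadata) {
  ids <- sample_ids(table)
  idx <- match(ids, metadata$sample_id)
  if (anyNA(idx)) {
    stop("metadata is missing sample(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(metadata$group[idx], ids)
}
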