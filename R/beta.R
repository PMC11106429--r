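#' Bray-Curtis dissimilarity among samples
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` over OTUs: 0 for identical
#' samples, 1 for samples with disjoint OTU support.
#'
#' @param table an [otu_table]; every sample must have a positive total.
#' @return Square symmetric matrix of dissimilarities in `[0, 1]` with sample
#'   ids as dimnames and a zero diagonal.
#' @export
bray_curtis <- function(table) {
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(sample_ids(table)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  as.matrix(vegan::vegdist(t(unclass(table)), method = "bray"))
}

check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (any(abs(diag(d)) > 1e-10)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("S", seq_len(nrow(d))),
                        paste0("S", seq_len(nrow(d))))
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of the squared
#' dissimilarities, eigendecomposition, coordinates = eigenvectors scaled by
#' the square root of their eigenvalues. When the input is
#' Euclidean-embeddable the configuration reproduces the distances exactly;
#' otherwise negative eigenvalues appear and are reported untouched (no
#' correction by default, since semimetric indices like Bray-Curtis are
#' commonly ordinated raw), excluded from the coordinates.
#'
#' @param d square symmetric dissimilarity matrix (or `dist`).
#' @param correction `"none"` (default), `"lingoes"`, or `"cailliez"` to make
#'   a semimetric input Euclidean before decomposition.
#' @return A list of class `pcoa_result`: `coordinates` (samples x positive
#'   axes, ordered by decreasing eigenvalue), `eigenvalues` (all, including
#'   negatives), `proportion_explained` (fractions of positive-eigenvalue
#'   variance, one per axis).
#' @export
pcoa <- function(d, correction = c("none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  d <- check_distance_matrix(d)
  if (nrow(d) < 3L) stop("PCoA needs at least 3 samples", call. = FALSE)
  fit <- ape::pcoa(stats::as.dist(d), correction = correction)
  eig <- fit$values$Eigenvalues
  if (correction != "none" && !is.null(fit$values$Corr_eig)) {
    eig <- fit$values$Corr_eig
  }
  coords <- fit$vectors
  if (correction != "none" && !is.null(fit$vectors.cor)) {
    coords <- fit$vectors.cor
  }
  pos <- eig[eig > 0]
  n_axes <- min(ncol(coords), length(pos))
  coords <- coords[, seq_len(n_axes), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis.", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = pos[seq_len(n_axes)] / sum(pos)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  pe <- round(100 * x$proportion_explained[seq_len(min(
    2, length(x$proportion_explained)))], 2)
  cat("PCoA of ", nrow(x$coordinates), " samples: first axes explain ",
      paste0(pe, "%", collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. The statistic is
#' `R = (mean rank between - mean rank within) / (M / 4)` with
#' `M = n (n - 1) / 2`, computed on the average-ranked dissimilarities;
#' R near 1 means groups are well separated, near 0 means no structure.
#' Significance comes from permuting group labels uniformly at random.
#'
#' @param d square symmetric dissimilarity matrix (or `dist`).
#' @param metadata a [sample_metadata] (or named character vector of group
#'   labels); at least 2 groups, each with at least 2 samples.
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutations.
#' @return A list of class `anosim_result`: `R`, `p_value` (the add-one
#'   estimator `(1 + #{permuted R >= observed}) / (1 + n_permutations)`),
#'   `n_permutations`, `seed`.
#' @export
anosim <- function(d, metadata, n_permutations = 999, seed = 1) {
  d <- check_distance_matrix(d)
  if (inherits(metadata, "sample_metadata") || is.data.frame(metadata)) {
    groups <- stats::setNames(metadata$group, metadata$sample_id)
  } else {
    groups <- metadata
  }
  if (!is.null(names(groups))) {
    missing <- setdiff(rownames(d), names(groups))
    if (length(missing)) {
      stop("metadata is missing sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    groups <- groups[rownames(d)]
  } else if (length(groups) != nrow(d)) {
    stop("group labels must match the number of samples", call. = FALSE)
  }
  tab <- table(groups)
  if (length(tab) < 2L) {
    stop("ANOSIM needs at least 2 groups", call. = FALSE)
  }
  if (any(tab < 2L)) {
    stop("every group needs at least 2 samples; offending group(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  fit <- vegan::anosim(stats::as.dist(d), grouping = factor(groups),
                       permutations = n_permutations)
  structure(list(R = unname(fit$statistic), p_value = fit$signif,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p_value, x$n_permutations))
  invisible(x)
}
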