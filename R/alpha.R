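#' Rarefy an OTU table to even depth
#'
#' Randomly subsamples each sample's reads, without replacement, down to
#' exactly `depth` reads, the standard normalization before diversity
#' comparison (e.g. to the lowest per-sample total in the study). OTU rows
#' that become all-zero are retained; dropping them is a separate, explicit
#' decision left to the caller.
#'
#' @param table an [otu_table].
#' @param depth target depth; must not exceed any sample's total. Use
#'   `min(colSums(table))` for the lowest-depth convention.
#' @param seed integer seed making the draw reproducible.
#' @param times number of independent rarefaction draws; with `times > 1`
#'   the element-wise mean of the draws is rounded back to integer counts.
#'   The default is a single one-shot draw.
#' @return A rarefied [otu_table] with every column summing to `depth`
#'   (exactly, when `times = 1`).
#' @export
rarefy <- function(table, depth, seed = 1, times = 1) {
  totals <- colSums(table)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  short <- totals < depth
  if (any(short)) {
    stop("depth ", depth, " exceeds the total reads of sample(s): ",
         paste(names(totals)[short], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  draws <- replicate(times, {
    r <- withCallingHandlers(
      vegan::rrarefy(t(unclass(table)), depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    t(r)
  }, simplify = FALSE)
  counts <- if (times == 1L) draws[[1]] else round(Reduce(`+`, draws) / times)
  otu_table(counts, otu_ids = otu_ids(table), sample_ids = sample_ids(table))
}

#' Shannon diversity index
#'
#' Entropy of the OTU proportion vector, `H = -sum(p_i * log(p_i))` over
#' nonzero proportions. Natural-log units (nats) by default.
#'
#' @param counts vector of non-negative counts with at least one positive
#'   entry.
#' @param base logarithm base; `exp(1)` for nats, 2 or 10 also common.
#' @return Shannon index, `0 <= H <= log(S_obs, base)`.
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- check_abundances(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimator
#'
#' Nonparametric richness from singleton and doubleton counts: the classic
#' estimator `S_obs + F1^2 / (2 * F2)`, switching to the bias-corrected form
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` when no doubletons are present
#' (the classic form is undefined at F2 = 0).
#'
#' @param counts vector of non-negative counts with at least one positive
#'   entry.
#' @return Estimated richness, always `>= S_obs`.
#' @export
chao1 <- function(counts) {
  counts <- check_abundances(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

check_abundances <- function(counts) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative with no missing values", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("all-zero count vector: diversity is undefined", call. = FALSE)
  }
  counts
}

#' Per-sample alpha diversity
#'
#' Observed richness, Shannon, and Chao1 for every sample of a table,
#' typically after [rarefy()].
#'
#' @param table an [otu_table].
#' @param base logarithm base for Shannon (natural log by default).
#' @return data.frame with one row per sample: `sample_id`, `depth`,
#'   `observed_otus`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  counts <- unclass(table)
  data.frame(
    sample_id = sample_ids(table),
    depth = colSums(counts),
    observed_otus = colSums(counts > 0),
    shannon = apply(counts, 2, shannon, base = base),
    chao1 = apply(counts, 2, chao1),
    row.names = NULL, stringsAsFactors = FALSE)
}
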