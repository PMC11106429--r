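#' Configure a synthetic community simulation
#'
#' Defines the design of a simulated amplicon survey: how many OTUs, which
#' treatment groups with how many replicate samples, per-sample sequencing
#' depth, negative-binomial overdispersion, planted blocks of correlated OTUs
#' (the co-occurrence ground truth), and a group effect shifting a fraction
#' of OTUs per group.
#'
#' The defaults emulate a three-treatment irrigation field design (groups FP,
#' DI, MF) profiled by amoA amplicon sequencing, but with 10 replicate
#' samples per group rather than 3 field plots: detecting Spearman
#' correlations at P < 0.01 is impossible at n = 3, so a sample size at
#' which the network stage is statistically meaningful is the default.
#'
#' @param n_otus number of OTUs in the community.
#' @param groups character vector of group labels.
#' @param replicates_per_group number of replicate samples per group (>= 2).
#' @param depth_mean mean sequencing depth (reads per sample).
#' @param depth_cv coefficient of variation of per-sample depth.
#' @param dispersion negative-binomial overdispersion of counts
#'   (variance = mu + dispersion * mu^2; larger = noisier).
#' @param modules data.frame with columns `size` and `intra_correlation`
#'   describing planted blocks of correlated OTUs, e.g. the output of
#'   [planted_modules()]. Default: no planted modules.
#' @param group_effect log-scale mean shift applied to the affected OTUs of
#'   each group (0 = no group structure).
#' @param effect_fraction fraction of OTUs shifted per group.
#' @param abundance_sigma log-normal sigma of the baseline OTU abundance
#'   profile; 1.5 gives the long-tailed rank-abundance curves typical of
#'   amplicon surveys.
#' @param seed integer seed; one seed governs all draws, with per-stage
#'   sub-streams derived deterministically from it.
#' @return A list of class `simulation_config`.
#' @seealso [generate_dataset()]
#' @export
simulation_config <- function(n_otus = 150,
                              groups = c("FP", "DI", "MF"),
                              replicates_per_group = 10,
                              depth_mean = 50000,
                              depth_cv = 0.1,
                              dispersion = 0.5,
                              modules = planted_modules(integer(0)),
                              group_effect = 1,
                              effect_fraction = 0.1,
                              abundance_sigma = 1.5,
                              seed = 1) {
  stopifnot(n_otus >= 1, depth_mean >= 1, depth_cv >= 0, dispersion > 0,
            group_effect >= 0, effect_fraction >= 0, effect_fraction <= 1)
  groups <- as.character(groups)
  if (length(groups) < 1L) stop("at least one group is required", call. = FALSE)
  if (replicates_per_group < 2L) {
    stop("replicates_per_group must be >= 2", call. = FALSE)
  }
  modules <- as.data.frame(modules)
  if (nrow(modules) && !all(c("size", "intra_correlation") %in% names(modules))) {
    stop("modules must have columns 'size' and 'intra_correlation'",
         call. = FALSE)
  }
  if (sum(modules$size) > n_otus) {
    stop("sum of module sizes (", sum(modules$size),
         ") exceeds n_otus (", n_otus, ")", call. = FALSE)
  }
  if (nrow(modules) && any(modules$intra_correlation < 0 |
                           modules$intra_correlation >= 1)) {
    stop("intra_correlation must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_otus = as.integer(n_otus), groups = groups,
                 replicates_per_group = as.integer(replicates_per_group),
                 depth_mean = depth_mean, depth_cv = depth_cv,
                 dispersion = dispersion, modules = modules,
                 group_effect = group_effect,
                 effect_fraction = effect_fraction,
                 abundance_sigma = abundance_sigma,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Describe planted correlation modules
#'
#' @param sizes integer vector of module sizes.
#' @param intra_correlation latent within-module correlation(s) in `[0, 1)`,
#'   recycled over modules.
#' @return data.frame with columns `size` and `intra_correlation`.
#' @export
planted_modules <- function(sizes, intra_correlation = 0.9) {
  sizes <- as.integer(sizes)
  data.frame(size = sizes,
             intra_correlation = rep_len(intra_correlation,
                                         length(sizes)))
}

#' Generate a synthetic OTU dataset with known structure
#'
#' Draws an OTU count table by a Gaussian-copula scheme: a latent
#' multivariate normal with block-diagonal correlation (one block per planted
#' module at its `intra_correlation`, zero elsewhere) is mapped through each
#' OTU's negative-binomial marginal. Marginal means come from a log-normal
#' baseline abundance profile scaled to the sample's depth; `group_effect`
#' multiplies the means of each group's designated OTUs by
#' `exp(group_effect)` in that group's samples. Designated blocks are
#' disjoint across groups (each group gets `effect_fraction * n_otus` OTUs
#' taken deterministically from the tail of the OTU list, away from the
#' planted modules at its head), so groups differ by construction when
#' `group_effect > 0`. Because
#' the copula fixes the rank structure, the planted latent correlation
#' survives into the counts up to discretization, which is exactly what
#' rank-based downstream statistics (Spearman networks, ANOSIM) see.
#'
#' @param config a [simulation_config].
#' @return A list of class `synthetic_dataset` with elements `table`
#'   ([otu_table]), `metadata` ([sample_metadata]), `true_modules` (named
#'   integer vector, `NA` for background OTUs), `true_correlation` (latent
#'   OTU-by-OTU correlation matrix), and `config`.
#' @examples
#' cfg <- simulation_config(n_otus = 40, replicates_per_group = 3,
#'                          depth_mean = 2000,
#'                          modules = planted_modules(c(5, 5)), seed = 42)
#' ds <- generate_dataset(cfg)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config", call. = FALSE)
  }
  n_otus <- config$n_otus
  n_samples <- length(config$groups) * config$replicates_per_group
  group_of <- rep(config$groups, each = config$replicates_per_group)
  otu_names <- sprintf("OTU%03d", seq_len(n_otus))
  sample_names <- paste0(group_of, ".", sequence(rep(
    config$replicates_per_group, length(config$groups))))

  # one global seed; deterministic per-stage sub-streams
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max, 3L)

  # stage 1: baseline relative abundances, long-tailed
  set.seed(stage_seeds[1])
  base <- stats::rlnorm(n_otus, meanlog = 0, sdlog = config$abundance_sigma)
  rel_abund <- base / sum(base)

  # stage 2: per-sample target depths
  set.seed(stage_seeds[2])
  depths <- round(stats::rnorm(n_samples, config$depth_mean,
                               config$depth_cv * config$depth_mean))
  depths <- pmax(depths, 1)

  # group effects: each group gets its own designated, disjoint block of
  # OTUs, assigned deterministically from the tail of the OTU list so that
  # (at the default module layout, which occupies the head) mean shifts and
  # planted correlation blocks stay on different OTUs
  n_affected <- round(config$effect_fraction * n_otus)
  effect_mult <- matrix(1, n_otus, length(config$groups),
                        dimnames = list(otu_names, config$groups))
  if (config$group_effect > 0 && n_affected > 0) {
    if (n_affected * length(config$groups) > n_otus) {
      stop("effect_fraction too large: ", length(config$groups),
           " disjoint blocks of ", n_affected, " OTUs do not fit into ",
           n_otus, " OTUs", call. = FALSE)
    }
    for (g in seq_along(config$groups)) {
      affected <- n_otus - g * n_affected + seq_len(n_affected)
      effect_mult[affected, g] <- exp(config$group_effect)
    }
  }

  # module membership: blocks occupy the leading OTUs in order
  true_modules <- rep(NA_integer_, n_otus)
  names(true_modules) <- otu_names
  sizes <- config$modules$size
  if (length(sizes)) {
    true_modules[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
  }

  # latent block-diagonal correlation
  sigma <- diag(n_otus)
  if (length(sizes)) {
    offset <- 0L
    for (m in seq_along(sizes)) {
      idx <- offset + seq_len(sizes[m])
      r <- config$modules$intra_correlation[m]
      sigma[idx, idx] <- r
      diag(sigma)[idx] <- 1
      offset <- offset + sizes[m]
    }
  }
  dimnames(sigma) <- list(otu_names, otu_names)

  # stage 3: latent normals -> copula -> NB counts
  set.seed(stage_seeds[3])
  z <- matrix(stats::rnorm(n_otus * n_samples), n_otus, n_samples)
  if (length(sizes)) {
    offset <- 0L
    for (m in seq_along(sizes)) {
      idx <- offset + seq_len(sizes[m])
      ch <- chol(sigma[idx, idx])
      z[idx, ] <- t(ch) %*% z[idx, , drop = FALSE]
      offset <- offset + sizes[m]
    }
  }
  u <- stats::pnorm(z)
  group_idx <- match(group_of, config$groups)
  mu <- (rel_abund * effect_mult[, group_idx, drop = FALSE]) *
    rep(depths, each = n_otus)
  size_nb <- 1 / config$dispersion
  counts <- matrix(stats::qnbinom(u, size = size_nb, mu = mu),
                   n_otus, n_samples)

  tab <- otu_table(counts, otu_ids = otu_names, sample_ids = sample_names)
  meta <- sample_metadata(sample_names, group_of)
  structure(list(table = tab, metadata = meta, true_modules = true_modules,
                 true_correlation = sigma, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic OTU dataset: ", nrow(x$table), " OTUs x ", ncol(x$table),
      " samples (", length(unique(x$metadata$group)), " groups), ",
      sum(!is.na(x$true_modules)), " OTUs in ",
      length(unique(stats::na.omit(x$true_modules))), " planted modules\n",
      sep = "")
  invisible(x)
}

#' Ground-truth co-occurrence edges of a synthetic dataset
#'
#' All within-module OTU pairs of the planted correlation blocks: the edge
#' set a perfect network-inference step would recover.
#'
#' @param dataset a `synthetic_dataset`.
#' @return data.frame with columns `from` and `to` (`from` < `to`
#'   lexicographically); zero rows when no modules were planted.
#' @export
ground_truth_edges <- function(dataset) {
  mods <- dataset$true_modules
  edges <- list()
  for (m in unique(stats::na.omit(mods))) {
    members <- sort(names(mods)[!is.na(mods) & mods == m])
    if (length(members) >= 2L) {
      pairs <- utils::combn(members, 2L)
      edges[[length(edges) + 1L]] <-
        data.frame(from = pairs[1, ], to = pairs[2, ],
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(edges)) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, edges)
}

#' Jaccard similarity of two edge sets
#'
#' Used to score planted-edge recovery: intersection over union of the
#' unordered OTU pairs in two edge tables.
#'
#' @param edges_a,edges_b data.frames with columns `from` and `to`.
#' @return Jaccard index in `[0, 1]`; 1 when both sets are empty.
#' @export
edge_jaccard <- function(edges_a, edges_b) {
  key <- function(e) {
    if (!nrow(e)) return(character(0))
    a <- pmin(e$from, e$to)
    b <- pmax(e$from, e$to)
    unique(paste(a, b, sep = "\r"))
  }
  ka <- key(edges_a)
  kb <- key(edges_b)
  un <- union(ka, kb)
  if (!length(un)) return(1)
  length(intersect(ka, kb)) / length(un)
}
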