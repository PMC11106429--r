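#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rank correlations among OTUs across samples, with
#' two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (`p = 0` at `|rho| = 1`). Ranks use average ties. OTUs present in fewer
#' than `min_prevalence` of the samples, and OTUs with constant counts
#' (whose rank correlation is undefined), are dropped before correlation;
#' constant OTUs additionally trigger a warning.
#'
#' Spearman significance at P < 0.01 requires |rho| close to 1 below about
#' n = 10 samples, so a warning is issued for small n; n < 4 is an error.
#'
#' @param table an [otu_table] with at least 4 samples.
#' @param min_prevalence minimum fraction of samples in which an OTU must be
#'   nonzero to enter the correlation (default 0: keep all OTUs).
#' @param exact use the exact permutation null distribution of the rank
#'   statistic for the p-values instead of the t approximation; only
#'   available at n <= 10 samples, and falls back to the approximation for
#'   pairs with tied ranks (where the exact distribution does not apply).
#' @return A list of class `correlation_result`: `rho` and `p` (symmetric
#'   OTU-by-OTU matrices), `n_samples`, `method`, `otu_ids`.
#' @export
spearman_matrix <- function(table, min_prevalence = 0, exact = FALSE) {
  counts <- unclass(table)
  n <- ncol(counts)
  if (n < 4L) {
    stop("Spearman correlation needs at least 4 samples, got ", n,
         call. = FALSE)
  }
  if (n < 10L) {
    warning("only ", n, " samples: correlations significant at P < 0.01 ",
            "require near-perfect |rho|", call. = FALSE)
  }
  prevalence <- rowMeans(counts > 0)
  counts <- counts[prevalence >= min_prevalence, , drop = FALSE]
  constant <- apply(counts, 1, function(x) all(x == x[1]))
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant OTU(s): ",
            paste(utils::head(rownames(counts)[constant], 5),
                  collapse = ", "),
            if (sum(constant) > 5) ", ..." else "", call. = FALSE)
    counts <- counts[!constant, , drop = FALSE]
  }
  if (nrow(counts) < 2L) {
    stop("fewer than 2 OTUs left after filtering", call. = FALSE)
  }
  ranks <- apply(counts, 1, rank)         # samples x OTUs, average ties
  rho <- stats::cor(ranks)                # Pearson on ranks = Spearman
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  if (exact) {
    if (n > 10L) {
      stop("exact p-values are only supported for n <= 10 samples",
           call. = FALSE)
    }
    for (i in seq_len(nrow(counts) - 1L)) {
      for (j in seq(i + 1L, nrow(counts))) {
        pij <- suppressWarnings(stats::cor.test(
          counts[i, ], counts[j, ], method = "spearman",
          exact = TRUE)$p.value)
        p[i, j] <- p[j, i] <- pij
      }
    }
  }
  dimnames(rho) <- dimnames(p) <- list(rownames(counts), rownames(counts))
  structure(list(rho = rho, p = p, n_samples = n, method = "spearman",
                 otu_ids = rownames(counts)),
            class = "correlation_result")
}

#' Build a co-occurrence network by thresholding correlations
#'
#' Retains an edge between two OTUs iff the correlation is strong
#' (`|rho| > rho_min`, strict) and significant (`p < p_max`, strict), the
#' standard "strong and significant" criterion (defaults rho > 0.7,
#' P < 0.01). Both signs count by default since strong negative
#' co-occurrence is as real as positive; `positive_only = TRUE` restricts to
#' `rho > rho_min`. Nodes are the OTUs incident to at least one retained
#' edge, so isolated OTUs do not inflate node counts.
#'
#' @param corr a `correlation_result` from [spearman_matrix()].
#' @param rho_min minimum absolute correlation (exclusive).
#' @param p_max maximum p-value (exclusive).
#' @param positive_only keep only positive correlations.
#' @return A list of class `cooccurrence_network` wrapping an undirected
#'   simple [igraph::graph] whose edges carry `rho` and `sign` attributes,
#'   plus the thresholds used. An empty network (0 nodes) is a valid result.
#' @export
build_network <- function(corr, rho_min = 0.7, p_max = 0.01,
                          positive_only = FALSE) {
  rho <- corr$rho
  p <- corr$p
  keep <- upper.tri(rho) & p < p_max &
    (if (positive_only) rho > rho_min else abs(rho) > rho_min)
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = rownames(rho)[idx[, 1]],
                      to = colnames(rho)[idx[, 2]],
                      rho = rho[keep],
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(graph = g, rho_min = rho_min, p_max = p_max),
            class = "cooccurrence_network")
}

#' Wrap an edge table (or igraph) as a co-occurrence network
#'
#' For networks that do not come from [build_network()] — e.g. graphs read
#' back from disk or reference graphs with known node and edge counts.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `rho`,
#'   or an [igraph::graph].
#' @param nodes optional character vector of node ids, to include isolated
#'   nodes beyond those incident to an edge.
#' @param rho_min,p_max thresholds to record on the object (`NA` if unknown).
#' @return A `cooccurrence_network`.
#' @export
as_cooccurrence_network <- function(edges, nodes = NULL, rho_min = NA,
                                    p_max = NA) {
  if (igraph::is_igraph(edges)) {
    g <- edges
  } else {
    if (is.null(edges$rho)) edges$rho <- NA_real_
    edges$sign <- ifelse(is.na(edges$rho) | edges$rho >= 0,
                         "positive", "negative")
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
  }
  structure(list(graph = g, rho_min = rho_min, p_max = p_max),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network: ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges",
      if (!is.na(x$rho_min)) sprintf(" (|rho| > %g, p < %g)",
                                     x$rho_min, x$p_max) else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname build_network
#' @param network a `cooccurrence_network`.
#' @export
network_nodes <- function(network) igraph::V(network$graph)$name

#' @rdname build_network
#' @export
network_edges <- function(network) {
  g <- network$graph
  if (igraph::ecount(g) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      rho = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE))
  }
  ends <- igraph::as_edgelist(g)
  rho <- igraph::E(g)$rho
  if (is.null(rho)) rho <- rep(NA_real_, nrow(ends))
  sgn <- igraph::E(g)$sign
  if (is.null(sgn)) sgn <- ifelse(is.na(rho) | rho >= 0,
                                  "positive", "negative")
  data.frame(from = ends[, 1], to = ends[, 2], rho = rho, sign = sgn,
             stringsAsFactors = FALSE)
}

#' Network topology metrics
#'
#' The standard co-occurrence descriptors of one network: node and edge
#' counts, average degree `2E/N`, edge density `2E/(N(N-1))`, linkage
#' density ("complexity") `E/N`, average shortest-path length over all
#' connected pairs (disconnected pairs excluded — multi-component networks
#' are the rule for thresholded correlation graphs), average local
#' clustering coefficient (nodes of degree < 2 contribute 0), and, when a
#' module partition is supplied, Newman modularity Q and the module count.
#'
#' @param network a `cooccurrence_network`.
#' @param modules optional named membership vector from [detect_modules()].
#' @return A list of class `network_topology`. For an empty network all
#'   metrics are `NA` (undefined), not zero.
#' @export
topology <- function(network, modules = NULL) {
  g <- network$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0L) {
    out <- list(nodes = 0L, edges = 0L, edge_density = NA_real_,
                average_degree = NA_real_, average_path_length = NA_real_,
                average_clustering_coefficient = NA_real_,
                complexity = NA_real_, modularity = NA_real_,
                n_modules = NA_integer_)
    return(structure(out, class = "network_topology"))
  }
  q <- NA_real_
  n_mod <- NA_integer_
  if (!is.null(modules)) {
    membership <- modules[igraph::V(g)$name]
    if (anyNA(membership)) {
      stop("module map does not cover all network nodes", call. = FALSE)
    }
    q <- igraph::modularity(g, membership)
    n_mod <- length(unique(membership))
  }
  structure(list(
    nodes = n,
    edges = e,
    edge_density = 2 * e / (n * (n - 1)),
    average_degree = 2 * e / n,
    average_path_length = if (e > 0) {
      igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    } else NA_real_,
    average_clustering_coefficient =
      igraph::transitivity(g, type = "localaverage", isolates = "zero"),
    complexity = e / n,
    modularity = q,
    n_modules = n_mod), class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat("Network topology\n")
  fmt <- function(v) if (is.na(v)) "NA" else format(round(v, 4))
  for (f in names(x)) cat(sprintf("  %-32s %s\n", f, fmt(x[[f]])))
  invisible(x)
}

#' @export
as.data.frame.network_topology <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Detect modules by Louvain modularity maximization
#'
#' Louvain community detection at resolution 1.0 on the unweighted graph,
#' seeded for reproducibility. Module labels are canonicalized by decreasing
#' module size (ties broken by first node appearance), so module 1 is always
#' the largest.
#'
#' @param network a `cooccurrence_network` with at least one edge.
#' @param seed integer seed.
#' @return Named integer vector: node id -> module id.
#' @export
detect_modules <- function(network, seed = 1) {
  g <- network$graph
  if (igraph::ecount(g) == 0L) {
    stop("cannot detect modules in a network with no edges", call. = FALSE)
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = 1)
  membership <- igraph::membership(cl)
  sizes <- table(membership)
  order_by_size <- order(-as.integer(sizes),
                         match(names(sizes), unique(as.character(membership))))
  relabel <- stats::setNames(seq_along(sizes), names(sizes)[order_by_size])
  out <- relabel[as.character(membership)]
  stats::setNames(as.integer(out), igraph::V(g)$name)
}

#' Within- and among-module connectivity (Zi-Pi) and node roles
#'
#' Guimera-Amaral topological roles. For node i in module s,
#' `Zi = (k_is - mean(k_s)) / sd(k_s)` standardizes its within-module degree
#' against the other nodes of its module (Zi = 0 when the module's
#' within-degree standard deviation is 0 — identical nodes are not hubs);
#' `Pi = 1 - sum_s (k_is / k_i)^2` measures how evenly its edges spread over
#' modules (0 = all edges in one module). Roles follow the 2.5 / 0.62
#' threshold grid via [classify_role()].
#'
#' @param network a `cooccurrence_network`.
#' @param modules named membership vector covering every network node.
#' @return data.frame with one row per node: `otu_id`, `module_id`,
#'   `degree`, `zi`, `pi`, `role`.
#' @export
zi_pi <- function(network, modules) {
  g <- network$graph
  nodes <- igraph::V(g)$name
  membership <- modules[nodes]
  if (anyNA(membership)) {
    stop("module map does not cover all network nodes", call. = FALSE)
  }
  deg <- igraph::degree(g)
  ends <- igraph::as_edgelist(g)
  mod_ids <- sort(unique(membership))
  # k[i, s]: edges of node i landing in module s
  k <- matrix(0L, length(nodes), length(mod_ids),
              dimnames = list(nodes, as.character(mod_ids)))
  if (nrow(ends)) {
    m_from <- as.character(membership[ends[, 2]])
    m_to <- as.character(membership[ends[, 1]])
    for (j in seq_len(nrow(ends))) {
      k[ends[j, 1], m_from[j]] <- k[ends[j, 1], m_from[j]] + 1L
      k[ends[j, 2], m_to[j]] <- k[ends[j, 2], m_to[j]] + 1L
    }
  }
  own <- as.character(membership)
  k_within <- k[cbind(seq_along(nodes), match(own, colnames(k)))]
  zi <- numeric(length(nodes))
  for (s in as.character(mod_ids)) {
    in_s <- own == s
    mu <- mean(k_within[in_s])
    sdev <- stats::sd(k_within[in_s])
    zi[in_s] <- if (is.na(sdev) || sdev == 0) 0 else
      (k_within[in_s] - mu) / sdev
  }
  pi_coef <- 1 - rowSums((k / pmax(deg, 1))^2)
  data.frame(otu_id = nodes, module_id = as.integer(membership),
             degree = as.integer(deg), zi = zi, pi = pi_coef,
             role = classify_role(zi, pi_coef),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a node's topological role from (Zi, Pi)
#'
#' The four-way grid at Zi = 2.5 and Pi = 0.62: peripheral
#' (Zi < 2.5, Pi < 0.62), connector (Zi < 2.5, Pi > 0.62), module hub
#' (Zi > 2.5, Pi < 0.62), network hub (Zi > 2.5, Pi > 0.62). Values exactly
#' on a threshold fall in the lower category (strict greater-than reading).
#'
#' @param zi within-module degree z-score(s).
#' @param pi participation coefficient(s) in `[0, 1]`.
#' @return character vector of roles.
#' @export
classify_role <- function(zi, pi) {
  stopifnot(length(zi) == length(pi))
  if (any(pi < -1e-9 | pi > 1 + 1e-9)) {
    stop("participation coefficient must be in [0, 1]", call. = FALSE)
  }
  hub <- zi > 2.5
  conn <- pi > 0.62
  ifelse(hub & conn, "network_hub",
         ifelse(hub, "module_hub",
                ifelse(conn, "connector", "peripheral")))
}

#' Write a network to disk
#'
#' Edge-list CSV (columns `source`, `target`, `rho`, `sign`) or GraphML with
#' the same edge attributes plus per-node `degree` and, when supplied,
#' `module` attributes. Correlations are written at 6 decimal places in the
#' edge list; GraphML stores full doubles.
#'
#' @param network a `cooccurrence_network`.
#' @param path output path.
#' @param format `"edgelist"` (CSV) or `"graphml"`.
#' @param modules optional named membership vector stored as a node
#'   attribute (GraphML only).
#' @export
write_network <- function(network, path, format = c("edgelist", "graphml"),
                          modules = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    edges <- network_edges(network)
    out <- data.frame(source = edges$from, target = edges$to,
                      rho = sprintf("%.6f", edges$rho), sign = edges$sign,
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    g <- network$graph
    igraph::V(g)$degree <- igraph::degree(g)
    if (!is.null(modules)) {
      igraph::V(g)$module <- as.integer(modules[igraph::V(g)$name])
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network back from disk
#'
#' @param path file written by [write_network()].
#' @param format `"edgelist"` or `"graphml"`.
#' @return A `cooccurrence_network`.
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    as_cooccurrence_network(data.frame(from = df$source, to = df$target,
                                       rho = df$rho,
                                       stringsAsFactors = FALSE))
  } else {
    as_cooccurrence_network(igraph::read_graph(path, format = "graphml"))
  }
}
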