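# Independent oracles and tiny fixtures shared across tests.

# Spearman via the classic tie-free rank formula 1 - 6*sum(d^2)/(n(n^2-1)).
# Only valid without ties; kept deliberately independent of the package's
# rank-then-Pearson route.
spearman_bruteforce <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# A 3 OTU x 3 sample toy table.
toy_table <- function() {
  otu_table(matrix(c(5L, 0L, 3L,
                     2L, 1L, 4L,
                     0L, 7L, 1L), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("OTU", 1:3),
                                   paste0("S", 1:3))))
}

# Hand-built correlation_result so thresholding can be tested in isolation.
fake_correlation <- function(rho, p, ids = NULL) {
  if (is.null(ids)) ids <- paste0("OTU", seq_len(nrow(rho)))
  dimnames(rho) <- dimnames(p) <- list(ids, ids)
  structure(list(rho = rho, p = p, n_samples = NA_integer_,
                 method = "spearman", otu_ids = ids),
            class = "correlation_result")
}

# Two disjoint k-cliques as a cooccurrence_network.
two_cliques <- function(k = 5) {
  g <- igraph::disjoint_union(igraph::make_full_graph(k),
                              igraph::make_full_graph(k))
  igraph::V(g)$name <- paste0("n", seq_len(2 * k))
  as_cooccurrence_network(g)
}
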