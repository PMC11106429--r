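test_that("Spearman matrix reproduces hand-computable coefficients", {
  mk <- function(...) {
    rows <- list(...)
    otu_table(matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
                     dimnames = list(paste0("o", seq_along(rows)),
                                     paste0("s", seq_along(rows[[1]])))))
  }
  tab <- mk(c(1L, 2L, 3L, 4L, 5L),
            c(2L, 4L, 6L, 8L, 10L),     # monotone with o1 -> rho 1
            c(5L, 4L, 3L, 2L, 1L),      # reversed -> rho -1
            c(2L, 1L, 4L, 3L, 5L))      # d^2 = (1,1,1,1,0) -> 1 - 24/120
  sm <- suppressWarnings(spearman_matrix(tab))
  expect_equal(sm$rho["o1", "o2"], 1)
  expect_equal(sm$rho["o1", "o3"], -1)
  expect_equal(sm$rho["o1", "o4"], 0.8)
  expect_equal(sm$rho["o1", "o4"],
               spearman_bruteforce(1:5, c(2, 1, 4, 3, 5)))
  expect_equal(sm$p["o1", "o2"], 0)    # |rho| = 1 -> p = 0
  expect_true(isSymmetric(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 4))
})

test_that("Spearman matches the brute-force rank formula and cor.test", {
  set.seed(17)
  for (i in 1:50) {
    x <- round(runif(8) * 1e6)
    y <- round(runif(8) * 1e6)
    if (anyDuplicated(x) || anyDuplicated(y)) next
    tab <- otu_table(rbind(a = x, b = y))
    sm <- suppressWarnings(spearman_matrix(tab))
    expect_lt(abs(sm$rho["a", "b"] - spearman_bruteforce(x, y)), 1e-12)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    expect_equal(sm$p["a", "b"], unname(ct$p.value), tolerance = 1e-10)
  }
})

test_that("exact permutation p-values are available at small n", {
  x <- c(10L, 30L, 20L, 50L, 40L, 60L)
  y <- c(15L, 40L, 10L, 55L, 30L, 70L)
  tab <- otu_table(rbind(a = x, b = y))
  sm <- suppressWarnings(spearman_matrix(tab, exact = TRUE))
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(sm$p["a", "b"], unname(ref$p.value))
  # exact p differs from the t approximation at this n
  sm_t <- suppressWarnings(spearman_matrix(tab))
  expect_false(isTRUE(all.equal(sm$p["a", "b"], sm_t$p["a", "b"])))

  big <- otu_table(matrix(as.integer(rpois(24, 20)), nrow = 2,
                          dimnames = list(c("a", "b"), NULL)))
  expect_error(spearman_matrix(big, exact = TRUE), "n <= 10")
})

test_that("prevalence and constant-OTU filters drop rows before correlation", {
  counts <- rbind(o1 = c(5L, 6L, 7L, 8L, 9L, 10L),
                  o2 = c(9L, 7L, 5L, 3L, 2L, 1L),
                  rare = c(2L, 0L, 0L, 0L, 0L, 0L),
                  flat = c(4L, 4L, 4L, 4L, 4L, 4L))
  tab <- otu_table(counts)
  sm <- NULL
  w <- capture_warnings(sm <- spearman_matrix(tab, min_prevalence = 0.5))
  expect_true(any(grepl("constant", w)))
  expect_setequal(sm$otu_ids, c("o1", "o2"))
  expect_error(spearman_matrix(otu_table(counts[, 1:3])), "4 samples")
})

test_that("edge thresholding is strict on both rho and p", {
  rho <- matrix(c(1, 0.71, 0.70, -0.9,
                  0.71, 1, 0.2, 0.1,
                  0.70, 0.2, 1, 0.3,
                  -0.9, 0.1, 0.3, 1), 4, 4)
  p <- matrix(0.005, 4, 4); diag(p) <- 0
  p[1, 4] <- p[4, 1] <- 0.02
  corr <- fake_correlation(rho, p)
  net <- build_network(corr, rho_min = 0.7, p_max = 0.01)
  edges <- network_edges(net)
  # 0.71 retained; 0.70 exactly rejected; -0.9 rejected on p
  expect_equal(nrow(edges), 1)
  expect_setequal(c(edges$from, edges$to), c("OTU1", "OTU2"))
  # isolated OTUs are not nodes
  expect_setequal(network_nodes(net), c("OTU1", "OTU2"))
  # negative edges count unless positive_only
  p[1, 4] <- p[4, 1] <- 0.001
  net2 <- build_network(fake_correlation(rho, p))
  expect_equal(nrow(network_edges(net2)), 2)
  expect_setequal(network_edges(net2)$sign, c("positive", "negative"))
  net3 <- build_network(fake_correlation(rho, p), positive_only = TRUE)
  expect_equal(nrow(network_edges(net3)), 1)
  # no qualifying pair -> empty network is a valid result
  net4 <- build_network(fake_correlation(diag(4), p))
  expect_equal(length(network_nodes(net4)), 0)
})

test_that("raising rho_min never adds edges", {
  ds <- generate_dataset(simulation_config(n_otus = 50, groups = "A",
                                           replicates_per_group = 20,
                                           depth_mean = 10000,
                                           group_effect = 0,
                                           modules = planted_modules(
                                             c(8, 8), 0.7),
                                           seed = 4))
  sm <- spearman_matrix(ds$table)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(r) {
    nrow(network_edges(build_network(sm, rho_min = r, p_max = 0.05)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("topology metrics satisfy their defining identities", {
  tri <- as_cooccurrence_network(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
  t_tri <- topology(tri)
  expect_equal(t_tri$average_clustering_coefficient, 1)
  expect_equal(t_tri$average_path_length, 1)
  expect_equal(t_tri$edge_density, 1)

  path3 <- as_cooccurrence_network(
    data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_equal(topology(path3)$average_path_length, 4 / 3)

  # identities 2E/N, 2E/(N(N-1)), E/N on an arbitrary random graph
  set.seed(6)
  g <- igraph::sample_gnm(60, 150)
  igraph::V(g)$name <- paste0("v", 1:60)
  topo <- topology(as_cooccurrence_network(g))
  expect_equal(topo$average_degree, 2 * 150 / 60)
  expect_equal(topo$edge_density, 2 * 150 / (60 * 59))
  expect_equal(topo$complexity, 150 / 60)
  expect_equal(topo$average_degree, 2 * topo$complexity)

  # empty network reports undefined metrics, not zeros
  empty <- build_network(fake_correlation(diag(3), matrix(1, 3, 3)))
  t_empty <- topology(empty)
  expect_true(is.na(t_empty$average_degree))
  expect_true(is.na(t_empty$average_path_length))
  expect_equal(t_empty$nodes, 0L)
})

test_that("Louvain modules are seeded, canonical, and recover planted cliques", {
  net <- two_cliques(5)
  m1 <- detect_modules(net, seed = 3)
  m2 <- detect_modules(net, seed = 3)
  expect_identical(m1, m2)
  expect_equal(length(unique(m1)), 2)
  expect_equal(igraph::modularity(net$graph, m1), 0.5)
  # canonical labels: module 1 is the largest
  sizes <- table(detect_modules(two_cliques(4), seed = 1))
  expect_true(all(diff(as.integer(sizes)) <= 0))

  # complete graph: a single module
  full <- as_cooccurrence_network(igraph::set_vertex_attr(
    igraph::make_full_graph(6), "name", value = letters[1:6]))
  expect_equal(length(unique(detect_modules(full, seed = 1))), 1)
  # Q of the everything-in-one-module partition is 0 for any graph
  expect_equal(igraph::modularity(net$graph,
                                  rep(1, igraph::vcount(net$graph))), 0)

  expect_error(detect_modules(build_network(
    fake_correlation(diag(3), matrix(1, 3, 3)))), "no edges")
})

test_that("Zi and Pi follow the Guimera-Amaral definitions", {
  # star module {h,b,c,d} bridged to a pair module {e,f}
  net <- as_cooccurrence_network(
    data.frame(from = c("h", "h", "h", "h", "e"),
               to   = c("b", "c", "d", "e", "f")))
  mods <- c(h = 1, b = 1, c = 1, d = 1, e = 2, f = 2)
  zp <- zi_pi(net, mods)
  rownames(zp) <- zp$otu_id

  # all-internal leaf: Pi = 0
  expect_equal(zp["b", "pi"], 0)
  # hub h: degree 4, 3 internal + 1 external -> 1 - (3/4)^2 - (1/4)^2
  expect_equal(zp["h", "pi"], 0.375)
  # e splits its degree evenly over two modules -> Pi = 0.5
  expect_equal(zp["e", "pi"], 0.5)
  # within-module degrees in module 1 are (3,1,1,1): mean 1.5, sd 1
  expect_equal(zp["h", "zi"], 1.5)
  expect_equal(zp["b", "zi"], -0.5)
  # module 2 has zero within-degree SD -> Zi = 0
  expect_equal(zp["e", "zi"], 0)
  # pi <= 1 - 1/m for nodes touching m <= 2 modules
  expect_true(all(zp$pi <= 1 - 1 / 2 + 1e-12))

  # uniform cliques: every Zi = 0, every node peripheral
  zp_clique <- zi_pi(two_cliques(4),
                     stats::setNames(rep(1:2, each = 4), paste0("n", 1:8)))
  expect_true(all(zp_clique$zi == 0))
  expect_true(all(zp_clique$role == "peripheral"))

  expect_error(zi_pi(net, mods[1:4]), "cover")
})

test_that("role classification uses the 2.5/0.62 grid with lower-boundary ties", {
  expect_equal(classify_role(3.0, 0.10), "module_hub")
  expect_equal(classify_role(1.0, 0.70), "connector")
  expect_equal(classify_role(3.1, 0.80), "network_hub")
  expect_equal(classify_role(0.0, 0.10), "peripheral")
  # boundary values fall in the lower category
  expect_equal(classify_role(2.5, 0.62), "peripheral")
  expect_equal(classify_role(2.5, 0.70), "connector")
  expect_equal(classify_role(3.0, 0.62), "module_hub")
  expect_error(classify_role(1, 1.4), "\\[0, 1\\]")
})

test_that("networks round-trip through edge-list CSV and GraphML", {
  ds <- generate_dataset(simulation_config(n_otus = 40, groups = "A",
                                           replicates_per_group = 30,
                                           depth_mean = 20000,
                                           group_effect = 0,
                                           modules = planted_modules(
                                             c(6, 6), 0.9),
                                           seed = 23))
  net <- build_network(spearman_matrix(ds$table))
  expect_gt(nrow(network_edges(net)), 0)
  mods <- detect_modules(net, seed = 1)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_network(net, csv, format = "edgelist")
  header <- readLines(csv, n = 1)
  expect_equal(header, "source,target,rho,sign")
  back <- read_network(csv, format = "edgelist")
  expect_setequal(network_nodes(back), network_nodes(net))
  expect_equal(nrow(network_edges(back)), nrow(network_edges(net)))
  # 6-decimal convention in the edge list
  expect_equal(network_edges(back)$rho, network_edges(net)$rho,
               tolerance = 1e-6)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, format = "graphml", modules = mods)
  back2 <- read_network(gml, format = "graphml")
  expect_setequal(network_nodes(back2), network_nodes(net))
  e_old <- network_edges(net)
  e_new <- network_edges(back2)
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key(e_new), key(e_old))
  expect_equal(sort(e_new$rho), sort(e_old$rho), tolerance = 1e-6)

  # single-edge and empty networks serialize cleanly
  one <- as_cooccurrence_network(data.frame(from = "a", to = "b", rho = 0.8))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_network(one, f1, format = "edgelist")
  expect_equal(length(readLines(f1)), 2)
  empty <- build_network(fake_correlation(diag(3), matrix(1, 3, 3)))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_network(empty, f2, format = "graphml")
  expect_equal(nrow(network_edges(read_network(f2, format = "graphml"))), 0)

  expect_error(write_network(net, csv, format = "gexf"), "should be one of")
})
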