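make_net <- function(edges, domains = NULL) {
  # assemble a conet_graph by hand for unit tests
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (is.null(domains)) domains <- rep("bacteria", igraph::vcount(g))
  g <- igraph::set_vertex_attr(g, "domain", value = domains)
  if (!"rho" %in% igraph::edge_attr_names(g))
    g <- igraph::set_edge_attr(g, "rho", value = 0.9)
  g <- igraph::set_edge_attr(g, "q", value = 0.001)
  g <- igraph::set_edge_attr(g, "sign",
                             value = ifelse(igraph::E(g)$rho >= 0, "+", "-"))
  structure(list(graph = g, r_threshold = 0.7, alpha = 0.05,
                 prevalence = 0, n_samples = 10,
                 n_taxa_tested = igraph::vcount(g),
                 n_pairs_tested = choose(igraph::vcount(g), 2)),
            class = "conet_graph")
}

clique_edges <- function(ids) {
  p <- t(utils::combn(ids, 2))
  data.frame(from = p[, 1], to = p[, 2], stringsAsFactors = FALSE)
}

test_that("build_network keeps only dual-threshold edges and drops isolates", {
  set.seed(30)
  n <- 12
  base <- stats::rnorm(n)
  # a mass-dominant independent background keeps compositional closure from
  # correlating the noise taxa with each other
  noise_b <- matrix(stats::rpois(n * 30, 20) + 1, n,
                    dimnames = list(NULL, paste0("noise", 1:30)))
  counts_b <- cbind(x1 = round(30 * exp(0.5 * base)) + 1,
                    x2 = round(30 * exp(0.5 * base +
                                          0.05 * stats::rnorm(n))) + 1,
                    noise_b)
  rownames(counts_b) <- paste0("S", 1:n)
  noise_f <- matrix(stats::rpois(n * 10, 20) + 1, n,
                    dimnames = list(NULL, paste0("fnoise", 1:10)))
  counts_f <- cbind(y1 = round(30 * exp(0.5 * base +
                                          0.05 * stats::rnorm(n))) + 1,
                    noise_f)
  rownames(counts_f) <- paste0("S", 1:n)
  net <- build_network(abundance_table(counts_b, "bacteria"),
                       abundance_table(counts_f, "fungi"),
                       r_threshold = 0.7, alpha = 0.05)
  g <- net$graph
  expect_true(all(abs(igraph::E(g)$rho) > 0.7))
  expect_true(all(igraph::E(g)$q < 0.05))
  expect_true(all(igraph::E(g)$sign == ifelse(igraph::E(g)$rho >= 0,
                                              "+", "-")))
  # the three co-varying taxa form a triangle across domains; pure-noise
  # taxa are isolated and dropped
  expect_setequal(igraph::V(g)$name, c("x1", "x2", "y1"))
  expect_equal(igraph::ecount(g), 3)
  expect_setequal(unique(igraph::V(g)$domain), c("bacteria", "fungi"))
  expect_error(build_network(
    abundance_table(counts_b[1:4, ], "bacteria"),
    abundance_table(counts_f[1:4, ], "fungi")), "at least 5")
})

test_that("null data yields an (almost) empty network", {
  set.seed(31)
  cb <- matrix(stats::rpois(16 * 40, 20), 16,
               dimnames = list(paste0("S", 1:16), paste0("b", 1:40)))
  cf <- matrix(stats::rpois(16 * 20, 20), 16,
               dimnames = list(paste0("S", 1:16), paste0("f", 1:20)))
  net <- build_network(abundance_table(cb, "bacteria"),
                       abundance_table(cf, "fungi"))
  expect_lte(igraph::ecount(net$graph), 1)
})

test_that("topology has the K4 / path closed forms and an oracle-checked
           clustering coefficient", {
  k4 <- make_net(clique_edges(paste0("n", 1:4)))
  expect_warning(topo0 <- topology(make_net(
    data.frame(from = character(0), to = character(0)))), "empty")
  expect_equal(topo0$edges, 0)
  topo <- topology(k4)
  expect_equal(topo$density, 1)
  expect_equal(topo$average_clustering, 1)
  expect_equal(topo$average_degree, 3)
  path3 <- make_net(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_equal(topology(path3)$average_clustering, 0)
  # random graph: local clustering against brute-force triangle counts
  set.seed(32)
  ids <- paste0("v", 1:10)
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < 0.4
  net <- make_net(data.frame(from = pairs[keep, 1], to = pairs[keep, 2]))
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  cc <- vapply(seq_len(nrow(adj)), function(v) {
    k <- sum(adj[v, ])
    if (k < 2) 0 else 2 * oracle_triangles(adj, v) / (k * (k - 1))
  }, numeric(1))
  expect_equal(topology(net)$average_clustering, mean(cc), tolerance = 1e-12)
  expect_equal(topology(net)$average_degree,
               2 * igraph::ecount(net$graph) / igraph::vcount(net$graph))
})

test_that("module detection separates disjoint cliques, Q matches oracle", {
  net <- make_net(rbind(clique_edges(paste0("a", 1:4)),
                        clique_edges(paste0("b", 1:4))))
  det <- detect_modules(net)
  mem <- det$membership
  expect_equal(length(unique(mem[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(mem[paste0("b", 1:4)])), 1)
  expect_equal(length(unique(mem)), 2)
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  expect_equal(det$modularity,
               oracle_modularity(adj, mem[rownames(adj)]), tolerance = 1e-12)
  expect_equal(det$modularity, 0.5, tolerance = 1e-12)  # two equal cliques
  # single clique: one module
  one <- detect_modules(make_net(clique_edges(paste0("c", 1:5))))
  expect_equal(length(unique(one$membership)), 1)
})

test_that("zi_pi matches closed forms and the per-definition oracle", {
  # star center in one module: center has the maximal Zi
  star <- make_net(data.frame(from = "hub", to = paste0("leaf", 1:6)))
  mem <- stats::setNames(rep(1, 7), c("hub", paste0("leaf", 1:6)))
  zp <- zi_pi(star, mem)
  expect_equal(zp$Pi, rep(0, 7))            # all edges inside the module
  expect_equal(max(zp$Zi), zp$Zi[zp$taxon == "hub"])
  adj <- igraph::as_adjacency_matrix(star$graph, sparse = FALSE)
  orc <- oracle_zipi(adj, mem[rownames(adj)])
  expect_equal(zp$Zi[match(rownames(adj), zp$taxon)], orc$zi,
               tolerance = 1e-12)
  # node with edges split evenly across m modules: Pi = 1 - 1/m
  spokes <- make_net(data.frame(from = "c", to = c("m1", "m2", "m3")))
  mem3 <- c(c = 4, m1 = 1, m2 = 2, m3 = 3)
  zp3 <- zi_pi(spokes, mem3)
  expect_equal(zp3$Pi[zp3$taxon == "c"], 1 - 1 / 3)
  expect_error(zi_pi(spokes, mem3[-1]), "without module")
  # random graph + random partition vs oracle; Zi means 0 within modules
  set.seed(33)
  ids <- paste0("v", 1:12)
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < 0.35
  net <- make_net(data.frame(from = pairs[keep, 1], to = pairs[keep, 2]))
  nodes <- igraph::V(net$graph)$name
  memr <- stats::setNames(sample(1:3, length(nodes), replace = TRUE), nodes)
  zp <- zi_pi(net, memr)
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  orc <- oracle_zipi(adj, memr[rownames(adj)])
  ix <- match(rownames(adj), zp$taxon)
  expect_equal(zp$Zi[ix], orc$zi, tolerance = 1e-12)
  expect_equal(zp$Pi[ix], orc$pi, tolerance = 1e-12)
  for (m in unique(memr)) {
    zs <- zp$Zi[zp$module == m]
    if (stats::sd(zp$within_degree[zp$module == m]) > 0)
      expect_equal(mean(zs), 0, tolerance = 1e-12)
  }
  expect_true(all(zp$Pi >= 0 & zp$Pi <= 1 - 1 / length(unique(memr)) + 1e-12))
})

test_that("role classification follows the Zi/Pi thresholds", {
  zp <- data.frame(taxon = paste0("t", 1:6),
                   module = 1, degree = 5, within_degree = 3,
                   Zi = c(3.0, 1.0, 3.0, 2.5, 0.0, 2.6),
                   Pi = c(0.5, 0.7, 0.7, 0.62, 0.62, 0.62))
  out <- classify_roles(zp)
  expect_equal(out$role, c("module hub", "connector", "network hub",
                           "peripheral", "peripheral", "module hub"))
  expect_setequal(attr(out, "keystone"), c("t1", "t2", "t3", "t6"))
})

test_that("analyze_network annotates vertices consistently", {
  net <- make_net(rbind(clique_edges(paste0("a", 1:4)),
                        clique_edges(paste0("b", 1:4))))
  res <- analyze_network(net)
  g <- res$net$graph
  expect_setequal(igraph::vertex_attr_names(g),
                  c("name", "domain", "module", "Zi", "Pi", "role"))
  expect_equal(res$topology$modularity, res$modularity)
  expect_equal(sort(unique(igraph::V(g)$module)),
               sort(unique(unname(res$membership))))
})
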