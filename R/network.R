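# Cross-domain co-occurrence network: construction, topology, module
# detection, Zi-Pi connectivity and keystone-role classification.

#' Build a bacterial-fungal co-occurrence network
#'
#' Taxa from both tables that pass the prevalence filter are tested
#' all-against-all (within and between domains) with Spearman correlation on
#' relative abundances; p-values are Benjamini-Hochberg adjusted over all
#' tested pairs of this build as one family; an edge is kept iff
#' `|rho| > r_threshold` and `q < alpha`. Nodes left without any edge are
#' dropped.
#'
#' @param bact,fungi `abundance_table`s over a shared sample set (>= 5
#'   samples).
#' @param r_threshold correlation magnitude cutoff (default 0.7).
#' @param alpha FDR cutoff (default 0.05).
#' @param prevalence minimum fraction of samples in which a taxon must be
#'   present (count > 0) to be tested; default 1/3.
#' @return A `conet_graph`: list with the igraph `graph` (vertex attributes
#'   `domain`, `phylum`, `genus`; edge attributes `rho`, `q`, `sign`) plus
#'   the build parameters and counts of taxa/pairs tested.
#' @export
build_network <- function(bact, fungi, r_threshold = 0.7, alpha = 0.05,
                          prevalence = 1 / 3) {
  shared <- intersect(rownames(bact$counts), rownames(fungi$counts))
  if (length(shared) < 5)
    stop("need at least 5 shared samples for rank correlation, got ",
         length(shared))
  pull <- function(tab) {
    counts <- tab$counts[shared, , drop = FALSE]
    keep <- colMeans(counts > 0) >= prevalence
    rel <- sweep(counts, 1, pmax(rowSums(counts), 1), "/")
    rel[, keep, drop = FALSE]
  }
  rb <- pull(bact)
  rf <- pull(fungi)
  x <- cbind(rb, rf)
  domain <- c(rep("bacteria", ncol(rb)), rep("fungi", ncol(rf)))
  names(domain) <- colnames(x)
  tax <- rbind(bact$taxonomy[match(colnames(rb), bact$taxonomy$taxon_id),
                             c("taxon_id", "phylum", "genus")],
               fungi$taxonomy[match(colnames(rf), fungi$taxonomy$taxon_id),
                              c("taxon_id", "phylum", "genus")])
  sm <- spearman_matrix(x)
  lt <- which(lower.tri(sm$rho), arr.ind = TRUE)
  q <- bh_adjust(sm$p[lt])
  rho <- sm$rho[lt]
  keep <- abs(rho) > r_threshold & q < alpha
  edges <- data.frame(from = colnames(x)[lt[keep, 2]],
                      to = colnames(x)[lt[keep, 1]],
                      rho = rho[keep], q = q[keep],
                      sign = ifelse(rho[keep] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "domain",
                               value = domain[igraph::V(g)$name])
  ix <- match(igraph::V(g)$name, tax$taxon_id)
  g <- igraph::set_vertex_attr(g, "phylum", value = tax$phylum[ix])
  g <- igraph::set_vertex_attr(g, "genus", value = tax$genus[ix])
  structure(list(graph = g, r_threshold = r_threshold, alpha = alpha,
                 prevalence = prevalence, n_samples = length(shared),
                 n_taxa_tested = ncol(x), n_pairs_tested = nrow(lt)),
            class = "conet_graph")
}

#' @export
print.conet_graph <- function(x, ...) {
  cat(sprintf(
    "conet_graph: %d nodes, %d edges (|rho|>%s, q<%s; %d taxa tested)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    format(x$r_threshold), format(x$alpha), x$n_taxa_tested))
  invisible(x)
}

#' Detect network modules by greedy modularity optimization
#'
#' Runs fast-greedy modularity maximization on the unweighted, sign-blind
#' graph. An edgeless graph yields singleton modules with Q = 0.
#'
#' @param net a `conet_graph`.
#' @param seed kept for interface stability; the greedy algorithm is
#'   deterministic given the node order, which is fixed at build time.
#' @return list: `membership` (named integer vector), `modularity` (Q of the
#'   partition), `method`.
#' @export
detect_modules <- function(net, seed = 1) {
  g <- net$graph
  if (igraph::ecount(g) == 0) {
    mem <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    return(list(membership = mem, modularity = 0, method = "fast_greedy"))
  }
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                         edge.attr.comb = "first")
  comm <- with_seed(seed, igraph::cluster_fast_greedy(gs, weights = NULL))
  # deterministic tie-break: among cuts within 1e-12 of the maximal Q,
  # take the coarsest partition (e.g. a single clique stays one module)
  best_mem <- igraph::membership(comm)
  best_q <- igraph::modularity(gs, best_mem)
  for (k in seq_len(igraph::vcount(gs))) {
    mem_k <- tryCatch(suppressWarnings(igraph::cut_at(comm, no = k)),
                      error = function(e) NULL)
    if (is.null(mem_k)) next
    q_k <- igraph::modularity(gs, mem_k)
    if (q_k > best_q + 1e-12 ||
        (q_k >= best_q - 1e-12 && max(mem_k) < max(best_mem))) {
      best_mem <- mem_k
      best_q <- q_k
    }
  }
  mem <- stats::setNames(as.integer(best_mem), igraph::V(g)$name)
  list(membership = mem, modularity = best_q, method = "fast_greedy")
}

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' `Zi = (k_is - mean_s) / sd_s` where `k_is` is node i's number of edges to
#' its own module s and the mean/sd are over s's members (0 when the sd is
#' 0 or the module is a singleton). `Pi = 1 - sum_t (k_it / k_i)^2` over all
#' modules t, with `k_i` the node's total degree (0 for degree-0 nodes).
#'
#' @param net a `conet_graph`.
#' @param membership named module assignment covering every node (e.g. from
#'   [detect_modules()], or planted truth).
#' @return data.frame: `taxon`, `module`, `degree`, `within_degree`, `Zi`,
#'   `Pi`.
#' @export
zi_pi <- function(net, membership) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(membership)))
    stop("node without module assignment: ",
         setdiff(nodes, names(membership))[1])
  mem <- membership[nodes]
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  a <- (a > 0) + 0
  deg <- rowSums(a)
  mods <- unique(mem)
  # k_it: node x module edge-count matrix
  kit <- sapply(mods, function(m) rowSums(a[, mem == m, drop = FALSE]))
  kit <- matrix(kit, nrow = length(nodes),
                dimnames = list(nodes, as.character(mods)))
  kis <- kit[cbind(seq_along(nodes), match(mem, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    ix <- which(mem == m)
    s <- stats::sd(kis[ix])
    zi[ix] <- if (length(ix) > 1 && s > 0) (kis[ix] - mean(kis[ix])) / s else 0
  }
  pi <- ifelse(deg == 0, 0, 1 - rowSums((kit / pmax(deg, 1))^2))
  data.frame(taxon = nodes, module = unname(mem), degree = unname(deg),
             within_degree = unname(kis), Zi = unname(zi), Pi = unname(pi),
             stringsAsFactors = FALSE)
}

#' Topological role of each node and the keystone set
#'
#' Network hubs have Zi > 2.5 and Pi > 0.62; module hubs Zi > 2.5 only;
#' connectors Pi > 0.62 only; everything else is peripheral. Keystone taxa
#' are the union of the three non-peripheral roles.
#'
#' @param zipi data.frame from [zi_pi()].
#' @param zi_threshold,pi_threshold role thresholds (defaults 2.5, 0.62).
#' @return `zipi` with a `role` column, plus attribute `keystone` (taxon
#'   ids).
#' @export
classify_roles <- function(zipi, zi_threshold = 2.5, pi_threshold = 0.62) {
  hi_z <- zipi$Zi > zi_threshold
  hi_p <- zipi$Pi > pi_threshold
  zipi$role <- ifelse(hi_z & hi_p, "network hub",
                      ifelse(hi_z, "module hub",
                             ifelse(hi_p, "connector", "peripheral")))
  attr(zipi, "keystone") <- zipi$taxon[zipi$role != "peripheral"]
  zipi
}

#' Topology summary of a co-occurrence network
#'
#' Node/edge counts, domain fractions, positive/negative edge fractions,
#' average degree `2E/N`, average local clustering coefficient (0 for
#' degree < 2 nodes), density `2E/(N(N-1))` and the modularity Q of the
#' detected (or supplied) partition.
#'
#' @param net a `conet_graph`.
#' @param membership optional module assignment; detected if omitted.
#' @return One-row data.frame of topology metrics.
#' @export
topology <- function(net, membership = NULL) {
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0 || e == 0) {
    warning("empty graph: all topology metrics are 0")
    return(data.frame(nodes = n, edges = e, bacterial_fraction = 0,
                      fungal_fraction = 0, positive_fraction = 0,
                      negative_fraction = 0, average_degree = 0,
                      average_clustering = 0, density = 0, modularity = 0))
  }
  if (is.null(membership)) {
    det <- detect_modules(net)
    membership <- det$membership
    q_mod <- det$modularity
  } else {
    q_mod <- igraph::modularity(g, as.integer(
      factor(membership[igraph::V(g)$name])))
  }
  dom <- igraph::V(g)$domain
  sgn <- igraph::E(g)$sign
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  data.frame(
    nodes = n, edges = e,
    bacterial_fraction = mean(dom == "bacteria"),
    fungal_fraction = mean(dom == "fungi"),
    positive_fraction = mean(sgn == "+"),
    negative_fraction = mean(sgn == "-"),
    average_degree = 2 * e / n,
    average_clustering = mean(cc),
    density = 2 * e / (n * (n - 1)),
    modularity = q_mod)
}

#' Run the full node-level network analysis
#'
#' Convenience wrapper: detects modules, computes Zi/Pi, classifies roles,
#' stores everything as vertex attributes and returns the pieces.
#'
#' @param net a `conet_graph`.
#' @param seed passed to [detect_modules()].
#' @return list: `net` (graph annotated with module/Zi/Pi/role), `zipi`
#'   (with roles), `membership`, `modularity`, `keystone`, `topology`.
#' @export
analyze_network <- function(net, seed = 1) {
  det <- detect_modules(net, seed)
  zp <- classify_roles(zi_pi(net, det$membership))
  g <- net$graph
  ix <- match(igraph::V(g)$name, zp$taxon)
  g <- igraph::set_vertex_attr(g, "module", value = zp$module[ix])
  g <- igraph::set_vertex_attr(g, "Zi", value = zp$Zi[ix])
  g <- igraph::set_vertex_attr(g, "Pi", value = zp$Pi[ix])
  g <- igraph::set_vertex_attr(g, "role", value = zp$role[ix])
  net$graph <- g
  list(net = net, zipi = zp, membership = det$membership,
       modularity = det$modularity, keystone = attr(zp, "keystone"),
       topology = topology(net, det$membership))
}
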