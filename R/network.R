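# Co-occurrence network inference: Spearman correlation screen over pooled
# bacterial/fungal/archaeal features, module detection, topology metrics,
# Zi-Pi node roles and per-treatment subnetworks.

#' Spearman correlation screen for co-occurrence edges
#'
#' Computes pairwise Spearman correlations between features (on per-sample
#' relative abundances) and retains pairs with `|rho| > r_min` and
#' `p < p_max`. p-values use the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` with average ranks for ties. Features
#' below the prevalence filter, or with constant abundance (undefined rho),
#' are excluded (the latter with a warning). Set `positive_only = TRUE` for
#' the literal `rho > r_min` reading that drops negative associations.
#'
#' @param features a `soilpem_features` table (domains are pooled)
#' @param r_min correlation threshold (strict, default 0.75)
#' @param p_max p-value threshold (strict, default 0.01)
#' @param prevalence_min minimum fraction of samples in which a feature must
#'   be present (default 0.2)
#' @param positive_only drop negative correlations (default FALSE)
#' @param relative use relative abundances (default) rather than raw counts
#' @return tibble of edge candidates: `feature_a`, `feature_b`, `rho`, `p`
#' @export
correlation_screen <- function(features, r_min = 0.75, p_max = 0.01,
                               prevalence_min = 0.2, positive_only = FALSE,
                               relative = TRUE) {
  cm <- feature_counts(features)
  n <- ncol(cm)
  if (n < 5) abort("need at least 5 samples for the correlation screen")
  keep <- rowMeans(cm > 0) >= prevalence_min
  cm <- cm[keep, , drop = FALSE]
  if (relative) cm <- sweep(cm, 2, pmax(colSums(cm), 1), "/")
  const <- apply(cm, 1, function(x) var(x) == 0)
  if (any(const)) {
    warn(sprintf("%d constant feature(s) excluded from the screen", sum(const)))
    cm <- cm[!const, , drop = FALSE]
  }
  if (nrow(cm) < 2) {
    return(tibble(feature_a = character(), feature_b = character(),
                  rho = numeric(), p = numeric()))
  }
  rho <- cor(t(cm), method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r_v <- rho[idx]
  p_v <- p[idx]
  pass <- if (positive_only) r_v > r_min else abs(r_v) > r_min
  pass <- pass & p_v < p_max
  tibble(
    feature_a = rownames(cm)[idx[pass, 1]],
    feature_b = rownames(cm)[idx[pass, 2]],
    rho = r_v[pass],
    p = p_v[pass]
  )
}

#' Build a co-occurrence network from screened edges
#'
#' Nodes are the features incident to at least one retained edge; edge weights
#' are the signed Spearman correlations.
#'
#' @param edges a [correlation_screen()] result
#' @param features the `soilpem_features` table the screen was run on (source
#'   of domain and taxonomy labels)
#' @return a `soilpem_network` list: `graph` (igraph), `nodes`, `edges`,
#'   `metrics` (filled by [topology_metrics()])
#' @export
build_network <- function(edges, features) {
  if (nrow(edges) == 0) abort("no edges passed the screen; empty network")
  ids <- sort(unique(c(edges$feature_a, edges$feature_b)))
  meta <- features[match(ids, features$feature_id),
                   c("feature_id", "domain", "taxonomy")]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$feature_a, to = edges$feature_b,
                   weight = edges$rho),
    directed = FALSE,
    vertices = data.frame(name = meta$feature_id, domain = meta$domain)
  )
  net <- structure(
    list(graph = g,
         nodes = mutate(as_tibble(meta), module = NA_integer_),
         edges = edges, metrics = NULL),
    class = "soilpem_network"
  )
  net$metrics <- topology_metrics(net)
  net
}

#' Detect modules by seeded multilevel (Louvain) modularity optimization
#'
#' Runs greedy multilevel community detection on the unweighted graph under a
#' fixed seed and stores the module id per node. The reported Q is the
#' standard Newman-Girvan modularity of the resulting partition on the
#' unweighted graph.
#'
#' @param network a `soilpem_network`
#' @param seed integer seed
#' @return the network with `nodes$module` filled and
#'   `metrics$modularity` / `metrics$n_modules` set
#' @export
detect_modules <- function(network, seed = 1L) {
  g <- network$graph
  if (igraph::ecount(g) < 1) abort("cannot detect modules in an empty graph")
  comm <- with_seed(seed, igraph::cluster_louvain(g, weights = NA))
  memb <- igraph::membership(comm)
  network$nodes$module <- as.integer(memb[network$nodes$feature_id])
  q <- igraph::modularity(g, memb, weights = rep(1, igraph::ecount(g)))
  network$metrics <- topology_metrics(network)
  network$metrics$modularity <- q
  network$metrics$n_modules <- length(unique(memb))
  network
}

#' Topology metrics of a co-occurrence network
#'
#' Node/edge counts, average degree (2E/N, the complexity measure), average
#' path length and diameter on the largest connected component, and the mean
#' local clustering coefficient with isolated and degree-1 nodes contributing
#' zero.
#'
#' @param network a `soilpem_network` (or bare igraph)
#' @return one-row tibble of metrics
#' @export
topology_metrics <- function(network) {
  g <- if (inherits(network, "igraph")) network else network$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) abort("empty graph")
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comps$membership == which.max(comps$csize)))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[igraph::degree(g) < 2] <- 0
  tibble(
    n_nodes = n,
    n_edges = e,
    average_degree = 2 * e / n,
    average_path_length = igraph::mean_distance(giant, directed = FALSE,
                                                weights = NA),
    diameter = igraph::diameter(giant, directed = FALSE, weights = NA),
    average_clustering = mean(cc),
    modularity = NA_real_,
    n_modules = NA_integer_
  )
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' For node i in module s: `Zi = (k_i,s - mean(k_,s)) / sd(k_,s)` over the
#' within-module degrees of module s (Zi = 0 when the module SD is zero);
#' `Pi = 1 - sum_s (k_is / k_i)^2` (0 for isolated nodes). Roles follow the
#' thresholds Zi = 2.5 and Pi = 0.62: network hubs exceed both, module hubs
#' exceed Zi only, connectors exceed Pi only, all others are peripherals.
#'
#' @param network a `soilpem_network` with modules assigned
#'   (see [detect_modules()])
#' @return tibble: `feature_id`, `domain`, `module`, `degree`, `zi`, `pi`,
#'   `role`
#' @export
zi_pi <- function(network) {
  nodes <- network$nodes
  if (anyNA(nodes$module)) abort("every node needs a module label; run detect_modules()")
  g <- network$graph
  ids <- igraph::V(g)$name
  memb <- nodes$module[match(ids, nodes$feature_id)]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- (adj != 0) * 1
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  # k_is: edges from node i into module s
  k_is <- vapply(mods, function(s) rowSums(adj[, memb == s, drop = FALSE]),
                 numeric(length(ids)))
  if (length(ids) == 1) k_is <- matrix(k_is, nrow = 1)
  k_own <- k_is[cbind(seq_along(ids), match(memb, mods))]
  zi <- numeric(length(ids))
  for (s in mods) {
    in_s <- memb == s
    mu <- mean(k_own[in_s])
    sg <- sd(k_own[in_s])
    zi[in_s] <- if (is.na(sg) || sg == 0) 0 else (k_own[in_s] - mu) / sg
  }
  pi <- ifelse(k == 0, 0, 1 - rowSums((k_is / pmax(k, 1))^2))
  role <- dplyr::case_when(
    zi > 2.5 & pi > 0.62 ~ "network_hub",
    zi > 2.5 ~ "module_hub",
    pi > 0.62 ~ "connector",
    TRUE ~ "peripheral"
  )
  tibble(
    feature_id = ids,
    domain = nodes$domain[match(ids, nodes$feature_id)],
    module = memb, degree = as.numeric(k), zi = zi, pi = as.numeric(pi),
    role = role
  )
}

#' Classify a (Zi, Pi) pair into its topological role
#'
#' @param zi within-module degree z-score
#' @param pi among-module connectivity
#' @return character role (vectorized)
#' @examples
#' node_role(c(3.0, 1.0, 2.6, 0), c(0.5, 0.7, 0.65, 0.1))
#' @export
node_role <- function(zi, pi) {
  dplyr::case_when(
    zi > 2.5 & pi > 0.62 ~ "network_hub",
    zi > 2.5 ~ "module_hub",
    pi > 0.62 ~ "connector",
    TRUE ~ "peripheral"
  )
}

#' Per-treatment subnetwork by node presence
#'
#' Induces the subgraph on nodes whose feature has a nonzero total count
#' across the treatment's samples, and recomputes topology metrics (module
#' labels are inherited from the full network).
#'
#' @param network a `soilpem_network`
#' @param features the feature table used to build the network
#' @param metadata a [sample_metadata()] tibble
#' @param treatment treatment label
#' @return a `soilpem_network` for the subgraph
#' @export
extract_subnetwork <- function(network, features, metadata, treatment) {
  samples <- metadata$sample_id[as.character(metadata$treatment) == treatment]
  if (length(samples) == 0) abort(paste0("no samples in treatment ", treatment))
  cm <- feature_counts(features)
  present <- rownames(cm)[rowSums(cm[, samples, drop = FALSE]) > 0]
  keep <- intersect(igraph::V(network$graph)$name, present)
  sg <- igraph::induced_subgraph(network$graph, keep)
  nodes <- filter(network$nodes, .data$feature_id %in% keep)
  el <- igraph::as_data_frame(sg, what = "edges")
  out <- structure(
    list(graph = sg, nodes = nodes,
         edges = tibble(feature_a = el$from, feature_b = el$to,
                        rho = el$weight, p = NA_real_),
         metrics = NULL),
    class = "soilpem_network"
  )
  out$metrics <- topology_metrics(out)
  if (!anyNA(nodes$module) && igraph::ecount(sg) > 0) {
    memb <- setNames(nodes$module, nodes$feature_id)[igraph::V(sg)$name]
    out$metrics$modularity <- igraph::modularity(sg, memb,
                                                 weights = rep(1, igraph::ecount(sg)))
    out$metrics$n_modules <- length(unique(memb))
  }
  out
}

#' Keystone (hub) taxa report
#'
#' Module and network hubs with domain and phylum labels, sorted by role then
#' descending Zi, plus per-domain node percentages of the whole network
#' (which sum to 100).
#'
#' @param topology a [zi_pi()] result
#' @param features the feature table (taxonomy source)
#' @return list with `hubs` tibble (feature_id, domain, phylum, module,
#'   degree, zi, pi, role) and `domain_composition` tibble (domain, n_nodes,
#'   percent)
#' @export
keystone_report <- function(topology, features) {
  hubs <- filter(topology, .data$role %in% c("network_hub", "module_hub"))
  hubs <- mutate(
    hubs,
    phylum = parse_phylum(features$taxonomy[match(.data$feature_id,
                                                  features$feature_id)])
  )
  hubs <- arrange(hubs, factor(.data$role, levels = c("network_hub", "module_hub")),
                  dplyr::desc(.data$zi))
  comp <- summarise(group_by(topology, .data$domain), n_nodes = n(), .groups = "drop")
  comp <- mutate(comp, percent = 100 * .data$n_nodes / sum(.data$n_nodes))
  list(hubs = select(hubs, "feature_id", "domain", "phylum", "module",
                     "degree", "zi", "pi", "role"),
       domain_composition = comp)
}

#' @export
tidy.soilpem_network <- function(x, ...) {
  if (anyNA(x$nodes$module)) x$nodes else zi_pi(x)
}

#' @export
glance.soilpem_network <- function(x, ...) x$metrics

#' @export
print.soilpem_network <- function(x, ...) {
  cat("co-occurrence network:", x$metrics$n_nodes, "nodes,",
      x$metrics$n_edges, "edges\n")
  print(x$metrics)
  invisible(x)
}

#' Write an edge list as tab-delimited text
#' @param network a `soilpem_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(network$edges, path, progress = FALSE)
  invisible(path)
}
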