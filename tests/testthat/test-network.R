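triangle_edges <- function(ids) {
  tibble::tibble(feature_a = ids[c(1, 2, 3)], feature_b = ids[c(2, 3, 1)],
                 rho = 1, p = 0)
}

fake_features <- function(ids, domain = "bacteria", taxonomy = "k__B;p__X") {
  ft <- tibble::tibble(feature_id = ids, domain = domain, taxonomy = taxonomy)
  class(ft) <- c("soilpem_features", class(ft))
  ft
}

net_from_edges <- function(edges, ids = NULL, modules = NULL) {
  ids <- ids %||% sort(unique(c(edges$feature_a, edges$feature_b)))
  net <- build_network(edges, fake_features(ids))
  if (!is.null(modules)) {
    net$nodes$module <- modules[net$nodes$feature_id]
  }
  net
}

test_that("correlation screen keeps perfect monotone pairs and honours strict thresholds", {
  md <- tiny_metadata(5, 4)
  n <- nrow(md)
  set.seed(1)
  base <- sample(100, n)
  counts <- rbind(
    f1 = base, f2 = base * 3 + 7,                 # identical ranks: rho = 1
    f3 = sample(100, n), f4 = sample(100, n),
    f5 = rep(4L, n)                               # constant: excluded
  )
  colnames(counts) <- md$sample_id
  ft <- feature_table(counts, "bacteria", "k__B;p__X", md)
  expect_warning(edges <- correlation_screen(ft, relative = FALSE), "constant")
  expect_true(any(edges$feature_a == "f1" & edges$feature_b == "f2"))
  expect_equal(edges$rho[edges$feature_a == "f1" & edges$feature_b == "f2"], 1)
  # thresholds are strict: an edge exactly at r_min is rejected
  rho_obs <- edges$rho[1]
  edges_strict <- suppressWarnings(
    correlation_screen(ft, r_min = rho_obs, relative = FALSE)
  )
  expect_false(any(abs(edges_strict$rho - rho_obs) < 1e-15))
})

test_that("screen p-values agree with exhaustive rank-permutation enumeration at n=5", {
  md <- tiny_metadata(5, 1)
  x <- c(40, 10, 20, 30, 50)   # rank pattern (4,1,2,3,5): rho = 0.4 vs y
  y <- c(10, 20, 30, 40, 50)
  counts <- rbind(f1 = x, f2 = y)
  colnames(counts) <- md$sample_id
  ft <- feature_table(round(counts), "bacteria", "t", md)
  edges <- correlation_screen(ft, r_min = 0, p_max = 1.0000001,
                              prevalence_min = 0, relative = FALSE)
  rho_obs <- cor(x, y, method = "spearman")
  # brute-force null over all 120 rank permutations (two-sided)
  perms <- soilpem:::all_permutations(5)
  rho_null <- vapply(perms, function(p) cor(x[p], y, method = "spearman"),
                     numeric(1))
  p_exact <- mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
  expect_equal(edges$rho, rho_obs, tolerance = 1e-12)
  expect_lt(abs(edges$p - p_exact), 0.02)
})

test_that("screen is symmetric in pair order and feature permutation", {
  ds <- tiny_dataset(6)
  e1 <- correlation_screen(ds$features)
  ftp <- ds$features[sample(nrow(ds$features)), ]
  class(ftp) <- class(ds$features)
  e2 <- correlation_screen(ftp)
  key <- function(e) sort(paste(pmin(e$feature_a, e$feature_b),
                                pmax(e$feature_a, e$feature_b)))
  expect_identical(key(e1), key(e2))
})

test_that("module detection: disjoint triangles give Q = 0.5, complete graph Q = 0", {
  ids <- letters[1:6]
  edges <- dplyr::bind_rows(triangle_edges(ids[1:3]), triangle_edges(ids[4:6]))
  net <- detect_modules(net_from_edges(edges), seed = 1)
  expect_equal(net$metrics$n_modules, 2)
  expect_equal(net$metrics$modularity, 0.5, tolerance = 1e-12)
  # brute-force partition evaluation of the same partition
  memb <- setNames(net$nodes$module, net$nodes$feature_id)
  expect_equal(net$metrics$modularity, modularity_oracle(edges, memb),
               tolerance = 1e-12)

  pairs <- t(combn(4, 2))
  k4 <- tibble::tibble(feature_a = letters[pairs[, 1]],
                       feature_b = letters[pairs[, 2]], rho = 1, p = 0)
  netk <- detect_modules(net_from_edges(k4), seed = 1)
  expect_equal(netk$metrics$n_modules, 1)
  expect_equal(netk$metrics$modularity, 0, tolerance = 1e-12)
})

test_that("spiked latent groups are recovered as modules (Rand index > 0.9)", {
  ft <- tiny_dataset(9)$features
  g1 <- ft$feature_id[1:10]
  g2 <- ft$feature_id[31:40]
  ft2 <- spike_network_structure(ft, list(a = g1, b = g2), strength = 0.95,
                                 seed = 3)
  edges <- suppressWarnings(correlation_screen(ft2, prevalence_min = 0))
  net <- detect_modules(build_network(edges, ft2), seed = 1)
  found <- net$nodes[net$nodes$feature_id %in% c(g1, g2), ]
  truth <- as.integer(found$feature_id %in% g1)
  # Rand index between true grouping and detected modules
  pairs <- t(combn(nrow(found), 2))
  same_truth <- truth[pairs[, 1]] == truth[pairs[, 2]]
  same_found <- found$module[pairs[, 1]] == found$module[pairs[, 2]]
  rand <- mean(same_truth == same_found)
  expect_gt(rand, 0.9)
  # spiked correlations are strong within groups, near zero across
  cm <- feature_counts(ft2)
  r_within <- cor(t(cm[g1, ]), method = "spearman")
  r_cross <- cor(t(cm[g1, ]), t(cm[g2, ]), method = "spearman")
  expect_gt(mean(r_within[upper.tri(r_within)]), 0.85)
  expect_lt(abs(mean(r_cross)), 0.15)
  expect_error(spike_network_structure(ft, list(a = g1, b = g1[1])), "disjoint")
})

test_that("strength-zero spikes leave only null-level edge counts", {
  ft <- tiny_dataset(10)$features
  ids <- ft$feature_id[1:30]
  ft0 <- spike_network_structure(ft, list(a = ids), strength = 0, seed = 5)
  edges <- suppressWarnings(correlation_screen(ft0, prevalence_min = 0))
  among <- edges$feature_a %in% ids & edges$feature_b %in% ids
  # null expectation for |rho| > 0.75 & p < 0.01 at n = 20 is well under 1%
  expect_lt(sum(among) / choose(30, 2), 0.01)
})

test_that("single spiked group covering all taxa yields one dominant module", {
  ft <- tiny_dataset(11)$features
  ft1 <- spike_network_structure(ft, list(all = ft$feature_id),
                                 strength = 0.9, seed = 2)
  edges <- suppressWarnings(correlation_screen(ft1, prevalence_min = 0))
  net <- detect_modules(build_network(edges, ft1), seed = 1)
  main <- max(table(net$nodes$module))
  expect_gt(main / nrow(net$nodes), 0.8)
})

test_that("topology metrics match hand-enumerated graphs", {
  tri <- net_from_edges(triangle_edges(c("a", "b", "c")))
  m <- tri$metrics
  expect_equal(m$average_degree, 2)
  expect_equal(m$average_clustering, 1)
  expect_equal(m$average_path_length, 1)
  expect_equal(m$diameter, 1)

  # path graph a-b-c-d: 6 pairs with distances (1,2,3,1,2,1)
  p4 <- tibble::tibble(feature_a = c("a", "b", "c"), feature_b = c("b", "c", "d"),
                       rho = 1, p = 0)
  m4 <- net_from_edges(p4)$metrics
  expect_equal(m4$average_path_length, 10 / 6, tolerance = 1e-12)
  expect_equal(m4$diameter, 3)
  expect_equal(m4$average_clustering, 0)
})

test_that("adding an edge never increases average path length", {
  set.seed(13)
  ids <- paste0("n", 1:8)
  pairs <- t(combn(8, 2))
  sel <- sample(nrow(pairs), 10)
  edges <- tibble::tibble(feature_a = ids[pairs[sel, 1]],
                          feature_b = ids[pairs[sel, 2]], rho = 1, p = 0)
  apl0 <- net_from_edges(edges, ids = ids)$metrics$average_path_length
  extra <- setdiff(seq_len(nrow(pairs)), sel)[1]
  edges2 <- dplyr::bind_rows(edges, tibble::tibble(
    feature_a = ids[pairs[extra, 1]], feature_b = ids[pairs[extra, 2]],
    rho = 1, p = 0
  ))
  apl1 <- net_from_edges(edges2, ids = ids)$metrics$average_path_length
  expect_lte(apl1, apl0 + 1e-12)
})

test_that("Zi-Pi closed forms and role thresholds", {
  # two triangles joined by one bridge: bridge endpoints split edges across modules
  ids <- letters[1:6]
  edges <- dplyr::bind_rows(
    triangle_edges(ids[1:3]), triangle_edges(ids[4:6]),
    tibble::tibble(feature_a = "c", feature_b = "d", rho = 1, p = 0)
  )
  modules <- setNames(rep(c(1L, 2L), each = 3), ids)
  net <- net_from_edges(edges, modules = modules)
  topo <- zi_pi(net)
  # node 'a': all edges inside its module -> Pi = 0
  expect_equal(topo$pi[topo$feature_id == "a"], 0)
  # node 'c': degree 3, 2 inside / 1 outside -> Pi = 1 - (4/9 + 1/9)
  expect_equal(topo$pi[topo$feature_id == "c"], 1 - 5 / 9, tolerance = 1e-12)

  # degree 4 split evenly across 2 modules -> Pi = 0.5
  star <- tibble::tibble(feature_a = "x", feature_b = c("p", "q", "r", "s"),
                         rho = 1, p = 0)
  mods <- c(x = 1L, p = 1L, q = 1L, r = 2L, s = 2L)
  topo2 <- zi_pi(net_from_edges(star, modules = mods))
  expect_equal(topo2$pi[topo2$feature_id == "x"], 0.5, tolerance = 1e-12)

  # role thresholds with network_hub precedence
  expect_equal(node_role(c(3.0, 1.0, 2.6, 2.4), c(0.5, 0.7, 0.65, 0.5)),
               c("module_hub", "connector", "network_hub", "peripheral"))
})

test_that("Zi has mean 0 and SD 1 within modules of a random modular graph", {
  ds <- tiny_dataset(12)
  edges <- suppressWarnings(correlation_screen(ds$features, r_min = 0.6))
  skip_if(nrow(edges) < 5)
  net <- detect_modules(build_network(edges, ds$features), seed = 1)
  topo <- zi_pi(net)
  for (m in unique(topo$module)) {
    z <- topo$zi[topo$module == m]
    if (length(z) > 1 && sd(z) > 0) {
      expect_equal(mean(z), 0, tolerance = 1e-10)
      expect_equal(sd(z), 1, tolerance = 1e-10)
    }
  }
})

test_that("subnetwork induction follows treatment presence", {
  ds <- tiny_dataset(13)
  edges <- correlation_screen(ds$features)
  net <- detect_modules(build_network(edges, ds$features), seed = 1)
  # treatment containing all samples reproduces the full network
  md_all <- sample_metadata(ds$metadata$sample_id, rep("CK", 20),
                            seq_len(20))
  full <- extract_subnetwork(net, ds$features, md_all, "CK")
  expect_equal(full$metrics$n_nodes, net$metrics$n_nodes)
  expect_equal(full$metrics$n_edges, net$metrics$n_edges)

  # a feature absent from a treatment loses its node there
  sub_ck <- extract_subnetwork(net, ds$features, ds$metadata, "CK")
  cm <- feature_counts(ds$features)
  ck_samples <- ds$metadata$sample_id[ds$metadata$treatment == "CK"]
  absent <- rownames(cm)[rowSums(cm[, ck_samples]) == 0]
  expect_false(any(sub_ck$nodes$feature_id %in% absent))
  expect_error(extract_subnetwork(net, ds$features, ds$metadata, "OPTX"),
               "no samples")
})

test_that("fertilization-activated taxa enlarge the OPTM subnetwork over CK", {
  ds <- generate_dataset(generator_config(seed = 5))
  edges <- correlation_screen(ds$features)
  net <- detect_modules(build_network(edges, ds$features), seed = 1)
  sub_ck <- extract_subnetwork(net, ds$features, ds$metadata, "CK")
  sub_om <- extract_subnetwork(net, ds$features, ds$metadata, "OPTM")
  expect_gt(sub_om$metrics$n_nodes, sub_ck$metrics$n_nodes)
  expect_gt(sub_om$metrics$n_edges, sub_ck$metrics$n_edges)
})

test_that("keystone report lists hubs with sane ordering and composition", {
  # star K_{1,20} under a single module: centre has maximal Zi
  ids <- c("hub", paste0("leaf", 1:20))
  star <- tibble::tibble(feature_a = "hub", feature_b = ids[-1], rho = 1, p = 0)
  mods <- setNames(rep(1L, 21), ids)
  net <- net_from_edges(star, modules = mods)
  topo <- zi_pi(net)
  rep_out <- keystone_report(topo, fake_features(ids))
  expect_equal(rep_out$hubs$feature_id[1], "hub")
  expect_equal(nrow(rep_out$hubs),
               sum(topo$role %in% c("module_hub", "network_hub")))
  expect_equal(sum(rep_out$domain_composition$percent), 100)

  # graph with nothing above thresholds -> empty report
  tri <- detect_modules(net_from_edges(triangle_edges(c("a", "b", "c"))), seed = 1)
  topo_tri <- zi_pi(tri)
  expect_equal(nrow(keystone_report(topo_tri, fake_features(c("a", "b", "c")))$hubs), 0)
})
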