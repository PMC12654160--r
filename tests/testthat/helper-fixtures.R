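# Shared fixtures, built in code at test time.

# small, fast synthetic study (few taxa, shallow depth)
tiny_config <- function(seed = 1, n_replicates = 4, ...) {
  generator_config(
    n_replicates = n_replicates,
    richness = c(bacteria = 60, fungi = 20, archaea = 10),
    depth = 3000,
    seed = seed,
    ...
  )
}

tiny_dataset <- function(seed = 1, ...) generate_dataset(tiny_config(seed, ...))

tiny_metadata <- function(n_treat = 2, n_rep = 2) {
  trts <- c("CK", "OPT", "OPTN", "OPTP", "OPTM")[seq_len(n_treat)]
  sample_metadata(
    sample_id = paste0(rep(trts, each = n_rep), "_", rep(seq_len(n_rep), n_treat)),
    treatment = rep(trts, each = n_rep),
    replicate = rep(seq_len(n_rep), n_treat)
  )
}

# latent chain X -> M -> Y with reflective indicator blocks, for PLS-PM tests
gen_plspm_chain <- function(n, b1 = 0.7, b2 = 0.6, loading = 0.9, seed = 1,
                            k = 3) {
  set.seed(seed)
  l1 <- rnorm(n)
  l2 <- b1 * l1 + sqrt(1 - b1^2) * rnorm(n)
  l3 <- b2 * l2 + sqrt(1 - b2^2) * rnorm(n)
  ind <- function(l, prefix) {
    m <- sapply(seq_len(k), function(i) loading * l + sqrt(1 - loading^2) * rnorm(n))
    colnames(m) <- paste0(prefix, seq_len(k))
    m
  }
  tibble::as_tibble(cbind(ind(l1, "f"), ind(l2, "m"), ind(l3, "y")))
}

chain_spec <- function(k = 3) {
  plspm_spec(
    blocks = list(fert = paste0("f", 1:k), pfrac = paste0("m", 1:k),
                  yield = paste0("y", 1:k)),
    paths = list(pfrac = "fert", yield = "pfrac")
  )
}

# independent Newman-Girvan modularity: Q = sum_s (e_ss - a_s^2) on the
# unweighted graph, computed directly from the edge list
modularity_oracle <- function(edges, membership) {
  m <- nrow(edges)
  ms <- membership[edges$feature_a]
  mt <- membership[edges$feature_b]
  q <- 0
  for (s in unique(membership)) {
    e_ss <- sum(ms == s & mt == s) / m
    a_s <- (sum(ms == s) + sum(mt == s)) / (2 * m)
    q <- q + e_ss - a_s^2
  }
  q
}

# independent Duncan oracle: pairwise significance from span range tests with
# containment protection; returns a k x k logical matrix (TRUE = significant)
# over groups sorted by decreasing mean
duncan_pairwise_oracle <- function(values, groups, alpha = 0.05) {
  gm <- sort(tapply(values, groups, mean), decreasing = TRUE)
  gn <- tapply(values, groups, length)[names(gm)]
  an <- stats::anova(stats::lm(values ~ factor(groups)))
  mse <- an$`Mean Sq`[2]
  dfe <- an$Df[2]
  n_eff <- length(gn) / sum(1 / gn)
  k <- length(gm)
  sig <- matrix(FALSE, k, k, dimnames = list(names(gm), names(gm)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      span <- j - i + 1
      crit <- stats::qtukey((1 - alpha)^(span - 1), span, dfe) * sqrt(mse / n_eff)
      sig[i, j] <- sig[j, i] <- (gm[i] - gm[j]) > crit
    }
  }
  # containment: pairs inside any non-significant stretch are non-significant
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) {
        for (a in i:(j - 1)) for (b in (a + 1):j) sig[a, b] <- sig[b, a] <- FALSE
      }
    }
  }
  sig
}

shares_letter <- function(groups_tbl) {
  k <- nrow(groups_tbl)
  out <- matrix(FALSE, k, k, dimnames = list(groups_tbl$group, groups_tbl$group))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      li <- strsplit(groups_tbl$letter[i], "")[[1]]
      lj <- strsplit(groups_tbl$letter[j], "")[[1]]
      out[i, j] <- length(intersect(li, lj)) > 0
    }
  }
  out
}
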