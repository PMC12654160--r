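# Alpha diversity (Shannon, Chao1), Bray-Curtis dissimilarity and NMDS
# ordination of community profiles.

#' Shannon diversity (natural log)
#'
#' `H = -sum p_i ln p_i` over taxa with nonzero counts.
#'
#' @param counts non-negative count (or abundance) vector
#' @return H in nats
#' @examples
#' shannon(c(1, 1, 1, 1))  # ln 4
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) abort("all-zero count vector")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1 singletons and F2 doubletons;
#' always at least the observed richness.
#'
#' @param counts non-negative integer count vector
#' @return estimated richness
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  if (sum(counts) <= 0) abort("all-zero count vector")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity of a feature table
#'
#' @param features a `soilpem_features` table
#' @param domain optional domain to restrict to ("bacteria", "fungi",
#'   "archaea"); default uses all features
#' @return tibble: `sample_id`, `richness`, `shannon`, `chao1`
#' @export
alpha_diversity <- function(features, domain = NULL) {
  if (!is.null(domain)) features <- filter(features, .data$domain %in% !!domain)
  cm <- feature_counts(features)
  tibble(
    sample_id = colnames(cm),
    richness = colSums(cm > 0),
    shannon = apply(cm, 2, shannon),
    chao1 = apply(cm, 2, chao1)
  )
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `1 - 2 sum min(a_i, b_i) / (sum a + sum b)`, in `[0, 1]`.
#'
#' @param a,b non-negative abundance vectors of equal length
#' @return dissimilarity
#' @examples
#' bray_curtis(c(1, 2), c(2, 1))
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) abort("length mismatch")
  if (sum(a) <= 0 || sum(b) <= 0) abort("both samples need positive totals")
  1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
}

#' Bray-Curtis dissimilarity matrix of a feature table
#'
#' @param features a `soilpem_features` table (or a numeric matrix,
#'   features x samples)
#' @return a symmetric `dist`-convertible matrix, samples x samples
#' @export
bray_curtis_matrix <- function(features) {
  cm <- if (is.matrix(features)) features else feature_counts(features)
  n <- ncol(cm)
  d <- matrix(0, n, n, dimnames = list(colnames(cm), colnames(cm)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(cm[, i], cm[, j])
    }
  }
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Seeded wrapper around \code{vegan::metaMDS} on a precomputed
#' dissimilarity. Stress is on the 0-1 scale; coordinates are identified only
#' up to rotation/reflection, under which stress is invariant.
#'
#' @param dist_mat square symmetric dissimilarity matrix with zero diagonal
#' @param k embedding dimension (default 2)
#' @param seed integer seed (fixes the random starts)
#' @param trymax maximum random starts
#' @return a `soilpem_nmds` list: `coordinates` tibble (sample_id, NMDS1,
#'   ...), `stress`, `converged`, `seed`
#' @export
nmds <- function(dist_mat, k = 2, seed = 1L, trymax = 20) {
  dist_mat <- as.matrix(dist_mat)
  if (!isSymmetric(unname(dist_mat), tol = 1e-10)) abort("dissimilarity matrix must be symmetric")
  if (any(abs(diag(dist_mat)) > 1e-12)) abort("dissimilarity matrix must have zero diagonal")
  fit <- with_seed(seed, suppressWarnings(
    vegan::metaMDS(as.dist(dist_mat), k = k, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  ))
  coords <- as_tibble(fit$points, .name_repair = "minimal")
  names(coords) <- paste0("NMDS", seq_len(k))
  coords <- bind_cols(
    tibble(sample_id = rownames(dist_mat) %||% as.character(seq_len(nrow(dist_mat)))),
    coords
  )
  structure(
    list(coordinates = coords, stress = fit$stress,
         converged = isTRUE(fit$converged) || (is.numeric(fit$converged) && fit$converged > 0),
         seed = seed),
    class = "soilpem_nmds"
  )
}

#' @export
tidy.soilpem_nmds <- function(x, ...) x$coordinates

#' @export
glance.soilpem_nmds <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged, seed = x$seed)
}

#' Seeded rarefaction of a feature table to a common depth
#'
#' Subsamples each sample's counts without replacement to `depth` (default the
#' minimum sample total). Optional: analyses default to unrarefied counts.
#'
#' @param features a `soilpem_features` table
#' @param depth target depth
#' @param seed integer seed
#' @return a rarefied `soilpem_features` table
#' @export
rarefy_features <- function(features, depth = NULL, seed = 1L) {
  cm <- feature_counts(features)
  depth <- depth %||% min(colSums(cm))
  if (any(colSums(cm) < depth)) abort("a sample has fewer counts than `depth`")
  with_seed(seed, {
    for (j in seq_len(ncol(cm))) {
      pool <- rep(seq_len(nrow(cm)), times = cm[, j])
      take <- sample(pool, depth)
      cm[, j] <- tabulate(take, nbins = nrow(cm))
    }
  })
  for (j in seq_len(ncol(cm))) features[[colnames(cm)[j]]] <- as.integer(cm[, j])
  features
}
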