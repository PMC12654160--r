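# Partial least squares path modelling (mode A outer model, centroid or
# factorial inner scheme, Lohmoller iteration) and random-forest importance
# with response-permutation significance.

#' Specify a PLS-PM model
#'
#' @param blocks named list; each element is a character vector of indicator
#'   column names forming one reflective (mode A) latent block
#' @param paths named list of inner paths `endogenous = c(predecessors...)`;
#'   the implied block adjacency must be acyclic (blocks must be listable in
#'   an order where every predecessor precedes its target)
#' @param scheme inner weighting scheme: "centroid" (default) or "factorial"
#' @param max_iter maximum outer/inner iterations (default 300)
#' @param tol convergence tolerance on the maximum outer-weight change
#'   (default 1e-7)
#' @return a `soilpem_plspm_spec` list
#' @examples
#' plspm_spec(
#'   blocks = list(fert = c("N_dose", "P_dose"), yield = "yield"),
#'   paths = list(yield = "fert")
#' )
#' @export
plspm_spec <- function(blocks, paths, scheme = c("centroid", "factorial"),
                       max_iter = 300, tol = 1e-7) {
  scheme <- match.arg(scheme)
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    abort("blocks must be a named list")
  }
  if (any(lengths(blocks) < 1)) abort("every block needs at least one indicator")
  bn <- names(blocks)
  bad <- setdiff(c(names(paths), unlist(paths)), bn)
  if (length(bad) > 0) {
    abort(paste0("path references unknown block(s): ", paste(bad, collapse = ", ")))
  }
  inner <- matrix(0, length(bn), length(bn), dimnames = list(bn, bn))
  for (endo in names(paths)) inner[endo, paths[[endo]]] <- 1
  # acyclicity via topological sort
  g <- igraph::graph_from_adjacency_matrix(t(inner), mode = "directed")
  if (!igraph::is_dag(g)) abort("inner path structure must be acyclic")
  structure(
    list(blocks = blocks, inner = inner, scheme = scheme,
         max_iter = max_iter, tol = tol),
    class = "soilpem_plspm_spec"
  )
}

#' Fit a PLS-PM model
#'
#' Indicators are standardized; outer weights start equal and are iterated
#' with mode A updates (weights = correlations of indicators with the block's
#' inner proxy) and the chosen inner scheme (centroid: signs of latent
#' correlations along inner edges; factorial: the correlations themselves)
#' until the maximum outer-weight change falls below `tol`. Latent scores are
#' standardized and sign-anchored so each block's mean loading is positive.
#' Path coefficients are OLS fits of each endogenous latent on its
#' predecessors; `R^2` per endogenous block, communality = squared loading,
#' and `GoF = sqrt(mean communality x mean R^2)`.
#'
#' @param data tibble or data frame containing every indicator column
#' @param spec a [plspm_spec()]
#' @return a `soilpem_plspm` list: `paths` (tibble from, to, coefficient),
#'   `outer` (tibble block, indicator, weight, loading, communality),
#'   `scores` (matrix n x blocks), `r_squared` (named vector), `gof`,
#'   `iterations`, `spec`
#' @export
plspm_fit <- function(data, spec) {
  blocks <- spec$blocks
  bn <- names(blocks)
  cols <- unlist(blocks, use.names = FALSE)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing indicator column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(data[, cols, drop = FALSE])
  if (anyNA(x)) abort("indicators must be complete (no missing values)")
  if (nrow(x) <= length(bn)) abort("need more samples than blocks")
  idx <- map(blocks, ~ match(.x, cols))
  eng <- plspm_engine(x, idx, spec)
  outer <- bind_rows(map(seq_along(bn), function(b) {
    ld <- eng$loadings[[b]]
    tibble(block = bn[b], indicator = blocks[[b]],
           weight = eng$w[[b]] / sqrt(sum(eng$w[[b]]^2)),
           loading = ld, communality = ld^2)
  }))
  paths <- tibble(from = eng$path_from, to = eng$path_to,
                  coefficient = eng$path_coef)
  gof <- sqrt(mean(outer$communality) * mean(eng$r2))
  structure(
    list(paths = paths, outer = outer, scores = eng$scores,
         r_squared = eng$r2, gof = gof, iterations = eng$iterations,
         spec = spec),
    class = "soilpem_plspm"
  )
}

# Numeric core of the Lohmoller iteration, shared by plspm_fit() and the
# bootstrap loop (which avoids per-resample tibble construction). `x` is the
# raw indicator matrix in spec column order; `idx` maps blocks to columns.
plspm_engine <- function(x, idx, spec) {
  bn <- names(spec$blocks)
  n <- nrow(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance indicator(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  x <- scale(x)
  adj <- spec$inner + t(spec$inner)  # neighbours for the inner approximation

  std <- function(v) (v - mean(v)) / (sd(v) * sqrt((n - 1) / n))
  # unit-variance scores in the 1/n metric, as is conventional for PLS-PM
  score_of <- function(w) {
    s <- vapply(seq_along(bn),
                function(b) std(x[, idx[[b]], drop = FALSE] %*% w[[b]]),
                numeric(n))
    colnames(s) <- bn
    s
  }
  w <- lapply(idx, function(ix) rep(1, length(ix)))
  scores <- score_of(w)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    rho <- cor(scores)
    inner_w <- adj * (if (spec$scheme == "centroid") sign(rho) else rho)
    z <- scores %*% t(inner_w)  # inner proxy per block
    w_new <- lapply(seq_along(bn), function(b) {
      zb <- z[, b]
      if (sd(zb) == 0) return(w[[b]])  # isolated block keeps its weights
      as.numeric(cor(x[, idx[[b]], drop = FALSE], zb))
    })
    delta <- max(vapply(seq_along(w), function(b) {
      max(abs(abs(w_new[[b]]) / sqrt(sum(w_new[[b]]^2)) -
                abs(w[[b]]) / sqrt(sum(w[[b]]^2))))
    }, numeric(1)))
    w <- w_new
    scores <- score_of(w)
    if (delta < spec$tol) break
    if (iterations >= spec$max_iter) {
      abort(sprintf("PLS-PM did not converge in %d iterations (last max weight change %.3g)",
                    spec$max_iter, delta))
    }
  }
  # sign anchor: mean loading positive per block
  loadings <- vector("list", length(bn))
  for (b in seq_along(bn)) {
    ld <- as.numeric(cor(x[, idx[[b]], drop = FALSE], scores[, b]))
    if (mean(ld) < 0) {
      scores[, b] <- -scores[, b]
      w[[b]] <- -w[[b]]
      ld <- -ld
    }
    loadings[[b]] <- ld
  }
  # the iteration loop rebuilds w without names; restore them so callers can
  # index blocks by name
  names(w) <- bn
  names(loadings) <- bn
  endo <- bn[rowSums(spec$inner) > 0]
  r2 <- setNames(numeric(length(endo)), endo)
  path_from <- character(0)
  path_to <- character(0)
  path_coef <- numeric(0)
  for (e in endo) {
    preds <- bn[spec$inner[e, ] == 1]
    y <- scores[, e]
    dm <- cbind(1, scores[, preds, drop = FALSE])
    beta <- qr.coef(qr(dm), y)
    res <- y - dm %*% beta
    r2[e] <- 1 - sum(res^2) / sum((y - mean(y))^2)
    path_from <- c(path_from, preds)
    path_to <- c(path_to, rep(e, length(preds)))
    path_coef <- c(path_coef, as.numeric(beta[-1]))
  }
  list(w = w, scores = scores, loadings = loadings, r2 = r2,
       path_from = path_from, path_to = path_to, path_coef = path_coef,
       iterations = iterations)
}

#' Bootstrap inference for PLS-PM path coefficients
#'
#' Refits the model on `bootstrap_n` seeded row resamples. Each refit's latent
#' orientations are aligned to the full-data fit (sign of the weight-vector
#' dot product per block). Two-sided p-values locate zero in the bootstrap
#' distribution: `p = 2 min((1 + #\{b <= 0\}), (1 + #\{b >= 0\})) / (B + 1)`
#' for paths with positive full-data sign (mirrored otherwise), capped at 1.
#'
#' @param data as in [plspm_fit()]
#' @param spec a [plspm_spec()]
#' @param bootstrap_n number of resamples (default 500)
#' @param seed integer seed
#' @param conf confidence level for percentile intervals (default 0.95)
#' @return tibble: `from`, `to`, `coefficient`, `boot_mean`, `boot_se`,
#'   `ci_lower`, `ci_upper`, `p_value`, `stars`, `n_boot_converged`
#' @export
plspm_bootstrap <- function(data, spec, bootstrap_n = 500, seed = 1L,
                            conf = 0.95) {
  full <- plspm_fit(data, spec)
  bn <- names(spec$blocks)
  n <- nrow(data)
  w_full <- split(full$outer$weight, factor(full$outer$block, levels = bn))
  cols <- unlist(spec$blocks, use.names = FALSE)
  xmat <- as.matrix(data[, cols, drop = FALSE])
  idx <- map(spec$blocks, ~ match(.x, cols))
  boot <- with_seed(seed, map(seq_len(bootstrap_n), function(i) {
    rows <- sample.int(n, n, replace = TRUE)
    eng <- tryCatch(plspm_engine(xmat[rows, , drop = FALSE], idx, spec),
                    error = function(e) NULL)
    if (is.null(eng)) return(NULL)
    # align latent orientations with the full-data fit
    flips <- map_dbl(bn, function(b) {
      sign(sum(eng$w[[b]] * w_full[[b]])) %||% 1
    })
    names(flips) <- bn
    flips[flips == 0] <- 1
    eng$path_coef * flips[eng$path_from] * flips[eng$path_to]
  }))
  ok <- !map_lgl(boot, is.null)
  if (mean(!ok) > 0.10) {
    abort(sprintf("%.0f%% of bootstrap resamples failed to converge",
                  100 * mean(!ok)))
  }
  bcoef <- do.call(rbind, boot[ok])  # resamples x paths
  alpha <- 1 - conf
  out <- full$paths
  stats <- map(seq_len(nrow(out)), function(i) {
    b <- bcoef[, i]
    bb <- length(b)
    p <- 2 * min((1 + sum(b <= 0)) / (bb + 1), (1 + sum(b >= 0)) / (bb + 1))
    tibble(
      boot_mean = mean(b), boot_se = sd(b),
      ci_lower = unname(quantile(b, alpha / 2)),
      ci_upper = unname(quantile(b, 1 - alpha / 2)),
      p_value = min(p, 1), n_boot_converged = bb
    )
  })
  out <- bind_cols(out, bind_rows(stats))
  out$stars <- p_stars(out$p_value)
  out
}

#' @export
tidy.soilpem_plspm <- function(x, ...) x$paths

#' @export
glance.soilpem_plspm <- function(x, ...) {
  tibble(gof = x$gof, mean_communality = mean(x$outer$communality),
         mean_r_squared = mean(x$r_squared), iterations = x$iterations,
         scheme = x$spec$scheme)
}

#' @export
print.soilpem_plspm <- function(x, ...) {
  cat(sprintf("PLS-PM (mode A, %s scheme), converged in %d iterations\n",
              x$spec$scheme, x$iterations))
  print(x$paths)
  cat(sprintf("GoF = %.4f; R2: %s\n", x$gof,
              paste(sprintf("%s = %.3f", names(x$r_squared), x$r_squared),
                    collapse = ", ")))
  invisible(x)
}

#' Random-forest importance with permutation significance
#'
#' Fits a regression forest and reports each predictor's %IncMSE (percentage
#' increase in out-of-bag MSE when the predictor is permuted). Significance is
#' assessed by refitting the forest on `n_perm` response-permuted datasets and
#' locating the observed %IncMSE in its null distribution:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param predictors tibble/data frame of numeric predictors (samples x p)
#' @param response numeric response
#' @param n_trees trees per forest (default 1000)
#' @param n_perm response permutations (default 200)
#' @param mtry variables tried per split; default `max(floor(p/3), 1)`
#' @param seed integer seed
#' @return a `soilpem_rf` tibble: `predictor`, `inc_mse`, `p_value`, `stars`,
#'   plus attributes `n_trees`, `n_perm`, `r_squared`
#' @export
rf_importance <- function(predictors, response, n_trees = 1000, n_perm = 200,
                          mtry = NULL, seed = 1L) {
  predictors <- as.data.frame(predictors[, vapply(predictors, is.numeric,
                                                  logical(1)), drop = FALSE])
  if (nrow(predictors) < 10) abort("need at least 10 samples")
  if (var(response) == 0) abort("constant response")
  mtry <- mtry %||% max(floor(ncol(predictors) / 3), 1)
  res <- with_seed(seed, {
    fit <- randomForest::randomForest(predictors, response, ntree = n_trees,
                                      mtry = mtry, importance = TRUE)
    obs <- fit$importance[, "%IncMSE"] /
      pmax(fit$importanceSD, .Machine$double.eps) # standardized, as reported
    obs_raw <- fit$importance[, "%IncMSE"]
    null <- matrix(NA_real_, n_perm, ncol(predictors))
    for (k in seq_len(n_perm)) {
      pfit <- randomForest::randomForest(predictors, sample(response),
                                         ntree = n_trees, mtry = mtry,
                                         importance = TRUE)
      null[k, ] <- pfit$importance[, "%IncMSE"] /
        pmax(pfit$importanceSD, .Machine$double.eps)
    }
    list(fit = fit, obs = obs, obs_raw = obs_raw, null = null)
  })
  p <- vapply(seq_along(res$obs), function(j) {
    (1 + sum(res$null[, j] >= res$obs[j])) / (n_perm + 1)
  }, numeric(1))
  out <- tibble(
    predictor = names(predictors),
    inc_mse = 100 * as.numeric(res$obs_raw) / res$fit$mse[n_trees],
    importance_z = as.numeric(res$obs),
    p_value = p,
    stars = p_stars(p)
  )
  out <- arrange(out, dplyr::desc(.data$inc_mse))
  attr(out, "n_trees") <- n_trees
  attr(out, "n_perm") <- n_perm
  attr(out, "r_squared") <- res$fit$rsq[n_trees]
  class(out) <- c("soilpem_rf", class(out))
  out
}
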