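# Distance-matrix association (Mantel permutation test), taxa-environment
# correlation panels, and the yield general linear model with SOM x AP
# interaction.

#' Mantel permutation test
#'
#' Correlates the strictly-lower-triangle entries of two distance matrices and
#' assesses significance by simultaneously permuting the rows and columns of
#' the second matrix. The p-value is one-sided ("greater"):
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`, so its resolution is
#' `1/(n_perm + 1)`. With `exhaustive = TRUE` all `n!` relabellings are
#' enumerated instead (small n only) and `p = #\{r_perm >= r_obs\} / n!`.
#'
#' @param dist_a,dist_b square symmetric matrices with zero diagonal, same
#'   dimension >= 4
#' @param method correlation of entries: "pearson" (default) or "spearman"
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @param exhaustive enumerate all permutations (requires n <= 7)
#' @return a `soilpem_mantel` tibble: `r`, `p`, `n_perm`, `method`, `seed`
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(20), 5)
#' d1 <- as.matrix(dist(x))
#' mantel_test(d1, d1, n_perm = 99)
#' @export
mantel_test <- function(dist_a, dist_b, method = c("pearson", "spearman"),
                        n_perm = 999, seed = 1L, exhaustive = FALSE) {
  method <- match.arg(method)
  dist_a <- as.matrix(dist_a)
  dist_b <- as.matrix(dist_b)
  n <- nrow(dist_a)
  if (n < 4) abort("need at least 4 samples")
  if (!all(dim(dist_b) == c(n, n))) abort("matrices must have the same dimension")
  for (m in list(dist_a, dist_b)) {
    if (!isSymmetric(unname(m), tol = 1e-10)) abort("distance matrices must be symmetric")
    if (any(abs(diag(m)) > 1e-12)) abort("distance matrices must have zero diagonal")
  }
  lower <- lower.tri(dist_a)
  a <- dist_a[lower]
  if (var(a) == 0 || var(dist_b[lower]) == 0) {
    abort("constant distance matrix: Mantel r undefined")
  }
  r_of <- function(perm) {
    cor(a, dist_b[perm, perm][lower], method = method)
  }
  r_obs <- r_of(seq_len(n))
  if (exhaustive) {
    if (n > 7) abort("exhaustive mode limited to n <= 7")
    perms <- all_permutations(n)
    r_null <- vapply(perms, r_of, numeric(1))
    p <- sum(r_null >= r_obs - 1e-12) / length(perms)
    n_used <- length(perms)
  } else {
    r_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      r_of(sample.int(n))
    }, numeric(1)))
    p <- (1 + sum(r_null >= r_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  out <- tibble(r = r_obs, p = p, n_perm = n_used, method = method,
                seed = as.integer(seed))
  class(out) <- c("soilpem_mantel", class(out))
  out
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in 0:(n - 1)) {
      k <- k + 1
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Map a p-value to its significance stars
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, empty otherwise.
#'
#' @param p numeric p-value(s)
#' @return character vector of star strings
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Pairwise correlation panel between two variable sets
#'
#' Correlates every column of `left` with every column of `right` (Pearson by
#' default), dropping incomplete pairs pairwise. Cells with a constant column
#' are flagged undefined (NA coefficient).
#'
#' @param left,right tibbles of numeric columns on the same samples (a shared
#'   `sample_id` column, if present, is used to align rows)
#' @param method "pearson" (default) or "spearman"
#' @return a `soilpem_panel` tibble: `row` (left variable), `col` (right
#'   variable), `coefficient`, `p`, `stars`
#' @export
correlation_panel <- function(left, right, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if ("sample_id" %in% names(left) && "sample_id" %in% names(right)) {
    right <- right[match(left$sample_id, right$sample_id), ]
  }
  lnum <- left[, vapply(left, is.numeric, logical(1)), drop = FALSE]
  rnum <- right[, vapply(right, is.numeric, logical(1)), drop = FALSE]
  grid <- tidyr::expand_grid(row = names(lnum), col = names(rnum))
  res <- pmap(grid, function(row, col) {
    x <- lnum[[row]]
    y <- rnum[[col]]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4 || var(x) == 0 || var(y) == 0) {
      return(tibble(coefficient = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    tibble(coefficient = unname(ct$estimate), p = ct$p.value)
  })
  out <- bind_cols(grid, bind_rows(res))
  out$stars <- p_stars(out$p)
  class(out) <- c("soilpem_panel", class(out))
  out
}

#' Yield general linear model with SOM x AP interaction
#'
#' Ordinary least squares of yield on centred SOM, centred AP and their
#' interaction (Gaussian identity link). Centring leaves the interaction
#' coefficient unchanged and makes the main effects interpretable at the
#' sample means.
#'
#' @param data tibble with columns `yield`, `SOM`, `AP`
#' @return a `soilpem_yield_glm` list: `coefficients` tibble (term, estimate,
#'   std_error, t_value, p_value), `r_squared`, `fit` (the lm object)
#' @export
yield_glm <- function(data) {
  if (nrow(data) <= 4) abort("need more than 4 samples")
  d <- tibble(
    yield = data$yield,
    SOM_c = data$SOM - mean(data$SOM),
    AP_c = data$AP - mean(data$AP)
  )
  fit <- lm(yield ~ SOM_c * AP_c, data = d)
  qrf <- qr(model.matrix(fit))
  if (qrf$rank < 4) {
    abort(sprintf("rank-deficient design (rank %d of 4); predictors are collinear",
                  qrf$rank))
  }
  sm <- summary(fit)
  coefs <- as_tibble(sm$coefficients, rownames = "term")
  names(coefs) <- c("term", "estimate", "std_error", "t_value", "p_value")
  coefs$term <- c("(Intercept)", "SOM", "AP", "SOM:AP")
  structure(
    list(coefficients = coefs, r_squared = sm$r.squared, fit = fit),
    class = "soilpem_yield_glm"
  )
}

#' @export
tidy.soilpem_yield_glm <- function(x, ...) x$coefficients

#' @export
glance.soilpem_yield_glm <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = length(residuals(x$fit)))
}

#' Mantel panel of community distances against environmental variables
#'
#' For each environmental variable, the Euclidean distance on the z-scored
#' variable is tested against the community Bray-Curtis distance.
#'
#' @param features a `soilpem_features` table
#' @param env tibble of environmental variables with `sample_id`
#' @param n_perm permutations per test
#' @param seed integer seed (advanced per variable)
#' @param method correlation method
#' @return tibble: `variable`, `r`, `p`, `stars`
#' @export
mantel_panel <- function(features, env, n_perm = 999, seed = 1L,
                         method = "pearson") {
  dcomm <- bray_curtis_matrix(features)
  env_ids <- env$sample_id %||% colnames(dcomm)
  env <- env[match(colnames(dcomm), env_ids), ]
  vars <- names(env)[vapply(env, is.numeric, logical(1))]
  out <- imap(setNames(vars, vars), function(v, nm) {
    z <- scale(env[[v]])[, 1]
    denv <- as.matrix(dist(z))
    m <- mantel_test(dcomm, denv, method = method, n_perm = n_perm,
                     seed = stage_seed(seed, match(v, vars)))
    tibble(variable = v, r = m$r, p = m$p)
  })
  out <- bind_rows(out)
  out$stars <- p_stars(out$p)
  out
}
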