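# Treatment-comparison machinery: one-way ANOVA, Duncan's multiple range
# test with letter grouping, and percent-change summaries.

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition. When every value is identical the
#' test is degenerate and is reported as F = 0, p = 1; zero within-group
#' variance with unequal means gives F = Inf, p = 0.
#'
#' @param values numeric response
#' @param groups group labels (coerced to character)
#' @param na_fatal if TRUE (default), missing values abort; ANOVA inputs must
#'   be complete
#' @return tibble with `f_value`, `p_value`, `mse`, `df_between`, `df_error`
#' @examples
#' one_way_anova(c(10, 11, 12, 20, 21, 22), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, groups, na_fatal = TRUE) {
  groups <- as.character(groups)
  if (anyNA(values) || anyNA(groups)) {
    if (na_fatal) abort("missing values are fatal for ANOVA inputs")
    keep <- complete.cases(values, groups)
    values <- values[keep]
    groups <- groups[keep]
  }
  ns <- table(groups)
  if (length(ns) < 2) abort("need at least 2 groups")
  if (any(ns < 2)) abort("need at least 2 observations per group")
  n <- length(values)
  k <- length(ns)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ss_between <- sum(as.numeric(ns) * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df_b <- k - 1
  df_e <- n - k
  mse <- ss_within / df_e
  if (ss_between == 0) {
    f <- 0
    p <- 1
  } else if (mse == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_between / df_b) / mse
    p <- pf(f, df_b, df_e, lower.tail = FALSE)
  }
  tibble(f_value = f, p_value = p, mse = mse, df_between = df_b, df_error = df_e)
}

# Duncan least significant range for span p at protection level
# 1 - (1 - alpha)^(p - 1), error df `df`, effective group size `n_eff`
duncan_lsr <- function(span, df, mse, n_eff, alpha) {
  prot <- (1 - alpha)^(span - 1)
  q <- qtukey(prot, nmeans = span, df = df, lower.tail = TRUE)
  q * sqrt(mse / n_eff)
}

# letter assignment over means sorted descending: ranges [i..j] with
# m_i - m_j <= LSR(span) are non-significant; containment protection applied;
# letters by the insert-and-absorb algorithm
assign_letters <- function(means_desc, lsr_by_span) {
  k <- length(means_desc)
  if (k == 1) return("a")
  nonsig <- matrix(TRUE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      span <- j - i + 1
      nonsig[i, j] <- (means_desc[i] - means_desc[j]) <= lsr_by_span[span]
    }
  }
  # containment: any pair inside a non-significant range is non-significant
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (nonsig[i, j]) {
        for (a in i:(j - 1)) for (b in (a + 1):j) nonsig[a, b] <- TRUE
      }
    }
  }
  # maximal non-significant stretches, skipping contained ones
  stretches <- list()
  last_end <- 0
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    if (j > last_end || i > last_end) {
      stretches[[length(stretches) + 1]] <- c(i, j)
      last_end <- j
    }
  }
  letters_out <- rep("", k)
  for (s in seq_along(stretches)) {
    rng <- stretches[[s]]
    idx <- rng[1]:rng[2]
    letters_out[idx] <- paste0(letters_out[idx], letters[s])
  }
  letters_out
}

#' Duncan's multiple range test with letter grouping
#'
#' Post-ANOVA multiple comparison using studentized-range critical values at
#' Duncan's span-dependent protection levels `1 - (1 - alpha)^(span - 1)`.
#' Means are sorted descending and letters assigned starting at "a" for the
#' largest; groups sharing any letter are not significantly different at
#' `alpha`. Unequal group sizes use the harmonic mean of the sizes.
#'
#' @param values numeric response
#' @param groups group labels
#' @param alpha significance level (default 0.05)
#' @return a `soilpem_duncan` list: `groups` (tibble: group, n, mean, se,
#'   letter, in descending mean order), `anova` (the [one_way_anova()] row),
#'   `alpha`
#' @examples
#' set.seed(1)
#' duncan_letters(rnorm(12, rep(c(0, 10, 20), each = 4), 0.5),
#'                rep(c("lo", "mid", "hi"), each = 4))
#' @export
duncan_letters <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) abort("need at least 2 groups")
  an <- one_way_anova(values, groups)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  gse <- tapply(values, groups, function(x) sd(x) / sqrt(length(x)))
  ord <- order(gm, decreasing = TRUE)
  gm <- gm[ord]; gn <- gn[ord]; gse <- gse[ord]
  n_eff <- length(gn) / sum(1 / gn)  # harmonic mean of group sizes
  k <- length(gm)
  lsr <- c(NA_real_, vapply(
    2:k, duncan_lsr, numeric(1),
    df = an$df_error, mse = an$mse, n_eff = n_eff, alpha = alpha
  ))
  letts <- if (an$mse == 0 && an$f_value == Inf) {
    # perfectly separated groups: all distinct letters by mean order, ties share
    letters[match(-gm, sort(unique(-gm)))]
  } else {
    assign_letters(as.numeric(gm), lsr)
  }
  structure(
    list(
      groups = tibble(group = names(gm), n = as.integer(gn),
                      mean = as.numeric(gm), se = as.numeric(gse),
                      letter = letts),
      anova = an, alpha = alpha
    ),
    class = "soilpem_duncan"
  )
}

#' Duncan letters from printed means and standard errors
#'
#' Reconstructs the pooled error mean square from per-group standard errors
#' under homoscedasticity (`MSE = mean(n * SE^2)`, error df `sum(n - 1)`) and
#' applies the same range test as [duncan_letters()]. This reproduces letter
#' patterns from published summary tables where raw replicates are
#' unavailable.
#'
#' @param means named numeric vector of group means
#' @param se per-group standard errors
#' @param n replicates per group (scalar or vector)
#' @param alpha significance level
#' @return a `soilpem_duncan` list (the `anova` element carries only `mse` and
#'   `df_error`)
#' @export
duncan_from_summary <- function(means, se, n = 4, alpha = 0.05) {
  k <- length(means)
  if (k < 2) abort("need at least 2 groups")
  n <- rep_len(n, k)
  mse <- mean(n * se^2)
  df_e <- sum(n - 1)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  n_eff <- k / sum(1 / n)
  lsr <- c(NA_real_, vapply(
    2:k, duncan_lsr, numeric(1),
    df = df_e, mse = mse, n_eff = n_eff, alpha = alpha
  ))
  letts <- assign_letters(as.numeric(m), lsr)
  structure(
    list(
      groups = tibble(group = names(m) %||% as.character(ord),
                      n = as.integer(n[ord]), mean = as.numeric(m),
                      se = as.numeric(se[ord]), letter = letts),
      anova = tibble(f_value = NA_real_, p_value = NA_real_, mse = mse,
                     df_between = k - 1, df_error = df_e),
      alpha = alpha
    ),
    class = "soilpem_duncan"
  )
}

#' Percent change relative to a reference
#'
#' `100 * (value - reference) / reference`; the reference must be positive.
#'
#' @param value treatment value(s)
#' @param reference reference value(s), > 0
#' @return percent change (vectorized)
#' @examples
#' percent_change(31.83, 17.70)
#' @export
percent_change <- function(value, reference) {
  if (any(reference <= 0)) abort("reference must be > 0")
  100 * (value - reference) / reference
}

#' @export
tidy.soilpem_duncan <- function(x, ...) x$groups

#' @export
glance.soilpem_duncan <- function(x, ...) {
  bind_cols(x$anova, tibble(alpha = x$alpha, n_groups = nrow(x$groups)))
}

#' @export
print.soilpem_duncan <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g)\n", x$alpha))
  if (is.finite(x$anova$f_value %||% NA)) {
    cat(sprintf("one-way ANOVA: F = %.4g, p = %.4g (df = %d, %d)\n",
                x$anova$f_value, x$anova$p_value,
                x$anova$df_between, x$anova$df_error))
  }
  print(x$groups)
  invisible(x)
}
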