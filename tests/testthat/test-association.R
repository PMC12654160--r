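rand_dist <- function(n, seed) {
  set.seed(seed)
  as.matrix(dist(matrix(rnorm(n * 3), n)))
}

test_that("mantel of a matrix with itself gives r = 1 at minimal p", {
  d <- rand_dist(10, 1)
  m <- mantel_test(d, d, n_perm = 99, seed = 3)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 100)
})

test_that("exhaustive mantel p equals brute-force enumeration on 4x4", {
  da <- rand_dist(4, 2)
  db <- rand_dist(4, 3)
  m <- mantel_test(da, db, exhaustive = TRUE)
  # independent enumeration over all 24 relabellings
  perms <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (c in setdiff(1:4, c(a, b))) {
    perms[[length(perms) + 1]] <- c(a, b, c, setdiff(1:4, c(a, b, c)))
  }
  lower <- lower.tri(da)
  r_obs <- cor(da[lower], db[lower])
  r_null <- vapply(perms, function(p) cor(da[lower], db[p, p][lower]), numeric(1))
  expect_equal(m$p, mean(r_null >= r_obs - 1e-12))
  expect_equal(m$n_perm, 24)
})

test_that("exhaustive and Monte-Carlo mantel p agree within 3 binomial SE", {
  da <- rand_dist(5, 4)
  db <- 0.6 * da + 0.4 * rand_dist(5, 5)
  p_ex <- mantel_test(da, db, exhaustive = TRUE)$p
  p_mc <- mantel_test(da, db, n_perm = 999, seed = 6)$p
  se <- sqrt(p_ex * (1 - p_ex) / 999)
  expect_lt(abs(p_mc - p_ex), 3 * se + 1 / 1000)
})

test_that("mantel r matches the vegan implementation and is relabel-invariant", {
  da <- rand_dist(12, 7)
  db <- rand_dist(12, 8)
  m <- mantel_test(da, db, n_perm = 99, seed = 1)
  v <- vegan::mantel(as.dist(da), as.dist(db), permutations = 99)
  expect_equal(m$r, unname(v$statistic), tolerance = 1e-12)
  perm <- sample(12)
  m2 <- mantel_test(da[perm, perm], db[perm, perm], n_perm = 99, seed = 1)
  expect_equal(m2$r, m$r, tolerance = 1e-12)
})

test_that("mantel rejects degenerate inputs", {
  d <- rand_dist(6, 9)
  expect_error(mantel_test(d[1:3, 1:3], d[1:3, 1:3]), "at least 4")
  expect_error(mantel_test(d, matrix(0, 6, 6)), "constant")
  expect_error(mantel_test(d, d[1:5, 1:5]), "dimension")
})

test_that("mantel null rejection rate is calibrated near 0.05", {
  set.seed(20)
  rej <- vapply(1:150, function(i) {
    da <- as.matrix(dist(rnorm(15)))
    db <- as.matrix(dist(rnorm(15)))
    mantel_test(da, db, n_perm = 99, seed = i)$p <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("significance stars follow the caption mapping exactly", {
  expect_equal(p_stars(c(0.0005, 0.0099, 0.049, 0.05, 0.2)),
               c("***", "**", "*", "", ""))
})

test_that("correlation panel flags exact linear relations and drops constants", {
  set.seed(21)
  x <- rnorm(10)
  left <- tibble::tibble(sample_id = paste0("s", 1:10), a = x)
  right <- tibble::tibble(sample_id = paste0("s", 1:10), b = 2 * x + 1,
                          flat = rep(1, 10))
  panel <- correlation_panel(left, right)
  cell <- panel[panel$row == "a" & panel$col == "b", ]
  expect_equal(cell$coefficient, 1, tolerance = 1e-12)
  expect_equal(cell$stars, "***")
  expect_true(is.na(panel$coefficient[panel$col == "flat"]))
})

test_that("a generated Citrate-P/yield correlation shows up as a significant cell", {
  set.seed(22)
  n <- 20
  z <- rnorm(n)
  citrate <- 25 + 4 * (0.9 * z + sqrt(1 - 0.81) * rnorm(n))
  yield <- 6 + 1.5 * z
  panel <- correlation_panel(
    tibble::tibble(Citrate_P = citrate),
    tibble::tibble(yield = yield)
  )
  expect_gt(panel$coefficient, 0.5)
  expect_true(panel$stars %in% c("*", "**", "***"))
})

test_that("yield GLM recovers a constructed interaction and is centring-stable", {
  set.seed(23)
  n <- 40
  som <- rnorm(n, 27, 3)
  ap <- rnorm(n, 50, 20)
  d <- tibble::tibble(SOM = som, AP = ap,
                      yield = (som - 27) * (ap - 50) + rnorm(n, 0, 0.01))
  fit <- yield_glm(d)
  co <- fit$coefficients
  expect_lt(co$p_value[co$term == "SOM:AP"], 1e-10)
  expect_equal(co$estimate[co$term == "SOM:AP"], 1, tolerance = 1e-3)

  # shifting the predictors leaves the interaction coefficient unchanged
  d2 <- dplyr::mutate(d, SOM = SOM + 100, AP = AP - 42)
  fit2 <- yield_glm(d2)
  expect_equal(fit2$coefficients$estimate[4], co$estimate[4], tolerance = 1e-9)
})

test_that("yield GLM interaction test is calibrated under the null", {
  set.seed(24)
  rej <- vapply(1:200, function(i) {
    n <- 20
    som <- rnorm(n, 27, 3)
    ap <- rnorm(n, 50, 20)
    y <- 5 + 0.2 * (som - 27) + 0.01 * (ap - 50) + rnorm(n, 0, 0.5)
    fit <- yield_glm(tibble::tibble(SOM = som, AP = ap, yield = y))
    fit$coefficients$p_value[4] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("generated positive SOM x AP interaction is recovered in sign with high power", {
  signs <- vapply(1:30, function(i) {
    ds <- generate_dataset(tiny_config(seed = 400 + i))
    fit <- yield_glm(ds$chemistry)
    fit$coefficients$estimate[fit$coefficients$term == "SOM:AP"] > 0
  }, logical(1))
  expect_gt(mean(signs), 0.8)
})

test_that("mantel panel runs over environmental variables with stars", {
  ds <- tiny_dataset(25)
  env <- ds$chemistry[, c("sample_id", "SOM", "AP", "pH")]
  mp <- mantel_panel(ds$features, env, n_perm = 99, seed = 1)
  expect_equal(mp$variable, c("SOM", "AP", "pH"))
  expect_true(all(mp$p > 0 & mp$p <= 1))
})
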