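make_plate <- function(assay, blank = 50, negative = 20, reference = 2000,
                       quench_ratio = 0.9) {
  tibble::tibble(
    role = c("assay", "blank", "negative_control", "reference_standard",
             "quench_standard"),
    fluorescence = c(assay, blank, negative, reference,
                     quench_ratio * reference + blank)
  )
}

test_that("plate with no net signal yields zero activity", {
  plate <- make_plate(assay = 50 + 20)  # assay = blank + negative contributions
  expect_equal(fluorescence_to_activity(plate), 0)
})

test_that("forward-simulated plate recovers the known activity", {
  # build assay fluorescence from a target activity by inverting the formula
  activity <- 123.456
  emission <- 2000 / 0.5
  quench <- 0.9
  nmol <- activity * 3 * 0.5 / (50 / 0.2)
  plate <- make_plate(assay = nmol * emission * quench + 50 + 20)
  expect_equal(fluorescence_to_activity(plate), activity, tolerance = 1e-9)
})

test_that("activity scales inversely with soil mass and time", {
  plate <- make_plate(assay = 800)
  a1 <- fluorescence_to_activity(plate, soil_g = 0.5)
  expect_equal(fluorescence_to_activity(plate, soil_g = 1.0), a1 / 2)
  expect_equal(fluorescence_to_activity(plate, incubation_h = 6), a1 / 2)
})

test_that("degenerate standards are fatal", {
  plate <- make_plate(assay = 800)
  plate$fluorescence[plate$role == "reference_standard"] <- 0
  expect_error(fluorescence_to_activity(plate), "emission|quench")
  expect_error(fluorescence_to_activity(make_plate(800)[-2, ]), "blank")
})

test_that("enzyme log-ratios match exact and high-precision cases", {
  # BG+CBH = e^2, NAG+LAP = e, ALP = e -> (2, 2, 1)
  r <- enzyme_ratios(tibble::tibble(BG = exp(2), CBH = 0, NAG = exp(1),
                                    LAP = 0, ALP = exp(1)))
  expect_equal(c(r$ec_n, r$ec_p, r$en_p), c(2, 2, 1), tolerance = 1e-12)

  r2 <- enzyme_ratios(tibble::tibble(BG = 60, CBH = 40, NAG = 20, LAP = 30,
                                     ALP = 80))
  expect_equal(r2$ec_n, log(100) / log(50), tolerance = 1e-12)
  expect_equal(r2$ec_p, log(100) / log(80), tolerance = 1e-12)
  expect_equal(r2$en_p, log(50) / log(80), tolerance = 1e-12)
  expect_equal(round(c(r2$ec_n, r2$ec_p, r2$en_p), 4), c(1.1772, 1.0509, 0.8927))
})

test_that("pool sums at or below 1 are flagged, not transformed", {
  expect_warning(
    r <- enzyme_ratios(tibble::tibble(BG = 0.5, CBH = 0.5, NAG = 10, LAP = 10,
                                      ALP = 10)),
    "flagged"
  )
  expect_true(r$flagged)
  expect_true(is.na(r$ec_n))
})

test_that("vector analysis reproduces closed-form cases", {
  # x = y = 0.5: length sqrt(0.5), 45 degrees, balanced
  v <- enzyme_vector(tibble::tibble(BG = 10, CBH = 0, NAG = 10, LAP = 0, ALP = 10))
  expect_equal(v$x, 0.5)
  expect_equal(v$y, 0.5)
  expect_equal(v$length, sqrt(0.5), tolerance = 1e-12)
  expect_equal(v$angle, 45)
  expect_equal(v$limitation, "balanced")

  # BG+CBH = 100, NAG+LAP = 50, ALP = 80
  v2 <- enzyme_vector(tibble::tibble(BG = 70, CBH = 30, NAG = 20, LAP = 30, ALP = 80))
  expect_equal(v2$x, 100 / 180, tolerance = 1e-12)
  expect_equal(v2$y, 100 / 150, tolerance = 1e-12)
  expect_equal(round(v2$length, 4), 0.8678)
  expect_equal(round(v2$angle, 2), 50.19)
  expect_equal(v2$limitation, "P_limited")

  # direct arctangent evaluation
  expect_equal(atan2(0.35, 0.8) * 180 / pi, 23.6294, tolerance = 1e-4)
})

test_that("angle is scale-invariant and complementary under x/y swap", {
  set.seed(42)
  for (i in 1:20) {
    act <- tibble::tibble(BG = runif(1, 1, 100), CBH = runif(1, 1, 100),
                          NAG = runif(1, 1, 100), LAP = runif(1, 1, 100),
                          ALP = runif(1, 1, 100))
    v <- enzyme_vector(act)
    v_scaled <- enzyme_vector(act * runif(1, 0.1, 10))
    expect_equal(v_scaled$x, v$x, tolerance = 1e-12)
    expect_equal(v_scaled$angle, v$angle, tolerance = 1e-12)
    # angle(x, y) + angle(y, x) = 90
    expect_equal(atan2(v$y, v$x) + atan2(v$x, v$y), pi / 2, tolerance = 1e-12)
  }
})

test_that("vector length strictly increases in the C-enzyme pool", {
  cpool <- seq(10, 200, by = 10)
  lens <- vapply(cpool, function(cp) {
    enzyme_vector(tibble::tibble(BG = cp, CBH = 0, NAG = 25, LAP = 25, ALP = 60))$length
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
})

test_that("vector summary separates configured treatment angles and finds negative coupling", {
  md <- sample_metadata(paste0("s", 1:8), rep(c("CK", "OPTP"), each = 4),
                        rep(1:4, 2))
  # angles 24.5 (CK) vs 22 (OPTP) with small within-treatment spread
  set.seed(7)
  target_angle <- rep(c(24.5, 22), each = 4) + rnorm(8, 0, 0.3)
  cpool <- rep(c(60, 90), each = 4)  # longer vectors where angle is smaller
  alp <- 45
  n_total <- (cpool + alp) / tan(target_angle * pi / 180) - cpool
  enz <- tibble::tibble(sample_id = md$sample_id, BG = cpool, CBH = 0,
                        NAG = n_total / 2, LAP = n_total / 2, ALP = alp)
  vs <- vector_summary(enz, md)
  ang <- dplyr::filter(vs$by_treatment, variable == "angle")
  expect_setequal(ang$letter, c("a", "b"))
  expect_gt(ang$mean[ang$group == "CK"], ang$mean[ang$group == "OPTP"])
  expect_lt(vs$regression$slope, 0)
})

test_that("identical samples give zero SE and a single letter", {
  md <- tiny_metadata(2, 3)
  enz <- tibble::tibble(sample_id = md$sample_id, BG = 50, CBH = 20, NAG = 30,
                        LAP = 100, ALP = 40)
  vs <- vector_summary(enz, md)
  expect_true(all(vs$by_treatment$se == 0))
  expect_true(all(vs$by_treatment$letter == "a"))
})
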