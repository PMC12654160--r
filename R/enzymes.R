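# Ecoenzymatic stoichiometry: fluorometric plate reduction, C:N:P enzyme
# log-ratios, and vector analysis (length = C limitation, angle >45 deg = P
# limitation, <45 deg = N limitation).

#' Compute an enzyme activity from a fluorometric plate
#'
#' Standard fluorometric reduction with negative-control and quench
#' corrections. The emission coefficient (fluorescence units per nmol) comes
#' from reference-standard wells (standard in buffer); the quench coefficient
#' is (quench standard - blank) / reference standard, i.e. the fraction of
#' standard fluorescence surviving in soil homogenate. Net assay fluorescence
#' is assay - blank - negative control. Activity is scaled by incubation time,
#' the homogenate-to-aliquot volume ratio, and dry soil mass; negative net
#' signal is floored at zero.
#'
#' @param plate tibble with columns `role` (one of "assay", "blank",
#'   "quench_standard", "negative_control", "reference_standard") and
#'   `fluorescence`; replicate wells are averaged
#' @param incubation_h incubation time (h)
#' @param soil_g dry soil mass in the homogenate (g)
#' @param homogenate_ml homogenate volume (mL)
#' @param aliquot_ul homogenate aliquot per well (uL)
#' @param standard_nmol amount of fluorophore standard per standard well (nmol)
#' @return activity in nmol per hour per g dry soil (single number)
#' @examples
#' plate <- tibble::tibble(
#'   role = c("assay", "blank", "negative_control", "reference_standard",
#'            "quench_standard"),
#'   fluorescence = c(500, 50, 20, 2000, 1850)
#' )
#' fluorescence_to_activity(plate)
#' @export
fluorescence_to_activity <- function(plate, incubation_h = 3, soil_g = 0.5,
                                     homogenate_ml = 50, aliquot_ul = 200,
                                     standard_nmol = 0.5) {
  roles <- c("assay", "blank", "quench_standard", "negative_control",
             "reference_standard")
  missing <- setdiff(roles, unique(plate$role))
  if (length(missing) > 0) {
    abort(paste0("plate is missing well role(s): ", paste(missing, collapse = ", ")))
  }
  if (incubation_h <= 0 || soil_g <= 0) abort("incubation time and soil mass must be > 0")
  m <- function(r) mean(plate$fluorescence[plate$role == r])
  emission <- m("reference_standard") / standard_nmol
  if (!is.finite(emission) || emission <= 0) {
    abort("degenerate reference standard: emission coefficient <= 0")
  }
  quench <- (m("quench_standard") - m("blank")) / m("reference_standard")
  if (!is.finite(quench) || quench <= 0) {
    abort("degenerate quench standard: quench coefficient <= 0")
  }
  net <- m("assay") - m("blank") - m("negative_control")
  nmol_in_well <- net / (emission * quench)
  act <- nmol_in_well * (homogenate_ml / (aliquot_ul / 1000)) /
    (incubation_h * soil_g)
  max(act, 0)
}

#' Ecoenzymatic stoichiometry log-ratios
#'
#' Per-sample log-ratios of enzyme pools: `ec_n = ln(BG+CBH)/ln(NAG+LAP)`,
#' `ec_p = ln(BG+CBH)/ln(ALP)`, `en_p = ln(NAG+LAP)/ln(ALP)`. A pool sum at or
#' below 1 makes a log-ratio sign-unstable; such samples are flagged (ratios
#' NA) and a warning names them.
#'
#' @param enzymes tibble with columns BG, CBH, NAG, LAP, ALP (and optionally
#'   `sample_id`, carried through)
#' @return tibble with `ec_n`, `ec_p`, `en_p`, `flagged`
#' @export
enzyme_ratios <- function(enzymes) {
  cpool <- enzymes$BG + enzymes$CBH
  npool <- enzymes$NAG + enzymes$LAP
  ppool <- enzymes$ALP
  flagged <- cpool <= 1 | npool <= 1 | ppool <= 1
  out <- tibble(
    ec_n = ifelse(flagged, NA_real_, log(cpool) / log(npool)),
    ec_p = ifelse(flagged, NA_real_, log(cpool) / log(ppool)),
    en_p = ifelse(flagged, NA_real_, log(npool) / log(ppool)),
    flagged = flagged
  )
  if ("sample_id" %in% names(enzymes)) {
    out <- bind_cols(tibble(sample_id = enzymes$sample_id), out)
  }
  if (any(flagged)) {
    warn(sprintf("%d sample(s) flagged: enzyme pool sum <= 1, log-ratio undefined",
                 sum(flagged)))
  }
  out
}

#' Ecoenzymatic vector analysis
#'
#' For each sample, `x = (BG+CBH)/((BG+CBH)+ALP)` (C- vs P-acquisition share)
#' and `y = (BG+CBH)/((BG+CBH)+(NAG+LAP))` (C- vs N-acquisition share). Vector
#' length is `sqrt(x^2+y^2)` (longer = stronger C limitation); the angle is
#' the two-argument arctangent of the point (x, y) measured from the x-axis,
#' in degrees. Angles above 45 indicate P limitation, below 45 N limitation,
#' exactly 45 balanced. Samples with x = y = 0 have an undefined angle and are
#' flagged.
#'
#' @param enzymes tibble with columns BG, CBH, NAG, LAP, ALP
#' @return tibble with `x`, `y`, `length`, `angle`, `limitation`, `flagged`
#' @examples
#' enzyme_vector(tibble::tibble(BG = 60, CBH = 20, NAG = 30, LAP = 150, ALP = 50))
#' @export
enzyme_vector <- function(enzymes) {
  cpool <- enzymes$BG + enzymes$CBH
  x <- cpool / (cpool + enzymes$ALP)
  y <- cpool / (cpool + enzymes$NAG + enzymes$LAP)
  flagged <- !is.finite(x) | !is.finite(y) | (x == 0 & y == 0)
  len <- sqrt(x^2 + y^2)
  angle <- ifelse(flagged, NA_real_, atan2(y, x) * 180 / pi)
  limitation <- dplyr::case_when(
    is.na(angle) ~ NA_character_,
    angle > 45 ~ "P_limited",
    angle < 45 ~ "N_limited",
    TRUE ~ "balanced"
  )
  out <- tibble(x = x, y = y, length = len, angle = angle,
                limitation = limitation, flagged = flagged)
  if ("sample_id" %in% names(enzymes)) {
    out <- bind_cols(tibble(sample_id = enzymes$sample_id), out)
  }
  out
}

#' Per-treatment summary of vector length and angle
#'
#' Computes per-sample vectors, then treatment means, standard errors and
#' Duncan letters for length and angle, plus the ordinary regression of angle
#' on length across samples (negative slope = N limitation eases as C
#' limitation intensifies).
#'
#' @param enzymes enzyme activity tibble with `sample_id`
#' @param metadata a [sample_metadata()] tibble
#' @param alpha significance level for Duncan letters
#' @return a `soilpem_vector_summary` list with `per_sample`, `by_treatment`
#'   (variable, treatment, mean, se, letter) and `regression` (slope,
#'   intercept, p_value, r_squared)
#' @export
vector_summary <- function(enzymes, metadata, alpha = 0.05) {
  vec <- enzyme_vector(enzymes)
  vec <- left_join(vec, metadata, by = "sample_id")
  vec <- filter(vec, !.data$flagged)
  if (min(table(as.character(vec$treatment))) < 2) {
    abort("need at least 2 replicates per treatment")
  }
  by_trt <- map(c(length = "length", angle = "angle"), function(v) {
    d <- duncan_letters(vec[[v]], vec$treatment, alpha = alpha)
    mutate(d$groups, variable = v, .before = 1)
  })
  if (stats::var(vec$length) > 0) {
    fit <- lm(angle ~ length, data = vec)
    sm <- summary(fit)
    regression <- tibble(
      slope = coef(fit)[["length"]],
      intercept = coef(fit)[["(Intercept)"]],
      p_value = sm$coefficients["length", "Pr(>|t|)"],
      r_squared = sm$r.squared
    )
  } else {
    # constant vector length: the slope is undefined
    regression <- tibble(slope = NA_real_, intercept = NA_real_,
                         p_value = NA_real_, r_squared = NA_real_)
  }
  structure(
    list(per_sample = vec, by_treatment = bind_rows(by_trt),
         regression = regression, alpha = alpha),
    class = "soilpem_vector_summary"
  )
}
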