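# Seeded synthetic-data generator emulating a 5-treatment x 4-replicate
# long-term fertilization trial: soil chemistry, bioavailable-P fractions,
# extracellular enzyme activities, per-domain OTU tables and a model-driven
# yield. Treatment contrasts of the defaults encode the study's reported
# effect structure so that every downstream stage has a known truth.

# Soil chemistry treatment means and standard errors (n = 4); SD = SE * 2.
CHEM_MEANS <- list(
  pH   = c(CK = 8.01, OPT = 7.75, OPTN = 7.67, OPTP = 7.67, OPTM = 7.70),
  SOM  = c(CK = 22.23, OPT = 26.57, OPTN = 27.45, OPTP = 26.92, OPTM = 33.16),
  TN   = c(CK = 1.23, OPT = 1.42, OPTN = 1.39, OPTP = 1.39, OPTM = 1.63),
  TP   = c(CK = 0.67, OPT = 0.99, OPTN = 1.03, OPTP = 1.15, OPTM = 1.09),
  AK   = c(CK = 82.64, OPT = 86.44, OPTN = 79.72, OPTP = 94.32, OPTM = 111.21),
  AP   = c(CK = 5.77, OPT = 48.69, OPTN = 39.89, OPTP = 92.63, OPTM = 62.84),
  AN   = c(CK = 80.30, OPT = 95.14, OPTN = 97.04, OPTP = 111.03, OPTM = 123.03),
  WEOC = c(CK = 151.90, OPT = 167.86, OPTN = 164.67, OPTP = 157.79, OPTM = 180.74),
  NO3N = c(CK = 1.09, OPT = 1.08, OPTN = 1.23, OPTP = 1.39, OPTM = 1.33),
  MBC  = c(CK = 261.89, OPT = 320.22, OPTN = 304.03, OPTP = 314.10, OPTM = 307.69),
  MBN  = c(CK = 17.71, OPT = 38.84, OPTN = 39.30, OPTP = 40.28, OPTM = 43.19),
  MBP  = c(CK = 0.35, OPT = 2.41, OPTN = 2.30, OPTP = 0.66, OPTM = 2.05)
)
CHEM_SE <- list(
  pH   = c(0.03, 0.04, 0.05, 0.11, 0.22),
  SOM  = c(0.73, 1.93, 2.24, 1.34, 2.35),
  TN   = c(0.10, 0.20, 0.03, 0.10, 0.04),
  TP   = c(0.02, 0.05, 0.15, 0.14, 0.04),
  AK   = c(3.74, 4.82, 8.58, 23.91, 12.84),
  AP   = c(5.84, 8.85, 6.07, 9.03, 9.53),
  AN   = c(13.34, 21.95, 24.22, 6.04, 19.79),
  WEOC = c(6.54, 18.05, 11.16, 7.67, 7.89),
  NO3N = c(0.07, 0.05, 0.24, 0.55, 0.15),
  MBC  = c(75.36, 65.78, 87.39, 91.94, 59.11),
  MBN  = c(8.20, 6.59, 11.71, 9.97, 6.24),
  MBP  = c(0.11, 0.48, 0.80, 0.25, 0.01)
)

# Bioavailable-P fraction means (mg/kg). CaCl2-P is flat across treatments;
# the other three encode the reported treatment contrasts (e.g. OPTM/OPT:
# Enzyme-P x1.6264, Citrate-P x1.1124, HCl-P x1.0949).
PFRACTION_MEANS <- list(
  CaCl2_P   = c(CK = 0.60, OPT = 0.62, OPTN = 0.61, OPTP = 0.63, OPTM = 0.64),
  Citrate_P = c(CK = 17.70, OPT = 28.6138, OPTN = 27.4297, OPTP = 30.50, OPTM = 31.83),
  Enzyme_P  = c(CK = 2.33, OPT = 2.30121, OPTN = 2.50, OPTP = 4.26018, OPTM = 3.74268),
  HCl_P     = c(CK = 238.02, OPT = 283.00, OPTN = 290.00, OPTP = 300.00, OPTM = 309.847)
)

# Enzyme activity means (nmol/h/g dry soil). OPTM/OPT ratios for BG, CBH and
# NAG are 1.2274, 1.4090 and 1.1809; ALP declines with fertilization. LAP is
# derived at config time from target vector angles (see derive_lap_means).
ENZYME_MEANS <- list(
  BG  = c(CK = 45, OPT = 60, OPTN = 62, OPTP = 65, OPTM = 60 * 1.2274),
  CBH = c(CK = 14, OPT = 20, OPTN = 21, OPTP = 23, OPTM = 20 * 1.4090),
  NAG = c(CK = 28, OPT = 38, OPTN = 40, OPTP = 48, OPTM = 38 * 1.1809),
  ALP = c(CK = 52, OPT = 45, OPTN = 44, OPTP = 39, OPTM = 43)
)
# target per-treatment mean vector angles (degrees); CK least N-relieved,
# OPTP most
ANGLE_TARGETS <- c(CK = 24.67, OPT = 23.8, OPTN = 23.4, OPTP = 21.86, OPTM = 22.9)

#' Derive LAP means from target vector angles
#'
#' Given C-enzyme (BG+CBH), NAG and ALP means and a target vector angle per
#' treatment, solve tan(angle) = (C + ALP) / (C + NAG + LAP) for LAP. This
#' pins the generator's mean ecoenzymatic vector angles to the configured
#' targets.
#'
#' @param bg,cbh,nag,alp named numeric vectors of treatment means
#' @param angle_deg named numeric vector of target angles in degrees
#' @return named numeric vector of LAP means
#' @export
derive_lap_means <- function(bg, cbh, nag, alp, angle_deg) {
  cpool <- bg + cbh
  n_total <- (cpool + alp) / tan(angle_deg * pi / 180) - cpool
  lap <- n_total - nag
  if (any(lap <= 0)) abort("angle targets imply non-positive LAP means")
  lap
}

#' Generator configuration
#'
#' Builds the full configuration of the synthetic study. Defaults emulate the
#' 5-treatment (CK, OPT, OPTN, OPTP, OPTM) x 4-replicate design: soil
#' chemistry centred on the study's treatment means with SD = SE * sqrt(4),
#' enzyme activities log-normal with treatment-mean ratios encoding the
#' reported percent contrasts, P fractions normal with reported contrasts,
#' OTU counts Dirichlet-multinomial with treatment-responsive taxa, and yield
#' from a linear model in SOM, AP, their interaction and Shannon diversity.
#'
#' @param n_replicates replicates per treatment (default 4)
#' @param treatments ordered treatment labels
#' @param chem_means,chem_sd named lists (per variable) of per-treatment means
#'   and standard deviations
#' @param pfraction_means named list of per-treatment P-fraction means (mg/kg)
#' @param pfraction_cv coefficient of variation for P fractions
#' @param enzyme_means named list of per-treatment means for BG, CBH, NAG,
#'   LAP, ALP (nmol/h/g); if `LAP` is absent it is derived from `angle_targets`
#' @param enzyme_cv coefficient of variation of the log-normal activity draws
#' @param angle_targets per-treatment target mean vector angles (degrees)
#' @param richness named vector: number of taxa per domain
#' @param depth sequencing depth per sample (total counts)
#' @param concentration Dirichlet concentration (overdispersion; larger =
#'   closer to multinomial)
#' @param responsive_fraction fraction of taxa per domain whose abundance
#'   responds to fertilization
#' @param effect_multipliers per-treatment abundance multipliers applied to
#'   responsive taxa
#' @param n_activated number of rare bacterial taxa switched on by
#'   fertilization (strongest under OPTM)
#' @param activation_multipliers per-treatment multipliers for activated taxa
#' @param yield_coef named list: intercept, b_SOM, b_AP, b_interaction,
#'   b_diversity, noise_sd (yield units are unitless by default)
#' @param seed integer seed; the same seed yields byte-identical datasets
#' @return a `soilpem_config` list
#' @export
generator_config <- function(n_replicates = 4,
                             treatments = TREATMENTS,
                             chem_means = CHEM_MEANS,
                             chem_sd = NULL,
                             pfraction_means = PFRACTION_MEANS,
                             pfraction_cv = 0.10,
                             enzyme_means = ENZYME_MEANS,
                             enzyme_cv = 0.08,
                             angle_targets = ANGLE_TARGETS,
                             richness = c(bacteria = 400, fungi = 160, archaea = 55),
                             depth = 10000,
                             concentration = 200,
                             responsive_fraction = 0.25,
                             effect_multipliers = c(CK = 1, OPT = 1.3, OPTN = 1.35,
                                                    OPTP = 1.4, OPTM = 1.6),
                             n_activated = 50,
                             activation_multipliers = c(CK = 1, OPT = 2000, OPTN = 2000,
                                                        OPTP = 2000, OPTM = 6000),
                             yield_coef = list(intercept = 6, b_SOM = 0.25,
                                               b_AP = 0.015, b_interaction = 0.004,
                                               b_diversity = 0.4, noise_sd = 0.35),
                             seed = 1L) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (is.null(chem_sd)) {
    chem_sd <- map(CHEM_SE, function(se) setNames(se * 2, TREATMENTS))
  }
  if (!("LAP" %in% names(enzyme_means))) {
    enzyme_means$LAP <- derive_lap_means(
      enzyme_means$BG, enzyme_means$CBH, enzyme_means$NAG, enzyme_means$ALP,
      angle_targets
    )
  }
  enzyme_means <- enzyme_means[ENZYME_COLS]
  stopifnot(
    all(map_lgl(chem_sd, ~ all(.x > 0))),
    pfraction_cv > 0, enzyme_cv > 0, depth > 0, concentration > 0,
    all(effect_multipliers > 0), all(activation_multipliers > 0)
  )
  structure(
    list(
      n_replicates = as.integer(n_replicates), treatments = treatments,
      chem_means = chem_means, chem_sd = chem_sd,
      pfraction_means = pfraction_means, pfraction_cv = pfraction_cv,
      enzyme_means = enzyme_means, enzyme_cv = enzyme_cv,
      richness = richness, depth = depth, concentration = concentration,
      responsive_fraction = responsive_fraction,
      effect_multipliers = effect_multipliers,
      n_activated = as.integer(n_activated),
      activation_multipliers = activation_multipliers,
      yield_coef = yield_coef, seed = as.integer(seed)
    ),
    class = "soilpem_config"
  )
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# log-normal draws parameterised by arithmetic mean and CV, so configured
# treatment-mean ratios hold in expectation
rlnorm_mean_cv <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a full synthetic study
#'
#' Draws, under `config$seed`, a balanced design with sample metadata, a
#' combined per-domain OTU table (Dirichlet-multinomial with
#' treatment-responsive and fertilization-activated taxa), soil chemistry,
#' P fractions, enzyme activities, and yield computed from the configured
#' linear model (centred SOM, AP, their interaction, a Shannon-diversity term,
#' Gaussian noise).
#'
#' @param config a [generator_config()]
#' @return a `soilpem_dataset` list: `metadata`, `features`, `chemistry`
#'   (includes `yield`), `enzymes`, `pfractions`, `config`
#' @examples
#' ds <- generate_dataset(generator_config(seed = 1))
#' dplyr::count(ds$metadata, treatment)
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "soilpem_config")) abort("config must be a generator_config()")
  with_seed(config$seed, {
    trts <- config$treatments
    nrep <- config$n_replicates
    metadata <- sample_metadata(
      sample_id = paste0(rep(trts, each = nrep), "_", rep(seq_len(nrep), length(trts))),
      treatment = rep(trts, each = nrep),
      replicate = rep(seq_len(nrep), length(trts))
    )
    n <- nrow(metadata)
    trt <- as.character(metadata$treatment)

    draw_normal_table <- function(means, sds) {
      as_tibble(map(names(means), function(v) {
        mu <- means[[v]][trt]
        sg <- if (is.list(sds)) sds[[v]][trt] else means[[v]][trt] * sds
        pmax(rnorm(n, mu, sg), 0)
      }) |> setNames(names(means)))
    }

    chemistry <- bind_cols(tibble(sample_id = metadata$sample_id),
                           draw_normal_table(config$chem_means, config$chem_sd))
    pfractions <- bind_cols(tibble(sample_id = metadata$sample_id),
                            draw_normal_table(config$pfraction_means,
                                              config$pfraction_cv))
    enzymes <- bind_cols(
      tibble(sample_id = metadata$sample_id),
      as_tibble(map(config$enzyme_means, function(mu) {
        rlnorm_mean_cv(n, mu[trt], config$enzyme_cv)
      }))
    )

    features <- generate_features(config, metadata)

    # yield from the configured linear model on centred predictors
    cf <- config$yield_coef
    som_c <- chemistry$SOM - mean(unlist(config$chem_means$SOM))
    ap_c <- chemistry$AP - mean(unlist(config$chem_means$AP))
    cm <- feature_counts(features)
    h <- apply(cm[features$domain == "bacteria", , drop = FALSE], 2, shannon)
    chemistry$yield <- pmax(
      cf$intercept + cf$b_SOM * som_c + cf$b_AP * ap_c +
        cf$b_interaction * som_c * ap_c +
        cf$b_diversity * (h - mean(h)) +
        rnorm(n, 0, cf$noise_sd),
      0
    )

    structure(
      list(metadata = metadata, features = features, chemistry = chemistry,
           enzymes = enzymes, pfractions = pfractions, config = config),
      class = "soilpem_dataset"
    )
  })
}

generate_features <- function(config, metadata) {
  trt <- as.character(metadata$treatment)
  n <- nrow(metadata)
  phyla <- list(
    bacteria = c("Actinobacteriota", "Proteobacteria", "Acidobacteriota",
                 "Chloroflexi", "Firmicutes", "Bacteroidota", "Gemmatimonadota"),
    fungi = c("Ascomycota", "Basidiomycota", "Mortierellomycota", "Chytridiomycota"),
    archaea = c("Crenarchaeota", "Thermoplasmatota", "Halobacterota")
  )
  out <- list()
  for (dom in names(config$richness)) {
    k <- config$richness[[dom]]
    base <- rlnorm(k, 0, 1.2)
    n_resp <- floor(k * config$responsive_fraction)
    responsive <- seq_len(n_resp)        # first block responds to fertilization
    n_act <- if (dom == "bacteria") min(config$n_activated, k - n_resp) else 0L
    activated <- if (n_act > 0) (n_resp + 1):(n_resp + n_act) else integer(0)
    if (n_act > 0) base[activated] <- mean(base) * 1e-4
    ids <- sprintf("%s_OTU%04d", dom, seq_len(k))
    ph <- sample(phyla[[dom]], k, replace = TRUE)
    tax <- sprintf("k__%s;p__%s", if (dom == "fungi") "Fungi" else
                     if (dom == "archaea") "Archaea" else "Bacteria", ph)
    counts <- matrix(0L, k, n, dimnames = list(ids, metadata$sample_id))
    for (j in seq_len(n)) {
      w <- base
      w[responsive] <- w[responsive] * config$effect_multipliers[[trt[j]]]
      if (n_act > 0) {
        w[activated] <- w[activated] * config$activation_multipliers[[trt[j]]]
      }
      p <- rdirichlet1(config$concentration * w / sum(w))
      counts[, j] <- rmultinom(1, config$depth, p)[, 1]
    }
    out[[dom]] <- feature_table(counts, dom, tax, metadata, feature_id = ids)
  }
  combined <- bind_rows(out)
  class(combined) <- c("soilpem_features", class(combined))
  combined
}

#' Spike a shared latent driver into groups of taxa
#'
#' Replaces the counts of each specified taxon group by draws from a Gaussian
#' copula with a group-shared latent factor, using a rank-preserving
#' log-normal transform that keeps each taxon's abundance scale. The factor
#' loading is chosen so the expected pairwise Spearman correlation within a
#' group equals `strength` (Pearson latent correlation 2*sin(pi*strength/6)
#' inverted through the Gaussian-copula rank-correlation identity).
#' Cross-group correlations are centred at zero.
#'
#' @param features a `soilpem_features` table
#' @param groups named list of disjoint character vectors of feature ids
#' @param strength target within-group Spearman correlation in (0, 1)
#' @param seed integer seed
#' @return the modified feature table
#' @export
spike_network_structure <- function(features, groups, strength = 0.9, seed = 1L) {
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids) > 0) abort("spiked groups must be disjoint")
  missing <- setdiff(ids, features$feature_id)
  if (length(missing) > 0) {
    abort(paste0("unknown feature id(s): ", paste(missing, collapse = ", ")))
  }
  if (strength < 0 || strength >= 1) abort("strength must be in [0, 1)")
  # latent pairwise Pearson that yields the target Spearman under a Gaussian
  # copula: rho_s = (6/pi) asin(r/2)  =>  r = 2 sin(pi rho_s / 6)
  r_latent <- 2 * sin(pi * strength / 6)
  loading <- sqrt(r_latent)
  cm <- feature_counts(features)
  n <- ncol(cm)
  with_seed(seed, {
    for (g in groups) {
      z <- rnorm(n)
      for (id in g) {
        i <- match(id, features$feature_id)
        lat <- loading * z + sqrt(1 - loading^2) * rnorm(n)
        mu <- log(mean(cm[i, ]) + 20)
        newc <- round(exp(mu + lat))
        features[i, colnames(cm)] <- as.list(as.integer(newc))
      }
    }
  })
  features
}

#' Write every table of a dataset as tab-delimited text
#'
#' @param dataset a [generate_dataset()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  write_feature_table(dataset$features, file.path(dir, "features.tsv"))
  write_sample_table(dataset$chemistry, file.path(dir, "chemistry.tsv"))
  write_sample_table(dataset$enzymes, file.path(dir, "enzymes.tsv"))
  write_sample_table(dataset$pfractions, file.path(dir, "pfractions.tsv"))
  invisible(dir)
}
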