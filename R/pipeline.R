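# End-to-end orchestration: simulate (or load) -> validate -> enzymes ->
# treatment statistics -> diversity/ordination -> network -> associations ->
# latent models, writing one report directory of TSVs plus a manifest.

#' Pipeline configuration
#'
#' @param out_dir report directory
#' @param simulate a [generator_config()] to generate the dataset; set
#'   `input_dir` instead to read tables written by [write_dataset()]
#' @param input_dir directory of TSV inputs (overrides `simulate`)
#' @param stages character vector of stages to run, a subset of
#'   `c("enzymes","group_stats","community","network","association","latent")`
#' @param r_min,p_max network screen thresholds
#' @param alpha Duncan significance level
#' @param n_perm permutations for Mantel and random-forest significance
#' @param bootstrap_n PLS-PM bootstrap resamples
#' @param rf_trees trees per random forest
#' @param seed global seed; per-stage seeds derive from it via [stage_seed()]
#' @return a `soilpem_pipeline_config` list
#' @export
pipeline_config <- function(out_dir,
                            simulate = generator_config(),
                            input_dir = NULL,
                            stages = c("enzymes", "group_stats", "community",
                                       "network", "association", "latent"),
                            r_min = 0.75, p_max = 0.01, alpha = 0.05,
                            n_perm = 199, bootstrap_n = 200, rf_trees = 500,
                            seed = 1L) {
  structure(
    list(out_dir = out_dir, simulate = simulate, input_dir = input_dir,
         stages = stages, r_min = r_min, p_max = p_max, alpha = alpha,
         n_perm = n_perm, bootstrap_n = bootstrap_n, rf_trees = rf_trees,
         seed = as.integer(seed)),
    class = "soilpem_pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; `simulate`
#' may be a mapping of [generator_config()] arguments.
#'
#' @param path YAML file
#' @return a `soilpem_pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (is.list(y$simulate)) do.call(generator_config, y$simulate) else generator_config()
  args <- y[setdiff(names(y), "simulate")]
  do.call(pipeline_config, c(args, list(simulate = sim)))
}

#' Numeric fertilizer-dose indicators from the design
#'
#' Encodes each treatment as relative N dose, relative P dose and a straw
#' (organic input) indicator: CK (0, 0, 0), OPT (1, 1, 0), OPTN (1.5, 1, 0),
#' OPTP (1, 1.5, 0), OPTM (1, 1, 1).
#'
#' @param metadata a [sample_metadata()] tibble
#' @return tibble: `sample_id`, `N_dose`, `P_dose`, `straw`
#' @export
treatment_doses <- function(metadata) {
  lvl <- as.character(metadata$treatment)
  tibble(
    sample_id = metadata$sample_id,
    N_dose = dplyr::case_when(lvl == "CK" ~ 0, lvl == "OPTN" ~ 1.5, TRUE ~ 1),
    P_dose = dplyr::case_when(lvl == "CK" ~ 0, lvl == "OPTP" ~ 1.5, TRUE ~ 1),
    straw = as.numeric(lvl == "OPTM")
  )
}

#' Default PLS-PM block structure for a pipeline dataset
#'
#' Fertilization doses -> P fractions -> enzyme activities and microbial
#' community -> yield, all reflective.
#'
#' @return a [plspm_spec()]
#' @export
default_plspm_spec <- function() {
  plspm_spec(
    blocks = list(
      fertilization = c("N_dose", "P_dose", "straw"),
      pfractions = c("Citrate_P", "Enzyme_P", "HCl_P"),
      enzymes = c("BG", "CBH", "NAG"),
      microbial = c("shannon", "richness"),
      yield = "yield"
    ),
    paths = list(
      pfractions = "fertilization",
      enzymes = c("fertilization", "pfractions"),
      microbial = c("fertilization", "pfractions"),
      yield = c("pfractions", "enzymes", "microbial")
    )
  )
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the dataset, refuses to run on fatal validation
#' findings, executes the enabled stages, and writes per-stage TSVs plus a
#' `manifest.yaml` recording thresholds and seeds. Outputs are byte-identical
#' for identical config and seed.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list of stage results
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  ds <- run_stage("data", {
    if (!is.null(config$input_dir)) {
      md <- readr::read_tsv(file.path(config$input_dir, "metadata.tsv"),
                            show_col_types = FALSE, progress = FALSE)
      metadata <- sample_metadata(md$sample_id, md$treatment, md$replicate)
      list(
        metadata = metadata,
        features = read_feature_table(file.path(config$input_dir, "features.tsv"), metadata),
        chemistry = read_soil_chemistry(file.path(config$input_dir, "chemistry.tsv")),
        enzymes = read_enzyme_table(file.path(config$input_dir, "enzymes.tsv")),
        pfractions = read_pfraction_table(file.path(config$input_dir, "pfractions.tsv"))
      )
    } else {
      sim <- config$simulate
      sim$seed <- stage_seed(seed, 1)
      generate_dataset(sim)
    }
  })

  report <- validate_dataset(ds$metadata, ds$features, ds$chemistry,
                             ds$enzymes, ds$pfractions)
  readr::write_tsv(report, file.path(config$out_dir, "validation.tsv"),
                   progress = FALSE)
  if (has_fatal(report)) {
    abort("validation found fatal issues; see validation.tsv")
  }
  write_dataset(ds, file.path(config$out_dir, "data"))
  results <- list(dataset = ds, validation = report)
  trt <- ds$metadata$treatment
  out <- function(name) file.path(config$out_dir, name)

  if ("enzymes" %in% config$stages) {
    results$enzymes <- run_stage("enzymes", {
      ratios <- suppressWarnings(enzyme_ratios(ds$enzymes))
      vs <- vector_summary(ds$enzymes, ds$metadata, alpha = config$alpha)
      readr::write_tsv(ratios, out("enzyme_ratios.tsv"), progress = FALSE)
      readr::write_tsv(vs$per_sample, out("enzyme_vectors.tsv"), progress = FALSE)
      readr::write_tsv(vs$by_treatment, out("vector_summary.tsv"), progress = FALSE)
      readr::write_tsv(vs$regression, out("vector_regression.tsv"), progress = FALSE)
      vs
    })
  }

  if ("group_stats" %in% config$stages) {
    results$group_stats <- run_stage("group_stats", {
      tabs <- list(chemistry = ds$chemistry, pfractions = ds$pfractions,
                   enzymes = ds$enzymes)
      summ <- bind_rows(imap(tabs, function(tab, tname) {
        vars <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], "sample_id")
        bind_rows(map(setNames(vars, vars), function(v) {
          d <- duncan_letters(tab[[v]], trt, alpha = config$alpha)
          mutate(d$groups, table = tname, variable = v, .before = 1)
        }))
      }))
      contrasts <- summ |>
        group_by(.data$table, .data$variable) |>
        summarise(
          pct_vs_CK = percent_change(.data$mean[.data$group == "OPTM"],
                                     .data$mean[.data$group == "CK"]),
          pct_vs_OPT = percent_change(.data$mean[.data$group == "OPTM"],
                                      .data$mean[.data$group == "OPT"]),
          .groups = "drop"
        )
      readr::write_tsv(summ, out("treatment_summary.tsv"), progress = FALSE)
      readr::write_tsv(contrasts, out("optm_contrasts.tsv"), progress = FALSE)
      list(summary = summ, contrasts = contrasts)
    })
  }

  if ("community" %in% config$stages) {
    results$community <- run_stage("community", {
      adiv <- bind_rows(map(
        setNames(unique(ds$features$domain), unique(ds$features$domain)),
        function(dom) mutate(alpha_diversity(ds$features, dom), domain = dom,
                             .before = 1)
      ))
      ord <- nmds(bray_curtis_matrix(ds$features), k = 2,
                  seed = stage_seed(seed, 3))
      readr::write_tsv(adiv, out("alpha_diversity.tsv"), progress = FALSE)
      readr::write_tsv(ord$coordinates, out("nmds_coordinates.tsv"), progress = FALSE)
      readr::write_tsv(glance(ord), out("nmds_stress.tsv"), progress = FALSE)
      list(alpha = adiv, nmds = ord)
    })
  }

  if ("network" %in% config$stages) {
    results$network <- run_stage("network", {
      edges <- correlation_screen(ds$features, r_min = config$r_min,
                                  p_max = config$p_max)
      net <- detect_modules(build_network(edges, ds$features),
                            seed = stage_seed(seed, 4))
      topo <- zi_pi(net)
      keys <- keystone_report(topo, ds$features)
      subs <- bind_rows(map(
        setNames(levels(trt), levels(trt)),
        function(t) mutate(extract_subnetwork(net, ds$features, ds$metadata, t)$metrics,
                           treatment = t, .before = 1)
      ))
      write_edge_list(net, out("network_edges.tsv"))
      readr::write_tsv(topo, out("network_zipi.tsv"), progress = FALSE)
      readr::write_tsv(net$metrics, out("network_metrics.tsv"), progress = FALSE)
      readr::write_tsv(subs, out("subnetwork_metrics.tsv"), progress = FALSE)
      readr::write_tsv(keys$hubs, out("keystone_taxa.tsv"), progress = FALSE)
      readr::write_tsv(keys$domain_composition, out("network_domains.tsv"),
                       progress = FALSE)
      list(network = net, topology = topo, keystones = keys, subnetworks = subs)
    })
  }

  if ("association" %in% config$stages) {
    results$association <- run_stage("association", {
      env <- left_join(ds$chemistry, ds$pfractions, by = "sample_id")
      mant <- mantel_panel(ds$features, env, n_perm = config$n_perm,
                           seed = stage_seed(seed, 5))
      phyla <- phylum_abundances(ds$features)
      panel <- correlation_panel(phyla, env)
      glm_fit <- yield_glm(ds$chemistry)
      readr::write_tsv(mant, out("mantel_tests.tsv"), progress = FALSE)
      readr::write_tsv(panel, out("correlation_panel.tsv"), progress = FALSE)
      readr::write_tsv(tidy(glm_fit), out("yield_glm.tsv"), progress = FALSE)
      list(mantel = mant, panel = panel, yield_glm = glm_fit)
    })
  }

  if ("latent" %in% config$stages) {
    results$latent <- run_stage("latent", {
      adiv <- alpha_diversity(ds$features, "bacteria")
      dat <- ds$chemistry |>
        left_join(ds$pfractions, by = "sample_id") |>
        left_join(ds$enzymes, by = "sample_id") |>
        left_join(adiv, by = "sample_id") |>
        left_join(treatment_doses(ds$metadata), by = "sample_id")
      rf <- rf_importance(
        select(dat, -"sample_id", -"yield", -"N_dose", -"P_dose", -"straw"),
        dat$yield, n_trees = config$rf_trees, n_perm = config$n_perm,
        seed = stage_seed(seed, 6)
      )
      spec <- default_plspm_spec()
      boot <- plspm_bootstrap(dat, spec, bootstrap_n = config$bootstrap_n,
                              seed = stage_seed(seed, 7))
      fit <- plspm_fit(dat, spec)
      readr::write_tsv(rf, out("rf_importance.tsv"), progress = FALSE)
      readr::write_tsv(boot, out("plspm_paths.tsv"), progress = FALSE)
      readr::write_tsv(fit$outer, out("plspm_loadings.tsv"), progress = FALSE)
      list(rf = rf, plspm = fit, plspm_boot = boot)
    })
  }

  manifest <- list(
    package = "soilpem",
    version = as.character(utils::packageVersion("soilpem")),
    seed = seed,
    stages = config$stages,
    thresholds = list(r_min = config$r_min, p_max = config$p_max,
                      alpha = config$alpha, n_perm = config$n_perm,
                      bootstrap_n = config$bootstrap_n)
  )
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(results)
}

#' Mean relative abundance per phylum per sample
#'
#' @param features a `soilpem_features` table
#' @param top keep the `top` most abundant phyla (default 10)
#' @return tibble: `sample_id` plus one relative-abundance column per phylum
#' @export
phylum_abundances <- function(features, top = 10) {
  cm <- feature_counts(features)
  rel <- sweep(cm, 2, pmax(colSums(cm), 1), "/")
  ph <- parse_phylum(features$taxonomy)
  agg <- rowsum(rel, ph)
  keep <- names(sort(rowSums(agg), decreasing = TRUE))[seq_len(min(top, nrow(agg)))]
  out <- as_tibble(t(agg[keep, , drop = FALSE]))
  bind_cols(tibble(sample_id = colnames(cm)), out)
}
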