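#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Inputs may be file paths
#' (literature CSV, biome GeoJSON, stack manifest directory) or in-memory
#' objects; when all three are `NULL` the synthetic generator supplies them.
#' Stage parameters default to the analysis constants the pipeline is built
#' around: a 100 km domain buffer, urban/agricultural exclusion, a
#' 100,000-pixel background sample, a 0.70 collinearity threshold, a 0.5
#' coverage threshold, and 99 cross-validation permutations at a 70/30
#' split.
#'
#' @param literature,biomes,stack Paths or objects ([lit_table()],
#'   [biome_layer()], [env_stack()]); `NULL` = synthesize.
#' @param synthetic A [synthetic_config()] used when inputs are `NULL`.
#' @param outdir Output directory (`NULL` = write nothing).
#' @param buffer_km Domain buffer in km.
#' @param excluded_habitats Habitat labels removed before analysis.
#' @param n_background Background pixel sample size.
#' @param n_bins Histogram bins per axis.
#' @param pairs Covariate pairs for the environmental-space comparison.
#' @param model_covariates Explanatory variables offered to the ensemble
#'   (screened for collinearity before fitting).
#' @param model An [ensemble_config()].
#' @param collinearity_threshold Pairwise |r| ceiling for retained
#'   covariates.
#' @param n_perm,train_frac Cross-validation permutations and training
#'   fraction.
#' @param threshold Coverage probability threshold.
#' @param lai_fill_window Focal window (cells) for LAI gap filling.
#' @param seed Master seed; stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(literature = NULL, biomes = NULL, stack = NULL,
                            synthetic = synthetic_config(),
                            outdir = NULL,
                            buffer_km = 100,
                            excluded_habitats = c("urban", "agricultural"),
                            n_background = 100000,
                            n_bins = 50,
                            pairs = list(c("MAT", "MAP"), c("dMAT", "dMAP"),
                                         c("LAI", "SOC"),
                                         c("plant_rich", "animal_rich")),
                            model_covariates = c("MAT", "MAP", "SOC", "LAI",
                                                 "plant_rich", "animal_rich"),
                            model = ensemble_config(),
                            collinearity_threshold = 0.70,
                            n_perm = 99, train_frac = 0.7, threshold = 0.5,
                            lai_fill_window = 19,
                            seed = 1) {
  cfg <- as.list(environment())
  for (nm in c("literature", "biomes", "stack")) {
    v <- cfg[[nm]]
    if (is.character(v) && !file.exists(v) && !dir.exists(v)) {
      stop_tropirep(sprintf("configured %s path does not exist: %s", nm, v),
                    "config_error")
    }
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_tropirep(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)), "pipeline_error")
  })
}

#' Run the full representativeness pipeline
#'
#' Sequences every stage: (synthesize or) load inputs; filter urban and
#' agricultural locations and re-allocate citations; build the buffered
#' tropical domain, clip and label locations, and summarize per-biome shares
#' and coarse density grids; fill LAI gaps and extract covariates at
#' locations and at a random background sample; compare occurrence, sampling
#' and citation frequencies in 2D environmental space; build pseudo-absences,
#' screen collinearity, fit the three-member ensemble, map the median
#' probability with its covered-area share, and cross-validate with
#' repeated stratified splits.
#'
#' With an `outdir`, the run writes `biome_summary.csv`, `histograms.json`,
#' `probability.asc`, `coverage_cv.json`, `filter_report.json`, density
#' grids, and `manifest.json` (package version, config echo, derived stage
#' seeds) — enough to reproduce the run exactly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with every stage result (`literature`,
#'   `filtered`, `domain`, `labeled`, `summary`, `density`, `background`,
#'   `histograms`, `pa_table`, `screen`, `model`, `map`, `cv`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  syn <- config$synthetic
  syn$seed <- derive_seed(seed, "synthetic")

  stack <- pipeline_stage("stack", {
    s <- config$stack
    if (is.null(s)) gen_stack(syn)
    else if (is.character(s)) read_stack(s)
    else s
  })
  biomes <- pipeline_stage("biomes", {
    b <- config$biomes
    if (is.null(b)) gen_biomes(stack, syn)
    else if (is.character(b)) read_biomes_geojson(b)
    else b
  })
  literature <- pipeline_stage("literature", {
    l <- config$literature
    if (is.null(l)) gen_literature(stack, syn)
    else if (is.character(l)) read_literature_table(l)
    else l
  })

  filtered <- pipeline_stage("filter", {
    filter_natural_habitats(literature, excluded = config$excluded_habitats)
  })

  domain <- pipeline_stage("domain", {
    build_domain(biomes, stack, buffer_km = config$buffer_km)
  })
  labeled <- pipeline_stage("assign", {
    assign_locations(filtered, biomes, domain)
  })
  areas <- pipeline_stage("areas", biome_areas(biomes, domain))
  summary_tbl <- pipeline_stage("summary", biome_summary(labeled, areas))
  density <- pipeline_stage("density", list(
    locations = grid_density(labeled, domain, weight = "locations"),
    citations = grid_density(labeled, domain, weight = "citations")
  ))

  stack_filled <- pipeline_stage("lai_fill", {
    if ("LAI" %in% names(stack$layers)) {
      filled <- focal_fill(stack$layers$LAI, window = config$lai_fill_window)
      env_stack(modifyList(stack$layers, list(LAI = filled)),
                domain_mask = stack$domain_mask & domain$buffered_mask)
    } else {
      env_stack(stack$layers,
                domain_mask = stack$domain_mask & domain$buffered_mask)
    }
  })

  background <- pipeline_stage("background", {
    sample_background(stack_filled, n = config$n_background,
                      seed = derive_seed(seed, "background"))
  })
  loc_cov <- pipeline_stage("extract", {
    extract_at_points(stack_filled,
                      labeled[c("longitude", "latitude",
                                "allocated_citations")])
  })
  histograms <- pipeline_stage("envspace", {
    env_space_comparison(background, loc_cov, pairs = config$pairs,
                         n_bins = config$n_bins)
  })

  pa <- pipeline_stage("pseudo_absences", {
    make_pseudo_absences(stack_filled, labeled,
                         seed = derive_seed(seed, "absences"),
                         covariates = config$model_covariates)
  })
  screen <- pipeline_stage("screen", {
    collinearity_screen(pa, covariates = config$model_covariates,
                        threshold = config$collinearity_threshold)
  })
  model <- pipeline_stage("fit", {
    fit_ensemble(pa, covariates = screen$retained, config = config$model,
                 seed = derive_seed(seed, "fit"))
  })
  map_res <- pipeline_stage("map", {
    predict_map(model, stack_filled, threshold = config$threshold)
  })
  cv <- pipeline_stage("crossval", {
    cross_validate(pa, covariates = screen$retained, config = config$model,
                   n_perm = config$n_perm, train_frac = config$train_frac,
                   seed = derive_seed(seed, "cv"))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("tropirep")),
    seed = seed,
    stage_seeds = list(
      synthetic = syn$seed,
      background = derive_seed(seed, "background"),
      absences = derive_seed(seed, "absences"),
      fit = derive_seed(seed, "fit"),
      cv = derive_seed(seed, "cv")
    ),
    parameters = config[c("buffer_km", "excluded_habitats", "n_background",
                          "n_bins", "model_covariates",
                          "collinearity_threshold", "n_perm", "train_frac",
                          "threshold", "lai_fill_window")],
    counts = list(
      input = as.list(summarize_counts(literature)),
      filtered = as.list(summarize_counts(filtered)),
      clipped = clip_report(labeled)
    ),
    screen = list(retained = screen$retained,
                  dropped = screen$dropped$variable),
    results = list(mean_auc = cv$mean_auc,
                   covered_fraction = map_res$covered_fraction)
  )

  result <- list(literature = literature, filtered = filtered,
                 biomes = biomes, stack = stack_filled, domain = domain,
                 labeled = labeled, areas = areas, summary = summary_tbl,
                 density = density, background = background,
                 histograms = histograms, pa_table = pa, screen = screen,
                 model = model, map = map_res, cv = cv, manifest = manifest)

  if (!is.null(config$outdir)) {
    pipeline_stage("write", write_pipeline_outputs(result, config$outdir))
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$summary, file.path(outdir, "biome_summary.csv"))
  write_hist2d_json(result$histograms, file.path(outdir, "histograms.json"))
  write_ascii_grid(result$map$probability,
                   file.path(outdir, "probability.asc"))
  write_ascii_grid(result$density$locations,
                   file.path(outdir, "location_density.asc"))
  write_ascii_grid(result$density$citations,
                   file.path(outdir, "citation_density.asc"))
  jsonlite::write_json(
    list(coverage = list(threshold = result$map$threshold,
                         covered_fraction = result$map$covered_fraction,
                         covered_area_km2 = result$map$covered_area_km2),
         cross_validation = list(
           n_permutations = result$cv$n_permutations,
           train_fraction = result$cv$train_fraction,
           mean_auc = result$cv$mean_auc, min_auc = result$cv$min_auc,
           max_auc = result$cv$max_auc, auc_values = result$cv$auc_values)),
    file.path(outdir, "coverage_cv.json"), auto_unbox = TRUE, digits = NA
  )
  write_filter_report(result$filtered, file.path(outdir, "filter_report.json"))
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @method autoplot biome_summary
#' @export
autoplot.biome_summary <- function(object, ...) {
  d <- object |>
    select("biome", "pct_area", "pct_locations", "pct_citations") |>
    tidyr::pivot_longer(-"biome", names_to = "share", values_to = "pct")
  ggplot(d, aes(.data$pct, .data$biome, fill = .data$share)) +
    geom_col(position = "dodge") +
    labs(x = "% of total", y = NULL, fill = NULL) +
    theme_minimal()
}
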