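#' Select rare species by prevalence
#'
#' Applies the two-stage prevalence rule used for rare-species modelling:
#' species with fewer than `max_occ_exclusive` occurrences are pre-selected
#' as rare, and among them only those with at least `min_occ` occurrences
#' are retained (enough records for meaningful presence-background models).
#'
#' @param occurrence_table tibble of occurrence records with a `species_id`
#'   column (and optionally `guild`).
#' @param min_occ minimum occurrence count, inclusive (default 5).
#' @param max_occ_exclusive rarity ceiling, exclusive (default 30).
#' @return A list with `species` (tibble `species_id`, `guild` if present,
#'   `n_occurrences` of the retained species) and `report` (tibble of
#'   selection-stage counts: total species, rare species below the ceiling,
#'   retained species).
#' @export
select_rare_species <- function(occurrence_table, min_occ = 5,
                                max_occ_exclusive = 30) {
  if (nrow(occurrence_table) == 0)
    stop("`occurrence_table` is empty", call. = FALSE)
  if (min_occ <= 0 || min_occ > max_occ_exclusive)
    stop("need 0 < min_occ <= max_occ_exclusive", call. = FALSE)
  counts <- occurrence_table |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      guild = if ("guild" %in% names(occurrence_table))
        dplyr::first(.data$guild) else NA_character_,
      n_occurrences = dplyr::n(), .groups = "drop")
  rare <- dplyr::filter(counts, .data$n_occurrences < max_occ_exclusive)
  kept <- dplyr::filter(rare, .data$n_occurrences >= min_occ)
  list(
    species = kept,
    report = tibble::tibble(
      stage = c("total", "rare", "retained"),
      n = c(nrow(counts), nrow(rare), nrow(kept))
    )
  )
}

#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with the defaults the
#' method prescribes: rarity window `[5, 30)`, 10,000 shared background
#' points, `|r| > 0.7` collinearity screening, 10 random stratified 80/20
#' cross-validation splits, Maxent-style + random-forest learners, block
#' aggregation factor 10 and 999-permutation Lee's L classification.
#'
#' @param scenario optional [synthetic_scenario()] — when supplied the run
#'   generates its own landscape, plots and virtual species cohort.
#' @param stack optional [predictor_stack()] for a real-data run.
#' @param occurrences optional occurrence tibble
#'   (`species_id, x, y, guild`) for a real-data run.
#' @param n_by_guild cohort composition for scenario runs (default
#'   33 mosses, 14 liverworts, 5 sphagna).
#' @param rarity_min_occurrences,rarity_max_occurrences prevalence window
#'   (inclusive minimum 5; exclusive maximum 30).
#' @param n_background number of shared background points (default 10000).
#' @param correlation_threshold collinearity cutoff (default 0.7).
#' @param keep_priority predictor preference order for the screen.
#' @param learners named list of learner descriptions.
#' @param n_reps,train_frac cross-validation scheme (10 and 0.8).
#' @param aggregation_factor block size for pre-Lee aggregation (10).
#' @param lee list of Lee-stage settings: `enabled`, `scheme`, `n_sims`,
#'   `permute`.
#' @param write_maps write per-species continuous/binary map CSVs.
#' @param seed master seed; all stage seeds are derived from it.
#' @return An `esm_config` list.
#' @export
esm_config <- function(scenario = NULL, stack = NULL, occurrences = NULL,
                       n_by_guild = c(moss = 33, liverwort = 14, sphagna = 5),
                       rarity_min_occurrences = 5,
                       rarity_max_occurrences = 30,
                       n_background = 10000,
                       correlation_threshold = 0.7,
                       keep_priority = c("NDWI1", "BSI"),
                       learners = list(maxent = maxent_learner(),
                                       rf = rf_learner()),
                       n_reps = 10, train_frac = 0.8,
                       aggregation_factor = 10,
                       lee = list(enabled = FALSE, scheme = "queen",
                                  n_sims = 999, permute = "y"),
                       write_maps = TRUE, seed = 1L) {
  if (rarity_min_occurrences <= 0 ||
      rarity_min_occurrences > rarity_max_occurrences)
    stop("need 0 < rarity_min_occurrences <= rarity_max_occurrences",
         call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must lie in (0, 1)", call. = FALSE)
  if (is.null(scenario) && (is.null(stack) || is.null(occurrences)))
    stop("supply either `scenario` or both `stack` and `occurrences`",
         call. = FALSE)
  structure(list(scenario = scenario, stack = stack,
                 occurrences = occurrences, n_by_guild = n_by_guild,
                 rarity_min_occurrences = rarity_min_occurrences,
                 rarity_max_occurrences = rarity_max_occurrences,
                 n_background = n_background,
                 correlation_threshold = correlation_threshold,
                 keep_priority = keep_priority, learners = learners,
                 n_reps = n_reps, train_frac = train_frac,
                 aggregation_factor = aggregation_factor, lee = lee,
                 write_maps = write_maps, seed = as.integer(seed)),
            class = "esm_config")
}

write_layer_csv <- function(layer, path) {
  utils::write.csv(unclass(layer), path, row.names = FALSE)
  invisible(path)
}

#' Run the rare-species ESM pipeline end to end
#'
#' Executes: landscape/cohort generation (scenario runs) or input loading,
#' prevalence-based species selection, background sampling, collinearity
#' screening, per-species ESM fitting and pooled cross-validation
#' evaluation, max-sensitivity-plus-specificity binarization, richness
#' stacking overall and per guild, and (optionally) local Lee's L
#' concordance between the overall and per-guild richness surfaces at the
#' aggregated resolution. Per-species failures are logged into the manifest
#' and do not abort the run.
#'
#' @param config an [esm_config()].
#' @param out_dir output directory (created if missing). Writes
#'   `metrics.csv`, `correlations.csv`, `selection_report.csv`,
#'   `richness_<group>.csv`, per-species map CSVs (optional) and
#'   `manifest.json`.
#' @return Invisibly, a list with `metrics`, `selection`, `screen`,
#'   `richness`, `lee`, `models` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("esm_run_")) {
  stopifnot(inherits(config, "esm_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  if (!is.null(config$scenario)) {
    scen <- config$scenario
    stack <- gen_predictor_stack(scen)
    plots <- gen_plot_network(scen)
    cohort <- simulate_cohort(stack, plots, n_by_guild = config$n_by_guild,
                              seed = derive_seed(seed, "cohort"))
    occurrences <- cohort$occurrences
  } else {
    stack <- config$stack
    occurrences <- config$occurrences
  }
  selection <- select_rare_species(occurrences,
                                   config$rarity_min_occurrences,
                                   config$rarity_max_occurrences)
  background <- make_background(stack, n = config$n_background,
                                seed = derive_seed(seed, "background"))
  screen <- correlation_filter(stack, background,
                               threshold = config$correlation_threshold,
                               keep_priority = config$keep_priority)
  retained_preds <- screen$retained
  species_ids <- selection$species$species_id
  metrics <- list(); models <- list(); binary_maps <- list()
  outcomes <- list()
  for (sp in species_ids) {
    occ_sp <- dplyr::filter(occurrences, .data$species_id == sp)
    res <- tryCatch({
      training <- assemble_training(occ_sp, background, stack)
      esm <- fit_esm(training, predictors = retained_preds,
                     learners = config$learners, n_reps = config$n_reps,
                     train_frac = config$train_frac,
                     seed = derive_seed(seed, paste0("fit_", sp)))
      met <- evaluate_esm(esm, species_id = sp)
      met$guild <- occ_sp$guild[1]
      met$n_occurrences <- nrow(occ_sp)
      if (!isTRUE(esm$unmodellable)) {
        cont <- predict_esm(esm, stack)
        bin <- binarize(cont, met$threshold)
        if (config$write_maps) {
          write_layer_csv(cont, file.path(out_dir,
                                          paste0("suitability_", sp, ".csv")))
          write_layer_csv(bin, file.path(out_dir,
                                         paste0("binary_", sp, ".csv")))
        }
        binary_maps[[sp]] <- bin
      }
      models[[sp]] <- esm
      metrics[[sp]] <- met
      list(status = "ok", unmodellable = isTRUE(esm$unmodellable))
    }, error = function(e) {
      metrics[[sp]] <<- tibble::tibble(
        species_id = sp, auc = NA_real_, tss = NA_real_,
        sensitivity = NA_real_, threshold = NA_real_,
        better_than_random = FALSE, guild = occ_sp$guild[1],
        n_occurrences = nrow(occ_sp))
      list(status = "error", message = conditionMessage(e))
    })
    outcomes[[sp]] <- res
  }
  metrics <- dplyr::bind_rows(metrics) |>
    dplyr::select("species_id", "guild", "n_occurrences", "auc", "tss",
                  "sensitivity", "threshold", "better_than_random")
  richness <- NULL
  if (length(binary_maps)) {
    ga <- stats::setNames(selection$species$guild,
                          selection$species$species_id)
    richness <- guild_richness(binary_maps, ga)
    for (g in names(richness))
      write_layer_csv(richness[[g]],
                      file.path(out_dir, paste0("richness_", g, ".csv")))
  }
  lee_results <- NULL
  if (isTRUE(config$lee$enabled) && !is.null(richness)) {
    agg <- lapply(richness, aggregate_mean,
                  factor = config$aggregation_factor)
    w <- build_weights(dim(agg$all), scheme = config$lee$scheme)
    lee_results <- lapply(setdiff(names(agg), "all"), function(g) {
      tryCatch(
        monte_carlo_classify(agg$all, agg[[g]], w,
                             n_sims = config$lee$n_sims,
                             seed = derive_seed(seed, paste0("lee_", g)),
                             permute = config$lee$permute),
        error = function(e) NULL)   # e.g. zero-variance guild surface
    })
    names(lee_results) <- setdiff(names(agg), "all")
  }
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(screen$correlations),
                   file.path(out_dir, "correlations.csv"))
  utils::write.csv(selection$report,
                   file.path(out_dir, "selection_report.csv"),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rarescape")),
    config_hash = rlang::hash(config),
    master_seed = seed,
    stage_seeds = list(background = derive_seed(seed, "background"),
                       cohort = derive_seed(seed, "cohort")),
    retained_predictors = retained_preds,
    dropped_predictors = screen$dropped,
    n_species = length(species_ids),
    outcomes = outcomes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(metrics = metrics, selection = selection, screen = screen,
                 richness = richness, lee = lee_results, models = models,
                 manifest = manifest, out_dir = out_dir))
}

#' Read or write a scenario-based run configuration as YAML
#'
#' Only scenario-driven configurations (no in-memory stacks or occurrence
#' tables) can be serialized.
#'
#' @param config an [esm_config()] built from a [synthetic_scenario()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` an
#'   [esm_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "esm_config"))
  if (is.null(config$scenario))
    stop("only scenario-based configs can be serialized", call. = FALSE)
  lst <- unclass(config)
  lst$scenario <- unclass(lst$scenario)
  lst$scenario$target_correlations <-
    as.list(as.data.frame(lst$scenario$target_correlations))
  lst$n_by_guild <- as.list(lst$n_by_guild)   # yaml drops names on vectors
  lst$learners <- lapply(config$learners, function(l)
    c(list(type = sub("_learner$", "", class(l)[1])), unclass(l)))
  lst$stack <- NULL; lst$occurrences <- NULL
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  sc <- lst$scenario
  scenario <- synthetic_scenario(
    grid_rows = sc$grid_rows, grid_cols = sc$grid_cols,
    cell_size = sc$cell_size, n_predictors = sc$n_predictors,
    autocorr_range = sc$autocorr_range,
    target_correlations = as.matrix(as.data.frame(sc$target_correlations)),
    n_plots = sc$n_plots, plot_clustering = sc$plot_clustering,
    seed = sc$seed)
  learners <- lapply(lst$learners, function(l) {
    switch(l$type,
           maxent = maxent_learner(regularization = l$regularization),
           rf = rf_learner(n_trees = l$n_trees),
           constant = constant_learner(p = l$p),
           stop("unknown learner type: ", l$type, call. = FALSE))
  })
  esm_config(
    scenario = scenario,
    n_by_guild = unlist(lst$n_by_guild),
    rarity_min_occurrences = lst$rarity_min_occurrences,
    rarity_max_occurrences = lst$rarity_max_occurrences,
    n_background = lst$n_background,
    correlation_threshold = lst$correlation_threshold,
    keep_priority = lst$keep_priority,
    learners = learners,
    n_reps = lst$n_reps, train_frac = lst$train_frac,
    aggregation_factor = lst$aggregation_factor,
    lee = lst$lee, write_maps = lst$write_maps, seed = lst$seed)
}
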