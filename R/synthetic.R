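#' Describe a synthetic landscape scenario
#'
#' A scenario fixes everything the synthetic landscape generator needs: grid
#' shape, number of standardized predictor layers and their target pairwise
#' Pearson correlations, the spatial autocorrelation range of each layer, and
#' the size of the sampling-plot network. The defaults emulate the study
#' design the package is built around: five weakly inter-correlated,
#' spatially autocorrelated, standardized predictors over a 30 m grid and a
#' network of 389 presence-only survey plots.
#'
#' @param grid_rows,grid_cols grid shape in cells (each at least 10).
#' @param cell_size cell edge length in metres (default 30).
#' @param n_predictors number of predictor layers (at least 2; default 5).
#' @param autocorr_range autocorrelation range in cells: the distance over
#'   which field correlation decays to roughly `exp(-1)` (default 8).
#' @param target_correlations symmetric positive-definite matrix of target
#'   pairwise Pearson correlations with unit diagonal (default identity,
#'   i.e. uncorrelated predictors).
#' @param n_plots number of survey plots (default 389).
#' @param plot_clustering non-negative clustering knob for the plot network:
#'   0 (default) samples plots uniformly without replacement; values > 0
#'   concentrate plots around a few seeded cluster centres with Gaussian
#'   spread `autocorr_range` cells.
#' @param seed integer seed driving every random draw in the scenario.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(grid_rows = 100, grid_cols = 100,
                               cell_size = 30, n_predictors = 5,
                               autocorr_range = 8,
                               target_correlations = diag(n_predictors),
                               n_plots = 389, plot_clustering = 0,
                               seed = 1L) {
  if (grid_rows < 10 || grid_cols < 10)
    stop("grid must be at least 10x10 cells", call. = FALSE)
  if (n_predictors < 2) stop("need at least 2 predictors", call. = FALSE)
  if (autocorr_range <= 0) stop("`autocorr_range` must be > 0", call. = FALSE)
  R <- as.matrix(target_correlations)
  if (nrow(R) != n_predictors || ncol(R) != n_predictors)
    stop("`target_correlations` must be ", n_predictors, "x", n_predictors,
         call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8))
    stop("`target_correlations` must be symmetric with unit diagonal",
         call. = FALSE)
  if (n_plots > grid_rows * grid_cols)
    stop("`n_plots` exceeds the number of grid cells", call. = FALSE)
  if (plot_clustering < 0) stop("`plot_clustering` must be >= 0", call. = FALSE)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size = cell_size,
                 n_predictors = as.integer(n_predictors),
                 autocorr_range = autocorr_range,
                 target_correlations = R,
                 n_plots = as.integer(n_plots),
                 plot_clustering = plot_clustering,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> ", x$grid_rows, "x", x$grid_cols, " grid, ",
      x$n_predictors, " predictors, ", x$n_plots, " plots, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# Derive a reproducible 31-bit sub-seed from a parent seed and a stage tag,
# so independent stages never share a random stream.
derive_seed <- function(seed, tag) {
  h <- rlang::hash(list(as.integer(seed), tag))
  as.integer(strtoi(substr(h, 1, 7), base = 16L)) %% 2147483647L
}

#' Generate a spatially autocorrelated Gaussian random field
#'
#' White noise is convolved (via FFT, on a torus) with an isotropic Gaussian
#' kernel of standard deviation `autocorr_range / 2` cells, then standardized
#' to zero mean and unit (population) standard deviation. The resulting field
#' has correlation approximately `exp(-(d / autocorr_range)^2)` at cell
#' distance `d`: close to 1 at lag 1 and essentially zero beyond twice the
#' range.
#'
#' @param rows,cols grid shape (each at least 10).
#' @param autocorr_range autocorrelation range in cells (> 0).
#' @param seed integer seed; the field is a pure function of its arguments.
#' @return A `rows` x `cols` [grid_layer()] with mean 0 and population sd 1.
#' @export
gen_gaussian_field <- function(rows, cols, autocorr_range, seed = 1L) {
  if (rows < 10 || cols < 10)
    stop("`rows` and `cols` must be at least 10", call. = FALSE)
  if (autocorr_range <= 0) stop("`autocorr_range` must be > 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(rows * cols), rows, cols)
  sigma <- autocorr_range / 2
  # separable Gaussian kernel on the torus
  dr <- pmin(0:(rows - 1), rows - (0:(rows - 1)))
  dc <- pmin(0:(cols - 1), cols - (0:(cols - 1)))
  ker <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(ker), inverse = TRUE))
  sm <- sm - mean(sm)
  sm <- sm / sqrt(mean(sm^2))
  grid_layer(sm, cell_size = 30)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a stack of correlated, standardized predictor layers
#'
#' Independent Gaussian random fields are generated per predictor, centred
#' and orthonormalized (QR), then linearly mixed through the Cholesky factor
#' of the target correlation matrix. Because the component fields are made
#' exactly orthogonal first, the empirical correlation matrix of the output
#' equals the target up to floating point. Each layer is standardized
#' (population sd).
#'
#' @param scenario a [synthetic_scenario()].
#' @return A [predictor_stack()] with layers named `env1..envK`,
#'   `standardized = TRUE`.
#' @export
gen_predictor_stack <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  R <- scenario$target_correlations
  ch <- tryCatch(chol(R), error = function(e)
    stop("`target_correlations` is not positive definite", call. = FALSE))
  k <- scenario$n_predictors
  nr <- scenario$grid_rows; nc <- scenario$grid_cols
  fields <- vapply(seq_len(k), function(i) {
    f <- gen_gaussian_field(nr, nc, scenario$autocorr_range,
                            seed = derive_seed(scenario$seed, paste0("field", i)))
    as.vector(unclass(f))
  }, numeric(nr * nc))
  fields <- scale(fields, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(fields))            # orthonormal columns, still centred
  mixed <- Q %*% ch * sqrt(nrow(Q))   # population-sd-1 columns, exact R
  layers <- lapply(seq_len(k), function(i)
    matrix(mixed[, i], nr, nc))
  names(layers) <- paste0("env", seq_len(k))
  predictor_stack(layers, cell_size = scenario$cell_size,
                  xmin = 0, ymin = 0, standardized = TRUE)
}

#' Generate a survey-plot network
#'
#' Plots are distinct cell centres, by default drawn uniformly without
#' replacement over the grid. With `plot_clustering > 0` in the scenario,
#' plots are drawn (still without replacement) with sampling weight
#' concentrated around `ceiling(plot_clustering)` random cluster centres.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A tibble with `plot_id`, `row`, `col`, `x`, `y` (cell centres).
#' @export
gen_plot_network <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  nr <- scenario$grid_rows; nc <- scenario$grid_cols
  ncell <- nr * nc
  if (scenario$n_plots > ncell)
    stop("`n_plots` exceeds the number of cells", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(scenario$seed, "plots"))
  if (scenario$plot_clustering > 0) {
    n_centres <- max(1L, ceiling(scenario$plot_clustering))
    centres <- cbind(stats::runif(n_centres, 1, nr),
                     stats::runif(n_centres, 1, nc))
    rows <- rep(seq_len(nr), times = nc)
    cols <- rep(seq_len(nc), each = nr)
    spread <- scenario$autocorr_range
    w <- rowSums(vapply(seq_len(n_centres), function(i)
      exp(-((rows - centres[i, 1])^2 + (cols - centres[i, 2])^2) /
            (2 * spread^2)), numeric(ncell))) + 1e-12
    cells <- sample.int(ncell, scenario$n_plots, replace = FALSE, prob = w)
  } else {
    cells <- sample.int(ncell, scenario$n_plots, replace = FALSE)
  }
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  tibble::tibble(
    plot_id = paste0("plot_", seq_along(cells)),
    row = row, col = col,
    x = (col - 0.5) * scenario$cell_size,
    y = (row - 0.5) * scenario$cell_size
  )
}

#' Describe a virtual species
#'
#' The species responds to exactly two predictors through a logit-linear
#' model with an optional interaction:
#' `logit(p) = b0 + a * z1 + b * z2 + c * z1 * z2`.
#'
#' @param species_id species identifier.
#' @param guild one of `"moss"`, `"liverwort"`, `"sphagna"`.
#' @param response_pair character vector of the two predictor names the
#'   species responds to.
#' @param coefficients numeric vector `(intercept, linear_a, linear_b,
#'   interaction)` on the logit scale.
#' @param target_occurrences presence count to generate, in `[5, 29]` (the
#'   rare-species prevalence window the pipeline is designed for).
#' @param seed integer seed.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(species_id, guild = c("moss", "liverwort", "sphagna"),
                         response_pair, coefficients,
                         target_occurrences, seed = 1L) {
  guild <- match.arg(guild)
  if (length(response_pair) != 2 || anyDuplicated(response_pair))
    stop("`response_pair` must be two distinct predictor names", call. = FALSE)
  if (length(coefficients) != 4 || !is.numeric(coefficients))
    stop("`coefficients` must be (intercept, linear_a, linear_b, interaction)",
         call. = FALSE)
  if (target_occurrences < 5 || target_occurrences > 29)
    stop("`target_occurrences` must lie in [5, 29]", call. = FALSE)
  structure(list(species_id = as.character(species_id), guild = guild,
                 response_pair = as.character(response_pair),
                 coefficients = as.numeric(coefficients),
                 target_occurrences = as.integer(target_occurrences),
                 seed = as.integer(seed)),
            class = "species_spec")
}

#' Generate presence records for a virtual species
#'
#' The true presence probability at each plot is the inverse logit of the
#' species' response applied to its two predictors (interaction included).
#' An exact presence count is achieved by weighted sampling of plots without
#' replacement, with weight proportional to the true probability; this keeps
#' prevalence reproducible while presences still concentrate where the
#' species' suitability is high.
#'
#' @param stack a [predictor_stack()] containing the response predictors.
#' @param plots a plot network tibble from [gen_plot_network()].
#' @param spec a [species_spec()].
#' @return An `occurrence_set`: a list with `occurrences` (tibble
#'   `species_id, x, y, guild`), `plot_probabilities` (tibble of all plots
#'   with the true probability surface and the presence indicator) and the
#'   generating `spec`.
#' @export
gen_species_occurrences <- function(stack, plots, spec) {
  stopifnot(inherits(spec, "species_spec"))
  if (nrow(plots) == 0) stop("`plots` is empty", call. = FALSE)
  miss <- setdiff(spec$response_pair, names(stack$layers))
  if (length(miss))
    stop("response predictors not in stack: ", paste(miss, collapse = ", "),
         call. = FALSE)
  z1 <- vapply(seq_len(nrow(plots)), function(i)
    stack$layers[[spec$response_pair[1]]][plots$row[i], plots$col[i]],
    numeric(1))
  z2 <- vapply(seq_len(nrow(plots)), function(i)
    stack$layers[[spec$response_pair[2]]][plots$row[i], plots$col[i]],
    numeric(1))
  b <- spec$coefficients
  p <- stats::plogis(b[1] + b[2] * z1 + b[3] * z2 + b[4] * z1 * z2)
  if (sum(p > 0) < spec$target_occurrences)
    stop("generation-failure: fewer plots with positive probability than ",
         "`target_occurrences`", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(spec$seed, paste0("occ_", spec$species_id)))
  chosen <- sample.int(nrow(plots), spec$target_occurrences,
                       replace = FALSE, prob = p)
  present <- logical(nrow(plots)); present[chosen] <- TRUE
  occ <- tibble::tibble(species_id = spec$species_id,
                        x = plots$x[chosen], y = plots$y[chosen],
                        guild = spec$guild)
  structure(list(
    occurrences = occ,
    plot_probabilities = dplyr::bind_cols(
      plots, tibble::tibble(probability = p, present = present)),
    spec = spec
  ), class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat("<occurrence_set> ", x$spec$species_id, " (", x$spec$guild, "): ",
      nrow(x$occurrences), " presences over ", nrow(x$plot_probabilities),
      " plots\n", sep = "")
  invisible(x)
}

#' Generate a cohort of virtual species over one landscape
#'
#' Convenience wrapper producing a multi-species occurrence table with the
#' guild composition and prevalence window of a rare-bryophyte survey:
#' each species responds to a random predictor pair with random logit-scale
#' coefficients, and receives a target occurrence count drawn uniformly
#' from `occurrence_range`.
#'
#' @param stack a [predictor_stack()].
#' @param plots plot network tibble.
#' @param n_by_guild named integer vector of species counts per guild
#'   (default `c(moss = 33, liverwort = 14, sphagna = 5)`).
#' @param occurrence_range inclusive prevalence window (default `c(5, 29)`).
#' @param effect_size absolute value of the linear response coefficients
#'   (default 3; signs are randomized, interaction 0, intercept -1).
#' @param seed integer seed.
#' @return A list with `occurrences` (bound tibble over species) and
#'   `specs` (list of [species_spec()]).
#' @export
simulate_cohort <- function(stack, plots,
                            n_by_guild = c(moss = 33, liverwort = 14,
                                           sphagna = 5),
                            occurrence_range = c(5, 29),
                            effect_size = 3, seed = 1L) {
  if (is.null(names(n_by_guild)) ||
      !all(names(n_by_guild) %in% c("moss", "liverwort", "sphagna")))
    stop("`n_by_guild` must be named with guilds moss/liverwort/sphagna",
         call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "cohort"))
  guilds <- rep(names(n_by_guild), times = n_by_guild)
  preds <- names(stack$layers)
  specs <- lapply(seq_along(guilds), function(i) {
    pair <- sample(preds, 2)
    signs <- sample(c(-1, 1), 2, replace = TRUE)
    species_spec(
      species_id = sprintf("sp_%02d", i), guild = guilds[i],
      response_pair = pair,
      coefficients = c(-1, signs[1] * effect_size, signs[2] * effect_size, 0),
      target_occurrences = sample(seq(occurrence_range[1],
                                      occurrence_range[2]), 1),
      seed = derive_seed(seed, paste0("sp", i))
    )
  })
  occ_sets <- lapply(specs, function(s) gen_species_occurrences(stack, plots, s))
  list(occurrences = dplyr::bind_rows(lapply(occ_sets, `[[`, "occurrences")),
       specs = specs, occurrence_sets = occ_sets)
}
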