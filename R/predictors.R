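#' Spectral and radar predictor indices
#'
#' Elementwise raster algebra for the predictor layers used by the pipeline.
#' All operations require aligned grids, propagate `NA` (nodata), and mask
#' cells where a formula's denominator vanishes.
#'
#' * `evi2(nir, red)`: two-band enhanced vegetation index,
#'   `2.5 * (NIR - RED) / (NIR + 2.4 * RED + 1)`; sensitive to
#'   photosynthetically active biomass.
#' * `ndwi1(nir, swir1)`: normalized difference water index,
#'   `(NIR - SWIR1) / (NIR + SWIR1)`, in `[-1, 1]`; sensitive to vegetation
#'   and soil moisture.
#' * `bsi(swir1, red, nir, blue)`: bare soil index in normalized-difference
#'   form, `((SWIR1 + RED) - (NIR + BLUE)) / ((SWIR1 + RED) + (NIR + BLUE))`,
#'   in `[-1, 1]`.
#' * `palsar_hvhh(hv, hh)`: ratio of HV- to HH-polarized L-band backscatter,
#'   `HV / HH`; indicative of forest structure.
#'
#' @param nir,red,swir1,blue,hv,hh aligned numeric matrices (or
#'   [grid_layer()]s) of band values.
#' @return A matrix/[grid_layer()] on the same grid.
#' @name spectral_indices
NULL

check_aligned <- function(...) {
  layers <- list(...)
  dims <- vapply(layers, function(l) dim(l), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("input layers are not aligned (grid shapes differ)", call. = FALSE)
  invisible(TRUE)
}

as_result_layer <- function(values, template) {
  if (is_grid_layer(template)) {
    m <- grid_meta(template)
    grid_layer(values, m$cell_size, m$xmin, m$ymin)
  } else values
}

mask_zero_denominator <- function(num, den, what) {
  bad <- !is.na(den) & den == 0
  out <- num / den
  if (any(bad)) {
    out[bad] <- NA_real_
    message(sum(bad), " cell(s) masked in ", what, " (zero denominator)")
  }
  out
}

#' @rdname spectral_indices
#' @export
evi2 <- function(nir, red) {
  check_aligned(nir, red)
  out <- 2.5 * (nir - red) / (nir + 2.4 * red + 1)
  as_result_layer(unclass(out), nir)
}

#' @rdname spectral_indices
#' @export
ndwi1 <- function(nir, swir1) {
  check_aligned(nir, swir1)
  out <- mask_zero_denominator(unclass(nir - swir1), unclass(nir + swir1),
                               "NDWI1")
  as_result_layer(out, nir)
}

#' @rdname spectral_indices
#' @export
bsi <- function(swir1, red, nir, blue) {
  check_aligned(swir1, red, nir, blue)
  a <- unclass(swir1 + red); b <- unclass(nir + blue)
  out <- mask_zero_denominator(a - b, a + b, "BSI")
  as_result_layer(out, swir1)
}

#' @rdname spectral_indices
#' @export
palsar_hvhh <- function(hv, hh) {
  check_aligned(hv, hh)
  out <- mask_zero_denominator(unclass(hv), unclass(hh), "PALSAR HV/HH")
  as_result_layer(out, hv)
}

#' Topographic position index over an annulus neighbourhood
#'
#' For each cell, TPI is the cell's elevation minus the mean elevation over
#' the annulus of cells whose centre-to-centre distance `d` (in pixels)
#' satisfies `inner_radius <= d <= outer_radius` (inclusive bounds; the
#' focal cell is never part of its own annulus since `inner_radius > 0`).
#' Near the raster edge the partial annulus mean over the available cells is
#' used; a cell whose annulus lies entirely outside the raster (or entirely
#' on nodata) is masked. Positive TPI marks ridges, negative marks valleys.
#'
#' @param dem elevation matrix or [grid_layer()] (metres).
#' @param inner_radius,outer_radius annulus radii in pixels,
#'   `0 < inner_radius < outer_radius` (defaults 15 and 20).
#' @return TPI layer on the same grid.
#' @export
tpi <- function(dem, inner_radius = 15, outer_radius = 20) {
  if (inner_radius >= outer_radius)
    stop("`inner_radius` must be smaller than `outer_radius`", call. = FALSE)
  if (inner_radius <= 0) stop("`inner_radius` must be > 0", call. = FALSE)
  v <- unclass(dem)
  nr <- nrow(v); nc <- ncol(v)
  r <- ceiling(outer_radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  d <- sqrt(off$dr^2 + off$dc^2)
  keep <- d >= inner_radius & d <= outer_radius
  off <- off[keep, , drop = FALSE]
  sums <- matrix(0, nr, nc)
  counts <- matrix(0, nr, nc)
  vz <- v; vz[is.na(vz)] <- 0
  vn <- !is.na(v)
  for (i in seq_len(nrow(off))) {
    dr <- off$dr[i]; dc <- off$dc[i]
    sr <- max(1, 1 - dr):min(nr, nr - dr)   # focal rows with neighbour inside
    sc <- max(1, 1 - dc):min(nc, nc - dc)
    if (length(sr) == 0 || length(sc) == 0) next
    sums[sr, sc] <- sums[sr, sc] + vz[sr + dr, sc + dc]
    counts[sr, sc] <- counts[sr, sc] + vn[sr + dr, sc + dc]
  }
  out <- v - sums / counts
  out[counts == 0] <- NA_real_
  as_result_layer(out, dem)
}

#' Standardize a layer to zero mean and unit variance
#'
#' Z-scores over unmasked cells using the population (divide-by-n) standard
#' deviation; masked cells stay masked. Idempotent up to floating point.
#'
#' @param layer numeric matrix or [grid_layer()].
#' @return Standardized layer on the same grid.
#' @export
standardize_layer <- function(layer) {
  v <- unclass(layer)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need at least 2 unmasked cells", call. = FALSE)
  mu <- mean(v[ok])
  sd_pop <- sqrt(mean((v[ok] - mu)^2))
  if (sd_pop == 0) stop("zero variance: cannot standardize", call. = FALSE)
  as_result_layer((v - mu) / sd_pop, layer)
}

#' Screen predictors for pairwise collinearity at background points
#'
#' Pearson correlations between all predictor pairs are computed at the
#' supplied background points. Predictors are then kept greedily in
#' `keep_priority` order: a predictor is dropped if its absolute correlation
#' with an already-kept predictor exceeds `threshold`. The result never
#' contains both members of a pair beyond the threshold, and the ordering
#' encodes the (domain-driven) preference of which member survives — by
#' default NDWI1 is preferred over BSI, reflecting the ecological choice of
#' a moisture-sensitive index for poikilohydric organisms.
#'
#' @param stack a [predictor_stack()].
#' @param background_points data frame with `x`, `y` of background points on
#'   the stack grid (at least 2 rows).
#' @param threshold absolute-correlation cutoff (default 0.7, exclusive).
#' @param keep_priority character vector ordering predictors from most to
#'   least preferred; predictors not listed rank after listed ones in stack
#'   order. Default puts `NDWI1` ahead of `BSI`.
#' @return A list with `retained` (character vector), `dropped`, and
#'   `correlations` (the full Pearson correlation matrix, for logging).
#' @export
correlation_filter <- function(stack, background_points, threshold = 0.7,
                               keep_priority = c("NDWI1", "BSI")) {
  if (nrow(background_points) < 2)
    stop("need at least 2 background points", call. = FALSE)
  vals <- extract_values(stack, background_points$x, background_points$y)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 2)
    stop("fewer than 2 background points fall on unmasked cells",
         call. = FALSE)
  cm <- stats::cor(as.matrix(vals))
  nm <- names(stack$layers)
  pri <- c(intersect(keep_priority, nm), setdiff(nm, keep_priority))
  retained <- character(0)
  for (p in pri) {
    if (!length(retained) || all(abs(cm[p, retained]) <= threshold))
      retained <- c(retained, p)
  }
  retained <- nm[nm %in% retained]   # back to stack order
  list(retained = retained, dropped = setdiff(nm, retained),
       correlations = cm)
}
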