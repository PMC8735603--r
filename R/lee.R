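#' Block-mean aggregation of a raster
#'
#' Averages `factor` x `factor` blocks of cells into one coarser cell (e.g.
#' factor 10 turns 30 m pixels into 300 m pixels). Nodata cells are ignored
#' within a block; a fully masked block becomes nodata. Partial blocks at
#' the right/top edge use the cells available.
#'
#' @param raster matrix or [grid_layer()].
#' @param factor integer aggregation factor (>= 2, default 10).
#' @return A coarser [grid_layer()]; cell size multiplied by `factor`.
#' @export
aggregate_mean <- function(raster, factor = 10) {
  if (factor < 2) stop("`factor` must be >= 2", call. = FALSE)
  v <- unclass(raster)
  nr <- nrow(v); nc <- ncol(v)
  br <- ceiling(nr / factor); bc <- ceiling(nc / factor)
  ri <- ceiling(seq_len(nr) / factor)
  ci <- ceiling(seq_len(nc) / factor)
  idx <- ri[row(v)] + (ci[col(v)] - 1L) * br
  ok <- !is.na(v)
  sums <- numeric(br * bc); counts <- numeric(br * bc)
  sums_t <- tapply(v[ok], idx[ok], sum)
  counts_t <- tapply(rep(1, sum(ok)), idx[ok], sum)
  sums[as.integer(names(sums_t))] <- sums_t
  counts[as.integer(names(counts_t))] <- counts_t
  out <- matrix(ifelse(counts > 0, sums / counts, NA_real_), br, bc)
  m <- grid_meta(raster)
  grid_layer(out, cell_size = m$cell_size * factor, xmin = m$xmin,
             ymin = m$ymin)
}

#' Build contiguity spatial weights over a raster grid
#'
#' Queen (8-neighbour) or rook (4-neighbour) contiguity on a `rows x cols`
#' grid, optionally row-standardized so each cell's weights sum to 1. Cells
#' have no self-links. Cells are ordered column-major (matching
#' `as.vector()` on the grid matrix).
#'
#' @param grid_shape integer vector `c(rows, cols)`, each >= 2.
#' @param scheme `"queen"` (default) or `"rook"`.
#' @param row_standardize divide each row of the weight matrix by its sum
#'   (default `TRUE`).
#' @return A `spatial_weights` object wrapping a sparse weight matrix `W`
#'   with the grid shape and scheme recorded.
#' @export
build_weights <- function(grid_shape, scheme = c("queen", "rook"),
                          row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  if (nr < 2 || nc < 2) stop("grid must be at least 2x2", call. = FALSE)
  offsets <- if (scheme == "queen") {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  rows_i <- rep(seq_len(nr), times = nc)
  cols_i <- rep(seq_len(nc), each = nr)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    r2 <- rows_i + offsets[k, 1]; c2 <- cols_i + offsets[k, 2]
    okk <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    from <- c(from, which(okk))
    to <- c(to, (r2[okk] + (c2[okk] - 1L) * nr))
  }
  W <- Matrix::sparseMatrix(i = from, j = to, x = 1,
                            dims = c(nr * nc, nr * nc))
  if (row_standardize) {
    rs <- Matrix::rowSums(W)
    W <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% W
  }
  structure(list(W = W, grid_shape = c(nr, nc), scheme = scheme,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights> ", x$scheme, " contiguity on ", x$grid_shape[1],
      "x", x$grid_shape[2], " grid",
      if (x$row_standardized) ", row-standardized", "\n", sep = "")
  invisible(x)
}

# Subset weights to unmasked cells and restore row standardization there,
# so masked cells drop out of every lag.
subset_weights <- function(weights, keep) {
  W <- weights$W[keep, keep, drop = FALSE]
  if (weights$row_standardized) {
    rs <- Matrix::rowSums(W)
    W <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% W
  }
  W
}

#' Local bivariate Lee's L statistic
#'
#' Lee's L integrates Pearson-style cross-correlation with the spatial
#' autocorrelation of each variable: with centred variables and spatial
#' lags `(W x)_i`, the local statistic is
#' `L_i = n * (Wx)_i * (Wy)_i / sqrt(sum(x^2) * sum(y^2))`. Cells masked in
#' either input are excluded from means, sums and lags (weights are
#' re-standardized over the unmasked cells).
#'
#' @param x,y aligned matrices or [grid_layer()]s.
#' @param weights a [build_weights()] object matching the grid shape.
#' @return A [grid_layer()] of per-cell local L values.
#' @export
local_lee <- function(x, y, weights) {
  check_aligned(x, y)
  vx <- as.vector(unclass(x)); vy <- as.vector(unclass(y))
  if (any(dim(x) != weights$grid_shape))
    stop("weights were built for a different grid shape", call. = FALSE)
  keep <- !is.na(vx) & !is.na(vy)
  n <- sum(keep)
  if (n < 2) stop("need at least 2 jointly unmasked cells", call. = FALSE)
  xt <- vx[keep] - mean(vx[keep])
  yt <- vy[keep] - mean(vy[keep])
  denom <- sqrt(sum(xt^2) * sum(yt^2))
  if (denom == 0) stop("zero variance in x or y", call. = FALSE)
  W <- subset_weights(weights, keep)
  lx <- as.vector(W %*% xt)
  ly <- as.vector(W %*% yt)
  out <- rep(NA_real_, length(vx))
  out[keep] <- n * lx * ly / denom
  as_result_layer(matrix(out, nrow(x), ncol(x)), x)
}

#' Centre and rescale local Lee's L values to \[-1, 1\]
#'
#' Subtracts the overall mean and divides by the maximum absolute centred
#' value, guaranteeing the result lies in `[-1, 1]` whatever the sign of
#' the extreme. An all-equal input rescales to all zeros.
#'
#' @param L_values matrix, layer or vector of local L values (`NA` allowed).
#' @return Rescaled values in the same shape.
#' @export
rescale_lee <- function(L_values) {
  v <- unclass(L_values)
  ok <- !is.na(v)
  if (!any(ok)) stop("no finite values", call. = FALSE)
  centred <- v - mean(v[ok])
  mx <- max(abs(centred[ok]))
  out <- if (mx == 0) centred else centred / mx
  if (is.matrix(v)) as_result_layer(out, L_values) else out
}

#' Monte Carlo significance classes for local Lee's L
#'
#' The observed per-cell local L is compared with its distribution under
#' `n_sims` conditional permutations: the values of `y` are permuted across
#' the unmasked cells (holding `x` and the weights fixed) and local L is
#' recomputed. Each cell's quantile is the rank of the observed value among
#' observed plus simulated (`rank / (n_sims + 1)`), so with 999 simulations
#' the attainable quantiles are 0.001 to 1.000. Cells with quantile above
#' 0.975 are classed `positive`, below 0.025 `negative`, otherwise
#' `not_significant`.
#'
#' @inheritParams local_lee
#' @param n_sims number of permutations (default 999).
#' @param seed integer seed.
#' @param permute `"y"` (default) for the conditional-on-x null, or
#'   `"both"` to permute the two variables independently.
#' @return A `lee_result`: list with layers `L`, `rescaled`, `quantile` and
#'   `class` (character matrix with values `negative`, `not_significant`,
#'   `positive`), plus the run metadata.
#' @export
monte_carlo_classify <- function(x, y, weights, n_sims = 999, seed = 1L,
                                 permute = c("y", "both")) {
  permute <- match.arg(permute)
  if (n_sims < 1) stop("`n_sims` must be >= 1", call. = FALSE)
  check_aligned(x, y)
  vx <- as.vector(unclass(x)); vy <- as.vector(unclass(y))
  keep <- !is.na(vx) & !is.na(vy)
  n <- sum(keep)
  if (n < 2) stop("need at least 2 jointly unmasked cells", call. = FALSE)
  xt <- vx[keep] - mean(vx[keep])
  yt <- vy[keep] - mean(vy[keep])
  denom <- sqrt(sum(xt^2) * sum(yt^2))
  if (denom == 0) stop("zero variance in x or y", call. = FALSE)
  W <- subset_weights(weights, keep)
  lx <- as.vector(W %*% xt)
  obs <- n * lx * as.vector(W %*% yt) / denom
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  exceed <- integer(n)   # simulated values strictly below observed
  ties <- integer(n)
  for (s in seq_len(n_sims)) {
    ys <- yt[sample.int(n)]
    lxs <- if (permute == "both") {
      as.vector(W %*% xt[sample.int(n)])
    } else lx
    sim <- n * lxs * as.vector(W %*% ys) / denom
    exceed <- exceed + (sim < obs)
    ties <- ties + (sim == obs)
  }
  # rank of the observed among observed + sims; ties split at their middle
  rnk <- exceed + 1 + ties / 2
  qtl <- rnk / (n_sims + 1)
  cls <- rep("not_significant", n)
  cls[qtl > 0.975] <- "positive"
  cls[qtl < 0.025] <- "negative"
  fill <- function(vals) {
    out <- rep(NA_real_, length(vx)); out[keep] <- vals
    as_result_layer(matrix(out, nrow(x), ncol(x)), x)
  }
  cls_all <- rep(NA_character_, length(vx)); cls_all[keep] <- cls
  structure(list(
    L = fill(obs),
    rescaled = fill(as.vector(rescale_lee(obs))),
    quantile = fill(qtl),
    class = matrix(cls_all, nrow(x), ncol(x)),
    n_sims = n_sims, seed = as.integer(seed), permute = permute,
    weights_scheme = weights$scheme,
    row_standardized = weights$row_standardized
  ), class = "lee_result")
}

#' @export
print.lee_result <- function(x, ...) {
  tab <- table(x$class, useNA = "no")
  cat("<lee_result> ", x$n_sims, " sims, ", x$weights_scheme,
      " weights; classes: ", paste(names(tab), tab, sep = "=",
                                   collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy lee_result
#' @export
tidy.lee_result <- function(x, ...) {
  base <- layer_coords(x$L)
  base$value <- NULL
  dplyr::bind_cols(
    base,
    L = as.vector(unclass(x$L)),
    rescaled = as.vector(unclass(x$rescaled)),
    quantile = as.vector(unclass(x$quantile)),
    class = as.vector(x$class)
  )
}

#' @method glance lee_result
#' @export
glance.lee_result <- function(x, ...) {
  cl <- x$class[!is.na(x$class)]
  tibble::tibble(
    n_cells = length(cl),
    prop_positive = mean(cl == "positive"),
    prop_negative = mean(cl == "negative"),
    mean_L = mean(unclass(x$L), na.rm = TRUE),
    n_sims = x$n_sims, weights_scheme = x$weights_scheme
  )
}
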