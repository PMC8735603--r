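# Independent brute-force oracles and small fixture builders.

# Strip grid/class attributes down to a bare matrix for value comparisons.
bare <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

# All-pairs AUC: probability a random presence outscores a random background
# row, ties counting one half.
auc_bruteforce <- function(scores, labels) {
  p <- scores[labels == 1]; b <- scores[labels == 0]
  total <- 0
  for (i in seq_along(p)) for (j in seq_along(b)) {
    total <- total + (p[i] > b[j]) + 0.5 * (p[i] == b[j])
  }
  total / (length(p) * length(b))
}

# Double-loop local Lee's L over an explicit dense weight matrix, excluding
# masked cells from means, sums and (re-standardized) lags.
lee_bruteforce <- function(x, y, W_dense, row_standardized = TRUE) {
  vx <- as.vector(unclass(x)); vy <- as.vector(unclass(y))
  keep <- which(!is.na(vx) & !is.na(vy))
  n <- length(keep)
  xt <- vx[keep] - mean(vx[keep]); yt <- vy[keep] - mean(vy[keep])
  denom <- sqrt(sum(xt^2) * sum(yt^2))
  out <- rep(NA_real_, length(vx))
  for (ii in seq_len(n)) {
    i <- keep[ii]
    w <- W_dense[i, keep]
    if (row_standardized && sum(w) > 0) w <- w / sum(w)
    lagx <- 0; lagy <- 0
    for (jj in seq_len(n)) {
      lagx <- lagx + w[jj] * xt[jj]
      lagy <- lagy + w[jj] * yt[jj]
    }
    out[i] <- n * lagx * lagy / denom
  }
  matrix(out, nrow(x), ncol(x))
}

# Dense binary contiguity matrix for a grid, column-major cell order.
contiguity_dense <- function(nr, nc, scheme = "queen") {
  n <- nr * nc
  W <- matrix(0, n, n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- r + (c - 1) * nr
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (scheme == "rook" && abs(dr) + abs(dc) != 1) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
        W[i, r2 + (c2 - 1) * nr] <- 1
    }
  }
  W
}

# Double-loop annulus TPI.
tpi_bruteforce <- function(dem, inner, outer) {
  nr <- nrow(dem); nc <- ncol(dem)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- c()
    for (r2 in seq_len(nr)) for (c2 in seq_len(nc)) {
      d <- sqrt((r2 - r)^2 + (c2 - c)^2)
      if (d >= inner && d <= outer && !is.na(dem[r2, c2]))
        vals <- c(vals, dem[r2, c2])
    }
    if (length(vals)) out[r, c] <- dem[r, c] - mean(vals)
  }
  out
}

# Pearson r from the raw sum formula (independent of stats::cor).
pearson_bruteforce <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# A small standardized stack of independent smooth fields.
make_test_stack <- function(k = 3, nr = 40, nc = 40, seed = 1) {
  scen <- synthetic_scenario(nr, nc, n_predictors = k, autocorr_range = 5,
                             n_plots = min(100, nr * nc), seed = seed)
  gen_predictor_stack(scen)
}

# Linearly separable presence-background training data on two predictors.
separable_training <- function(n_pres = 20, n_bg = 100, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    a = c(rnorm(n_pres, 3, 0.3), rnorm(n_bg, -3, 0.3)),
    b = rnorm(n_pres + n_bg),
    .label = rep(c(1L, 0L), c(n_pres, n_bg)),
    .weight = rep(c(1, n_pres / n_bg), c(n_pres, n_bg))
  )
}

# A hand-built esm_technique whose retained models predict fixed
# probabilities; for exactness tests of the averaging arithmetic.
constant_technique <- function(technique, pairs, weights, probs,
                               score = 0.5, somers = weights) {
  fits <- lapply(probs, function(p)
    fit_learner(constant_learner(p),
                matrix(0, 2, 2, dimnames = list(NULL, c("za", "zb"))),
                c(0, 1), c(1, 1)))
  names(fits) <- vapply(pairs, paste, character(1), collapse = ":")
  models <- tibble::tibble(
    var1 = vapply(pairs, `[`, character(1), 1),
    var2 = vapply(pairs, `[`, character(1), 2),
    somers_d = somers, retained = weights > 0, weight = weights)
  structure(list(technique = technique, learner = constant_learner(0.5),
                 models = models, fits = fits, score = score,
                 oos = matrix(c(0.4, 0.6), 2, 1), splits = list(),
                 labels = c(0L, 1L), empty = !any(weights > 0)),
            class = "esm_technique")
}
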