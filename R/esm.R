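#' Sample background (pseudo-absence) points from a predictor stack
#'
#' Points are drawn uniformly over the unmasked cells of the stack (a cell
#' is unmasked when every layer is non-`NA` there) and placed at cell
#' centres. One shared background set is normally used for all species of a
#' run. By default sampling is with replacement, so `n` may exceed the
#' number of cells (as when 10,000 points are requested from a small grid).
#'
#' @param stack a [predictor_stack()].
#' @param n number of background points (default 10000).
#' @param seed integer seed.
#' @param replace sample cells with replacement (default `TRUE`). With
#'   `replace = FALSE`, `n` must not exceed the number of unmasked cells.
#' @return A tibble with `x`, `y` and one column per predictor.
#' @export
make_background <- function(stack, n = 10000, seed = 1L, replace = TRUE) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  vals <- lapply(stack$layers, as.vector)
  ok <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  cells <- which(ok)
  if (!replace && n > length(cells))
    stop("`n` exceeds the number of unmasked cells and `replace = FALSE`",
         call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pick <- if (replace) cells[sample.int(length(cells), n, replace = TRUE)]
          else cells[sample.int(length(cells), n, replace = FALSE)]
  row <- ((pick - 1L) %% stack$nrow) + 1L
  col <- ((pick - 1L) %/% stack$nrow) + 1L
  out <- tibble::tibble(
    x = stack$xmin + (col - 0.5) * stack$cell_size,
    y = stack$ymin + (row - 0.5) * stack$cell_size
  )
  dplyr::bind_cols(out, tibble::as_tibble(lapply(vals, function(v) v[pick])))
}

#' Assemble presence-background training data with balanced class weights
#'
#' Presence rows receive weight 1 and each background row receives weight
#' `n_presences / n_background`, so the two classes contribute equal total
#' weight to every fit. Rows with missing predictor values are dropped.
#'
#' @param occurrences tibble of presence records with `x`, `y` (predictor
#'   values are extracted from `stack`), or already carrying predictor
#'   columns if `stack` is `NULL`.
#' @param background background tibble from [make_background()].
#' @param stack optional [predictor_stack()] used to extract presence
#'   predictor values.
#' @return A tibble with the predictor columns plus `.label` (1 = presence,
#'   0 = background) and `.weight`.
#' @export
assemble_training <- function(occurrences, background, stack = NULL) {
  if (nrow(occurrences) == 0) stop("no presence records", call. = FALSE)
  if (nrow(background) == 0) stop("no background points", call. = FALSE)
  pred_cols <- setdiff(names(background), c("x", "y"))
  if (!is.null(stack)) {
    pres <- extract_values(stack, occurrences$x, occurrences$y)
  } else {
    miss <- setdiff(pred_cols, names(occurrences))
    if (length(miss))
      stop("occurrences lack predictor columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    pres <- occurrences[pred_cols]
  }
  pres <- pres[stats::complete.cases(pres), , drop = FALSE]
  bg <- background[pred_cols]
  bg <- bg[stats::complete.cases(bg), , drop = FALSE]
  if (nrow(pres) == 0) stop("all presences fall on masked cells", call. = FALSE)
  n_p <- nrow(pres); n_b <- nrow(bg)
  dplyr::bind_rows(
    dplyr::mutate(pres, .label = 1L, .weight = 1),
    dplyr::mutate(bg, .label = 0L, .weight = n_p / n_b)
  )
}

#' Enumerate all bivariate predictor pairs
#'
#' @param predictor_names character vector of at least two distinct names.
#' @return A tibble with columns `var1`, `var2`: all `choose(n, 2)`
#'   unordered pairs in lexicographic order.
#' @export
enumerate_pairs <- function(predictor_names) {
  nm <- as.character(predictor_names)
  if (length(nm) < 2 || anyDuplicated(nm))
    stop("need at least 2 distinct predictor names", call. = FALSE)
  nm <- sort(nm)
  cmb <- utils::combn(nm, 2)
  tibble::tibble(var1 = cmb[1, ], var2 = cmb[2, ])
}

#' Convert AUC to Somers' D
#'
#' Somers' D is the rank-correlation skill score `2 * AUC - 1`: 0 for a
#' random classifier, 1 for a perfect one.
#'
#' @param auc_value AUC in `[0, 1]`.
#' @return `2 * auc_value - 1`.
#' @export
somers_d <- function(auc_value) {
  if (any(auc_value < 0 | auc_value > 1))
    stop("`auc_value` must lie in [0, 1]", call. = FALSE)
  2 * auc_value - 1
}

# Repeated stratified 80/20 split-sample scheme: each rep samples
# train_frac of the presences and of the background independently, so every
# validation fold holds at least one row of each class by construction.
make_splits <- function(labels, n_reps = 10, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1, n_reps >= 1)
  pres <- which(labels == 1); bg <- which(labels == 0)
  if (length(pres) < 2 || length(bg) < 2)
    stop("cannot stratify: need >= 2 rows of each class", call. = FALSE)
  n_tp <- min(length(pres) - 1L, max(1L, round(train_frac * length(pres))))
  n_tb <- min(length(bg) - 1L, max(1L, round(train_frac * length(bg))))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_reps), function(r) {
    tp <- sample(pres, n_tp); tb <- sample(bg, n_tb)
    list(train = c(tp, tb), val = c(setdiff(pres, tp), setdiff(bg, tb)))
  })
}

# Out-of-split predictions for one bivariate model: an n x n_reps matrix,
# NA outside each rep's validation fold.
oos_bivariate <- function(data, pair, learner, splits, seed) {
  X <- as.matrix(data[, pair, drop = FALSE])
  y <- data$.label; w <- data$.weight
  out <- matrix(NA_real_, nrow(data), length(splits))
  for (r in seq_along(splits)) {
    s <- splits[[r]]
    fit <- fit_learner(learner, X[s$train, , drop = FALSE], y[s$train],
                       w[s$train], seed = derive_seed(seed, paste0("rep", r)))
    out[s$val, r] <- predict_prob(fit, X[s$val, , drop = FALSE])
  }
  out
}

split_mean_auc <- function(oos, labels) {
  aucs <- apply(oos, 2, function(p) {
    ok <- !is.na(p)
    auc(p[ok], labels[ok])
  })
  mean(aucs)
}

#' Cross-validate one bivariate model
#'
#' Runs the repeated stratified split-sample scheme (by default 10 random
#' 80/20 splits), fits the learner on each training portion, scores each
#' validation portion by AUC, and returns Somers' D of the mean AUC.
#'
#' @param data training tibble from [assemble_training()].
#' @param pair character vector of two predictor names.
#' @param learner an `esm_learner` (see [learners]).
#' @param n_reps number of random splits (default 10).
#' @param train_frac training fraction per split (default 0.8).
#' @param seed integer seed.
#' @return Somers' D score (`2 * mean validation AUC - 1`).
#' @export
crossvalidate_bivariate <- function(data, pair, learner, n_reps = 10,
                                    train_frac = 0.8, seed = 1L) {
  if (sum(data$.label == 1) < 5)
    stop("need at least 5 presences", call. = FALSE)
  miss <- setdiff(pair, names(data))
  if (length(miss)) stop("unknown predictors: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  splits <- make_splits(data$.label, n_reps, train_frac,
                        seed = derive_seed(seed, "splits"))
  oos <- oos_bivariate(data, pair, learner, splits, seed)
  somers_d(split_mean_auc(oos, data$.label))
}

#' Skill-proportional ensemble weights from Somers' D scores
#'
#' Models with non-positive scores receive weight 0 (they are not retained);
#' the remaining weights are proportional to the scores and sum to 1. If no
#' score is positive, all weights are 0.
#'
#' @param scores numeric vector of Somers' D scores.
#' @return Numeric weight vector of the same length.
#' @examples
#' ensemble_weights(c(0.6, 0.2, -0.1))   # 0.75, 0.25, 0
#' @export
ensemble_weights <- function(scores) {
  w <- pmax(scores, 0)
  w[scores <= 0] <- 0
  if (sum(w) > 0) w / sum(w) else w
}

#' Fit a technique-level Ensemble of Small Models
#'
#' Every candidate bivariate model is fitted and scored by cross-validated
#' Somers' D; models with positive score are retained with weights
#' proportional to their score (so each model's contribution is
#' proportional to its predictive accuracy); retained models are refitted
#' on all data for prediction. If no model beats random the ensemble is
#' empty and flagged.
#'
#' The technique-level ensemble score is the Somers' D of the pooled
#' out-of-split ensemble predictions under the same splits used to score
#' the sub-models.
#'
#' @inheritParams crossvalidate_bivariate
#' @param pairs tibble of candidate pairs from [enumerate_pairs()].
#' @param splits optional pre-built split list (used by [fit_esm()] to share
#'   one split scheme across techniques).
#' @return An `esm_technique` object.
#' @export
fit_esm_technique <- function(data, pairs, learner, n_reps = 10,
                              train_frac = 0.8, seed = 1L, splits = NULL) {
  if (nrow(pairs) == 0) stop("`pairs` is empty", call. = FALSE)
  if (is.null(splits))
    splits <- make_splits(data$.label, n_reps, train_frac,
                          seed = derive_seed(seed, "splits"))
  labels <- data$.label
  technique <- sub("_learner$", "", class(learner)[1])
  oos_list <- vector("list", nrow(pairs))
  split_auc <- matrix(NA_real_, nrow(pairs), length(splits))
  for (j in seq_len(nrow(pairs))) {
    pair <- c(pairs$var1[j], pairs$var2[j])
    oos_list[[j]] <- oos_bivariate(data, pair, learner, splits,
                                   seed = derive_seed(seed, paste0("pair", j)))
    split_auc[j, ] <- apply(oos_list[[j]], 2, function(p) {
      ok <- !is.na(p)
      auc(p[ok], labels[ok])
    })
  }
  d <- somers_d(rowMeans(split_auc))
  retained <- d > 0
  weight <- ensemble_weights(d)
  models <- dplyr::mutate(pairs, somers_d = d, retained = retained,
                          weight = weight)
  if (any(retained)) {
    # Out-of-split ensemble predictions for evaluation: when scoring split
    # r, sub-models are retained and weighted by their skill on the OTHER
    # splits only, so no cell of the evaluation matrix was touched by the
    # weights that average it (guards against selection bias on weak
    # species).
    ens_oos <- matrix(NA_real_, nrow(data), length(splits))
    for (r in seq_along(splits)) {
      d_r <- somers_d(rowMeans(split_auc[, -r, drop = FALSE]))
      w_r <- ensemble_weights(d_r)
      if (sum(w_r) == 0) w_r <- rep(1 / length(d_r), length(d_r))
      val <- splits[[r]]$val
      ens_oos[val, r] <- Reduce(`+`, Map(function(m, w) m[val, r] * w,
                                         oos_list, w_r))
    }
    pooled <- !is.na(ens_oos)
    score <- somers_d(auc(ens_oos[pooled],
                          matrix(labels, nrow(data), length(splits))[pooled]))
    idx <- which(retained)
    fits <- lapply(idx, function(j) {
      pair <- c(pairs$var1[j], pairs$var2[j])
      fit_learner(learner, as.matrix(data[, pair, drop = FALSE]),
                  labels, data$.weight,
                  seed = derive_seed(seed, paste0("refit", j)))
    })
    names(fits) <- paste(pairs$var1[idx], pairs$var2[idx], sep = ":")
  } else {
    ens_oos <- NULL; score <- NA_real_; fits <- list()
  }
  structure(list(technique = technique, learner = learner, models = models,
                 fits = fits, score = score, oos = ens_oos,
                 splits = splits, labels = labels,
                 empty = !any(retained)),
            class = "esm_technique")
}

#' @export
print.esm_technique <- function(x, ...) {
  cat("<esm_technique> ", x$technique, ": ", sum(x$models$retained), "/",
      nrow(x$models), " bivariate models retained",
      if (x$empty) " (not better than random)" else
        sprintf(", ensemble Somers' D = %.3f", x$score), "\n", sep = "")
  invisible(x)
}

#' Combine technique-level ensembles into a final ESM
#'
#' Cross-technique weights are proportional to each technique ensemble's
#' cross-validated Somers' D clamped at zero and normalized to sum to 1; an
#' empty or non-positive-scoring technique receives weight 0 (the other
#' technique then carries weight 1). If all non-empty techniques score
#' non-positively they are weighted equally; if every technique is empty the
#' species is marked unmodellable.
#'
#' @param ... `esm_technique` objects (typically Maxent and RF), or a single
#'   list of them.
#' @return An `esm_model`.
#' @export
combine_techniques <- function(...) {
  techs <- list(...)
  if (length(techs) == 1 && !inherits(techs[[1]], "esm_technique"))
    techs <- techs[[1]]
  stopifnot(all(vapply(techs, inherits, logical(1), "esm_technique")))
  names(techs) <- vapply(techs, `[[`, character(1), "technique")
  nonempty <- !vapply(techs, `[[`, logical(1), "empty")
  if (!any(nonempty)) {
    return(structure(list(techniques = techs, cross_weights =
                            stats::setNames(rep(0, length(techs)), names(techs)),
                          oos = NULL, labels = techs[[1]]$labels,
                          unmodellable = TRUE),
                     class = "esm_model"))
  }
  raw <- vapply(techs, function(t) if (t$empty) 0 else max(t$score, 0),
                numeric(1))
  w <- if (sum(raw) > 0) raw / sum(raw) else
    stats::setNames(as.numeric(nonempty) / sum(nonempty), names(techs))
  use <- names(w)[w > 0]
  oos <- Reduce(`+`, Map(function(t, wt) t$oos * wt, techs[use], w[use]))
  structure(list(techniques = techs, cross_weights = w, oos = oos,
                 labels = techs[[which(nonempty)[1]]]$labels,
                 unmodellable = FALSE),
            class = "esm_model")
}

#' Fit a full Ensemble of Small Models for one species
#'
#' Enumerates all bivariate predictor pairs, fits and scores them under both
#' learner families with one shared repeated-split scheme, builds the two
#' technique-level ensembles, and combines them with skill-proportional
#' cross-technique weights.
#'
#' @param data training tibble from [assemble_training()].
#' @param predictors predictor names to use (default: every non-metadata
#'   column of `data`).
#' @param learners named list of learner descriptions (default Maxent-style
#'   penalized logistic plus random forest).
#' @param n_reps,train_frac split-sample scheme (defaults 10 and 0.8).
#' @param seed integer seed.
#' @return An `esm_model` with components `techniques`, `cross_weights`,
#'   pooled out-of-split ensemble predictions (`oos`), and `unmodellable`.
#' @export
fit_esm <- function(data, predictors = NULL,
                    learners = list(maxent = maxent_learner(),
                                    rf = rf_learner()),
                    n_reps = 10, train_frac = 0.8, seed = 1L) {
  if (is.null(predictors))
    predictors <- setdiff(names(data), c(".label", ".weight"))
  pairs <- enumerate_pairs(predictors)
  splits <- make_splits(data$.label, n_reps, train_frac,
                        seed = derive_seed(seed, "splits"))
  techs <- lapply(seq_along(learners), function(i)
    fit_esm_technique(data, pairs, learners[[i]],
                      seed = derive_seed(seed, names(learners)[i] %||%
                                           paste0("tech", i)),
                      splits = splits))
  out <- combine_techniques(techs)
  out$predictors <- predictors
  out$n_presences <- sum(data$.label == 1)
  out$n_background <- sum(data$.label == 0)
  out$params <- list(n_reps = n_reps, train_frac = train_frac, seed = seed)
  out
}

#' @export
print.esm_model <- function(x, ...) {
  cat("<esm_model>", if (isTRUE(x$unmodellable)) " (unmodellable)", "\n",
      sep = "")
  for (nm in names(x$techniques)) {
    t <- x$techniques[[nm]]
    cat(sprintf("  %-8s weight %.3f, %d/%d models retained%s\n", nm,
                x$cross_weights[[nm]], sum(t$models$retained),
                nrow(t$models),
                if (t$empty) "" else sprintf(", D = %.3f", t$score)))
  }
  invisible(x)
}

# Pooled out-of-split ensemble predictions with their labels, on [0, 1].
pooled_oos <- function(esm) {
  if (is.null(esm$oos)) return(NULL)
  keep <- !is.na(esm$oos)
  lab <- matrix(esm$labels, nrow(esm$oos), ncol(esm$oos))
  tibble::tibble(label = lab[keep], prob = esm$oos[keep])
}

#' Predict a continuous suitability map from a fitted ESM
#'
#' Per cell, retained bivariate probabilities are averaged with the
#' within-technique weights, then across techniques with the cross-technique
#' weights, and scaled to integers 0-1000. Cells where any predictor needed
#' by a contributing model is masked become nodata.
#'
#' @param esm a non-empty `esm_model` from [fit_esm()].
#' @param stack a [predictor_stack()] containing every predictor used by the
#'   retained models.
#' @return A [grid_layer()] of integers in `[0, 1000]` (`NA` = nodata).
#' @export
predict_esm <- function(esm, stack) {
  if (isTRUE(esm$unmodellable))
    stop("cannot predict from an unmodellable (empty) ensemble", call. = FALSE)
  used <- unique(unlist(lapply(esm$techniques, function(t)
    if (!t$empty) c(t$models$var1[t$models$retained],
                    t$models$var2[t$models$retained]))))
  miss <- setdiff(used, names(stack$layers))
  if (length(miss))
    stop("stack lacks predictor layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- lapply(stack$layers[used], as.vector)
  ok <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  n_ok <- sum(ok)
  total <- rep(0, n_ok)
  for (nm in names(esm$techniques)) {
    t <- esm$techniques[[nm]]
    wt <- esm$cross_weights[[nm]]
    if (t$empty || wt <= 0) next
    tech_pred <- rep(0, n_ok)
    ret <- which(t$models$retained)
    for (j in ret) {
      pair <- c(t$models$var1[j], t$models$var2[j])
      X <- cbind(vals[[pair[1]]][ok], vals[[pair[2]]][ok])
      colnames(X) <- pair
      tech_pred <- tech_pred +
        t$models$weight[j] * predict_prob(t$fits[[paste(pair, collapse = ":")]], X)
    }
    total <- total + wt * tech_pred
  }
  out <- rep(NA_real_, stack$nrow * stack$ncol)
  out[ok] <- round(pmin(pmax(total, 0), 1) * 1000)
  grid_layer(matrix(out, stack$nrow, stack$ncol),
             cell_size = stack$cell_size, xmin = stack$xmin, ymin = stack$ymin)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the sub-model table of a fitted ESM
#'
#' @param x an `esm_model`.
#' @param ... unused.
#' @return A tibble with one row per candidate bivariate model per
#'   technique: `technique`, `var1`, `var2`, `somers_d`, `retained`,
#'   `weight` (within technique) and `cross_weight`.
#' @method tidy esm_model
#' @export
tidy.esm_model <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$techniques), function(nm) {
    dplyr::mutate(x$techniques[[nm]]$models, technique = nm,
                  cross_weight = x$cross_weights[[nm]], .before = 1)
  }))
}

#' One-row summary of a fitted ESM
#'
#' @param x an `esm_model`.
#' @param ... unused.
#' @return A tibble with presence/background counts, candidate and retained
#'   model counts, and the pooled cross-validated evaluation metrics.
#' @method glance esm_model
#' @export
glance.esm_model <- function(x, ...) {
  met <- evaluate_esm(x)
  tibble::tibble(
    n_presences = x$n_presences %||% NA_integer_,
    n_background = x$n_background %||% NA_integer_,
    n_candidates = nrow(x$techniques[[1]]$models),
    n_retained = sum(vapply(x$techniques, function(t)
      sum(t$models$retained), integer(1))),
    auc = met$auc, tss = met$tss, sensitivity = met$sensitivity,
    threshold = met$threshold, better_than_random = met$better_than_random
  )
}
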