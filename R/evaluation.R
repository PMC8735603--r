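#' Rank-based AUC for presence-background scores
#'
#' The area under the ROC curve computed as the Mann-Whitney probability
#' that a randomly chosen presence outscores a randomly chosen background
#' row, with ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (1 = presence); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("labels must contain both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic
#'
#' `sensitivity + specificity - 1`, a prevalence-independent skill measure
#' in `[-1, 1]`.
#'
#' @param sensitivity,specificity values in `[0, 1]`.
#' @return TSS value.
#' @export
tss <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  sensitivity + specificity - 1
}

#' Sensitivity at a threshold
#'
#' Fraction of presence rows whose score is at least the threshold
#' (presence is predicted when `score >= threshold`).
#'
#' @inheritParams auc
#' @param threshold finite cutoff.
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_at <- function(scores, labels, threshold) {
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  pres <- scores[labels == 1]
  if (length(pres) == 0) stop("no presence rows", call. = FALSE)
  mean(pres >= threshold)
}

specificity_at <- function(scores, labels, threshold) {
  bg <- scores[labels == 0]
  if (length(bg) == 0) stop("no background rows", call. = FALSE)
  mean(bg < threshold)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans every distinct observed score as a candidate cutoff and returns
#' the one maximizing sensitivity + specificity (the TSS optimum, since TSS
#' is that sum minus one). Ties are broken toward the lowest threshold.
#'
#' @inheritParams auc
#' @return The selected threshold (one of the observed scores).
#' @export
max_sss_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("labels must contain both classes", call. = FALSE)
  cand <- sort(unique(scores))
  sss <- vapply(cand, function(th)
    sensitivity_at(scores, labels, th) + specificity_at(scores, labels, th),
    numeric(1))
  cand[which.max(sss)]   # which.max returns the first (lowest) maximizer
}

#' Binarize a continuous suitability map
#'
#' @param continuous_map suitability layer on the 0-1000 integer scale.
#' @param threshold cutoff in `[0, 1000]`; cells with `value >= threshold`
#'   become 1, others 0. Nodata propagates.
#' @return A binary layer on the same grid.
#' @export
binarize <- function(continuous_map, threshold) {
  v <- unclass(continuous_map)
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  as_result_layer(matrix(out, nrow(v), ncol(v)), continuous_map)
}

#' Evaluate a fitted ESM from its pooled cross-validation predictions
#'
#' The final ensemble's out-of-split predictions (pooled over the repeated
#' 80/20 splits) are scored against the held-out labels: AUC, the
#' maximum-sensitivity-plus-specificity threshold on the 0-1000 scale, TSS
#' and sensitivity at that threshold. Following the reporting rule for
#' presence-background studies, sensitivity is reported only when the model
#' is better than random (`auc > 0.5`); otherwise it is `NA`. An
#' unmodellable species yields `NA` metrics and
#' `better_than_random = FALSE`.
#'
#' @param esm an `esm_model` from [fit_esm()].
#' @param species_id optional identifier carried into the output.
#' @return A one-row tibble: `species_id`, `auc`, `tss`, `sensitivity`,
#'   `threshold`, `better_than_random`.
#' @export
evaluate_esm <- function(esm, species_id = NA_character_) {
  if (isTRUE(esm$unmodellable) || is.null(esm$oos)) {
    return(tibble::tibble(species_id = species_id, auc = NA_real_,
                          tss = NA_real_, sensitivity = NA_real_,
                          threshold = NA_real_, better_than_random = FALSE))
  }
  po <- pooled_oos(esm)
  scores <- round(po$prob * 1000)
  a <- auc(scores, po$label)
  th <- max_sss_threshold(scores, po$label)
  sens <- sensitivity_at(scores, po$label, th)
  spec <- specificity_at(scores, po$label, th)
  btr <- a > 0.5
  tibble::tibble(species_id = species_id, auc = a,
                 tss = tss(sens, spec),
                 sensitivity = if (btr) sens else NA_real_,
                 threshold = th, better_than_random = btr)
}

#' Correlation between species prevalence and predictive accuracy
#'
#' Pearson correlation between per-species occurrence counts and AUC,
#' overall and per guild (guild values with fewer than 3 species, or zero
#' variance in either variable, yield `NA` with a warning suppressed to a
#' flag column).
#'
#' @param metrics_table tibble with at least `n_occurrences` and `auc`
#'   columns, and optionally `guild`.
#' @return A tibble with `group` (`"all"` plus each guild), `n`, and
#'   `pearson_r`.
#' @export
occurrences_vs_auc <- function(metrics_table) {
  tab <- dplyr::filter(metrics_table, is.finite(.data$auc),
                       is.finite(.data$n_occurrences))
  if (nrow(tab) < 3)
    stop("need at least 3 species with finite AUC and counts", call. = FALSE)
  safe_cor <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }
  out <- tibble::tibble(group = "all", n = nrow(tab),
                        pearson_r = safe_cor(tab$n_occurrences, tab$auc))
  if ("guild" %in% names(tab)) {
    per <- tab |>
      dplyr::group_by(.data$guild) |>
      dplyr::summarise(n = dplyr::n(),
                       pearson_r = safe_cor(.data$n_occurrences, .data$auc),
                       .groups = "drop") |>
      dplyr::rename(group = "guild")
    out <- dplyr::bind_rows(out, per)
  }
  out
}
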