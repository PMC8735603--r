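test_that("background sampling is uniform over unmasked cells and seeded", {
  st <- make_test_stack(k = 2, nr = 20, nc = 20, seed = 2)
  st$layers$env1[3, 4] <- NA   # mask one cell in one layer
  bg <- make_background(st, 1000, seed = 7)
  expect_equal(nrow(bg), 1000)
  expect_false(any(is.na(bg$env1)))
  expect_identical(bg, make_background(st, 1000, seed = 7))

  one <- make_background(st, 1, seed = 3)
  idx <- cell_index(grid_layer(st$layers$env2, st$cell_size), one$x, one$y)
  expect_equal(one$env2, st$layers$env2[idx$row, idx$col])

  expect_error(make_background(st, 500, seed = 1, replace = FALSE),
               "exceeds")
})

test_that("training assembly balances total class weights", {
  st <- make_test_stack(k = 2, nr = 20, nc = 20, seed = 5)
  bg <- make_background(st, 1000, seed = 1)
  occ <- tibble::tibble(x = bg$x[1:10], y = bg$y[1:10])
  tr <- assemble_training(occ, bg, st)
  expect_equal(unique(tr$.weight[tr$.label == 0]), 10 / 1000)
  expect_equal(sum(tr$.weight[tr$.label == 1]),
               sum(tr$.weight[tr$.label == 0]))

  balanced <- assemble_training(occ, bg[1:10, ], st)
  expect_true(all(balanced$.weight == 1))

  five <- assemble_training(occ[1:5, ], bg, st)
  expect_equal(sum(five$.label), 5)
  expect_error(assemble_training(occ[0, ], bg, st), "presence")
})

test_that("pair enumeration is complete and lexicographic", {
  p5 <- enumerate_pairs(c("TPI", "EVI2", "NDWI1", "VCF", "PALSAR_HVHH"))
  expect_equal(nrow(p5), 10)
  expect_equal(nrow(enumerate_pairs(c("a", "b"))), 1)
  expect_equal(nrow(enumerate_pairs(letters[1:6])), 15)
  expect_true(all(p5$var1 < p5$var2))
  expect_identical(p5, p5[order(p5$var1, p5$var2), ])
  expect_error(enumerate_pairs("a"), "at least 2")
  expect_error(enumerate_pairs(c("a", "a")), "distinct")
})

test_that("Somers' D is 2*AUC - 1 on [0,1]", {
  expect_equal(somers_d(0.5), 0)
  expect_equal(somers_d(1), 1)
  expect_equal(somers_d(0.75), 0.5)
  expect_error(somers_d(1.2), "\\[0, 1\\]")
})

test_that("splits stratify by class and never leak validation rows", {
  labels <- rep(c(1L, 0L), c(7, 100))
  for (seed in 1:5) {
    splits <- rarescape:::make_splits(labels, n_reps = 10, seed = seed)
    expect_length(splits, 10)
    for (s in splits) {
      expect_length(intersect(s$train, s$val), 0)
      expect_setequal(c(s$train, s$val), seq_along(labels))
      expect_gte(sum(labels[s$val] == 1), 1)
      expect_gte(sum(labels[s$val] == 0), 1)
      expect_gte(sum(labels[s$train] == 1), 1)
    }
  }
})

test_that("cross-validation scores separable data near 1 and null data near 0", {
  tr <- separable_training(n_pres = 20, n_bg = 100, seed = 3)
  d_rf <- crossvalidate_bivariate(tr, c("a", "b"), rf_learner(100), seed = 1)
  d_mx <- crossvalidate_bivariate(tr, c("a", "b"), maxent_learner(), seed = 1)
  expect_gt(d_rf, 0.9)
  expect_gt(d_mx, 0.9)

  null_scores <- sapply(1:10, function(s) {
    set.seed(s)
    tr0 <- tr
    tr0$.label <- sample(tr0$.label)
    tr0$.weight <- ifelse(tr0$.label == 1, 1, sum(tr0$.label) /
                            sum(tr0$.label == 0))
    crossvalidate_bivariate(tr0, c("a", "b"), rf_learner(100), seed = s)
  })
  expect_lt(abs(mean(null_scores)), 0.15)
  expect_error(crossvalidate_bivariate(tr[c(1:3, 30:60), ], c("a", "b"),
                                       rf_learner(50)), "at least 5")
})

test_that("technique ensembles retain positive-score models with proportional weights", {
  expect_equal(ensemble_weights(c(0.6, 0.2, -0.1)), c(0.75, 0.25, 0))
  expect_equal(ensemble_weights(c(-0.2, -0.1)), c(0, 0))
  expect_equal(ensemble_weights(0.4), 1)

  tr <- separable_training(n_pres = 15, n_bg = 80, seed = 2)
  tr$c <- rnorm(nrow(tr))
  tech <- fit_esm_technique(tr, enumerate_pairs(c("a", "b", "c")),
                            rf_learner(100), seed = 4)
  expect_s3_class(tech, "esm_technique")
  ret <- tech$models[tech$models$retained, ]
  expect_equal(sum(ret$weight), 1)
  expect_true(all(ret$somers_d > 0))
  expect_equal(ret$weight, ret$somers_d / sum(ret$somers_d))
  expect_false(tech$empty)

  # constant probabilities carry no skill: ensemble is empty and flagged
  tech0 <- fit_esm_technique(tr, enumerate_pairs(c("a", "b", "c")),
                             constant_learner(0.5), seed = 4)
  expect_true(tech0$empty)
  expect_equal(sum(tech0$models$retained), 0)
})

test_that("cross-technique weights are skill-proportional with degenerate fallbacks", {
  t1 <- constant_technique("maxent", list(c("za", "zb")), 1, 0.7, score = 0.4)
  t2 <- constant_technique("rf", list(c("za", "zb")), 1, 0.3, score = 0.4)
  esm <- combine_techniques(t1, t2)
  expect_equal(unname(esm$cross_weights), c(0.5, 0.5))

  t2$score <- 0.2
  t1$score <- 0.6
  esm2 <- combine_techniques(t1, t2)
  expect_equal(unname(esm2$cross_weights), c(0.75, 0.25))

  t2$empty <- TRUE
  esm3 <- combine_techniques(t1, t2)
  expect_equal(unname(esm3$cross_weights), c(1, 0))

  t1$empty <- TRUE
  esm4 <- combine_techniques(t1, t2)
  expect_true(esm4$unmodellable)
})

test_that("ensemble prediction is the weighted convex combination of sub-models", {
  st <- predictor_stack(list(za = matrix(0, 5, 5), zb = matrix(0, 5, 5),
                             zc = matrix(0, 5, 5)))
  tech <- constant_technique("rf", list(c("za", "zb"), c("za", "zc")),
                             weights = c(0.75, 0.25), probs = c(0.8, 0.4))
  esm <- structure(list(techniques = list(rf = tech),
                        cross_weights = c(rf = 1), unmodellable = FALSE),
                   class = "esm_model")
  map <- predict_esm(esm, st)
  expect_true(all(unclass(map) == 700))   # 0.75*0.8 + 0.25*0.4 = 0.7

  single <- constant_technique("rf", list(c("za", "zb")), 1, 0.5)
  esm1 <- structure(list(techniques = list(rf = single),
                         cross_weights = c(rf = 1), unmodellable = FALSE),
                    class = "esm_model")
  expect_true(all(unclass(predict_esm(esm1, st)) == 500))
  expect_error(predict_esm(esm, predictor_stack(list(za = matrix(0, 5, 5)))),
               "lacks predictor")
})

test_that("full ESM fits are deterministic and within probability bounds", {
  st <- make_test_stack(k = 3, nr = 25, nc = 25, seed = 6)
  scen <- synthetic_scenario(25, 25, n_predictors = 3, n_plots = 150, seed = 6)
  plots <- gen_plot_network(scen)
  spec <- species_spec("d1", "moss", c("env1", "env2"), c(-1, 3, -2, 0), 18,
                       seed = 2)
  occ <- gen_species_occurrences(st, plots, spec)
  bg <- make_background(st, 300, seed = 4)
  tr <- assemble_training(occ$occurrences, bg, st)
  learners <- list(maxent = maxent_learner(), rf = rf_learner(100))
  esm1 <- fit_esm(tr, learners = learners, seed = 9)
  esm2 <- fit_esm(tr, learners = learners, seed = 9)
  expect_equal(tidy(esm1), tidy(esm2))
  expect_equal(sum(esm1$cross_weights), 1)

  map <- predict_esm(esm1, st)
  v <- unclass(map)
  expect_true(all(v >= 0 & v <= 1000, na.rm = TRUE))
  expect_identical(unclass(map), unclass(predict_esm(esm2, st)))

  g <- glance(esm1)
  expect_equal(g$n_presences, 18)
  expect_equal(g$n_candidates, 3)
})

test_that("maxent-style learner responds monotonically and stays flat on noise", {
  set.seed(10)
  n <- 300
  z1 <- rnorm(n); z2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(2.5 * z1))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  X <- cbind(a = z1, b = z2)
  fit <- fit_learner(maxent_learner(), X, y, rep(1, n), seed = 1)
  grid_z <- seq(-2, 2, length.out = 41)
  p <- predict_prob(fit, cbind(a = grid_z, b = 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(p[41], p[1])
  expect_gt(cor(grid_z, p, method = "spearman"), 0.9)

  # no signal: predicted surface is nearly flat over the training range
  ranges <- sapply(1:20, function(s) {
    set.seed(s)
    y0 <- rbinom(n, 1, 0.3)
    if (length(unique(y0)) < 2) y0[1:2] <- c(0L, 1L)
    f0 <- fit_learner(maxent_learner(), X, y0, rep(1, n), seed = s)
    p0 <- predict_prob(f0, X)
    max(p0) - min(p0)
  })
  expect_lt(stats::median(ranges), 0.2)
  expect_lt(mean(ranges > 0.2), 0.25)
})

test_that("random-forest learner separates signal and honours its seed", {
  tr <- separable_training(25, 120, seed = 8)
  X <- as.matrix(tr[, c("a", "b")])
  fit <- fit_learner(rf_learner(200), X, tr$.label, tr$.weight, seed = 2)
  p <- predict_prob(fit, X)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(auc(p, tr$.label), 1)
  fit2 <- fit_learner(rf_learner(200), X, tr$.label, tr$.weight, seed = 2)
  expect_equal(predict_prob(fit2, X), p)
  expect_error(fit_learner(rf_learner(50), X, rep(1, nrow(X)), tr$.weight),
               "single-class")
})
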