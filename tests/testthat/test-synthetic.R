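test_that("gaussian fields are deterministic, standardized, and autocorrelated", {
  f1 <- gen_gaussian_field(40, 40, 6, seed = 11)
  f2 <- gen_gaussian_field(40, 40, 6, seed = 11)
  expect_identical(unclass(f1), unclass(f2))
  expect_lt(abs(mean(f1)), 1e-9)
  expect_lt(abs(sqrt(mean((unclass(f1) - mean(f1))^2)) - 1), 1e-9)

  # correlation at lag 1 exceeds correlation at twice the range
  f <- unclass(gen_gaussian_field(100, 100, 8, seed = 21))
  lag_cor <- function(m, L) cor(as.vector(m[, 1:(ncol(m) - L)]),
                                as.vector(m[, (1 + L):ncol(m)]))
  expect_gt(lag_cor(f, 1), lag_cor(f, 16))
  expect_gt(lag_cor(f, 1), 0.8)
  expect_lt(abs(lag_cor(f, 16)), 0.25)

  expect_error(gen_gaussian_field(5, 40, 6), "at least 10")
  expect_error(gen_gaussian_field(40, 40, 0), "autocorr_range")
})

test_that("predictor stacks honour the target correlation structure", {
  R <- diag(5); R[1, 2] <- R[2, 1] <- 0.9
  scen <- synthetic_scenario(100, 100, target_correlations = R, seed = 5)
  st <- gen_predictor_stack(scen)
  expect_length(st$layers, 5)
  expect_named(st$layers, paste0("env", 1:5))
  emp <- cor(sapply(st$layers, as.vector))
  expect_gt(abs(emp[1, 2]), 0.7)
  others <- abs(emp[upper.tri(emp)])
  expect_true(all(others[others < 0.5] < 0.3))
  expect_lt(abs(emp[1, 2] - 0.9), 0.1)

  # identity target: all off-diagonal correlations near zero
  st0 <- gen_predictor_stack(synthetic_scenario(100, 100, seed = 6))
  emp0 <- cor(sapply(st0$layers, as.vector))
  expect_lt(max(abs(emp0[upper.tri(emp0)])), 0.3)

  # infeasible (non-positive-definite) target is rejected
  bad <- diag(3); bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9; bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(gen_predictor_stack(
    synthetic_scenario(20, 20, n_predictors = 3, target_correlations = bad)),
    "positive definite")
})

test_that("plot networks are distinct, exhaustive when asked, deterministic", {
  scen <- synthetic_scenario(100, 100, n_plots = 389, seed = 2)
  plots <- gen_plot_network(scen)
  expect_equal(nrow(plots), 389)
  expect_equal(nrow(dplyr::distinct(plots, row, col)), 389)

  full <- synthetic_scenario(10, 12, n_plots = 120, seed = 3)
  all_cells <- gen_plot_network(full)
  expect_equal(nrow(dplyr::distinct(all_cells, row, col)), 120)

  expect_identical(gen_plot_network(scen), gen_plot_network(scen))
  expect_error(synthetic_scenario(10, 10, n_plots = 101), "exceeds")
})

test_that("virtual species probabilities follow the logit response", {
  st <- make_test_stack(k = 3, nr = 30, nc = 30, seed = 7)
  scen <- synthetic_scenario(30, 30, n_predictors = 3, n_plots = 200, seed = 7)
  plots <- gen_plot_network(scen)

  flat <- species_spec("flat", "moss", c("env1", "env2"), c(0, 0, 0, 0), 10)
  occ_flat <- gen_species_occurrences(st, plots, flat)
  expect_true(all(occ_flat$plot_probabilities$probability == 0.5))
  expect_equal(nrow(occ_flat$occurrences), 10)

  strong <- species_spec("strong", "liverwort", c("env1", "env2"),
                         c(0, 3, 0, 0), 25, seed = 9)
  occ <- gen_species_occurrences(st, plots, strong)
  pp <- occ$plot_probabilities
  expect_gt(mean(pp$probability[pp$present]),
            mean(pp$probability[!pp$present]))
  expect_true(dplyr::between(nrow(occ$occurrences), 5, 29))

  # interaction term enters the linear predictor
  inter <- species_spec("int", "moss", c("env1", "env2"), c(0, 0, 0, 2), 10)
  occ_i <- gen_species_occurrences(st, plots, inter)
  z1 <- extract_values(st, plots$x, plots$y)$env1
  z2 <- extract_values(st, plots$x, plots$y)$env2
  expect_equal(occ_i$plot_probabilities$probability,
               plogis(2 * z1 * z2), tolerance = 1e-12)

  expect_identical(gen_species_occurrences(st, plots, strong)$occurrences,
                   occ$occurrences)
  expect_error(species_spec("x", "moss", c("env1", "env2"), c(0, 0, 0, 0), 40),
               "\\[5, 29\\]")
  expect_error(species_spec("x", "moss", c("env1", "env1"), c(0, 0, 0, 0), 10),
               "distinct")
})

test_that("cohorts reproduce the requested guild composition and prevalence", {
  st <- make_test_stack(k = 3, nr = 30, nc = 30, seed = 13)
  scen <- synthetic_scenario(30, 30, n_predictors = 3, n_plots = 200, seed = 13)
  plots <- gen_plot_network(scen)
  co <- simulate_cohort(st, plots, n_by_guild = c(moss = 4, liverwort = 2,
                                                  sphagna = 1), seed = 3)
  counts <- dplyr::count(co$occurrences, guild)
  expect_equal(nrow(dplyr::distinct(co$occurrences, species_id)), 7)
  per_sp <- dplyr::count(co$occurrences, species_id)
  expect_true(all(dplyr::between(per_sp$n, 5, 29)))
  expect_setequal(counts$guild, c("moss", "liverwort", "sphagna"))
})
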