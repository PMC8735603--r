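test_that("block-mean aggregation averages blocks and shrinks the grid", {
  expect_equal(bare(aggregate_mean(matrix(7, 20, 20), 10)),
               matrix(7, 2, 2))
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(unclass(aggregate_mean(m, 2))[1, 1], 2.5)
  big <- matrix(rnorm(300 * 300), 300, 300)
  expect_equal(dim(aggregate_mean(big, 10)), c(30, 30))

  # nodata ignored within a block; fully masked block is nodata
  mm <- matrix(c(1, NA, 3, NA), 2, 2)
  expect_equal(unclass(aggregate_mean(mm, 2))[1, 1], 2)
  expect_true(is.na(unclass(aggregate_mean(matrix(NA_real_, 2, 2), 2))[1, 1]))

  # partial edge blocks use available cells
  odd <- matrix(1:9, 3, 3)
  agg <- aggregate_mean(odd, 2)
  expect_equal(dim(agg), c(2, 2))
  expect_equal(unclass(agg)[2, 2], 9)
  expect_error(aggregate_mean(m, 1), ">= 2")
})

test_that("contiguity weights match queen/rook neighbourhood definitions", {
  w <- build_weights(c(5, 5))
  W <- as.matrix(w$W)
  centre <- 3 + 2 * 5   # row 3, col 3
  expect_equal(sum(W[centre, ] > 0), 8)
  expect_true(all(W[centre, W[centre, ] > 0] == 1 / 8))
  corner <- 1
  expect_equal(sum(W[corner, ] > 0), 3)
  expect_equal(sum(W[corner, ]), 1)
  expect_equal(diag(W), rep(0, 25))

  wr <- build_weights(c(5, 5), scheme = "rook", row_standardize = FALSE)
  Wr <- as.matrix(wr$W)
  expect_equal(sum(Wr[centre, ] > 0), 4)
  expect_true(all(Wr[Wr > 0] == 1))
  expect_error(build_weights(c(1, 5)), "at least 2x2")
})

test_that("local Lee's L matches the brute-force double loop", {
  set.seed(30)
  for (shape in list(c(8, 8), c(10, 10), c(6, 9))) {
    x <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    y <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    w <- build_weights(shape)
    Wd <- contiguity_dense(shape[1], shape[2])
    expect_equal(unclass(local_lee(x, y, w)), lee_bruteforce(x, y, Wd),
                 tolerance = 1e-12)
  }
  # with masked cells
  x <- matrix(rnorm(64), 8, 8); y <- matrix(rnorm(64), 8, 8)
  x[c(3, 17, 40)] <- NA; y[c(5, 17)] <- NA
  w <- build_weights(c(8, 8))
  expect_equal(unclass(local_lee(x, y, w)),
               lee_bruteforce(x, y, contiguity_dense(8, 8)),
               tolerance = 1e-12)
  # rook scheme
  wr <- build_weights(c(8, 8), scheme = "rook")
  expect_equal(unclass(local_lee(x, y, wr)),
               lee_bruteforce(x, y, contiguity_dense(8, 8, "rook")),
               tolerance = 1e-12)
})

test_that("local Lee's L reduces to Pearson r under identity weights", {
  set.seed(31)
  x <- matrix(rnorm(100), 10, 10); y <- matrix(rnorm(100), 10, 10)
  wI <- structure(list(W = Matrix::Diagonal(100), grid_shape = c(10, 10),
                       scheme = "identity", row_standardized = FALSE),
                  class = "spatial_weights")
  L <- local_lee(x, y, wI)
  expect_equal(mean(unclass(L)), pearson_bruteforce(as.vector(x),
                                                    as.vector(y)),
               tolerance = 1e-9)
})

test_that("local Lee's L is symmetric, affine-invariant, and non-negative for y = x", {
  set.seed(32)
  x <- matrix(rnorm(81), 9, 9); y <- matrix(rnorm(81), 9, 9)
  w <- build_weights(c(9, 9))
  expect_equal(unclass(local_lee(x, y, w)), unclass(local_lee(y, x, w)))
  expect_equal(unclass(local_lee(3.2 * x + 7, y, w)),
               unclass(local_lee(x, y, w)), tolerance = 1e-9)
  expect_true(all(unclass(local_lee(x, x, w)) >= 0))
  expect_error(local_lee(matrix(1, 9, 9), y, w), "variance")
})

test_that("rescaling centres at zero and divides by the extreme", {
  expect_equal(rescale_lee(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(rescale_lee(c(4, 4, 4)), c(0, 0, 0))
  set.seed(33)
  v <- rnorm(50)
  r <- rescale_lee(v)
  expect_lte(max(r), 1); expect_gte(min(r), -1)
  expect_true(max(r) == 1 || min(r) == -1)
  expect_lt(abs(mean(r)), 1e-12)
})

test_that("Monte Carlo classes flag strong associations and respect the quantile rule", {
  # strongly structured smooth surface: broad gradient plus smooth noise
  x <- outer(seq(-1, 1, length.out = 30), seq(-1, 1, length.out = 30), "+") +
    0.3 * unclass(gen_gaussian_field(30, 30, 6, seed = 41))
  w <- build_weights(c(30, 30))
  res <- monte_carlo_classify(x, x, w, n_sims = 999, seed = 1)
  cls <- res$class[!is.na(res$class)]
  expect_gt(mean(cls == "positive"), 0.5)

  q <- unclass(res$quantile); cl <- res$class
  expect_true(all((cl == "positive") == (q > 0.975), na.rm = TRUE))
  expect_true(all((cl == "negative") == (q < 0.025), na.rm = TRUE))
  expect_true(all(q >= 1 / 1000 & q <= 1))

  res2 <- monte_carlo_classify(x, x, w, n_sims = 999, seed = 1)
  expect_identical(unclass(res2$quantile), unclass(res$quantile))
  expect_error(monte_carlo_classify(x, x, w, n_sims = 0), "n_sims")
})

test_that("independent white-noise fields are rarely classed significant", {
  w <- build_weights(c(20, 20))
  rates <- sapply(1:5, function(s) {
    set.seed(s)
    x <- matrix(rnorm(400), 20, 20)
    y <- matrix(rnorm(400), 20, 20)
    res <- monte_carlo_classify(x, y, w, n_sims = 199, seed = s)
    cls <- res$class[!is.na(res$class)]
    mean(cls == "positive")
  })
  expect_lt(mean(rates), 0.08)
  expect_gt(mean(rates), 0.001)
})
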