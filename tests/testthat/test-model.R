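test_that("the network has the stated shape contract and seeded initialization", {
  cfg5 <- placement_model_config(5L, input_resolution = 32L, seed = 1L)
  cfg9 <- placement_model_config(9L, input_resolution = 32L, seed = 1L)
  m5 <- build_model(cfg5)
  m9 <- build_model(cfg9)
  expect_length(m5$conv, 5L)
  expect_length(m5$fc, 3L)

  x <- array(stats::runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_equal(nrow(model_forward(m5, x)), 5L)
  expect_equal(nrow(model_forward(m9, x)), 9L)

  # same seed, same weights; different seed, different weights
  expect_identical(build_model(cfg5)$conv, m5$conv)
  cfg5b <- cfg5; cfg5b$seed <- 2L
  expect_false(identical(build_model(cfg5b)$conv[[1]]$W, m5$conv[[1]]$W))

  expect_error(placement_model_config(7L), "head_size")
  expect_error(placement_model_config(5L, dropout_rate = 1), "dropout_rate")
})

test_that("dropout behaviour: deterministic when off, stochastic at rate 0.5, inert at rate 0", {
  x <- array(stats::runif(32 * 32 * 3), dim = c(32, 32, 3))
  m <- build_model(placement_model_config(5L, input_resolution = 32L,
                                          dropout_rate = 0.5, seed = 3L))
  expect_identical(model_forward(m, x), model_forward(m, x))

  m0 <- build_model(placement_model_config(5L, input_resolution = 32L,
                                           dropout_rate = 0, seed = 3L))
  set.seed(1)
  expect_equal(model_forward(m0, x, dropout_active = TRUE),
               model_forward(m0, x, dropout_active = FALSE))

  set.seed(2)
  outs <- replicate(100, model_forward(m, x, dropout_active = TRUE)[1, 1])
  expect_gt(stats::var(outs), 0)

  bad <- array(0, dim = c(16, 16, 3))
  expect_error(model_forward(m, bad), "resolution mismatch")
})

test_that("all outputs are finite and normalization round-trips", {
  cfg <- placement_model_config(9L, input_resolution = 32L, seed = 5L)
  m <- build_model(cfg)
  x <- array(stats::runif(32 * 32 * 3 * 4), dim = c(32, 32, 3, 4))
  out <- model_forward(m, x)
  expect_true(all(is.finite(out)))
  v <- matrix(stats::rnorm(18, sd = 10), 9, 2)
  expect_equal(denormalize_params(normalize_params(v, cfg), cfg), v)
})

test_that("backpropagation matches finite differences through conv, pool, ReLU and FC", {
  sb <- asNamespace("scoutbox")
  cfg <- placement_model_config(5L, dropout_rate = 0, input_resolution = 32L,
                                width_multiplier = 0.05, seed = 7L)
  model <- build_model(cfg)
  set.seed(42)
  x <- array(stats::runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  truth <- matrix(stats::runif(10, -0.2, 0.6), 5, 2)

  loss_of <- function(m) loss_rmse(sb$forward_pass(m, x), truth)
  fw <- sb$forward_pass(model, x, keep_cache = TRUE)
  lg <- loss_rmse(fw$out, truth, gradient = TRUE)
  grads <- sb$backward_pass(model, fw$cache, lg$grad)

  eps <- 1e-6
  check_block <- function(get, set, g, k = 4) {
    p <- get(model)
    idx <- sample(length(p), min(k, length(p)))
    for (i in idx) {
      m1 <- set(model, `[<-`(p, i, p[i] + eps))
      m2 <- set(model, `[<-`(p, i, p[i] - eps))
      num <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
  for (l in c(1L, 3L, 5L)) {
    check_block(function(m) m$conv[[l]]$W,
                function(m, p) { m$conv[[l]]$W[] <- p; m }, grads$conv[[l]]$W)
  }
  for (l in 1:3) {
    check_block(function(m) m$fc[[l]]$W,
                function(m, p) { m$fc[[l]]$W[] <- p; m }, grads$fc[[l]]$W)
    check_block(function(m) m$fc[[l]]$b,
                function(m, p) { m$fc[[l]]$b[] <- p; m }, grads$fc[[l]]$b, k = 2)
  }
})

test_that("checkpoints embed the config and round-trip through disk", {
  m <- build_model(placement_model_config(9L, input_resolution = 32L, seed = 9L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$cfg, m$cfg)
  x <- array(stats::runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_identical(model_forward(m2, x), model_forward(m, x))

  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), junk)
  expect_error(load_model(junk), "placement_model")
})
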