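ae_spec <- model_spec("autoencoding", layer_sizes = c(15, 10, 6))

test_that("model building is seed-deterministic and mirrors the decoder", {
  m1 <- build_model(ae_spec, seed = 7)
  m2 <- build_model(ae_spec, seed = 7)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_model(ae_spec, seed = 8)
  expect_false(identical(m1$layers, m3$layers))

  x <- matrix(rnorm(4 * 15), 4, 15)
  out <- model_forward(m1, x)
  expect_equal(dim(out$output), c(4, 15))        # decoder mirrors to input
  expect_equal(dim(out$structured), c(4, 6))
})

test_that("classifier outputs normalized class probabilities", {
  spec <- model_spec("classification", layer_sizes = c(5, 8, 4),
                     n_classes = 10)
  m <- build_model(spec, seed = 1)
  p <- model_forward(m, matrix(rnorm(6 * 5), 6, 5))$output
  expect_equal(dim(p), c(6, 10))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
})

test_that("composite loss decomposes as task + alpha * penalty", {
  g <- disjoint_pairs_graph(3)
  z <- matrix(rnorm(10 * 6), 10, 6)

  cfg0 <- train_config(alpha = 0, regularizer = "gsr")
  expect_identical(composite_loss(1.5, z, g, cfg0), 1.5)

  zc <- matrix(2, 10, 6)
  cfg <- train_config(alpha = 3, regularizer = "gsr")
  expect_equal(composite_loss(0.7, zc, g, cfg), 0.7)

  cfg01 <- train_config(alpha = 0.1, regularizer = "gsr")
  p <- pairwise_penalty_oracle(z, g$weights)
  expect_equal(composite_loss(2, z, g, cfg01), 2 + 0.1 * p,
               tolerance = 1e-10)
  expect_error(composite_loss(1, z, NULL, cfg), "graph")
})

test_that("l1 and l2 penalties are mean absolute and mean squared activation", {
  z <- matrix(c(-2, 1, 0, 3), 2, 2)
  expect_equal(composite_loss(0, z, config = train_config(alpha = 1,
                                                          regularizer = "l1")),
               mean(abs(z)))
  expect_equal(composite_loss(0, z, config = train_config(alpha = 1,
                                                          regularizer = "l2")),
               mean(z^2))
})

test_that("training traces satisfy the objective decomposition", {
  dat <- generate_module_data(3, n_samples = 128, seed = 1)
  spec <- model_spec("autoencoding", layer_sizes = c(3, 16, 6))
  g <- disjoint_pairs_graph(3)
  cfg <- train_config(alpha = 0.5, epochs = 5, seed = 2, regularizer = "gsr")
  fit <- train(build_model(spec, seed = 2), dat$data, graph = g, config = cfg)
  expect_equal(nrow(fit$trace), 5)
  expect_true(all(is.finite(unlist(fit$trace))))
  expect_equal(fit$trace$composite,
               fit$trace$task_loss + 0.5 * fit$trace$penalty,
               tolerance = 1e-8)
})

test_that("identical configurations reproduce identical traces", {
  dat <- generate_module_data(2, n_samples = 64, seed = 3)
  spec <- model_spec("autoencoding", layer_sizes = c(2, 8, 4))
  cfg <- train_config(alpha = 0, epochs = 4, seed = 5)
  f1 <- train(build_model(spec, seed = 5), dat$data, config = cfg)
  f2 <- train(build_model(spec, seed = 5), dat$data, config = cfg)
  expect_identical(f1$trace, f2$trace)
})

test_that("momentum SGD trains deterministically and reduces the loss", {
  dat <- generate_module_data(2, n_samples = 128, seed = 14)
  spec <- model_spec("autoencoding", layer_sizes = c(2, 8, 4))
  cfg <- train_config(epochs = 40, batch_size = 128, learning_rate = 0.05,
                      seed = 15, optimizer = "sgd")
  f1 <- train(build_model(spec, seed = 15), dat$data, config = cfg)
  f2 <- train(build_model(spec, seed = 15), dat$data, config = cfg)
  expect_identical(f1$trace, f2$trace)
  expect_lt(f1$trace$task_loss[40], f1$trace$task_loss[1])
})

test_that("a zero-weight graph penalty reproduces the unregularized run", {
  dat <- generate_module_data(2, n_samples = 64, seed = 6)
  spec <- model_spec("autoencoding", layer_sizes = c(2, 8, 4))
  g <- disjoint_pairs_graph(2)
  f_none <- train(build_model(spec, seed = 7), dat$data,
                  config = train_config(alpha = 0, epochs = 4, seed = 7))
  f_gsr0 <- train(build_model(spec, seed = 7), dat$data, graph = g,
                  config = train_config(alpha = 0, epochs = 4, seed = 7,
                                        regularizer = "gsr"))
  expect_equal(f_none$trace$task_loss, f_gsr0$trace$task_loss)
  expect_equal(f_none$trace$composite, f_gsr0$trace$composite)
})

test_that("one epoch on ten samples yields a finite length-1 trace", {
  dat <- generate_module_data(2, n_samples = 10, seed = 8)
  spec <- model_spec("autoencoding", layer_sizes = c(2, 4, 4))
  fit <- train(build_model(spec, seed = 8), dat$data,
               config = train_config(epochs = 1, seed = 8))
  expect_equal(nrow(fit$trace), 1)
  expect_true(all(is.finite(unlist(fit$trace))))
})

test_that("strong graph regularization lowers the final penalty", {
  g <- disjoint_pairs_graph(3)
  spec <- model_spec("autoencoding", layer_sizes = c(3, 16, 6))
  diffs <- vapply(1:5, function(s) {
    dat <- generate_module_data(3, n_samples = 256, seed = 100 + s)
    f0 <- train(build_model(spec, seed = 200 + s), dat$data,
                config = train_config(alpha = 0, epochs = 30, seed = 200 + s))
    fr <- train(build_model(spec, seed = 200 + s), dat$data, graph = g,
                config = train_config(alpha = 100, epochs = 30,
                                      seed = 200 + s, regularizer = "gsr"))
    p0 <- gsr_penalty(structured_activations(f0$model, dat$data), g)
    pr <- gsr_penalty(structured_activations(fr$model, dat$data), g)
    pr - p0
  }, numeric(1))
  expect_lt(median(diffs), 0)
  expect_true(all(diffs < 0))
})

test_that("training rejects invalid configurations and data", {
  dat <- generate_module_data(2, n_samples = 32, seed = 9)
  spec <- model_spec("autoencoding", layer_sizes = c(2, 4, 4))
  m <- build_model(spec, seed = 9)
  expect_error(train(m, dat$data,
                     config = train_config(regularizer = "gsr")),
               "requires a feature graph")
  expect_error(train(m, dat$data, graph = disjoint_pairs_graph(3),
                     config = train_config(regularizer = "gsr")),
               "6 nodes.*4 units")
  bad <- dat$data; bad[1, 1] <- NA
  expect_error(train(m, bad, config = train_config()), "non-finite")
  expect_error(train_config(alpha = -1), "nonnegative")
})

test_that("regularizer comparison selects from the grid and reports spreads", {
  dat <- generate_hierarchy_data(per_cluster = 60, seed = 10)
  labels <- dat$super
  set.seed(10)
  test_idx <- sample.int(nrow(dat$data), 90)
  spec <- model_spec("classification", layer_sizes = c(15, 16, 9),
                     n_classes = 3)
  cfg <- train_config(epochs = 15, seed = 11)
  tab <- compare_regularizers(dat$data[-test_idx, ], labels[-test_idx],
                              dat$data[test_idx, ], labels[test_idx],
                              spec, grid = c(1e-4, 1e-3),
                              config = cfg, graph = grid_graph(3, 3),
                              n_replicates = 3)
  expect_setequal(tab$regularizer, c("none", "l1", "l2", "gsr"))
  expect_true(is.na(tab$coefficient[tab$regularizer == "none"]))
  expect_true(all(tab$coefficient[tab$regularizer != "none"] %in%
                    c(1e-4, 1e-3)))
  expect_true(all(tab$test_mean >= 0 & tab$test_mean <= 1))
  # at tiny coefficients every penalty leaves accuracy within 2 points of
  # the unregularized run
  none_acc <- tab$test_mean[tab$regularizer == "none"]
  expect_true(all(abs(tab$test_mean - none_acc) <= 0.02))
  expect_error(
    compare_regularizers(dat$data[-test_idx, ], labels[-test_idx],
                         dat$data[test_idx, ], labels[test_idx],
                         spec, grid = numeric(0), config = cfg),
    "non-empty")
})

test_that("a single-value grid is selected as-is", {
  dat <- generate_hierarchy_data(per_cluster = 30, seed = 12)
  spec <- model_spec("classification", layer_sizes = c(15, 8, 4),
                     n_classes = 3)
  set.seed(12)
  idx <- sample.int(nrow(dat$data), 40)
  tab <- compare_regularizers(dat$data[-idx, ], dat$super[-idx],
                              dat$data[idx, ], dat$super[idx],
                              spec, grid = 1e-3,
                              config = train_config(epochs = 5, seed = 13),
                              regularizers = c("none", "l2"),
                              n_replicates = 2)
  expect_equal(tab$coefficient[tab$regularizer == "l2"], 1e-3)
})
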