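test_that("forward pass reproduces a hand-computed affine+ReLU composition", {
  cfg <- model_config(input_dim = 2, hidden_dims = 2, output_dim = 1,
                      dropout_rate = 0, seed = 1)
  model <- list(config = cfg,
                weights = list(W = list(matrix(c(1, -1, 2, 0), 2, 2),
                                        matrix(c(3, -2), 2, 1)),
                               b = list(c(1, -1), 0.5)))
  x <- matrix(c(2, -1), 1, 2)
  # hidden pre-act: (2*1 + -1*-1 + 1, 2*2 + 0 + -1) = (4, 3); ReLU keeps both
  # output: 4*3 + 3*(-2) + 0.5 = 6.5
  expect_equal(forward_pixels(model, x)[1, 1], 6.5)

  # negative pre-activation is clipped before the output layer
  x2 <- matrix(c(-2, 0), 1, 2)
  # hidden: (-2 + 1, -4 - 1) = (-1, -5) -> (0, 0); output = 0.5
  expect_equal(forward_pixels(model, x2)[1, 1], 0.5)

  # zero weights give identically zero outputs (zero bias)
  z <- list(config = cfg,
            weights = list(W = list(matrix(0, 2, 2), matrix(0, 2, 1)),
                           b = list(c(0, 0), 0)))
  expect_true(all(forward_pixels(z, matrix(rnorm(10), 5, 2)) == 0))

  # inference has no dropout: identical outputs across calls
  b <- tiny_bundle(seed = 1)
  ex <- tiny_examples(b)
  fit <- train(ex[1:4], tiny_config(epochs = 2), crop_names = b$truth$crop_names)
  xs <- matrix(rnorm(32), 2, 16)
  expect_identical(forward_pixels(fit, xs), forward_pixels(fit, xs))

  expect_error(forward_pixels(fit, matrix(0, 1, 4)), "feature width")
})

test_that("aggregation head is the exact arithmetic mean over pixels", {
  p <- matrix(c(1, 2, 3, 9, 9, 9), 3, 2)
  expect_equal(aggregate_prediction(p, 1), 2)
  expect_equal(aggregate_prediction(matrix(7, 5, 2), 2), 7)
  # oracle: naive loop mean on random instances
  set.seed(99)
  for (i in 1:20) {
    n <- sample(1:1000, 1); C <- sample(1:9, 1)
    m <- matrix(rnorm(n * C), n, C)
    ci <- sample(C, 1)
    acc <- 0
    for (r in seq_len(n)) acc <- acc + m[r, ci]
    expect_equal(aggregate_prediction(m, ci), acc / n, tolerance = 1e-12)
  }
  expect_error(aggregate_prediction(matrix(1, 1, 2), 3), "out of range")
})

test_that("indicator masking zeroes every unobserved crop's error", {
  preds <- c(10, 20, 30)
  expect_equal(masked_l1_loss(preds, 25, crop_indicator(2, 3)), 5)
  expect_equal(masked_l1_loss(preds, 30, crop_indicator(3, 3)), 0)
  # dot-product form with a full label vector: E = (3, 1, 4), pick 2nd
  expect_equal(masked_l1_loss(c(5, 6, 9), c(2, 5, 5),
                              crop_indicator(2, 3)), 1)
  # perturbing unobserved labels leaves the loss bit-identical
  l1 <- masked_l1_loss(preds, c(25, 25, 25), crop_indicator(2, 3))
  l2 <- masked_l1_loss(preds, c(-1e6, 25, 999), crop_indicator(2, 3))
  expect_identical(l1, l2)
  expect_error(masked_l1_loss(preds, 1, c(1, 1, 0)), "one-hot")
})

test_that("training overfits one group and is seed-deterministic", {
  b <- tiny_bundle(seed = 7)
  ex <- tiny_examples(b)
  std <- fit_standardizer(ex)
  cfg <- model_config(input_dim = 16, output_dim = 3, dropout_rate = 0,
                      epochs = 300, batch_groups = 8, seed = 1)
  fit <- train(ex[2], cfg, crop_names = b$truth$crop_names,
               standardizer = std)
  # the L1 subgradient keeps a constant magnitude near the optimum, so the
  # epoch loss oscillates at the step-size scale; the loss must reach the
  # overfit level within the default epoch budget
  expect_lt(min(fit$training_log), 1e-2)
  expect_lt(tail(fit$training_log, 1), 5e-2)

  cfg2 <- tiny_config(epochs = 10)
  f1 <- train(ex, cfg2, crop_names = b$truth$crop_names)
  f2 <- train(ex, cfg2, crop_names = b$truth$crop_names)
  expect_identical(f1$weights, f2$weights)
})

test_that("only the observed crop's output head receives gradient", {
  b <- tiny_bundle(seed = 7)
  ex <- tiny_examples(b)
  std <- fit_standardizer(ex)
  exs <- apply_standardizer(ex, std, "forward")
  e <- exs[[1]]
  cfg <- tiny_config()
  ws <- cropsuit:::with_seed(3, cropsuit:::init_weights(cfg))
  cache <- cropsuit:::nn_forward(ws, cfg, e$features, training = FALSE)
  agg <- mean(cache$out[, e$crop_index])
  dout <- matrix(0, nrow(cache$out), ncol(cache$out))
  dout[, e$crop_index] <- sign(agg - e$label) / nrow(cache$out)
  g <- cropsuit:::nn_backward(ws, cfg, cache, dout)
  L <- length(ws$W)
  other <- setdiff(seq_len(cfg$output_dim), e$crop_index)
  expect_true(all(g$W[[L]][, other] == 0))
  expect_true(all(g$b[[L]][other] == 0))
  expect_gt(sum(abs(g$W[[L]][, e$crop_index])), 0)
  # shared layers receive gradient from this single example
  expect_gt(sum(abs(g$W[[1]])), 0)

  # numerical check against finite differences on a few coordinates
  lossfun <- function(w) {
    out <- cropsuit:::nn_forward(w, cfg, e$features, FALSE)$out
    abs(mean(out[, e$crop_index]) - e$label)
  }
  h <- 1e-6
  for (coord in list(c(1, 1), c(3, 2))) {
    wp <- ws; wp$W[[L]][coord[1], other[1]] <- wp$W[[L]][coord[1], other[1]] + h
    expect_equal(lossfun(wp), lossfun(ws))  # exactly flat direction
    wq <- ws; wq$W[[1]][coord[1], coord[2]] <- wq$W[[1]][coord[1], coord[2]] + h
    num <- (lossfun(wq) - lossfun(ws)) / h
    expect_equal(num, g$W[[1]][coord[1], coord[2]], tolerance = 1e-3)
  }
})

test_that("aggregation and loss are invariant to pixel permutation", {
  b <- tiny_bundle(seed = 11)
  ex <- tiny_examples(b)
  fit <- train(ex, tiny_config(epochs = 20), crop_names = b$truth$crop_names)
  e <- ex[[3]]
  p1 <- predict_example(fit, e)
  set.seed(2)
  e2 <- e; e2$features <- e$features[sample(nrow(e$features)), , drop = FALSE]
  p2 <- predict_example(fit, e2)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("pixel-map prediction equals the manual standardize-forward-invert", {
  b <- tiny_bundle(seed = 13)
  ex <- tiny_examples(b)
  fit <- train(ex, tiny_config(epochs = 20), crop_names = b$truth$crop_names)
  g <- b$grids[["2013"]]
  arr <- predict_pixel_yield(fit, g)
  dm <- dim(g$values)
  xs <- apply_standardizer(matrix(g$values, dm[1] * dm[2], dm[3]),
                           fit$standardizer, "forward")
  manual <- apply_standardizer(forward_pixels(fit, xs), fit$standardizer,
                               "inverse", what = "label")
  expect_equal(as.vector(arr), as.vector(manual), tolerance = 1e-12)

  # constant grid gives a spatially constant map
  gc <- g; gc$values <- array(0.3, dim = dm)
  arrc <- predict_pixel_yield(fit, gc)
  expect_equal(max(apply(arrc, 3, function(m) diff(range(m)))), 0)

  # nodata propagates
  gn <- g; gn$nodata_mask[1, 1] <- TRUE
  expect_true(all(is.na(predict_pixel_yield(fit, gn)[1, 1, ])))
})
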