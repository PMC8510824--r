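# Hand-assembled cascade whose layer j emits the constant code vector
# layer_probs[j, ] from all three forests; follows the documented cfnforest
# layout so the fusion arithmetic can be checked exactly.
make_const_cascade <- function(layer_probs, codec, base_dim,
                               region = confidence_region(),
                               mode = "normalized") {
  fsets <- list(c(2, 3, 4), c(2, 3, 5), c(2, 4, 5))
  L <- codec$L
  N <- nrow(layer_probs)
  layers <- lapply(seq_len(N), function(j) {
    width <- if (j == 1) base_dim else base_dim + 3 * L
    list(forests = lapply(fsets, function(fs)
      const_forest(matrix(layer_probs[j, ], 1), codec, width, fs)),
      input_width = width)
  })
  structure(list(layers = layers, codec = codec, region = region,
                 weights_mode = mode,
                 layer_weights = layer_weight(seq_len(N), N, mode),
                 base_input_dim = base_dim, n_layers = N,
                 control = cfnforest_control()),
            class = "cfnforest")
}

test_that("feature augmentation appends three code blocks after the base", {
  X <- matrix(rnorm(10 * 10), 10, 10)
  outs <- lapply(1:3, function(i) matrix(runif(10 * 2), 10, 2))
  A <- augment_features(X, outs)
  expect_equal(ncol(A), 16)  # 10 + 3 * 2
  expect_identical(A[, 1:10], unname(X))
  expect_equal(A[, 11:12], outs[[1]])
  expect_equal(A[, 15:16], outs[[3]])
  expect_error(augment_features(X, lapply(1:3, function(i)
    matrix(0, 9, 2))), "row counts")
  expect_error(augment_features(X, outs[1:2]), "3 forests")
})

test_that("layer fusion is the componentwise three-forest mean", {
  o <- list(matrix(c(0, 0), 1), matrix(c(0.3, 0.6), 1),
            matrix(c(0.6, 0), 1))
  expect_equal(fuse_outputs(o), matrix(c(0.3, 0.2), 1))
  same <- matrix(runif(6), 2, 3)
  expect_equal(fuse_outputs(list(same, same, same)), same)
  lo <- pmin(o[[1]], o[[2]], o[[3]])
  hi <- pmax(o[[1]], o[[2]], o[[3]])
  f <- fuse_outputs(o)
  expect_true(all(f >= lo & f <= hi))
  expect_error(fuse_outputs(list(same, same, same[1, , drop = FALSE])),
               "shape")
})

test_that("the confidence gate requires every component in the region", {
  wx <- make_worked_example()
  s <- confidence_split(wx, confidence_region(0.2, 0.8))
  # (0.07,0.03), (0.83,0.12) and (0.95,0.14) have all components in
  # [0,0.2] U [0.8,1]; the middle two do not
  expect_equal(s$confident, c(1L, 4L, 5L))
  expect_equal(s$uncertain, c(2L, 3L))

  # boundaries are closed
  sb <- confidence_split(matrix(c(0.2, 0.8), 1), confidence_region())
  expect_equal(sb$confident, 1L)

  expect_error(confidence_split(matrix(c(-0.1, 0.5), 1)), "\\[0, 1\\]")
  expect_error(confidence_region(0.9, 0.1), "low <= high")
})

test_that("layer weights follow the triangular scheme and sum to one", {
  expect_equal(layer_weight(1, 1), 1)
  expect_equal(layer_weight(1:3, 3), c(1 / 6, 1 / 3, 1 / 2))
  expect_equal(sum(layer_weight(1:5, 5)), 1)
  # literal printed form: i / (1 + 2 + ... + i)
  expect_equal(layer_weight(2, 3, mode = "literal"), 2 / 3)
  expect_equal(layer_weight(1:3, 3, mode = "literal"),
               c(1, 2 / 3, 1 / 2))
  expect_error(layer_weight(4, 3), "out of range")
})

test_that("prediction fuses layers with renormalized weights on early exit", {
  codec <- class_codec(paste0("c", 1:4))
  # wide-open uncertainty band forces full traversal:
  # y_f = (1/3)(0.1,0.1) + (2/3)(0.7,0.9) = (0.5, 0.6333)
  m <- make_const_cascade(rbind(c(0.1, 0.1), c(0.7, 0.9)), codec, 3,
                          region = confidence_region(0.05, 0.95))
  sc <- predict(m, matrix(0, 4, 3), type = "score")
  expect_equal(unname(sc[1, ]), c(0.5, 19 / 30), tolerance = 1e-9)
  expect_equal(attr(sc, "exit_layer"), rep(2L, 4))

  # default region: layer 1 already confident, exit with y_f = y_1
  m2 <- make_const_cascade(rbind(c(0.1, 0.1), c(0.7, 0.9)), codec, 3)
  sc2 <- predict(m2, matrix(0, 2, 3), type = "score")
  expect_equal(unname(sc2[1, ]), c(0.1, 0.1), tolerance = 1e-9)
  expect_equal(attr(sc2, "exit_layer"), rep(1L, 2))

  # single-layer model: y_f is exactly the fused layer output
  m1 <- make_const_cascade(rbind(c(0.35, 0.44)), codec, 3)
  sc1 <- predict(m1, matrix(0, 1, 3), type = "score")
  expect_equal(unname(sc1[1, ]), c(0.35, 0.44), tolerance = 1e-9)

  expect_error(predict(m, matrix(0, 1, 7)), "expected 3")
})

test_that("a gate-disabling region reduces prediction to the first layer", {
  codec <- class_codec(c("a", "b"))
  m <- make_const_cascade(rbind(0.42, 0.9), codec, 2,
                          region = confidence_region(0.5, 0.5))
  sc <- predict(m, matrix(0, 3, 2), type = "score")
  expect_equal(unname(sc[, 1]), rep(0.42, 3), tolerance = 1e-9)
  expect_equal(attr(sc, "exit_layer"), rep(1L, 3))
})

test_that("fitting grows, validates and trims the cascade on synthetic data", {
  d <- make_dataset(synthetic_spec(n_per_class = c(20, 20), n_genes = 8,
                                   n_informative = 4, shift = 3,
                                   missing_rate = 0, seed = 61))
  X <- as.matrix(zscore_normalize(d$x)$x)
  ctl <- cfnforest_control(K = 2,
                           gggp = gggp_control(population_size = 10,
                                               generations = 4),
                           pso = pso_control(swarm_size = 8,
                                             iterations = 8),
                           outer_rounds = 1, max_layers = 2)
  fit <- cfnforest(X, d$y, ctl, seed = 62)
  expect_s3_class(fit, "cfnforest")
  expect_gte(fit$n_layers, 1)
  expect_lte(fit$n_layers, 2)
  # retained depth maximizes recorded validation accuracy
  expect_equal(fit$validation$accuracy[fit$n_layers],
               max(fit$validation$accuracy))
  # uncertain training counts never grow layer over layer
  expect_true(all(diff(fit$validation$n_uncertain_train) <= 0))
  # weights are normalized over the final depth
  expect_equal(sum(fit$layer_weights), 1)

  p <- predict(fit, X)
  expect_s3_class(p, "factor")
  expect_equal(levels(p), levels(d$y))
  sc <- predict(fit, X, type = "score")
  expect_true(all(sc >= 0 & sc <= 1))
  # exit layers are stable across reruns on the same data
  expect_identical(attr(predict(fit, X), "exit_layer"),
                   attr(p, "exit_layer"))

  # max_layers = 1 forces a single layer with weight 1
  ctl1 <- cfnforest_control(K = 1,
                            gggp = gggp_control(population_size = 6,
                                                generations = 2),
                            pso = pso_control(swarm_size = 5,
                                              iterations = 3),
                            outer_rounds = 1, max_layers = 1)
  fit1 <- cfnforest(X, d$y, ctl1, seed = 63)
  expect_equal(fit1$n_layers, 1L)
  expect_equal(fit1$layer_weights, 1)
})

test_that("fitting fails clearly when a class cannot populate the holdout", {
  X <- matrix(rnorm(10), 5, 2)
  y <- factor(c("a", "a", "a", "a", "b"))
  expect_error(cfnforest(X, y, cfnforest_control()), "too few samples")
})
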