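test_that("random generation respects the grammar", {
  # depth bound 1 leaves no room for a function node
  g1 <- fnt_grammar(c(2, 3), input_dim = 5, max_depth = 1)
  set.seed(31)
  for (i in 1:10) expect_equal(random_fnt(g1)$root$type, "leaf")

  # validity sweep over a larger sample
  g <- fnt_grammar(c(2, 3), input_dim = 5, max_depth = 4)
  set.seed(32)
  for (i in 1:200) {
    tr <- random_fnt(g)
    expect_true(is_grammar_valid(tr, c(2, 3), 5, 4))
  }

  # same seed, same tree; different seed, (almost surely) different tree
  set.seed(33); a <- random_fnt(g)
  set.seed(33); b <- random_fnt(g)
  expect_identical(a, b)

  expect_error(fnt_grammar(c(2, 3), input_dim = 0), "terminal")
})

test_that("crossover preserves grammar validity and the parents", {
  g <- fnt_grammar(c(2, 3), input_dim = 4, max_depth = 4)
  set.seed(34)
  for (i in 1:100) {
    a <- random_fnt(g)
    b <- random_fnt(g)
    a0 <- a
    b0 <- b
    off <- crossover_fnt(a, b, g)
    expect_true(is_grammar_valid(off[[1]], c(2, 3), 4, 4))
    expect_true(is_grammar_valid(off[[2]], c(2, 3), 4, 4))
    expect_identical(a, a0)
    expect_identical(b, b0)
  }

  # two single leaves can only swap leaves
  la <- fnt(fnt_leaf(1), c(2, 3), 4)
  lb <- fnt(fnt_leaf(3), c(2, 3), 4)
  off <- crossover_fnt(la, lb, g)
  expect_equal(off[[1]]$root, lb$root)
  expect_equal(off[[2]]$root, la$root)
})

test_that("mutation is probabilistic, grammar-safe and non-destructive", {
  g <- fnt_grammar(c(2, 3), input_dim = 4, max_depth = 4)
  set.seed(35)
  tr <- random_fnt(g)
  expect_identical(mutate_fnt(tr, g, prob = 0), tr)

  # forced mutation of a single leaf yields a fresh valid tree
  leaf <- fnt(fnt_leaf(2), c(2, 3), 4)
  m <- mutate_fnt(leaf, g, prob = 1)
  expect_true(is_grammar_valid(m, c(2, 3), 4, 4))

  for (i in 1:100) {
    t0 <- random_fnt(g)
    m <- mutate_fnt(t0, g, prob = 1)
    expect_true(is_grammar_valid(m, c(2, 3), 4, 4))
  }
})

test_that("tournament selection minimizes fitness", {
  # full tournament with distinct fitnesses always finds the global best
  f <- c(0.5, 0.2, 0.9, 0.4)
  set.seed(36)
  for (i in 1:20) expect_equal(select_tournament(f, size = 4), 2L)

  # size-2 tournament between 0.1 and 0.9 always returns 0.1
  for (i in 1:20) expect_equal(select_tournament(c(0.1, 0.9), 2), 1L)

  # size-1 tournament is a uniform draw
  draws <- replicate(4000, select_tournament(f, 1))
  props <- tabulate(draws, 4) / 4000
  expect_true(all(abs(props - 0.25) < 0.05))
})

test_that("structure evolution solves a leaf-recoverable target", {
  set.seed(37)
  X <- matrix(runif(15 * 3), 15, 3)  # columns already in [0, 1]
  y <- X[, 2]                        # exactly a single-leaf tree
  g <- fnt_grammar(c(2, 3), input_dim = 3, max_depth = 3)
  res <- evolve_structure(X, y, g,
                          gggp_control(population_size = 30,
                                       generations = 15),
                          seed = 38)
  expect_lt(res$fitness, 1e-4)
  expect_equal(res$tree$root$type, "leaf")
  expect_equal(res$tree$root$feature, 2L)
})

test_that("elitism makes the best-ever fitness non-increasing", {
  set.seed(39)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- as.numeric(X[, 1] > 0)
  g <- fnt_grammar(c(2, 3), 4, 4)
  res <- evolve_structure(X, y, g,
                          gggp_control(population_size = 15,
                                       generations = 10), seed = 40)
  expect_true(all(diff(res$trace) <= 0))
})

test_that("evolution is deterministic under a fixed seed", {
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- runif(12)
  g <- fnt_grammar(c(2, 3), 3, 3)
  ctl <- gggp_control(population_size = 10, generations = 5)
  a <- evolve_structure(X, y, g, ctl, seed = 41)
  b <- evolve_structure(X, y, g, ctl, seed = 41)
  expect_identical(a, b)
})

test_that("alternating training improves on structure search alone", {
  set.seed(42)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- as.numeric(X[, 1] - X[, 3] > 0)
  g <- fnt_grammar(c(2, 3), 4, 4)
  gc <- gggp_control(population_size = 15, generations = 6)
  pc <- pso_control(swarm_size = 12, iterations = 15)

  # one round = evolve then one PSO pass; PSO must not regress
  set.seed(43)
  es <- evolve_structure(X, y, g, gc)
  po <- optimize_params(es$tree, X, y, pc)
  expect_lte(po$fitness, es$fitness)

  res <- train_fnt(X, y, g, gc, pc, outer_rounds = 2, seed = 44)
  expect_lte(res$fitness, min(res$round_fitness))
  expect_true(all(res$round_fitness >= res$fitness))
})

test_that("training recovers a well-separated two-class signal", {
  d <- make_dataset(synthetic_spec(n_per_class = c(25, 25), n_genes = 12,
                                   n_informative = 4, shift = 3,
                                   missing_rate = 0, seed = 45))
  nz <- zscore_normalize(d$x)
  X <- as.matrix(nz$x)
  codec <- class_codec(levels(d$y))
  y <- encode_label(d$y, codec)[, 1]
  g <- fnt_grammar(c(2, 3, 4), ncol(X), 5)
  res <- train_fnt(X, y, g,
                   gggp_control(population_size = 20, generations = 10),
                   pso_control(swarm_size = 30, iterations = 20),
                   outer_rounds = 2, seed = 46)
  scores <- pmin(pmax(predict(res$tree, X), 0), 1)
  acc <- mean(decode_output(matrix(scores), codec)$labels == d$y)
  expect_gte(acc, 0.95)
})
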