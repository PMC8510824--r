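## Grammar-guided genetic programming over tree structures and the
## alternating structure/parameter training loop.

#' Tree grammar
#'
#' Encodes the context-free grammar that generation, crossover and mutation
#' respect: one production per permitted arity (a nonterminal expands to a
#' `+M` node with M nonterminal children) plus one production per terminal
#' (a nonterminal expands to an input feature), under a depth bound. Because
#' the production set is fully determined by the function set and the
#' terminals by `input_dim`, the grammar is represented by those plus
#' `max_depth`; validity of any tree is arity membership, leaf-index range and
#' the depth bound (see [validate_fnt()]).
#'
#' @param function_set integer arities >= 2, e.g. `c(2, 3, 4)`. The set is
#'   user-configurable and never hard-coded; cascade layers use three
#'   different sets to create structural diversity.
#' @param input_dim number of terminals (input features).
#' @param max_depth maximum tree depth (single node = depth 1). Default 5,
#'   which bounds bloat on thousands-of-genes inputs.
#' @return a list of class `fnt_grammar`.
#' @export
fnt_grammar <- function(function_set = c(2, 3, 4), input_dim, max_depth = 5) {
  function_set <- sort(unique(as.integer(function_set)))
  if (length(function_set) == 0L || any(function_set < 2L))
    stop("function_set must be a non-empty set of arities >= 2")
  input_dim <- as.integer(input_dim)
  if (is.na(input_dim) || input_dim < 1L)
    stop("grammar has no terminal production: input_dim must be >= 1")
  max_depth <- as.integer(max_depth)
  if (max_depth < 1L) stop("max_depth must be >= 1")
  structure(list(function_set = function_set, input_dim = input_dim,
                 max_depth = max_depth), class = "fnt_grammar")
}

## grow a random grammar-valid subtree of depth <= depth_left;
## weights and biases drawn from U(-1, 1)
.grow_node <- function(grammar, depth_left, p_leaf = 0.5) {
  if (depth_left <= 1L || stats::runif(1) < p_leaf)
    return(fnt_leaf(sample.int(grammar$input_dim, 1L)))
  fs <- grammar$function_set
  arity <- fs[sample.int(length(fs), 1L)]
  children <- lapply(seq_len(arity), function(j)
    .grow_node(grammar, depth_left - 1L, p_leaf))
  fnt_node(children, stats::runif(arity, -1, 1), stats::runif(1, -1, 1))
}

#' Generate a random grammar-valid tree
#'
#' Grow-style generation: interior positions become function nodes with
#' probability 0.5 (0.9 at the root, so degenerate single-leaf trees are rare
#' but legal), weights and biases drawn from U(-1, 1). With `max_depth = 1`
#' the tree is necessarily a single leaf.
#'
#' @param grammar an [fnt_grammar()].
#' @return an `fnt`.
#' @export
random_fnt <- function(grammar) {
  stopifnot(inherits(grammar, "fnt_grammar"))
  root <- if (grammar$max_depth <= 1L || stats::runif(1) < 0.1) {
    fnt_leaf(sample.int(grammar$input_dim, 1L))
  } else {
    fs <- grammar$function_set
    arity <- fs[sample.int(length(fs), 1L)]
    children <- lapply(seq_len(arity), function(j)
      .grow_node(grammar, grammar$max_depth - 1L))
    fnt_node(children, stats::runif(arity, -1, 1), stats::runif(1, -1, 1))
  }
  fnt(root, grammar$function_set, grammar$input_dim)
}

## enumerate nodes: list of (path, depth, height); path = integer child
## indices from the root (empty = root)
.node_table <- function(node, path = integer(0), depth = 1L) {
  h <- .node_depth(node)
  rows <- list(list(path = path, depth = depth, height = h))
  if (node$type == "func")
    for (j in seq_along(node$children))
      rows <- c(rows, .node_table(node$children[[j]], c(path, j), depth + 1L))
  rows
}

.get_subtree <- function(node, path) {
  for (j in path) node <- node$children[[j]]
  node
}

.set_subtree <- function(node, path, new) {
  if (length(path) == 0L) return(new)
  j <- path[1L]
  node$children[[j]] <- .set_subtree(node$children[[j]], path[-1L], new)
  node
}

#' Grammar-safe subtree crossover
#'
#' Swaps one uniformly chosen subtree of `a` with one of `b`, restricted to
#' swap points that keep both offspring within the grammar's depth bound
#' (arity validity is automatic since parents share the grammar). A crossover
#' point is drawn uniformly in `a`; among `b`'s depth-legal points one is
#' drawn uniformly; if no legal pair exists for any point of `a`, copies of
#' the parents are returned. Parents are never modified.
#'
#' @param a,b `fnt` trees sharing `grammar`.
#' @param grammar an [fnt_grammar()].
#' @return list of two offspring `fnt` trees.
#' @export
crossover_fnt <- function(a, b, grammar) {
  stopifnot(inherits(a, "fnt"), inherits(b, "fnt"))
  ta <- .node_table(a$root)
  tb <- .node_table(b$root)
  depth_b <- vapply(tb, `[[`, integer(1), "depth")
  height_b <- vapply(tb, `[[`, integer(1), "height")
  md <- grammar$max_depth
  for (ia in sample.int(length(ta))) {
    da <- ta[[ia]]$depth
    ha <- ta[[ia]]$height
    legal <- which(da - 1L + height_b <= md & depth_b - 1L + ha <= md)
    if (length(legal) > 0L) {
      ib <- legal[sample.int(length(legal), 1L)]
      sub_a <- .get_subtree(a$root, ta[[ia]]$path)
      sub_b <- .get_subtree(b$root, tb[[ib]]$path)
      ra <- .set_subtree(a$root, ta[[ia]]$path, sub_b)
      rb <- .set_subtree(b$root, tb[[ib]]$path, sub_a)
      return(list(fnt(ra, grammar$function_set, grammar$input_dim),
                  fnt(rb, grammar$function_set, grammar$input_dim)))
    }
  }
  list(a, b)
}

#' Grammar-safe point mutation
#'
#' With probability `prob`, replaces a uniformly chosen node by a freshly
#' grown grammar-valid random subtree that fits the remaining depth
#' allowance; otherwise returns the tree unchanged. The input tree is never
#' mutated in place.
#'
#' @param tree an `fnt`.
#' @param grammar an [fnt_grammar()].
#' @param prob mutation probability in \[0, 1\].
#' @return an `fnt`.
#' @export
mutate_fnt <- function(tree, grammar, prob = 0.2) {
  stopifnot(inherits(tree, "fnt"))
  if (stats::runif(1) >= prob) return(tree)
  tab <- .node_table(tree$root)
  i <- sample.int(length(tab), 1L)
  depth_left <- grammar$max_depth - tab[[i]]$depth + 1L
  new_sub <- .grow_node(grammar, depth_left)
  fnt(.set_subtree(tree$root, tab[[i]]$path, new_sub),
      grammar$function_set, grammar$input_dim)
}

#' Tournament selection (fitness minimized)
#'
#' Samples `size` distinct individuals uniformly and returns the index of the
#' one with minimal fitness (ties: first sampled among the minima). Sampling
#' without replacement makes a full-population tournament deterministic: it
#' always returns the global best.
#'
#' @param fitnesses numeric vector of population fitnesses.
#' @param size tournament size (<= population size).
#' @return the selected individual's index.
#' @export
select_tournament <- function(fitnesses, size = 3) {
  n <- length(fitnesses)
  if (n == 0L) stop("empty population")
  size <- min(as.integer(size), n)
  idx <- sample.int(n, size, replace = FALSE)
  idx[which.min(fitnesses[idx])]
}

#' Genetic-programming settings
#'
#' @param population_size number of trees per generation.
#' @param generations number of generational sweeps.
#' @param crossover_prob probability that a selected parent pair is recombined
#'   rather than copied.
#' @param mutation_prob per-offspring mutation probability.
#' @param tournament_size tournament size for selection (default 3).
#' @param weight_draws weight resamplings per structure evaluation: each
#'   individual is scored with its current weights and `weight_draws - 1`
#'   fresh U(-1, 1) draws, keeping the best. A structure's fitness under one
#'   arbitrary weight setting is a poor proxy for its potential; a few random
#'   restarts make the structure search see topology quality rather than
#'   weight luck.
#' @param tol stop early when the best fitness falls below this.
#' @return a list of class `gggp_control`.
#' @export
gggp_control <- function(population_size = 30, generations = 20,
                         crossover_prob = 0.8, mutation_prob = 0.2,
                         tournament_size = 3, weight_draws = 3, tol = 1e-4) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            tournament_size >= 1, tournament_size <= population_size,
            weight_draws >= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 tournament_size = as.integer(tournament_size),
                 weight_draws = as.integer(weight_draws),
                 tol = tol),
            class = "gggp_control")
}

## score one individual: its current weights plus (weight_draws - 1) fresh
## U(-1, 1) draws; returns the best-scoring version and its fitness
.eval_individual <- function(tree, X, y, weight_draws) {
  f <- fnt_fitness(tree, X, y)
  np <- n_params(tree)
  if (np > 0L && weight_draws > 1L) {
    for (k in seq_len(weight_draws - 1L)) {
      cand <- set_params(tree, stats::runif(np, -1, 1))
      fc <- fnt_fitness(cand, X, y)
      if (fc < f) {
        f <- fc
        tree <- cand
      }
    }
  }
  list(tree = tree, fitness = f)
}

#' Evolve a tree structure by grammar-guided genetic programming
#'
#' Generational loop with elitism of 1 (the best individual is copied into the
#' next generation unchanged, so the best-ever fitness is monotone
#' non-increasing): parents chosen by tournament, recombined with probability
#' `crossover_prob`, mutated with probability `mutation_prob`. The initial
#' population is depth-ramped (target depths cycle over 2..max_depth), so
#' small and large structures compete from the start. Stops after
#' `generations` rounds or as soon as the best fitness drops below
#' `control$tol`.
#'
#' @param X samples-by-features matrix (preprocessed).
#' @param y numeric coded targets in \[0, 1\].
#' @param grammar an [fnt_grammar()].
#' @param control a [gggp_control()].
#' @param init optional list of `fnt` trees injected into the initial
#'   population (e.g. an incumbent from a previous training round).
#' @param seed optional integer seed.
#' @return list with `tree` (best ever), `fitness`, and `trace` (best-ever
#'   fitness after each generation, starting with the initial population).
#' @export
evolve_structure <- function(X, y, grammar, control = gggp_control(),
                             init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n_pop <- control$population_size
  pop <- vector("list", n_pop)
  n_init <- 0L
  if (!is.null(init)) {
    n_init <- min(length(init), n_pop)
    for (i in seq_len(n_init)) {
      validate_fnt(init[[i]], grammar)
      pop[[i]] <- init[[i]]
    }
  }
  ramp <- if (grammar$max_depth > 2L) seq(2L, grammar$max_depth)
    else grammar$max_depth
  for (i in seq_len(n_pop)[seq_len(n_pop) > n_init]) {
    g_i <- grammar
    g_i$max_depth <- ramp[1L + (i %% length(ramp))]
    pop[[i]] <- random_fnt(g_i)
  }
  ev <- lapply(pop, function(tr) .eval_individual(tr, X, y, control$weight_draws))
  pop <- lapply(ev, `[[`, "tree")
  fit <- vapply(ev, `[[`, numeric(1), "fitness")
  best_i <- which.min(fit)
  best <- pop[[best_i]]
  best_f <- fit[best_i]
  trace <- numeric(control$generations + 1L)
  trace[1L] <- best_f
  gen_done <- 0L
  for (gen in seq_len(control$generations)) {
    if (best_f < control$tol) break
    newpop <- vector("list", n_pop)
    newpop[[1L]] <- pop[[which.min(fit)]]  # elitism of 1
    k <- 1L
    while (k < n_pop) {
      p1 <- pop[[select_tournament(fit, control$tournament_size)]]
      p2 <- pop[[select_tournament(fit, control$tournament_size)]]
      off <- if (stats::runif(1) < control$crossover_prob)
        crossover_fnt(p1, p2, grammar) else list(p1, p2)
      for (o in off) {
        if (k >= n_pop) break
        k <- k + 1L
        newpop[[k]] <- mutate_fnt(o, grammar, control$mutation_prob)
      }
    }
    ev <- lapply(newpop, function(tr) .eval_individual(tr, X, y, control$weight_draws))
    pop <- lapply(ev, `[[`, "tree")
    fit <- vapply(ev, `[[`, numeric(1), "fitness")
    if (min(fit) < best_f) {
      best_f <- min(fit)
      best <- pop[[which.min(fit)]]
    }
    gen_done <- gen
    trace[gen + 1L] <- best_f
  }
  list(tree = best, fitness = best_f,
       trace = trace[seq_len(gen_done + 1L)])
}

#' Train a flexible neural tree: alternating structure and parameter search
#'
#' Alternates structure evolution ([evolve_structure()]) with parameter
#' refinement by PSO ([optimize_params()]) for up to `outer_rounds` rounds.
#' From round two onward the incumbent best tree is injected into the GGGP
#' initial population so search refines rather than restarts. Stops early
#' when the post-PSO fitness falls below `tol` or the relative improvement
#' over the previous round is below `rel_tol`. Returns the tree whose
#' post-PSO fitness is minimal over all rounds.
#'
#' @param X,y training matrix and coded targets.
#' @param grammar an [fnt_grammar()].
#' @param gggp a [gggp_control()].
#' @param pso a [pso_control()].
#' @param outer_rounds maximum number of alternations (default 3).
#' @param tol absolute fitness tolerance for early stopping.
#' @param rel_tol minimal relative per-round improvement to continue.
#' @param seed optional integer seed.
#' @return list with `tree`, `fitness`, and `round_fitness` (post-PSO fitness
#'   per completed round).
#' @export
train_fnt <- function(X, y, grammar, gggp = gggp_control(),
                      pso = pso_control(), outer_rounds = 3, tol = 1e-4,
                      rel_tol = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  best_f <- Inf
  round_f <- numeric(0)
  prev_f <- Inf
  for (r in seq_len(outer_rounds)) {
    es <- evolve_structure(X, y, grammar, gggp,
                           init = if (is.null(best)) NULL else list(best))
    po <- optimize_params(es$tree, X, y, pso)
    round_f <- c(round_f, po$fitness)
    if (po$fitness < best_f) {
      best_f <- po$fitness
      best <- po$tree
    }
    if (best_f < tol) break
    if (is.finite(prev_f) && (prev_f - best_f) < rel_tol * max(prev_f, 1e-12))
      break
    prev_f <- best_f
  }
  list(tree = best, fitness = best_f, round_fitness = round_f)
}
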