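# Independent oracles and fixture builders, written against the documented
# contracts only (never the package internals).

# Naive scalar recursive tree evaluator: the second, straightforward
# implementation the vectorized evaluator must agree with.
naive_eval <- function(node, x) {
  if (node$type == "leaf") return(x[node$feature])
  z <- node$bias
  for (j in seq_along(node$children))
    z <- z + node$weights[j] * naive_eval(node$children[[j]], x)
  1 / (1 + exp(-z))
}

# Exhaustive node walk collecting leaf feature indices (oracle for
# used_features), deliberately a different traversal order (right-to-left).
walk_features <- function(node) {
  if (node$type == "leaf") return(node$feature)
  out <- integer(0)
  for (j in rev(seq_along(node$children)))
    out <- c(out, walk_features(node$children[[j]]))
  out
}

# Depth of a node by direct recursion.
walk_depth <- function(node) {
  if (node$type == "leaf") return(1L)
  1L + max(vapply(node$children, walk_depth, integer(1)))
}

# Grammar validity check used on evolved populations: arity membership,
# leaf range, depth bound, weight-count consistency.
is_grammar_valid <- function(tree, function_set, input_dim, max_depth) {
  ok <- TRUE
  rec <- function(node) {
    if (node$type == "leaf") {
      if (node$feature < 1L || node$feature > input_dim) ok <<- FALSE
    } else {
      if (!(length(node$children) %in% function_set)) ok <<- FALSE
      if (length(node$weights) != length(node$children)) ok <<- FALSE
      for (ch in node$children) rec(ch)
    }
  }
  rec(tree$root)
  ok && walk_depth(tree$root) <= max_depth
}

# Brute-force KNN imputation oracle: exhaustively ranked neighbor list per
# missing cell, Euclidean distance over genes observed in both samples.
brute_impute <- function(v, k, ref = v, self = TRUE) {
  out <- v
  for (i in seq_len(nrow(v))) {
    for (g in which(is.na(v[i, ]))) {
      d <- rep(Inf, nrow(ref))
      for (j in seq_len(nrow(ref))) {
        if (self && j == i) next
        shared <- !is.na(v[i, ]) & !is.na(ref[j, ])
        if (!any(shared)) next
        d[j] <- sqrt(sum((v[i, shared] - ref[j, shared])^2))
      }
      elig <- which(!is.na(ref[, g]) & is.finite(d))
      elig <- elig[order(d[elig], elig)]
      nb <- elig[seq_len(min(k, length(elig)))]
      out[i, g] <- mean(ref[nb, g])
    }
  }
  out
}

# A tree with constant output p regardless of input: two zero-weight leaves
# and bias logit(p).
const_tree <- function(p, input_dim, function_set = c(2, 3, 4)) {
  fnt(fnt_node(list(fnt_leaf(1), fnt_leaf(1)), c(0, 0), qlogis(p)),
      function_set, input_dim)
}

# A hand-assembled forest of constant trees (one group per row of `probs`,
# one tree per column), matching the documented fnt_forest layout.
const_forest <- function(probs, codec, input_dim,
                         function_set = c(2, 3, 4)) {
  groups <- lapply(seq_len(nrow(probs)), function(g)
    list(trees = lapply(probs[g, ], const_tree, input_dim = input_dim,
                        function_set = function_set),
         boot_idx = NULL))
  structure(list(groups = groups, K = nrow(probs), codec = codec,
                 function_set = sort(unique(as.integer(function_set))),
                 input_dim = input_dim,
                 grammar = fnt_grammar(function_set, input_dim)),
            class = "fnt_forest")
}

# Random grammar-valid tree for property sweeps (uses the package generator).
random_tree_for <- function(function_set, input_dim, max_depth) {
  random_fnt(fnt_grammar(function_set, input_dim, max_depth))
}
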