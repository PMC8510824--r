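## Flexible neural tree core: node constructors, evaluator, parameter vector
## bridge, RMSE fitness, feature usage, JSON persistence.

#' Sigmoid activation with overflow guard
#'
#' The pre-activation is clamped to \[-500, 500\] before exponentiation, which
#' avoids floating overflow while changing results by less than 1e-200.
#'
#' @param z numeric vector.
#' @return numeric vector in (0, 1).
#' @keywords internal
sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -500), 500)))

#' Flexible neural tree nodes
#'
#' `fnt_leaf(feature)` builds a terminal node emitting the value of one input
#' feature (1-based index). `fnt_node(children, weights, bias)` builds a
#' non-leaf node of arity M = `length(children)` computing
#' `sigmoid(sum_j weights[j] * child_j + bias)`. Leaves carry no weights of
#' their own; weights live on the parent's incoming edges.
#'
#' @param feature 1-based input feature index.
#' @param children list of child nodes (length M >= 2).
#' @param weights numeric vector of length M.
#' @param bias scalar bias.
#' @return a node (nested list) usable as the root of an [fnt()].
#' @export
fnt_leaf <- function(feature) {
  feature <- as.integer(feature)
  if (length(feature) != 1L || is.na(feature) || feature < 1L)
    stop("feature must be a single positive integer index")
  list(type = "leaf", feature = feature)
}

#' @rdname fnt_leaf
#' @export
fnt_node <- function(children, weights, bias) {
  if (!is.list(children) || length(children) < 2L)
    stop("a function node needs at least 2 children")
  if (length(weights) != length(children))
    stop("need exactly one weight per child (", length(children), ")")
  list(type = "func", arity = length(children),
       weights = as.numeric(weights), bias = as.numeric(bias),
       children = children)
}

#' Flexible neural tree
#'
#' A tree-shaped neural network: non-leaf nodes `+M` apply a sigmoid to a
#' weighted sum of their M children plus a bias, leaves emit input feature
#' values. Both the topology and the weights are learned (see
#' [evolve_structure()], [optimize_params()], [train_fnt()]).
#'
#' @param root the root node ([fnt_leaf()] or [fnt_node()]).
#' @param function_set integer vector of permitted non-leaf arities
#'   (all >= 2), e.g. `c(2, 3, 4)`.
#' @param input_dim number of input features the leaves index into.
#' @return object of class `fnt`.
#' @export
fnt <- function(root, function_set, input_dim) {
  function_set <- sort(unique(as.integer(function_set)))
  if (length(function_set) == 0L || any(function_set < 2L))
    stop("function_set must be a non-empty set of arities >= 2")
  input_dim <- as.integer(input_dim)
  if (input_dim < 1L) stop("input_dim must be positive")
  obj <- structure(list(root = root, function_set = function_set,
                        input_dim = input_dim), class = "fnt")
  .check_node(root, function_set, input_dim)
  obj
}

.check_node <- function(node, function_set, input_dim) {
  if (node$type == "leaf") {
    if (node$feature > input_dim)
      stop("leaf feature index ", node$feature,
           " out of range for input_dim ", input_dim)
  } else {
    if (!node$arity %in% function_set)
      stop("node arity ", node$arity, " not in the function set {",
           paste(function_set, collapse = ","), "}")
    if (length(node$children) != node$arity ||
        length(node$weights) != node$arity)
      stop("node arity, child count and weight count must agree")
    for (ch in node$children) .check_node(ch, function_set, input_dim)
  }
  invisible(TRUE)
}

#' Validate a tree against a grammar
#'
#' Checks arity membership in the function set, leaf index range and the
#' depth bound of `grammar`.
#'
#' @param tree an `fnt`.
#' @param grammar an [fnt_grammar()]; when `NULL` only structural checks run.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_fnt <- function(tree, grammar = NULL) {
  stopifnot(inherits(tree, "fnt"))
  fs <- if (is.null(grammar)) tree$function_set else grammar$function_set
  dim <- if (is.null(grammar)) tree$input_dim else grammar$input_dim
  .check_node(tree$root, fs, dim)
  if (!is.null(grammar) && tree_depth(tree) > grammar$max_depth)
    stop("tree depth ", tree_depth(tree), " exceeds max_depth ",
         grammar$max_depth)
  invisible(TRUE)
}

.node_depth <- function(node) {
  if (node$type == "leaf") return(1L)
  1L + max(vapply(node$children, .node_depth, integer(1)))
}

#' Depth of a flexible neural tree (a single node has depth 1)
#' @param tree an `fnt` or a bare node.
#' @return integer depth.
#' @export
tree_depth <- function(tree) {
  node <- if (inherits(tree, "fnt")) tree$root else tree
  .node_depth(node)
}

.eval_node <- function(node, X) {
  if (node$type == "leaf") return(X[, node$feature])
  z <- rep.int(node$bias, nrow(X))
  for (j in seq_along(node$children))
    z <- z + node$weights[j] * .eval_node(node$children[[j]], X)
  sigmoid(z)
}

#' Evaluate a flexible neural tree
#'
#' Computes the tree output bottom-up: leaves emit the input feature value,
#' non-leaf nodes emit `sigmoid(sum_j w_j I_j + bias)`. When the root is a
#' function node the output lies strictly in (0, 1).
#'
#' @param object an `fnt`.
#' @param newdata numeric vector of length `input_dim`, or a matrix with
#'   `input_dim` columns (one output per row).
#' @param ... unused.
#' @return numeric vector of outputs, one per input row.
#' @export
predict.fnt <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim)
    stop("newdata has ", ncol(newdata), " columns; expected ",
         object$input_dim)
  if (any(!is.finite(newdata))) stop("inputs must be finite")
  .eval_node(object$root, newdata)
}

#' @export
print.fnt <- function(x, ...) {
  cat(sprintf("flexible neural tree: depth %d, %d parameters, features {%s}\n",
              tree_depth(x), n_params(x),
              paste(used_features(x), collapse = ",")))
  invisible(x)
}

.collect_params <- function(node) {
  if (node$type == "leaf") return(numeric(0))
  c(node$weights, node$bias,
    unlist(lapply(node$children, .collect_params), use.names = FALSE))
}

#' Parameter vector bridge
#'
#' `flatten_params()` lays out all weights and biases in deterministic
#' pre-order: for each function node first its weights `w_1..w_M`, then its
#' bias, then the parameters of its children left to right. `set_params()` is
#' the inverse; `set_params(tree, flatten_params(tree))` is the identity.
#' `n_params()` is the vector length (sum of arity + 1 over function nodes).
#'
#' @param tree an `fnt`.
#' @param v numeric vector of length `n_params(tree)`.
#' @return `flatten_params`: numeric vector; `set_params`: a new `fnt`.
#' @export
flatten_params <- function(tree) {
  stopifnot(inherits(tree, "fnt"))
  .collect_params(tree$root)
}

.install_params <- function(node, v, pos) {
  if (node$type == "leaf") return(list(node = node, pos = pos))
  m <- node$arity
  node$weights <- v[pos:(pos + m - 1L)]
  node$bias <- v[pos + m]
  pos <- pos + m + 1L
  for (j in seq_len(m)) {
    r <- .install_params(node$children[[j]], v, pos)
    node$children[[j]] <- r$node
    pos <- r$pos
  }
  list(node = node, pos = pos)
}

#' @rdname flatten_params
#' @export
set_params <- function(tree, v) {
  stopifnot(inherits(tree, "fnt"))
  need <- n_params(tree)
  if (length(v) != need)
    stop("parameter vector has length ", length(v), "; expected ", need)
  tree$root <- .install_params(tree$root, as.numeric(v), 1L)$node
  tree
}

#' @rdname flatten_params
#' @export
n_params <- function(tree) {
  stopifnot(inherits(tree, "fnt"))
  length(.collect_params(tree$root))
}

#' Root-mean-square-error fitness of a tree on coded targets
#'
#' `sqrt(mean((y - output)^2))`; 0 iff the tree reproduces every target
#' exactly. Smaller is better; all search operators minimize this.
#'
#' @param tree an `fnt`.
#' @param X samples-by-features numeric matrix.
#' @param y numeric target vector in \[0, 1\], one per row of `X`.
#' @return nonnegative scalar.
#' @export
fnt_fitness <- function(tree, X, y) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty dataset")
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  out <- predict(tree, X)
  sqrt(mean((y - out)^2))
}

.collect_features <- function(node) {
  if (node$type == "leaf") return(node$feature)
  unlist(lapply(node$children, .collect_features), use.names = FALSE)
}

#' Input features referenced by a tree's leaves
#'
#' @param tree an `fnt`.
#' @return sorted integer vector of distinct 1-based feature indices.
#' @export
used_features <- function(tree) {
  stopifnot(inherits(tree, "fnt"))
  sort(unique(.collect_features(tree$root)))
}

## ---- JSON persistence ------------------------------------------------------

.node_to_list <- function(node) {
  if (node$type == "leaf")
    list(type = "leaf", feature = node$feature)
  else
    list(type = "func", arity = node$arity, weights = node$weights,
         bias = node$bias, children = lapply(node$children, .node_to_list))
}

.node_from_list <- function(lst) {
  if (lst$type == "leaf") return(fnt_leaf(lst$feature))
  fnt_node(lapply(lst$children, .node_from_list),
           unlist(lst$weights), lst$bias)
}

#' Serialize / restore a flexible neural tree as JSON
#'
#' The schema is a nested document: leaves `{type, feature}`, function nodes
#' `{type, arity, weights, bias, children}`, wrapped with the function set and
#' input dimension. `fnt_from_json(fnt_to_json(tree))` reproduces the tree.
#'
#' @param tree an `fnt`.
#' @param json a JSON string produced by `fnt_to_json`.
#' @return `fnt_to_json`: a JSON string; `fnt_from_json`: an `fnt`.
#' @export
fnt_to_json <- function(tree) {
  stopifnot(inherits(tree, "fnt"))
  jsonlite::toJSON(list(function_set = tree$function_set,
                        input_dim = tree$input_dim,
                        root = .node_to_list(tree$root)),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname fnt_to_json
#' @export
fnt_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  fnt(.node_from_list(lst$root), unlist(lst$function_set), lst$input_dim)
}
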