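## M-ary class decomposition and bagged FNT Group Forests.

#' M-ary class codec
#'
#' Bijection between M class labels and binary codes of length
#' L = ceiling(log2(M)): class i (0-based, in the order of `classes`) maps to
#' the L-bit big-endian binary representation of i. For M not a power of two
#' the unused codes are excluded from decoding. The code order is the class
#' order, so models are portable as long as the class list is kept.
#'
#' @param classes character vector of M >= 2 distinct class labels.
#' @return object of class `class_codec` with fields `classes`, `L` and
#'   `codes` (M-by-L 0/1 matrix, rownames = classes).
#' @export
class_codec <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (anyDuplicated(classes)) stop("duplicate class labels")
  M <- length(classes)
  L <- max(1L, ceiling(log2(M)))
  codes <- matrix(vapply(seq_len(M) - 1L, function(i)
    as.integer(intToBits(i))[L:1], integer(L)), nrow = M, ncol = L,
    byrow = TRUE)
  dimnames(codes) <- list(classes, paste0("bit", seq_len(L)))
  structure(list(classes = classes, L = L, codes = codes),
            class = "class_codec")
}

#' @export
print.class_codec <- function(x, ...) {
  cat(sprintf("M-ary codec: %d classes, %d code bit(s)\n",
              length(x$classes), x$L))
  print(x$codes)
  invisible(x)
}

#' Encode labels as binary code targets
#'
#' @param labels vector of class labels (all must be in the codec's class
#'   list).
#' @param codec a [class_codec()].
#' @return numeric 0/1 matrix, one row per label, L columns (the per-bit
#'   regression targets).
#' @export
encode_label <- function(labels, codec) {
  stopifnot(inherits(codec, "class_codec"))
  labels <- as.character(labels)
  bad <- !labels %in% codec$classes
  if (any(bad))
    stop("unknown label(s): ", paste(unique(labels[bad]), collapse = ", "))
  out <- codec$codes[match(labels, codec$classes), , drop = FALSE]
  storage.mode(out) <- "double"
  rownames(out) <- NULL
  out
}

#' Decode score vectors to class labels
#'
#' Returns, per row, the class whose code minimizes the Euclidean distance to
#' the score vector, together with that distance. Only the M valid codes
#' compete (unused codes for non-power-of-two M are never returned); ties are
#' broken by the smallest class index.
#'
#' @param scores numeric vector of length L, or a matrix with L columns, all
#'   components in \[0, 1\].
#' @param codec a [class_codec()].
#' @return list with `labels` (factor over the codec classes) and `distance`
#'   (numeric vector).
#' @export
decode_output <- function(scores, codec) {
  stopifnot(inherits(codec, "class_codec"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  scores <- as.matrix(scores)
  if (ncol(scores) != codec$L)
    stop("scores have ", ncol(scores), " components; expected ", codec$L)
  if (any(scores < 0 | scores > 1))
    stop("score components must lie in [0, 1]")
  d2 <- vapply(seq_along(codec$classes), function(i)
    rowSums(sweep(scores, 2L, codec$codes[i, ], `-`)^2),
    numeric(nrow(scores)))
  d2 <- matrix(d2, nrow = nrow(scores))
  best <- apply(d2, 1L, which.min)  # first minimum = smallest class index
  list(labels = factor(codec$classes[best], levels = codec$classes),
       distance = sqrt(d2[cbind(seq_len(nrow(d2)), best)]))
}

#' Train an FNT Group Forest
#'
#' Bagging of FNT Groups: each of the K groups draws a bootstrap sample (n
#' draws with replacement, redrawn up to `max_retries` times if any class
#' present in `y` is missing from the draw) and trains L =
#' `codec$L` flexible neural trees via [train_fnt()], tree b targeting bit b
#' of the encoded labels. All groups share one function set.
#'
#' @param X samples-by-features numeric matrix (preprocessed).
#' @param y class labels aligned with the rows of `X`.
#' @param codec a [class_codec()]; defaults to the classes present in `y`.
#' @param K number of FNT Groups (default 5).
#' @param function_set arities for the shared grammar.
#' @param max_depth tree depth bound.
#' @param gggp,pso,outer_rounds training budgets passed to [train_fnt()].
#' @param seed optional integer seed.
#' @param max_retries bootstrap redraw limit before erroring.
#' @return object of class `fnt_forest`.
#' @export
train_forest <- function(X, y, codec = NULL, K = 5,
                         function_set = c(2, 3, 4), max_depth = 5,
                         gggp = gggp_control(), pso = pso_control(),
                         outer_rounds = 3, seed = NULL, max_retries = 100) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (is.null(codec)) codec <- class_codec(unique(y))
  present <- unique(y)
  grammar <- fnt_grammar(function_set, input_dim = ncol(X),
                         max_depth = max_depth)
  B <- encode_label(y, codec)
  n <- nrow(X)
  groups <- vector("list", K)
  for (g in seq_len(K)) {
    idx <- NULL
    for (try in seq_len(max_retries)) {
      cand <- sample.int(n, n, replace = TRUE)
      if (all(present %in% y[cand])) { idx <- cand; break }
    }
    if (is.null(idx))
      stop("bootstrap sample missing a class after ", max_retries,
           " redraws; too few samples per class")
    trees <- vector("list", codec$L)
    for (b in seq_len(codec$L)) {
      tf <- train_fnt(X[idx, , drop = FALSE], B[idx, b], grammar,
                      gggp = gggp, pso = pso, outer_rounds = outer_rounds)
      trees[[b]] <- tf$tree
    }
    groups[[g]] <- list(trees = trees, boot_idx = idx)
  }
  structure(list(groups = groups, K = as.integer(K), codec = codec,
                 function_set = grammar$function_set,
                 input_dim = ncol(X), grammar = grammar),
            class = "fnt_forest")
}

#' Predict code-probability vectors with an FNT Group Forest
#'
#' Each group emits `(tree_1(x), ..., tree_L(x))`; the forest output is the
#' componentwise mean over the K groups, so it is a convex combination of the
#' group outputs. Outputs are clamped to \[0, 1\] to guard against degenerate
#' single-leaf trees whose raw feature output can leave the sigmoid range.
#'
#' @param object an `fnt_forest`.
#' @param newdata matrix with `input_dim` columns.
#' @param ... unused.
#' @return numeric matrix, rows = samples, L columns, components in \[0, 1\].
#' @export
predict.fnt_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim)
    stop("newdata has ", ncol(newdata), " columns; expected ",
         object$input_dim)
  L <- object$codec$L
  acc <- matrix(0, nrow(newdata), L)
  for (grp in object$groups) {
    out <- vapply(grp$trees, function(tr) predict(tr, newdata),
                  numeric(nrow(newdata)))
    out <- matrix(out, nrow = nrow(newdata), ncol = L)
    acc <- acc + pmin(pmax(out, 0), 1)
  }
  acc / object$K
}

#' @export
print.fnt_forest <- function(x, ...) {
  cat(sprintf(
    "FNT Group Forest: %d groups x %d trees, function set {%s}, %d inputs\n",
    x$K, x$codec$L, paste(x$function_set, collapse = ","), x$input_dim))
  invisible(x)
}
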