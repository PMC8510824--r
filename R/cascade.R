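## The cascade: layers of three function-set-diverse forests, feature
## augmentation, confidence-gated early exit, automatic depth and weighted
## layer fusion.

#' Prediction confidence region
#'
#' The region is `[0, low] U [high, 1]` (closed intervals). A sample is
#' confident when *every* component of its fused code vector lies in the
#' region. Setting `low == high` makes every sample confident, i.e. disables
#' the gate.
#'
#' @param low,high region bounds with `0 <= low <= high <= 1`.
#' @return list of class `confidence_region`.
#' @export
confidence_region <- function(low = 0.2, high = 0.8) {
  if (!(low >= 0 && low <= high && high <= 1))
    stop("need 0 <= low <= high <= 1")
  structure(list(low = low, high = high), class = "confidence_region")
}

#' Split samples by prediction confidence
#'
#' Partitions rows of a fused output matrix into the confident set (every
#' component in the region — set Y, which exits the cascade) and the
#' uncertain set (set X, which continues to the next layer). Order is
#' preserved within each part; the parts are disjoint and exhaustive.
#'
#' @param scores matrix of code components in \[0, 1\] (L columns).
#' @param region a [confidence_region()].
#' @return list with integer index vectors `confident` and `uncertain`.
#' @export
confidence_split <- function(scores, region = confidence_region()) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  scores <- as.matrix(scores)
  if (any(scores < 0 | scores > 1))
    stop("score components must lie in [0, 1]")
  ok <- scores <= region$low | scores >= region$high
  conf <- rowSums(ok) == ncol(scores)
  list(confident = which(conf), uncertain = which(!conf))
}

#' Augment base features with a layer's forest outputs
#'
#' Columns are the original features followed by the three forests' code
#' outputs in fixed order; width = base + 3 * L. The first base-width columns
#' equal `x_base` exactly.
#'
#' @param x_base base feature matrix.
#' @param layer_outputs list of 3 matrices of equal width L >= 1 with the
#'   same row count as `x_base`.
#' @return the augmented matrix.
#' @export
augment_features <- function(x_base, layer_outputs) {
  x_base <- as.matrix(x_base)
  if (length(layer_outputs) != 3L) stop("expected outputs of 3 forests")
  L <- ncol(layer_outputs[[1L]])
  if (is.null(L) || L < 1L) stop("layer outputs must have width >= 1")
  for (o in layer_outputs) {
    if (nrow(o) != nrow(x_base)) stop("row counts do not agree")
    if (ncol(o) != L) stop("layer outputs must share one width")
  }
  out <- cbind(x_base, layer_outputs[[1L]], layer_outputs[[2L]],
               layer_outputs[[3L]])
  colnames(out) <- NULL
  out
}

#' Fuse the three forests of one layer
#'
#' Componentwise mean of the three forests' code outputs; the result is the
#' layer's contribution to the weighted final output and is bounded by the
#' componentwise min/max of the inputs.
#'
#' @param layer_outputs list of 3 equal-shape matrices.
#' @return matrix of the same shape.
#' @export
fuse_outputs <- function(layer_outputs) {
  if (length(layer_outputs) != 3L) stop("expected outputs of 3 forests")
  d <- dim(layer_outputs[[1L]])
  for (o in layer_outputs)
    if (!identical(dim(o), d)) stop("layer outputs must share one shape")
  (layer_outputs[[1L]] + layer_outputs[[2L]] + layer_outputs[[3L]]) / 3
}

#' Per-layer fusion weights
#'
#' Default (`"normalized"`): `w_i = i / (1 + 2 + ... + N)`, increasing in the
#' layer index and summing to 1, so deeper layers carry more weight and the
#' fused output is a proper weighted average. `"literal"` evaluates the
#' printed form `w_i = i / (1 + 2 + ... + i)` (equal to `2 / (i + 1)`),
#' which is decreasing and does not sum to 1.
#'
#' @param i layer index (vectorized), `1 <= i <= N`.
#' @param N total number of layers.
#' @param mode `"normalized"` (default) or `"literal"`.
#' @return numeric weights.
#' @export
layer_weight <- function(i, N, mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  i <- as.integer(i)
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  if (any(i < 1L | i > N)) stop("layer index out of range 1..", N)
  if (mode == "normalized") i / sum(seq_len(N))
  else vapply(i, function(j) j / sum(seq_len(j)), numeric(1))
}

#' Cascade training settings
#'
#' @param K FNT Groups per forest.
#' @param function_sets list of 3 distinct arities sets, one per forest in
#'   every layer; defaults to `{2,3,4}`, `{2,3,5}`, `{2,4,5}`.
#' @param max_depth tree depth bound.
#' @param gggp a [gggp_control()].
#' @param pso a [pso_control()].
#' @param outer_rounds structure/parameter alternations per tree.
#' @param confidence a [confidence_region()].
#' @param weights layer-weight mode, `"normalized"` or `"literal"`.
#' @param max_layers cap on cascade depth.
#' @param min_gain minimal absolute validation-accuracy improvement that
#'   counts as progress.
#' @param patience number of consecutive non-improving layers tolerated
#'   before growth stops.
#' @param validation_fraction fraction of the training set held out to
#'   validate each added layer.
#' @param train_on `"uncertain"` (default: layers after the first are trained
#'   only on still-uncertain training samples) or `"all"`.
#' @return list of class `cfnforest_control`.
#' @export
cfnforest_control <- function(K = 5,
                              function_sets = list(c(2, 3, 4), c(2, 3, 5),
                                                   c(2, 4, 5)),
                              max_depth = 5,
                              gggp = gggp_control(), pso = pso_control(),
                              outer_rounds = 3,
                              confidence = confidence_region(),
                              weights = c("normalized", "literal"),
                              max_layers = 5, min_gain = 0.005, patience = 1,
                              validation_fraction = 0.25,
                              train_on = c("uncertain", "all")) {
  weights <- match.arg(weights)
  train_on <- match.arg(train_on)
  if (length(function_sets) != 3L)
    stop("function_sets must list exactly 3 arities sets")
  keys <- vapply(function_sets, function(fs)
    paste(sort(unique(as.integer(fs))), collapse = ","), character(1))
  if (anyDuplicated(keys))
    stop("the 3 function sets must be pairwise distinct")
  stopifnot(K >= 1, max_layers >= 1, patience >= 1,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(K = as.integer(K), function_sets = function_sets,
                 max_depth = as.integer(max_depth), gggp = gggp, pso = pso,
                 outer_rounds = outer_rounds, confidence = confidence,
                 weights = weights, max_layers = as.integer(max_layers),
                 min_gain = min_gain, patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 train_on = train_on),
            class = "cfnforest_control")
}

## stratified holdout: per class, round(frac * n_c) rows (at least 1) go to
## validation; errors when a class cannot populate both parts
.stratified_holdout <- function(y, frac) {
  val <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_c <- length(idx)
    n_val <- max(1L, round(frac * n_c))
    if (n_val >= n_c)
      stop("class '", cl, "' has too few samples (", n_c,
           ") for a ", frac, " validation split; use a larger training set ",
           "or a smaller validation_fraction")
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

## outputs of one layer's three forests on a matrix
.layer_outputs <- function(layer, X) lapply(layer$forests, predict, X)

#' Fit a Cascade Flexible Neural Forest
#'
#' Grows a cascade of layers, each holding three FNT Group Forests with
#' different function sets. Layer 1 is trained on the full training split;
#' each later layer (by default) only on the samples still uncertain after
#' the previous layer, with the previous layer's 3 * L code outputs appended
#' to the original features. After each layer the whole cascade is scored on
#' a stratified validation holdout; growth stops when accuracy stops
#' improving by at least `min_gain` for `patience` consecutive layers, when
#' no uncertain samples remain, or at `max_layers`. The returned model is
#' trimmed to the depth with the best validation accuracy.
#'
#' @param x samples-by-genes numeric matrix or [expression_matrix()]
#'   (preprocessed: imputed and normalized).
#' @param y factor (or vector coercible to one) of class labels, one per row.
#' @param control a [cfnforest_control()].
#' @param seed optional integer seed; the whole fit is deterministic given
#'   the seed.
#' @return object of class `cfnforest`.
#' @seealso [predict.cfnforest()], [run_cv()]
#' @export
cfnforest <- function(x, y, control = cfnforest_control(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "expr_matrix")) x <- as.matrix(x)
  x <- as.matrix(x)
  if (anyNA(x)) stop("x has missing values; impute before fitting")
  y <- droplevels(as.factor(y))
  if (nrow(x) != length(y)) stop("rows of x must match length of y")
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  codec <- class_codec(levels(y))
  L <- codec$L
  region <- control$confidence

  val_idx <- .stratified_holdout(y, control$validation_fraction)
  tr_idx <- setdiff(seq_along(y), val_idx)
  X_tr <- x[tr_idx, , drop = FALSE]
  y_tr <- y[tr_idx]
  X_val <- x[val_idx, , drop = FALSE]
  y_val <- y[val_idx]

  layers <- list()
  val_acc <- numeric(0)
  n_uncertain <- integer(0)
  act <- seq_along(tr_idx)      # training rows still flowing
  X_act <- X_tr
  bad_streak <- 0L
  best_acc <- -Inf

  for (ell in seq_len(control$max_layers)) {
    forests <- lapply(control$function_sets, function(fs)
      train_forest(X_act, y_tr[act], codec = codec, K = control$K,
                   function_set = fs, max_depth = control$max_depth,
                   gggp = control$gggp, pso = control$pso,
                   outer_rounds = control$outer_rounds))
    layer <- list(forests = forests, input_width = ncol(X_act))
    layers[[ell]] <- layer

    # gate the training stream
    outs <- .layer_outputs(layer, X_act)
    fused <- fuse_outputs(outs)
    split <- confidence_split(fused, region)
    keep <- split$uncertain
    n_uncertain <- c(n_uncertain, length(keep))

    # validate the cascade at its current depth
    model_now <- .as_cfnforest(layers, codec, region, control, ncol(x))
    pred_val <- predict(model_now, X_val)
    acc <- mean(pred_val == y_val)
    val_acc <- c(val_acc, acc)

    if (acc - best_acc < control$min_gain && ell > 1L) {
      bad_streak <- bad_streak + 1L
      if (bad_streak >= control$patience) break
    } else {
      bad_streak <- 0L
    }
    if (acc > best_acc) best_acc <- acc

    if (length(keep) == 0L) break
    y_next <- if (control$train_on == "uncertain") y_tr[keep] else y_tr
    cls <- unique(as.character(y_next))
    if (length(cls) < 2L || length(keep) < 2L * length(cls)) break

    if (control$train_on == "uncertain") {
      act <- act[keep]
      X_act <- augment_features(X_tr[act, , drop = FALSE],
                                lapply(outs, function(o)
                                  o[keep, , drop = FALSE]))
    } else {
      act <- act
      X_act <- augment_features(X_tr[act, , drop = FALSE], outs)
    }
  }

  depth <- which.max(val_acc)  # first maximum
  model <- .as_cfnforest(layers[seq_len(depth)], codec, region, control,
                         ncol(x))
  model$validation <- data.frame(layer = seq_along(val_acc),
                                 accuracy = val_acc,
                                 n_uncertain_train = n_uncertain)
  model$levels <- levels(y)
  model
}

.as_cfnforest <- function(layers, codec, region, control, base_input_dim) {
  N <- length(layers)
  structure(list(layers = layers, codec = codec, region = region,
                 weights_mode = control$weights,
                 layer_weights = layer_weight(seq_len(N), N,
                                              control$weights),
                 base_input_dim = base_input_dim, n_layers = N,
                 control = control),
            class = "cfnforest")
}

#' Predict with a Cascade Flexible Neural Forest
#'
#' Samples flow through the layers with feature augmentation. At each layer
#' the three forests' outputs are fused (componentwise mean) into the layer
#' score `y_i`; a sample whose every component lies in the confidence region
#' exits with the weighted fusion `y_f = sum_{i<=j} w_i y_i / sum_{i<=j} w_i`
#' (weights renormalized over the layers it traversed); samples reaching the
#' last layer use all weights. Labels are the nearest valid class codes.
#'
#' @param object a fitted [cfnforest()].
#' @param newdata matrix with `base_input_dim` columns.
#' @param type `"class"` for labels (default) or `"score"` for the fused
#'   code matrix `y_f`.
#' @param ... unused.
#' @return a factor or a score matrix; both carry an `exit_layer` integer
#'   attribute giving the layer at which each sample left the cascade.
#' @export
predict.cfnforest <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  if (inherits(newdata, "expr_matrix")) newdata <- as.matrix(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$base_input_dim)
    stop("newdata has ", ncol(newdata), " columns; expected ",
         object$base_input_dim)
  n <- nrow(newdata)
  L <- object$codec$L
  N <- object$n_layers
  w <- object$layer_weights
  num <- matrix(0, n, L)
  den <- numeric(n)
  exit <- integer(n)
  act <- seq_len(n)
  X_cur <- newdata
  for (j in seq_len(N)) {
    outs <- .layer_outputs(object$layers[[j]], X_cur)
    yj <- fuse_outputs(outs)
    num[act, ] <- num[act, , drop = FALSE] + w[j] * yj
    den[act] <- den[act] + w[j]
    if (j < N) {
      split <- confidence_split(yj, object$region)
      exit[act[split$confident]] <- j
      keep <- split$uncertain
      act <- act[keep]
      if (length(act) == 0L) break
      X_cur <- augment_features(newdata[act, , drop = FALSE],
                                lapply(outs, function(o)
                                  o[keep, , drop = FALSE]))
    } else {
      exit[act] <- N
    }
  }
  yf <- num / den
  res <- if (type == "score") yf else decode_output(yf, object$codec)$labels
  attr(res, "exit_layer") <- exit
  res
}

#' @export
print.cfnforest <- function(x, ...) {
  cat(sprintf(
    "Cascade Flexible Neural Forest: %d layer(s), %d classes (%d code bits)\n",
    x$n_layers, length(x$codec$classes), x$codec$L))
  cat(sprintf("  layer weights (%s): %s\n", x$weights_mode,
              paste(signif(x$layer_weights, 4), collapse = ", ")))
  cat(sprintf("  confidence region: [0, %.3g] U [%.3g, 1]\n",
              x$region$low, x$region$high))
  if (!is.null(x$validation)) {
    cat("  validation accuracy by depth: ",
        paste(sprintf("%.3f", x$validation$accuracy), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.cfnforest <- function(object, ...) {
  print(object)
  for (j in seq_len(object$n_layers)) {
    lay <- object$layers[[j]]
    feats <- sort(unique(unlist(lapply(lay$forests, function(fo)
      unlist(lapply(fo$groups, function(g)
        lapply(g$trees, used_features)))))))
    cat(sprintf("  layer %d: input width %d, features used: %s\n",
                j, lay$input_width, paste(feats, collapse = ",")))
  }
  invisible(object)
}

#' Plot cascade validation accuracy by depth
#'
#' @param x a fitted `cfnforest` (must carry validation records).
#' @param ... passed to [graphics::plot()].
#' @export
plot.cfnforest <- function(x, ...) {
  if (is.null(x$validation)) stop("model has no validation record")
  graphics::plot(x$validation$layer, x$validation$accuracy, type = "b",
                 xlab = "cascade depth (layers)",
                 ylab = "validation accuracy", ...)
  graphics::abline(v = x$n_layers, lty = 2)
  invisible(x)
}
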