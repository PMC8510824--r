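## Stratified cross-validation and macro metrics.

#' Stratified k-fold plan
#'
#' Shuffles each class's indices and deals them round-robin across the k
#' folds, so the folds partition all samples and per-class counts across
#' folds differ by at most 1.
#'
#' @param y factor of class labels (every class needs >= k members).
#' @param k number of folds.
#' @param seed optional integer seed.
#' @return list of class `fold_plan` with `k` and `folds` (list of sorted
#'   index vectors).
#' @export
stratified_kfold <- function(y, k = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.factor(y)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  counts <- table(y)
  small <- names(counts)[counts < k]
  if (length(small) > 0L)
    stop("class(es) with fewer than k = ", k, " members: ",
         paste(small, collapse = ", "))
  folds <- vector("list", k)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    f <- rep_len(seq_len(k), length(idx))
    for (j in seq_len(k))
      folds[[j]] <- c(folds[[j]], idx[f == j])
  }
  structure(list(k = k, folds = lapply(folds, sort)), class = "fold_plan")
}

#' Multi-class classification metrics
#'
#' Per-class one-vs-rest precision, recall and F1 from the confusion matrix
#' (0/0 conventions: an undefined ratio is 0), their unweighted macro
#' averages, and overall accuracy.
#'
#' @param truth factor (or vector) of reference labels; its levels define the
#'   class list.
#' @param pred predicted labels (must lie in the class list).
#' @param levels optional explicit class list.
#' @return object of class `metrics_report` with `confusion`, `per_class`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `accuracy`, `n`.
#' @export
evaluate_predictions <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- if (is.factor(truth)) base::levels(truth)
    else unique(as.character(truth))
  truth <- factor(as.character(truth), levels = levels)
  pred_chr <- as.character(pred)
  if (any(!pred_chr %in% levels))
    stop("predicted label(s) outside the class list: ",
         paste(unique(pred_chr[!pred_chr %in% levels]), collapse = ", "))
  if (length(truth) != length(pred_chr))
    stop("truth and pred must have equal length")
  pred <- factor(pred_chr, levels = levels)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    confusion = cm,
    per_class = data.frame(class = levels, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1),
                           row.names = NULL, stringsAsFactors = FALSE),
    macro_precision = mean(prec), macro_recall = mean(rec),
    macro_f1 = mean(f1), accuracy = sum(tp) / sum(cm),
    n = sum(cm)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d | accuracy %.4f | macro P %.4f / R %.4f / F1 %.4f\n",
    x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Stratified cross-validation of the cascade on an expression matrix
#'
#' For each fold: the training split is filtered for excessive missingness,
#' KNN-imputed, and standardized; its normalization statistics (and the
#' imputed training matrix as neighbor pool) are reused on the test split so
#' no test information leaks into preprocessing or training. A cascade is
#' fitted per fold and scored on its test split. The aggregate reports the
#' mean and sample standard deviation (n - 1) of the per-fold macro metrics
#' and accuracy.
#'
#' @param x an [expression_matrix()] (may contain missing values) or a plain
#'   numeric matrix.
#' @param y factor of class labels aligned with the rows of `x`.
#' @param k number of folds (default 5).
#' @param control a [cfnforest_control()].
#' @param seed optional integer seed for the fold plan and all training
#'   randomness.
#' @param impute_k neighbors for KNN imputation.
#' @param missing_threshold missing-fraction cutoff for sample filtering.
#' @param repeats number of repeated cross-validation rounds (default 1).
#' @return list of class `cv_report`: `folds` (per-fold `metrics_report`s),
#'   `summary` (data frame of metric means and sds), `k`, `repeats`.
#' @export
run_cv <- function(x, y, k = 5, control = cfnforest_control(), seed = NULL,
                   impute_k = 5, missing_threshold = 0.2, repeats = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(x, "expr_matrix")) x <- expression_matrix(as.matrix(x))
  y <- droplevels(as.factor(y))
  if (nrow(x$values) != length(y)) stop("rows of x must match length of y")
  fold_reports <- list()
  for (r in seq_len(repeats)) {
    plan <- stratified_kfold(y, k)
    for (f in seq_len(k)) {
      te <- plan$folds[[f]]
      tr <- setdiff(seq_along(y), te)
      x_tr <- x[tr, ]
      y_tr <- y[tr]
      filt <- filter_missing_samples(x_tr, missing_threshold)
      kept <- !rownames(x_tr$values) %in% filt$removed
      y_tr <- y_tr[kept]
      x_tr <- if (anyNA(filt$x$values)) knn_impute(filt$x, impute_k)
        else filt$x
      x_te <- x[te, ]
      if (anyNA(x_te$values))
        x_te <- knn_impute(x_te, impute_k, reference = x_tr)
      norm <- zscore_normalize(x_tr)
      x_te <- apply_normalization(x_te, norm$stats)
      fit <- cfnforest(norm$x, y_tr, control = control)
      pred <- predict(fit, x_te)
      rep_f <- evaluate_predictions(y[te], pred, levels = levels(y))
      rep_f$train_ids <- rownames(x_tr$values)
      rep_f$stats <- norm$stats
      fold_reports[[length(fold_reports) + 1L]] <- rep_f
    }
  }
  take <- function(field) vapply(fold_reports, `[[`, numeric(1), field)
  metrics <- c("accuracy", "macro_precision", "macro_recall", "macro_f1")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(take(m)), numeric(1)),
    sd = vapply(metrics, function(m)
      if (length(fold_reports) > 1L) stats::sd(take(m)) else NA_real_,
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(folds = fold_reports, summary = summary, k = k,
                 repeats = repeats), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d repeat(s), %d fold fits)\n",
              x$k, x$repeats, length(x$folds)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
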