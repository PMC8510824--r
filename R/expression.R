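#' Expression matrix container
#'
#' A light wrapper around a samples-by-genes numeric matrix. Missing values are
#' stored as `NA` in `values`; the missing mask is derived with
#' [missing_mask()]. Sample and gene identifiers must be unique and live in the
#' matrix dimnames.
#'
#' @param values numeric matrix, rows = samples, columns = genes. Entries must
#'   be finite or `NA` (missing).
#' @param sample_ids,gene_ids character vectors of identifiers; default to the
#'   dimnames of `values`, or `S1..Sn` / `G1..Gp` when absent.
#' @return an object of class `expr_matrix`.
#' @examples
#' x <- expression_matrix(matrix(rnorm(6), 2, 3))
#' dim(x)
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values))
    stop("length of sample_ids (", length(sample_ids),
         ") does not match row count (", nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("length of gene_ids (", length(gene_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (any(is.nan(values)) || any(is.infinite(values)))
    stop("expression values must be finite or NA")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values), class = "expr_matrix")
}

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
`[.expr_matrix` <- function(x, i, j) {
  expression_matrix(x$values[i, j, drop = FALSE])
}

#' @export
print.expr_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf("expression matrix: %d samples x %d genes (%d missing values)\n",
              nrow(x$values), ncol(x$values), n_miss))
  invisible(x)
}

#' Missing-value mask of an expression matrix
#'
#' @param x an `expr_matrix`.
#' @return logical matrix, `TRUE` where the entry is missing.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  is.na(x$values)
}

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of gene identifiers and a first column of sample
#' identifiers. Empty cells and the token `NA` denote missing values. The
#' header may either carry a leading cell for the ID column or omit it
#' (classic R convention).
#'
#' @param path file path.
#' @param delimiter field separator, default `","`.
#' @param transpose set `TRUE` for genes-by-samples files; the returned object
#'   is always samples-by-genes.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = ",", transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  fields <- utils::count.fields(path, sep = delimiter, quote = "\"",
                                blank.lines.skip = FALSE)
  fields <- fields[!is.na(fields)]
  if (length(fields) < 2L) stop("file has no data rows: ", path)
  body <- fields[-1L]
  if (length(unique(body)) > 1L) {
    ref <- body[1L]
    bad <- which(body != ref)[1L] + 1L
    stop(sprintf("ragged input: line %d has %d fields but line 2 has %d",
                 bad, body[bad - 1L], ref))
  }
  if (!fields[1L] %in% c(body[1L], body[1L] - 1L))
    stop(sprintf("ragged input: header has %d fields but data rows have %d",
                 fields[1L], body[1L]))
  df <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE, row.names = 1L,
                      check.names = FALSE, na.strings = c("NA", ""),
                      quote = "\"", comment.char = "",
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("row.names", conditionMessage(e)))
        stop("duplicate sample IDs in first column of ", path, call. = FALSE)
      stop(e)
    })
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("non-numeric values in expression file ", path,
         " (only numbers, empty cells and 'NA' are allowed)")
  if (transpose) m <- t(m)
  expression_matrix(m)
}

#' Write an expression matrix to a delimited text file
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(x))` round-trips doubles bit-exactly;
#' missing entries are written as `NA`.
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delimiter = ",") {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  chr <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
  dim(chr) <- dim(v)
  header <- paste(c("sample_id", colnames(v)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], chr[i, ]), collapse = delimiter), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample label file
#'
#' Two-column delimited file: sample ID, class label.
#'
#' @param path file path.
#' @param delimiter field separator.
#' @param levels optional explicit class list; defaults to order of first
#'   appearance. The class order defines the M-ary code assignment downstream.
#' @return a named factor (names = sample IDs).
#' @export
read_labels <- function(path, delimiter = ",", levels = NULL) {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file must have two columns (sample_id, label)")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in label file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lab <- as.character(df[[2L]])
  if (is.null(levels)) levels <- unique(lab)
  if (!all(lab %in% levels))
    stop("labels outside the class list: ",
         paste(unique(lab[!lab %in% levels]), collapse = ", "))
  out <- factor(lab, levels = levels)
  names(out) <- ids
  out
}

#' Write labels to a two-column delimited file
#' @param y named factor of labels.
#' @param path output path.
#' @param delimiter field separator.
#' @export
write_labels <- function(y, path, delimiter = ",") {
  writeLines(c(paste("sample_id", "label", sep = delimiter),
               paste(names(y), as.character(y), sep = delimiter)), path)
  invisible(path)
}

#' Filter samples with excessive missingness
#'
#' Removes every sample whose fraction of missing gene values is strictly
#' greater than `threshold` (a sample missing exactly the threshold fraction is
#' retained). The gene set and the order of retained samples are unchanged.
#'
#' @param x an `expr_matrix`.
#' @param threshold maximum tolerated missing fraction, default 0.20.
#' @return list with `x` (filtered matrix) and `removed` (character vector of
#'   dropped sample IDs).
#' @export
filter_missing_samples <- function(x, threshold = 0.20) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  frac <- rowMeans(is.na(x$values))
  drop <- frac > threshold
  if (all(drop))
    stop("all samples exceed the missing-value threshold (", threshold,
         "); consider relaxing it")
  list(x = expression_matrix(x$values[!drop, , drop = FALSE]),
       removed = rownames(x$values)[drop])
}

## Euclidean distance between target row i and every reference row, over genes
## observed in both; Inf where no gene is shared.
.knn_distances <- function(vi, ref_values, ref_obs) {
  obs_i <- !is.na(vi)
  shared <- ref_obs & rep(obs_i, each = nrow(ref_values))
  diff <- sweep(ref_values, 2L, vi, `-`)
  diff[!shared] <- 0
  d2 <- rowSums(diff^2, na.rm = TRUE)
  d2[rowSums(shared) == 0L] <- Inf
  sqrt(d2)
}

#' K-nearest-neighbor imputation of missing expression values
#'
#' Each missing cell (sample i, gene g) is replaced by the mean of `k` nearest
#' samples that observe gene g, with distances computed as Euclidean distance
#' over the genes observed in both samples. Observed entries are never
#' altered. When fewer than `k` eligible neighbors exist, all of them are used.
#'
#' @param x an `expr_matrix` to impute.
#' @param k number of neighbors, default 5.
#' @param reference optional `expr_matrix` supplying the neighbor pool (same
#'   gene set); by default `x` itself (a sample is never its own neighbor).
#'   Passing a complete training matrix here lets test-fold samples be imputed
#'   without touching other test samples.
#' @return an `expr_matrix` with no missing values.
#' @export
knn_impute <- function(x, k = 5, reference = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  self <- is.null(reference)
  ref <- if (self) x else reference
  stopifnot(inherits(ref, "expr_matrix"))
  if (!identical(colnames(ref$values), colnames(x$values)))
    stop("reference gene set does not match")
  if (self && k >= nrow(x$values))
    stop("k must be smaller than the number of samples")
  v <- x$values
  if (!anyNA(v)) return(x)
  rv <- ref$values
  ref_obs <- !is.na(rv)
  never <- colSums(ref_obs) == 0L
  if (any(never))
    stop("cannot impute: gene(s) missing in every sample: ",
         paste(colnames(rv)[never], collapse = ", "))
  out <- v
  for (i in which(rowSums(is.na(v)) > 0L)) {
    d <- .knn_distances(v[i, ], rv, ref_obs)
    if (self) d[i] <- Inf
    for (g in which(is.na(v[i, ]))) {
      elig <- which(ref_obs[, g] & is.finite(d))
      if (length(elig) == 0L)
        stop("cannot impute gene ", colnames(v)[g], " for sample ",
             rownames(v)[i], ": no eligible neighbor")
      ord <- elig[order(d[elig], elig)]
      nb <- ord[seq_len(min(k, length(ord)))]
      out[i, g] <- mean(rv[nb, g])
    }
  }
  expression_matrix(out)
}

#' Per-gene standardization
#'
#' Transforms each gene column f to (f - mean(f)) / spread(f), where the spread
#' is by default the population standard deviation (z-score); `divisor = "var"`
#' divides by the population variance instead (the literal printed form of the
#' normalization). Constant columns (spread 0) map to all-zeros. The returned
#' statistics can be re-applied to held-out samples with
#' [apply_normalization()].
#'
#' @param x an `expr_matrix` without missing values (impute first).
#' @param divisor `"sd"` (default, z-score) or `"var"`.
#' @return list with `x` (normalized matrix) and `stats` (data frame:
#'   `gene_id`, `mean`, `spread`, plus the divisor as an attribute).
#' @export
zscore_normalize <- function(x, divisor = c("sd", "var")) {
  stopifnot(inherits(x, "expr_matrix"))
  divisor <- match.arg(divisor)
  v <- x$values
  if (anyNA(v))
    stop("missing values present; run knn_impute() before normalization")
  mu <- colMeans(v)
  varp <- colMeans(sweep(v, 2L, mu, `-`)^2)
  spread <- if (divisor == "sd") sqrt(varp) else varp
  stats <- data.frame(gene_id = colnames(v), mean = mu, spread = spread,
                      row.names = NULL, stringsAsFactors = FALSE)
  attr(stats, "divisor") <- divisor
  list(x = apply_normalization(x, stats), stats = stats)
}

#' Apply previously fitted normalization statistics
#'
#' @param x an `expr_matrix` without missing values; its gene set must match
#'   `stats$gene_id`.
#' @param stats data frame produced by [zscore_normalize()].
#' @return normalized `expr_matrix`.
#' @export
apply_normalization <- function(x, stats) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (anyNA(v)) stop("missing values present; impute first")
  if (!identical(colnames(v), as.character(stats$gene_id)))
    stop("gene set does not match the normalization statistics")
  centered <- sweep(v, 2L, stats$mean, `-`)
  s <- stats$spread
  scaled <- sweep(centered, 2L, ifelse(s > 0, s, 1), `/`)
  scaled[, s == 0] <- 0
  expression_matrix(scaled)
}
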