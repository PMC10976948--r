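# Calibration/validation partitioning: Kennard-Stone space-filling selection
# run independently inside each maturity class at a 3:1 train:test ratio.

#' Kennard-Stone sample selection
#'
#' Deterministic space-filling selection: the first two picks are the pair
#' at maximal Euclidean distance; every subsequent pick maximizes the
#' minimum distance to the already-selected set. Ties break to the lowest
#' sample index, making the selection fully reproducible.
#'
#' @param X numeric sample x feature matrix.
#' @param n_select number of samples to select, `2 <= n_select <= nrow(X)`.
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select < 2 || n_select > n)
    stop("n_select must be in [2, ", n, "]")
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- -Inf
  # first pair: maximal distance; which.max scans column-major so the first
  # hit is the lexicographically lowest (col, row) pair
  hit <- which.max(D2)
  i <- (hit - 1L) %% n + 1L
  j <- (hit - 1L) %/% n + 1L
  sel <- sort(c(i, j))
  mind <- pmin(D2[, sel[1]], D2[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_select) {
    nxt <- which.max(mind)          # first max = lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D2[, nxt])
    mind[nxt] <- -Inf
  }
  sel
}

#' Class-stratified Kennard-Stone train/test split
#'
#' Runs [kennard_stone()] independently within each class, selecting
#' `round-half-up(frac * n_class)` samples for training (`frac = ratio /
#' (ratio + 1)`); the remainder forms the test set. With the default 3:1
#' ratio and classes of 400/400/700, this yields 300/300/525 training
#' samples (1,125 train / 375 test).
#'
#' @param table a labelled [spectra_table()].
#' @param ratio train:test ratio (default 3, i.e. 3:1).
#' @return An object of class `split_result`: list with `train_ids`,
#'   `test_ids` (character sample ids, train in selection order), `ratio`
#'   and `per_class_counts` (class x c(train, test) matrix).
#' @export
stratified_split <- function(table, ratio = 3) {
  stopifnot(inherits(table, "spectra_table"))
  if (is.null(table$labels)) stop("stratified split needs a labelled table")
  frac <- ratio / (ratio + 1)
  classes <- sort(unique(table$labels))
  train_idx <- integer()
  counts <- matrix(0L, length(classes), 2,
                   dimnames = list(as.character(classes), c("train", "test")))
  for (k in seq_along(classes)) {
    rows <- which(table$labels == classes[k])
    if (length(rows) < 4)
      stop("class ", classes[k], " has fewer than 4 samples")
    n_train <- floor(frac * length(rows) + 0.5)   # round half up
    picked <- kennard_stone(table$reflectance[rows, , drop = FALSE], n_train)
    train_idx <- c(train_idx, rows[picked])
    counts[k, ] <- c(n_train, length(rows) - n_train)
  }
  test_idx <- setdiff(seq_len(nrow(table$reflectance)), train_idx)
  structure(list(train_ids = table$sample_ids[train_idx],
                 test_ids = table$sample_ids[test_idx],
                 ratio = ratio, per_class_counts = counts),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("split_result:", length(x$train_ids), "train /", length(x$test_ids),
      "test (", x$ratio, ": 1 )\n")
  print(x$per_class_counts)
  invisible(x)
}

#' Persist / restore a split as JSON
#'
#' @param split a `split_result`.
#' @param path file path.
#' @return `path` invisibly / a `split_result`.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  jsonlite::write_json(list(train_ids = split$train_ids,
                            test_ids = split$test_ids, ratio = split$ratio,
                            per_class_counts = as.data.frame(split$per_class_counts)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- as.matrix(x$per_class_counts)
  structure(list(train_ids = x$train_ids, test_ids = x$test_ids,
                 ratio = x$ratio, per_class_counts = counts),
            class = "split_result")
}
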