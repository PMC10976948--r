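# Model evaluation and pipeline orchestration: confusion matrices, overall
# accuracy (trace/total, equivalently the one-vs-rest collapsed binary
# accuracy per class), per-class precision/recall, and the
# chain x selector x model comparison grid with a shared train/test split
# and a leakage seam (selection and tuning only ever see training rows).

#' Confusion matrix
#'
#' `counts[i, j]` = number of samples with true class `i` predicted as `j`.
#'
#' @param y_true,y_pred equal-length label vectors, values within `classes`.
#' @param classes class label set (default: union observed).
#' @return A `confusion_matrix` (integer matrix, rows = true).
#' @export
confusion_matrix <- function(y_true, y_pred,
                             classes = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length")
  if (length(y_true) && !all(c(y_true, y_pred) %in% classes))
    stop("unknown label outside the class set")
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  if (length(y_true)) {
    tab <- table(factor(y_true, classes), factor(y_pred, classes))
    cm[] <- as.integer(tab)
  }
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Overall accuracy (percent)
#'
#' Multiclass overall accuracy: `trace / total * 100`. For any class's
#' one-vs-rest collapse of the same matrix this equals the binary accuracy
#' `(TP + TN) / (TP + FN + TN + FP)`.
#'
#' @param cm a [confusion_matrix()].
#' @return Accuracy in percent.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total * 100
}

#' Per-class precision and recall (percent)
#'
#' `precision_c = counts[c, c] / column-sum c`, `recall_c = counts[c, c] /
#' row-sum c`. A zero denominator leaves the metric `NA` (reported absent),
#' with the supporting counts alongside.
#'
#' @param cm a [confusion_matrix()].
#' @return A data.frame with columns `class`, `precision`, `recall`,
#'   `support` (true count) and `predicted_n`.
#' @export
precision_recall <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  d <- diag(cm)
  col_s <- colSums(cm)
  row_s <- rowSums(cm)
  data.frame(class = rownames(cm),
             precision = ifelse(col_s > 0, d / col_s * 100, NA_real_),
             recall = ifelse(row_s > 0, d / row_s * 100, NA_real_),
             support = as.integer(row_s),
             predicted_n = as.integer(col_s),
             row.names = NULL)
}

#' Evaluation report for one model on one data partition
#'
#' @param y_true,y_pred label vectors.
#' @param classes class label set.
#' @param provenance named list describing chain/selector/model/seeds.
#' @return An `eval_report`: confusion matrix plus accuracy, per-class
#'   precision/recall, and macro-averaged precision.
#' @export
eval_report <- function(y_true, y_pred, classes = sort(unique(y_true)),
                        provenance = list()) {
  cm <- confusion_matrix(y_true, y_pred, classes)
  pr <- precision_recall(cm)
  structure(list(confusion = cm, accuracy = accuracy(cm), per_class = pr,
                 macro_precision = mean(pr$precision, na.rm = TRUE),
                 provenance = provenance),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report: accuracy", sprintf("%.2f%%", x$accuracy), "\n")
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Configuration for the comparison grid
#'
#' @param data a labelled [spectra_table()] (untrimmed; the grid trims it).
#' @param chains pretreatment chain tokens (see [preprocess_chain()]).
#' @param selectors any of `"full"`, `"spa"`, `"cars"`, `"ivissa"`,
#'   `"cars-spa"`, `"ivissa-spa"`.
#' @param models any of `"elm"`, `"knn"`, `"rf"`, `"plsda"`, `"svm"`.
#' @param seed master seed: fixes the shared split, every selector and
#'   every tuner.
#' @param trim wavelength interval kept before any processing.
#' @param selector_args named list of per-selector argument overrides, e.g.
#'   `list(cars = list(n_mc = 100))`.
#' @param model_args named list of per-model [model_spec()] argument
#'   overrides, e.g. `list(svm = list(pso = list(n_iter = 10)))`.
#' @param stage_observer optional `function(stage, chain, selector, model,
#'   sample_ids)` called with the sample ids entering selection
#'   (`stage = "select"`) and tuning (`stage = "train"`); the grid's
#'   leakage seam.
#' @param output_dir optional directory; each finished cell is stored as
#'   JSON there and re-read instead of recomputed on a rerun.
#' @return A `grid_config`.
#' @export
grid_config <- function(data, chains = "raw", selectors = "full",
                        models = c("elm", "knn", "rf", "plsda", "svm"),
                        seed = 1, trim = c(420, 982), selector_args = list(),
                        model_args = list(), stage_observer = NULL,
                        output_dir = NULL) {
  stopifnot(inherits(data, "spectra_table"))
  if (is.null(data$labels)) stop("grid needs a labelled table")
  ok_sel <- c("full", "spa", "cars", "ivissa", "cars-spa", "ivissa-spa")
  if (!all(selectors %in% ok_sel))
    stop("unknown selector(s): ", paste(setdiff(selectors, ok_sel),
                                        collapse = ", "))
  structure(list(data = data, chains = chains, selectors = selectors,
                 models = models, seed = as.integer(seed), trim = trim,
                 selector_args = selector_args, model_args = model_args,
                 stage_observer = stage_observer, output_dir = output_dir),
            class = "grid_config")
}

run_selector <- function(name, Xtr, ytr, wl, seed, args, parents) {
  a <- function(def, key) utils::modifyList(def, if (is.null(args[[key]]))
    list() else args[[key]])
  switch(name,
    full = NULL,
    spa = do.call(select_spa, c(list(Xtr, ytr, wavelengths = wl, seed = seed),
                                a(list(), "spa"))),
    cars = do.call(select_cars, c(list(Xtr, ytr, wavelengths = wl,
                                       seed = seed), a(list(), "cars"))),
    ivissa = do.call(select_ivissa, c(list(Xtr, ytr, wavelengths = wl,
                                           seed = seed), a(list(), "ivissa"))),
    `cars-spa` = do.call(select_hybrid,
                         c(list(parents$cars, Xtr, ytr, wavelengths = wl,
                                seed = seed), a(list(), "cars-spa"))),
    `ivissa-spa` = do.call(select_hybrid,
                           c(list(parents$ivissa, Xtr, ytr, wavelengths = wl,
                                  seed = seed), a(list(), "ivissa-spa"))))
}

#' Run the pretreatment x selector x model comparison grid
#'
#' For every cell: trim, apply the pretreatment chain, reuse one shared
#' class-stratified Kennard-Stone 3:1 split (computed once on the trimmed
#' raw table), run the wavelength selector on training rows only, train the
#' model with its inner tuning on training rows only, and report training
#' and test accuracy plus per-class metrics. Test rows never reach
#' selection or tuning. A cell failure is recorded in the `error` column
#' and the grid continues.
#'
#' @param config a [grid_config()].
#' @return A `grid_result`: list with `table` (one row per cell: accuracies,
#'   feature counts, chosen hyperparameters), `reports` (per-cell
#'   [eval_report()]s for the test partition), `split` (the shared
#'   `split_result`) and `selections` (per chain/selector).
#' @export
run_grid <- function(config) {
  stopifnot(inherits(config, "grid_config"))
  trimmed <- trim_wavelengths(config$data, config$trim[1], config$trim[2])
  split <- stratified_split(trimmed)
  tr_rows <- match(split$train_ids, trimmed$sample_ids)
  te_rows <- match(split$test_ids, trimmed$sample_ids)
  observer <- config$stage_observer
  cells <- list(); reports <- list(); selections <- list()
  cache_path <- function(id) if (is.null(config$output_dir)) NULL else
    file.path(config$output_dir, paste0(gsub("[^a-z0-9]+", "_", id), ".json"))
  for (chain_tok in config$chains) {
    proc <- apply_chain(trimmed, chain_tok)
    Xtr <- proc$reflectance[tr_rows, , drop = FALSE]
    ytr <- proc$labels[tr_rows]
    Xte <- proc$reflectance[te_rows, , drop = FALSE]
    yte <- proc$labels[te_rows]
    parents <- list()
    for (sel_tok in config$selectors) {
      parent_key <- sub("-spa$", "", sel_tok)
      if (grepl("-spa$", sel_tok) && is.null(parents[[parent_key]])) {
        if (!is.null(observer))
          observer("select", chain_tok, parent_key, NA, split$train_ids)
        parents[[parent_key]] <- tryCatch(
          run_selector(parent_key, Xtr, ytr, proc$wavelengths, config$seed,
                       config$selector_args, NULL),
          error = function(e) e)
      }
      if (!is.null(observer))
        observer("select", chain_tok, sel_tok, NA, split$train_ids)
      sel <- if (sel_tok %in% names(parents)) parents[[sel_tok]] else tryCatch(
        run_selector(sel_tok, Xtr, ytr, proc$wavelengths, config$seed,
                     config$selector_args, parents),
        error = function(e) e)
      if (inherits(sel, "error")) {
        for (model_tok in config$models) {
          cells[[length(cells) + 1L]] <-
            data.frame(chain = chain_tok, selector = sel_tok,
                       model = model_tok, n_features = NA_integer_,
                       train_accuracy = NA_real_, test_accuracy = NA_real_,
                       chosen = NA_character_,
                       error = conditionMessage(sel))
        }
        next
      }
      if (sel_tok %in% c("cars", "ivissa")) parents[[sel_tok]] <- sel
      bands <- if (is.null(sel)) seq_len(ncol(Xtr)) else sel$selected
      selections[[paste(chain_tok, sel_tok, sep = "|")]] <- sel
      for (model_tok in config$models) {
        cell_id <- paste(chain_tok, sel_tok, model_tok, sep = "|")
        cp <- cache_path(cell_id)
        if (!is.null(cp) && file.exists(cp)) {
          row <- jsonlite::read_json(cp, simplifyVector = TRUE)
          if (is.null(row$error)) row$error <- NA_character_
          cells[[length(cells) + 1L]] <- as.data.frame(row)
          next
        }
        if (!is.null(observer))
          observer("train", chain_tok, sel_tok, model_tok, split$train_ids)
        res <- tryCatch({
          margs <- config$model_args[[model_tok]]
          spec <- do.call(model_spec,
                          c(list(algorithm = model_tok, seed = config$seed),
                            if (is.null(margs)) list() else margs))
          fit <- train_model(Xtr[, bands, drop = FALSE], ytr, spec)
          pred_tr <- predict(fit, Xtr[, bands, drop = FALSE])
          pred_te <- predict(fit, Xte[, bands, drop = FALSE])
          rep_te <- eval_report(yte, pred_te, classes = sort(unique(proc$labels)),
                                provenance = list(chain = chain_tok,
                                                  selector = sel_tok,
                                                  model = model_tok,
                                                  seed = config$seed))
          reports[[cell_id]] <- rep_te
          data.frame(chain = chain_tok, selector = sel_tok, model = model_tok,
                     n_features = length(bands),
                     train_accuracy = accuracy(confusion_matrix(ytr, pred_tr)),
                     test_accuracy = rep_te$accuracy,
                     chosen = paste(names(fit$chosen), unlist(fit$chosen),
                                    sep = "=", collapse = ","),
                     error = NA_character_)
        }, error = function(e)
          data.frame(chain = chain_tok, selector = sel_tok, model = model_tok,
                     n_features = length(bands), train_accuracy = NA_real_,
                     test_accuracy = NA_real_, chosen = NA_character_,
                     error = conditionMessage(e)))
        if (!is.null(cp) && is.na(res$error)) {
          dir.create(dirname(cp), showWarnings = FALSE, recursive = TRUE)
          jsonlite::write_json(as.list(res), cp, auto_unbox = TRUE,
                               digits = NA)
        }
        cells[[length(cells) + 1L]] <- res
      }
    }
  }
  structure(list(table = do.call(rbind, cells), reports = reports,
                 split = split, selections = selections,
                 seed = config$seed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("grid_result:", nrow(x$table), "cell(s)\n")
  print(x$table[, c("chain", "selector", "model", "n_features",
                    "train_accuracy", "test_accuracy")], digits = 4)
  invisible(x)
}

#' Write the grid table as CSV
#'
#' @param x a `grid_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(x, path) {
  stopifnot(inherits(x, "grid_result"))
  data.table::fwrite(x$table, path)
  invisible(path)
}
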