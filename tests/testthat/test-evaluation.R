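test_that("confusion matrix counts match hand tallies and validate labels", {
  cm <- confusion_matrix(c(1, 1, 2, 3), c(1, 2, 2, 3), classes = 1:3)
  expect_equal(cm["1", "2"], 1L, ignore_attr = TRUE)
  expect_equal(sum(diag(cm)), 3)
  expect_equal(sum(cm), 4)
  perfect <- confusion_matrix(rep(1:3, 4), rep(1:3, 4), classes = 1:3)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  empty <- confusion_matrix(integer(), integer(), classes = 1:3)
  expect_equal(sum(empty), 0)
  expect_error(confusion_matrix(c(1, 9), c(1, 1), classes = 1:3), "unknown")
  expect_error(confusion_matrix(1:3, 1:2), "length")
})

test_that("overall accuracy is trace/total and matches every one-vs-rest binary collapse", {
  cm <- confusion_matrix(c(1, 1, 2, 3), c(1, 2, 2, 3), classes = 1:3)
  expect_equal(accuracy(cm), 75)
  perfect <- confusion_matrix(rep(1:3, 4), rep(1:3, 4), classes = 1:3)
  expect_equal(accuracy(perfect), 100)
  expect_error(accuracy(confusion_matrix(integer(), integer(), classes = 1)),
               "empty")
  # brute-force collapse: per class c, binary accuracy of the 2x2 table
  # (c vs rest) computed by direct counting over the raw label vectors
  set.seed(71)
  y_true <- sample(1:3, 200, replace = TRUE)
  y_pred <- ifelse(stats::runif(200) < 0.7, y_true, sample(1:3, 200, TRUE))
  cm3 <- confusion_matrix(y_true, y_pred, classes = 1:3)
  for (cl in 1:3) {
    tp <- sum(y_true == cl & y_pred == cl)
    tn <- sum(y_true != cl & y_pred != cl)
    binary <- (tp + tn) / 200 * 100
    collapsed <- confusion_matrix(as.integer(y_true == cl),
                                  as.integer(y_pred == cl), classes = 0:1)
    expect_equal(accuracy(collapsed), binary)
  }
})

test_that("precision and recall handle perfect, hand-counted and degenerate cases", {
  perfect <- confusion_matrix(rep(1:3, 5), rep(1:3, 5), classes = 1:3)
  pr <- precision_recall(perfect)
  expect_equal(pr$precision, rep(100, 3))
  expect_equal(pr$recall, rep(100, 3))
  cm <- structure(matrix(c(8L, 1L, 2L, 9L), 2,
                         dimnames = list(true = 1:2, predicted = 1:2)),
                  class = c("confusion_matrix", "matrix", "array"))
  pr2 <- precision_recall(cm)
  expect_equal(pr2$precision[1], 8 / 9 * 100)
  expect_equal(pr2$recall[1], 8 / 10 * 100)
  never <- confusion_matrix(c(1, 1, 2), c(2, 2, 2), classes = 1:2)
  pr3 <- precision_recall(never)
  expect_true(is.na(pr3$precision[1]))   # class 1 never predicted
  expect_equal(pr3$recall[1], 0)
})

small_grid_config <- function(seed = 1, observer = NULL,
                              selectors = c("full", "spa"),
                              models = c("plsda", "knn")) {
  gs <- generate_spectra(small_spec(n_bands = 40,
                                    class_sizes = c(20, 20, 28), seed = 77))
  grid_config(gs$table, chains = c("raw", "d1st"), selectors = selectors,
              models = models, seed = seed,
              selector_args = list(spa = list(n_min = 2, n_max = 8),
                                   cars = list(n_mc = 30, n_runs = 1),
                                   `cars-spa` = list(n_min = 2)),
              model_args = list(knn = list(grid = list(k = 5:7)),
                                plsda = list(grid = list(ncomp = 1:4))),
              stage_observer = observer)
}

test_that("the grid populates every cell, reports full-band counts for 'full', and is deterministic", {
  res <- run_grid(small_grid_config())
  expect_equal(nrow(res$table), 2 * 2 * 2)
  expect_true(all(is.na(res$table$error)))
  n_bands_trimmed <- sum({
    wl <- seq(400, 1000, length.out = 40); wl >= 420 & wl <= 982
  })
  full_rows <- res$table$selector == "full"
  expect_true(all(res$table$n_features[full_rows] == n_bands_trimmed))
  expect_true(all(res$table$n_features[!full_rows] <= 8))
  expect_true(all(res$table$train_accuracy >= 0 &
                    res$table$train_accuracy <= 100))
  res2 <- run_grid(small_grid_config())
  expect_identical(res$table, res2$table)
  # per-cell test reports carry consistent confusion totals
  for (rep in res$reports) expect_equal(sum(rep$confusion), 17)
})

test_that("selection and tuning never see test rows in any grid cell", {
  seen <- list()
  observer <- function(stage, chain, selector, model, sample_ids) {
    seen[[length(seen) + 1]] <<- list(stage = stage, ids = sample_ids)
  }
  cfg <- small_grid_config(observer = observer,
                           selectors = c("full", "cars", "cars-spa"),
                           models = "plsda")
  res <- run_grid(cfg)
  expect_true(all(is.na(res$table$error)))
  expect_gt(length(seen), 0)
  test_ids <- res$split$test_ids
  train_ids <- res$split$train_ids
  for (ev in seen) {
    expect_length(intersect(ev$ids, test_ids), 0)
    expect_true(all(ev$ids %in% train_ids))
  }
  expect_true(any(vapply(seen, function(e) e$stage == "select", logical(1))))
  expect_true(any(vapply(seen, function(e) e$stage == "train", logical(1))))
})

test_that("a failing cell is recorded and the grid continues", {
  gs <- generate_spectra(small_spec(n_bands = 40,
                                    class_sizes = c(20, 20, 28), seed = 77))
  cfg <- grid_config(gs$table, chains = "raw", selectors = c("spa", "full"),
                     models = "plsda",
                     selector_args = list(spa = list(n_max = 999)),
                     model_args = list(plsda = list(grid = list(ncomp = 1:3))))
  res <- run_grid(cfg)
  spa_rows <- res$table$selector == "spa"
  expect_true(all(!is.na(res$table$error[spa_rows])))
  expect_true(all(is.na(res$table$error[!spa_rows])))
  expect_true(all(is.finite(res$table$test_accuracy[!spa_rows])))
})

test_that("finished cells are reused from the output directory", {
  dir <- tempfile(); dir.create(dir)
  cfg <- small_grid_config()
  cfg$output_dir <- dir
  res1 <- run_grid(cfg)
  files <- list.files(dir)
  expect_equal(length(files), nrow(res1$table))
  res2 <- run_grid(cfg)   # all cells read back from cache
  expect_equal(res2$table$test_accuracy, res1$table$test_accuracy)
})

test_that("grid results export to CSV", {
  res <- run_grid(small_grid_config())
  f <- tempfile(fileext = ".csv")
  write_grid_csv(res, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(res$table))
  expect_equal(back$test_accuracy, res$table$test_accuracy)
})
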