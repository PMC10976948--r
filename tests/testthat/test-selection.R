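# Small labelled dataset with planted informative bands, trimmed to the
# 420-982 nm body as every selector run in the pipeline is.
selector_fixture <- function(seed = 11, n_bands = 40, sizes = c(30, 30, 40)) {
  gs <- generate_spectra(synthetic_spec(
    n_bands = n_bands, class_sizes = sizes, seed = seed,
    informative_bands = c(18, 24, 30, 36)))
  tab <- trim_wavelengths(gs$table)
  planted <- match(gs$table$wavelengths[gs$truth$informative_bands],
                   tab$wavelengths)
  list(X = tab$reflectance, y = tab$labels, planted = planted)
}

test_that("SPA projection chains equal the Gram-Schmidt oracle from every start", {
  set.seed(51)
  X <- matrix(rnorm(20 * 5), 20, 5)
  chains <- hyperseed:::spa_chains_cpp(X, 5L, 1e-12)
  for (s in 1:5) {
    expect_equal(chains[[s]] + 1L, spa_oracle_chain(X, s, 5),
                 info = paste("start", s))
  }
})

test_that("SPA never selects both of two identical columns", {
  set.seed(52)
  X <- matrix(rnorm(30 * 6), 30, 6)
  X[, 4] <- X[, 2]                      # duplicate column
  chains <- hyperseed:::spa_chains_cpp(X, 6L, 1e-12)
  for (s in 1:6)
    expect_false(all(c(1L, 3L) %in% chains[[s]]))  # 0-based ids of 2 and 4
})

test_that("SPA returns a minimal-RMSE subset with its diagnostics curve", {
  fx <- selector_fixture()
  res <- select_spa(fx$X, fx$y, n_min = 2, n_max = 12, seed = 3)
  expect_s3_class(res, "selection_result")
  expect_false(anyDuplicated(res$selected) > 0)
  expect_true(all(res$selected %in% seq_len(ncol(fx$X))))
  expect_equal(res$rmse, min(res$rmse_curve$rmse))
  expect_gte(length(res$selected), 2)
  expect_lte(length(res$selected), 12)
  # with a small n_min SPA prunes collinear features by design, so ask only
  # that the choice lands on planted-feature support (centre or shoulder)
  support <- unique(c(fx$planted - 1, fx$planted, fx$planted + 1))
  expect_gte(sum(res$selected %in% support), 2)
  res2 <- select_spa(fx$X, fx$y, n_min = 2, n_max = 12, seed = 3)
  expect_identical(res$selected, res2$selected)
  expect_error(select_spa(fx$X, fx$y, n_max = 1000), "exceeds")
})

test_that("the CARS shrinkage schedule satisfies its endpoint constraints exactly", {
  for (p in c(30, 293)) for (N in c(50, 1000)) {
    edf <- hyperseed:::cars_edf(p, N)
    expect_equal(edf$ratio(1), 1, tolerance = 1e-12)
    expect_equal(edf$ratio(N), 2 / p, tolerance = 1e-9)
    expect_true(all(diff(edf$ratio(1:N)) < 0))
  }
})

test_that("CARS retained counts run from p down to 2, non-increasing", {
  fx <- selector_fixture()
  res <- select_cars(fx$X, fx$y, n_mc = 60, n_runs = 2, seed = 5)
  counts <- res$retained_trace
  expect_equal(counts[1], ncol(fx$X))
  expect_equal(counts[length(counts)], 2)
  expect_true(all(diff(counts) <= 0))
  expect_false(res$stopped_early)
})

test_that("the CARS winner beats the full-band model on the same folds", {
  fx <- selector_fixture()
  res <- select_cars(fx$X, fx$y, n_mc = 60, n_runs = 2, seed = 5)
  foldid <- make_folds(nrow(fx$X), 5, seed = 5)
  rmsecv <- function(cols) min(pls_cv_rmse(fx$X[, cols, drop = FALSE], fx$y,
                                           ncomp = min(10, length(cols)),
                                           foldid = foldid))
  expect_equal(min(res$rmsecv_trace), rmsecv(res$selected), tolerance = 1e-10)
  expect_lte(rmsecv(res$selected), rmsecv(seq_len(ncol(fx$X))))
  expect_gte(sum(fx$planted %in% res$selected), 3)
  res2 <- select_cars(fx$X, fx$y, n_mc = 60, n_runs = 2, seed = 5)
  expect_identical(res$selected, res2$selected)
})

test_that("IVISSA weights stay in [0, 1] on the elite-frequency lattice and the result is seeded-deterministic", {
  fx <- selector_fixture()
  res <- suppressWarnings(select_ivissa(fx$X, fx$y, n_submodels = 100,
                                        max_rounds = 10, seed = 6))
  expect_true(all(res$weights_trace >= 0 & res$weights_trace <= 1))
  n_elite <- ceiling(0.1 * 100)
  lattice <- res$weights_trace * n_elite
  expect_equal(lattice, round(lattice), tolerance = 1e-9)
  res2 <- suppressWarnings(select_ivissa(fx$X, fx$y, n_submodels = 100,
                                         max_rounds = 10, seed = 6))
  expect_identical(res$selected, res2$selected)
  expect_gte(sum(fx$planted %in% res$selected), 3)
})

test_that("IVISSA recovers a single signal interval with little excess", {
  set.seed(53)
  n <- 80; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(1, 2, 3, 2, 1)
  y <- drop(X[, 13:17] %*% beta)        # noiseless single-interval signal
  r1 <- suppressWarnings(select_ivissa(X, y, n_submodels = 150,
                                       max_rounds = 25, seed = 1))
  expect_true(all(13:17 %in% r1$selected))
  expect_lte(length(setdiff(r1$selected, 13:17)), 6)
  r2 <- suppressWarnings(select_ivissa(X, y, n_submodels = 150,
                                       max_rounds = 25, seed = 99))
  expect_true(all(13:17 %in% r2$selected))
})

test_that("hybrid refinement is a coordinate-correct subset of its parent", {
  fx <- selector_fixture()
  parent <- select_cars(fx$X, fx$y, n_mc = 60, n_runs = 2, seed = 5)
  hy <- select_hybrid(parent, fx$X, fx$y, n_min = 2, seed = 3)
  expect_true(all(hy$selected %in% parent$selected))
  expect_lte(length(hy$selected), length(parent$selected))
  expect_equal(hy$method, "cars-spa")
  # parent = all bands reduces the hybrid to plain SPA
  all_parent <- hyperseed:::new_selection_result(
    "cars", seq_len(ncol(fx$X)), seq_len(ncol(fx$X)), params = list(),
    seed = 1)
  hy_all <- select_hybrid(all_parent, fx$X, fx$y, n_min = 2, n_max = 12,
                          seed = 3)
  plain <- select_spa(fx$X, fx$y, n_min = 2, n_max = 12, seed = 3)
  expect_identical(sort(hy_all$selected), sort(plain$selected))
  narrow <- hyperseed:::new_selection_result("cars", 5L, seq_len(ncol(fx$X)),
                                             params = list(), seed = 1)
  expect_error(select_hybrid(narrow, fx$X, fx$y), "fewer than 2")
})

test_that("selection results round-trip through JSON", {
  fx <- selector_fixture()
  res <- select_spa(fx$X, fx$y, n_min = 2, n_max = 10, seed = 3)
  f <- tempfile(fileext = ".json")
  write_selection(res, f)
  back <- read_selection(f)
  expect_equal(back$selected, res$selected)
  expect_equal(back$method, res$method)
  expect_equal(back$wavelengths, res$wavelengths)
})
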