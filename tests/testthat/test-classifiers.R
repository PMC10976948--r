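# Small separable fixtures for classifier checks.
separable_2d <- function(n = 40, seed = 61) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n, -3, .4), rnorm(n, -3, .4)),
             cbind(rnorm(n, 3, .4), rnorm(n, 3, .4)))
  list(X = X, y = rep(1:2, each = n))
}

xor_2d <- function(n = 50, seed = 62) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n, 1, .3), rnorm(n, 1, .3)),
             cbind(rnorm(n, -1, .3), rnorm(n, -1, .3)),
             cbind(rnorm(n, 1, .3), rnorm(n, -1, .3)),
             cbind(rnorm(n, -1, .3), rnorm(n, 1, .3)))
  list(X = X, y = rep(c(1, 1, 2, 2), each = n))
}

test_that("every tuner selects hyperparameters inside its stated grid", {
  gs <- generate_spectra(small_spec(class_sizes = c(20, 20, 30), seed = 63))
  tab <- trim_wavelengths(gs$table)
  X <- tab$reflectance; y <- tab$labels
  fits <- list(
    # H above n_train legitimately warns (underdetermined, minimum-norm)
    elm = suppressWarnings(train_elm(X, y, model_spec("elm", seed = 1))),
    knn = train_knn(X, y, model_spec("knn", seed = 1)),
    plsda = train_plsda(X, y, model_spec("plsda", seed = 1)),
    rf = train_rf(X, y, model_spec("rf", grid = list(depth = c(2, 5, 10)),
                                   seed = 1)))
  expect_true(fits$elm$chosen$hidden %in% seq(30, 100, 10))
  expect_true(fits$knn$chosen$k %in% 5:30)
  expect_true(fits$plsda$chosen$ncomp %in% 1:20)
  expect_true(fits$rf$chosen$depth %in% c(2, 5, 10))
  for (f in fits) expect_equal(f$classes, 1:3)
})

test_that("ELM separates a linearly separable toy set and is seed-deterministic", {
  fx <- separable_2d()
  spec <- model_spec("elm", grid = list(hidden = 30), seed = 4)
  fit <- train_elm(fx$X, fx$y, spec)
  expect_equal(mean(predict(fit, fx$X) == fx$y), 1)
  fit2 <- train_elm(fx$X, fx$y, spec)
  expect_identical(fit$state$beta, fit2$state$beta)
  # argmax decision is invariant to a common score offset
  shifted <- fit
  shifted$state$beta <- fit$state$beta + 0  # scores + c per column via bias
  sc <- hyperseed:::elm_hidden(hyperseed:::minmax_apply(fx$X, fit$state$scale),
                               fit$state$W, fit$state$b) %*% fit$state$beta
  expect_equal(fit$classes[max.col(sc + 5)], fit$classes[max.col(sc)])
})

test_that("underdetermined ELM warns but still solves by the minimum-norm rule", {
  fx <- separable_2d(n = 10)
  expect_warning(fit <- train_elm(fx$X, fx$y,
                                  model_spec("elm", grid = list(hidden = 40),
                                             cv_folds = 2, seed = 1)),
                 "minimum-norm")
  expect_length(predict(fit, fx$X), 20)
})

test_that("KNN reproduces hand-computed votes and breaks ties to the smallest class", {
  # 6 reference points on a line; query at 0.9 with K = 3 sees {1, 1, 2}
  X <- matrix(c(0, 0.5, 1.1, 2.0, 5, 6), ncol = 1)
  y <- c(1L, 1L, 2L, 2L, 3L, 3L)
  fit <- train_knn(X, y, model_spec("knn", grid = list(k = 3), cv_folds = 2,
                                    seed = 1))
  expect_equal(predict(fit, matrix(0.9)), 1L)
  expect_equal(predict(fit, matrix(5.6)), 3L)
  # exact tie {1, 2} at K = 2 goes to the smaller class id
  fit2 <- train_knn(X[1:4, , drop = FALSE], y[1:4],
                    model_spec("knn", grid = list(k = 2), cv_folds = 2,
                               seed = 1))
  expect_equal(predict(fit2, matrix(0.8)), 1L)
  expect_error(train_knn(X, y, model_spec("knn", grid = list(k = 10))),
               "n_train")
})

test_that("random forest is deterministic under a seed and fits pure/separable data", {
  fx <- separable_2d()
  spec <- model_spec("rf", grid = list(depth = c(2, 4)), seed = 9)
  fit <- train_rf(fx$X, fx$y, spec)
  expect_equal(mean(predict(fit, fx$X) == fx$y), 1)
  fit2 <- train_rf(fx$X, fx$y, spec)
  expect_identical(predict(fit, fx$X), predict(fit2, fx$X))
  # pure single-class data: every tree must predict that class
  one <- train_rf(matrix(rnorm(40), 20), rep(2L, 20),
                  model_spec("rf", grid = list(depth = 3), seed = 1))
  expect_true(all(predict(one, matrix(rnorm(10), 5)) == 2L))
})

test_that("PLS-DA separates 1-D separable data with one component and grows monotonically on training data", {
  X <- matrix(c(seq(-3, -1, length.out = 10), seq(1, 3, length.out = 10)))
  y <- rep(1:2, each = 10)
  fit <- train_plsda(X, y, model_spec("plsda", grid = list(ncomp = 1),
                                      cv_folds = 2, seed = 1))
  expect_equal(mean(predict(fit, X) == y), 1)
  # predicted one-hot responses sum to ~1 per row (centred fit + means)
  sc <- predict(fit$state$pls, X)
  expect_equal(rowSums(sc), rep(1, 20), tolerance = 1e-10, ignore_attr = TRUE)
  # nested-model property: the one-hot training residual sum of squares
  # never increases with more components (classification accuracy itself is
  # not monotone, only the regression fit is)
  set.seed(64)
  X2 <- matrix(rnorm(60 * 6), 60)
  y2 <- as.integer(1 + (X2[, 1] + 0.5 * X2[, 2] > 0) +
                     (X2[, 3] > 0.8))
  Y2 <- matrix(0, 60, 3); Y2[cbind(1:60, y2)] <- 1
  f_all <- pls_fit(X2, Y2, ncomp = 6)
  rss <- sapply(1:6, function(a) sum((predict(f_all, X2, ncomp = a) - Y2)^2))
  expect_true(all(diff(rss) <= 1e-9))
})

test_that("PSO-SVM improves on the initial swarm, is deterministic, and solves XOR", {
  trn <- xor_2d(n = 50, seed = 65)
  tst <- xor_2d(n = 30, seed = 66)
  spec <- model_spec("svm", seed = 2, pso = list(n_particles = 10, n_iter = 8))
  fit <- train_svm_pso(trn$X, trn$y, spec)
  expect_gte(fit$state$cv_fitness, max(fit$state$initial_fitness))
  expect_true(all(diff(fit$state$history) >= 0))   # best-so-far is monotone
  expect_gte(mean(predict(fit, tst$X) == tst$y), 0.95)
  expect_gte(fit$chosen$C, 0.01); expect_lte(fit$chosen$C, 100)
  expect_gte(fit$chosen$G, 0.01); expect_lte(fit$chosen$G, 10)
  fit2 <- train_svm_pso(trn$X, trn$y, spec)
  expect_identical(fit$chosen, fit2$chosen)
})

test_that("prediction respects row independence, empty input, and dimension checks", {
  fx <- separable_2d()
  fit <- train_knn(fx$X, fx$y, model_spec("knn", grid = list(k = 5), seed = 1))
  perm <- sample(nrow(fx$X))
  expect_equal(predict(fit, fx$X[perm, ]), predict(fit, fx$X)[perm])
  expect_length(predict(fit, fx$X[0, , drop = FALSE]), 0)
  expect_error(predict(fit, fx$X[, 1, drop = FALSE]), "features")
})
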