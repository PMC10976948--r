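# The five maturity classifiers with their stated hyperparameter grids:
# extreme learning machine (sigmoid hidden layer, H = 30..100 step 10),
# k-nearest neighbours (K = 5..30), random forest (500 trees, depth 1..20),
# PLS-DA (latent variables 1..20) and an RBF SVM tuned by particle swarm
# optimization over (C, G) with 5-fold cross-validated accuracy as fitness.
# All tuners use stratified 5-fold CV on the training set and explicit seeds.

#' Classifier specification
#'
#' @param algorithm one of `"elm"`, `"knn"`, `"rf"`, `"plsda"`, `"svm"`.
#' @param grid hyperparameter grid; defaults to the study grid of the
#'   algorithm (ELM: hidden neurons `seq(30, 100, 10)`; KNN: `5:30`;
#'   RF: depth `1:20` at 500 trees; PLS-DA: components `1:20`;
#'   SVM: PSO bounds `C` in (0.01, 100], `G` in (0.01, 10]).
#' @param cv_folds inner cross-validation folds.
#' @param pso PSO settings for the SVM tuner: `n_particles`, `n_iter`,
#'   `inertia` (start/end), `cognitive`, `social`.
#' @param seed RNG seed for all stochastic parts of training/tuning.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("elm", "knn", "rf", "plsda", "svm"),
                       grid = NULL, cv_folds = 5,
                       pso = list(n_particles = 20, n_iter = 50,
                                  inertia = c(0.9, 0.4), cognitive = 2,
                                  social = 2),
                       seed = 1) {
  algorithm <- match.arg(algorithm)
  default_grid <- switch(algorithm,
    elm = list(hidden = seq(30, 100, by = 10)),
    knn = list(k = 5:30),
    rf = list(depth = 1:20, trees = 500),
    plsda = list(ncomp = 1:20),
    svm = list(C = c(0.01, 100), G = c(0.01, 10)))
  if (is.null(grid)) grid <- default_grid
  grid <- utils::modifyList(default_grid, grid)
  pso_default <- list(n_particles = 20, n_iter = 50, inertia = c(0.9, 0.4),
                      cognitive = 2, social = 2)
  pso <- utils::modifyList(pso_default, pso)
  structure(list(algorithm = algorithm, grid = grid, cv_folds = cv_folds,
                 pso = pso, seed = as.integer(seed)),
            class = "model_spec")
}

new_trained_model <- function(spec, chosen, state, classes, cv_accuracy = NULL) {
  structure(list(spec = spec, algorithm = spec$algorithm, chosen = chosen,
                 state = state, classes = classes, cv_accuracy = cv_accuracy),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model [", x$algorithm, "]: ",
      paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", "),
      "; classes ", paste(x$classes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

one_hot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

# min-max scale columns to [-1, 1] using training statistics
minmax_fit <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- hi - lo; rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}
minmax_apply <- function(X, sc) {
  2 * sweep(sweep(X, 2, sc$lo), 2, sc$rng, `/`) - 1
}

# Moore-Penrose pseudoinverse via SVD (minimum-norm least squares)
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

elm_hidden <- function(X, W, b) {
  Z <- X %*% W
  Z <- sweep(Z, 2, b, `+`)
  1 / (1 + exp(-Z))
}

elm_train_once <- function(X, Y, H, seed) {
  d <- ncol(X)
  Wb <- with_seed(seed, list(W = matrix(stats::runif(d * H, -1, 1), d, H),
                             b = stats::runif(H, -1, 1)))
  Hm <- elm_hidden(X, Wb$W, Wb$b)
  beta <- pinv(Hm) %*% Y
  list(W = Wb$W, b = Wb$b, beta = beta)
}

#' Train an extreme learning machine
#'
#' Random input weights and biases (uniform on \[-1, 1\], seeded), sigmoid
#' hidden layer, and minimum-norm least-squares output weights onto one-hot
#' targets. Inputs are min-max normalised to \[-1, 1\] with training
#' statistics (part of the ELM definition here: it keeps the sigmoid out of
#' saturation for percent-reflectance inputs). The hidden-layer size is
#' chosen by inner CV accuracy over the grid.
#'
#' @param X training sample x feature matrix.
#' @param y integer class labels.
#' @param spec a [model_spec()] with `algorithm = "elm"`.
#' @return A `trained_model`.
#' @export
train_elm <- function(X, y, spec = model_spec("elm")) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  sc <- minmax_fit(X)
  Xs <- minmax_apply(X, sc)
  Y <- one_hot(y, classes)
  grid <- spec$grid$hidden
  if (any(grid > nrow(X)))
    warning("hidden-layer sizes exceeding n_train are underdetermined; ",
            "solved by the minimum-norm rule")
  foldid <- make_folds(nrow(X), spec$cv_folds, seed = spec$seed, labels = y)
  acc <- vapply(grid, function(H) {
    correct <- 0L
    for (k in sort(unique(foldid))) {
      tr <- foldid != k
      fit <- elm_train_once(Xs[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                            H, seed = spec$seed + H)
      sc_te <- elm_hidden(Xs[!tr, , drop = FALSE], fit$W, fit$b) %*% fit$beta
      pred <- classes[max.col(sc_te, ties.method = "first")]
      correct <- correct + sum(pred == y[!tr])
    }
    correct / nrow(X)
  }, numeric(1))
  H_best <- grid[which.max(acc)]
  fit <- elm_train_once(Xs, Y, H_best, seed = spec$seed + H_best)
  new_trained_model(spec, chosen = list(hidden = H_best),
                    state = c(fit, list(scale = sc)), classes = classes,
                    cv_accuracy = stats::setNames(acc, grid))
}

knn_vote <- function(D, y_ref, K, classes) {
  # D: query x reference distances; majority vote, ties -> smallest class id
  apply(D, 1, function(d) {
    nb <- y_ref[order(d)[seq_len(K)]]
    counts <- tabulate(match(nb, classes), length(classes))
    classes[which.max(counts)]
  })
}

#' Train a k-nearest-neighbours classifier
#'
#' Features are standardised with training mean/sd; K is chosen by inner CV
#' accuracy over the grid; prediction is the majority label among the K
#' Euclidean nearest training points, ties breaking to the smallest class
#' id.
#'
#' @inheritParams train_elm
#' @param spec a [model_spec()] with `algorithm = "knn"`.
#' @return A `trained_model`.
#' @export
train_knn <- function(X, y, spec = model_spec("knn")) {
  X <- as.matrix(X)
  n <- nrow(X)
  classes <- sort(unique(y))
  grid <- spec$grid$k
  if (any(grid >= n)) stop("K must be smaller than n_train (", n, ")")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  sq <- rowSums(Xs^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(Xs)
  D2[D2 < 0] <- 0
  foldid <- make_folds(n, spec$cv_folds, seed = spec$seed, labels = y)
  acc <- vapply(grid, function(K) {
    correct <- 0L
    for (k in sort(unique(foldid))) {
      te <- which(foldid == k); tr <- which(foldid != k)
      pred <- knn_vote(D2[te, tr, drop = FALSE], y[tr], K, classes)
      correct <- correct + sum(pred == y[te])
    }
    correct / n
  }, numeric(1))
  K_best <- grid[which.max(acc)]
  new_trained_model(spec, chosen = list(k = K_best),
                    state = list(X = Xs, y = y, center = ctr, scale = scl),
                    classes = classes, cv_accuracy = stats::setNames(acc, grid))
}

#' Train a random forest
#'
#' 500 bootstrap-trained trees (ranger) at each candidate maximum depth;
#' the depth is chosen by inner CV accuracy; prediction is the majority
#' vote of the ensemble.
#'
#' @inheritParams train_elm
#' @param spec a [model_spec()] with `algorithm = "rf"`.
#' @return A `trained_model`.
#' @export
train_rf <- function(X, y, spec = model_spec("rf")) {
  X <- as.matrix(X)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  classes <- sort(unique(y))
  yf <- factor(y, levels = classes)
  dat <- data.frame(.class = yf, X, check.names = FALSE)
  foldid <- make_folds(nrow(X), spec$cv_folds, seed = spec$seed, labels = y)
  fit_one <- function(rows, depth) {
    ranger::ranger(dependent.variable.name = ".class", data = dat[rows, ],
                   num.trees = spec$grid$trees, max.depth = depth,
                   seed = spec$seed, num.threads = 1)
  }
  acc <- vapply(spec$grid$depth, function(depth) {
    correct <- 0L
    for (k in sort(unique(foldid))) {
      te <- which(foldid == k); tr <- which(foldid != k)
      fit <- fit_one(tr, depth)
      pred <- stats::predict(fit, dat[te, ], num.threads = 1)$predictions
      correct <- correct + sum(as.integer(as.character(pred)) == y[te])
    }
    correct / nrow(X)
  }, numeric(1))
  depth_best <- spec$grid$depth[which.max(acc)]
  fit <- fit_one(seq_len(nrow(X)), depth_best)
  new_trained_model(spec, chosen = list(depth = depth_best,
                                        trees = spec$grid$trees),
                    state = list(forest = fit, feat_names = colnames(X)),
                    classes = classes,
                    cv_accuracy = stats::setNames(acc, spec$grid$depth))
}

#' Train a PLS-DA classifier
#'
#' Latent-variable regression onto one-hot class indicators; the component
#' count is chosen by inner CV accuracy (capped below `min(n, p)` with a
#' warning when the grid exceeds it); prediction is the argmax of the
#' predicted response.
#'
#' @inheritParams train_elm
#' @param spec a [model_spec()] with `algorithm = "plsda"`.
#' @return A `trained_model`.
#' @export
train_plsda <- function(X, y, spec = model_spec("plsda")) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  Y <- one_hot(y, classes)
  cap <- min(nrow(X) - 1, ncol(X))
  grid <- spec$grid$ncomp
  if (max(grid) > cap) {
    warning("component grid capped at ", cap)
    grid <- grid[grid <= cap]
  }
  foldid <- make_folds(nrow(X), spec$cv_folds, seed = spec$seed, labels = y)
  correct <- matrix(0, length(grid), 1)
  for (k in sort(unique(foldid))) {
    te <- which(foldid == k); tr <- which(foldid != k)
    fit <- pls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                   ncomp = max(grid))
    for (gi in seq_along(grid)) {
      a <- min(grid[gi], fit$ncomp)
      sc <- predict(fit, X[te, , drop = FALSE], ncomp = a)
      pred <- classes[max.col(sc, ties.method = "first")]
      correct[gi] <- correct[gi] + sum(pred == y[te])
    }
  }
  acc <- correct[, 1] / nrow(X)
  n_best <- grid[which.max(acc)]
  fit <- pls_fit(X, Y, ncomp = n_best)
  new_trained_model(spec, chosen = list(ncomp = n_best), state = list(pls = fit),
                    classes = classes, cv_accuracy = stats::setNames(acc, grid))
}

svm_cv_accuracy <- function(X, yf, C, G, foldid) {
  correct <- 0L
  for (k in sort(unique(foldid))) {
    te <- which(foldid == k); tr <- which(foldid != k)
    fit <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                      cost = C, gamma = G, scale = FALSE)
    pred <- stats::predict(fit, X[te, , drop = FALSE])
    correct <- correct + sum(pred == yf[te])
  }
  correct / length(yf)
}

#' Train an RBF SVM tuned by particle swarm optimization
#'
#' Particles encode `(C, G)`; fitness is 5-fold cross-validated accuracy;
#' positions are clamped to the grid bounds; the best particle's `(C, G)`
#' is refit on the full training set. Features are standardised with
#' training statistics; multiclass handling is one-vs-one (libsvm).
#'
#' @inheritParams train_elm
#' @param spec a [model_spec()] with `algorithm = "svm"`.
#' @return A `trained_model`; `state$history` holds the per-iteration best
#'   fitness and `state$initial_fitness` the fitness of the initial swarm.
#' @export
train_svm_pso <- function(X, y, spec = model_spec("svm")) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  yf <- factor(y, levels = classes)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  foldid <- make_folds(nrow(X), spec$cv_folds, seed = spec$seed, labels = y)
  # particles move in log10(C), log10(G) space: (C, G) act multiplicatively,
  # and a linear walk over (0, 100] would waste most of the swarm on
  # equivalent large values
  lo <- log10(c(spec$grid$C[1], spec$grid$G[1]))
  hi <- log10(c(spec$grid$C[2], spec$grid$G[2]))
  np <- spec$pso$n_particles; ni <- spec$pso$n_iter
  out <- with_seed(spec$seed, {
    # Latin-hypercube start: stratify each axis into np bins so the swarm
    # cannot miss a narrow viable (C, G) region entirely
    lhs <- function() (sample.int(np) - stats::runif(np)) / np
    pos <- cbind(lo[1] + lhs() * (hi[1] - lo[1]),
                 lo[2] + lhs() * (hi[2] - lo[2]))
    vmax0 <- 0.2 * (hi - lo)
    vel <- cbind(stats::runif(np, -vmax0[1], vmax0[1]),
                 stats::runif(np, -vmax0[2], vmax0[2]))
    fit_p <- apply(pos, 1, function(q)
      svm_cv_accuracy(Xs, yf, 10^q[1], 10^q[2], foldid))
    initial_fitness <- fit_p
    pbest <- pos; pbest_f <- fit_p
    g_i <- which.max(pbest_f)
    gbest <- pbest[g_i, ]; gbest_f <- pbest_f[g_i]
    history <- numeric(ni)
    vmax <- 0.2 * (hi - lo)
    for (it in seq_len(ni)) {
      w <- spec$pso$inertia[1] +
        (spec$pso$inertia[2] - spec$pso$inertia[1]) * (it - 1) / max(1, ni - 1)
      r1 <- matrix(stats::runif(np * 2), np, 2)
      r2 <- matrix(stats::runif(np * 2), np, 2)
      vel <- w * vel +
        spec$pso$cognitive * r1 * (pbest - pos) +
        spec$pso$social * r2 * matrix(gbest, np, 2, byrow = TRUE) -
        spec$pso$social * r2 * pos
      vel <- pmin(pmax(vel, -matrix(vmax, np, 2, byrow = TRUE)),
                  matrix(vmax, np, 2, byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lo, np, 2, byrow = TRUE)),
                  matrix(hi, np, 2, byrow = TRUE))
      f <- apply(pos, 1, function(q)
        svm_cv_accuracy(Xs, yf, 10^q[1], 10^q[2], foldid))
      upd <- f > pbest_f
      pbest[upd, ] <- pos[upd, , drop = FALSE]
      pbest_f[upd] <- f[upd]
      if (max(pbest_f) > gbest_f) {
        g_i <- which.max(pbest_f)
        gbest <- pbest[g_i, ]; gbest_f <- pbest_f[g_i]
      }
      history[it] <- gbest_f
    }
    list(gbest = 10^gbest, gbest_f = gbest_f, history = history,
         initial_fitness = initial_fitness)
  })
  fit <- e1071::svm(Xs, yf, kernel = "radial", cost = out$gbest[1],
                    gamma = out$gbest[2], scale = FALSE)
  new_trained_model(spec,
                    chosen = list(C = out$gbest[1], G = out$gbest[2]),
                    state = list(svm = fit, center = ctr, scale = scl,
                                 history = out$history,
                                 initial_fitness = out$initial_fitness,
                                 cv_fitness = out$gbest_f),
                    classes = classes)
}

#' Train a classifier according to its specification
#'
#' @param X training sample x feature matrix.
#' @param y integer class labels.
#' @param spec a [model_spec()].
#' @return A `trained_model`.
#' @export
train_model <- function(X, y, spec) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$algorithm,
         elm = train_elm(X, y, spec),
         knn = train_knn(X, y, spec),
         rf = train_rf(X, y, spec),
         plsda = train_plsda(X, y, spec),
         svm = train_svm_pso(X, y, spec))
}

#' Predict class labels
#'
#' @param object a `trained_model`.
#' @param newdata numeric matrix with the feature count seen at fit.
#' @param ... unused.
#' @return Integer vector of class labels (empty for empty input).
#' @export
predict.trained_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p_fit <- switch(object$algorithm,
    elm = nrow(object$state$W),
    knn = ncol(object$state$X),
    rf = length(object$state$feat_names),
    plsda = object$state$pls$p,
    svm = length(object$state$center))
  if (nrow(newdata) > 0 && ncol(newdata) != p_fit)
    stop("newdata has ", ncol(newdata), " features, model was fit on ", p_fit)
  if (nrow(newdata) == 0) return(integer(0))
  switch(object$algorithm,
    elm = {
      Xs <- minmax_apply(newdata, object$state$scale)
      sc <- elm_hidden(Xs, object$state$W, object$state$b) %*%
        object$state$beta
      object$classes[max.col(sc, ties.method = "first")]
    },
    knn = {
      Xs <- scale(newdata, center = object$state$center,
                  scale = object$state$scale)
      sq_a <- rowSums(Xs^2); sq_b <- rowSums(object$state$X^2)
      D2 <- outer(sq_a, sq_b, `+`) - 2 * tcrossprod(Xs, object$state$X)
      as.integer(knn_vote(D2, object$state$y, object$chosen$k,
                          object$classes))
    },
    rf = {
      colnames(newdata) <- object$state$feat_names
      pred <- stats::predict(object$state$forest,
                             data.frame(newdata, check.names = FALSE),
                             num.threads = 1)$predictions
      as.integer(as.character(pred))
    },
    plsda = {
      sc <- predict(object$state$pls, newdata)
      if (is.null(dim(sc))) sc <- matrix(sc, ncol = 1)
      object$classes[max.col(sc, ties.method = "first")]
    },
    svm = {
      Xs <- scale(newdata, center = object$state$center,
                  scale = object$state$scale)
      as.integer(as.character(stats::predict(object$state$svm, Xs)))
    })
}
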