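# Wavelength selection over preprocessed training spectra: the successive
# projections algorithm (SPA), competitive adaptive reweighted sampling
# (CARS), an iterative variable-space shrinkage interval selector (IVISSA),
# and the hybrid chains CARS-SPA / IVISSA-SPA. All selectors regress the
# numerically coded class labels (1/2/3); CARS and IVISSA use the compiled
# PLS core, SPA evaluates subsets by validation RMSE of a least-squares fit
# on the selected bands.

new_selection_result <- function(method, selected, wavelengths, params,
                                 seed, ...) {
  selected <- as.integer(selected)
  stopifnot(!anyDuplicated(selected))
  structure(c(list(method = method, selected = selected,
                   wavelengths = wavelengths[selected], params = params,
                   seed = seed), list(...)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$method, "]: ", length(x$selected),
      " band(s)\n", sep = "")
  invisible(x)
}

#' Successive projections algorithm (SPA)
#'
#' Builds, for every candidate start band, a chain that repeatedly adds the
#' band with the largest column norm after orthogonal projection onto the
#' complement of the already-chosen columns (so collinear bands are never
#' both taken). Every (start, size) subset with size in `n_min..n_max` is
#' scored by the RMSE of a least-squares fit on a held-out validation
#' portion of the training data; the subset with minimal RMSE wins, ties
#' going to the smaller subset, then the lower start band.
#'
#' @param X training sample x band matrix.
#' @param y numeric response (class labels coded 1/2/3).
#' @param wavelengths band centres in nm (defaults to band indices).
#' @param n_min,n_max subset-size range searched (`n_max <= ncol(X)`).
#' @param val_fraction fraction of training rows held out (stratified on
#'   `y`) for subset scoring.
#' @param seed RNG seed for the validation split.
#' @return A `selection_result` with the winning band indices (selection
#'   order) and `rmse_curve` (size vs RMSE for the winning start).
#' @export
select_spa <- function(X, y, wavelengths = seq_len(ncol(X)),
                       n_min = 10, n_max = 100, val_fraction = 0.25,
                       seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  if (n_max > p) stop("n_max (", n_max, ") exceeds band count (", p, ")")
  if (n_min < 1 || n_min > n_max) stop("need 1 <= n_min <= n_max")
  # stratified validation split so every class is represented
  val <- with_seed(seed, {
    unlist(lapply(unique(y), function(cl) {
      rows <- which(y == cl)
      sample(rows, max(1, round(val_fraction * length(rows))))
    }))
  })
  tr <- setdiff(seq_len(nrow(X)), val)
  chains <- spa_chains_cpp(X, as.integer(n_max), 1e-12)
  best <- list(rmse = Inf, size = Inf, start = Inf, chain = NULL, curve = NULL)
  for (s in seq_len(p)) {
    chain <- chains[[s]] + 1L              # 0-based -> 1-based
    if (length(chain) < n_min) next
    rmse <- spa_eval_chain_cpp(X[tr, , drop = FALSE], y[tr],
                               X[val, , drop = FALSE], y[val],
                               as.integer(chain - 1L))
    sizes <- n_min:length(chain)
    for (k in sizes) {
      r <- rmse[k]
      if (is.finite(r) &&
          (r < best$rmse - 1e-12 ||
           (abs(r - best$rmse) <= 1e-12 &&
            (k < best$size || (k == best$size && s < best$start))))) {
        best <- list(rmse = r, size = k, start = s, chain = chain,
                     curve = data.frame(size = sizes, rmse = rmse[sizes]))
      }
    }
  }
  if (is.null(best$chain))
    stop("no chain reached the minimum subset size ", n_min)
  new_selection_result("spa", best$chain[seq_len(best$size)], wavelengths,
                       params = list(n_min = n_min, n_max = n_max,
                                     val_fraction = val_fraction),
                       seed = seed, rmse_curve = best$curve,
                       start_band = best$start, rmse = best$rmse)
}

# Exponentially decreasing function of CARS, fixed by its two endpoint
# constraints r_1 = 1 and r_N = 2/p.
cars_edf <- function(p, n_mc) {
  k <- log(p / 2) / (n_mc - 1)
  a <- exp(k)
  list(a = a, k = k, ratio = function(i) a * exp(-k * i))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Per run, iterates `n_mc` Monte-Carlo rounds: fit a PLS regression on a
#' random calibration subset (mean-centred) restricted to the currently
#' retained bands, take absolute regression coefficients as weights, then
#' shrink the retained set to the count fixed by the exponentially
#' decreasing function (from all `p` bands down to 2) by an adaptive
#' reweighted draw without replacement, probability proportional to
#' coefficient magnitude. The retained set with minimal cross-validated
#' RMSE across iterations wins the run; the best of `n_runs` runs (seeds
#' `seed + 0..n_runs-1`) is returned.
#'
#' @param X training sample x band matrix.
#' @param y numeric response.
#' @param wavelengths band centres in nm.
#' @param n_mc Monte-Carlo iterations per run.
#' @param n_runs independent repetitions.
#' @param cv_folds folds of the internal RMSECV criterion.
#' @param ncomp_max maximum PLS components.
#' @param cal_fraction calibration-subset fraction per iteration.
#' @param seed base RNG seed.
#' @return A `selection_result` with `rmsecv_trace` and `retained_trace`
#'   (per-iteration values for the winning run) and `chosen_run`.
#' @export
select_cars <- function(X, y, wavelengths = seq_len(ncol(X)),
                        n_mc = 1000, n_runs = 5, cv_folds = 5,
                        ncomp_max = 10, cal_fraction = 0.8, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X); n <- nrow(X)
  if (n_mc < 2) stop("n_mc must be >= 2")
  edf <- cars_edf(p, n_mc)
  foldid <- make_folds(n, cv_folds, seed = seed)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    runs[[r]] <- with_seed(seed + r - 1L, {
      retained <- seq_len(p)
      rmsecv <- numeric(n_mc)
      counts <- integer(n_mc)
      sets <- vector("list", n_mc)
      stopped <- FALSE
      for (i in seq_len(n_mc)) {
        keep_n <- max(2L, min(length(retained), round(edf$ratio(i) * p)))
        cal <- sample.int(n, max(2, round(cal_fraction * n)))
        nc <- min(ncomp_max, length(retained), length(cal) - 1)
        fit <- pls_fit(X[cal, retained, drop = FALSE], y[cal], ncomp = nc)
        w <- abs(fit$coef[, 1, fit$ncomp])
        if (all(w == 0)) w <- rep(1, length(w))
        pick <- if (keep_n < length(retained)) {
          sample.int(length(retained), keep_n, prob = w)
        } else seq_along(retained)
        retained <- sort(retained[pick])
        if (length(retained) < 2) { stopped <- TRUE; counts <- counts[1:(i - 1)]
          rmsecv <- rmsecv[1:(i - 1)]; sets <- sets[1:(i - 1)]; break }
        counts[i] <- length(retained)
        cvr <- pls_cv_rmse(X[, retained, drop = FALSE], y,
                           ncomp = min(ncomp_max, length(retained)),
                           foldid = foldid)
        rmsecv[i] <- min(cvr)
        sets[[i]] <- retained
      }
      best_i <- which.min(rmsecv)
      list(selected = sets[[best_i]], rmsecv = rmsecv, counts = counts,
           best_rmsecv = rmsecv[best_i], best_iter = best_i,
           stopped_early = stopped)
    })
  }
  chosen <- which.min(vapply(runs, `[[`, numeric(1), "best_rmsecv"))
  win <- runs[[chosen]]
  new_selection_result("cars", win$selected, wavelengths,
                       params = list(n_mc = n_mc, n_runs = n_runs,
                                     cv_folds = cv_folds,
                                     ncomp_max = ncomp_max,
                                     cal_fraction = cal_fraction,
                                     edf_a = edf$a, edf_k = edf$k),
                       seed = seed, rmsecv_trace = win$rmsecv,
                       retained_trace = win$counts, chosen_run = chosen,
                       best_iter = win$best_iter,
                       stopped_early = win$stopped_early)
}

# RMSECV (min over components) of a column subset; shared by IVISSA stages.
subset_rmsecv <- function(X, y, cols, foldid, ncomp_max) {
  if (!length(cols)) return(Inf)
  min(pls_cv_rmse(X[, cols, drop = FALSE], y,
                  ncomp = min(ncomp_max, length(cols)), foldid = foldid))
}

#' Iterative variable-space shrinkage interval selector (IVISSA)
#'
#' Global stage: per-band sampling weights (initialised at 0.5) drive a
#' weighted binary matrix sampling of `n_submodels` inclusion vectors per
#' round (band j appears in exactly `round(w_j * n_submodels)` submodels);
#' each submodel is scored by PLS RMSECV and every band's weight is updated
#' to its frequency among the `top_fraction` best submodels. Rounds stop
#' when all weights reach 0/1, when the best submodel RMSECV has not
#' improved for `patience` rounds, or at `max_rounds` (then the set with
#' weight above 0.5 is returned with a warning). Local stage: each surviving
#' contiguous band interval is widened/narrowed one band at a time, keeping
#' changes that lower RMSECV.
#'
#' @param X training sample x band matrix.
#' @param y numeric response.
#' @param wavelengths band centres in nm.
#' @param n_submodels submodels per round (>= 100).
#' @param top_fraction fraction of submodels defining the elite set.
#' @param max_rounds global-stage round cap.
#' @param cv_folds,ncomp_max internal PLS RMSECV settings.
#' @param patience rounds without elite-RMSECV improvement before stopping.
#' @param seed RNG seed.
#' @return A `selection_result` with `weights_trace` (rounds x bands
#'   matrix), `rmsecv_trace` (best submodel per round) and `converged`.
#' @export
select_ivissa <- function(X, y, wavelengths = seq_len(ncol(X)),
                          n_submodels = 1000, top_fraction = 0.1,
                          max_rounds = 50, cv_folds = 5, ncomp_max = 10,
                          patience = 3, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X); n <- nrow(X)
  if (n_submodels < 100) stop("n_submodels must be >= 100")
  foldid <- make_folds(n, cv_folds, seed = seed)
  w <- rep(0.5, p)
  w_trace <- matrix(NA_real_, 0, p)
  best_trace <- numeric()
  converged <- FALSE
  with_seed(seed, {
    stall <- 0L
    best_so_far <- Inf
    for (round_i in seq_len(max_rounds)) {
      inc_counts <- round(w * n_submodels)
      inc <- matrix(FALSE, n_submodels, p)
      for (j in seq_len(p)) {
        if (inc_counts[j] >= n_submodels) inc[, j] <- TRUE
        else if (inc_counts[j] > 0)
          inc[sample.int(n_submodels, inc_counts[j]), j] <- TRUE
      }
      scores <- vapply(seq_len(n_submodels), function(m) {
        subset_rmsecv(X, y, which(inc[m, ]), foldid, ncomp_max)
      }, numeric(1))
      elite <- order(scores)[seq_len(max(1, ceiling(top_fraction * n_submodels)))]
      w <- colMeans(inc[elite, , drop = FALSE])
      w_trace <- rbind(w_trace, w)
      best_trace <- c(best_trace, min(scores))
      if (all(w %in% c(0, 1))) { converged <- TRUE; break }
      if (min(scores) < best_so_far - 1e-9) {
        best_so_far <- min(scores); stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) { converged <- TRUE; break }
      }
    }
  })
  if (!converged)
    warning("IVISSA global stage hit max_rounds without convergence; ",
            "returning the weight > 0.5 set")
  sel <- if (all(w %in% c(0, 1))) which(w == 1) else which(w > 0.5)
  if (!length(sel)) sel <- order(w, decreasing = TRUE)[1:2]
  # local stage: widen/narrow each contiguous interval by one band per move
  sel <- sort(sel)
  base_r <- subset_rmsecv(X, y, sel, foldid, ncomp_max)
  repeat {
    improved <- FALSE
    runs_ <- split(sel, cumsum(c(1, diff(sel) != 1)))
    for (iv in runs_) {
      cand <- list(widen_l = if (min(iv) > 1) union(sel, min(iv) - 1L),
                   widen_r = if (max(iv) < p) union(sel, max(iv) + 1L),
                   narrow_l = if (length(iv) > 1) setdiff(sel, min(iv)),
                   narrow_r = if (length(iv) > 1) setdiff(sel, max(iv)))
      for (cc in cand) {
        if (is.null(cc) || length(cc) < 1) next
        r <- subset_rmsecv(X, y, sort(cc), foldid, ncomp_max)
        if (r < base_r - 1e-9) {
          sel <- sort(cc); base_r <- r; improved <- TRUE; break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  new_selection_result("ivissa", sel, wavelengths,
                       params = list(n_submodels = n_submodels,
                                     top_fraction = top_fraction,
                                     max_rounds = max_rounds,
                                     cv_folds = cv_folds,
                                     ncomp_max = ncomp_max,
                                     patience = patience),
                       seed = seed, weights_trace = w_trace,
                       rmsecv_trace = best_trace, converged = converged,
                       final_weights = w, rmsecv = base_r)
}

#' Hybrid selection: SPA refinement of a parent selection
#'
#' Runs [select_spa()] on the column submatrix restricted to the parent's
#' selected bands and maps the result back to the original band coordinate
#' system, yielding the CARS-SPA / IVISSA-SPA chains.
#'
#' @param first a `selection_result` from [select_cars()] or
#'   [select_ivissa()] (or any parent).
#' @param X,y the same training data the parent saw.
#' @param wavelengths band centres in nm for the full axis.
#' @param n_min,n_max SPA subset-size range; the effective maximum is capped
#'   at the parent's selection size.
#' @param ... passed to [select_spa()].
#' @return A `selection_result` with method `"<parent>-spa"`; its indices
#'   are a subset of `first$selected`.
#' @export
select_hybrid <- function(first, X, y, wavelengths = seq_len(ncol(X)),
                          n_min = 10, n_max = 100, ...) {
  stopifnot(inherits(first, "selection_result"))
  parent <- sort(first$selected)
  if (length(parent) < 2) stop("parent selection has fewer than 2 bands")
  n_max_eff <- min(n_max, length(parent))
  n_min_eff <- min(n_min, n_max_eff)
  sub <- select_spa(X[, parent, drop = FALSE], y,
                    wavelengths = wavelengths[parent],
                    n_min = n_min_eff, n_max = n_max_eff, ...)
  out <- new_selection_result(paste0(first$method, "-spa"),
                              parent[sub$selected], wavelengths,
                              params = c(sub$params, list(parent = first$method)),
                              seed = sub$seed, rmse_curve = sub$rmse_curve,
                              rmse = sub$rmse)
  out
}

#' Serialize / restore a selection result as JSON
#'
#' @param x a `selection_result`.
#' @param path file path.
#' @return `path` invisibly / a `selection_result`.
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  out <- unclass(x)
  if (!is.null(out$weights_trace)) out$weights_trace <- NULL  # bulky
  if (!is.null(out$rmse_curve)) out$rmse_curve <- as.list(out$rmse_curve)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "selection_result")
}

#' Plot a selection result
#'
#' For SPA-style results, draws the RMSE-vs-subset-size curve; for all
#' methods, marks the selected bands over an optional mean spectrum.
#'
#' @param x a `selection_result`.
#' @param mean_spectrum optional numeric vector (one value per band of the
#'   full axis) to draw under the selected-band markers.
#' @param full_wavelengths wavelength axis for `mean_spectrum`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.selection_result <- function(x, mean_spectrum = NULL,
                                  full_wavelengths = NULL, ...) {
  if (!is.null(x$rmse_curve) && is.null(mean_spectrum)) {
    graphics::plot(x$rmse_curve$size, x$rmse_curve$rmse, type = "b",
                   xlab = "number of selected bands", ylab = "RMSE",
                   main = paste(toupper(x$method), "subset-size curve"), ...)
    graphics::abline(v = length(x$selected), lty = 2)
  } else {
    if (is.null(mean_spectrum) || is.null(full_wavelengths))
      stop("need mean_spectrum and full_wavelengths for a band-marker plot")
    graphics::plot(full_wavelengths, mean_spectrum, type = "l",
                   xlab = "wavelength (nm)", ylab = "mean reflectance (%)",
                   main = paste(toupper(x$method), "selected bands"), ...)
    graphics::points(x$wavelengths,
                     mean_spectrum[x$selected], col = 2, pch = 19)
  }
  invisible(x)
}
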