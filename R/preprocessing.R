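# Spectral pretreatments applied row-wise to a spectra table: Savitzky-Golay
# smoothing, first/second derivatives on the wavelength grid, standard
# normal variate, polynomial detrending, and ordered combinations of these.

#' Savitzky-Golay smoothing
#'
#' Each spectrum is replaced by the centre value of a moving least-squares
#' polynomial fit; at the edges the terminal-window polynomial is evaluated
#' at the outlying points (so a spectrum that is globally a polynomial of
#' the fit order is reproduced exactly).
#'
#' @param x a [spectra_table()].
#' @param window odd window length `>= 3` and `<= n_bands`.
#' @param polyorder polynomial order `< window`.
#' @return A [spectra_table()].
#' @export
sg_smooth <- function(x, window = 11, polyorder = 3) {
  stopifnot(inherits(x, "spectra_table"))
  p <- length(x$wavelengths)
  if (window %% 2 == 0 || window < 3)
    stop("parameter error: window must be odd and >= 3")
  if (polyorder >= window)
    stop("parameter error: polyorder must be < window")
  if (window > p) stop("parameter error: window exceeds band count")
  sm <- t(apply(x$reflectance, 1, signal::sgolayfilt, p = polyorder,
                n = window))
  out <- spectra_table(sm, x$wavelengths, labels = x$labels,
                       sample_ids = x$sample_ids)
  out$provenance <- c(x$provenance, sprintf("sg(w=%d,p=%d)", window, polyorder))
  out
}

#' Spectral derivative on the wavelength grid
#'
#' First derivative: central differences at interior bands, one-sided at the
#' ends (units become %/nm). Second derivative: the three-point second
#' difference for a non-uniform grid at interior bands, with end bands
#' copying their nearest interior value (units %/nm^2). Spacing is taken
#' from the wavelength vector, so non-uniform grids are handled correctly.
#'
#' @param x a [spectra_table()].
#' @param order 1 or 2.
#' @return A [spectra_table()].
#' @export
derivative <- function(x, order = 1) {
  stopifnot(inherits(x, "spectra_table"), order %in% c(1, 2))
  X <- x$reflectance
  wl <- x$wavelengths
  p <- length(wl)
  if (p < order + 1) stop("too few bands for derivative of order ", order)
  out <- matrix(0, nrow(X), p)
  if (order == 1) {
    i <- 2:(p - 1)
    out[, i] <- (X[, i + 1] - X[, i - 1]) /
      rep(wl[i + 1] - wl[i - 1], each = nrow(X))
    out[, 1] <- (X[, 2] - X[, 1]) / (wl[2] - wl[1])
    out[, p] <- (X[, p] - X[, p - 1]) / (wl[p] - wl[p - 1])
  } else {
    if (p < 3) stop("too few bands for a second derivative")
    i <- 2:(p - 1)
    h1 <- wl[i] - wl[i - 1]
    h2 <- wl[i + 1] - wl[i]
    out[, i] <- 2 * (sweep(X[, i + 1, drop = FALSE], 2, h2, `/`) -
                     sweep(X[, i, drop = FALSE], 2, h1 * h2 / (h1 + h2), `/`) +
                     sweep(X[, i - 1, drop = FALSE], 2, h1, `/`)) /
      rep(h1 + h2, each = nrow(X))
    out[, 1] <- out[, 2]
    out[, p] <- out[, p - 1]
  }
  res <- spectra_table(out, wl, labels = x$labels, sample_ids = x$sample_ids)
  res$provenance <- c(x$provenance, paste0("d", order))
  res
}

#' Standard normal variate
#'
#' Standardizes every spectrum to mean 0 and standard deviation 1, removing
#' additive offsets and multiplicative scatter.
#'
#' @param x a [spectra_table()].
#' @return A [spectra_table()].
#' @export
snv <- function(x) {
  stopifnot(inherits(x, "spectra_table"))
  mu <- rowMeans(x$reflectance)
  sd_ <- apply(x$reflectance, 1, stats::sd)
  zero <- sd_ == 0
  if (any(zero))
    stop("constant spectrum, SNV undefined for sample(s): ",
         paste(x$sample_ids[zero], collapse = ", "))
  out <- (x$reflectance - mu) / sd_
  res <- spectra_table(out, x$wavelengths, labels = x$labels,
                       sample_ids = x$sample_ids)
  res$provenance <- c(x$provenance, "snv")
  res
}

#' Polynomial detrend
#'
#' Subtracts from every spectrum its least-squares polynomial of the given
#' degree in wavelength; the residual is orthogonal to the polynomial basis,
#' so detrending is idempotent.
#'
#' @param x a [spectra_table()].
#' @param degree polynomial degree (`< n_bands`); 2 is the usual companion
#'   to SNV.
#' @return A [spectra_table()].
#' @export
detrend <- function(x, degree = 2) {
  stopifnot(inherits(x, "spectra_table"))
  p <- length(x$wavelengths)
  if (degree >= p) stop("degree must be < number of bands")
  wl <- scale(x$wavelengths)[, 1]          # centred/scaled for conditioning
  V <- outer(wl, 0:degree, `^`)
  Q <- qr.Q(qr(V))
  fitted <- (x$reflectance %*% Q) %*% t(Q)
  res <- spectra_table(x$reflectance - fitted, x$wavelengths,
                       labels = x$labels, sample_ids = x$sample_ids)
  res$provenance <- c(x$provenance, sprintf("detrend(d=%d)", degree))
  res
}

#' Pretreatment chains
#'
#' Parses an ordered chain token such as `"sg+d2nd"` into a validated chain.
#' The supported study variants are `raw`, `sg`, `d1st`, `d2nd`, `snv`,
#' `detrend`, `sg+d1st`, `sg+d2nd`, `snv+detrend`; any other combination of
#' the five steps requires `override = TRUE`.
#'
#' @param tokens chain string (steps joined by `+`), or character vector of
#'   steps. `"raw"` is the empty chain.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param detrend_degree detrend polynomial degree.
#' @param override allow chains outside the nine study variants.
#' @return An object of class `preprocess_chain`.
#' @export
preprocess_chain <- function(tokens = "raw", sg_window = 11, sg_polyorder = 3,
                             detrend_degree = 2, override = FALSE) {
  if (length(tokens) == 1 && grepl("+", tokens, fixed = TRUE))
    tokens <- strsplit(tokens, "+", fixed = TRUE)[[1]]
  tokens <- tolower(trimws(tokens))
  if (identical(tokens, "raw")) tokens <- character()
  known <- c("sg", "d1st", "d2nd", "snv", "detrend")
  if (!all(tokens %in% known))
    stop("unknown pretreatment step(s): ",
         paste(setdiff(tokens, known), collapse = ", "))
  variants <- list(character(), "sg", "d1st", "d2nd", "snv", "detrend",
                   c("sg", "d1st"), c("sg", "d2nd"), c("snv", "detrend"))
  if (!override && !any(vapply(variants, identical, logical(1), y = tokens)))
    stop("chain '", paste(tokens, collapse = "+"),
         "' is not one of the nine study variants (use override = TRUE)")
  structure(list(steps = tokens,
                 params = list(sg_window = sg_window,
                               sg_polyorder = sg_polyorder,
                               detrend_degree = detrend_degree)),
            class = "preprocess_chain")
}

#' @export
print.preprocess_chain <- function(x, ...) {
  cat("preprocess_chain:",
      if (length(x$steps)) paste(x$steps, collapse = " + ") else "raw", "\n")
  invisible(x)
}

#' Apply a pretreatment chain to a spectra table
#'
#' Steps are applied left to right; the wavelength axis and labels are
#' carried through and every step is appended to the table's provenance.
#'
#' @param x a [spectra_table()].
#' @param chain a [preprocess_chain()] or a chain token string.
#' @return A [spectra_table()].
#' @export
apply_chain <- function(x, chain) {
  stopifnot(inherits(x, "spectra_table"))
  if (is.character(chain)) chain <- preprocess_chain(chain)
  stopifnot(inherits(chain, "preprocess_chain"))
  for (step in chain$steps) {
    x <- switch(step,
      sg = sg_smooth(x, chain$params$sg_window, chain$params$sg_polyorder),
      d1st = derivative(x, 1),
      d2nd = derivative(x, 2),
      snv = snv(x),
      detrend = detrend(x, chain$params$detrend_degree))
  }
  x
}
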