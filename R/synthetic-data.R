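# Synthetic three-stage maturity data with the spectral structure the
# pipeline assumes: near-coincident class means in the blue-green region,
# class separation concentrated at planted "informative" NIR bands, heavy
# sensor noise at both spectral edges, and (in cube mode) an invertible
# reflectance-calibration forward model.

#' Specification for the synthetic maturity dataset
#'
#' Defines a three-class (green / yellow / fully mature) reflectance dataset
#' on an equally spaced wavelength grid. Class-mean curves share a smooth
#' sigmoidal base profile; class differences are planted as narrow features
#' (one-band shoulders) centred on `informative_bands`, with amplitudes that
#' increase with wavelength across the near-infrared. Per-band Gaussian noise
#' uses `edge_noise_sd` outside the 420-982 nm body and `body_noise_sd`
#' inside it.
#'
#' @param n_bands number of spectral bands (>= 2).
#' @param wl_min,wl_max wavelength range in nm.
#' @param class_sizes integer vector of per-class sample counts
#'   (green, yellow, mature).
#' @param informative_bands integer band indices (1-based) carrying class
#'   signal; default picks 8 bands spread over 750-960 nm.
#' @param edge_noise_sd,body_noise_sd noise standard deviations in
#'   reflectance percent; `edge_noise_sd` must exceed `body_noise_sd`.
#' @param seed RNG seed; all generator randomness is local to the call.
#' @return A validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bands = 314, wl_min = 400, wl_max = 1000,
                           class_sizes = c(green = 400, yellow = 400,
                                           mature = 700),
                           informative_bands = NULL,
                           edge_noise_sd = 5, body_noise_sd = 1,
                           seed = 1) {
  if (!is.numeric(n_bands) || length(n_bands) != 1 || n_bands < 2)
    stop("invalid synthetic_spec field 'n_bands': need a count >= 2")
  if (!(wl_min < wl_max))
    stop("invalid synthetic_spec field 'wl_min/wl_max': need wl_min < wl_max")
  if (length(class_sizes) < 1 || any(class_sizes < 1))
    stop("invalid synthetic_spec field 'class_sizes': all must be >= 1")
  if (length(class_sizes) > 3)
    stop("invalid synthetic_spec field 'class_sizes': at most 3 classes")
  wavelengths <- seq(wl_min, wl_max, length.out = n_bands)
  if (is.null(informative_bands)) {
    targets <- seq(750, 960, length.out = 8)
    targets <- targets[targets > wl_min & targets < wl_max]
    informative_bands <- unique(vapply(targets, function(t)
      which.min(abs(wavelengths - t)), integer(1)))
  }
  informative_bands <- as.integer(informative_bands)
  if (any(informative_bands < 1 | informative_bands > n_bands))
    stop("invalid synthetic_spec field 'informative_bands': out of band range")
  if (!(edge_noise_sd > body_noise_sd))
    stop("invalid synthetic_spec field 'edge_noise_sd': must exceed body_noise_sd")
  if (body_noise_sd < 0)
    stop("invalid synthetic_spec field 'body_noise_sd': must be >= 0")
  structure(list(n_bands = as.integer(n_bands), wl_min = wl_min,
                 wl_max = wl_max, class_sizes = as.integer(class_sizes),
                 informative_bands = sort(informative_bands),
                 edge_noise_sd = edge_noise_sd, body_noise_sd = body_noise_sd,
                 seed = as.integer(seed), wavelengths = wavelengths),
            class = "synthetic_spec")
}

# Evaluate code with a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Shared sigmoidal base curve (percent reflectance): low blue-green plateau
# rising to a broad NIR plateau.
base_curve <- function(wl) 10 + 40 / (1 + exp(-(wl - 690) / 55))

# Per-class mean curves. Class separation is injected only at the planted
# informative bands (triangular features with one-band shoulders at 30%
# amplitude); feature amplitude grows linearly across the planted sequence so
# divergence increases with wavelength. The green class stays at the base
# curve and the fully mature class carries the full feature amplitude; the
# yellow class takes an alternating partial gain across the features, so the
# three class means span two directions (stages have distinct signatures,
# not one scaled spectrum).
class_mean_curves <- function(spec) {
  wl <- spec$wavelengths
  p <- spec$n_bands
  ib <- spec$informative_bands
  n_classes <- length(spec$class_sizes)
  sep <- numeric(p)                # green-to-mature separation profile
  y_mult <- numeric(p)             # yellow's per-band partial gain
  if (length(ib)) {
    amps <- seq(4, 12, length.out = length(ib))
    y_gain <- rep(c(0.65, 0.25), length.out = length(ib))
    for (k in seq_along(ib)) {
      b <- ib[k]
      support <- intersect(c(b - 1, b, b + 1), seq_len(p))
      shoulder <- c(0.3, 1, 0.3)[match(support, c(b - 1, b, b + 1))]
      sep[support] <- sep[support] + shoulder * amps[k]
      y_mult[support] <- y_gain[k]
    }
  }
  base <- base_curve(wl)
  means <- rbind(base, base + y_mult * sep, base + sep)
  dimnames(means) <- NULL
  means[seq_len(n_classes), , drop = FALSE]
}

# Per-band noise sd: edge_noise_sd outside the 420-982 nm body.
band_noise_sd <- function(spec) {
  wl <- spec$wavelengths
  ifelse(wl < 420 | wl > 982, spec$edge_noise_sd, spec$body_noise_sd)
}

#' Generate a synthetic labelled spectra table
#'
#' Draws `sum(class_sizes)` spectra around the class-mean curves of `spec`
#' with independent per-band Gaussian noise, clips to \[0, 100\] percent, and
#' returns the table together with its ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `table` (a [spectra_table()]) and `truth`
#'   (list with `labels` and `informative_bands`).
#' @export
generate_spectra <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  means <- class_mean_curves(spec)
  sds <- band_noise_sd(spec)
  n <- sum(spec$class_sizes)
  labels <- rep(seq_along(spec$class_sizes), spec$class_sizes)
  refl <- with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(n * spec$n_bands), n, spec$n_bands)
    means[labels, , drop = FALSE] + sweep(noise, 2, sds, `*`)
  })
  refl <- pmin(pmax(refl, 0), 100)
  tab <- spectra_table(refl, spec$wavelengths, labels = labels,
                       provenance = "synthetic")
  list(table = tab,
       truth = list(labels = labels,
                    informative_bands = spec$informative_bands))
}

#' Grid layout for synthetic hypercubes
#'
#' Places elliptical "seeds" on a regular grid over a bright background
#' plate. Reference levels define the calibration forward model: the raw
#' cube is `dark + reflectance/100 * (white - dark)`.
#'
#' @param n_seeds number of seeds to place.
#' @param image_rows,image_cols image size in pixels.
#' @param radius_r,radius_c ellipse semi-axes in pixels.
#' @param background_reflectance plate reflectance in percent; must exceed
#'   the seed reflectance at 440 nm so a threshold can separate them.
#' @param dark_level,white_level reference sensor counts.
#' @return An object of class `cube_layout`.
#' @export
cube_layout <- function(n_seeds = 6, image_rows = 60, image_cols = 90,
                        radius_r = 6, radius_c = 6,
                        background_reflectance = 80,
                        dark_level = 100, white_level = 900) {
  cell <- 2 * max(radius_r, radius_c) + 4
  grid_rows <- image_rows %/% cell
  grid_cols <- image_cols %/% cell
  if (n_seeds > grid_rows * grid_cols)
    stop("layout error: ", n_seeds, " seeds do not fit a ", grid_rows, " x ",
         grid_cols, " grid at this image size")
  structure(list(n_seeds = as.integer(n_seeds), image_rows = image_rows,
                 image_cols = image_cols, radius_r = radius_r,
                 radius_c = radius_c, cell = cell, grid_rows = grid_rows,
                 grid_cols = grid_cols,
                 background_reflectance = background_reflectance,
                 dark_level = dark_level, white_level = white_level),
            class = "cube_layout")
}

#' Generate synthetic raw/dark/white hypercubes with ground truth
#'
#' Seeds are placed row-major on the layout grid and assigned maturity
#' classes round-robin. Each seed's planted spectrum is its class-mean curve
#' plus seeded per-band noise; all pixels of a seed share that spectrum. The
#' raw cube is the exact calibration inverse, so applying reflectance
#' calibration to the returned triple recovers the planted spectra.
#'
#' @param spec a [synthetic_spec()]; `class_sizes` is ignored in cube mode
#'   (sample count is `layout$n_seeds`).
#' @param layout a [cube_layout()].
#' @return List with `raw`, `dark`, `white` ([hypercube()]s) and `truth`
#'   (list with `labels`, `informative_bands`, `seed_mask`, `planted`
#'   reflectance matrix, one row per seed).
#' @export
generate_cube <- function(spec, layout = cube_layout()) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(layout, "cube_layout"))
  means <- class_mean_curves(spec)
  sds <- band_noise_sd(spec)
  p <- spec$n_bands
  n <- layout$n_seeds
  labels <- rep_len(seq_len(nrow(means)), n)
  planted <- with_seed(spec$seed, {
    noise <- matrix(stats::rnorm(n * p), n, p)
    means[labels, , drop = FALSE] + sweep(noise, 2, sds, `*`)
  })
  planted <- pmin(pmax(planted, 0), 100)

  refl <- array(layout$background_reflectance,
                c(layout$image_rows, layout$image_cols, p))
  seed_mask <- matrix(0L, layout$image_rows, layout$image_cols)
  for (s in seq_len(n)) {
    gr <- (s - 1) %/% layout$grid_cols
    gc <- (s - 1) %% layout$grid_cols
    cr <- gr * layout$cell + layout$cell / 2
    cc <- gc * layout$cell + layout$cell / 2
    rows <- seq_len(layout$image_rows)
    cols <- seq_len(layout$image_cols)
    inside <- outer(((rows - cr) / layout$radius_r)^2,
                    ((cols - cc) / layout$radius_c)^2, `+`) <= 1
    seed_mask[inside] <- s
    idx <- which(inside)
    for (b in seq_len(p)) {
      plane <- refl[, , b]
      plane[idx] <- planted[s, b]
      refl[, , b] <- plane
    }
  }
  dark <- array(layout$dark_level, dim(refl))
  white <- array(layout$white_level, dim(refl))
  raw <- dark + refl / 100 * (white - dark)
  list(raw = hypercube(raw, spec$wavelengths, "raw"),
       dark = hypercube(dark, spec$wavelengths, "dark"),
       white = hypercube(white, spec$wavelengths, "white"),
       truth = list(labels = labels,
                    informative_bands = spec$informative_bands,
                    seed_mask = seed_mask, planted = planted))
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param truth the `truth` element returned by [generate_spectra()] or
#'   [generate_cube()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  if (!is.null(out$seed_mask)) out$seed_mask <- as.vector(t(out$seed_mask))
  if (!is.null(out$planted)) out$planted <- NULL  # bulky; kept in-memory only
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
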