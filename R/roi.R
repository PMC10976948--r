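# Region-of-interest extraction: reflectance calibration of raw cubes,
# segmentation at a reference band via Otsu's threshold, connected-component
# labelling of the seed mask, per-seed mean spectra, and wavelength trimming.

#' Reflectance calibration against dark and white references
#'
#' Converts raw sensor counts to percent reflectance:
#' `(raw - dark) / (white - dark) * 100`, elementwise. Pixels/bands where
#' `white <= dark` carry no usable dynamic range; they are set to `NA` and
#' their count reported in a warning (downstream extraction skips them).
#'
#' @param raw,dark,white [hypercube()]s sharing shape and wavelength axis.
#' @return A calibrated [hypercube()] (values in percent reflectance).
#' @export
calibrate <- function(raw, dark, white) {
  for (cube in list(raw, dark, white)) stopifnot(inherits(cube, "hypercube"))
  if (!identical(dim(raw$values), dim(dark$values)) ||
      !identical(dim(raw$values), dim(white$values)))
    stop("dimension error: raw/dark/white cubes differ in shape")
  if (!isTRUE(all.equal(raw$wavelengths, dark$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, white$wavelengths)))
    stop("dimension error: raw/dark/white wavelength axes differ")
  denom <- white$values - dark$values
  bad <- denom <= 0
  vals <- (raw$values - dark$values) / denom * 100
  if (any(bad)) {
    vals[bad] <- NA_real_
    warning(sum(bad), " pixel-band(s) with white <= dark excluded from calibration")
  }
  out <- hypercube(array(0, dim(vals)), raw$wavelengths, kind = "calibrated")
  out$values <- vals  # bypass finite check: NA marks excluded pixels
  out
}

#' Extract the image plane nearest a target wavelength
#'
#' @param cube a [hypercube()].
#' @param target_nm target wavelength in nm. Nearest band wins; at an exact
#'   tie the lower wavelength is taken. A target outside the axis range
#'   clamps to the nearest end (with a warning).
#' @return A rows x cols numeric matrix.
#' @export
select_band <- function(cube, target_nm) {
  stopifnot(inherits(cube, "hypercube"))
  wl <- cube$wavelengths
  if (!length(wl)) stop("empty cube")
  if (target_nm < min(wl) || target_nm > max(wl))
    warning("target ", target_nm, " nm outside axis range [", min(wl), ", ",
            max(wl), "]; using nearest end band")
  idx <- which.min(abs(wl - target_nm))  # which.min takes the first = lower wl
  cube$values[, , idx]
}

#' Otsu threshold with seed-polarity resolution
#'
#' Finds the threshold maximizing between-class variance over a 256-bin
#' histogram of the image range (a plateau of equally good thresholds, as
#' arises between well-separated modes, resolves to its midpoint), then
#' returns the binary mask of the side holding the seeds. With `seeds_are = "auto"` the side with more connected
#' regions of smaller mean area is taken as the seed side (seeds are many
#' small blobs, the plate is one large region); `"below"`/`"above"` force
#' the polarity.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param seeds_are `"auto"`, `"below"` or `"above"` (relative to threshold).
#' @return List with `threshold` (scalar) and `mask` (logical matrix, `TRUE`
#'   on seed pixels).
#' @export
otsu_threshold <- function(image, seeds_are = c("auto", "below", "above")) {
  seeds_are <- match.arg(seeds_are)
  v <- as.vector(image)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) stop("degenerate input: constant image has no threshold")
  nbins <- 256L
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          nbins), nbins)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[nbins]; total_m <- m[nbins]
  # candidate threshold after bin t: classes {<=t}, {>t}
  w0 <- w[-nbins]; w1 <- total_w - w0
  mu0 <- m[-nbins] / w0
  mu1 <- (total_m - m[-nbins]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!is.finite(between)] <- -Inf
  # a plateau of maximizing thresholds (an empty gap between modes) is
  # resolved to its midpoint, keeping the threshold centred between modes
  maxv <- max(between)
  cand <- which(between >= maxv * (1 - 1e-12))
  threshold <- mean(edges[cand + 1L])
  below <- image <= threshold
  mask <- switch(seeds_are,
    below = below,
    above = !below,
    auto = {
      side <- function(mk) {
        sm <- label_components(mk, min_area = 1)
        c(n = sm$n_seeds,
          mean_area = if (sm$n_seeds) sum(sm$labels > 0) / sm$n_seeds else Inf)
      }
      a <- side(below); b <- side(!below)
      pick_below <- if (a["n"] != b["n"]) a["n"] > b["n"]
                    else a["mean_area"] <= b["mean_area"]
      if (pick_below) below else !below
    })
  list(threshold = threshold, mask = mask)
}

#' Label connected components of a binary mask
#'
#' 8-connected regions with at least `min_area` pixels are labelled
#' `1..n_seeds` in raster order of each region's first (topmost, then
#' leftmost) pixel; smaller regions are dropped to background.
#'
#' @param mask logical (or 0/1) matrix.
#' @param min_area minimum region area in pixels.
#' @return An object of class `seed_mask`: list with `labels` (integer
#'   matrix, 0 = background), `n_seeds`, `min_area`.
#' @export
label_components <- function(mask, min_area = 20) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  stack <- integer(nr * nc)  # linear (column-major) pixel indices
  # scan row-major (raster order): rows outer, columns inner
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] && labels[i, j] == 0L) {
        cur <- cur + 1L
        # depth-first flood fill, 8-connectivity
        labels[i, j] <- cur
        stack[1L] <- (j - 1L) * nr + i
        top <- 1L
        while (top > 0L) {
          lin <- stack[top]; top <- top - 1L
          pj <- (lin - 1L) %/% nr + 1L
          pi <- lin - (pj - 1L) * nr
          for (di in -1:1) for (dj in -1:1) {
            ni <- pi + di; nj <- pj + dj
            if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
                mask[ni, nj] && labels[ni, nj] == 0L) {
              labels[ni, nj] <- cur
              top <- top + 1L
              stack[top] <- (nj - 1L) * nr + ni
            }
          }
        }
      }
    }
  }
  if (cur > 0L) {
    areas <- tabulate(labels[labels > 0L], cur)
    keep <- which(areas >= min_area)
    # order kept regions by raster position of their first pixel;
    # row-major scan over t(labels) linearizes raster order
    scan <- as.vector(t(labels))
    first_pos <- vapply(keep, function(k) which(scan == k)[1], numeric(1))
    keep <- keep[order(first_pos)]
    remap <- integer(cur)
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    cur <- length(keep)
  }
  structure(list(labels = labels, n_seeds = cur, min_area = min_area),
            class = "seed_mask")
}

#' @export
print.seed_mask <- function(x, ...) {
  cat("seed_mask:", x$n_seeds, "region(s), min_area =", x$min_area, "px\n")
  invisible(x)
}

#' Mean spectrum per labelled seed region
#'
#' Row `i` of the result is the per-band mean of the calibrated cube over
#' the pixels of region `i`; pixels excluded by calibration (`NA`) are
#' skipped band-wise.
#'
#' @param cube a calibrated [hypercube()].
#' @param seeds a `seed_mask` from [label_components()].
#' @return A [spectra_table()] with one row per region (ids `"seed1"...`).
#' @export
extract_mean_spectra <- function(cube, seeds) {
  stopifnot(inherits(cube, "hypercube"), inherits(seeds, "seed_mask"))
  if (cube$kind != "calibrated")
    warning("extracting spectra from a non-calibrated cube")
  if (seeds$n_seeds == 0) stop("seed mask is empty")
  d <- dim(cube$values)
  flat <- matrix(cube$values, nrow = d[1] * d[2])   # pixels x bands
  lab <- as.vector(seeds$labels)
  idx <- lab > 0
  grp <- lab[idx]
  sums <- rowsum(ifelse(is.na(flat[idx, , drop = FALSE]), 0,
                        flat[idx, , drop = FALSE]), grp)
  cnts <- rowsum((!is.na(flat[idx, , drop = FALSE])) * 1, grp)
  means <- sums / cnts
  if (any(!is.finite(means)))
    stop("region with no valid pixels at some band after calibration masking")
  spectra_table(means, cube$wavelengths,
                sample_ids = paste0("seed", seq_len(seeds$n_seeds)),
                provenance = "roi-mean")
}

#' Trim a spectra table to a closed wavelength interval
#'
#' Keeps exactly the bands with `lo <= wavelength <= hi` (closed interval),
#' preserving order. Defaults drop the noisy spectral edges, restricting the
#' analysis to 420-982 nm.
#'
#' @param table a [spectra_table()].
#' @param lo,hi interval endpoints in nm (`lo < hi`).
#' @return A [spectra_table()].
#' @export
trim_wavelengths <- function(table, lo = 420, hi = 982) {
  stopifnot(inherits(table, "spectra_table"), lo < hi)
  keep <- which(table$wavelengths >= lo & table$wavelengths <= hi)
  if (!length(keep))
    stop("no band inside [", lo, ", ", hi, "] nm")
  out <- subset_spectra(table, bands = keep)
  out$provenance <- c(table$provenance, sprintf("trim[%g,%g]", lo, hi))
  out
}

#' One-call seed extraction from a calibrated cube
#'
#' Selects the reference plane (default 440 nm), thresholds it with
#' [otsu_threshold()], labels components and extracts per-seed mean spectra.
#'
#' @param cube a calibrated [hypercube()].
#' @param ref_nm reference wavelength for segmentation.
#' @param min_area minimum seed area in pixels.
#' @param seeds_are polarity flag, see [otsu_threshold()].
#' @return List with `seeds` (a `seed_mask`) and `table` (a
#'   [spectra_table()]).
#' @export
segment_seeds <- function(cube, ref_nm = 440, min_area = 20,
                          seeds_are = "auto") {
  plane <- select_band(cube, ref_nm)
  ot <- otsu_threshold(plane, seeds_are = seeds_are)
  seeds <- label_components(ot$mask, min_area = min_area)
  list(seeds = seeds, table = extract_mean_spectra(cube, seeds))
}
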