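#' Hypercube: rows x cols x bands image stack with a wavelength axis
#'
#' @param values numeric 3-D array (rows x cols x bands), sensor counts or
#'   percent reflectance.
#' @param wavelengths strictly increasing nm vector, length = `dim(values)[3]`.
#' @param kind one of `"raw"`, `"dark"`, `"white"`, `"calibrated"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, wavelengths,
                      kind = c("raw", "dark", "white", "calibrated")) {
  kind <- match.arg(kind)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("values must be a rows x cols x bands array")
  wavelengths <- as.numeric(wavelengths)
  if (dim(values)[3] != length(wavelengths))
    stop("band count (", dim(values)[3], ") != wavelength count (",
         length(wavelengths), ")")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(values = values, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat("hypercube (", x$kind, "): ", d[1], " x ", d[2], " px, ", d[3],
      " bands (", round(min(x$wavelengths), 1), "-",
      round(max(x$wavelengths), 1), " nm)\n", sep = "")
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

# ---- ENVI dialect I/O ------------------------------------------------------
# Plain-text .hdr + binary cube. Only the keys the pipeline needs are
# handled: samples (cols), lines (rows), bands, interleave (bsq/bil/bip),
# data type (4 = float32, 5 = float64), byte order, wavelength = {...}.

#' Write a hypercube in the ENVI layout
#'
#' Emits `<path>` (binary, band-sequential float32, little endian) and
#' `<path>.hdr` (text header carrying the wavelength list).
#'
#' @param cube a [hypercube()].
#' @param path data-file path; the header is written at `paste0(path, ".hdr")`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "data type = 4",
           "interleave = bsq",
           "byte order = 0",
           paste0("wavelength = {", paste(cube$wavelengths, collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # bsq: band planes in order; within a plane ENVI is row-major (pixel runs
  # along samples), so transpose each plane before writeBin
  for (b in seq_len(d[3])) {
    writeBin(as.vector(t(cube$values[, , b])), con, size = 4L,
             endian = "little")
  }
  invisible(path)
}

#' Read a hypercube from the ENVI layout
#'
#' @param path data-file path; the header is looked up at
#'   `paste0(path, ".hdr")` (or `path` with extension swapped to `.hdr`).
#' @param kind cube kind tag to attach, see [hypercube()].
#' @return A [hypercube()].
#' @export
read_envi <- function(path, kind = "raw") {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr_path)) stop("no ENVI header found for ", path)
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_key <- function(key) {
    m <- regmatches(txt, regexpr(paste0("(?im)^\\s*", key, "\\s*=\\s*([^\\n{]+)$"),
                                 txt, perl = TRUE))
    if (!length(m)) return(NA_character_)
    trimws(sub("^[^=]*=", "", m[1]))
  }
  ns <- as.integer(get_key("samples"))
  nl <- as.integer(get_key("lines"))
  nb <- as.integer(get_key("bands"))
  dtype <- as.integer(get_key("data type"))
  interleave <- tolower(get_key("interleave"))
  border <- get_key("byte order")
  endian <- if (!is.na(border) && as.integer(border) == 1) "big" else "little"
  wl_m <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt,
                                  perl = TRUE))
  if (!length(wl_m)) stop("header has no wavelength list")
  wl_body <- sub("^[^{]*\\{", "", sub("\\}$", "", wl_m[1]))
  wl <- as.numeric(trimws(strsplit(wl_body, ",")[[1]]))
  if (anyNA(c(ns, nl, nb)) || length(wl) != nb)
    stop("malformed ENVI header: ", hdr_path)
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type ", dtype))
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "numeric", n = ns * nl * nb, size = size,
                      endian = endian)
  if (length(raw_vals) != ns * nl * nb) stop("truncated ENVI data file")
  arr <- array(NA_real_, c(nl, ns, nb))
  if (identical(interleave, "bsq")) {
    a <- array(raw_vals, c(ns, nl, nb))       # sample fastest, then line
    arr <- aperm(a, c(2, 1, 3))
  } else if (identical(interleave, "bil")) {
    a <- array(raw_vals, c(ns, nb, nl))       # sample, band, line
    arr <- aperm(a, c(3, 1, 2))
  } else if (identical(interleave, "bip")) {
    a <- array(raw_vals, c(nb, ns, nl))       # band, sample, line
    arr <- aperm(a, c(3, 2, 1))
  } else {
    stop("unsupported interleave: ", interleave)
  }
  hypercube(arr, wl, kind = kind)
}
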