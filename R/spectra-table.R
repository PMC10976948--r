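#' Spectra table: samples x bands reflectance with a wavelength axis
#'
#' The central exchange object of the pipeline: a numeric matrix of
#' reflectance (percent, rows = samples) together with the wavelength (nm)
#' of every column, optional integer class labels (1 = green, 2 = yellow,
#' 3 = fully mature) and sample identifiers. A `provenance` character vector
#' records the processing steps the table has been through.
#'
#' @param reflectance numeric matrix, samples x bands.
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, length `ncol(reflectance)`.
#' @param labels optional integer class ids, length `nrow(reflectance)`.
#' @param sample_ids optional character ids; defaults to `"s1".."sn"`.
#' @param provenance character vector of processing-step tags.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(reflectance, wavelengths, labels = NULL,
                          sample_ids = NULL, provenance = character()) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(reflectance) != length(wavelengths))
    stop("column count (", ncol(reflectance), ") != wavelength count (",
         length(wavelengths), ")")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(reflectance) || any(!is.finite(reflectance)))
    stop("reflectance contains non-finite entries")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(reflectance))
      stop("labels length != sample count")
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("s", seq_len(nrow(reflectance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance))
    stop("sample_ids length != sample count")
  structure(list(reflectance = reflectance, wavelengths = wavelengths,
                 labels = labels, sample_ids = sample_ids,
                 provenance = as.character(provenance)),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat("spectra_table:", nrow(x$reflectance), "samples x",
      length(x$wavelengths), "bands (",
      round(min(x$wavelengths), 1), "-", round(max(x$wavelengths), 1), "nm )\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(sprintf("%d:%d", as.integer(names(table(x$labels))),
                                   as.integer(table(x$labels))),
                           collapse = "  "), "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectra_table <- function(x) dim(x$reflectance)

#' Subset a spectra table by sample and/or band
#'
#' @param x a [spectra_table()].
#' @param samples integer/logical index over rows, or character sample ids.
#' @param bands integer/logical index over bands.
#' @return A `spectra_table`.
#' @export
subset_spectra <- function(x, samples = NULL, bands = NULL) {
  stopifnot(inherits(x, "spectra_table"))
  if (is.null(samples)) samples <- seq_len(nrow(x$reflectance))
  if (is.character(samples)) samples <- match(samples, x$sample_ids)
  if (anyNA(samples)) stop("unknown sample ids")
  if (is.null(bands)) bands <- seq_along(x$wavelengths)
  spectra_table(x$reflectance[samples, bands, drop = FALSE],
                x$wavelengths[bands],
                labels = if (!is.null(x$labels)) x$labels[samples],
                sample_ids = x$sample_ids[samples],
                provenance = x$provenance)
}

#' Write / read a spectra table as CSV
#'
#' Layout: columns `sample_id`, `label` (empty when absent), then one column
#' per band whose header is the wavelength in nm. Processing provenance is
#' carried in a leading `#` comment line and restored on read.
#'
#' @param x a [spectra_table()].
#' @param path file path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a `spectra_table`.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_table"))
  df <- data.table::data.table(sample_id = x$sample_ids,
                               label = if (is.null(x$labels)) NA_integer_ else x$labels)
  mat <- data.table::as.data.table(x$reflectance)
  data.table::setnames(mat, as.character(x$wavelengths))
  df <- cbind(df, mat)
  writeLines(paste0("# provenance: ", paste(x$provenance, collapse = ";")),
             path)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  first <- readLines(path, n = 1L)
  prov <- character()
  if (startsWith(first, "# provenance:")) {
    tag <- trimws(sub("^# provenance:", "", first))
    if (nzchar(tag)) prov <- strsplit(tag, ";", fixed = TRUE)[[1]]
  }
  df <- data.table::fread(path, skip = if (startsWith(first, "#")) 1L else 0L)
  wl_cols <- setdiff(names(df), c("sample_id", "label"))
  labels <- df$label
  if (all(is.na(labels))) labels <- NULL
  spectra_table(as.matrix(df[, wl_cols, with = FALSE]),
                as.numeric(wl_cols), labels = labels,
                sample_ids = df$sample_id, provenance = prov)
}
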