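#' Read a 2-D image with optional b-value metadata
#'
#' Supported formats (by extension): NIfTI-1 (`.nii`, `.nii.gz`), PNG
#' (`.png`, via the png package; intensities are returned on the
#' \[0, 1\] scale PNG readers use), and plain CSV/TSV matrices (no
#' header). For 3-D NIfTI volumes, `slice` selects one slice. A b-value
#' is picked up from a JSON sidecar (`<path without extension>.json`,
#' field `bvalue`) when present, else from the `bvalue` argument.
#'
#' @param path File path.
#' @param slice Slice index for 3-D volumes (default 1).
#' @param bvalue Optional b-value when no sidecar exists.
#' @param allow_negative Negative pixels are an error unless this is
#'   TRUE, in which case they are clipped to 0 with a warning.
#' @return Numeric matrix with attribute `bvalue` (NA when unknown).
#' @export
read_image <- function(path, slice = 1L, bvalue = NULL,
                       allow_negative = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  img <- switch(
    ext,
    nii = {
      v <- RNifti::readNifti(path)
      a <- as.array(v)
      if (length(dim(a)) == 3) a <- a[, , slice]
      if (length(dim(a)) != 2) {
        stop("NIfTI payload is not 2-D after slice selection", call. = FALSE)
      }
      unclass(a)
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("the png package is required to read PNG images", call. = FALSE)
      }
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    tsv = as.matrix(utils::read.delim(path, header = FALSE)),
    dcm = stop("DICOM reading is not supported; convert to NIfTI first",
               call. = FALSE),
    stop("unknown image format: .", ext, call. = FALSE)
  )
  storage.mode(img) <- "double"
  dimnames(img) <- NULL
  if (any(img < 0)) {
    if (!allow_negative) {
      stop("image contains negative values (use allow_negative = TRUE ",
           "to clip at 0)", call. = FALSE)
    }
    warning("clipping ", sum(img < 0), " negative pixels to 0",
            call. = FALSE)
    img[img < 0] <- 0
  }
  side <- sub("\\.gz$", "", path)
  side <- sub("\\.[^.]*$", ".json", side)
  b <- NA_real_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta[["bvalue"]])) b <- as.numeric(meta[["bvalue"]])
  }
  if (is.na(b) && !is.null(bvalue)) b <- as.numeric(bvalue)
  attr(img, "bvalue") <- b
  img
}

#' Write a 2-D image (NIfTI, PNG, or CSV), with optional b-value sidecar
#'
#' @param img Numeric matrix.
#' @param path Destination; format from the extension (`.nii`/`.nii.gz`,
#'   `.png` — intensities must be in \[0, 1\] — or `.csv`).
#' @param bvalue Optional; when given, a JSON sidecar with the b-value is
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bvalue = NULL) {
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  switch(
    ext,
    nii = RNifti::writeNifti(RNifti::asNifti(img), path),
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("the png package is required to write PNG images",
             call. = FALSE)
      }
      png::writePNG(img, path)
    },
    csv = utils::write.table(img, path, sep = ",", row.names = FALSE,
                             col.names = FALSE),
    stop("unknown image format: .", ext, call. = FALSE)
  )
  if (!is.null(bvalue)) {
    side <- sub("\\.gz$", "", path)
    side <- sub("\\.[^.]*$", ".json", side)
    jsonlite::write_json(list(bvalue = bvalue), side, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a simulated series to disk
#'
#' One NIfTI stack (b index along the third dimension), a JSON sidecar
#' with b-values, seed and phantom parameters, and a CSV of the noiseless
#' per-compartment means.
#'
#' @param series A `dwmr_series`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"series"`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_series <- function(series, dir, stem = "series") {
  stopifnot(inherits(series, "dwmr_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- array(unlist(series$images),
               dim = c(dim(series$images[[1]]), length(series$images)))
  nii <- file.path(dir, paste0(stem, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(arr), nii)
  spec <- series$spec
  side <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(bvalues = spec$bvalues, seed = spec$seed,
         noise_sigma = spec$noise_sigma, shape = spec$shape,
         background = list(s0 = spec$background_s0,
                           adc = spec$background_adc),
         compartments = lapply(spec$compartments, unclass)),
    side, auto_unbox = TRUE, digits = NA)
  means <- file.path(dir, paste0(stem, "_noiseless_means.csv"))
  readr::write_csv(series_noiseless_means(series), means)
  invisible(c(image = nii, sidecar = side, means = means))
}

#' Write a metrics table as CSV
#'
#' Full-precision columns plus `*_display` companions rounded the way the
#' tables are usually printed (two decimals).
#'
#' @param table Metrics tibble (e.g. from [bvalue_scan()] or
#'   [sweep_smoothing_factor()]).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(table, path) {
  if (!nrow(table)) warning("writing an empty metrics table", call. = FALSE)
  out <- tibble::as_tibble(table)
  for (cl in intersect(c("signal_mean", "signal_sd", "snr", "cnr"),
                       names(out))) {
    out[[paste0(cl, "_display")]] <- round(out[[cl]], 2)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#'
#' @param path CSV path.
#' @return Tibble with the full-precision columns (display columns
#'   dropped).
#' @export
read_metrics_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out[, !grepl("_display$", names(out)), drop = FALSE]
}
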