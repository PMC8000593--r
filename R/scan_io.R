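#' Construct a raw whole-body scan
#'
#' A `raw_scan` holds one 16-bit whole-body acquisition: a rows-by-columns
#' matrix of non-negative counts (natively 1024 x 512) containing both
#' planar views. In the default `"side_by_side"` layout the anterior (AP)
#' view occupies the left half of the columns and the posterior (PA) view
#' the right half; a `"stacked"` layout (views in top/bottom halves of the
#' rows) is accepted for data recorded that way.
#'
#' @param pixels numeric or integer matrix of counts, all `>= 0`.
#' @param scan_id identifier string.
#' @param layout `"side_by_side"` (default) or `"stacked"`.
#' @return object of class `raw_scan`.
#' @export
raw_scan <- function(pixels, scan_id = "scan", layout = c("side_by_side", "stacked")) {
  layout <- match.arg(layout)
  if (!is.matrix(pixels)) stopf("scan pixels must be a matrix")
  if (any(pixels < 0)) stopf("scan counts must be non-negative")
  structure(list(pixels = pixels, scan_id = as.character(scan_id),
                 layout = layout, dims = dim(pixels)),
            class = "raw_scan")
}

#' @export
#' @method print raw_scan
print.raw_scan <- function(x, ...) {
  cat(sprintf("<raw_scan %s: %d x %d, layout %s, total counts %.0f>\n",
              x$scan_id, x$dims[1], x$dims[2], x$layout, sum(x$pixels)))
  invisible(x)
}

scan_dialect_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = "tiff",
         png = "png",
         raw = , bin = "raw16",
         dcm = "dicom",
         stopf("cannot infer scan dialect from extension '.%s' (%s)", ext, path))
}

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25)
  as.integer(hdr[25])  # IHDR bit-depth byte
}

#' Read a whole-body scan image
#'
#' Counts are preserved bit-exactly; no rescaling is applied. Supported
#' dialects: 16-bit (or 8-bit) single-channel TIFF and PNG, and `raw16`
#' (headerless little-endian unsigned 16-bit, row-major, dimensions given
#' by `dims`). The `dicom` dialect is declared for interoperability but is
#' not implemented in this build; 16-bit TIFF is the canonical interchange
#' format.
#'
#' @param path image file.
#' @param dialect `"auto"` (by extension), `"tiff"`, `"png"` or `"raw16"`.
#' @param dims frame dimensions (rows, cols) for `raw16`, default
#'   `c(1024, 512)`.
#' @param scan_id identifier; defaults to the file stem.
#' @param layout passed to [raw_scan()].
#' @return a [raw_scan()].
#' @export
read_scan <- function(path, dialect = c("auto", "tiff", "png", "raw16", "dicom"),
                      dims = c(1024L, 512L),
                      scan_id = tools::file_path_sans_ext(basename(path)),
                      layout = "side_by_side") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("cannot read scan: file not found: %s", path)
  if (dialect == "auto") dialect <- scan_dialect_from_path(path)
  pixels <- switch(dialect,
    tiff = {
      img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                      error = function(e) stopf("decode error for %s: %s", path, conditionMessage(e)))
      if (length(dim(img)) != 2) stopf("format error: %s is not single-channel grayscale", path)
      storage.mode(img) <- "integer"
      img
    },
    png = {
      depth <- png_bit_depth(path)
      if (!depth %in% c(8L, 16L)) stopf("format error: %s has unsupported bit depth %d", path, depth)
      img <- tryCatch(png::readPNG(path),
                      error = function(e) stopf("decode error for %s: %s", path, conditionMessage(e)))
      if (length(dim(img)) != 2) stopf("format error: %s is not single-channel grayscale", path)
      m <- round(img * (2^depth - 1))
      storage.mode(m) <- "integer"
      m
    },
    raw16 = {
      n <- prod(dims)
      info <- file.info(path)
      if (is.na(info$size) || info$size != 2 * n)
        stopf("format error: %s has %s bytes, expected %d for %d x %d raw16",
              path, info$size, 2 * n, dims[1], dims[2])
      v <- readBin(path, "integer", n = n, size = 2, signed = FALSE, endian = "little")
      matrix(v, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    },
    dicom = stopf("dicom dialect is not supported by this build; convert to 16-bit TIFF")
  )
  raw_scan(pixels, scan_id = scan_id, layout = layout)
}

#' Write a whole-body scan image
#'
#' Writes the counts losslessly (values are rounded half away from zero if
#' fractional, and must fit in 16 bits).
#'
#' @param scan a [raw_scan()] (or bare matrix).
#' @param path destination; dialect inferred from the extension unless given.
#' @param dialect `"auto"`, `"tiff"` or `"raw16"`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, dialect = c("auto", "tiff", "raw16")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- scan_dialect_from_path(path)
  pixels <- if (inherits(scan, "raw_scan")) scan$pixels else scan
  pixels <- round_half_away(pixels)
  if (any(pixels < 0) || any(pixels > 65535))
    stopf("scan counts outside [0, 65535] cannot be written as 16-bit")
  if (dialect == "tiff") {
    tiff::writeTIFF(pixels / 65535, path, bits.per.sample = 16L, compression = "none")
  } else {
    v <- as.integer(t(pixels))
    # writeBin stores the low 16 bits; values were range-checked above
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(v, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Write a fused three-channel chest image as 8-bit PNG
#'
#' @param fused a [fused_image()].
#' @param path destination `.png`.
#' @return `path`, invisibly.
#' @export
write_fused_png <- function(fused, path) {
  png::writePNG(fused$channels / 255, path)
  invisible(path)
}

#' Read a fused three-channel chest image from 8-bit PNG
#'
#' @param path `.png` file written by [write_fused_png()].
#' @param boxes optional box data frame to attach.
#' @param source_id identifier; defaults to the file stem.
#' @return a [fused_image()].
#' @export
read_fused_png <- function(path, boxes = empty_boxes(),
                           source_id = tools::file_path_sans_ext(basename(path))) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3)
    stopf("format error: %s is not a 3-channel image", path)
  ch <- round(arr[, , 1:3] * 255)
  storage.mode(ch) <- "integer"
  fused_image(ch, boxes = boxes, source_id = source_id)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with header
#' `image,label,patient_id,cohort,patient_positive`; one row per scan.
#' `patient_positive` is true iff the scan has at least one ground-truth
#' metastasis box. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest CSV.
#' @return data frame with an extra `dir` attribute for path resolution.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "label", "patient_id", "cohort", "patient_positive")
  if (!all(need %in% names(df)))
    stopf("manifest %s must have columns: %s", path, paste(need, collapse = ","))
  if (anyDuplicated(df$image) || anyDuplicated(df$label))
    stopf("manifest %s has duplicate paths", path)
  df$patient_positive <- as.logical(df$patient_positive)
  attr(df, "dir") <- dirname(path)
  df
}

#' Write a dataset manifest
#'
#' @param manifest data frame with the manifest columns.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("image", "label", "patient_id", "cohort", "patient_positive")
  write.csv(manifest[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
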