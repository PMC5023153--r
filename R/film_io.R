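#' Read a 48-bit RGB film scan from TIFF
#'
#' Accepts 16-bit-per-sample, 3-sample RGB TIFF files (uncompressed or
#' LZW), the format flatbed film scanners produce in transmission mode.
#' 8-bit input is rejected rather than silently upscaled. Pixel spacing is
#' taken from the TIFF resolution tag when present, otherwise from the
#' `dpi` argument; with neither available reading fails.
#'
#' @param path TIFF file path.
#' @param dpi fallback resolution when the file carries no resolution tag.
#' @param scanner_id scanner identifier recorded on the scan.
#' @return A [film_scan()].
#' @export
read_tiff_scan <- function(path, dpi = NULL, scanner_id = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits) || bits != 16) {
    stop("expected 16 bits per sample, got ",
         if (is.null(bits)) "unknown" else bits,
         " (8-bit scans are not upscaled)", call. = FALSE)
  }
  if (length(dim(img)) != 3 || dim(img)[3] < 3) {
    stop("expected a 3-channel RGB image", call. = FALSE)
  }
  xres <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit")
  file_dpi <- if (!is.null(xres) && (is.null(unit) || unit == "inch")) xres
  if (is.null(file_dpi) && is.null(dpi)) {
    stop("TIFF carries no resolution tag and no fallback dpi was given",
         call. = FALSE)
  }
  use_dpi <- if (!is.null(file_dpi)) file_dpi else dpi
  H <- dim(img)[1]; W <- dim(img)[2]
  px <- array(0L, c(3, H, W))
  for (k in 1:3) px[k, , ] <- as.integer(round(img[, , k] * 65535))
  film_scan(px, dpi = use_dpi, scanner_id = scanner_id)
}

#' Write a film scan to 16-bit TIFF
#'
#' @param scan a [film_scan()].
#' @param path output path.
#' @param compression `"none"` (default) or `"LZW"`.
#' @return `path`, invisibly.
#' @export
write_tiff_scan <- function(scan, path, compression = c("none", "LZW")) {
  stopifnot(inherits(scan, "film_scan"))
  compression <- match.arg(compression)
  d <- dim(scan$pixels)
  img <- array(0, c(d[2], d[3], 3))
  for (k in 1:3) img[, , k] <- scan$pixels[k, , ] / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = compression)
  invisible(path)
}

#' Extract a robust ROI response from a scan
#'
#' Returns the trimmed mean (central 80% of pixel values) of the normalized
#' channel values inside a rectangular region of interest. Rectangles are
#' 0-based, half-open `[r0, r1) x [c0, c1)` with the origin at the top-left
#' pixel; ROIs must cover at least 100 pixels so the trimmed mean is
#' meaningful against scanner noise and edge artifacts.
#'
#' @param scan a [film_scan()].
#' @param rectangle integer vector `c(r0, r1, c0, c1)`.
#' @param channel `"R"`, `"G"` or `"B"`.
#' @return Mean normalized response, a scalar in (0, 1].
#' @export
extract_roi_response <- function(scan, rectangle, channel) {
  stopifnot(inherits(scan, "film_scan"), length(rectangle) == 4)
  r0 <- rectangle[1]; r1 <- rectangle[2]
  c0 <- rectangle[3]; c1 <- rectangle[4]
  d <- dim(scan$pixels)
  if (r0 < 0 || c0 < 0 || r1 > d[2] || c1 > d[3] || r1 <= r0 || c1 <= c0) {
    stop("ROI rectangle outside image bounds or degenerate", call. = FALSE)
  }
  if ((r1 - r0) * (c1 - c0) < 100) {
    stop("ROI must cover at least 100 pixels (got ",
         (r1 - r0) * (c1 - c0), ")", call. = FALSE)
  }
  vals <- scan_channel_response(scan, channel)[(r0 + 1):r1, (c0 + 1):c1]
  mean(vals, trim = 0.1)
}

#' Read / write a dose plane as a plain-text matrix
#'
#' The exchange format for plan grids and reconstructed dose maps: a
#' 3-line header (`rows: <n>`, `cols: <n>`, `spacing_mm: <s>`) followed by
#' the row-major dose matrix in cGy with 2 decimal places. Writing then
#' reading reproduces the map within 0.005 cGy.
#'
#' @param map a [dose_map()] (or any object with `dose` and `spacing_mm`).
#' @param path file path.
#' @return `read_dose_plane()` returns a [dose_map()];
#'   `write_dose_plane()` returns `path` invisibly.
#' @export
write_dose_plane <- function(map, path) {
  stopifnot(is.matrix(map$dose), is.numeric(map$spacing_mm))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("rows: ", nrow(map$dose)),
               paste0("cols: ", ncol(map$dose)),
               paste0("spacing_mm: ", format(map$spacing_mm, digits = 17))),
             con)
  utils::write.table(format(round(map$dose, 2), nsmall = 2, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_plane
#' @export
read_dose_plane <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 4) stop("malformed dose plane file: ", path,
                              call. = FALSE)
  hdr <- function(i, key) {
    m <- regmatches(lines[i], regexec(paste0("^", key, ":\\s*(\\S+)$"),
                                      lines[i]))[[1]]
    if (length(m) != 2) {
      stop("malformed dose plane header (expected '", key, ": <value>'): ",
           lines[i], call. = FALSE)
    }
    as.numeric(m[2])
  }
  rows <- hdr(1, "rows"); cols <- hdr(2, "cols")
  spacing <- hdr(3, "spacing_mm")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != rows) {
    stop("dose plane body has ", length(body), " rows, header says ", rows,
         call. = FALSE)
  }
  vals <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  if (any(lengths(vals) != cols) || anyNA(unlist(vals))) {
    stop("dose plane body does not match header dimensions (", rows, " x ",
         cols, ")", call. = FALSE)
  }
  dose_map(matrix(unlist(vals), rows, cols, byrow = TRUE), spacing)
}

#' Read a workflow configuration file
#'
#' Run configuration is structured text (YAML) holding the calibration
#' coefficient file path, reference/calibration ROI rectangles, the
#' reference dose, gamma parameters and the simulator seed. Only light
#' validation is performed here; each consumer validates the fields it
#' uses.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed config file: ", path, call. = FALSE)
  cfg
}
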