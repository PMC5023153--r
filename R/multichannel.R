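#' Film scan container
#'
#' Holds a 48-bit RGB flatbed scan of radiochromic film as three 16-bit
#' channel planes plus the scan geometry. Pixel spacing is `25.4/dpi` mm.
#'
#' @param pixels integer array `c(3, H, W)` of channel values in
#'   `[0, 65535]`, channel order R, G, B.
#' @param dpi scan resolution in dots per inch (72 by default).
#' @param scanner_id free-text scanner identifier.
#' @param scan_time scan timestamp (`POSIXct` or text).
#' @return An object of class `film_scan`.
#' @export
film_scan <- function(pixels, dpi = 72, scanner_id = "unknown",
                      scan_time = Sys.time()) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[1] == 3,
            dim(pixels)[2] >= 1, dim(pixels)[3] >= 1, dpi > 0)
  if (min(pixels) < 0 || max(pixels) > 65535) {
    stop("channel values must lie in [0, 65535]", call. = FALSE)
  }
  structure(list(pixels = pixels, dpi = dpi,
                 spacing_mm = 25.4 / dpi,
                 scanner_id = scanner_id, scan_time = scan_time),
            class = "film_scan")
}

#' @export
print.film_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<film_scan> %d x %d px, %g dpi (%.4f mm/px), scanner '%s'\n",
              d[2], d[3], x$dpi, x$spacing_mm, x$scanner_id))
  invisible(x)
}

# normalized response plane of one channel, in (0, 1]
scan_channel_response <- function(scan, channel) {
  k <- match(match.arg(channel, c("R", "G", "B")), c("R", "G", "B"))
  scan$pixels[k, , ] / 65535
}

#' Dose map container
#'
#' A reconstructed (or planned) absolute dose plane in cGy on a regular
#' pixel grid, origin at the top-left pixel center.
#'
#' @param dose numeric `H x W` matrix of doses in cGy.
#' @param spacing_mm pixel spacing in mm.
#' @param mask optional logical `H x W` matrix flagging unreliable pixels
#'   (out-of-range responses, solver boundary hits); `TRUE` = flagged.
#' @return An object of class `dose_map`.
#' @export
dose_map <- function(dose, spacing_mm, mask = NULL) {
  stopifnot(is.matrix(dose), is.numeric(dose), spacing_mm > 0)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(dose), ncol(dose))
  stopifnot(is.logical(mask), all(dim(mask) == dim(dose)))
  structure(list(dose = dose, spacing_mm = spacing_mm, mask = mask),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf(
    "<dose_map> %d x %d px @ %.4f mm, dose [%.2f, %.2f] cGy, %d flagged px\n",
    nrow(x$dose), ncol(x$dose), x$spacing_mm,
    min(x$dose, na.rm = TRUE), max(x$dose, na.rm = TRUE), sum(x$mask)))
  invisible(x)
}

#' Project a dose map onto a coarser grid
#'
#' Block-averages a dose map by an integer factor, the standard projection
#' of a high-resolution film dose map onto the coarser grid of a treatment
#' planning system before comparison. Trailing rows/columns that do not
#' fill a complete block are dropped. Averaging over \eqn{f^2} film pixels
#' also suppresses per-pixel scanner noise by the same factor.
#'
#' @param map a [dose_map()].
#' @param factor integer downsampling factor (>= 1).
#' @return A [dose_map()] with spacing `factor *` the input spacing. A
#'   block is flagged in the output mask if any contributing pixel was
#'   flagged.
#' @export
project_dose_map <- function(map, factor) {
  stopifnot(inherits(map, "dose_map"), factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(map)
  H <- (nrow(map$dose) %/% factor) * factor
  W <- (ncol(map$dose) %/% factor) * factor
  block <- function(m) {
    m <- m[seq_len(H), seq_len(W), drop = FALSE]
    s1 <- colMeans(array(m, c(factor, H %/% factor, W)))       # rows
    t(colMeans(array(t(s1), c(factor, W %/% factor, H %/% factor))))  # cols
  }
  dose_map(block(map$dose), map$spacing_mm * factor,
           mask = block(map$mask * 1) > 0)
}

#' Single-channel dose reconstruction
#'
#' The traditional baseline: per-pixel closed-form inversion of one
#' channel's calibration curve. Responses outside the achievable interval
#' are clamped to the nearer domain boundary and the pixel is flagged in
#' the output mask.
#'
#' @param scan a [film_scan()].
#' @param curve the (session-rescaled) [calibration_curve()] for `channel`.
#' @param channel which color channel to invert (defaults to the curve's).
#' @return A [dose_map()].
#' @export
single_channel_dose <- function(scan, curve, channel = curve$channel) {
  stopifnot(inherits(scan, "film_scan"), inherits(curve, "calibration_curve"))
  if (channel != curve$channel) {
    stop("curve is for channel ", curve$channel, ", not ", channel,
         call. = FALSE)
  }
  x <- scan_channel_response(scan, channel)
  rng <- response_range(curve)
  flagged <- x < rng[1] | x > rng[2]
  x_cl <- pmin(pmax(x, rng[1]), rng[2])
  dose <- curve$c + curve$b / (x_cl - curve$a)
  dose_map(matrix(dose, nrow(x), ncol(x)), scan$spacing_mm,
           mask = matrix(flagged, nrow(x), ncol(x)))
}

# closed-form disturbance for fixed dose grid:
#   delta(D) = sum_k x_k X_k(D) / sum_k X_k(D)^2 - 1, clamped to +/- delta_max
# xm: n x 3 response matrix; Xk: 3-vector of model responses at one dose.
delta_at <- function(xm, Xk, delta_max) {
  d <- as.vector(xm %*% Xk) / sum(Xk^2) - 1
  pmin(pmax(d, -delta_max), delta_max)
}

# objective F(D, delta) = sum_k (x_k - (1+delta) X_k(D))^2, vectorized over
# pixels (rows of xm) with per-pixel doses D (same length as rows).
objective_at <- function(xm, curves, D, delta_max) {
  X <- vapply(curves, eval_response_raw, numeric(length(D)), dose = D)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  d <- rowSums(xm * X) / rowSums(X^2) - 1
  d <- pmin(pmax(d, -delta_max), delta_max)
  list(F = rowSums((xm - (1 + d) * X)^2), delta = d)
}

#' Solve one pixel of the triple-channel dose reconstruction
#'
#' Finds the dose `D` and multiplicative disturbance `delta` minimizing
#' \deqn{F(D, \Delta) = \sum_k [x_k - (1+\Delta) X_k(D)]^2}
#' over the dose domain and `|delta| <= delta_max`. For fixed `D` the
#' optimal disturbance has the closed form
#' \eqn{\Delta(D) = \sum_k x_k X_k(D) / \sum_k X_k(D)^2 - 1}; the outer 1-D
#' problem is solved on a dense dose grid followed by golden-section
#' refinement. Ties are broken toward the smaller dose.
#'
#' @param x_rgb numeric length-3 vector of measured normalized responses
#'   (R, G, B).
#' @param curves named list of three session [calibration_curve()]s.
#' @param delta_max disturbance bound (default 0.1).
#' @param grid_step dose grid step in cGy (default 0.5).
#' @param refine_tol dose refinement tolerance in cGy (default 0.01).
#' @return List with `dose` (cGy), `delta`, and `boundary` (logical: the
#'   minimizer sits on the dose-domain boundary).
#' @export
solve_pixel <- function(x_rgb, curves, delta_max = 0.1, grid_step = 0.5,
                        refine_tol = 0.01) {
  stopifnot(is.numeric(x_rgb), length(x_rgb) == 3)
  if (all(x_rgb == 0)) {
    stop("invalid pixel: all-zero channel triplet", call. = FALSE)
  }
  res <- solve_pixels(matrix(x_rgb, 1, 3), curves, delta_max = delta_max,
                      grid_step = grid_step, refine_tol = refine_tol)
  list(dose = res$dose[1], delta = res$delta[1], boundary = res$boundary[1])
}

# Vectorized triple-channel solve over n pixels. xm: n x 3 responses.
solve_pixels <- function(xm, curves, delta_max = 0.1, grid_step = 0.5,
                         refine_tol = 0.01) {
  stopifnot(is.matrix(xm), ncol(xm) == 3, length(curves) == 3)
  dom <- curves[[1]]$dose_domain
  for (cv in curves) stopifnot(all(cv$dose_domain == dom))
  n <- nrow(xm)
  grid <- seq(dom[1], dom[2], by = grid_step)
  if (grid[length(grid)] < dom[2]) grid <- c(grid, dom[2])
  bestF <- rep(Inf, n)
  bestD <- rep(dom[1], n)
  # ascending sweep with strict improvement => ties resolve to smaller dose
  for (D in grid) {
    Xk <- vapply(curves, eval_response_raw, numeric(1), dose = D)
    d <- delta_at(xm, Xk, delta_max)
    F <- rowSums((xm - outer(1 + d, Xk))^2)
    imp <- F < bestF
    bestF[imp] <- F[imp]
    bestD[imp] <- D
  }
  # vectorized golden-section refinement on [bestD - step, bestD + step]
  gr <- (sqrt(5) - 1) / 2
  lo <- pmax(bestD - grid_step, dom[1])
  hi <- pmin(bestD + grid_step, dom[2])
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- objective_at(xm, curves, x1, delta_max)$F
  f2 <- objective_at(xm, curves, x2, delta_max)$F
  while (max(hi - lo) > refine_tol) {
    left <- f1 <= f2   # <= keeps the left (smaller-dose) bracket on ties
    hi[left] <- x2[left]
    x2[left] <- x1[left]
    f2[left] <- f1[left]
    x1[left] <- hi[left] - gr * (hi[left] - lo[left])
    f1[left] <- objective_at(xm[left, , drop = FALSE], curves, x1[left],
                             delta_max)$F
    rt <- !left
    lo[rt] <- x1[rt]
    x1[rt] <- x2[rt]
    f1[rt] <- f2[rt]
    x2[rt] <- lo[rt] + gr * (hi[rt] - lo[rt])
    f2[rt] <- objective_at(xm[rt, , drop = FALSE], curves, x2[rt],
                           delta_max)$F
  }
  D <- (lo + hi) / 2
  # keep the grid optimum where refinement cannot improve on it
  fin <- objective_at(xm, curves, D, delta_max)
  keep_grid <- bestF < fin$F
  D[keep_grid] <- bestD[keep_grid]
  fin <- objective_at(xm, curves, D, delta_max)
  boundary <- D <= dom[1] + refine_tol | D >= dom[2] - refine_tol
  list(dose = D, delta = fin$delta, boundary = boundary)
}

#' Triple-channel dose reconstruction with disturbance correction
#'
#' Applies [solve_pixel()] to every pixel of a scan, jointly estimating the
#' absolute dose and the per-pixel multiplicative disturbance (film
#' thickness variation and similar dose-independent perturbations common to
#' the three channels).
#'
#' @param scan a [film_scan()].
#' @param curves named list of three session-rescaled [calibration_curve()]s
#'   (`R`, `G`, `B`). Pass raw lot curves only deliberately (no-protocol
#'   baseline).
#' @inheritParams solve_pixel
#' @return List with `dose` (a [dose_map()], mask = boundary/invalid pixels)
#'   and `disturbance` (class `disturbance_map`: matrix `delta`, same mask).
#' @export
triple_channel_dose <- function(scan, curves, delta_max = 0.1,
                                grid_step = 0.5, refine_tol = 0.01) {
  stopifnot(inherits(scan, "film_scan"))
  d <- dim(scan$pixels)
  H <- d[2]; W <- d[3]
  xm <- cbind(as.vector(scan$pixels[1, , ] / 65535),
              as.vector(scan$pixels[2, , ] / 65535),
              as.vector(scan$pixels[3, , ] / 65535))
  invalid <- rowSums(xm == 0) == 3
  res <- solve_pixels(xm, curves, delta_max = delta_max,
                      grid_step = grid_step, refine_tol = refine_tol)
  flagged <- res$boundary | invalid
  dosev <- res$dose
  dosev[invalid] <- NA_real_
  deltav <- res$delta
  deltav[invalid] <- NA_real_
  if (mean(flagged) > 0.05) {
    warning(sprintf("%.1f%% of pixels flagged (boundary or invalid)",
                    100 * mean(flagged)), call. = FALSE)
  }
  maskm <- matrix(flagged, H, W)
  list(
    dose = dose_map(matrix(dosev, H, W), scan$spacing_mm, mask = maskm),
    disturbance = structure(
      list(delta = matrix(deltav, H, W), mask = maskm),
      class = "disturbance_map"))
}

#' @export
print.disturbance_map <- function(x, ...) {
  cat(sprintf("<disturbance_map> %d x %d px, delta in [%+.4f, %+.4f]\n",
              nrow(x$delta), ncol(x$delta),
              min(x$delta, na.rm = TRUE), max(x$delta, na.rm = TRUE)))
  invisible(x)
}
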