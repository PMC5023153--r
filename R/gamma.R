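#' Gamma-test parameters
#'
#' @param dose_tol_percent dose-difference criterion, percent of the
#'   normalization dose (3 by default).
#' @param dta_mm distance-to-agreement criterion in mm (3 by default).
#' @param normalization `"global_max_of_reference"` (default) normalizes the
#'   dose criterion to the maximum of the reference (plan) map;
#'   `"fixed_value"` uses `normalization_value`.
#' @param normalization_value fixed normalization dose in cGy (used only for
#'   `normalization = "fixed_value"`).
#' @param low_dose_threshold_percent reference-dose threshold below which
#'   pixels are excluded from evaluation (percent of the normalization dose).
#' @param search_radius_factor search radius, in multiples of `dta_mm`.
#' @param interp_subdivisions reference interpolation factor (subdivisions
#'   per reference pixel).
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(dose_tol_percent = 3, dta_mm = 3,
                         normalization = c("global_max_of_reference",
                                           "fixed_value"),
                         normalization_value = NULL,
                         low_dose_threshold_percent = 10,
                         search_radius_factor = 3,
                         interp_subdivisions = 10) {
  normalization <- match.arg(normalization)
  stopifnot(dose_tol_percent > 0, dta_mm > 0, search_radius_factor > 0,
            interp_subdivisions >= 1,
            low_dose_threshold_percent >= 0, low_dose_threshold_percent < 100)
  if (normalization == "fixed_value") {
    stopifnot(is.numeric(normalization_value), normalization_value > 0)
  }
  structure(list(dose_tol_percent = dose_tol_percent, dta_mm = dta_mm,
                 normalization = normalization,
                 normalization_value = normalization_value,
                 low_dose_threshold_percent = low_dose_threshold_percent,
                 search_radius_factor = search_radius_factor,
                 interp_subdivisions = as.integer(interp_subdivisions)),
            class = "gamma_params")
}

# bilinear interpolation of matrix `mat` (grid spacing 1 between indices,
# 1-based) at fractional row/column index grids
bilinear_at <- function(mat, ri, ci) {
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- pmin(pmax(ri, 1), nr)
  ci <- pmin(pmax(ci, 1), nc)
  r0 <- pmin(floor(ri), nr - 1); c0 <- pmin(floor(ci), nc - 1)
  fr <- ri - r0; fc <- ci - c0
  idx <- function(r, c) mat[cbind(as.vector(r), as.vector(c))]
  R0 <- matrix(r0, length(ri), length(ci))
  C0 <- matrix(c0, length(ri), length(ci), byrow = TRUE)
  FR <- matrix(fr, length(ri), length(ci))
  FC <- matrix(fc, length(ri), length(ci), byrow = TRUE)
  v <- (1 - FR) * (1 - FC) * idx(R0, C0) +
       (1 - FR) * FC       * idx(R0, C0 + 1) +
       FR       * (1 - FC) * idx(R0 + 1, C0) +
       FR       * FC       * idx(R0 + 1, C0 + 1)
  v
}

# resample a dose_map to a target spacing over its own extent (bilinear)
resample_dose_map <- function(map, spacing_mm) {
  if (isTRUE(all.equal(map$spacing_mm, spacing_mm))) return(map)
  ext_r <- (nrow(map$dose) - 1) * map$spacing_mm
  ext_c <- (ncol(map$dose) - 1) * map$spacing_mm
  ri <- seq(0, ext_r, by = spacing_mm) / map$spacing_mm + 1
  ci <- seq(0, ext_c, by = spacing_mm) / map$spacing_mm + 1
  dose_map(bilinear_at(map$dose, ri, ci), spacing_mm)
}

#' Gamma-index comparison of a measured dose map against a reference
#'
#' Computes the per-pixel gamma index
#' \deqn{\gamma = \min_r \sqrt{ (\Delta d / \Delta D_{tol})^2 +
#'   (\Delta r / \mathrm{DTA})^2 }}
#' where the minimum runs over a search disk in the reference map,
#' interpolated bilinearly at `interp_subdivisions` per pixel, with
#' \eqn{\Delta D_{tol}} = `dose_tol_percent` of the normalization dose. The
#' search is limited to `search_radius_factor * dta_mm`. Pixels whose
#' reference dose is below `low_dose_threshold_percent` of the
#' normalization dose are excluded from evaluation. Both maps are assumed
#' aligned at the top-left pixel center; if the spacings differ the
#' reference is first resampled (bilinear) to the measured spacing.
#'
#' @param measured,reference [dose_map()] objects.
#' @param params a [gamma_params()].
#' @return An object of class `gamma_result`: `gamma` matrix (NA where not
#'   evaluated), `evaluated_mask`, `pass_fraction` (percent, full
#'   precision), and the parameters used.
#' @export
gamma_map <- function(measured, reference, params = gamma_params()) {
  stopifnot(inherits(measured, "dose_map"), inherits(reference, "dose_map"),
            inherits(params, "gamma_params"))
  norm_dose <- switch(params$normalization,
    global_max_of_reference = max(reference$dose, na.rm = TRUE),
    fixed_value = params$normalization_value)
  if (!is.finite(norm_dose) || norm_dose <= 0) {
    stop("normalization dose must be positive and finite", call. = FALSE)
  }
  reference <- resample_dose_map(reference, measured$spacing_mm)
  s <- measured$spacing_mm
  f <- params$interp_subdivisions
  Hr <- nrow(reference$dose); Wr <- ncol(reference$dose)
  Hm <- nrow(measured$dose);  Wm <- ncol(measured$dose)
  # overlap: measured pixel centers that fall inside the reference extent
  in_r <- seq_len(Hm) <= Hr
  in_c <- seq_len(Wm) <= Wr
  if (!any(in_r) || !any(in_c)) {
    stop("measured and reference maps do not overlap", call. = FALSE)
  }
  # fine reference grid, step s/f over the reference extent
  fine_r <- seq(1, Hr, by = 1 / f)
  fine_c <- seq(1, Wr, by = 1 / f)
  ref_fine <- bilinear_at(reference$dose, fine_r, fine_c)
  s_fine <- s / f

  threshold <- params$low_dose_threshold_percent / 100 * norm_dose
  eval_mask <- matrix(FALSE, Hm, Wm)
  eval_mask[in_r, in_c] <-
    reference$dose[seq_len(sum(in_r)), seq_len(sum(in_c))] >= threshold
  if (!any(eval_mask)) {
    stop("no pixels above the low-dose threshold to evaluate", call. = FALSE)
  }

  idx <- which(eval_mask, arr.ind = TRUE)
  meas <- measured$dose[idx]
  mrow <- (idx[, 1] - 1L) * f   # 0-based fine-grid positions
  mcol <- (idx[, 2] - 1L) * f

  # candidate displacements within the search disk, sorted by distance
  max_mm <- params$search_radius_factor * params$dta_mm
  kmax <- floor(max_mm / s_fine)
  dr <- rep(-kmax:kmax, times = 2 * kmax + 1)
  dc <- rep(-kmax:kmax, each = 2 * kmax + 1)
  dist2_mm <- (dr^2 + dc^2) * s_fine^2
  keep <- dist2_mm <= max_mm^2
  dr <- dr[keep]; dc <- dc[keep]; dist2_mm <- dist2_mm[keep]
  ord <- order(dist2_mm)
  d2term <- dist2_mm[ord] / params$dta_mm^2

  dose_tol <- params$dose_tol_percent / 100 * norm_dose
  g2 <- gamma_search_kernel(meas, as.integer(mrow), as.integer(mcol),
                            ref_fine, as.integer(dr[ord]),
                            as.integer(dc[ord]), d2term, 1 / dose_tol^2)
  gamma <- matrix(NA_real_, Hm, Wm)
  gamma[idx] <- sqrt(g2)
  structure(list(gamma = gamma, evaluated_mask = eval_mask,
                 pass_fraction = 100 * mean(gamma[idx] <= 1),
                 params = params, normalization_dose = norm_dose),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %.1f%% of %d evaluated pixels passing (%g%%/%g mm, norm %.1f cGy)\n",
    pass_rate(x), sum(x$evaluated_mask), x$params$dose_tol_percent,
    x$params$dta_mm, x$normalization_dose))
  invisible(x)
}

#' Gamma passing rate
#'
#' Percentage of evaluated pixels with gamma <= 1, reported to one decimal.
#'
#' @param result a `gamma_result` from [gamma_map()].
#' @return Passing rate in percent, rounded to 1 decimal place.
#' @export
pass_rate <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  n <- sum(result$evaluated_mask)
  if (n < 1) stop("no evaluated pixels", call. = FALSE)
  round(100 * mean(result$gamma[result$evaluated_mask] <= 1), 1)
}
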