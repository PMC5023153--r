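#' Flatbed scanner response model
#'
#' Scanner-to-scanner (and session-to-session) differences in absolute
#' film response are modelled as a per-channel affine map of the true
#' normalized response — a gain and an offset — plus additive pixel noise.
#' This is exactly the perturbation class the One-scan rescaling corrects.
#'
#' @param scanner_id free-text identifier.
#' @param gain length-3 multiplicative factors (R, G, B), all > 0.
#' @param offset length-3 additive response shifts (R, G, B).
#' @param noise_sd pixel noise standard deviation in response units (>= 0).
#' @param seed integer seed driving this scanner's noise stream.
#' @return An object of class `scanner_model`.
#' @export
scanner_model <- function(scanner_id, gain = c(1, 1, 1),
                          offset = c(0, 0, 0), noise_sd = 0,
                          seed = 20140129) {
  stopifnot(length(gain) == 3, all(gain > 0), length(offset) == 3,
            noise_sd >= 0)
  structure(list(scanner_id = scanner_id, gain = gain, offset = offset,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scanner_model")
}

#' Default cross-facility scanner perturbation
#'
#' A second-facility scanner whose absolute response differs from the
#' calibration scanner by a few percent per channel — enough to produce
#' multi-percent dose errors around 160 cGy when its scans are inverted
#' with the other scanner's calibration function, which is the failure mode
#' the One-scan protocol exists to fix.
#'
#' @inheritParams scanner_model
#' @return A [scanner_model()] with gain (0.97, 0.97, 0.98) and offset
#'   (+0.02, +0.02, +0.015).
#' @export
facility_b_scanner <- function(noise_sd = 0.002, seed = 20140129) {
  scanner_model("facility-B", gain = c(0.97, 0.97, 0.98),
                offset = c(0.02, 0.02, 0.015), noise_sd = noise_sd,
                seed = seed)
}

#' Synthetic EBT3-like lot calibration curves
#'
#' A plausible set of per-channel rational dose-response coefficients for a
#' radiochromic film lot read in transmission mode: the red channel is the
#' most sensitive at low dose, green intermediate with the widest dynamic
#' range at high dose, blue the least dose-sensitive. These synthetic
#' coefficients define the simulator's ground truth; they are not
#' measurements of any physical lot.
#'
#' @param lot_id lot identifier recorded on the curves.
#' @param dose_domain calibration validity interval in cGy.
#' @return Named list of three [calibration_curve()]s.
#' @export
default_lot_curves <- function(lot_id = "SIM-LOT-1",
                               dose_domain = c(0, 320)) {
  list(
    R = calibration_curve("R", a = 0.17, b = 45, c = -100, dose_domain,
                          lot_id = lot_id),
    G = calibration_curve("G", a = 0.30, b = 65, c = -180, dose_domain,
                          lot_id = lot_id),
    B = calibration_curve("B", a = 0.467, b = 52, c = -300, dose_domain,
                          lot_id = lot_id))
}

# separable Gaussian smoothing with edge renormalization; sd in pixels
gauss_smooth <- function(mat, sd_px) {
  if (sd_px <= 0) return(mat)
  smooth1 <- function(n) {
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sd_px)
    K / rowSums(K)
  }
  Kr <- smooth1(nrow(mat))
  Kc <- smooth1(ncol(mat))
  Kr %*% mat %*% t(Kc)
}

# smooth zero-mean random field scaled so max|field| = amplitude;
# correlation length is the Gaussian smoothing sd in mm
smooth_random_field <- function(shape, amplitude, corr_mm, spacing_mm) {
  if (amplitude == 0) return(matrix(0, shape[1], shape[2]))
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  z <- gauss_smooth(z, corr_mm / spacing_mm)
  z <- z - mean(z)
  z / max(abs(z)) * amplitude
}

#' Generate a three-level dose-painting VMAT-like phantom plan
#'
#' Builds a highly modulated planned dose grid: a wavy-edged treated field
#' over a low-dose bath, painted in three broad bands at ascending dose
#' levels with wavy (seed-dependent) boundaries and Gaussian-smoothed,
#' penumbra-like edges. The painted regions are deliberately wider than the
#' penumbra and distance-to-agreement scales, so each dose level contributes
#' genuine low-gradient area to a gamma comparison — a gamma test at 3 mm
#' DTA has no power over dose errors in pure-gradient regions. The highest
#' two levels together cover most of the field, as in a dose-escalation
#' painting plan. Deterministic given the seed.
#'
#' @param shape `c(H, W)` in pixels.
#' @param levels ascending dose levels in cGy for the nested regions
#'   (default 80/160/240).
#' @param spacing_mm pixel spacing in mm (default 25.4/72, i.e. 72 dpi).
#' @param bath_cGy out-of-field bath dose (default 10 cGy).
#' @param edge_sd_mm Gaussian edge smoothing in mm (default 2).
#' @param dose_domain calibration domain the plan must respect.
#' @param seed integer seed for the boundary modulation.
#' @return An object of class `phantom_plan` with fields `dose`,
#'   `spacing_mm`, `description`.
#' @export
make_vmat_pattern <- function(shape = c(200, 200), levels = c(80, 160, 240),
                              spacing_mm = 25.4 / 72, bath_cGy = 10,
                              edge_sd_mm = 2, dose_domain = c(0, 320),
                              seed = 20140129) {
  stopifnot(length(shape) == 2, all(shape >= 16), length(levels) == 3,
            all(diff(levels) > 0))
  if (any(levels < dose_domain[1]) || any(levels > dose_domain[2])) {
    stop("dose levels outside the calibration domain [", dose_domain[1],
         ", ", dose_domain[2], "] cGy", call. = FALSE)
  }
  withr::with_seed(seed, {
    H <- shape[1]; W <- shape[2]
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    yy <- matrix(seq_len(H) - cy, H, W)      # rows
    xx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)  # cols
    # wavy-edged treated field (rounded square, ~82% of the half-extent)
    half <- min(H, W) / 2
    th <- atan2(yy, xx)
    amp <- stats::runif(2, 0.015, 0.035)
    phs <- stats::runif(2, 0, 2 * pi)
    fmod <- 1 + amp[1] * sin(3 * th + phs[1]) + amp[2] * sin(5 * th + phs[2])
    p <- 8  # superellipse exponent: rounded-square field
    fhalf <- 0.88 * half
    in_field <- (abs(xx / (fhalf * fmod))^p + abs(yy / (fhalf * fmod))^p) <= 1
    # three painted bands: 15% / 42.5% / 42.5% of the field width, wavy
    # borders; the escalated levels dominate, as in a boost painting plan
    wamp <- stats::runif(2, 1.5, 3) / spacing_mm  # boundary waviness, px
    wfreq <- stats::runif(2, 1.5, 2.5) * 2 * pi / H
    wphs <- stats::runif(2, 0, 2 * pi)
    b1 <- -0.35 * 2 * fhalf + wamp[1] * sin(wfreq[1] * yy + wphs[1])
    b2 <-  0.1 * 2 * fhalf + wamp[2] * sin(wfreq[2] * yy + wphs[2])
    dose <- matrix(bath_cGy, H, W)
    dose[in_field] <- levels[1]
    dose[in_field & xx > b1] <- levels[2]
    dose[in_field & xx > b2] <- levels[3]
    dose <- gauss_smooth(dose, edge_sd_mm / spacing_mm)
    structure(list(dose = dose, spacing_mm = spacing_mm,
                   description = sprintf(
                     "3-level dose-painting pattern %d/%d/%d cGy over %g cGy bath",
                     levels[1], levels[2], levels[3], bath_cGy)),
              class = "phantom_plan")
  })
}

#' @export
print.phantom_plan <- function(x, ...) {
  cat(sprintf("<phantom_plan> %d x %d px @ %.4f mm: %s\n",
              nrow(x$dose), ncol(x$dose), x$spacing_mm, x$description))
  invisible(x)
}

#' Render a film scan of a planned dose distribution
#'
#' Inverts the measurement chain: per pixel and channel the recorded
#' response is
#' \deqn{X = g_k \, X_k(D) \, (1 + \Delta(r)) + o_k + \epsilon,}
#' with \eqn{X_k} the lot calibration curve, \eqn{(g_k, o_k)} the scanner's
#' affine response transform, \eqn{\Delta} a smooth multiplicative
#' disturbance field (film thickness variation), and \eqn{\epsilon} pixel
#' noise. Responses are quantized to 16 bits. Responses pushed outside
#' (0, 1] are clipped and counted; more than 1% clipped raises a warning.
#'
#' @param plan a [make_vmat_pattern()] plan (or any `phantom_plan`).
#' @param curves named list of three ground-truth [calibration_curve()]s.
#' @param scanner a [scanner_model()].
#' @param disturbance_amplitude maximum |delta| of the disturbance field.
#' @param disturbance_corr_mm correlation length of the field in mm.
#' @param seed integer seed; `NULL` draws from the current RNG stream
#'   (used by [render_strip_set()] for a shared stream across strips).
#' @return A [film_scan()]; the simulated disturbance field is attached as
#'   attribute `"disturbance"`.
#' @export
render_scan <- function(plan, curves, scanner,
                        disturbance_amplitude = 0,
                        disturbance_corr_mm = 10, seed = scanner$seed) {
  stopifnot(inherits(plan, "phantom_plan"), inherits(scanner, "scanner_model"),
            length(curves) == 3)
  render <- function() {
    H <- nrow(plan$dose); W <- ncol(plan$dose)
    delta <- smooth_random_field(c(H, W), disturbance_amplitude,
                                 disturbance_corr_mm, plan$spacing_mm)
    px <- array(0L, c(3, H, W))
    clipped <- 0L
    for (k in 1:3) {
      N <- eval_response(curves[[k]], plan$dose)
      X <- scanner$gain[k] * N * (1 + delta) + scanner$offset[k]
      if (scanner$noise_sd > 0) {
        X <- X + stats::rnorm(length(X), sd = scanner$noise_sd)
      }
      clipped <- clipped + sum(X <= 0 | X > 1)
      X <- pmin(pmax(X, 0), 1)
      px[k, , ] <- as.integer(round(X * 65535))
    }
    if (clipped > 0.01 * 3 * H * W) {
      warning(sprintf("%.1f%% of rendered responses clipped to (0, 1]",
                      100 * clipped / (3 * H * W)), call. = FALSE)
    }
    scan <- film_scan(px, dpi = 25.4 / plan$spacing_mm,
                      scanner_id = scanner$scanner_id)
    attr(scan, "disturbance") <- delta
    scan
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Render a set of uniform calibration/reference strips
#'
#' One uniform-dose strip per requested dose, all rendered with the same
#' scanner model and one shared noise stream seeded from the scanner seed,
#' emulating strips digitized together in a single scan frame.
#'
#' @param doses vector of strip doses in cGy.
#' @param curves named list of three ground-truth [calibration_curve()]s.
#' @param scanner a [scanner_model()].
#' @param strip_shape strip size in pixels, `c(H, W)`.
#' @param spacing_mm pixel spacing in mm.
#' @return Named list (by dose) of [film_scan()]s.
#' @export
render_strip_set <- function(doses, curves, scanner,
                             strip_shape = c(40, 60),
                             spacing_mm = 25.4 / 72) {
  dom <- curves[[1]]$dose_domain
  if (any(doses < dom[1]) || any(doses > dom[2])) {
    stop("strip doses outside the calibration domain", call. = FALSE)
  }
  withr::with_seed(scanner$seed, {
    strips <- lapply(doses, function(D) {
      plan <- structure(list(dose = matrix(D, strip_shape[1], strip_shape[2]),
                             spacing_mm = spacing_mm,
                             description = sprintf("uniform %g cGy strip", D)),
                        class = "phantom_plan")
      render_scan(plan, curves, scanner, disturbance_amplitude = 0,
                  seed = NULL)
    })
    names(strips) <- as.character(doses)
    strips
  })
}

#' Central ROI rectangle for a strip of given shape
#'
#' Returns the 0-based, half-open `c(r0, r1, c0, c1)` rectangle covering
#' the central part of a strip, keeping a fractional margin away from the
#' edges (where physical strips show cutting and handling artifacts).
#'
#' @param strip_shape `c(H, W)` in pixels.
#' @param margin fractional margin on each side (default 0.25).
#' @return Integer rectangle `c(r0, r1, c0, c1)`.
#' @export
strip_roi <- function(strip_shape, margin = 0.25) {
  H <- strip_shape[1]; W <- strip_shape[2]
  c(floor(H * margin), ceiling(H * (1 - margin)),
    floor(W * margin), ceiling(W * (1 - margin)))
}
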