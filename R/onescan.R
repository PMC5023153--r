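#' Reference-film measurement pair for One-scan rescaling
#'
#' The One-scan protocol scans the application film together with two
#' reference films from the same production lot: one unexposed and one
#' exposed to a known dose similar to the highest dose on the application
#' film (160 cGy by default). Their measured responses anchor the affine
#' rescaling of the generic calibration curve to the current scan session.
#'
#' @param response_zero measured normalized response of the unexposed strip.
#' @param response_ref measured normalized response of the exposed strip.
#' @param dose_ref known dose of the exposed strip in cGy (> 0).
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(response_zero, response_ref, dose_ref = 160) {
  stopifnot(is.numeric(response_zero), is.numeric(response_ref),
            is.numeric(dose_ref), dose_ref > 0)
  if (response_zero == response_ref) {
    stop("degenerate reference pair: the two strips have identical response",
         call. = FALSE)
  }
  structure(list(point_low = calibration_point(0, response_zero),
                 point_high = calibration_point(dose_ref, response_ref)),
            class = "reference_pair")
}

#' Compute One-scan rescaling parameters from two reference films
#'
#' The session-specific response is modelled as an affine map of the generic
#' normalized response, \eqn{X(D) = \alpha + \beta N(D)}. With two reference
#' measurements \eqn{(X_i, D_i)} and \eqn{N_i = N(D_i)} the parameters are
#' the unique solution of the 2x2 linear system:
#' \deqn{\beta = (X_1 - X_2)/(N_1 - N_2), \quad
#'       \alpha = (N_1 X_2 - N_2 X_1)/(N_1 - N_2).}
#'
#' @param generic the generic (lot-level) [calibration_curve()] for the same
#'   channel as the reference measurements.
#' @param refs a [reference_pair()].
#' @return An object of class `rescale_params` with fields `channel`,
#'   `alpha`, `beta`.
#' @export
compute_rescale <- function(generic, refs) {
  stopifnot(inherits(generic, "calibration_curve"),
            inherits(refs, "reference_pair"))
  N1 <- eval_response(generic, refs$point_low$dose)
  N2 <- eval_response(generic, refs$point_high$dose)
  if (abs(N1 - N2) < 1e-12) {
    stop("degenerate references: generic curve gives equal responses at ",
         "the two reference doses", call. = FALSE)
  }
  X1 <- refs$point_low$response
  X2 <- refs$point_high$response
  beta <- (X1 - X2) / (N1 - N2)
  alpha <- (N1 * X2 - N2 * X1) / (N1 - N2)
  structure(list(channel = generic$channel, alpha = alpha, beta = beta),
            class = "rescale_params")
}

#' @export
print.rescale_params <- function(x, ...) {
  cat(sprintf("<rescale_params> channel %s: alpha = %.6g, beta = %.6g\n",
              x$channel, x$alpha, x$beta))
  invisible(x)
}

#' Apply One-scan rescaling to a generic calibration curve
#'
#' The rational family is closed under affine response maps: for the
#' standard form, `a' = alpha + beta * a` and `b' = beta * b` with the pole
#' `c` unchanged. The rescaled curve must still satisfy the curve
#' invariants (finite, strictly decreasing on the dose domain), otherwise
#' the rescale is rejected.
#'
#' @param generic a [calibration_curve()].
#' @param params a `rescale_params` object from [compute_rescale()].
#' @return The session-specific [calibration_curve()].
#' @export
apply_rescale <- function(generic, params) {
  stopifnot(inherits(generic, "calibration_curve"),
            inherits(params, "rescale_params"))
  if (params$beta == 0) stop("invalid rescale: beta must be nonzero",
                             call. = FALSE)
  tryCatch(
    calibration_curve(generic$channel,
                      a = params$alpha + params$beta * generic$a,
                      b = params$beta * generic$b,
                      c = generic$c,
                      dose_domain = generic$dose_domain,
                      lot_id = generic$lot_id, form = generic$form),
    error = function(e) {
      stop("rescale rejected: ", conditionMessage(e), call. = FALSE)
    })
}

#' Rescale all three channel curves from reference-strip responses
#'
#' Convenience wrapper running [compute_rescale()] and [apply_rescale()]
#' independently per color channel, as the protocol prescribes.
#'
#' @param generics named list of generic curves (`R`, `G`, `B`).
#' @param refs named list of [reference_pair()]s, same names.
#' @return Named list of session-specific curves.
#' @export
rescale_channels <- function(generics, refs) {
  stopifnot(is.list(generics), is.list(refs),
            all(names(generics) %in% names(refs)))
  out <- lapply(names(generics), function(k) {
    apply_rescale(generics[[k]], compute_rescale(generics[[k]], refs[[k]]))
  })
  names(out) <- names(generics)
  out
}

#' Check the exposure-to-scan timing rule
#'
#' Radiochromic film continues to darken after exposure. When the
#' application and reference films are exposed within a time window `t`,
#' scanning must wait at least `4 t` after the last exposure to keep the
#' dose error from post-exposure intensification below 0.5%.
#'
#' @param exposure_window_minutes the exposure time window t (> 0), minutes.
#' @param exposure_to_scan_minutes elapsed time between (last) exposure and
#'   scanning, minutes.
#' @return A list with `ok` (logical), `required_minimum_minutes`, and the
#'   inputs. Violations are reported, not raised, so workflows can log them.
#' @export
check_timing <- function(exposure_window_minutes, exposure_to_scan_minutes) {
  stopifnot(is.numeric(exposure_window_minutes),
            is.numeric(exposure_to_scan_minutes))
  if (exposure_window_minutes <= 0) {
    stop("exposure window must be > 0 minutes", call. = FALSE)
  }
  if (exposure_to_scan_minutes < 0) {
    stop("exposure-to-scan delay cannot be negative", call. = FALSE)
  }
  minimum <- 4 * exposure_window_minutes
  list(ok = exposure_to_scan_minutes >= minimum,
       required_minimum_minutes = minimum,
       exposure_window_minutes = exposure_window_minutes,
       exposure_to_scan_minutes = exposure_to_scan_minutes)
}
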