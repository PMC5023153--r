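#' Construct a per-channel calibration curve
#'
#' A calibration curve maps absorbed dose (cGy) to the normalized scanner
#' response of one color channel of radiochromic film. Two equivalent
#' rational parameterisations are supported:
#'
#' * `"standard"`: \eqn{X(D) = a + b/(D - c)}, the form used for lot-level
#'   dose-response data. For a film-like (darkening) response the fitter and
#'   validator require `b > 0` and the pole `c` strictly below the dose
#'   domain, so the curve is finite and strictly decreasing on the domain.
#' * `"saturating"`: \eqn{X(D) = A + B D/(D + C)}. Internally this is the
#'   same rational family (`a = A + B`, `b = -B C`, `c = -C`), so curves can
#'   be converted losslessly between forms.
#'
#' @param channel one of `"R"`, `"G"`, `"B"`.
#' @param a,b,c coefficients of the standard form. `a` is the asymptotic
#'   response at infinite dose, `b` has units response*cGy, and `c` (cGy)
#'   locates the pole of the rational function.
#' @param dose_domain closed dose interval `c(D_min, D_max)` in cGy on which
#'   the curve is considered valid.
#' @param lot_id film production lot identifier.
#' @param form parameterisation to report the curve in; coefficients are
#'   always *supplied* as the standard-form `a`, `b`, `c`.
#' @return An object of class `calibration_curve`.
#' @seealso [eval_response()], [invert_response()], [fit_calibration()]
#' @export
calibration_curve <- function(channel, a, b, c, dose_domain, lot_id = "unknown",
                              form = c("standard", "saturating")) {
  form <- match.arg(form)
  channel <- match.arg(channel, c("R", "G", "B"))
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(dose_domain) == 2, dose_domain[1] < dose_domain[2],
            dose_domain[1] >= 0)
  curve <- structure(
    list(channel = channel, a = a, b = b, c = c,
         dose_domain = as.numeric(dose_domain), lot_id = lot_id, form = form),
    class = "calibration_curve")
  validate_curve(curve)
  curve
}

# Invariants: pole strictly below the domain and b > 0, so the response is
# finite and strictly decreasing over the whole dose domain.
validate_curve <- function(curve) {
  if (!(curve$c < curve$dose_domain[1])) {
    stop("invalid calibration curve: pole c = ", format(curve$c),
         " must lie strictly below the dose domain [",
         curve$dose_domain[1], ", ", curve$dose_domain[2], "] cGy",
         call. = FALSE)
  }
  if (curve$b <= 0) {
    stop("invalid calibration curve: b = ", format(curve$b),
         " must be > 0 for a response that decreases with dose",
         call. = FALSE)
  }
  invisible(curve)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> channel %s, lot %s (%s form)\n",
              x$channel, x$lot_id, x$form))
  if (x$form == "saturating") {
    p <- standard_to_saturating(x)
    cat(sprintf("  X(D) = %.5g + %.5g*D/(D + %.5g)\n", p$A, p$B, p$C))
  } else {
    cat(sprintf("  X(D) = %.5g + %.5g/(D - %.5g)\n", x$a, x$b, x$c))
  }
  cat(sprintf("  dose domain [%g, %g] cGy, response range [%.4f, %.4f]\n",
              x$dose_domain[1], x$dose_domain[2],
              eval_response(x, x$dose_domain[2]),
              eval_response(x, x$dose_domain[1])))
  invisible(x)
}

# A + B*D/(D+C) = (A+B) - B*C/(D+C): standard (a,b,c) = (A+B, -B*C, -C),
# hence A = a + b/c, B = -b/c, C = -c.
standard_to_saturating <- function(curve) {
  list(A = curve$a - curve$b / curve$c, B = curve$b / curve$c, C = -curve$c)
}

#' Evaluate the calibration response at a dose
#'
#' @param curve a [calibration_curve()].
#' @param dose dose(s) in cGy; must lie within the curve's dose domain.
#' @return Normalized response value(s), same length as `dose`.
#' @export
eval_response <- function(curve, dose) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(dose))
  out <- dose < curve$dose_domain[1] - 1e-9 | dose > curve$dose_domain[2] + 1e-9
  if (any(out)) {
    stop(sprintf("dose %g cGy outside the calibration domain [%g, %g] cGy",
                 dose[out][1], curve$dose_domain[1], curve$dose_domain[2]),
         call. = FALSE)
  }
  if (any(dose == curve$c)) {
    stop("dose coincides with the pole of the calibration function",
         call. = FALSE)
  }
  curve$a + curve$b / (dose - curve$c)
}

# Unchecked evaluation used by the pixel solvers on dense dose grids that are
# constructed to lie inside the domain.
eval_response_raw <- function(curve, dose) {
  curve$a + curve$b / (dose - curve$c)
}

#' Invert the calibration curve: response to dose
#'
#' Closed-form inverse of the rational calibration function,
#' \eqn{D = c + b/(X - a)}. Responses outside the achievable interval
#' (the responses at the domain endpoints) are an error; no clamping is
#' performed here.
#'
#' @param curve a [calibration_curve()].
#' @param response normalized response value(s).
#' @return Dose(s) in cGy.
#' @export
invert_response <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(response))
  rng <- response_range(curve)
  bad <- response < rng[1] - 1e-12 | response > rng[2] + 1e-12
  if (any(bad)) {
    stop(sprintf(
      "response %.6g outside the achievable interval [%.6g, %.6g]",
      response[bad][1], rng[1], rng[2]), call. = FALSE)
  }
  curve$c + curve$b / (response - curve$a)
}

# achievable response interval over the dose domain (curve is decreasing)
response_range <- function(curve) {
  c(eval_response(curve, curve$dose_domain[2]),
    eval_response(curve, curve$dose_domain[1]))
}

#' Create a calibration data point
#'
#' @param dose delivered dose in cGy (>= 0).
#' @param response dimensionless normalized pixel value in (0, 1]: mean ROI
#'   16-bit pixel value divided by 65535.
#' @return An object of class `calibration_point`.
#' @export
calibration_point <- function(dose, response) {
  stopifnot(is.numeric(dose), length(dose) == 1, dose >= 0,
            is.numeric(response), length(response) == 1,
            response > 0, response <= 1)
  structure(list(dose = dose, response = response),
            class = "calibration_point")
}

# exact solve of a + b/(D - c) through three (dose, response) points
solve_three_point <- function(D, X) {
  stopifnot(length(D) == 3, length(X) == 3)
  r <- (X[1] - X[2]) / (X[2] - X[3])
  num <- (D[2] - D[1]) * D[3] - r * (D[3] - D[2]) * D[1]
  den <- (D[2] - D[1]) - r * (D[3] - D[2])
  if (abs(den) < .Machine$double.eps * max(abs(D))) {
    stop("degenerate three-point configuration for the rational solve",
         call. = FALSE)
  }
  c_hat <- num / den
  b_hat <- (X[1] - X[2]) * (D[1] - c_hat) * (D[2] - c_hat) / (D[2] - D[1])
  a_hat <- X[1] - b_hat / (D[1] - c_hat)
  list(a = a_hat, b = b_hat, c = c_hat)
}

#' Fit a calibration curve to measured dose-response points
#'
#' Least-squares fit of the rational response function to measured
#' (dose, response) pairs, minimizing the sum of squared response residuals.
#' With exactly three distinct doses the exact algebraic interpolant is
#' returned. With more points, nonlinear least squares
#' (Levenberg-Marquardt, [minpack.lm::nlsLM()]) is run, initialized from the
#' exact three-point solve through the lowest, a middle, and the highest
#' dose point, which removes initialization sensitivity.
#'
#' Degenerate fits — a pole inside the dose domain, or a non-decreasing
#' curve — are rejected with an error rather than returned.
#'
#' @param points list of [calibration_point()]s (at least 3 distinct doses),
#'   or a data.frame with columns `dose` and `response`.
#' @param channel,lot_id metadata carried into the fitted curve.
#' @param form output parameterisation, see [calibration_curve()].
#' @param dose_domain dose validity interval for the fitted curve; defaults
#'   to the span of the calibration doses.
#' @return A fitted [calibration_curve()].
#' @export
fit_calibration <- function(points, channel = "R", lot_id = "unknown",
                            form = c("standard", "saturating"),
                            dose_domain = NULL) {
  form <- match.arg(form)
  df <- as_point_frame(points)
  if (length(unique(df$dose)) < 3) {
    stop("calibration requires at least 3 points with distinct doses (got ",
         length(unique(df$dose)), ")", call. = FALSE)
  }
  if (is.null(dose_domain)) dose_domain <- range(df$dose)
  ord <- order(df$dose)
  df <- df[ord, ]
  n <- nrow(df)
  # exact 3-point solve through lowest, middle, highest dose
  idx <- c(1L, as.integer(ceiling(n / 2)), n)
  if (length(unique(df$dose[idx])) < 3) idx <- match(unique(df$dose), df$dose)[1:3]
  start <- solve_three_point(df$dose[idx], df$response[idx])
  if (n > 3) {
    fit <- minpack.lm::nlsLM(
      response ~ a + b / (dose - c), data = df, start = start,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, maxiter = 500))
    start <- as.list(stats::coef(fit))
  }
  curve <- tryCatch(
    calibration_curve(channel, start$a, start$b, start$c,
                      dose_domain = dose_domain, lot_id = lot_id, form = form),
    error = function(e) {
      stop("calibration fit rejected: ", conditionMessage(e), call. = FALSE)
    })
  curve
}

as_point_frame <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("dose", "response") %in% names(points)))
    return(points[, c("dose", "response")])
  }
  stopifnot(is.list(points), length(points) >= 1)
  do.call(rbind, lapply(points, function(p) {
    stopifnot(inherits(p, "calibration_point"))
    data.frame(dose = p$dose, response = p$response)
  }))
}

#' Fit residual sum of squares of a curve on calibration points
#'
#' @inheritParams fit_calibration
#' @param curve a [calibration_curve()].
#' @return Sum of squared response residuals.
#' @export
calibration_rss <- function(curve, points) {
  df <- as_point_frame(points)
  sum((df$response - eval_response(curve, df$dose))^2)
}

#' Write / read calibration coefficients
#'
#' The coefficient file is structured text (YAML) holding the lot id and,
#' per channel, the form, coefficients and dose domain. Writing then reading
#' reproduces the curves exactly (coefficients are stored at full double
#' precision).
#'
#' @param curves a named list of [calibration_curve()]s (names `R`, `G`, `B`).
#' @param path file path.
#' @return `read_calibration()` returns the named list of curves;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(curves, path) {
  stopifnot(is.list(curves), length(curves) >= 1)
  lot <- unique(vapply(curves, function(cv) cv$lot_id, character(1)))
  stopifnot(length(lot) == 1)
  payload <- list(
    lot_id = lot,
    channels = lapply(curves, function(cv) {
      list(channel = cv$channel, form = cv$form,
           a = format(cv$a, digits = 17), b = format(cv$b, digits = 17),
           c = format(cv$c, digits = 17),
           dose_min = cv$dose_domain[1], dose_max = cv$dose_domain[2])
    }))
  yaml::write_yaml(payload, path, precision = 17)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("no such calibration file: ", path, call. = FALSE)
  payload <- yaml::read_yaml(path)
  if (is.null(payload$channels)) {
    stop("malformed calibration file (missing 'channels'): ", path,
         call. = FALSE)
  }
  curves <- lapply(payload$channels, function(ch) {
    calibration_curve(ch$channel, as.numeric(ch$a), as.numeric(ch$b),
                      as.numeric(ch$c), c(ch$dose_min, ch$dose_max),
                      lot_id = payload$lot_id, form = ch$form)
  })
  names(curves) <- vapply(curves, function(cv) cv$channel, character(1))
  curves
}
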