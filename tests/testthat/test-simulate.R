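test_that("phantom plan contains the three dose levels and the bath", {
  plan <- make_vmat_pattern(c(200, 200), seed = 1)
  d <- plan$dose
  expect_equal(dim(d), c(200, 200))
  # each level contributes a real plateau: many pixels within 1 cGy of it
  for (lev in c(10, 80, 160, 240)) {
    expect_gt(sum(abs(d - lev) < 1), 400)
  }
  expect_true(all(d >= 0 & d <= 320))
})

test_that("plan generation is bit-identical for the same seed", {
  p1 <- make_vmat_pattern(c(80, 80), seed = 77)
  p2 <- make_vmat_pattern(c(80, 80), seed = 77)
  p3 <- make_vmat_pattern(c(80, 80), seed = 78)
  expect_identical(p1$dose, p2$dose)
  expect_false(identical(p1$dose, p3$dose))
})

test_that("plan edges are smoothed: gradients are bounded by the edge width", {
  plan <- make_vmat_pattern(c(150, 150), seed = 2, edge_sd_mm = 2)
  gx <- abs(diff(plan$dose)) / plan$spacing_mm          # cGy per mm
  # a 2 mm Gaussian penumbra on a 230 cGy step cannot exceed ~46 cGy/mm
  expect_lt(max(gx), 230 / (sqrt(2 * pi) * 2) + 1)
  expect_gt(max(gx), 10)  # but the field edge is a genuine gradient
})

test_that("levels outside the calibration domain are rejected", {
  expect_error(make_vmat_pattern(levels = c(80, 160, 400)), "domain")
  expect_error(make_vmat_pattern(levels = c(160, 80, 240)))
})

test_that("rendering is deterministic and reproducible end to end", {
  lot <- default_lot_curves()
  plan <- make_vmat_pattern(c(50, 50), seed = 4)
  sc <- scanner_model("s", noise_sd = 0.002, seed = 4)
  s1 <- render_scan(plan, lot, sc, disturbance_amplitude = 0.02)
  s2 <- render_scan(plan, lot, sc, disturbance_amplitude = 0.02)
  expect_identical(s1$pixels, s2$pixels)
  expect_identical(attr(s1, "disturbance"), attr(s2, "disturbance"))
  # and the written TIFF is byte-identical
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_tiff_scan(s1, p1); write_tiff_scan(s2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("an ideal scanner renders the exact quantized lot response", {
  lot <- default_lot_curves()
  plan <- structure(list(dose = matrix(160, 20, 20), spacing_mm = 25.4 / 72,
                         description = "uniform"), class = "phantom_plan")
  sc <- scanner_model("ideal", noise_sd = 0, seed = 1)
  scan <- render_scan(plan, lot, sc)
  for (k in 1:3) {
    want <- as.integer(round(eval_response(lot[[k]], 160) * 65535))
    expect_true(all(scan$pixels[k, , ] == want))
  }
})

test_that("scanner gain and offset shift the rendered response affinely", {
  lot <- default_lot_curves()
  plan <- structure(list(dose = matrix(160, 20, 20), spacing_mm = 25.4 / 72,
                         description = "uniform"), class = "phantom_plan")
  sc <- facility_b_scanner(noise_sd = 0)
  scan <- render_scan(plan, lot, sc)
  for (k in 1:3) {
    want <- sc$gain[k] * eval_response(lot[[k]], 160) + sc$offset[k]
    expect_equal(unname(scan$pixels[k, 1, 1]) / 65535, want,
                 tolerance = 1 / 65535)
  }
})

test_that("pixel noise has the configured standard deviation", {
  lot <- default_lot_curves()
  plan <- structure(list(dose = matrix(100, 80, 80), spacing_mm = 25.4 / 72,
                         description = "uniform"), class = "phantom_plan")
  sc <- scanner_model("noisy", noise_sd = 0.002, seed = 6)
  scan <- render_scan(plan, lot, sc)
  for (k in 1:3) {
    s <- stats::sd(scan$pixels[k, , ] / 65535)
    expect_lt(abs(s - 0.002) / 0.002, 0.10)
  }
})

test_that("the disturbance field respects its amplitude and smoothness", {
  lot <- default_lot_curves()
  plan <- make_vmat_pattern(c(100, 100), seed = 7)
  sc <- scanner_model("s", noise_sd = 0, seed = 7)
  scan <- render_scan(plan, lot, sc, disturbance_amplitude = 0.02,
                      disturbance_corr_mm = 10)
  delta <- attr(scan, "disturbance")
  expect_equal(max(abs(delta)), 0.02)
  expect_lt(abs(mean(delta)), 0.005)
  # smooth: neighbouring pixels differ by far less than the amplitude
  expect_lt(max(abs(diff(delta))), 0.004)
})

test_that("strip sets invert and refit to the generating curves", {
  lot <- default_lot_curves()
  clean <- scanner_model("cal", noise_sd = 0, seed = 8)
  doses <- c(0, 80, 160, 320)
  strips <- render_strip_set(doses, lot, clean)
  roi <- strip_roi(c(40, 60))
  for (k in c("R", "G", "B")) {
    pts <- data.frame(
      dose = doses,
      response = vapply(strips, extract_roi_response, numeric(1),
                        rectangle = roi, channel = k))
    fit <- fit_calibration(pts, channel = k)
    expect_lt(abs(fit$a - lot[[k]]$a), 1e-3)
    expect_lt(abs(fit$b - lot[[k]]$b) / lot[[k]]$b, 1e-3)
    expect_lt(abs(fit$c - lot[[k]]$c) / abs(lot[[k]]$c), 1e-3)
  }
})

test_that("strip doses outside the calibration domain are rejected", {
  lot <- default_lot_curves()
  sc <- scanner_model("cal", noise_sd = 0, seed = 1)
  expect_error(render_strip_set(c(0, 400), lot, sc), "domain")
})

test_that("strip ROI responses feed the reference pair as measured", {
  lot <- default_lot_curves()
  sc <- facility_b_scanner(noise_sd = 0.002, seed = 9)
  strips <- render_strip_set(c(0, 160), lot, sc)
  roi <- strip_roi(c(40, 60))
  n0 <- extract_roi_response(strips[["0"]], roi, "R")
  n1 <- extract_roi_response(strips[["160"]], roi, "R")
  refs <- reference_pair(n0, n1, 160)
  expect_equal(refs$point_low$response, n0)
  expect_equal(refs$point_high$response, n1)
  # and the rescaled curve reproduces both measurements
  curve <- apply_rescale(lot$R, compute_rescale(lot$R, refs))
  expect_equal(eval_response(curve, 0), n0, tolerance = 1e-12)
  expect_equal(eval_response(curve, 160), n1, tolerance = 1e-12)
})

test_that("the full noiseless chain reproduces the plan at 100% passing", {
  lot <- default_lot_curves()
  plan <- make_vmat_pattern(c(80, 80), seed = 13)
  sc <- scanner_model("ideal", noise_sd = 0, seed = 13)
  scan <- render_scan(plan, lot, sc)
  rec <- triple_channel_dose(scan, lot)
  g <- gamma_map(rec$dose, dose_map(plan$dose, plan$spacing_mm))
  expect_equal(pass_rate(g), 100.0)
})

test_that("rescaling removes an affine response perturbation; raw inversion does not", {
  lot <- default_lot_curves()
  plan <- structure(list(dose = matrix(240, 30, 30), spacing_mm = 25.4 / 72,
                         description = "uniform"), class = "phantom_plan")
  sc_b <- facility_b_scanner(noise_sd = 0)
  scan <- render_scan(plan, lot, sc_b)
  strips <- render_strip_set(c(0, 160), lot, sc_b)
  roi <- strip_roi(c(40, 60))
  session <- lapply(c(R = "R", G = "G", B = "B"), function(k) {
    refs <- reference_pair(extract_roi_response(strips[["0"]], roi, k),
                           extract_roi_response(strips[["160"]], roi, k),
                           160)
    apply_rescale(lot[[k]], compute_rescale(lot[[k]], refs))
  })
  raw <- triple_channel_dose(scan, lot)
  fixed <- triple_channel_dose(scan, session)
  err_raw <- mean(abs(raw$dose$dose - 240))
  err_fixed <- mean(abs(fixed$dose$dose - 240))
  expect_gt(err_raw, 5)       # multi-percent systematic error uncorrected
  expect_lt(err_fixed, 0.5)   # removed by the session rescale
})
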