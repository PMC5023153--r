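# Independent oracles used across test files. These deliberately avoid the
# package's own numerical paths: plain loops and direct formula evaluation.

# reference curve used in most closed-form examples
example_curve <- function(domain = c(0, 400)) {
  calibration_curve("R", a = 0.20, b = 40, c = -50, dose_domain = domain,
                    lot_id = "TEST")
}

# brute-force minimizer of F(D, delta) on a rectangular grid
brute_force_pixel <- function(x_rgb, curves, d_grid, delta_grid) {
  best <- Inf; bestD <- NA; bestDelta <- NA
  X <- sapply(curves, function(cv) cv$a + cv$b / (d_grid - cv$c))
  for (j in seq_along(delta_grid)) {
    Fj <- rowSums((matrix(x_rgb, length(d_grid), 3, byrow = TRUE) -
                   (1 + delta_grid[j]) * X)^2)
    i <- which.min(Fj)
    if (Fj[i] < best) {
      best <- Fj[i]; bestD <- d_grid[i]; bestDelta <- delta_grid[j]
    }
  }
  c(dose = bestD, delta = bestDelta)
}

# exhaustive all-pairs gamma on small maps: no search kernel, no shared code.
# Upsamples the reference by `sub` with its own bilinear interpolation.
brute_force_gamma <- function(meas, ref, spacing, dose_tol, dta,
                              radius_mm, sub = 10) {
  Hr <- nrow(ref); Wr <- ncol(ref)
  fine_n_r <- (Hr - 1) * sub + 1
  fine_n_c <- (Wr - 1) * sub + 1
  fine <- matrix(NA_real_, fine_n_r, fine_n_c)
  for (i in seq_len(fine_n_r)) {
    ri <- 1 + (i - 1) / sub
    r0 <- min(floor(ri), Hr - 1); fr <- ri - r0
    for (j in seq_len(fine_n_c)) {
      ci <- 1 + (j - 1) / sub
      c0 <- min(floor(ci), Wr - 1); fc <- ci - c0
      fine[i, j] <- (1 - fr) * (1 - fc) * ref[r0, c0] +
        (1 - fr) * fc * ref[r0, c0 + 1] +
        fr * (1 - fc) * ref[r0 + 1, c0] +
        fr * fc * ref[r0 + 1, c0 + 1]
    }
  }
  s_fine <- spacing / sub
  g <- matrix(NA_real_, nrow(meas), ncol(meas))
  for (i in seq_len(nrow(meas))) {
    for (j in seq_len(ncol(meas))) {
      p_r <- (i - 1) * sub + 1
      p_c <- (j - 1) * sub + 1
      best <- Inf
      for (fi in seq_len(fine_n_r)) {
        for (fj in seq_len(fine_n_c)) {
          dist2 <- ((fi - p_r)^2 + (fj - p_c)^2) * s_fine^2
          if (dist2 > radius_mm^2) next
          gg <- ((fine[fi, fj] - meas[i, j]) / dose_tol)^2 + dist2 / dta^2
          if (gg < best) best <- gg
        }
      }
      g[i, j] <- sqrt(best)
    }
  }
  g
}

# smooth dose field with gradients, all values well above a 10% threshold
gamma_test_field <- function(n) {
  x <- seq(0, 1, length.out = n)
  120 + 80 * outer(sin(pi * x), cos(pi * x)) + 20 * outer(x, x)
}

# small uniform scan built directly from integer pixel values
uniform_scan <- function(value_rgb, H = 20, W = 20, dpi = 72) {
  px <- array(0L, c(3, H, W))
  for (k in 1:3) px[k, , ] <- as.integer(value_rgb[k])
  film_scan(px, dpi = dpi)
}
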