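test_that("peak tracking measures width, amplitude and drift across an array", {
  one <- make_fid(line_spec(0.5, 1, 2), n_points = 8192, dwell = 4e-4)
  sp <- fourier_transform(one, 16384)
  tp <- track_peak(sp)
  expect_equal(tp$fwhm_hz, 2, tolerance = 0.02 * 2)
  # amplitude scales linearly
  sp2 <- sp; sp2$data <- sp2$data * 3.5
  expect_equal(track_peak(sp2)$amplitude / tp$amplitude, 3.5, tolerance = 1e-9)
  # a drifting line is tracked exactly on the grid (drift = 2 grid steps)
  step_ppm <- (1 / (16384 * 4e-4)) / 500
  drift_ppm <- 2 * step_ppm * (0:4)
  rows <- do.call(rbind, lapply(drift_ppm, function(d)
    make_fid(line_spec(0.5 + d, 1, 2), n_points = 8192, dwell = 4e-4)$data))
  spd <- fourier_transform(fid_set(rows, 4e-4, 500), 16384)
  pos <- track_peak(spd)$position_ppm
  expect_equal(diff(pos), diff(0.5 + drift_ppm), tolerance = 1e-6)
  # below-threshold increments yield NA, not errors
  weak <- spd; weak$data[3, ] <- weak$data[3, ] * 1e-6
  tpw <- track_peak(weak, threshold = 0.5 * max(Re(weak$data)))
  expect_true(is.na(tpw$position_ppm[3]))
  expect_false(anyNA(tpw$position_ppm[-3]))
})

test_that("temperature change inverts the printed calibration coefficients", {
  # TSP: +1.14e-2 ppm shift is exactly +1 K
  tsp <- temperature_calibration("tsp")
  expect_equal(estimate_temperature_change(c(4.70, 4.70 + 1.14e-2), tsp)[2], 1)
  # HDO: +2.97e-4 ppm is +1 K
  hdo <- temperature_calibration("hdo")
  expect_equal(estimate_temperature_change(c(4.70, 4.70 + 2.97e-4), hdo)[2], 1)
  expect_equal(estimate_temperature_change(c(4.7, 4.7), hdo)[2], 0)
  # exactly linear in the displacement
  d <- c(0, 1e-4, 5e-4, -3e-4)
  dt <- estimate_temperature_change(4.7 + d, hdo)
  expect_equal(estimate_temperature_change(4.7 + 3 * d, hdo), 3 * dt, tolerance = 1e-12)
})

test_that("phase deviation is recovered from dispersion-mode excursions", {
  base <- make_fid(line_spec(0, 1, 8), n_points = 4096, dwell = 4e-4)
  sp <- fourier_transform(base, 8192)
  expect_lt(abs(estimate_phase_deviation(sp)), 0.01)
  for (phi in c(2, 5, 10)) {
    est <- estimate_phase_deviation(phase_spectra(sp, phi, 0))
    expect_lt(abs(est - phi), 0.5)
  }
  # odd symmetry
  p <- estimate_phase_deviation(phase_spectra(sp, 7, 0))
  m <- estimate_phase_deviation(phase_spectra(sp, -7, 0))
  expect_equal(p, -m, tolerance = 0.02)
  # brute-force oracle over |phi| <= 20 degrees
  for (phi in seq(-20, 20, by = 5)) {
    est <- estimate_phase_deviation(phase_spectra(sp, phi, 0))
    expect_lt(abs(est - phi), 0.2)
  }
})

test_that("integration removes baseline tilt and normalises on request", {
  fid <- make_fid(line_spec(0, 2, 0, 3), n_points = 4096, dwell = 4e-4)
  sp <- fourier_transform(fid)
  ppm <- axis_ppm(sp)
  # pure linear baseline integrates to zero after tilt correction
  lin <- sp
  lin$data[1, ] <- complex(real = 4 + 2 * seq(-1, 1, length.out = length(ppm)))
  off_region <- list(c(1.2, 2.2))
  expect_equal(unname(integrate_regions(lin, off_region)[1, 1]), 0, tolerance = 1e-10)
  # a Lorentzian integrated over +-20 linewidths matches the closed form:
  # the full-spectrum integral is A * SW / (2 sfrq) ppm, of which the
  # +-20 lw window captures (2/pi) atan(40)
  lor <- make_fid(line_spec(0, 2, 3), n_points = 4096, dwell = 4e-4)
  spl <- fourier_transform(lor)
  w20 <- 20 * 3 / spl$sfrq
  got <- integrate_regions(spl, list(c(-w20, w20)), tilt_correction = FALSE)[1, 1]
  expected <- 2 * (1 / lor$dwell) / (2 * spl$sfrq) * (2 / pi) * atan(40)
  expect_equal(unname(got), expected, tolerance = 0.01)
  # normalisation pins the chosen region
  two <- make_fid(list(line_spec(-1, 1, 0, 3), line_spec(1, 3, 0, 3)),
                  n_points = 4096, dwell = 4e-4)
  spt <- fourier_transform(two)
  tab <- integrate_regions(spt, list(c(-1.6, -0.4), c(0.4, 1.6)),
                           normalize_region = 1, normalize_value = 100)
  expect_equal(unname(tab[1, 1]), 100)
  expect_equal(unname(tab[1, 2]), 300, tolerance = 0.01)
})

test_that("binning conserves total intensity at every width", {
  dd <- mixture_set(n_points = 1024)
  sp <- fourier_transform(dd$fid)
  total <- rowSums(Re(sp$data))
  for (w in c(0.04, 0.1, 1)) {
    b <- bin_spectra(sp, w)
    expect_equal(rowSums(b$matrix), total, tolerance = 1e-10)
  }
  full <- bin_spectra(sp, diff(range(axis_ppm(sp))) * 1.01)
  expect_equal(ncol(full$matrix), 1)
  n_wide <- ncol(bin_spectra(sp, 0.08)$matrix)
  n_half <- ncol(bin_spectra(sp, 0.04)$matrix)
  expect_lte(abs(n_half - 2 * n_wide), 1)
})

test_that("alignment undoes constructed shifts and reduces dispersion", {
  fid <- make_fid(list(line_spec(-1, 1, 3), line_spec(1, 0.6, 3)),
                  n_points = 2048, dwell = 4e-4)
  base <- fourier_transform(fid)
  # majority of increments unshifted so the median target is the truth
  shifts <- c(0, 0, 0, 7, -5)
  rows <- do.call(rbind, rep(list(base$data), 5))
  spm <- spectrum_set(rows, base$axis_hz, base$sfrq)
  shifted <- align_spectra(spm, shifts = shifts)
  # manual zero shift is the identity
  expect_identical(align_spectra(spm, shifts = rep(0, 5))$data, spm$data)
  # auto alignment recovers the inverse shifts exactly (noiseless)
  undone <- align_spectra(shifted, max_shift = 12)
  expect_equal(as.vector(undone$meta$align_shifts), -shifts)
  rms <- function(s) {
    med <- apply(Re(s$data), 2, median)
    sqrt(mean(sweep(Re(s$data), 2, med)^2))
  }
  expect_lt(rms(undone), rms(shifted))
})
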