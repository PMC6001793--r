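test_that("zero-fill pads, truncates and is idempotent", {
  fid <- make_fid(line_spec(0, 1, 2), n_points = 256, dwell = 1e-4)
  expect_identical(zero_fill(fid, 256)$data, fid$data)
  zf <- zero_fill(fid, 512)
  expect_identical(zf$data[, 1:256, drop = FALSE], fid$data)
  expect_true(all(zf$data[, 257:512] == 0))
  expect_identical(zero_fill(zf, 512)$data, zf$data)
  expect_identical(zero_fill(fid, 128)$data, fid$data[, 1:128, drop = FALSE])
  # truncating a slowly-decaying line spreads energy into sinc wiggles
  slow <- make_fid(line_spec(0, 1, 0.2), n_points = 4096, dwell = 4e-4)
  sp_full <- fourier_transform(slow)
  sp_trunc <- fourier_transform(zero_fill(slow, 512), 4096)
  re_f <- Re(sp_full$data[1, ]); re_t <- Re(sp_trunc$data[1, ])
  expect_lt(min(re_t), min(re_f))               # truncation deepens the wiggles
  expect_lt(min(re_t), -0.01 * max(re_t))
})

test_that("apodisation has unit weight at t = 0 and the stated FWHM effect", {
  fid <- make_fid(line_spec(0.5, 1, 3), n_points = 512, dwell = 1e-4)
  expect_identical(apodise(fid, apod_params(0, 0))$data, fid$data)
  expect_equal(apod_weights(0, apod_params(12, 7)), 1)
  cf <- fid_set(matrix(rep(1 + 0i, 8192), 1), dwell = 4e-4, sfrq = 500)
  spl <- fourier_transform(apodise(cf, apod_params(2, 0)), 16384)
  expect_equal(measure_fwhm(spl), 2, tolerance = grid_step_hz(spl))
  spg <- fourier_transform(apodise(cf, apod_params(0, 2)), 16384)
  expect_equal(measure_fwhm(spg), 2, tolerance = grid_step_hz(spg))
})

test_that("Lorentzian apodisation is additive in lw", {
  fid <- make_fid(line_spec(0.5, 1, 3), n_points = 512, dwell = 1e-4)
  a <- apodise(apodise(fid, apod_params(1.5, 0)), apod_params(2.5, 0))
  b <- apodise(fid, apod_params(4, 0))
  expect_equal(a$data, b$data, tolerance = 1e-14)
})

test_that("Fourier transform is linear, energy-conserving and peaks correctly", {
  n <- 1024; dw <- 1e-4
  f0 <- 1250  # on-grid: 1250 = 128 * (1/dw)/1024
  t <- (0:(n - 1)) * dw
  x <- fid_set(matrix(exp(2i * pi * f0 * t), 1), dw, 500)
  sp <- fourier_transform(x)
  expect_equal(sp$axis_hz[which.max(abs(sp$data[1, ]))], f0)
  z <- fid_set(matrix(0 + 0i, 1, 64), dw, 500)
  expect_true(all(fourier_transform(z)$data == 0))
  a <- make_fid(line_spec(-1, 1, 4, phase_deg = 20), n_points = n, dwell = dw)
  b <- make_fid(line_spec(1.3, 0.5, 2), n_points = n, dwell = dw)
  ab <- fid_set(a$data + b$data, dw, 500)
  lin <- fourier_transform(a)$data + fourier_transform(b)$data
  expect_equal(fourier_transform(ab)$data, lin, tolerance = 1e-12)
  # Parseval with the first point halved
  xh <- a$data[1, ]; xh[1] <- xh[1] / 2
  expect_equal(sum(abs(fourier_transform(a)$data)^2), n * sum(abs(xh)^2),
               tolerance = 1e-10)
})

test_that("FT and save_as_fid are inverse operations", {
  dd <- mixture_set(n_points = 512)
  sp <- fourier_transform(dd$fid)
  back <- save_as_fid(sp)
  expect_equal(back$data, dd$fid$data, tolerance = 1e-12)
  expect_equal(fourier_transform(back)$data, sp$data, tolerance = 1e-10)
  # real-only reconstruction by conjugate symmetry on a decayed line
  f3 <- make_fid(line_spec(0, 1, 20), n_points = 4096, dwell = 2e-4)
  sp3 <- fourier_transform(f3)
  back3 <- save_as_fid(sp3, real_only = TRUE)
  expect_equal(abs(fourier_transform(back3)$data), abs(sp3$data), tolerance = 1e-8)
})

test_that("phasing identities: zero phase, pivot invariance, dispersion to absorption", {
  fid <- make_fid(line_spec(0, 1, 2), n_points = 4096, dwell = 4e-4)
  sp <- fourier_transform(fid)
  expect_equal(phase_spectra(sp, 0, 0)$data, sp$data, tolerance = 1e-15)
  j <- which.max(abs(sp$data[1, ]))
  for (ph1 in c(-90, 30, 180)) {
    ph <- phase_spectra(sp, 0, ph1, pivot_hz = sp$axis_hz[j])
    expect_equal(ph$data[1, j], sp$data[1, j], tolerance = 1e-12)
  }
  disp <- fourier_transform(make_fid(line_spec(0, 1, 2, phase_deg = -90),
                                     n_points = 4096, dwell = 4e-4))
  absd <- phase_spectra(disp, 90, 0)
  re <- Re(absd$data[1, ]); jj <- which.max(re)
  expect_equal(re[(jj - 1):(jj - 40)], re[(jj + 1):(jj + 40)], tolerance = 1e-8)
})

test_that("autophase recovers injected misphasing within a degree", {
  f3 <- make_fid(list(line_spec(-1.5, 1, 2), line_spec(0.3, 0.7, 2),
                      line_spec(1.8, 0.5, 2)), n_points = 4096, dwell = 4e-4)
  sp <- fourier_transform(f3, 8192)
  ph <- autophase(sp)$meta$autophase
  expect_lt(abs(ph[1, "ph0"]), 1)
  expect_lt(abs(ph[1, "ph1"]), 1)
  mis <- phase_spectra(sp, -30, -40)
  est <- autophase(mis)$meta$autophase
  expect_lt(abs(est[1, "ph0"] - 30), 1)
  expect_lt(abs(est[1, "ph1"] - 40), 1)
  # global mode applies one phase pair to all increments
  arr <- fid_set(rbind(f3$data, f3$data), 4e-4, 500)
  marr <- phase_spectra(fourier_transform(arr, 8192), -20, 0)
  ga <- autophase(marr, mode = "global")$meta$autophase
  expect_equal(ga[1, ], ga[2, ])
  expect_warning(autophase(fourier_transform(fid_set(matrix(0i, 1, 64) +
    complex(real = rnorm(64, 0, 1e-12)), 1e-4, 500))), class = "nmr_warning")
})

test_that("baseline correction removes polynomials exactly and is idempotent", {
  # Gaussian line: negligible real-part tails outside the signal region
  fid <- make_fid(line_spec(0, 1, 0, 4), n_points = 2048, dwell = 4e-4)
  sp <- fourier_transform(fid)
  ppm <- axis_ppm(sp)
  x <- seq(-1, 1, length.out = length(ppm))
  poly_base <- 5 + 3 * x - 2 * x^2
  dirty <- sp
  dirty$data[1, ] <- dirty$data[1, ] + poly_base
  signal <- list(c(-0.3, 0.3))
  fixed <- baseline_correct(dirty, signal_regions = signal, order = 2)
  off <- abs(ppm) > 0.5
  expect_lt(max(abs(Re(fixed$data[1, off]))), 1e-8)
  # already-flat baseline is (nearly) untouched
  clean <- baseline_correct(sp, signal_regions = signal, order = 2)
  again <- baseline_correct(clean, signal_regions = signal, order = 2)
  expect_lt(max(abs(Re(again$data) - Re(clean$data))), 1e-10)
  # auto mode converges to the manual answer
  auto <- baseline_correct(dirty, signal_regions = "auto", order = 2)
  expect_equal(Re(auto$data[1, off]), Re(fixed$data[1, off]), tolerance = 1e-6)
  expect_error(baseline_correct(dirty, signal_regions = list(range(ppm)), order = 2),
               class = "nmr_data_error")
})

test_that("chemical shift referencing moves the ppm axis as assigned", {
  fid <- make_fid(line_spec(1, 1, 2), n_points = 2048, dwell = 4e-4)
  sp <- fourier_transform(fid)
  p0 <- track_peak(sp)$position_ppm
  expect_identical(set_reference(sp, p0, p0)$ref_offset_hz, sp$ref_offset_hz)
  ref0 <- set_reference(sp, p0, 0)
  expect_equal(track_peak(ref0)$position_ppm, 0, tolerance = 1e-9)
  # composition of two referencings equals a single one
  two <- set_reference(set_reference(sp, p0, 3), 3, 5)
  one <- set_reference(sp, p0, 5)
  expect_equal(two$ref_offset_hz, one$ref_offset_hz, tolerance = 1e-9)
})
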