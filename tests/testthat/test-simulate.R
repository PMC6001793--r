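test_that("single-line FID gives the closed-form Lorentzian width", {
  fid <- make_fid(line_spec(1, 1, 1), n_points = 8192, dwell = 4e-4)
  sp <- fourier_transform(fid, 16384)
  expect_equal(measure_fwhm(sp), 1, tolerance = grid_step_hz(sp))
  expect_equal(track_peak(sp)$position_ppm, 1, tolerance = 1e-3)
})

test_that("generators are pure functions of parameters and seed", {
  a <- make_fid(line_spec(0, 1, 2), n_points = 256, dwell = 1e-4,
                noise_sigma = 0.1, seed = 99)
  b <- make_fid(line_spec(0, 1, 2), n_points = 256, dwell = 1e-4,
                noise_sigma = 0.1, seed = 99)
  expect_identical(a$data, b$data)
  z <- make_fid(line_spec(0, 0, 2), n_points = 256, dwell = 1e-4)
  expect_true(all(z$data == 0))
  expect_error(make_fid(line_spec(50, 1, 2), n_points = 256, dwell = 1e-4),
               class = "nmr_data_error")
  expect_error(make_fid(line_spec(0, 1, 2), n_points = 8), class = "nmr_data_error")
})

test_that("noise-free diffusion set satisfies the attenuation law exactly", {
  dd <- make_diffusion_set(line_spec(0.5, 1, 2, D = 5e-10), n_increments = 8,
                           gmax = 0.5, gmin = 0, n_points = 256, dwell = 2e-4)
  base <- make_fid(line_spec(0.5, 1, 2, D = 5e-10), n_points = 256, dwell = 2e-4)
  # g = 0 increment is the unattenuated FID, exactly
  expect_equal(dd$fid$data[1, ], base$data[1, ], tolerance = 1e-14)
  att <- st_attenuation(dd$encoding, 5e-10)
  for (i in c(3, 8)) {
    expect_equal(dd$fid$data[i, ], att[i] * base$data[1, ], tolerance = 1e-12)
  }
  # unit exponent gives e^-1
  enc1 <- diffusion_encoding(g = sqrt(1 / (GAMMA_1H^2 * (2e-3)^2 * 0.1)))
  expect_equal(st_attenuation(enc1, 1), exp(-1), tolerance = 1e-12)
})

test_that("relaxation generator matches the recovery/decay closed forms", {
  tau <- c(0.1, 0.3, 0.6931472, 2, 10)
  l <- line_spec(0, 1, 2, t1 = 1, t2 = 0.5)
  ir <- make_relaxation_set(l, relaxation_encoding(tau, "inversion_recovery"),
                            n_points = 128, dwell = 1e-4)
  amp <- ir$fid$data[, 1]  # t = 0 point carries the line amplitude
  # null point at tau = T1 ln 2
  expect_equal(Mod(amp[3]), 0, tolerance = 1e-7)
  # tau >> T1 recovers the full amplitude
  base <- make_fid(l, n_points = 128, dwell = 1e-4)
  expect_equal(amp[5], base$data[1, 1], tolerance = 1e-4)
  t2 <- make_relaxation_set(l, relaxation_encoding(c(0.25, 0.5, 1), "t2_decay"),
                            n_points = 128, dwell = 1e-4)
  expect_equal(t2$fid$data[2, 1], base$data[1, 1] / exp(1), tolerance = 1e-12)
})

test_that("reaction cube is trilinear by construction", {
  enc <- default_encoding(n = 10)
  lines <- list(line_spec(-2, 1, 8, D = 5e-10, component_id = 1),
                line_spec(1, 0.7, 8, D = 1e-10, component_id = 2))
  tt <- seq(0, 1, length.out = 6)
  conc1 <- matrix(exp(-2 * tt), ncol = 1)
  cube1 <- make_reaction_cube(lines[1], enc, conc1, fn = 64)
  for (m in 1:3) {
    d <- svd(nmrarray:::unfold(cube1$cube, m))$d
    expect_lt(d[2] / d[1], 1e-12)  # rank one in every unfolding
  }
  expect_error(make_reaction_cube(lines, enc, conc1, fn = 64), class = "nmr_data_error")
  zero <- make_reaction_cube(lines[1], enc, matrix(c(0, 1, 1, 1, 1, 1)), fn = 64)
  expect_true(all(zero$cube[1, , ] == 0))
})

test_that("lineshape distortion multiplies every increment identically", {
  dd <- mixture_set(n_points = 512)
  t <- (0:511) * 2e-4
  env <- exp(-pi * 1.5 * t)
  dis <- distort_lineshape(dd$fid, env)
  expect_equal(dis$data, sweep(dd$fid$data, 2, as.complex(env), "*"), tolerance = 1e-15)
  idm <- distort_lineshape(dd$fid, rep(1 + 0i, 512))
  expect_identical(idm$data, dd$fid$data)
  # an exponential envelope adds exactly its width to every line
  one <- make_fid(line_spec(0, 1, 1), n_points = 8192, dwell = 4e-4)
  tb <- (0:8191) * 4e-4
  broad <- distort_lineshape(one, exp(-pi * 2 * tb))
  sp <- fourier_transform(broad, 16384)
  expect_equal(measure_fwhm(sp), 3, tolerance = 2 * grid_step_hz(sp))
  # random smooth envelope is reproducible
  r1 <- distort_lineshape(dd$fid, "random_smooth", seed = 5)
  r2 <- distort_lineshape(dd$fid, "random_smooth", seed = 5)
  expect_identical(r1$data, r2$data)
})

test_that("pure shift raw data embeds the continuous decoupled FID", {
  lines <- list(line_spec(-1, 1, 2), line_spec(1.2, 0.7, 2))
  raw <- make_pureshift_raw(lines, chunks = 8, chunk_points = 32, first_chunk = 24,
                            drop_points = 2, dwell = 1e-4)
  expect_equal(dim(raw$data), c(8L, 34L))  # drop_points + chunk_points
  # chunk 2's kept window starts where chunk 1's contribution ends
  truth <- nmrarray:::eval_lines(nmrarray:::as_line_list(lines),
                                 (24 + 0:31) * 1e-4, 500, 0)
  expect_equal(raw$data[2, 3:34], truth, tolerance = 1e-14)
})
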