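tau_grid <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.5, 3, 6)

test_that("inversion recovery: three-parameter fit, null point, long-time limit", {
  y <- 1 - 2 * exp(-tau_grid / 1.0)
  f <- fit_t1_ir(y, tau_grid)
  expect_lt(abs(f$params$T1 - 1) / 1, 1e-8)
  expect_lt(abs(f$params$A - 1), 1e-8)
  expect_lt(abs(f$params$B + 2), 1e-8)
  # model null point at tau = T1 ln 2 and recovery to A at long tau
  A <- f$params$A; B <- f$params$B; T1 <- f$params$T1
  expect_equal(A + B * exp(-T1 * log(2) / T1), 0, tolerance = 1e-8)
  expect_equal(A + B * exp(-100 / T1), A, tolerance = 1e-8)
  # imperfect inversion is absorbed by B
  y2 <- 0.8 - 1.5 * exp(-tau_grid / 0.6)
  f2 <- fit_t1_ir(y2, tau_grid)
  expect_lt(abs(f2$params$T1 - 0.6) / 0.6, 1e-8)
  # the constrained two-parameter form agrees on perfect-inversion data
  f3 <- fit_t1_ir(y, tau_grid, two_parameter = TRUE)
  expect_lt(abs(f3$params$T1 - f$params$T1), 1e-8)
})

test_that("saturation recovery fit and its fixed points", {
  y <- 2 * (1 - exp(-tau_grid / 0.7))
  f <- fit_t1_sr(y, tau_grid)
  expect_lt(abs(f$params$T1 - 0.7) / 0.7, 1e-8)
  A <- f$params$A; T1 <- f$params$T1
  expect_equal(A * (1 - exp(-T1 / T1)), A * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(A * (1 - exp(0)), 0)
})

test_that("T2 fit accepts times or counters and is reparameterization-invariant", {
  y <- 3 * exp(-tau_grid / 0.5)
  f <- fit_t2(y, tau_grid)
  expect_lt(abs(f$params$T2 - 0.5) / 0.5, 1e-8)
  expect_equal(f$params$I0 * exp(-1), 3 * exp(-1), tolerance = 1e-8)
  fc <- fit_t2(y, counters = tau_grid / 0.01, loop_duration = 0.01)
  expect_equal(fc$params$T2, f$params$T2, tolerance = 1e-10)
  fc2 <- fit_t2(y, counters = tau_grid / 0.02, loop_duration = 0.02)
  expect_equal(fc2$params$T2, fc$params$T2, tolerance = 1e-10)
  expect_error(fit_t2(y), class = "nmr_data_error")
})

test_that("relaxation fits are amplitude-scale invariant", {
  y <- 3 * exp(-tau_grid / 0.5)
  expect_equal(fit_t2(10 * y, tau_grid)$params$T2, fit_t2(y, tau_grid)$params$T2,
               tolerance = 1e-10)
  yir <- 1 - 2 * exp(-tau_grid / 1.2)
  expect_equal(fit_t1_ir(5 * yir, tau_grid)$params$T1,
               fit_t1_ir(yir, tau_grid)$params$T1, tolerance = 1e-10)
})

test_that("the ROSY map mirrors the DOSY construction with a T or rate axis", {
  enc <- relaxation_encoding(tau_grid, mode = "t2_decay")
  rr <- make_relaxation_set(list(line_spec(-2, 1, 3, t2 = 1.0),
                                 line_spec(1.5, 0.7, 3, t2 = 0.2)),
                            enc, n_points = 2048, dwell = 2e-4)
  sp <- fourier_transform(rr$fid)
  pk <- pick_peaks(sp, threshold = 0.2 * max(Re(sp$data)))
  dec <- peak_decays(sp, pk)
  fits <- lapply(seq_len(nrow(pk)), function(p)
    fit_t2(dec[, p], enc$times, position_ppm = pk$ppm[p]))
  mapT <- build_rosy_map(fits)
  expect_equal(rowSums(mapT$matrix),
               vapply(fits, function(f) f$amplitude, numeric(1)), tolerance = 0.01)
  Tpos <- mapT$rate_axis[apply(mapT$matrix, 1, which.max)]
  mapR <- build_rosy_map(fits, rate = TRUE)
  Rpos <- mapR$rate_axis[apply(mapR$matrix, 1, which.max)]
  expect_equal(Tpos * Rpos, c(1, 1), tolerance = 0.05)
})

test_that("RSCORE resolves relaxation mixtures and matches the univariate fit", {
  enc <- relaxation_encoding(c(0.02, 0.05, 0.1, 0.2, 0.4, 0.7, 1.1, 1.6, 2.2, 3),
                             mode = "t2_decay")
  mix <- make_relaxation_set(list(line_spec(-2, 0.6, 3, t2 = 1.0, component_id = 1),
                                  line_spec(1.5, 0.4, 3, t2 = 0.2, component_id = 2)),
                             enc, n_points = 2048, dwell = 2e-4)
  sp <- fourier_transform(mix$fid)
  rs <- rscore_fit(sp, enc, decomposition_options(2, kernel = "t2", init = "logspace"))
  expect_equal(sort(rs$params), c(0.2, 1.0), tolerance = 1e-3)
  truth1 <- Re(fourier_transform(make_relaxation_set(
    list(line_spec(-2, 0.6, 3, t2 = 1.0)), relaxation_encoding(1e-6 + 0.001, mode = "t2_decay"),
    n_points = 2048, dwell = 2e-4)$fid)$data[1, ])
  ord <- order(rs$params, decreasing = TRUE)
  expect_gt(cor(rs$spectra[ord[1], ], truth1), 0.999)
  # nonneg respected
  rsn <- rscore_fit(sp, enc, decomposition_options(2, kernel = "t2", nonneg = TRUE,
                                                   init = "logspace"))
  expect_gte(min(rsn$spectra), 0)
  # single component agrees with fit_t2 on the same decays
  one <- make_relaxation_set(list(line_spec(0, 1, 3, t2 = 0.5)), enc,
                             n_points = 1024, dwell = 2e-4)
  spo <- fourier_transform(one$fid)
  rs1 <- rscore_fit(spo, enc, decomposition_options(1, kernel = "t2", init = "logspace"))
  pk <- pick_peaks(spo, threshold = 0.5 * max(Re(spo$data)))
  f <- fit_t2(peak_decays(spo, pk)[, 1], enc$times)
  expect_equal(rs1$params[1], f$params$T2, tolerance = 1e-4)
})
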