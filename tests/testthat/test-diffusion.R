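test_that("Stejskal-Tanner attenuation obeys its closed forms", {
  enc <- default_encoding()
  enc$g[1] <- 0
  expect_equal(st_attenuation(enc, 5e-10, increments = 1), 1)
  enc1 <- diffusion_encoding(g = sqrt(1 / (GAMMA_1H^2 * (2e-3)^2 * 0.1)))
  expect_equal(st_attenuation(enc1, 1), exp(-1), tolerance = 1e-12)
  # NUG exponent: ln(attenuation) = -(XD) - 0.1 (XD)^2
  enc_nug <- diffusion_encoding(enc1$g, nug_coeffs = c(1, 0.1))
  xd <- st_exponent(enc_nug) * 2
  expect_equal(log(st_attenuation(enc_nug, 2)), -xd - 0.1 * xd^2, tolerance = 1e-12)
})

test_that("peak picking finds resolved lines with sub-grid positions", {
  fid <- make_fid(list(line_spec(-1.3, 1, 2), line_spec(0.9, 0.6, 2)),
                  n_points = 4096, dwell = 4e-4)
  sp <- fourier_transform(fid, 8192)
  pk <- pick_peaks(sp, threshold = 0.1 * max(Re(sp$data)))
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$ppm), c(-1.3, 0.9), tolerance = 2e-4)
  expect_equal(nrow(pick_peaks(sp, threshold = 2 * max(Re(sp$data)))), 0)
})

test_that("noiseless monoexponential fit recovers D to machine-level accuracy", {
  dd <- make_diffusion_set(line_spec(0.5, 1, 2, D = 5e-10), n_increments = 16,
                           gmax = 0.5, n_points = 2048, dwell = 2e-4)
  sp <- fourier_transform(dd$fid)
  pk <- pick_peaks(sp, threshold = 0.5 * max(Re(sp$data)))
  fit <- fit_monoexp(peak_decays(sp, pk)[, 1], dd$encoding, position_ppm = pk$ppm[1])
  expect_lt(abs(fit$params$D - 5e-10) / 5e-10, 1e-6)
  expect_gte(fit$rss, 0)
  expect_true(all(unlist(fit$se) >= 0))
})

test_that("flat decays yield D at the lower bound with a warning", {
  enc <- default_encoding()
  expect_warning(fit <- fit_monoexp(rep(3, 16), enc), class = "nmr_warning")
  expect_lt(fit$params$D, 1e-14 / max(st_exponent(enc)))
  expect_true(fit$at_bound)
})

test_that("monoexponential fit is scale-equivariant and parameterization-invariant", {
  enc_g <- default_encoding(spacing = "equal_g")
  y <- 2.5 * st_attenuation(enc_g, 3e-10)
  f1 <- fit_monoexp(y, enc_g)
  f2 <- fit_monoexp(10 * y, enc_g)
  expect_equal(f2$params$I0 / f1$params$I0, 10, tolerance = 1e-12)
  expect_equal(f2$params$D, f1$params$D, tolerance = 1e-12)
  # same decay expressed on an equal-g^2 grid gives the same D
  enc_g2 <- default_encoding(spacing = "equal_g2")
  f3 <- fit_monoexp(2.5 * st_attenuation(enc_g2, 3e-10), enc_g2)
  expect_equal(f3$params$D, f1$params$D, tolerance = 1e-9)
  # NUG with c = (1) reproduces the pure-exponential fit
  enc_nug <- diffusion_encoding(enc_g$g, nug_coeffs = 1)
  f4 <- fit_monoexp(y, enc_nug)
  expect_equal(f4$params$D, f1$params$D, tolerance = 1e-12)
})

test_that("Monte-Carlo noise study: unbiased D and calibrated standard errors", {
  enc <- diffusion_encoding(seq(0.02, 0.6, length.out = 16))
  X <- st_exponent(enc)
  truth <- 5e-10
  set.seed(42)
  Dhat <- numeric(200); se <- numeric(200)
  for (s in seq_len(200)) {
    y <- exp(-X * truth) + rnorm(16, 0, 0.01)
    f <- fit_monoexp(y, enc)
    Dhat[s] <- f$params$D; se[s] <- f$se$D
  }
  expect_lt(abs(mean(Dhat) - truth) / truth, 0.01)
  expect_lt(abs(sd(Dhat) - mean(se)) / mean(se), 0.3)
})

test_that("multiexponential reduction keeps only significant components", {
  enc <- diffusion_encoding(seq(0.02, 0.6, length.out = 16))
  X <- st_exponent(enc)
  y2 <- exp(-X * 5e-10) + exp(-X * 0.5e-10)
  set.seed(1)
  m2 <- fit_multiexp(y2, enc, max_components = 3)
  expect_equal(m2$n_components, 2)
  expect_equal(sort(m2$D), c(0.5e-10, 5e-10), tolerance = 1e-3)
  expect_equal(sum(m2$I0), 2, tolerance = 1e-8)  # total amplitude at g = 0
  m1 <- fit_multiexp(2 * exp(-X * 3e-10), enc, max_components = 2)
  expect_equal(m1$n_components, 1)
})

test_that("the DOSY map builds normalised ridges at the fitted coefficients", {
  dd <- make_diffusion_set(list(line_spec(-2, 1, 3, D = 5e-10),
                                line_spec(2, 0.7, 3, D = 0.5e-10)),
                           n_increments = 16, gmax = 0.5, n_points = 2048, dwell = 2e-4)
  res <- dosy(fourier_transform(dd$fid), dd$encoding)
  expect_equal(nrow(res$peaks), 2)
  expect_equal(sort(res$peaks$D), c(0.5e-10, 5e-10), tolerance = 1e-5)
  # every ridge integrates (sums) to its peak amplitude
  sums <- rowSums(res$map$matrix)
  amps <- vapply(res$map$peaks, function(f) f$amplitude, numeric(1))
  expect_equal(sums, amps, tolerance = 0.01)
  # separated D values give non-overlapping ridges
  M <- res$map$matrix / max(res$map$matrix)
  overlap <- colSums(M > 0.01) > 1
  expect_false(any(overlap))
  # the error floor keeps ridges at least one bin wide
  widths <- apply(res$map$matrix, 1, function(r) sum(r > 0.01 * max(r)))
  expect_true(all(widths >= 2))
})
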