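test_that("SCORE recovers a single component essentially exactly", {
  dd <- make_diffusion_set(list(line_spec(-1, 1, 3, D = 3e-10),
                                line_spec(1.5, 0.6, 4, D = 3e-10)),
                           n_increments = 12, gmax = 0.5, gmin = 0.02,
                           spacing = "equal_g2", n_points = 1024, dwell = 2e-4)
  sp <- fourier_transform(dd$fid)
  fit <- score_fit(sp, dd$encoding, decomposition_options(1))
  expect_lt(abs(fit$params[1] - 3e-10) / 3e-10, 1e-6)
  truth <- Re(sp$data[1, ])
  expect_gt(cor(fit$spectra[1, ], truth), 0.999999)
  expect_equal(sum(fit$fractions), 100, tolerance = 1e-9)
})

test_that("SCORE resolves the two-component mixture with correct fractions", {
  dd <- mixture_set()
  X <- Re(fourier_transform(dd$fid)$data)
  fit <- score_fit(X, dd$encoding, decomposition_options(2, init = "decra"))
  expect_equal(sort(fit$params), c(1e-10, 5e-10), tolerance = 1e-4)
  expect_equal(sort(fit$fractions), c(40, 60), tolerance = 0.5 / 60)
  # spectral correlation with the component ground truth
  sp1 <- fourier_transform(make_diffusion_set(mixture_lines()[1:2], n_increments = 1,
    gmax = 0.01, n_points = 2048, dwell = 2e-4)$fid)
  sp2 <- fourier_transform(make_diffusion_set(mixture_lines()[3:4], n_increments = 1,
    gmax = 0.01, n_points = 2048, dwell = 2e-4)$fid)
  ord <- order(fit$params, decreasing = TRUE)
  expect_gt(cor(fit$spectra[ord[1], ], Re(sp1$data[1, ])), 0.999)
  expect_gt(cor(fit$spectra[ord[2], ], Re(sp2$data[1, ])), 0.999)
  # best-so-far objective trace is non-increasing
  expect_true(all(diff(fit$trace) <= 0))
  # non-negativity constraint is honoured
  nn <- score_fit(X, dd$encoding, decomposition_options(2, nonneg = TRUE, init = "decra"))
  expect_gte(min(nn$spectra), 0)
  expect_equal(sum(nn$fractions), 100, tolerance = 1e-9)
})

test_that("DECRA is an exact algebraic inverse for noiseless exponentials", {
  dd <- mixture_set()
  X <- Re(fourier_transform(dd$fid)$data)
  d <- decra(X, dd$encoding, 2)
  expect_lt(max(abs(sort(d$params) - c(1e-10, 5e-10)) / c(1e-10, 5e-10)), 1e-8)
  expect_equal(sort(d$fractions), c(40, 60), tolerance = 0.5 / 60)
  # one component: rho is the exact geometric decay factor
  one <- make_diffusion_set(line_spec(0, 1, 3, D = 2e-10), n_increments = 10,
                            gmax = 0.5, gmin = 0.02, spacing = "equal_g2",
                            n_points = 512, dwell = 2e-4)
  X1 <- Re(fourier_transform(one$fid)$data)
  d1 <- decra(X1, one$encoding, 1)
  dX <- diff(st_exponent(one$encoding))[1]
  expect_equal(Re(d1$rho), exp(-2e-10 * dX), tolerance = 1e-10)
  # SCORE started from DECRA ends at or below DECRA's residual
  s <- score_fit(X, dd$encoding, decomposition_options(2, init = "decra"))
  expect_lte(s$resid_norm, d$resid_norm)
})

test_that("DECRA insists on an equally spaced exponent grid", {
  bad <- make_diffusion_set(line_spec(0, 1, 3, D = 2e-10), n_increments = 10,
                            gmax = 0.5, gmin = 0.02, spacing = "equal_g",
                            n_points = 256, dwell = 2e-4)
  expect_error(decra(Re(fourier_transform(bad$fid)$data), bad$encoding, 1),
               regexp = "resample", class = "nmr_data_error")
  # interpolation regime: as many components as increments - 1
  set.seed(3)
  enc <- default_encoding(n = 6)
  X6 <- st_exponent(enc)
  Dr <- sort(10^runif(5, -10.5, -9))
  M <- exp(-outer(X6, Dr)) %*% matrix(abs(rnorm(5 * 40)), 5, 40)
  d <- suppressWarnings(decra(M, enc, 5))
  expect_equal(length(d$params), 5)
  expect_lt(d$resid_norm / sqrt(sum(M^2)), 1e-8)
})

test_that("OUTSCORE minimises spectral cross-talk", {
  disjoint <- make_diffusion_set(list(line_spec(-2, 0.6, 3, D = 5e-10, component_id = 1),
                                      line_spec(2, 0.4, 3, D = 1e-10, component_id = 2)),
                                 n_increments = 16, gmax = 0.55, gmin = 0.02,
                                 spacing = "equal_g2", n_points = 1024, dwell = 2e-4)
  Xo <- Re(fourier_transform(disjoint$fid)$data)
  oo <- outscore_fit(Xo, disjoint$encoding, decomposition_options(2, init = "decra"))
  expect_equal(sort(oo$params), c(1e-10, 5e-10), tolerance = 1e-3)
  expect_lt(oo$crosstalk, 1e-3)
  # on overlapped data, OUTSCORE's returned cross-talk <= SCORE's
  dd <- mixture_set()
  X <- Re(fourier_transform(dd$fid)$data)
  crosstalk_of <- function(S) {
    n <- sqrt(rowSums(S^2))
    sum(abs(S[1, ]) * abs(S[2, ])) / (n[1] * n[2])
  }
  so <- score_fit(X, dd$encoding, decomposition_options(2, init = "decra"))
  os <- outscore_fit(X, dd$encoding, decomposition_options(2, init = "decra"))
  expect_lte(crosstalk_of(os$spectra), crosstalk_of(so$spectra) + 1e-12)
})

test_that("regularised ILT localises a single exponential and is monotone in lambda", {
  enc <- default_encoding()
  b <- st_attenuation(enc, 3e-10)
  r <- ilt(b, enc, lambda = 1e-6, nonneg = TRUE)
  jmax <- which.max(r$x)
  jtrue <- which.min(abs(log(r$grid) - log(3e-10)))
  expect_lte(abs(jmax - jtrue), 1)
  # Tikhonov monotonicity (unconstrained solution path)
  r1 <- ilt(b, enc, lambda = 1e-4, nonneg = FALSE)
  r2 <- ilt(b, enc, lambda = 1e-2, nonneg = FALSE)
  expect_lte(r1$resid_norm, r2$resid_norm)
  expect_gte(r1$sol_norm, r2$sol_norm)
  # zero data gives the zero distribution
  r0 <- ilt(rep(0, 16), enc, lambda = 1e-3, grid = r$grid, nonneg = TRUE)
  expect_true(all(r0$x == 0))
  # GCV picks a lambda that still localises the peak
  rg <- ilt(b, enc, lambda = "gcv", nonneg = TRUE)
  expect_lte(abs(which.max(rg$x) - jtrue), 1)
  expect_s3_class(rg$gcv, "data.frame")
  # a grid missing the decay rate warns about edge mass
  widegrid <- exp(seq(log(1e-8), log(1e-7), length.out = 16))
  expect_warning(ilt(b, enc, grid = widegrid, lambda = 1e-6), class = "nmr_warning")
})
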