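#' @title Synthetic data generation
#' @description Closed-form generators for every class of input the analysis
#'   modules consume: multi-line complex FIDs, diffusion-attenuated arrays,
#'   relaxation arrays, trilinear reaction cubes, lineshape distortions and
#'   interferogram-style pure shift raw data. All generators are pure
#'   functions of their parameters and a seed.
#' @name simulate
NULL

#' Spectral line specification
#'
#' One resonance line: position, amplitude, Lorentzian/Gaussian widths,
#' phase, and the per-component physical parameters (diffusion coefficient,
#' T1, T2) used by the arrayed generators. J-multiplets are modelled as
#' explicit line lists.
#'
#' @param shift_ppm chemical shift, ppm.
#' @param amplitude signal amplitude (>= 0).
#' @param lw_hz Lorentzian FWHM, Hz.
#' @param gw_hz Gaussian FWHM, Hz.
#' @param phase_deg line phase, degrees.
#' @param D diffusion coefficient, m^2/s.
#' @param t1,t2 longitudinal/transverse relaxation times, s.
#' @param component_id integer grouping lines into mixture components.
#' @export
line_spec <- function(shift_ppm, amplitude = 1, lw_hz = 1, gw_hz = 0, phase_deg = 0,
                      D = 5e-10, t1 = 1, t2 = 0.5, component_id = 1L) {
  if (amplitude < 0 || lw_hz < 0 || gw_hz < 0) stop_data("amplitude, lw, gw must be >= 0")
  if (D <= 0 || t1 <= 0 || t2 <= 0) stop_data("D, t1, t2 must be > 0")
  structure(list(shift_ppm = shift_ppm, amplitude = amplitude, lw_hz = lw_hz,
                 gw_hz = gw_hz, phase_deg = phase_deg, D = D, t1 = t1, t2 = t2,
                 component_id = as.integer(component_id)),
            class = "line_spec")
}

as_line_list <- function(lines) {
  if (inherits(lines, "line_spec")) lines <- list(lines)
  lapply(lines, function(l) {
    if (!inherits(l, "line_spec")) l <- do.call(line_spec, as.list(l))
    l
  })
}

# evaluate the noiseless multi-line FID at arbitrary times (s)
eval_lines <- function(lines, t, sfrq, ref_offset_hz = 0) {
  s <- complex(real = numeric(length(t)), imaginary = numeric(length(t)))
  for (l in lines) {
    f <- ppm_to_hz(l$shift_ppm, sfrq, ref_offset_hz)
    s <- s + l$amplitude *
      exp(1i * (2 * pi * f * t + l$phase_deg * pi / 180)) *
      exp(-pi * l$lw_hz * pmax(t, 0)) *
      exp(-(pi * l$gw_hz * pmax(t, 0) / (2 * sqrt(log(2))))^2)
  }
  s
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

complex_noise <- function(n, sigma) {
  complex(real = stats::rnorm(n, 0, sigma), imaginary = stats::rnorm(n, 0, sigma))
}

#' Simulate a (multi-line) FID
#'
#' s(t) = sum_k A_k exp(i(2 pi f_k t + phi_k)) exp(-pi lw_k t)
#' exp(-(pi gw_k t / (2 sqrt(ln 2)))^2) plus complex circular Gaussian noise.
#'
#' @param lines list of [line_spec()]s.
#' @param n_points complex points (>= 16).
#' @param dwell seconds per point.
#' @param sfrq spectrometer frequency, MHz.
#' @param noise_sigma noise standard deviation per quadrature, absolute units.
#' @param seed RNG seed (required when `noise_sigma > 0` for reproducibility).
#' @param ref_offset_hz ppm-zero offset, Hz.
#' @return A [fid_set()] with one increment.
#' @export
make_fid <- function(lines, n_points = 4096, dwell = 1e-4, sfrq = 500,
                     noise_sigma = 0, seed = NULL, ref_offset_hz = 0) {
  lines <- as_line_list(lines)
  if (n_points < 16L) stop_data("n_points must be >= 16")
  sw <- 1 / dwell
  for (l in lines) {
    f <- ppm_to_hz(l$shift_ppm, sfrq, ref_offset_hz)
    if (abs(f) >= sw / 2) stop_data("line at %g ppm (%g Hz) is outside the sweep width", l$shift_ppm, f)
  }
  t <- (seq_len(n_points) - 1) * dwell
  s <- eval_lines(lines, t, sfrq, ref_offset_hz)
  if (noise_sigma > 0) s <- s + with_seed(seed, complex_noise(n_points, noise_sigma))
  fid_set(matrix(s, nrow = 1), dwell = dwell, sfrq = sfrq, ref_offset_hz = ref_offset_hz,
          meta = list(lines = lines))
}

#' Simulate a diffusion-encoded array
#'
#' Each increment i scales every component k by the Stejskal-Tanner factor
#' exp(-sum_m c_m (X_i D_k)^m) with X_i = gamma^2 delta^2 g_i^2 Delta'
#' (pure exponential for `nug_coeffs = 1`).
#'
#' @param lines list of [line_spec()]s (components via `component_id`, `D`).
#' @param n_increments number of gradient steps.
#' @param gmax maximum gradient amplitude, T/m.
#' @param gmin minimum gradient amplitude, T/m (0 gives an unattenuated
#'   first increment).
#' @param spacing `"equal_g"` (linear in g) or `"equal_g2"` (linear in g^2,
#'   i.e. equally spaced X as DECRA and PowerSlicing require).
#' @param gamma,delta,big_delta_prime,nug_coeffs,sequence_type see
#'   [diffusion_encoding()].
#' @param n_points,dwell,sfrq,noise_sigma,seed,ref_offset_hz see [make_fid()].
#' @return list with elements `fid` (a [fid_set()] carrying a gradient axis)
#'   and `encoding` (a [diffusion_encoding()]).
#' @export
make_diffusion_set <- function(lines, n_increments = 16, gmax = 0.5, gmin = 0,
                               spacing = c("equal_g", "equal_g2"),
                               gamma = GAMMA_1H, delta = 2e-3, big_delta_prime = 0.1,
                               nug_coeffs = 1, sequence_type = "bipolar",
                               n_points = 4096, dwell = 1e-4, sfrq = 500,
                               noise_sigma = 0, seed = NULL, ref_offset_hz = 0) {
  spacing <- match.arg(spacing)
  if (gmax <= 0) stop_data("gmax must be > 0")
  g <- switch(spacing,
              equal_g = seq(gmin, gmax, length.out = n_increments),
              equal_g2 = sqrt(seq(gmin^2, gmax^2, length.out = n_increments)))
  enc <- diffusion_encoding(g, gamma = gamma, delta = delta,
                            big_delta_prime = big_delta_prime,
                            nug_coeffs = nug_coeffs, sequence_type = sequence_type)
  lines <- as_line_list(lines)
  base <- make_fid(lines, n_points, dwell, sfrq, 0, NULL, ref_offset_hz)
  t <- (seq_len(n_points) - 1) * dwell
  X <- st_exponent(enc)
  data <- matrix(0 + 0i, n_increments, n_points)
  for (l in lines) {
    row <- eval_lines(list(l), t, sfrq, ref_offset_hz)
    att <- st_attenuation(enc, l$D)
    data <- data + outer(att, row)
  }
  if (noise_sigma > 0)
    data <- data + with_seed(seed, matrix(complex_noise(length(data), noise_sigma),
                                          n_increments, n_points))
  fid <- fid_set(data, dwell = dwell, sfrq = sfrq, ref_offset_hz = ref_offset_hz,
                 arrays = list(increment_axis(g, "gradient", "g (T/m)")),
                 meta = list(lines = lines))
  list(fid = fid, encoding = enc)
}

#' Simulate a relaxation array
#'
#' Component amplitudes follow A(1 - 2 exp(-tau/T1)) (inversion recovery),
#' A(1 - exp(-tau/T1)) (saturation recovery) or A exp(-t/T2) (T2 decay).
#'
#' @param lines list of [line_spec()]s (`t1`/`t2` fields used per mode).
#' @param encoding a [relaxation_encoding()].
#' @param n_points,dwell,sfrq,noise_sigma,seed,ref_offset_hz see [make_fid()].
#' @return list with `fid` and `encoding`.
#' @export
make_relaxation_set <- function(lines, encoding, n_points = 4096, dwell = 1e-4,
                                sfrq = 500, noise_sigma = 0, seed = NULL,
                                ref_offset_hz = 0) {
  if (!inherits(encoding, "relaxation_encoding")) stop_data("encoding must be a relaxation_encoding")
  lines <- as_line_list(lines)
  tau <- encoding$times
  t <- (seq_len(n_points) - 1) * dwell
  data <- matrix(0 + 0i, length(tau), n_points)
  for (l in lines) {
    row <- eval_lines(list(l), t, sfrq, ref_offset_hz)
    amp <- switch(encoding$mode,
                  inversion_recovery = 1 - 2 * exp(-tau / l$t1),
                  saturation_recovery = 1 - exp(-tau / l$t1),
                  t2_decay = exp(-tau / l$t2))
    data <- data + outer(amp, row)
  }
  if (noise_sigma > 0)
    data <- data + with_seed(seed, matrix(complex_noise(length(data), noise_sigma),
                                          length(tau), n_points))
  fid <- fid_set(data, dwell = dwell, sfrq = sfrq, ref_offset_hz = ref_offset_hz,
                 arrays = list(increment_axis(tau, "delay", "tau (s)")),
                 meta = list(lines = lines, relaxation_mode = encoding$mode))
  list(fid = fid, encoding = encoding)
}

# real absorption Lorentzian/Gaussian component spectrum on a frequency grid
component_spectrum <- function(lines, axis_hz, sfrq, ref_offset_hz = 0) {
  s <- numeric(length(axis_hz))
  for (l in lines) {
    f0 <- ppm_to_hz(l$shift_ppm, sfrq, ref_offset_hz)
    if (l$gw_hz > 0) {
      sig <- l$gw_hz / (2 * sqrt(2 * log(2)))
      s <- s + l$amplitude * exp(-((axis_hz - f0)^2) / (2 * sig^2))
    } else {
      hw <- l$lw_hz / 2
      s <- s + l$amplitude * hw^2 / (hw^2 + (axis_hz - f0)^2)
    }
  }
  s
}

#' Simulate a trilinear reaction cube
#'
#' X[j, i, f] = sum_k c_k(t_j) exp(-X_i D_k) s_k(f): component spectra in
#' the frequency mode, Stejskal-Tanner decays in the gradient mode, and
#' user-supplied concentration profiles in the time mode. Trilinear by
#' construction.
#'
#' @param lines list of [line_spec()]s grouped by `component_id`.
#' @param encoding a [diffusion_encoding()].
#' @param concentrations matrix [n_times x n_components] of c_k(t_j).
#' @param fn frequency points.
#' @param sfrq spectrometer frequency, MHz.
#' @param sw sweep width, Hz.
#' @param noise_sigma,seed Gaussian noise level and seed.
#' @return list with `cube` ([n_times x n_increments x fn]), `axis_hz`,
#'   `spectra` (truth, components x fn), `decays`, `concentrations`.
#' @export
make_reaction_cube <- function(lines, encoding, concentrations, fn = 256,
                               sfrq = 500, sw = 5000, noise_sigma = 0, seed = NULL) {
  lines <- as_line_list(lines)
  concentrations <- as.matrix(concentrations)
  comp_ids <- sort(unique(vapply(lines, function(l) l$component_id, integer(1))))
  if (ncol(concentrations) != length(comp_ids))
    stop_data("concentrations must have one column per component")
  axis_hz <- ft_axis_hz(fn, sw)
  X <- st_exponent(encoding)
  S <- t(vapply(comp_ids, function(id) {
    component_spectrum(Filter(function(l) l$component_id == id, lines), axis_hz, sfrq)
  }, numeric(fn)))
  D <- vapply(comp_ids, function(id) {
    Filter(function(l) l$component_id == id, lines)[[1]]$D
  }, numeric(1))
  decays <- exp(-outer(X, D))               # n_inc x K
  n_t <- nrow(concentrations)
  cube <- array(0, dim = c(n_t, length(X), fn))
  for (k in seq_along(comp_ids)) {
    cube <- cube + outer(concentrations[, k], outer(decays[, k], S[k, ]))
  }
  if (noise_sigma > 0)
    cube <- cube + with_seed(seed, array(stats::rnorm(length(cube), 0, noise_sigma), dim(cube)))
  list(cube = cube, axis_hz = axis_hz, spectra = S, decays = decays,
       concentrations = concentrations, D = D)
}

#' Apply a common lineshape distortion
#'
#' Multiplies every increment's FID by the same complex envelope, modelling
#' field inhomogeneity that affects all lines identically -- the
#' precondition reference deconvolution ([fiddle()]) exploits.
#'
#' @param fid a [fid_set()].
#' @param envelope complex vector of length `n_points`, or a function of
#'   time (s) returning one.
#' @param seed seed for `envelope = "random_smooth"`, a reproducible smooth
#'   random distortion.
#' @export
distort_lineshape <- function(fid, envelope, seed = NULL) {
  if (!inherits(fid, "fid_set")) stop_data("distort_lineshape expects a fid_set")
  np <- ncol(fid$data)
  t <- (seq_len(np) - 1) * fid$dwell
  if (identical(envelope, "random_smooth")) {
    env <- with_seed(seed, {
      n_modes <- 4L
      amp <- stats::runif(n_modes, 0.05, 0.2)
      frq <- stats::runif(n_modes, 0.2, 2) / max(t)
      phs <- stats::runif(n_modes, 0, 2 * pi)
      mod <- rowSums(vapply(seq_len(n_modes), function(m)
        amp[m] * sin(2 * pi * frq[m] * t + phs[m]), numeric(np)))
      exp(-pi * 2 * t) * exp(1i * mod)
    })
  } else if (is.function(envelope)) {
    env <- envelope(t)
  } else {
    env <- envelope
    if (length(env) != np) stop_data("envelope length must equal n_points")
  }
  fid$data <- sweep(fid$data, 2L, as.complex(env), "*")
  fid
}

#' Simulate interferogram-style pure shift raw data
#'
#' Builds the pseudo-2D raw data whose increment i holds the continuous
#' homodecoupled FID evaluated on the time window chunk i occupies in the
#' reconstructed FID, preceded by `drop_points` lead-in points, so that
#' [ps_reconstruct()] has an exact target.
#'
#' @param lines decoupled (singlet) [line_spec()] list.
#' @param chunks number of increments.
#' @param chunk_points data points per chunk.
#' @param first_chunk points kept from the first chunk (<= `chunk_points`).
#' @param drop_points points discarded from the start of each chunk.
#' @param dwell,sfrq,ref_offset_hz acquisition parameters.
#' @return A [fid_set()] with `chunks` increments of
#'   `drop_points + chunk_points` points; the reconstruction parameters are
#'   stored in `meta$pureshift`.
#' @export
make_pureshift_raw <- function(lines, chunks = 16, chunk_points = 64,
                               first_chunk = chunk_points, drop_points = 0,
                               dwell = 1e-4, sfrq = 500, ref_offset_hz = 0) {
  lines <- as_line_list(lines)
  if (first_chunk > chunk_points) stop_data("first_chunk must be <= chunk_points")
  if (drop_points < 0) stop_data("drop_points must be >= 0")
  starts <- c(0L, first_chunk + (seq_len(chunks - 1L) - 1L) * chunk_points)
  np <- drop_points + chunk_points
  data <- matrix(0 + 0i, chunks, np)
  for (i in seq_len(chunks)) {
    idx <- (starts[i] - drop_points) + seq_len(np) - 1L
    data[i, ] <- eval_lines(lines, idx * dwell, sfrq, ref_offset_hz)
  }
  fid_set(data, dwell = dwell, sfrq = sfrq, ref_offset_hz = ref_offset_hz,
          arrays = list(increment_axis(seq_len(chunks), "counter", "chunk")),
          meta = list(lines = lines,
                      pureshift = list(chunks = chunks, chunk_points = chunk_points,
                                       first_chunk = first_chunk,
                                       drop_points = drop_points,
                                       chunk_duration = chunk_points * dwell)))
}
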