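#' @title Basic FID and spectrum processing
#' @description Zero-filling, apodisation, Fourier transformation, manual and
#'   automatic phase correction, polynomial baseline correction and chemical
#'   shift referencing.
#' @name processing
NULL

#' Zero-fill or truncate a FID set
#'
#' @param fid a [fid_set()].
#' @param fn target number of complex points (the Fourier number). Padding
#'   with zeros when `fn > n_points`, truncation otherwise. Idempotent for a
#'   fixed `fn`.
#' @export
zero_fill <- function(fid, fn) {
  if (!inherits(fid, "fid_set")) stop_data("zero_fill expects a fid_set")
  fn <- as.integer(fn)
  if (fn < 2L) stop_data("fn must be >= 2")
  np <- ncol(fid$data)
  if (fn == np) return(fid)
  if (fn < np) {
    fid$data <- fid$data[, seq_len(fn), drop = FALSE]
  } else {
    pad <- matrix(0 + 0i, nrow(fid$data), fn - np)
    fid$data <- cbind(fid$data, pad)
  }
  fid
}

#' Time-domain apodisation weights
#'
#' w(t) = exp(-pi * lw * t - (pi * gw * t / (2 sqrt(ln 2)))^2): multiplying a
#' FID by w convolves the spectrum with a Lorentzian of FWHM `lw` Hz and a
#' Gaussian of FWHM `gw` Hz.
#'
#' @param t times, s.
#' @param params an [apod_params()].
#' @export
apod_weights <- function(t, params) {
  exp(-pi * params$lw * t - (pi * params$gw * t / (2 * sqrt(log(2))))^2)
}

#' Apodise a FID set
#'
#' @param fid a [fid_set()].
#' @param params an [apod_params()] (additional Lorentzian/Gaussian FWHM, Hz).
#' @export
apodise <- function(fid, params) {
  if (!inherits(fid, "fid_set")) stop_data("apodise expects a fid_set")
  if (!inherits(params, "apod_params")) params <- do.call(apod_params, as.list(params))
  t <- (seq_len(ncol(fid$data)) - 1) * fid$dwell
  w <- apod_weights(t, params)
  fid$data <- sweep(fid$data, 2L, w, "*")
  fid
}

# One-row discrete FT with the first-point-halved convention; returns the
# spectrum reordered to a descending frequency axis.
ft_row <- function(x) {
  n <- length(x)
  x[1] <- x[1] / 2
  y <- stats::fft(x)
  asc <- c(y[(n / 2 + 1):n], y[1:(n / 2)])   # -SW/2 .. SW/2 - df, ascending
  rev(asc)
}

ift_row <- function(s) {
  n <- length(s)
  asc <- rev(s)
  y <- c(asc[(n / 2 + 1):n], asc[1:(n / 2)])
  x <- stats::fft(y, inverse = TRUE) / n
  x[1] <- x[1] * 2
  x
}

ft_axis_hz <- function(fn, sw) {
  df <- sw / fn
  rev(seq.int(-fn / 2, fn / 2 - 1) * df)
}

#' Fourier transform a FID set
#'
#' Discrete FT with the first point of each FID halved (the standard
#' DC-offset convention). The spectrum has `fn` complex points on a
#' descending frequency axis spanning the sweep width, centred on the
#' carrier.
#'
#' @param fid a [fid_set()].
#' @param fn Fourier number (complex points); defaults to the FID length,
#'   rounded up to even. Zero-filling/truncation is applied internally.
#' @return A [spectrum_set()].
#' @export
fourier_transform <- function(fid, fn = NULL) {
  if (!inherits(fid, "fid_set")) stop_data("fourier_transform expects a fid_set")
  if (is.null(fn)) fn <- ncol(fid$data)
  fn <- as.integer(fn)
  if (fn %% 2L == 1L) fn <- fn + 1L
  fid <- zero_fill(fid, fn)
  sp <- t(apply(fid$data, 1L, ft_row))
  if (nrow(fid$data) == 1L) sp <- matrix(sp, nrow = 1L)
  spectrum_set(sp, axis_hz = ft_axis_hz(fn, 1 / fid$dwell), sfrq = fid$sfrq,
               ref_offset_hz = fid$ref_offset_hz, arrays = fid$arrays, meta = fid$meta)
}

#' Inverse Fourier transform back to the time domain
#'
#' Inverse of [fourier_transform()]: any processing applied in the frequency
#' domain (phasing, baseline correction, reference deconvolution) is
#' irreversibly baked into the returned FIDs. With `real_only = TRUE` the
#' imaginary part is discarded and reconstructed from the real part by
#' conjugate (Hilbert-type) symmetry, which is exact for fully decayed
#' causal signals.
#'
#' @param spec a [spectrum_set()].
#' @param real_only use only the real part of the spectra.
#' @return A [fid_set()].
#' @export
save_as_fid <- function(spec, real_only = FALSE) {
  if (!inherits(spec, "spectrum_set")) stop_data("save_as_fid expects a spectrum_set")
  if (any(!is.finite(Re(spec$data))) || any(!is.finite(Im(spec$data))))
    stop_data("spectra must be finite")
  fn <- ncol(spec$data)
  sw <- sweep_width(spec)
  rows <- lapply(seq_len(nrow(spec$data)), function(i) {
    s <- spec$data[i, ]
    if (!real_only) return(ift_row(s))
    g <- ift_row(complex(real = Re(s), imaginary = 0))
    # Re(S) transforms to (f(t) + Conj(f(-t)))/2; for a decayed causal FID
    # the two halves do not overlap, so doubling the first half restores f.
    f <- g
    half <- fn / 2
    f[2:half] <- 2 * g[2:half]
    f[1] <- complex(real = Re(g[1]), imaginary = 0) # t = 0 survives once
    f[(half + 1):fn] <- 0
    f
  })
  data <- do.call(rbind, rows)
  fid_set(data, dwell = 1 / sw, sfrq = spec$sfrq, ref_offset_hz = spec$ref_offset_hz,
          arrays = spec$arrays, meta = spec$meta)
}

#' Apply zeroth/first order phase correction
#'
#' S'(f) = S(f) exp(i (ph0 + ph1 (f - pivot)/SW) pi/180). In `"global"` mode
#' one (ph0, ph1) pair is applied to every increment; in `"individual"` mode
#' `ph0`/`ph1` may be vectors with one entry per increment.
#'
#' @param spec a [spectrum_set()].
#' @param ph0,ph1 phases in degrees.
#' @param pivot_hz pivot frequency for the first-order term, Hz; default the
#'   position of the tallest peak.
#' @param mode `"global"` or `"individual"`.
#' @export
phase_spectra <- function(spec, ph0 = 0, ph1 = 0, pivot_hz = NULL,
                          mode = c("global", "individual")) {
  mode <- match.arg(mode)
  if (!inherits(spec, "spectrum_set")) stop_data("phase_spectra expects a spectrum_set")
  n_inc <- nrow(spec$data)
  if (is.null(pivot_hz)) {
    j <- which.max(abs(spec$data[1, ]))
    pivot_hz <- spec$axis_hz[j]
  }
  sw <- sweep_width(spec)
  if (mode == "global") {
    ph0 <- rep(ph0[1], n_inc); ph1 <- rep(ph1[1], n_inc)
  } else {
    ph0 <- rep_len(ph0, n_inc); ph1 <- rep_len(ph1, n_inc)
  }
  for (i in seq_len(n_inc)) {
    ang <- (ph0[i] + ph1[i] * (spec$axis_hz - pivot_hz) / sw) * pi / 180
    spec$data[i, ] <- spec$data[i, ] * exp(1i * ang)
  }
  spec$ph0 <- spec$ph0 + ph0
  spec$ph1 <- spec$ph1 + ph1
  spec$pivot_hz <- pivot_hz
  spec
}

# Negative-real penalty over the signal region plus a small
# absorption-matching tie-break. The tie-break compares Re against the
# magnitude envelope on the strong points only (near peak tops, where the
# two agree at the correct phase); on the tails the magnitude retains the
# dispersion contribution and would bias the estimate.
autophase_objective <- function(ph, row, axis_hz, pivot_hz, sw, sel, sel_top) {
  ang <- (ph[1] + ph[2] * (axis_hz - pivot_hz) / sw) * pi / 180
  rot <- row * exp(1i * ang)
  re <- Re(rot)[sel]
  sum(pmax(0, -re)^2) + 1e-3 * sum(abs(Re(rot)[sel_top] - abs(row)[sel_top]))
}

#' Automatic phase correction
#'
#' Estimates (ph0, ph1) by minimising a penalty on negative real intensity
#' over the signal region, with a small absorption-shape tie-break
#' (coarse grid search followed by Nelder-Mead refinement), then applies the
#' phases with [phase_spectra()]. In `"global"` mode the phases estimated on
#' the first increment are applied to all increments.
#'
#' @param spec a [spectrum_set()].
#' @param mode `"global"` or `"individual"`.
#' @return The phased [spectrum_set()]; the applied phases are recorded in
#'   `meta$autophase` as a matrix with columns ph0, ph1.
#' @export
autophase <- function(spec, mode = c("global", "individual")) {
  mode <- match.arg(mode)
  if (!inherits(spec, "spectrum_set")) stop_data("autophase expects a spectrum_set")
  sw <- sweep_width(spec)
  n_inc <- nrow(spec$data)
  rows <- if (mode == "global") 1L else seq_len(n_inc)
  est <- matrix(0, length(rows), 2)
  for (r in seq_along(rows)) {
    row <- spec$data[rows[r], ]
    mg <- abs(row)
    noise <- stats::mad(mg, center = 0)
    thr <- max(5 * noise, 0.02 * max(mg))
    sel <- mg > thr & spec$mask
    sel_top <- mg > 0.2 * max(mg) & spec$mask
    if (!any(sel)) {
      warn_nmr("autophase: no signal above the noise; returning (0, 0)")
      next
    }
    j <- which.max(mg * spec$mask)
    pivot_hz <- spec$axis_hz[j]
    grid <- expand.grid(ph0 = seq(-180, 170, by = 15), ph1 = seq(-180, 180, by = 20))
    # seed the grid with a per-peak phase regression: at a resolved peak
    # maximum the spectral phase equals the misphase at that frequency
    pk_idx <- which(mg > thr & spec$mask)
    pk_idx <- pk_idx[pk_idx > 1L & pk_idx < length(mg)]
    pk_idx <- pk_idx[mg[pk_idx] >= mg[pk_idx - 1L] & mg[pk_idx] > mg[pk_idx + 1L]]
    if (length(pk_idx) >= 1L) {
      th <- Arg(row[pk_idx]) * 180 / pi
      x <- (spec$axis_hz[pk_idx] - pivot_hz) / sw
      th <- th - th[which(pk_idx == j)][1]
      th <- ((th + 180) %% 360) - 180   # unwrap relative to the pivot peak
      ph1_0 <- if (length(pk_idx) > 1L) -sum(th * x) / sum(x^2) else 0
      ph0_0 <- -mean(Arg(row[j]) * 180 / pi)
      grid <- rbind(grid, c(ph0_0, ph1_0))
    }
    vals <- apply(grid, 1L, function(p)
      autophase_objective(p, row, spec$axis_hz, pivot_hz, sw, sel, sel_top))
    best <- as.numeric(grid[which.min(vals), ])
    opt <- stats::optim(best, autophase_objective, row = row, axis_hz = spec$axis_hz,
                        pivot_hz = pivot_hz, sw = sw, sel = sel, sel_top = sel_top,
                        method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-12))
    opt <- stats::optim(opt$par, autophase_objective, row = row, axis_hz = spec$axis_hz,
                        pivot_hz = pivot_hz, sw = sw, sel = sel, sel_top = sel_top,
                        method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-12))
    est[r, ] <- opt$par
  }
  est[, 1] <- ((est[, 1] + 180) %% 360) - 180
  if (mode == "global") {
    out <- phase_spectra(spec, est[1, 1], est[1, 2], mode = "global")
    est <- matrix(est, n_inc, 2, byrow = TRUE)
  } else {
    out <- phase_spectra(spec, est[, 1], est[, 2], mode = "individual")
  }
  colnames(est) <- c("ph0", "ph1")
  out$meta$autophase <- est
  out
}

#' Polynomial baseline correction
#'
#' Fits a polynomial of degree `order` to the real part of each spectrum
#' over the baseline (non-signal) points and subtracts it. With
#' `signal_regions = "auto"` the baseline set is found iteratively: fit,
#' re-classify points with |residual| < 3 sigma as baseline, refit, until the
#' classification is stable (at most 20 iterations).
#'
#' @param spec a [spectrum_set()].
#' @param signal_regions list of ppm intervals `c(lo, hi)` containing signal
#'   (excluded from the fit), or `"auto"`.
#' @param order polynomial degree.
#' @export
baseline_correct <- function(spec, signal_regions = "auto", order = 2) {
  if (!inherits(spec, "spectrum_set")) stop_data("baseline_correct expects a spectrum_set")
  fn <- ncol(spec$data)
  x <- seq(-1, 1, length.out = fn)   # scaled abscissa for conditioning
  basis <- if (order >= 1) cbind(1, stats::poly(x, degree = order, raw = FALSE))
           else matrix(1, fn, 1)
  auto <- identical(signal_regions, "auto")
  if (!auto) {
    ppm <- axis_ppm(spec)
    base_sel <- rep(TRUE, fn)
    for (rg in signal_regions) base_sel[ppm >= min(rg) & ppm <= max(rg)] <- FALSE
    if (sum(base_sel) <= order + 1L)
      stop_data("polynomial order %d needs more than %d baseline points", order, sum(base_sel))
  }
  for (i in seq_len(nrow(spec$data))) {
    re <- Re(spec$data[i, ])
    if (auto) {
      sel <- rep(TRUE, fn)
      for (it in seq_len(20L)) {
        fit <- stats::lm.fit(basis[sel, , drop = FALSE], re[sel])
        pred <- drop(basis %*% fit$coefficients)
        r <- re - pred
        sigma <- stats::sd(r[sel])
        new_sel <- abs(r) < 3 * sigma
        if (sum(new_sel) <= order + 1L) break
        if (identical(new_sel, sel)) { sel <- new_sel; break }
        sel <- new_sel
      }
    } else {
      sel <- base_sel
    }
    fit <- stats::lm.fit(basis[sel, , drop = FALSE], re[sel])
    pred <- drop(basis %*% fit$coefficients)
    spec$data[i, ] <- complex(real = re - pred, imaginary = Im(spec$data[i, ]))
  }
  spec
}

#' Set the chemical shift reference
#'
#' Shifts the ppm calibration so that the peak observed at
#' `peak_ppm_observed` reads `ppm_assigned`; the underlying Hz axis is
#' untouched.
#'
#' @param spec a [spectrum_set()].
#' @param peak_ppm_observed current ppm reading of the reference peak.
#' @param ppm_assigned ppm value it should read.
#' @export
set_reference <- function(spec, peak_ppm_observed, ppm_assigned) {
  if (!inherits(spec, "spectrum_set")) stop_data("set_reference expects a spectrum_set")
  hz <- ppm_to_hz(peak_ppm_observed, spec$sfrq, spec$ref_offset_hz)
  spec$ref_offset_hz <- hz - ppm_assigned * spec$sfrq
  spec
}

#' @export
plot.spectrum_set <- function(x, increment = 1, xlab = "ppm", ...) {
  ppm <- axis_ppm(x)
  graphics::plot(ppm, Re(x$data[increment, ]), type = "l", xlim = rev(range(ppm)),
                 xlab = xlab, ylab = "intensity", ...)
  invisible(x)
}
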