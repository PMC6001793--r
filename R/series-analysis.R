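#' @title Arrayed-spectra diagnostics
#' @description Per-increment peak tracking (frequency, linewidth,
#'   amplitude), temperature estimation from a reference-peak shift,
#'   phase-deviation estimation from dispersion-mode peak excursions,
#'   integration with baseline tilt correction, spectral binning and
#'   alignment.
#' @name series-analysis
NULL

#' Temperature calibration constants
#'
#' ppm-per-kelvin temperature coefficients of the HDO and TSP chemical
#' shifts in D2O (2.97e-4 and 1.14e-2 ppm/K respectively).
#'
#' @param mode `"hdo"` or `"tsp"`.
#' @param coeff_hdo,coeff_tsp coefficients, ppm/K (> 0).
#' @export
temperature_calibration <- function(mode = c("hdo", "tsp"),
                                    coeff_hdo = 2.97e-4, coeff_tsp = 1.14e-2) {
  mode <- match.arg(mode)
  if (coeff_hdo <= 0 || coeff_tsp <= 0) stop_data("temperature coefficients must be > 0")
  structure(list(mode = mode, coeff_hdo = coeff_hdo, coeff_tsp = coeff_tsp,
                 coeff = if (mode == "hdo") coeff_hdo else coeff_tsp),
            class = "temperature_calibration")
}

fwhm_interp <- function(re, j, axis_hz) {
  half <- re[j] / 2
  fn <- length(re)
  l <- j
  while (l > 1L && re[l] > half) l <- l - 1L
  r <- j
  while (r < fn && re[r] > half) r <- r + 1L
  if (re[l] > half || re[r] > half) return(NA_real_)
  fl <- axis_hz[l] + (axis_hz[l + 1L] - axis_hz[l]) * (re[l] - half) / (re[l] - re[l + 1L])
  fr <- axis_hz[r] + (axis_hz[r - 1L] - axis_hz[r]) * (re[r] - half) / (re[r] - re[r - 1L])
  abs(fl - fr)
}

#' Track the tallest peak across an array
#'
#' For each increment the tallest real-part peak above `threshold` within
#' the window is located (parabolic position refinement) and its full width
#' at half height is measured by linear interpolation. Increments with no
#' peak above threshold yield `NA` rows rather than errors.
#'
#' @param spec a [spectrum_set()].
#' @param window_ppm optional `c(lo, hi)` ppm window.
#' @param threshold intensity threshold (default 0).
#' @return data.frame with one row per increment: `position_ppm`,
#'   `fwhm_hz`, `amplitude`.
#' @export
track_peak <- function(spec, window_ppm = NULL, threshold = 0) {
  if (!inherits(spec, "spectrum_set")) stop_data("track_peak expects a spectrum_set")
  ppm <- axis_ppm(spec)
  ok <- spec$mask
  if (!is.null(window_ppm)) ok <- ok & ppm >= min(window_ppm) & ppm <= max(window_ppm)
  n_inc <- nrow(spec$data)
  out <- data.frame(position_ppm = rep(NA_real_, n_inc), fwhm_hz = NA_real_,
                    amplitude = NA_real_)
  step_ppm <- ppm[2] - ppm[1]
  for (i in seq_len(n_inc)) {
    re <- Re(spec$data[i, ])
    cand <- which(ok & re > threshold)
    if (!length(cand)) next
    j <- cand[which.max(re[cand])]
    if (j > 1L && j < length(re)) {
      y0 <- re[j - 1L]; y1 <- re[j]; y2 <- re[j + 1L]
      denom <- y0 - 2 * y1 + y2
      frac <- if (abs(denom) > 0) max(min(0.5 * (y0 - y2) / denom, 0.5), -0.5) else 0
      out$position_ppm[i] <- ppm[j] + frac * step_ppm
      out$amplitude[i] <- y1 - 0.25 * (y0 - y2) * frac
    } else {
      out$position_ppm[i] <- ppm[j]
      out$amplitude[i] <- re[j]
    }
    out$fwhm_hz[i] <- fwhm_interp(re, j, spec$axis_hz)
  }
  out
}

#' Temperature change from reference-peak positions
#'
#' Delta T_i = (delta_i - delta_1) / coeff: the change relative to the first
#' increment, assuming the tracked peak (HDO or TSP in D2O) moves to higher
#' ppm as the temperature rises with the calibration slope.
#'
#' @param positions_ppm per-increment peak positions (e.g.
#'   `track_peak(...)$position_ppm`).
#' @param calibration a [temperature_calibration()].
#' @return numeric vector of temperature changes, K (first element 0).
#' @export
estimate_temperature_change <- function(positions_ppm, calibration = temperature_calibration("hdo")) {
  if (!inherits(calibration, "temperature_calibration"))
    stop_config("calibration must be a temperature_calibration")
  (positions_ppm - positions_ppm[1]) / calibration$coeff
}

#' Phase deviation from dispersion-mode excursions
#'
#' The spectrum phase is temporarily shifted by +90 deg so that a small
#' phase deviation phi turns into an asymmetry of the positive and negative
#' peak excursions P and N of the near-dispersion line:
#' rho = (P - N)/(P + N). For a Lorentzian lineshape the excursions have the
#' closed forms P = cos^2(phi) / (2w(1 - sin phi)) and
#' N = cos^2(phi) / (2w(1 + sin phi)) (half-width w), so rho = -sin(phi),
#' inverted exactly as phi = -asin(rho) (monotone for |phi| < 90 deg).
#'
#' @param spec a [spectrum_set()] with a near-Lorentzian line in the window
#'   (apply broad Lorentzian apodisation first if needed).
#' @param window_ppm `c(lo, hi)` ppm window containing the line.
#' @return numeric vector: phase deviation per increment, degrees; `NA`
#'   with a warning where |rho| leaves the invertible range.
#' @export
estimate_phase_deviation <- function(spec, window_ppm = NULL) {
  if (!inherits(spec, "spectrum_set")) stop_data("estimate_phase_deviation expects a spectrum_set")
  shifted <- phase_spectra(spec, ph0 = 90, ph1 = 0, mode = "global")
  ppm <- axis_ppm(spec)
  ok <- spec$mask
  if (!is.null(window_ppm)) ok <- ok & ppm >= min(window_ppm) & ppm <= max(window_ppm)
  vapply(seq_len(nrow(spec$data)), function(i) {
    re <- Re(shifted$data[i, ok])
    P <- max(re); N <- -min(re)
    if (P + N <= 0) return(NA_real_)
    rho <- (P - N) / (P + N)
    if (abs(rho) > 1) {
      warn_nmr("phase deviation: excursion ratio outside the invertible range")
      return(NA_real_)
    }
    -asin(rho) * 180 / pi
  }, numeric(1))
}

#' Integrate spectral regions
#'
#' Region sum times the ppm step. `tilt_correction` subtracts, per region,
#' the straight line through the means of the first and last
#' max(1, 3% of region) points (baseline offset and tilt). With
#' `normalize_region` the row of integrals is scaled so that region reads
#' `normalize_value`.
#'
#' @param spec a [spectrum_set()].
#' @param regions list of `c(lo, hi)` ppm intervals.
#' @param tilt_correction subtract the edge-to-edge baseline line.
#' @param normalize_region index into `regions`, or `NULL`.
#' @param normalize_value target value for the normalisation region.
#' @return matrix [n_increments x n_regions] of integrals.
#' @export
integrate_regions <- function(spec, regions, tilt_correction = TRUE,
                              normalize_region = NULL, normalize_value = 100) {
  if (!inherits(spec, "spectrum_set")) stop_data("integrate_regions expects a spectrum_set")
  ppm <- axis_ppm(spec)
  step <- abs(ppm[2] - ppm[1])
  out <- matrix(NA_real_, nrow(spec$data), length(regions))
  for (rix in seq_along(regions)) {
    rg <- regions[[rix]]
    sel <- which(ppm >= min(rg) & ppm <= max(rg) & spec$mask)
    if (!length(sel)) stop_data("integral region [%g, %g] ppm is empty", min(rg), max(rg))
    m <- max(1L, round(0.03 * length(sel)))
    for (i in seq_len(nrow(spec$data))) {
      re <- Re(spec$data[i, sel])
      if (tilt_correction && length(sel) > 2L * m) {
        x <- seq_along(re)
        x1 <- mean(x[seq_len(m)]); y1 <- mean(re[seq_len(m)])
        x2 <- mean(x[length(x) - seq_len(m) + 1L]); y2 <- mean(re[length(x) - seq_len(m) + 1L])
        slope <- (y2 - y1) / (x2 - x1)
        re <- re - (y1 + slope * (x - x1))
      }
      out[i, rix] <- sum(re) * step
    }
  }
  if (!is.null(normalize_region)) {
    ref <- out[, normalize_region]
    out <- out * normalize_value / ref
  }
  colnames(out) <- vapply(regions, function(rg) sprintf("%.3f..%.3f", min(rg), max(rg)), "")
  out
}

#' Bin spectra
#'
#' Sums real intensities into contiguous ppm bins; the total intensity is
#' conserved.
#'
#' @param spec a [spectrum_set()].
#' @param bin_width_ppm bin width, ppm.
#' @return list with `matrix` [n_increments x n_bins] and `centers_ppm`.
#' @export
bin_spectra <- function(spec, bin_width_ppm) {
  if (!inherits(spec, "spectrum_set")) stop_data("bin_spectra expects a spectrum_set")
  if (bin_width_ppm <= 0) stop_data("bin width must be > 0")
  ppm <- axis_ppm(spec)
  lo <- min(ppm); hi <- max(ppm)
  n_bins <- max(1L, ceiling((hi - lo) / bin_width_ppm - 1e-9))
  edges <- lo + bin_width_ppm * seq.int(0L, n_bins)
  idx <- pmin(pmax(findInterval(ppm, edges, rightmost.closed = TRUE), 1L), n_bins)
  M <- matrix(0, nrow(spec$data), n_bins)
  for (i in seq_len(nrow(spec$data))) {
    re <- Re(spec$data[i, ])
    M[i, ] <- vapply(seq_len(n_bins), function(b) sum(re[idx == b]), numeric(1))
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  list(matrix = M, centers_ppm = centers)
}

shift_row <- function(v, k) {
  # integer-point shift toward higher index, zero-filled (non-circular)
  n <- length(v)
  out <- rep(0 * v[1], n)
  if (k >= 0) {
    if (k < n) out[(k + 1L):n] <- v[seq_len(n - k)]
  } else {
    if (-k < n) out[seq_len(n + k)] <- v[(-k + 1L):n]
  }
  out
}

#' Align a series of spectra
#'
#' Manual mode applies a per-increment integer-point shift (edges
#' zero-filled, non-circular). Auto mode shifts each interval of each
#' increment by the integer offset maximising the cross-correlation with
#' the median spectrum, searching within `max_shift` points.
#'
#' @param spec a [spectrum_set()].
#' @param shifts integer vector, one per increment (manual mode).
#' @param intervals list of `c(lo, hi)` ppm intervals (auto mode); default
#'   one interval covering the full axis.
#' @param max_shift search half-window, points (auto mode).
#' @return the aligned [spectrum_set()]; applied shifts are recorded in
#'   `meta$align_shifts`.
#' @export
align_spectra <- function(spec, shifts = NULL, intervals = NULL, max_shift = 50L) {
  if (!inherits(spec, "spectrum_set")) stop_data("align_spectra expects a spectrum_set")
  n_inc <- nrow(spec$data)
  if (!is.null(shifts)) {
    shifts <- rep_len(as.integer(shifts), n_inc)
    for (i in seq_len(n_inc)) spec$data[i, ] <- shift_row(spec$data[i, ], shifts[i])
    spec$meta$align_shifts <- matrix(shifts, ncol = 1)
    return(spec)
  }
  ppm <- axis_ppm(spec)
  if (is.null(intervals)) intervals <- list(range(ppm))
  target <- apply(Re(spec$data), 2L, stats::median)
  rec <- matrix(0L, n_inc, length(intervals))
  for (rix in seq_along(intervals)) {
    rg <- intervals[[rix]]
    sel <- which(ppm >= min(rg) & ppm <= max(rg))
    tg <- target[sel]
    for (i in seq_len(n_inc)) {
      seg <- Re(spec$data[i, sel])
      ks <- seq.int(-max_shift, max_shift)
      cc <- vapply(ks, function(k) sum(shift_row(seg, k) * tg), numeric(1))
      k <- ks[which.max(cc)]
      rec[i, rix] <- k
      spec$data[i, sel] <- shift_row(spec$data[i, sel], k)
    }
  }
  spec$meta$align_shifts <- rec
  spec
}
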