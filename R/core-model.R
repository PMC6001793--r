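#' @title Domain model for arrayed 1D NMR data
#' @description Constructors and helpers for the in-memory containers shared
#'   by every processing and analysis function: time-domain [fid_set()],
#'   frequency-domain [spectrum_set()], increment axes, apodisation
#'   parameters, and the diffusion/relaxation encodings.
#' @name core-model
NULL

#' Magnetogyric ratio of 1H
#'
#' In rad s^-1 T^-1; the default for diffusion encodings.
#' @export
GAMMA_1H <- 2.6752218744e8

as_complex_matrix <- function(data) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  if (!is.complex(data)) storage.mode(data) <- "complex"
  data
}

#' Increment axis of an arrayed acquisition
#'
#' Describes the variable stepped between the rows of an array: gradient
#' amplitude (T/m), a delay or evolution time (s), a loop counter, or a
#' generic index.
#'
#' @param values numeric vector, one entry per step along this axis.
#' @param kind one of `"gradient"`, `"delay"`, `"counter"`, `"time"`,
#'   `"generic"`.
#' @param label free text.
#' @return An object of class `increment_axis`.
#' @export
increment_axis <- function(values, kind = c("gradient", "delay", "counter", "time", "generic"),
                           label = "") {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) == 0L) stop_data("increment axis must have at least one value")
  if (any(!is.finite(values))) stop_data("increment axis values must be finite")
  if (kind == "gradient" && any(values < 0)) stop_data("gradient values must be >= 0")
  structure(list(kind = kind, values = values, label = label), class = "increment_axis")
}

#' Time-domain data set (one or more FIDs)
#'
#' The universal input object: a complex matrix with one free induction
#' decay per row, plus the acquisition metadata needed to interpret it.
#' A two-axis array is stored flattened row-major with the first axis
#' fastest (Bruker `ser` ordering).
#'
#' @param data complex matrix, increments in rows, points in columns
#'   (a plain vector is taken as a single FID).
#' @param dwell seconds per complex point.
#' @param sfrq spectrometer frequency in MHz.
#' @param ref_offset_hz frequency of the ppm-axis zero relative to the
#'   carrier, Hz.
#' @param arrays list of up to two [increment_axis()] records whose lengths
#'   multiply to the number of rows.
#' @param meta free-form provenance list.
#' @return An object of class `fid_set`.
#' @export
fid_set <- function(data, dwell, sfrq, ref_offset_hz = 0, arrays = list(), meta = list()) {
  data <- as_complex_matrix(data)
  if (ncol(data) < 2L) stop_data("fid_set needs at least 2 complex points")
  if (!is.numeric(dwell) || !is.finite(dwell) || dwell <= 0) stop_data("dwell must be > 0")
  if (!is.numeric(sfrq) || !is.finite(sfrq) || sfrq <= 0) stop_data("sfrq must be > 0")
  if (!is.finite(ref_offset_hz)) stop_data("ref_offset_hz must be finite")
  check_arrays(arrays, nrow(data))
  structure(list(data = data, dwell = dwell, sfrq = sfrq,
                 ref_offset_hz = ref_offset_hz, arrays = arrays, meta = meta),
            class = "fid_set")
}

check_arrays <- function(arrays, n_inc) {
  if (length(arrays) > 2L) stop_data("at most two increment axes are supported")
  for (a in arrays) {
    if (!inherits(a, "increment_axis")) stop_data("arrays must contain increment_axis objects")
  }
  if (length(arrays)) {
    n <- prod(vapply(arrays, function(a) length(a$values), numeric(1)))
    if (n != n_inc) {
      stop_data("increment axis lengths (product %d) do not match %d increments", n, n_inc)
    }
  }
  invisible(TRUE)
}

#' Frequency-domain data set
#'
#' The universal processed object: complex spectra (one per row) with a
#' uniform descending frequency axis (left = high ppm) and the cumulative
#' phase state.
#'
#' @param data complex matrix, increments in rows, `fn` frequency points in
#'   columns.
#' @param axis_hz descending frequency axis, Hz relative to the carrier.
#' @param sfrq spectrometer frequency, MHz.
#' @param ref_offset_hz Hz position of ppm zero (see [fid_set()]).
#' @param ph0,ph1 cumulative zeroth/first order phase applied, degrees.
#' @param pivot_hz first-order phase pivot, Hz.
#' @param arrays,meta as in [fid_set()].
#' @param mask optional logical vector, `FALSE` marks columns excluded from
#'   analysis (set by [prune()]).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(data, axis_hz, sfrq, ref_offset_hz = 0, ph0 = 0, ph1 = 0,
                         pivot_hz = 0, arrays = list(), meta = list(), mask = NULL) {
  data <- as_complex_matrix(data)
  fn <- ncol(data)
  if (length(axis_hz) != fn) stop_data("axis_hz length must equal number of columns")
  d <- diff(axis_hz)
  if (any(d >= 0)) stop_data("axis_hz must be strictly descending")
  if (fn > 2L && diff(range(d)) > 1e-6 * abs(mean(d))) stop_data("axis_hz spacing must be uniform")
  if (is.null(mask)) mask <- rep(TRUE, fn)
  if (length(mask) != fn) stop_data("mask length must equal fn")
  check_arrays(arrays, nrow(data))
  structure(list(data = data, axis_hz = axis_hz, sfrq = sfrq,
                 ref_offset_hz = ref_offset_hz, ph0 = ph0, ph1 = ph1,
                 pivot_hz = pivot_hz, arrays = arrays, meta = meta, mask = mask),
            class = "spectrum_set")
}

#' Apodisation parameters
#'
#' `lw` and `gw` are the additional Lorentzian and Gaussian linewidths at
#' half height (Hz) that time-domain weighting convolves into the spectrum.
#' `lw` may be negative (Lorentz-Gauss resolution enhancement); `gw >= 0`.
#'
#' @param lw Lorentzian broadening, Hz.
#' @param gw Gaussian broadening, Hz.
#' @export
apod_params <- function(lw = 0, gw = 0) {
  if (!is.finite(lw) || !is.finite(gw)) stop_data("lw and gw must be finite")
  if (gw < 0) stop_data("gw must be >= 0")
  structure(list(lw = lw, gw = gw), class = "apod_params")
}

#' Diffusion encoding (Stejskal-Tanner constants)
#'
#' Gradient amplitudes plus the constants of the attenuation law
#' I(g) = I0 exp(-gamma^2 delta^2 g^2 D Delta'), optionally generalised by
#' non-uniform-gradient (NUG) power-series coefficients.
#'
#' @param g gradient amplitudes, T/m, one per increment.
#' @param gamma magnetogyric ratio, rad s^-1 T^-1.
#' @param delta gradient pulse duration, s.
#' @param big_delta_prime corrected diffusion-encoding time Delta', s.
#' @param nug_coeffs coefficients c_1..c_m of the NUG exponent
#'   sum_m c_m (gamma^2 delta^2 g^2 Delta' D)^m; `c(1)` disables NUG.
#' @param sequence_type `"bipolar"`, `"monopolar"` or `"other"`.
#' @export
diffusion_encoding <- function(g, gamma = GAMMA_1H, delta = 2e-3, big_delta_prime = 0.1,
                               nug_coeffs = 1, sequence_type = c("bipolar", "monopolar", "other")) {
  sequence_type <- match.arg(sequence_type)
  g <- as.numeric(g)
  if (any(g < 0)) stop_data("gradient amplitudes must be >= 0")
  if (delta <= 0) stop_data("delta must be > 0")
  if (big_delta_prime <= 0) stop_data("big_delta_prime must be > 0")
  if (length(nug_coeffs) < 1L || nug_coeffs[1] != 1)
    stop_data("nug_coeffs[1] must be 1 (c1 = 1; pure exponential when nug_coeffs = 1)")
  structure(list(g = g, gamma = gamma, delta = delta,
                 big_delta_prime = big_delta_prime, nug_coeffs = as.numeric(nug_coeffs),
                 sequence_type = sequence_type),
            class = "diffusion_encoding")
}

#' Exponent variable of the Stejskal-Tanner law
#'
#' X_i = gamma^2 delta^2 g_i^2 Delta', so that the pure-exponential
#' attenuation is exp(-X_i D).
#'
#' @param encoding a [diffusion_encoding()].
#' @return numeric vector, s/m^2.
#' @export
st_exponent <- function(encoding) {
  encoding$gamma^2 * encoding$delta^2 * encoding$g^2 * encoding$big_delta_prime
}

#' Relaxation encoding
#'
#' @param times evolution times, s (used directly), or `NULL` when
#'   `counters` are given.
#' @param mode `"inversion_recovery"`, `"saturation_recovery"` or `"t2_decay"`.
#' @param counters optional loop counters (e.g. a `vclist`); effective times
#'   are `counters * loop_duration`.
#' @param loop_duration s; multiplies counters, required with them.
#' @export
relaxation_encoding <- function(times = NULL,
                                mode = c("inversion_recovery", "saturation_recovery", "t2_decay"),
                                counters = NULL, loop_duration = NULL) {
  mode <- match.arg(mode)
  if (is.null(times)) {
    if (is.null(counters)) stop_data("either times or counters must be given")
    if (is.null(loop_duration) || loop_duration <= 0)
      stop_data("loop_duration must be > 0 when counters are supplied")
    times <- as.numeric(counters) * loop_duration
  }
  times <- as.numeric(times)
  if (any(times <= 0)) stop_data("evolution times must be strictly positive")
  if (any(diff(sort(times)) <= 0)) stop_data("evolution times must be distinct")
  structure(list(times = times, mode = mode, counters = counters,
                 loop_duration = loop_duration),
            class = "relaxation_encoding")
}

#' @export
print.fid_set <- function(x, ...) {
  cat(sprintf("<fid_set> %d increment(s) x %d complex points\n", nrow(x$data), ncol(x$data)))
  cat(sprintf("  dwell %.6g s (sweep width %.6g Hz), sfrq %.6g MHz\n",
              x$dwell, 1 / x$dwell, x$sfrq))
  for (a in x$arrays) {
    cat(sprintf("  axis [%s] %d values%s\n", a$kind, length(a$values),
                if (nzchar(a$label)) paste0(" (", a$label, ")") else ""))
  }
  invisible(x)
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d increment(s) x fn %d\n", nrow(x$data), ncol(x$data)))
  cat(sprintf("  axis %.6g .. %.6g Hz (%.4g .. %.4g ppm), ph0 %.3g deg, ph1 %.3g deg\n",
              x$axis_hz[1], x$axis_hz[length(x$axis_hz)],
              axis_ppm(x)[1], axis_ppm(x)[length(x$axis_hz)], x$ph0[1], x$ph1[1]))
  if (!all(x$mask)) cat(sprintf("  %d of %d columns masked out\n", sum(!x$mask), ncol(x$data)))
  invisible(x)
}

n_increments <- function(x) nrow(x$data)
n_points <- function(x) ncol(x$data)
sweep_width <- function(x) {
  if (inherits(x, "fid_set")) 1 / x$dwell else abs(x$axis_hz[1] - x$axis_hz[length(x$axis_hz)]) *
      length(x$axis_hz) / (length(x$axis_hz) - 1)
}

#' Convert chemical shift to frequency
#'
#' `hz = ppm * sfrq + ref_offset_hz`, with frequencies measured relative to
#' the carrier; [hz_to_ppm()] is the exact inverse.
#'
#' @param ppm chemical shift(s), ppm.
#' @param sfrq spectrometer frequency, MHz.
#' @param ref_offset_hz Hz position of ppm zero.
#' @export
ppm_to_hz <- function(ppm, sfrq, ref_offset_hz = 0) {
  if (any(!is.finite(ppm)) || !is.finite(sfrq) || !is.finite(ref_offset_hz))
    stop_data("non-finite input to ppm_to_hz")
  if (sfrq <= 0) stop_data("sfrq must be > 0")
  ppm * sfrq + ref_offset_hz
}

#' @rdname ppm_to_hz
#' @param hz frequency (relative to carrier), Hz.
#' @export
hz_to_ppm <- function(hz, sfrq, ref_offset_hz = 0) {
  if (any(!is.finite(hz)) || !is.finite(sfrq) || !is.finite(ref_offset_hz))
    stop_data("non-finite input to hz_to_ppm")
  if (sfrq <= 0) stop_data("sfrq must be > 0")
  (hz - ref_offset_hz) / sfrq
}

#' ppm axis of a spectrum set
#' @param spec a [spectrum_set()].
#' @export
axis_ppm <- function(spec) hz_to_ppm(spec$axis_hz, spec$sfrq, spec$ref_offset_hz)

#' Remove increments and mask spectral regions
#'
#' Increments named in `drop_increments` are deleted from the data and from
#' every increment axis in lockstep. For spectra, `drop_regions` (a list of
#' ppm intervals `c(lo, hi)`) marks the corresponding columns as masked:
#' they stay in the data but are excluded from peak picking, fitting,
#' decomposition and integration.
#'
#' @param x a [fid_set()] or [spectrum_set()].
#' @param drop_increments integer indices of rows to remove.
#' @param drop_regions list of length-2 ppm intervals (spectra only).
#' @return object of the same class.
#' @export
prune <- function(x, drop_increments = integer(), drop_regions = list()) {
  UseMethod("prune")
}

prune_rows <- function(x, drop_increments) {
  if (!length(drop_increments)) return(x)
  drop_increments <- unique(as.integer(drop_increments))
  if (any(drop_increments < 1L | drop_increments > nrow(x$data)))
    stop_data("drop_increments out of range")
  keep <- setdiff(seq_len(nrow(x$data)), drop_increments)
  if (!length(keep)) stop_data("cannot prune all increments")
  x$data <- x$data[keep, , drop = FALSE]
  if (length(x$arrays) == 1L) {
    x$arrays[[1]]$values <- x$arrays[[1]]$values[keep]
  } else if (length(x$arrays) == 2L) {
    # flattened two-axis arrays only support whole-slice pruning; fall back
    # to a generic axis when arbitrary rows are removed
    x$arrays <- list(increment_axis(seq_along(keep), kind = "generic", label = "pruned"))
  }
  x
}

#' @export
prune.fid_set <- function(x, drop_increments = integer(), drop_regions = list()) {
  if (length(drop_regions)) stop_data("spectral regions can only be pruned on a spectrum_set")
  prune_rows(x, drop_increments)
}

#' @export
prune.spectrum_set <- function(x, drop_increments = integer(), drop_regions = list()) {
  x <- prune_rows(x, drop_increments)
  if (length(drop_regions)) {
    ppm <- axis_ppm(x)
    for (rg in drop_regions) {
      if (length(rg) != 2L) stop_data("each drop region must be c(lo, hi) in ppm")
      sel <- ppm >= min(rg) & ppm <= max(rg)
      if (!any(sel)) stop_data("drop region [%g, %g] ppm is outside the axis", min(rg), max(rg))
      x$mask[sel] <- FALSE
    }
    if (!any(x$mask)) stop_data("cannot mask every point of the spectrum")
  }
  x
}
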