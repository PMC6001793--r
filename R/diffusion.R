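#' @title Univariate diffusion analysis (DOSY)
#' @description Peak picking, Stejskal-Tanner decay fitting (mono- and
#'   multi-exponential, with optional NUG correction) and construction of
#'   the pseudo-2D DOSY map.
#' @name diffusion
NULL

#' Stejskal-Tanner attenuation factor
#'
#' exp(-sum_m c_m (X_i D)^m) with X_i = gamma^2 delta^2 g_i^2 Delta'; the
#' pure exponential exp(-X_i D) when `nug_coeffs = 1`.
#'
#' @param encoding a [diffusion_encoding()].
#' @param D diffusion coefficient, m^2/s.
#' @param increments increment indices (default all).
#' @export
st_attenuation <- function(encoding, D, increments = NULL) {
  X <- st_exponent(encoding)
  if (!is.null(increments)) X <- X[increments]
  xd <- X * D
  expo <- 0
  for (m in seq_along(encoding$nug_coeffs)) expo <- expo + encoding$nug_coeffs[m] * xd^m
  exp(-expo)
}

#' Pick peaks in a spectrum
#'
#' Local maxima of the real part above `threshold`, restricted to
#' `window_ppm` when given and to unmasked columns; positions are refined by
#' three-point parabolic interpolation.
#'
#' @param spec a [spectrum_set()].
#' @param threshold absolute intensity threshold.
#' @param window_ppm optional `c(lo, hi)` ppm window.
#' @param increment row to pick on (default 1).
#' @return data.frame with columns `index`, `ppm`, `hz`, `height`.
#' @export
pick_peaks <- function(spec, threshold = 0, window_ppm = NULL, increment = 1L) {
  if (!inherits(spec, "spectrum_set")) stop_data("pick_peaks expects a spectrum_set")
  re <- Re(spec$data[increment, ])
  ppm <- axis_ppm(spec)
  ok <- spec$mask
  if (!is.null(window_ppm)) ok <- ok & ppm >= min(window_ppm) & ppm <= max(window_ppm)
  fn <- length(re)
  idx <- which(ok & re > threshold)
  idx <- idx[idx > 1L & idx < fn]
  is_max <- re[idx] >= re[idx - 1L] & re[idx] > re[idx + 1L]
  idx <- idx[is_max]
  # parabolic refinement in index space
  if (length(idx)) {
    y0 <- re[idx - 1L]; y1 <- re[idx]; y2 <- re[idx + 1L]
    denom <- (y0 - 2 * y1 + y2)
    frac <- ifelse(abs(denom) > 0, 0.5 * (y0 - y2) / denom, 0)
    frac <- pmax(pmin(frac, 0.5), -0.5)
    step_ppm <- ppm[2] - ppm[1]
    pos_ppm <- ppm[idx] + frac * step_ppm
    height <- y1 - 0.25 * (y0 - y2) * frac
  } else {
    pos_ppm <- numeric(0); height <- numeric(0)
  }
  data.frame(index = idx, ppm = pos_ppm,
             hz = ppm_to_hz(pos_ppm, spec$sfrq, spec$ref_offset_hz),
             height = height)
}

two_point_D_init <- function(y, X) {
  pos <- which(y > 0)
  if (length(pos) < 2L) return(1e-10)
  i <- pos[1]; j <- pos[length(pos)]
  if (X[j] == X[i]) return(1e-10)
  D0 <- log(y[i] / y[j]) / (X[j] - X[i])
  if (!is.finite(D0) || D0 <= 0) D0 <- 1 / max(X[X > 0])
  D0
}

new_peak_fit <- function(position_ppm, amplitude, params, se, rss, n, extra = list()) {
  structure(c(list(position_ppm = position_ppm, amplitude = amplitude,
                   params = params, se = se, rss = rss, n_points_used = n), extra),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  nm <- names(x$params)
  cat("<peak_fit>", if (!is.na(x$position_ppm)) sprintf("at %.4f ppm", x$position_ppm) else "", "\n")
  for (i in seq_along(x$params)) {
    cat(sprintf("  %s = %.6g (se %.3g)\n", nm[i], x$params[[i]], x$se[[i]]))
  }
  cat(sprintf("  rss %.4g over %d points\n", x$rss, x$n_points_used))
  invisible(x)
}

#' @export
coef.peak_fit <- function(object, ...) unlist(object$params)

#' Monoexponential Stejskal-Tanner fit (HR-DOSY)
#'
#' Nonlinear least squares for (I0, D) in
#' I_i = I0 exp(-sum_m c_m (X_i D)^m), initialised from a two-point
#' log-linear estimate. Standard errors come from the Jacobian at the
#' solution. Non-decaying data yield D at the lower bound with
#' `at_bound = TRUE`.
#'
#' @param decays amplitude per increment.
#' @param encoding a [diffusion_encoding()] (NUG coefficients honoured).
#' @param position_ppm optional peak position recorded in the result.
#' @return A `peak_fit` with parameters `I0`, `D`.
#' @export
fit_monoexp <- function(decays, encoding, position_ppm = NA_real_) {
  y <- as.numeric(decays)
  if (length(y) < 3L) stop_data("monoexponential fit needs at least 3 increments")
  X <- st_exponent(encoding)
  if (length(X) != length(y)) stop_data("decays and encoding lengths differ")
  cc <- encoding$nug_coeffs
  model <- function(I0, D) {
    xd <- X * D
    expo <- 0
    for (m in seq_along(cc)) expo <- expo + cc[m] * xd^m
    I0 * exp(-expo)
  }
  D0 <- two_point_D_init(y, X)
  fit <- try(minpack.lm::nlsLM(y ~ model(I0, D),
                               start = list(I0 = max(abs(y)), D = D0),
                               lower = c(I0 = -Inf, D = 0),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) stop_data("monoexponential fit failed: %s", as.character(fit))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(I0 = NA_real_, D = NA_real_))
  rss <- sum(stats::resid(fit)^2)
  at_bound <- cf[["D"]] <= .Machine$double.eps * max(1, 1 / max(X[X > 0]))
  if (at_bound) warn_nmr("non-decaying data: D at lower bound")
  new_peak_fit(position_ppm, cf[["I0"]], list(I0 = cf[["I0"]], D = cf[["D"]]),
               list(I0 = unname(se["I0"]), D = unname(se["D"])),
               rss, length(y), list(at_bound = at_bound))
}

fit_k_exponentials <- function(y, X, k, n_restarts = 3L) {
  n <- length(y)
  Xp <- X[X > 0]
  span <- c(0.1 / max(Xp), 3 / stats::median(Xp))
  best <- NULL
  inits <- list(exp(seq(log(span[1]), log(span[2]), length.out = k)))
  for (r in seq_len(n_restarts)) {
    jitter <- exp(stats::runif(k, -0.5, 0.5))
    inits[[r + 1L]] <- inits[[1]] * jitter
  }
  resid_fun <- function(par) {
    D <- exp(par)
    C <- exp(-outer(X, D))
    a <- stats::lm.fit(C, y)$coefficients
    y - drop(C %*% a)
  }
  for (D0 in inits) {
    fit <- try(minpack.lm::nls.lm(par = log(D0), fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(maxiter = 300)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(NULL)
  D <- exp(best$fit$par)
  C <- exp(-outer(X, D))
  ls <- stats::lsfit(C, y, intercept = FALSE)
  a <- ls$coefficients
  rss <- sum(ls$residuals^2)
  # standard errors by full-parameter Jacobian (a, D)
  se <- tryCatch({
    J <- cbind(C, -sweep(C * outer(X, rep(1, k)), 2, a, "*"))
    sc <- sqrt(colSums(J^2))          # rescale: D columns carry the 1/X scale
    sc[sc == 0] <- 1
    Js <- sweep(J, 2, sc, "/")
    sigma2 <- rss / max(1, n - 2 * k)
    cv <- sigma2 * solve(crossprod(Js))
    sqrt(pmax(diag(cv), 0)) / sc
  }, error = function(e) rep(NA_real_, 2 * k))
  ord <- order(D, decreasing = TRUE)
  list(I0 = a[ord], D = D[ord], rss = rss,
       se_I0 = se[seq_len(k)][ord], se_D = se[k + seq_len(k)][ord])
}

#' Multiexponential fit with statistical reduction
#'
#' Fits K, K-1, ... exponential components and keeps the largest k for which
#' the F-test of k against k-1 components is significant (p < `alpha`) and
#' every amplitude exceeds `amp_z` times its standard error. A model that
#' already fits to machine precision is never enlarged.
#'
#' @param decays amplitude per increment.
#' @param encoding a [diffusion_encoding()] (pure exponential kernel).
#' @param max_components K, the largest number of components tried.
#' @param alpha F-test significance level.
#' @param amp_z amplitude/SE threshold.
#' @return object of class `decay_model`: fields `n_components`, `I0`, `D`,
#'   `se_I0`, `se_D`, `rss`.
#' @export
fit_multiexp <- function(decays, encoding, max_components = 2L, alpha = 0.05, amp_z = 2) {
  y <- as.numeric(decays)
  X <- st_exponent(encoding)
  n <- length(y)
  if (max_components < 1L) stop_data("max_components must be >= 1")
  fits <- vector("list", max_components)
  for (k in seq_len(max_components)) {
    if (n < 2 * k + 1L) break
    fits[[k]] <- fit_k_exponentials(y, X, k)
  }
  tss <- sum(y^2)
  chosen <- 1L
  for (k in seq_len(max_components)[-1]) {
    if (is.null(fits[[k]]) || is.null(fits[[k - 1L]])) break
    rss_small <- fits[[k - 1L]]$rss
    rss_big <- fits[[k]]$rss
    if (rss_small <= 1e-14 * tss) break        # smaller model already exact
    df_big <- n - 2 * k
    if (df_big <= 0) break
    Fstat <- ((rss_small - rss_big) / 2) / (rss_big / df_big)
    p <- stats::pf(Fstat, 2, df_big, lower.tail = FALSE)
    amp_ok <- all(is.finite(fits[[k]]$se_I0)) &&
      all(abs(fits[[k]]$I0) > amp_z * fits[[k]]$se_I0)
    if (p < alpha && amp_ok) chosen <- k else break
  }
  f <- fits[[chosen]]
  structure(list(kind = if (length(encoding$nug_coeffs) > 1L) "nug" else "exponential",
                 n_components = chosen, I0 = f$I0, D = f$D,
                 se_I0 = f$se_I0, se_D = f$se_D, rss = f$rss),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("<decay_model> %d component(s)\n", x$n_components))
  for (k in seq_len(x$n_components)) {
    cat(sprintf("  I0 = %.6g, D = %.6g m^2/s (se %.3g)\n", x$I0[k], x$D[k], x$se_D[k]))
  }
  invisible(x)
}

#' Extract per-peak decay amplitudes across an array
#'
#' Real-part height at each picked peak index, per increment (HR-DOSY
#' practice).
#'
#' @param spec a [spectrum_set()] array.
#' @param peaks data.frame from [pick_peaks()].
#' @return matrix [n_increments x n_peaks].
#' @export
peak_decays <- function(spec, peaks) {
  sapply(peaks$index, function(j) Re(spec$data[, j]))
}

#' Pseudo-2D map from per-peak fits
#'
#' Each peak contributes a Gaussian ridge along the rate axis (log-spaced D
#' or linear T), centred at its fitted value with a standard deviation equal
#' to the fit standard error (floored at one bin), normalised so that the
#' ridge sums to the peak amplitude.
#'
#' @param fits list of `peak_fit`s (from [fit_monoexp()] or the relaxation
#'   fitters).
#' @param rate_range `c(lo, hi)` for the rate axis; default spans
#'   0.1x..10x the fitted values.
#' @param n_bins number of rate bins.
#' @param log_axis log-space the rate axis (TRUE for D).
#' @param param which fitted parameter to place (`"D"` or `"T"`).
#' @return object of class `pseudo_map`: `matrix` [n_peaks x n_bins],
#'   `shift_ppm`, `rate_axis`, `peaks`.
#' @export
build_pseudo_map <- function(fits, rate_range = NULL, n_bins = 64, log_axis = TRUE,
                             param = "D") {
  fits <- fits[!vapply(fits, is.null, logical(1))]
  vals <- vapply(fits, function(f) f$params[[param]], numeric(1))
  ses <- vapply(fits, function(f) {
    s <- f$se[[param]]
    if (is.null(s) || !is.finite(s)) 0 else s
  }, numeric(1))
  amps <- vapply(fits, function(f) f$amplitude, numeric(1))
  if (is.null(rate_range)) rate_range <- c(0.1 * min(vals), 10 * max(vals))
  axis <- if (log_axis) exp(seq(log(rate_range[1]), log(rate_range[2]), length.out = n_bins))
          else seq(rate_range[1], rate_range[2], length.out = n_bins)
  u <- if (log_axis) log(axis) else axis
  bin_w <- u[2] - u[1]
  M <- matrix(0, length(fits), n_bins)
  for (p in seq_along(fits)) {
    centre <- if (log_axis) log(vals[p]) else vals[p]
    sig <- if (log_axis) ses[p] / vals[p] else ses[p]   # delta-method on log scale
    sig <- max(sig, bin_w)                              # floor: one bin
    ridge <- exp(-0.5 * ((u - centre) / sig)^2)
    M[p, ] <- amps[p] * ridge / sum(ridge)
  }
  structure(list(matrix = M,
                 shift_ppm = vapply(fits, function(f) f$position_ppm, numeric(1)),
                 rate_axis = axis, peaks = fits, param = param, log_axis = log_axis),
            class = "pseudo_map")
}

#' @export
print.pseudo_map <- function(x, ...) {
  cat(sprintf("<pseudo_map> %d peak(s) x %d %s bins [%.3g .. %.3g]\n",
              nrow(x$matrix), ncol(x$matrix), x$param,
              x$rate_axis[1], x$rate_axis[length(x$rate_axis)]))
  invisible(x)
}

#' @export
plot.pseudo_map <- function(x, ...) {
  graphics::image(x$shift_ppm[order(x$shift_ppm)],
                  if (x$log_axis) log10(x$rate_axis) else x$rate_axis,
                  x$matrix[order(x$shift_ppm), , drop = FALSE],
                  xlab = "ppm", ylab = if (x$log_axis) paste0("log10 ", x$param) else x$param, ...)
  invisible(x)
}

#' One-call DOSY analysis
#'
#' Peak picking, per-peak monoexponential Stejskal-Tanner fits and map
#' construction.
#'
#' @param spec phased [spectrum_set()] array.
#' @param encoding a [diffusion_encoding()].
#' @param threshold peak-picking threshold (default 5% of the maximum).
#' @param n_bins,rate_range map axis controls, see [build_pseudo_map()].
#' @return list with `peaks` (data.frame incl. D and SE), `fits`, `map`.
#' @export
dosy <- function(spec, encoding, threshold = NULL, n_bins = 64, rate_range = NULL) {
  if (is.null(threshold)) threshold <- 0.05 * max(Re(spec$data[1, ]))
  pk <- pick_peaks(spec, threshold)
  if (!nrow(pk)) stop_data("no peaks above threshold")
  dec <- peak_decays(spec, pk)
  fits <- lapply(seq_len(nrow(pk)), function(p)
    fit_monoexp(dec[, p], encoding, position_ppm = pk$ppm[p]))
  map <- build_pseudo_map(fits, rate_range = rate_range, n_bins = n_bins,
                          log_axis = TRUE, param = "D")
  tab <- data.frame(ppm = pk$ppm,
                    D = vapply(fits, function(f) f$params$D, numeric(1)),
                    se_D = vapply(fits, function(f) f$se$D %||% NA_real_, numeric(1)),
                    I0 = vapply(fits, function(f) f$params$I0, numeric(1)),
                    rss = vapply(fits, function(f) f$rss, numeric(1)))
  list(peaks = tab, fits = fits, map = map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
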