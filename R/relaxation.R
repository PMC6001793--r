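#' @title Relaxation analysis (ROSY)
#' @description Per-peak T1/T2 fitting, the relaxation analogue of the DOSY
#'   map, and the RSCORE multivariate variant.
#' @name relaxation
NULL

relax_fit <- function(y, times, formula_env, start, lower, position_ppm, tname) {
  fit <- try(minpack.lm::nlsLM(formula_env$formula, data = formula_env$data,
                               start = start, lower = lower,
                               control = minpack.lm::nls.lm.control(maxiter = 300)),
             silent = TRUE)
  if (inherits(fit, "try-error")) stop_data("relaxation fit failed: %s", as.character(fit))
  cf <- as.list(stats::coef(fit))
  se <- tryCatch(as.list(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) stats::setNames(as.list(rep(NA_real_, length(cf))), names(cf)))
  new_peak_fit(position_ppm, cf[[1]], cf, se, sum(stats::resid(fit)^2), length(y))
}

#' T1 inversion-recovery fit
#'
#' Robust three-parameter fit I(tau) = A + B exp(-tau/T1) (B < 0 expected;
#' B = -2A for perfect inversion). `two_parameter = TRUE` fixes B = -2A.
#'
#' @param decays amplitude per increment.
#' @param times recovery delays tau, s (or a [relaxation_encoding()]).
#' @param two_parameter fix B = -2A.
#' @param position_ppm recorded in the result.
#' @return A `peak_fit` with parameters `A`, `B` (unless fixed), `T1`.
#' @export
fit_t1_ir <- function(decays, times, two_parameter = FALSE, position_ppm = NA_real_) {
  if (inherits(times, "relaxation_encoding")) times <- times$times
  y <- as.numeric(decays)
  A0 <- y[which.max(times)]
  T10 <- max(times) / 3
  d <- data.frame(y = y, tau = times)
  if (two_parameter) {
    fe <- list(formula = y ~ A * (1 - 2 * exp(-tau / T1)), data = d)
    fit <- relax_fit(y, times, fe, list(A = A0, T1 = T10),
                     c(A = -Inf, T1 = 1e-12), position_ppm, "T1")
  } else {
    fe <- list(formula = y ~ A + B * exp(-tau / T1), data = d)
    fit <- relax_fit(y, times, fe, list(A = A0, B = y[which.min(times)] - A0, T1 = T10),
                     c(A = -Inf, B = -Inf, T1 = 1e-12), position_ppm, "T1")
  }
  fit$params$T <- fit$params$T1
  fit$se$T <- fit$se$T1
  fit$amplitude <- abs(fit$params$A)
  fit
}

#' T1 saturation-recovery fit
#'
#' Two-parameter fit I(tau) = A (1 - exp(-tau/T1)).
#'
#' @inheritParams fit_t1_ir
#' @export
fit_t1_sr <- function(decays, times, position_ppm = NA_real_) {
  if (inherits(times, "relaxation_encoding")) times <- times$times
  y <- as.numeric(decays)
  d <- data.frame(y = y, tau = times)
  fe <- list(formula = y ~ A * (1 - exp(-tau / T1)), data = d)
  fit <- relax_fit(y, times, fe, list(A = y[which.max(times)], T1 = max(times) / 3),
                   c(A = -Inf, T1 = 1e-12), position_ppm, "T1")
  fit$params$T <- fit$params$T1
  fit$se$T <- fit$se$T1
  fit$amplitude <- abs(fit$params$A)
  fit
}

#' T2 decay fit (CPMG/PROJECT style)
#'
#' Fits I(t) = I0 exp(-t/T2), with t either given directly or as
#' `counters * loop_duration` (echo-train loop counters).
#'
#' @param decays amplitude per increment.
#' @param times echo times, s; or `NULL` when `counters` given.
#' @param counters loop counters (e.g. a `vclist`).
#' @param loop_duration seconds per loop, multiplies the counters.
#' @param position_ppm recorded in the result.
#' @return A `peak_fit` with parameters `I0`, `T2`.
#' @export
fit_t2 <- function(decays, times = NULL, counters = NULL, loop_duration = NULL,
                   position_ppm = NA_real_) {
  if (inherits(times, "relaxation_encoding")) times <- times$times
  if (is.null(times)) {
    if (is.null(counters) || is.null(loop_duration))
      stop_data("fit_t2 needs times, or counters plus loop_duration")
    times <- as.numeric(counters) * loop_duration
  }
  y <- as.numeric(decays)
  d <- data.frame(y = y, t = times)
  fe <- list(formula = y ~ I0 * exp(-t / T2), data = d)
  fit <- relax_fit(y, times, fe,
                   list(I0 = y[which.min(times)], T2 = max(times) / 3),
                   c(I0 = -Inf, T2 = 1e-12), position_ppm, "T2")
  fit$params$T <- fit$params$T2
  fit$se$T <- fit$se$T2
  fit$amplitude <- abs(fit$params$I0)
  fit
}

#' Pseudo-2D relaxation (ROSY) map
#'
#' As [build_pseudo_map()] over relaxation time T (or rate 1/T).
#'
#' @param fits list of `peak_fit`s from the relaxation fitters.
#' @param rate if `TRUE` plot 1/T instead of T.
#' @param rate_range,n_bins axis controls.
#' @export
build_rosy_map <- function(fits, rate = FALSE, rate_range = NULL, n_bins = 64) {
  if (rate) {
    fits <- lapply(fits, function(f) {
      tv <- f$params$T
      se <- f$se$T
      f$params$R <- 1 / tv
      f$se$R <- if (is.null(se) || !is.finite(se)) 0 else se / tv^2
      f
    })
    build_pseudo_map(fits, rate_range = rate_range, n_bins = n_bins,
                     log_axis = TRUE, param = "R")
  } else {
    build_pseudo_map(fits, rate_range = rate_range, n_bins = n_bins,
                     log_axis = TRUE, param = "T")
  }
}

#' RSCORE: multivariate relaxation resolution
#'
#' The [score_fit()] machinery with a relaxation kernel (`"t1ir"`, `"t1sr"`
#' or `"t2"`), fitting one T per component.
#'
#' @param X numeric matrix [n_increments x fn] or [spectrum_set()].
#' @param encoding a [relaxation_encoding()] (or times vector).
#' @param opts a [decomposition_options()] with a relaxation kernel; the
#'   default kernel follows the encoding's mode.
#' @export
rscore_fit <- function(X, encoding, opts = NULL) {
  if (is.numeric(encoding)) encoding <- relaxation_encoding(encoding, mode = "t2_decay")
  if (is.null(opts)) {
    kern <- switch(encoding$mode,
                   inversion_recovery = "t1ir",
                   saturation_recovery = "t1sr",
                   t2_decay = "t2")
    opts <- decomposition_options(n_components = 1L, kernel = kern, init = "logspace")
  }
  if (!opts$kernel %in% c("t1ir", "t1sr", "t2"))
    stop_config("rscore_fit needs a relaxation kernel")
  fit <- score_fit(X, encoding, opts)
  fit$method <- "RSCORE"
  fit
}
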