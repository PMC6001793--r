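#' @title Trilinear (PARAFAC) analysis and PowerSlicing
#' @description Alternating-least-squares PARAFAC for three-way arrays,
#'   PowerSlicing to trilinearise exponential two-way data, and factor
#'   diagnostics (leverages, residuals).
#' @name multiway
NULL

khatri_rao <- function(A, B) {
  # columnwise Kronecker: rows indexed (a-1)*nrow(B) + b
  F <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), F)
  for (f in seq_len(F)) out[, f] <- kronecker(A[, f], B[, f])
  out
}

unfold <- function(X, mode) {
  d <- dim(X)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  matrix(aperm(X, perm), d[mode])
}

ls_update <- function(Xn, Z, nonneg) {
  if (!nonneg) {
    G <- crossprod(Z)
    return(t(solve(G, t(Xn %*% Z))))
  }
  out <- matrix(0, nrow(Xn), ncol(Z))
  for (r in seq_len(nrow(Xn))) out[r, ] <- pracma::lsqnonneg(Z, Xn[r, ])$x
  out
}

parafac_model <- function(A, B, C) {
  # X-hat as mode-1 unfolding
  A %*% t(khatri_rao(C, B))
}

parafac_init <- function(X, F, init, nonneg, seed) {
  d <- dim(X)
  svd_init <- function(mode) {
    u <- svd(unfold(X, mode))$u
    m <- u[, seq_len(min(F, ncol(u))), drop = FALSE]
    if (ncol(m) < F) m <- cbind(m, matrix(stats::rnorm(d[mode] * (F - ncol(m))), d[mode]))
    if (any(nonneg)) m <- abs(m)
    m
  }
  rand_init <- function(mode) {
    m <- matrix(stats::rnorm(d[mode] * F), d[mode], F)
    if (any(nonneg)) abs(m) else m
  }
  if (identical(init, "svd")) {
    list(list(A = svd_init(1), B = svd_init(2), C = svd_init(3)))
  } else if (identical(init, "random")) {
    with_seed(seed, list(list(A = rand_init(1), B = rand_init(2), C = rand_init(3))))
  } else if (identical(init, "best_of_n")) {
    with_seed(seed, c(list(list(A = svd_init(1), B = svd_init(2), C = svd_init(3))),
                      lapply(seq_len(5), function(i)
                        list(A = rand_init(1), B = rand_init(2), C = rand_init(3)))))
  } else stop_config("unknown init '%s'", init)
}

als_run <- function(X, start, nonneg, tol, max_iter) {
  X1 <- unfold(X, 1); X2 <- unfold(X, 2); X3 <- unfold(X, 3)
  ssx <- sum(X^2)
  A <- start$A; B <- start$B; C <- start$C
  fit_old <- -Inf
  fit_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- ls_update(X1, khatri_rao(C, B), nonneg[1])
    B <- ls_update(X2, khatri_rao(C, A), nonneg[2])
    C <- ls_update(X3, khatri_rao(B, A), nonneg[3])
    # unit-norm B and C, scale into A
    for (f in seq_len(ncol(A))) {
      nb <- sqrt(sum(B[, f]^2)); nc <- sqrt(sum(C[, f]^2))
      if (nb > 0) B[, f] <- B[, f] / nb
      if (nc > 0) C[, f] <- C[, f] / nc
      A[, f] <- A[, f] * nb * nc
    }
    res2 <- sum((X1 - parafac_model(A, B, C))^2)
    fit <- 100 * (1 - res2 / ssx)
    fit_trace <- c(fit_trace, fit)
    if (fit < fit_old - 1e-10) {
      stop_data("PARAFAC ALS diverged at iteration %d (fit %.10g -> %.10g)", it, fit_old, fit)
    }
    if (is.finite(fit_old) && abs(fit - fit_old) < tol * 100) { converged <- TRUE; break }
    fit_old <- fit
  }
  list(A = A, B = B, C = C, fit = fit_old, iterations = it,
       converged = converged, fit_trace = fit_trace)
}

#' PARAFAC trilinear decomposition
#'
#' Alternating least squares on each mode's unfolding of
#' X_ijk = sum_f a_if b_jf c_kf, with optional per-mode non-negativity
#' (row-wise non-negative least squares). Columns of B and C are unit-norm
#' with the scale carried in A; components are ordered by explained
#' variation. Deterministic given `seed`.
#'
#' @param X three-way numeric array.
#' @param F number of components (within every unfolding's rank bound).
#' @param nonneg logical length 3 (recycled): non-negativity per mode.
#' @param init `"svd"` (leading singular vectors of the unfoldings),
#'   `"random"`, or `"best_of_n"` (5 random + 1 svd, short burn-in, keep the
#'   best).
#' @param tol relative change in fit (fraction) at which to stop.
#' @param max_iter iteration budget.
#' @param seed RNG seed for random initialisation.
#' @return object of class `trilinear_factors`: `A`, `B`, `C`, `fit`
#'   (percent explained), `iterations`, `converged`.
#' @export
parafac <- function(X, F, nonneg = FALSE, init = "svd", tol = 1e-9,
                    max_iter = 2500L, seed = 1L) {
  if (length(dim(X)) != 3L) stop_data("parafac expects a three-way array")
  nonneg <- rep_len(as.logical(nonneg), 3L)
  if (F > min(vapply(1:3, function(m) min(dim(unfold(X, m))), numeric(1))))
    stop_data("F exceeds the rank bound of an unfolding")
  starts <- parafac_init(X, F, init, nonneg, seed)
  if (length(starts) > 1L) {
    burns <- lapply(starts, function(s) als_run(X, s, nonneg, tol = 0, max_iter = 30L))
    best <- which.max(vapply(burns, function(b) b$fit, numeric(1)))
    starts <- list(list(A = burns[[best]]$A, B = burns[[best]]$B, C = burns[[best]]$C))
  }
  res <- als_run(X, starts[[1]], nonneg, tol, max_iter)
  expl <- colSums(res$A^2)
  ord <- order(expl, decreasing = TRUE)
  structure(list(A = res$A[, ord, drop = FALSE], B = res$B[, ord, drop = FALSE],
                 C = res$C[, ord, drop = FALSE], fit = res$fit,
                 iterations = res$iterations, converged = res$converged,
                 fit_trace = res$fit_trace),
            class = "trilinear_factors")
}

#' @export
print.trilinear_factors <- function(x, ...) {
  cat(sprintf("<trilinear_factors> %d component(s), fit %.6f%%, %d iteration(s)%s\n",
              ncol(x$A), x$fit, x$iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' PowerSlicing: trilinearise exponential two-way data
#'
#' Builds a three-way array from shifted column windows (unit-shift slabs):
#' slab s holds columns s..s+L-1 of `X2`, giving `cube[p, l, s] =
#' X2[p, s+l-1]`. For pure exponentials in the column variable the cube is
#' exactly trilinear with third-mode loadings rho_k^s.
#'
#' @param X2 matrix [points x n_increments], increments equally spaced in
#'   the exponent variable.
#' @param slabs number of slabs S (>= 2).
#' @param slab_length L; defaults to `n_increments - slabs + 1`.
#' @param encoding optional [diffusion_encoding()]; when given, equal
#'   spacing of the Stejskal-Tanner exponent is enforced (as in [decra()]).
#' @return array [points x L x S].
#' @export
power_slice <- function(X2, slabs = 3L, slab_length = NULL, encoding = NULL) {
  X2 <- as.matrix(X2)
  n_inc <- ncol(X2)
  if (slabs < 2L) stop_data("slabs must be >= 2")
  if (is.null(slab_length)) slab_length <- n_inc - slabs + 1L
  if (slab_length + slabs - 1L > n_inc)
    stop_data("slab_length + slabs - 1 must be <= n_increments")
  if (!is.null(encoding)) {
    dx <- diff(st_exponent(encoding))
    if (max(abs(dx - dx[1])) > 1e-6 * abs(dx[1]))
      stop_data("PowerSlicing requires equally spaced exponent values; resample the gradient list")
  }
  cube <- array(0, dim = c(nrow(X2), slab_length, slabs))
  for (s in seq_len(slabs)) {
    cube[, , s] <- X2[, s + seq_len(slab_length) - 1L]
  }
  cube
}

#' Decay parameters from sliced-cube factors
#'
#' For a PARAFAC model of a [power_slice()]d cube the slab-mode loadings of
#' component k are proportional to rho_k^s; the decay rate follows from the
#' mean log-ratio of consecutive loadings: D_k = -mean(diff(log c_k)) / dX.
#'
#' @param factors a `trilinear_factors` from [parafac()] on a sliced cube.
#' @param dX spacing of the Stejskal-Tanner exponent between increments.
#' @param mode which mode holds the slab loadings (default 3).
#' @return numeric vector of decay parameters (D in m^2/s).
#' @export
slab_decay_rates <- function(factors, dX, mode = 3L) {
  C <- switch(mode, factors$A, factors$B, factors$C)
  apply(C, 2L, function(cc) {
    s <- sign(cc[which.max(abs(cc))])
    cc <- cc * s
    if (any(cc <= 0)) return(NA_real_)
    -mean(diff(log(cc))) / dX
  })
}

#' Greedy factor matching against a reference
#'
#' Permutes (and sign-flips) estimated components to best match reference
#' factors, maximising the product of per-mode congruences (absolute
#' cosines). Used to compare a PARAFAC solution with ground truth.
#'
#' @param est,ref `trilinear_factors`-like lists with `A`, `B`, `C`.
#' @return list with the permuted `est` and a `congruence` matrix
#'   [modes x components].
#' @export
match_factors <- function(est, ref) {
  F <- ncol(ref$A)
  modes <- c("A", "B", "C")
  cong <- function(a, b) abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  score <- matrix(1, F, F)
  for (m in modes) {
    for (i in seq_len(F)) for (j in seq_len(F)) {
      score[i, j] <- score[i, j] * cong(est[[m]][, i], ref[[m]][, j])
    }
  }
  perm <- integer(F)
  avail <- seq_len(F)
  for (j in seq_len(F)) {
    i <- avail[which.max(score[avail, j])]
    perm[j] <- i
    avail <- setdiff(avail, i)
  }
  out <- est
  for (m in modes) out[[m]] <- est[[m]][, perm, drop = FALSE]
  # align signs mode-pairwise (flip two modes together to keep the model)
  for (f in seq_len(F)) {
    sa <- sign(sum(out$A[, f] * ref$A[, f]))
    sb <- sign(sum(out$B[, f] * ref$B[, f]))
    if (sa < 0 && sb < 0) {
      out$A[, f] <- -out$A[, f]; out$B[, f] <- -out$B[, f]
    }
  }
  cmat <- rbind(A = vapply(seq_len(F), function(f) cong(out$A[, f], ref$A[, f]), numeric(1)),
                B = vapply(seq_len(F), function(f) cong(out$B[, f], ref$B[, f]), numeric(1)),
                C = vapply(seq_len(F), function(f) cong(out$C[, f], ref$C[, f]), numeric(1)))
  list(est = out, congruence = cmat, permutation = perm)
}

#' PARAFAC diagnostics
#'
#' Per-mode leverages (diagonal of F (F'F)^-1 F') and residual sums of
#' squares per mode slice, for spotting corrupted slabs, gradient levels or
#' spectral regions.
#'
#' @param factors a `trilinear_factors`.
#' @param X the modelled three-way array.
#' @return list with `leverage` (list of 3 vectors) and `residual_ss`
#'   (list of 3 vectors).
#' @export
parafac_diagnostics <- function(factors, X) {
  R <- X - array(parafac_model(factors$A, factors$B, factors$C), dim(X))
  lev <- function(M) diag(M %*% solve(crossprod(M)) %*% t(M))
  list(leverage = list(mode1 = lev(factors$A), mode2 = lev(factors$B), mode3 = lev(factors$C)),
       residual_ss = list(mode1 = apply(R^2, 1, sum),
                          mode2 = apply(R^2, 2, sum),
                          mode3 = apply(R^2, 3, sum)))
}
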