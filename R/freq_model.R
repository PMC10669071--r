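# Frequency-domain representation of the bivariate VAR model and the
# zero-lag (instantaneous) interaction extraction.
#
# Index convention, used everywhere: channel 1 = IBI, channel 2 = SBP;
# matrix entry [i, j] maps source channel j into target channel i. The
# coefficient transform is A(f) = sum_k A_k exp(-i 2 pi f k / fs) (lag-0
# term zero before extraction), the noise transfer is H(f) = (I - A(f))^-1
# and the cross-spectral matrix is the factorization S(f) = H Sigma H*.
# S is stored unnormalized: the one-sided spectral density in units^2/Hz is
# (2/fs) * S, so that the density integrated over [0, fs/2] equals the
# process variance.

.freq_A <- function(coeffs, a0, freqs, fs) {
  nf <- length(freqs)
  A <- array(0 + 0i, dim = c(2, 2, nf))
  for (idx in seq_len(nf)) {
    Af <- a0 + 0i
    for (k in seq_along(coeffs)) {
      Af <- Af + coeffs[[k]] * exp(-2i * pi * freqs[idx] * k / fs)
    }
    A[, , idx] <- Af
  }
  A
}

.rebuild_HS <- function(A, sigma, freqs) {
  nf <- length(freqs)
  H <- array(0 + 0i, dim = dim(A))
  S <- array(0 + 0i, dim = dim(A))
  I2 <- diag(2)
  for (idx in seq_len(nf)) {
    M <- I2 - A[, , idx]
    detM <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    if (Mod(detM) < 1e-12) {
      stop(sprintf("I - A(f) is singular at f = %.5f Hz (marginal model)",
                   freqs[idx]), call. = FALSE)
    }
    Hf <- solve(M)
    H[, , idx] <- Hf
    S[, , idx] <- Hf %*% sigma %*% Conj(t(Hf))
  }
  list(H = H, S = S)
}

#' Transform a VAR model into the frequency domain
#'
#' Evaluates the lag polynomial on a linear frequency grid over
#' `[0, fs/2]`, inverts it into the noise-to-signal transfer matrix
#' `H(f) = (I - A(f))^-1` and factorizes the cross-spectral matrix
#' `S(f) = H(f) Sigma H(f)*`. The returned model has no instantaneous
#' interactions yet (`D = I`); see [extract_instantaneous()].
#'
#' @param model a [estimate_var()] model (must be stable), or any list with
#'   `p`, `coeffs`, `sigma` and optionally `fs`.
#' @param n_freq number of frequency points (>= 64; default 512).
#' @param fs sampling frequency in Hz; defaults to `model$fs`.
#' @return An object of class `freq_model`: `freqs`, complex arrays `A`,
#'   `H`, `S` of dim `c(2, 2, n_freq)`, `sigma`, `D`, `zero_lag_path`
#'   (`"none"` here), `b0` (0 here), `fs`, plus the time-domain pieces
#'   needed to propagate an extraction.
#' @examples
#' m <- list(p = 1, coeffs = list(matrix(c(.5, 0, 0, .5), 2)),
#'           sigma = diag(2), fs = 4)
#' fm <- to_frequency_domain(m, n_freq = 128)
#' @export
to_frequency_domain <- function(model, n_freq = 512L, fs = model$fs) {
  n_freq <- as.integer(n_freq)
  if (is.null(fs)) stop("fs must be supplied", call. = FALSE)
  if (n_freq < 64L) stop("n_freq must be >= 64", call. = FALSE)
  st <- diagnose_stability(model)
  if (!st$stable) {
    stop(sprintf("model is unstable (spectral radius %.3f >= 1)",
                 st$spectral_radius), call. = FALSE)
  }
  freqs <- seq(0, fs / 2, length.out = n_freq)
  coeffs <- lapply(model$coeffs, unname)
  A <- .freq_A(coeffs, matrix(0, 2, 2), freqs, fs)
  hs <- .rebuild_HS(A, model$sigma, freqs)
  structure(list(freqs = freqs, A = A, H = hs$H, S = hs$S,
                 sigma = unname(model$sigma), D = diag(2),
                 zero_lag_path = "none", b0 = 0,
                 fs = fs, p = model$p, coeffs = coeffs,
                 a0 = matrix(0, 2, 2)),
            class = "freq_model")
}

#' @export
print.freq_model <- function(x, ...) {
  cat(sprintf("freq_model: %d frequencies on [0, %g] Hz, VAR(%d)\n",
              length(x$freqs), max(x$freqs), x$p))
  if (x$zero_lag_path != "none") {
    cat(sprintf("  instantaneous path %s extracted, b0 = %.4f\n",
                x$zero_lag_path, x$b0))
  }
  invisible(x)
}

.path_index <- function(path) {
  # (target, source) channel indices of the zero-lag path
  switch(path,
         "sbp->ibi" = c(target = 1L, source = 2L),
         "ibi->sbp" = c(target = 2L, source = 1L),
         stop(sprintf("unknown path '%s'; use 'sbp->ibi' or 'ibi->sbp'",
                      path), call. = FALSE))
}

#' Extract the instantaneous (zero-lag) interaction
#'
#' Diagonalizes the residual covariance `Sigma = D Sigma_diag D^T` with a
#' unit-diagonal triangular `D` whose single off-diagonal entry
#' `b0 = sigma_12 / sigma_source^2` sits in the (target, source) position
#' of the chosen path, so the source channel's innovation enters the target
#' at lag zero. The noise transfer becomes `H' = H D`, the lag matrices are
#' remapped as `A'_k = D^-1 A_k` with a new zero-lag term
#' `A'_0 = I - D^-1`, and the cross-spectral matrix is unchanged. The
#' physiologically recommended default path is `"sbp->ibi"` (fast
#' baroreflex).
#'
#' @param fm a [to_frequency_domain()] model with `zero_lag_path = "none"`.
#' @param path `"sbp->ibi"` (default) or `"ibi->sbp"`.
#' @return A `freq_model` with diagonal `sigma`, the extraction matrix `D`,
#'   the reported zero-lag coefficient `b0`, and `A`, `H` updated.
#' @examples
#' m <- list(p = 1, coeffs = list(matrix(0, 2, 2)),
#'           sigma = matrix(c(4, 2, 2, 3), 2), fs = 4)
#' fm <- extract_instantaneous(to_frequency_domain(m, 64), "ibi->sbp")
#' fm$b0  # 0.5
#' @export
extract_instantaneous <- function(fm, path = "sbp->ibi") {
  stopifnot(inherits(fm, "freq_model"))
  if (fm$zero_lag_path != "none") {
    stop("instantaneous interactions already extracted", call. = FALSE)
  }
  idx <- .path_index(path)
  sg <- fm$sigma
  det_s <- sg[1, 1] * sg[2, 2] - sg[1, 2]^2
  if (det_s <= sg[1, 1] * sg[2, 2] * 1e-12) {
    stop("residual covariance is (near-)singular; cannot extract",
         call. = FALSE)
  }
  b0 <- sg[idx["target"], idx["source"]] / sg[idx["source"], idx["source"]]
  D <- diag(2)
  D[idx["target"], idx["source"]] <- b0
  sigma_diag <- diag(2)
  sigma_diag[idx["source"], idx["source"]] <- sg[idx["source"], idx["source"]]
  sigma_diag[idx["target"], idx["target"]] <-
    sg[idx["target"], idx["target"]] - b0 * sg[1, 2]
  Dinv <- diag(2)
  Dinv[idx["target"], idx["source"]] <- -b0
  a0 <- diag(2) - Dinv
  coeffs <- lapply(fm$coeffs, function(Ak) Dinv %*% Ak)
  A <- .freq_A(coeffs, a0, fm$freqs, fm$fs)
  # H' = H D carries the diagonalized sources; S is invariant
  nf <- length(fm$freqs)
  H <- fm$H
  for (i in seq_len(nf)) H[, , i] <- fm$H[, , i] %*% D
  out <- fm
  out$A <- A
  out$H <- H
  out$sigma <- sigma_diag
  out$sigma_raw <- sg
  out$D <- D
  out$zero_lag_path <- path
  out$b0 <- b0
  out$coeffs <- coeffs
  out$a0 <- a0
  out
}
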