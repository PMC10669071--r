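# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithmic paths: the MODWT oracle builds explicit
# cascade filters and convolves directly; the spectral oracles use closed
# forms.

# Level-j MODWT filters by explicit cascade construction:
# g_1 = g/sqrt(2); at level j the filter is the convolution of the
# level-(j-1) scaling filter with the base filter upsampled by 2^(j-1).
cascade_filters <- function(wavelet, d) {
  base <- baroloop:::.wavelet_filter(wavelet)
  g0 <- base$g / sqrt(2)
  h0 <- base$h / sqrt(2)
  upsample <- function(f, by) {
    out <- numeric((length(f) - 1) * by + 1)
    out[seq(1, length(out), by = by)] <- f
    out
  }
  g <- g0
  filters <- vector("list", d)
  filters[[1]] <- list(h = h0, g = g0)
  for (j in seq_len(d)[-1]) {
    up <- 2^(j - 1)
    hj <- stats::convolve(g, rev(upsample(h0, up)), type = "open")
    gj <- stats::convolve(g, rev(upsample(g0, up)), type = "open")
    filters[[j]] <- list(h = hj, g = gj)
    g <- gj
  }
  filters
}

# direct circular convolution MODWT: w_{j,t} = sum_l f_l x_{(t-l) mod N}
modwt_direct <- function(x, d, wavelet) {
  n <- length(x)
  filters <- cascade_filters(wavelet, d)
  apply_filter <- function(f) {
    out <- numeric(n)
    for (t in seq_len(n)) {
      idx <- ((t - 1) - (seq_along(f) - 1)) %% n + 1
      out[t] <- sum(f * x[idx])
    }
    out
  }
  list(details = lapply(filters, function(fl) apply_filter(fl$h)),
       smooth = apply_filter(filters[[d]]$g))
}

# closed-form spectrum of an AR(1) x_t = a x_{t-1} + e_t, var(e) = s2,
# unnormalized to match the freq_model S convention
ar1_spectrum <- function(a, s2, freqs, fs) {
  s2 / Mod(1 - a * exp(-2i * pi * freqs / fs))^2
}

# stable random bivariate VAR(1) model for property sweeps
random_stable_var1 <- function(seed) {
  set.seed(seed)
  repeat {
    A <- matrix(stats::runif(4, -0.7, 0.7), 2, 2)
    if (max(Mod(eigen(A, only.values = TRUE)$values)) < 0.9) break
  }
  L <- matrix(c(stats::runif(1, 0.5, 2), stats::runif(1, -0.5, 0.5),
                0, stats::runif(1, 0.5, 2)), 2, 2)
  list(p = 1L, coeffs = list(A), sigma = L %*% t(L), fs = 4)
}

# random symmetric positive definite 2x2 matrix
random_spd2 <- function() {
  L <- matrix(c(stats::runif(1, 0.3, 2), stats::rnorm(1, 0, 0.8),
                0, stats::runif(1, 0.3, 2)), 2, 2)
  L %*% t(L)
}

# transfer_function / coherence_function stubs on an arbitrary grid, for
# hand-computable estimator cases
make_tf <- function(freqs, gain, direction = "sbp->ibi") {
  structure(list(freqs = freqs, values = gain + 0i, gain = abs(gain),
                 phase = rep(0, length(freqs)), kind = "stub",
                 direction = direction, units = "ms/mmHg"),
            class = "transfer_function")
}

make_coh <- function(freqs, values) {
  structure(list(freqs = freqs, values = values, kind = "stub",
                 direction = NA_character_),
            class = "coherence_function")
}
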