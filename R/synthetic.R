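# Ground-truth generators: closed-loop bivariate VAR realizations with
# known transfer functions, and physiologically shaped IBI/SBP beat series
# for end-to-end pipeline tests.

#' Specification of a closed-loop VAR simulation
#'
#' Describes a bivariate VAR(p) forward model with Gaussian innovations.
#' When `b0` is `NULL`, `sigma` is the full innovation covariance (possibly
#' correlated). When `b0` is given, `sigma` must be diagonal: it is the
#' covariance of the orthogonal sources `eps`, and the innovations are
#' built as `w = D eps` where the unit-diagonal triangular `D` carries `b0`
#' on the `b0_path` (target, source) entry — the generative counterpart of
#' [extract_instantaneous()].
#'
#' @param coeffs list of 2x2 lag matrices (channel order IBI, SBP; entry
#'   `[i, j]` couples source j into target i).
#' @param sigma 2x2 innovation covariance (diagonal when `b0` is given).
#' @param n number of samples to keep.
#' @param fs sampling frequency in Hz (default 4).
#' @param seed integer RNG seed.
#' @param burn_in initial samples discarded (default 1000).
#' @param b0 optional instantaneous coefficient.
#' @param b0_path `"sbp->ibi"` (default) or `"ibi->sbp"`.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(coeffs, sigma, n, fs = 4, seed = 1,
                            burn_in = 1000L, b0 = NULL,
                            b0_path = "sbp->ibi") {
  coeffs <- lapply(coeffs, function(m) {
    m <- unname(as.matrix(m))
    stopifnot(all(dim(m) == c(2, 2)), all(is.finite(m)))
    m
  })
  sigma <- unname(as.matrix(sigma))
  stopifnot(all(dim(sigma) == c(2, 2)))
  if (max(abs(sigma - t(sigma))) > 1e-12 ||
      any(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("sigma must be symmetric positive definite", call. = FALSE)
  }
  if (!is.null(b0)) {
    if (abs(sigma[1, 2]) > 1e-12) {
      stop("with b0 given, sigma must be the diagonal source covariance",
           call. = FALSE)
    }
    .path_index(b0_path)  # validates
  }
  spec <- structure(list(coeffs = coeffs, sigma = sigma, n = as.integer(n),
                         fs = fs, seed = as.integer(seed),
                         burn_in = as.integer(burn_in), b0 = b0,
                         b0_path = b0_path, p = length(coeffs)),
                    class = "simulation_spec")
  st <- diagnose_stability(spec)
  if (!st$stable) {
    stop(sprintf("specified model is unstable (spectral radius %.3f)",
                 st$spectral_radius), call. = FALSE)
  }
  spec
}

# effective innovation covariance and the D carrying an instantaneous path
.spec_innovation <- function(spec) {
  D <- diag(2)
  if (!is.null(spec$b0)) {
    idx <- .path_index(spec$b0_path)
    D[idx["target"], idx["source"]] <- spec$b0
  }
  list(D = D, sigma_w = D %*% spec$sigma %*% t(D))
}

#' Simulate a closed-loop bivariate VAR realization
#'
#' Iterates the spec's lag recursion with Gaussian innovations, discards
#' the burn-in, and returns the two channels labelled (IBI, SBP). The
#' output is bit-reproducible for a given seed; the caller's RNG state is
#' left untouched.
#'
#' @param spec a [simulation_spec()].
#' @return A [uniform_series()] of length `spec$n`.
#' @examples
#' sim <- simulate_closed_loop_var(synthetic_preset("uncoupled", n = 1024,
#'                                                  seed = 7))
#' @export
simulate_closed_loop_var <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  p <- spec$p
  n_tot <- spec$n + spec$burn_in
  inn <- .spec_innovation(spec)
  # w_t = D eps_t with eps ~ N(0, spec$sigma); chol covers the b0-free
  # case too since then D = I and sigma may be full
  R <- chol(spec$sigma)
  eps <- matrix(stats::rnorm(2 * n_tot), n_tot, 2) %*% R
  w <- eps %*% t(inn$D)
  Y <- matrix(0, n_tot, 2)
  for (t in (p + 1):n_tot) {
    acc <- w[t, ]
    for (k in seq_len(p)) {
      acc <- acc + spec$coeffs[[k]] %*% Y[t - k, ]
    }
    Y[t, ] <- acc
  }
  keep <- (spec$burn_in + 1):n_tot
  uniform_series(ibi = Y[keep, 1], sbp = Y[keep, 2], fs = spec$fs,
                 meta = list(spec_seed = spec$seed, preset = spec$preset))
}

#' Reference simulation presets
#'
#' Three study conditions with known ground truth:
#' \describe{
#'   \item{uncoupled}{VAR(1) with independent channels — null reference.}
#'   \item{baroreflex}{VAR(2) with one-way SBP-to-IBI coupling (lagged plus
#'     an instantaneous path, `b0 = 0.5`) and resonant SBP dynamics — the
#'     coupled reference used for parameter-recovery checks.}
#'   \item{bidirectional}{VAR(2) closed loop with both arms active and
#'     correlated innovations.}
#' }
#'
#' @param name preset name.
#' @param n samples (default 8192).
#' @param seed RNG seed.
#' @return A [simulation_spec()] with the preset name recorded.
#' @export
synthetic_preset <- function(name = c("uncoupled", "baroreflex",
                                      "bidirectional"),
                             n = 8192L, seed = 1L) {
  name <- match.arg(name)
  spec <- switch(name,
    uncoupled = simulation_spec(
      coeffs = list(matrix(c(0.5, 0, 0, 0.6), 2, 2)),
      sigma = diag(2), n = n, seed = seed),
    baroreflex = simulation_spec(
      coeffs = list(matrix(c(0.6, 0, 0.9, 0.7), 2, 2),
                    matrix(c(-0.3, 0, -0.4, -0.35), 2, 2)),
      sigma = diag(c(1, 0.8)), n = n, seed = seed,
      b0 = 0.5, b0_path = "sbp->ibi"),
    bidirectional = simulation_spec(
      coeffs = list(matrix(c(0.5, 0.2, 0.6, 0.8), 2, 2),
                    matrix(c(-0.25, 0.05, -0.3, -0.4), 2, 2)),
      sigma = matrix(c(1, 0.3, 0.3, 0.8), 2, 2), n = n, seed = seed))
  spec$preset <- name
  spec
}

#' Exact frequency-domain model implied by a simulation spec
#'
#' The analytic ground truth against which estimates are validated: builds
#' the frequency-domain model from the spec's own coefficients and its
#' effective innovation covariance (including any generative instantaneous
#' path), optionally extracting the zero-lag interaction.
#'
#' @param spec a [simulation_spec()].
#' @param n_freq frequency grid size.
#' @param extract_path `NULL` for the lagged-only model, or a path for
#'   [extract_instantaneous()].
#' @return A `freq_model`.
#' @export
analytic_freq_model <- function(spec, n_freq = 512L, extract_path = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  inn <- .spec_innovation(spec)
  fm <- to_frequency_domain(
    list(p = spec$p, coeffs = spec$coeffs, sigma = inn$sigma_w,
         fs = spec$fs),
    n_freq = n_freq)
  if (!is.null(extract_path)) fm <- extract_instantaneous(fm, extract_path)
  fm
}

#' Generate a physiologically shaped beat series
#'
#' Builds an IBI series as a baseline plus LF (~0.1 Hz) and HF (~0.25 Hz)
#' oscillations, a slow VLF drift and white noise, with beat times given by
#' the cumulative IBIs, and an SBP series linearly coupled to the IBI with
#' its own noise. This emulates the rhythms a short supine recording shows,
#' not real baroreflex dynamics: it is a fixture generator for the
#' resample/detrend/window stages.
#'
#' @param n_beats number of beats (>= 64).
#' @param seed RNG seed.
#' @param params named list overriding any of: `ibi_ms` (baseline, 1000),
#'   `lf_amp_ms` (25), `hf_amp_ms` (15), `vlf_amp_ms` (30), `vlf_freq_hz`
#'   (0.01), `lf_freq_hz` (0.1), `hf_freq_hz` (0.25), `ibi_noise_ms` (5),
#'   `sbp_mmhg` (120), `coupling_mmhg_per_ms` (0.03), `sbp_noise_mmhg` (2).
#' @return A [beat_series()].
#' @examples
#' b <- generate_physio_like(300, seed = 1)
#' range(b$ibi)
#' @export
generate_physio_like <- function(n_beats, seed = 1L, params = list()) {
  n_beats <- as.integer(n_beats)
  if (n_beats < 64L) stop("n_beats must be >= 64", call. = FALSE)
  p <- utils::modifyList(list(
    ibi_ms = 1000, lf_amp_ms = 25, hf_amp_ms = 15, vlf_amp_ms = 30,
    vlf_freq_hz = 0.01, lf_freq_hz = 0.1, hf_freq_hz = 0.25,
    ibi_noise_ms = 5, sbp_mmhg = 120, coupling_mmhg_per_ms = 0.03,
    sbp_noise_mmhg = 2), params)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  time <- numeric(n_beats)
  ibi <- numeric(n_beats)
  t_cur <- 0
  for (i in seq_len(n_beats)) {
    time[i] <- t_cur
    ibi[i] <- p$ibi_ms +
      p$lf_amp_ms * sin(2 * pi * p$lf_freq_hz * t_cur) +
      p$hf_amp_ms * sin(2 * pi * p$hf_freq_hz * t_cur) +
      p$vlf_amp_ms * sin(2 * pi * p$vlf_freq_hz * t_cur) +
      stats::rnorm(1, sd = p$ibi_noise_ms)
    if (ibi[i] <= 0) {
      stop("parameters yield a non-positive IBI", call. = FALSE)
    }
    t_cur <- t_cur + ibi[i] / 1000
  }
  sbp <- p$sbp_mmhg + p$coupling_mmhg_per_ms * (ibi - p$ibi_ms) +
    stats::rnorm(n_beats, sd = p$sbp_noise_mmhg)
  if (any(sbp <= 0)) {
    stop("parameters yield a non-positive SBP", call. = FALSE)
  }
  beat_series(time = time, ibi = ibi, sbp = sbp)
}
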