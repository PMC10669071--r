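#' Build a wavelet detrending plan from a reference frequency
#'
#' The MODWT splits the axis `[0, f_N]` (`f_N = fs/2`, the Nyquist
#' frequency) into dyadic bands; the approximation at depth `d` carries
#' `[0, f_N / 2^d)`, so the realized trend cutoff is `f_C = f_N / 2^d`.
#' Given a reference frequency `f_ref`, the plan selects the depth whose
#' deepest detail band `[f_N/2^d, f_N/2^(d-1))` contains `f_ref`, i.e.
#' `d = ceiling(log2(f_N) - log2(f_ref))`, and uses that band's lower edge
#' as the cutoff. With the defaults `fs = 4`, `f_ref = 0.04` this yields a
#' six-level decomposition and a 0.03125 Hz cutoff, which suppresses the
#' very-low-frequency band while leaving the 0.04-0.4 Hz range to the
#' details.
#'
#' @param fs sampling frequency in Hz.
#' @param f_ref reference frequency in Hz, `0 < f_ref < fs/2`. Ignored when
#'   `d` is given directly.
#' @param d optional explicit decomposition depth (overrides `f_ref`).
#' @param wavelet one of [wavelet_names()].
#' @param border `"extend"` (reflect the series before transforming, then
#'   crop; default) or `"none"` (circular).
#' @return An object of class `detrend_plan` with fields `fs`, `f_N`,
#'   `f_ref`, `d`, `f_C`, `wavelet`, `border`.
#' @examples
#' select_decomposition_level(4, 0.04)  # d = 6, cutoff 0.03125 Hz
#' select_decomposition_level(4, 0.07)  # d = 5, cutoff 0.0625 Hz
#' @export
select_decomposition_level <- function(fs, f_ref = 0.04, d = NULL,
                                       wavelet = "d8",
                                       border = c("extend", "none")) {
  border <- match.arg(border)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  f_N <- fs / 2
  if (is.null(d)) {
    if (!is.numeric(f_ref) || f_ref <= 0 || f_ref >= f_N) {
      stop(sprintf("f_ref must lie in (0, %g) Hz", f_N), call. = FALSE)
    }
    d <- as.integer(ceiling(log2(f_N) - log2(f_ref)))
    d <- max(d, 1L)
  } else {
    d <- as.integer(d)
    if (d < 1L) stop("d must be >= 1", call. = FALSE)
    f_ref <- NA_real_
  }
  .wavelet_filter(wavelet)  # validates the name
  structure(list(fs = fs, f_N = f_N, f_ref = f_ref, d = d,
                 f_C = f_N / 2^d, wavelet = wavelet, border = border),
            class = "detrend_plan")
}

#' @export
print.detrend_plan <- function(x, ...) {
  cat(sprintf(paste0("detrend_plan: fs = %g Hz, %d levels, cutoff %g Hz ",
                     "(wavelet %s, border %s)\n"),
              x$fs, x$d, x$f_C, x$wavelet, x$border))
  invisible(x)
}

#' Frequency band of the deepest detail level
#'
#' @param plan a [select_decomposition_level()] plan.
#' @return Numeric `c(lo, hi)` in Hz: the half-open dyadic band
#'   `[f_N/2^d, f_N/2^(d-1))` carried by detail level `d`.
#' @export
deepest_detail_band <- function(plan) {
  stopifnot(inherits(plan, "detrend_plan"))
  c(lo = plan$f_N / 2^plan$d, hi = plan$f_N / 2^(plan$d - 1))
}

#' Wavelet detrending of a uniformly sampled channel
#'
#' Subtracts the channel mean, then estimates the slow trend as the MODWT
#' approximation at the plan's depth (all detail levels zeroed before
#' inverse transform) and subtracts it. With `border = "extend"` the series
#' is first extended by reflection at both ends by the level-`d` filter
#' support, transformed, and cropped back, which avoids the wrap-around
#' artefacts of the circular transform at the record edges.
#'
#' @param x numeric vector sampled at `plan$fs`.
#' @param plan a `detrend_plan` from [select_decomposition_level()].
#' @param return_trend if `TRUE`, return a list with `detrended` and
#'   `trend`; otherwise just the detrended vector.
#' @return Numeric vector (or list, see `return_trend`). The detrended
#'   series has mean ~0.
#' @examples
#' plan <- select_decomposition_level(4, 0.04)
#' t <- seq(0, 255.75, by = 0.25)
#' x <- 0.05 * t + sin(2 * pi * 0.1 * t)
#' y <- modwt_detrend(x, plan)
#' @export
modwt_detrend <- function(x, plan, return_trend = FALSE) {
  stopifnot(inherits(plan, "detrend_plan"))
  x <- as.numeric(x)
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  filt <- .wavelet_filter(plan$wavelet)
  support <- (2^plan$d - 1) * (filt$L - 1) + 1
  if (n < support) {
    stop(sprintf(paste0("series of length %d is shorter than the level-%d ",
                        "filter support (%d); decrease the depth or widen ",
                        "the window"), n, plan$d, support), call. = FALSE)
  }
  if (plan$border == "extend") {
    e <- min(n - 1L, support)
    # reflect without repeating the edge sample
    left <- xc[(e + 1L):2L]
    right <- xc[(n - 1L):(n - e)]
    ext <- c(left, xc, right)
    trend <- .modwt_trend(ext, plan$d, plan$wavelet)[(e + 1L):(e + n)]
  } else {
    trend <- .modwt_trend(xc, plan$d, plan$wavelet)
  }
  out <- xc - trend
  out <- out - mean(out)
  if (return_trend) list(detrended = out, trend = trend + mu) else out
}

#' Detrend both channels of a uniform series
#'
#' Convenience wrapper applying [modwt_detrend()] to the IBI and SBP
#' channels with a common plan built from the series' own sampling
#' frequency.
#'
#' @param series a [uniform_series()].
#' @param f_ref reference frequency in Hz (default 0.04).
#' @param wavelet,border passed to [select_decomposition_level()].
#' @return A [uniform_series()] with detrended channels; the plan is stored
#'   in `meta$detrend_plan`.
#' @export
detrend_series <- function(series, f_ref = 0.04, wavelet = "d8",
                           border = "extend") {
  stopifnot(inherits(series, "uniform_series"))
  plan <- select_decomposition_level(series$fs, f_ref, wavelet = wavelet,
                                     border = border)
  out <- uniform_series(modwt_detrend(series$ibi, plan),
                        modwt_detrend(series$sbp, plan),
                        fs = series$fs, t0 = series$t0, meta = series$meta)
  out$meta$detrend_plan <- plan
  out
}
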