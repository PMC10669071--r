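#' Spectral band definition
#'
#' Half-open frequency band `[lo, hi)`. The conventional defaults are
#' LF = [0.04, 0.15) Hz and HF = [0.15, 0.4) Hz; see [default_bands()].
#'
#' @param name band label (e.g. "LF").
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return An object of class `freq_band`.
#' @export
freq_band <- function(name, lo, hi) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo > 0 && lo < hi)) {
    stop("band edges must satisfy 0 < lo < hi", call. = FALSE)
  }
  structure(list(name = as.character(name), lo = lo, hi = hi),
            class = "freq_band")
}

#' Default LF and HF bands
#'
#' @return List of two [freq_band()]s: LF = [0.04, 0.15) Hz,
#'   HF = [0.15, 0.4) Hz.
#' @export
default_bands <- function() {
  list(LF = freq_band("LF", 0.04, 0.15), HF = freq_band("HF", 0.15, 0.4))
}

.band_methods <- c("mean", "coherence_threshold", "gaussian_weight",
                   "max_coherence")

#' Reduce a transfer function to a per-band scalar index
#'
#' Four estimation strategies over the in-band grid points:
#' \describe{
#'   \item{mean}{arithmetic mean of the gain.}
#'   \item{coherence_threshold}{mean of the gain restricted to points whose
#'     squared coherence exceeds `threshold` (default 0.5 n.u.); the
#'     estimate is unavailable (`available = FALSE`, value `NA`) when no
#'     point qualifies.}
#'   \item{gaussian_weight}{gain average under Gaussian weights centred at
#'     the band midpoint with standard deviation `(hi - lo)/4`, truncated
#'     to the band and normalized to sum to one.}
#'   \item{max_coherence}{gain at the in-band frequency of maximal squared
#'     coherence; ties break to the lowest frequency.}
#' }
#'
#' @param tf a `transfer_function`.
#' @param coh a `coherence_function` on the same frequency grid.
#' @param band a [freq_band()].
#' @param method one of `"mean"`, `"coherence_threshold"`,
#'   `"gaussian_weight"`, `"max_coherence"`.
#' @param threshold squared-coherence threshold for the threshold method.
#' @param sigma_frac Gaussian width as a fraction of the band width
#'   (default 1/4).
#' @return An object of class `band_estimate`: `band`, `method`, `value`
#'   (gain in the transfer units, `NA` when unavailable), `available`,
#'   `threshold`, `n_points`.
#' @export
band_estimate <- function(tf, coh, band,
                          method = c("mean", "coherence_threshold",
                                     "gaussian_weight", "max_coherence"),
                          threshold = 0.5, sigma_frac = 0.25) {
  stopifnot(inherits(tf, "transfer_function"),
            inherits(coh, "coherence_function"),
            inherits(band, "freq_band"))
  method <- match.arg(method)
  if (length(tf$freqs) != length(coh$freqs) ||
      max(abs(tf$freqs - coh$freqs)) > 1e-9) {
    stop("transfer and coherence functions are on different grids",
         call. = FALSE)
  }
  sel <- which(tf$freqs >= band$lo & tf$freqs < band$hi)
  if (length(sel) == 0L) {
    stop(sprintf("band %s [%g, %g) contains no grid points", band$name,
                 band$lo, band$hi), call. = FALSE)
  }
  g <- tf$gain[sel]
  c2 <- coh$values[sel]
  f <- tf$freqs[sel]
  available <- TRUE
  used <- length(sel)
  value <- switch(method,
    mean = mean(g),
    coherence_threshold = {
      ok <- c2 > threshold
      used <- sum(ok)
      if (used == 0L) { available <- FALSE; NA_real_ } else mean(g[ok])
    },
    gaussian_weight = {
      mid <- (band$lo + band$hi) / 2
      sd_w <- (band$hi - band$lo) * sigma_frac
      w <- exp(-0.5 * ((f - mid) / sd_w)^2)
      sum(w * g) / sum(w)
    },
    max_coherence = g[which.max(c2)])  # which.max: first (lowest f) on ties
  structure(list(band = band, method = method, value = value,
                 available = available,
                 threshold = if (method == "coherence_threshold") threshold
                             else NA_real_,
                 n_points = used, units = tf$units, kind = tf$kind,
                 direction = tf$direction),
            class = "band_estimate")
}

#' @export
print.band_estimate <- function(x, ...) {
  val <- if (x$available) sprintf("%.3f %s", x$value, x$units) else "N/A"
  cat(sprintf("%s %s [%s]: %s\n", x$band$name, x$kind, x$method, val))
  invisible(x)
}

#' Tabulate band estimates over transfer kinds, bands and methods
#'
#' Computes the full Cartesian product of the requested transfer functions,
#' bands and estimation methods against a single coherence function, in a
#' deterministic row order (transfer kind, then band, then method).
#' Unavailable coherence-threshold cells are kept as rows with `value = NA`
#' and `available = FALSE`, never dropped.
#'
#' @param tfs named list of `transfer_function`s.
#' @param coh a `coherence_function` on the same grid.
#' @param bands list of [freq_band()]s (default [default_bands()]).
#' @param methods character vector of methods (default all four).
#' @param threshold squared-coherence threshold (default 0.5).
#' @return A `data.frame` with columns `transfer`, `direction`, `band`,
#'   `method`, `value`, `available`, `n_points`, `units`.
#' @export
estimate_all <- function(tfs, coh, bands = default_bands(),
                         methods = .band_methods, threshold = 0.5) {
  if (inherits(tfs, "transfer_function")) tfs <- list(tfs)
  if (is.null(names(tfs))) {
    names(tfs) <- vapply(tfs, `[[`, character(1), "kind")
  }
  methods <- match.arg(methods, .band_methods, several.ok = TRUE)
  rows <- list()
  for (nm in names(tfs)) {
    for (band in bands) {
      for (method in methods) {
        est <- band_estimate(tfs[[nm]], coh, band, method,
                             threshold = threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          transfer = nm, direction = est$direction, band = band$name,
          method = method, value = est$value, available = est$available,
          n_points = est$n_points, units = est$units,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
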