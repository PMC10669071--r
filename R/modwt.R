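# Maximal overlap discrete wavelet transform (MODWT), pyramid algorithm of
# Percival & Walden. Non-decimated, shift-invariant, energy preserving under
# circular boundary treatment; used here solely for trend isolation.

# Scaling (low-pass) filters, unit energy. "d8" is the 16-tap Daubechies
# extremal-phase wavelet with 8 vanishing moments (named d16 in some R HRV
# packages, db8 elsewhere).
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  d8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
         0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
         0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
         -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
         -0.004870352993451574, -0.00039174037337694705,
         0.0006754494064505693, -0.00011747678412476953)
)

#' Supported wavelets
#'
#' @return Character vector of wavelet identifiers: `"d8"` (Daubechies,
#'   16 taps, default everywhere in the package) and `"haar"`.
#' @export
wavelet_names <- function() names(.wavelet_filters)

.wavelet_filter <- function(wavelet) {
  g <- .wavelet_filters[[wavelet]]
  if (is.null(g)) {
    stop(sprintf("unknown wavelet '%s'; available: %s", wavelet,
                 paste(names(.wavelet_filters), collapse = ", ")),
         call. = FALSE)
  }
  L <- length(g)
  # quadrature mirror: h_l = (-1)^l g_{L-1-l}
  h <- rev(g) * (-1)^(seq_len(L) - 1)
  list(g = g, h = h, L = L)
}

# one circular MODWT filtering step at level j (filters pre-scaled by 1/sqrt2)
.modwt_step <- function(v, filt, j) {
  n <- length(v)
  shift <- 2^(j - 1)
  w <- numeric(n)
  s <- numeric(n)
  idx0 <- seq_len(n) - 1L
  for (l in seq_len(filt$L)) {
    tap <- (idx0 - (l - 1L) * shift) %% n + 1L
    w <- w + filt$h[l] * v[tap]
    s <- s + filt$g[l] * v[tap]
  }
  list(w = w, v = s)
}

.imodwt_step <- function(w, v, filt, j) {
  n <- length(v)
  shift <- 2^(j - 1)
  out <- numeric(n)
  idx0 <- seq_len(n) - 1L
  for (l in seq_len(filt$L)) {
    tap <- (idx0 + (l - 1L) * shift) %% n + 1L
    out <- out + filt$h[l] * w[tap] + filt$g[l] * v[tap]
  }
  out
}

#' Maximal overlap discrete wavelet transform
#'
#' Decomposes `x` into `d` levels of detail coefficients plus one smooth
#' (approximation) vector, all of the original length (the transform is not
#' decimated). Circular boundary treatment; see [modwt_detrend()] for the
#' reflection-based border handling used in the detrending pipeline.
#'
#' @param x numeric vector.
#' @param d number of decomposition levels (>= 1).
#' @param wavelet one of [wavelet_names()].
#' @return A list with `details` (list of `d` numeric vectors, level 1 =
#'   highest frequency band), `smooth` (approximation at level `d`),
#'   `wavelet` and `d`.
#' @export
modwt <- function(x, d, wavelet = "d8") {
  x <- as.numeric(x)
  filt <- .wavelet_filter(wavelet)
  if (d < 1L) stop("d must be >= 1", call. = FALSE)
  support <- (2^d - 1) * (filt$L - 1) + 1
  if (length(x) < support) {
    stop(sprintf(paste0("series of length %d is shorter than the level-%d ",
                        "filter support (%d); use fewer levels or a longer ",
                        "window"), length(x), d, support), call. = FALSE)
  }
  filt_sc <- list(g = filt$g / sqrt(2), h = filt$h / sqrt(2), L = filt$L)
  details <- vector("list", d)
  v <- x
  for (j in seq_len(d)) {
    st <- .modwt_step(v, filt_sc, j)
    details[[j]] <- st$w
    v <- st$v
  }
  structure(list(details = details, smooth = v, wavelet = wavelet, d = d),
            class = "modwt")
}

#' Inverse maximal overlap discrete wavelet transform
#'
#' @param w a decomposition from [modwt()], possibly with edited
#'   coefficients.
#' @return The reconstructed numeric vector.
#' @export
imodwt <- function(w) {
  stopifnot(inherits(w, "modwt"))
  filt <- .wavelet_filter(w$wavelet)
  filt_sc <- list(g = filt$g / sqrt(2), h = filt$h / sqrt(2), L = filt$L)
  v <- w$smooth
  for (j in rev(seq_len(w$d))) {
    v <- .imodwt_step(w$details[[j]], v, filt_sc, j)
  }
  v
}

# smooth-only reconstruction: the wavelet trend at level d
.modwt_trend <- function(x, d, wavelet) {
  w <- modwt(x, d, wavelet)
  for (j in seq_len(w$d)) w$details[[j]][] <- 0
  imodwt(w)
}
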