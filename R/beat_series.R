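#' Beat-to-beat cardiovascular series
#'
#' A `beat_series` holds one beat-to-beat recording: the time of each beat
#' (seconds), the interbeat interval ending at that beat (IBI, milliseconds)
#' and the systolic blood pressure of that beat (SBP, mmHg). It is the
#' event-based representation from which all uniformly sampled analyses
#' start.
#'
#' @param time numeric vector of beat times in seconds, strictly increasing.
#' @param ibi numeric vector of interbeat intervals in milliseconds, > 0.
#' @param sbp numeric vector of systolic pressures in mmHg, > 0.
#'
#' @return An object of class `beat_series`: a list with elements `time`,
#'   `ibi` and `sbp`.
#' @examples
#' b <- beat_series(time = c(0, 1, 2.01), ibi = c(1000, 1010, 990),
#'                  sbp = c(120, 118, 121))
#' length(b$time)
#' @export
beat_series <- function(time, ibi, sbp) {
  time <- as.numeric(time)
  ibi <- as.numeric(ibi)
  sbp <- as.numeric(sbp)
  n <- length(time)
  if (n < 2L || length(ibi) != n || length(sbp) != n) {
    stop("beat_series requires three equal-length vectors of length >= 2",
         call. = FALSE)
  }
  if (anyNA(time) || any(!is.finite(time))) {
    stop("beat times must be finite", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("beat times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(ibi)) || any(ibi <= 0)) {
    stop("IBI values must be finite and strictly positive (ms)", call. = FALSE)
  }
  if (any(!is.finite(sbp)) || any(sbp <= 0)) {
    stop("SBP values must be finite and strictly positive (mmHg)", call. = FALSE)
  }
  structure(list(time = time, ibi = ibi, sbp = sbp), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("beat_series: %d beats over %.1f s\n", length(x$time),
              diff(range(x$time))))
  cat(sprintf("  mean IBI %.1f ms (HR %.1f bpm), mean SBP %.1f mmHg\n",
              mean(x$ibi), 60000 / mean(x$ibi), mean(x$sbp)))
  invisible(x)
}

#' Read a beat-to-beat recording from delimited text
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the header line)
#' with one row per beat. Columns are located by name through `column_map`;
#' the defaults match the common `Time`, `RR`, `SBP` layout. Time is taken
#' in seconds, IBI in milliseconds and SBP in mmHg; declare
#' `ibi_unit = "s"` in `column_map` for recordings whose interbeat column is
#' in seconds (values are converted to ms).
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named list overriding the column names and units:
#'   elements `time`, `ibi`, `sbp` (column names) and optionally `ibi_unit`
#'   (`"ms"`, the default, or `"s"`).
#' @return A validated [beat_series()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("Time,RR,SBP", "0,1000,120", "1,1010,118", "2.01,990,121"), f)
#' read_beat_recording(f)
#' @export
read_beat_recording <- function(path, column_map = list()) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  map <- utils::modifyList(
    list(time = "Time", ibi = "RR", sbp = "SBP", ibi_unit = "ms"), column_map)
  if (!map$ibi_unit %in% c("ms", "s")) {
    stop("ibi_unit must be 'ms' or 's'", call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (role in c("time", "ibi", "sbp")) {
    nm <- map[[role]]
    if (!nm %in% names(df)) {
      stop(sprintf("column '%s' (%s) not found in %s; available: %s",
                   nm, role, path, paste(names(df), collapse = ", ")),
           call. = FALSE)
    }
    col <- df[[nm]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   nm, bad), call. = FALSE)
    }
  }
  ibi <- df[[map$ibi]]
  if (map$ibi_unit == "s") ibi <- ibi * 1000
  beat_series(time = df[[map$time]], ibi = ibi, sbp = df[[map$sbp]])
}

#' Write a beat-to-beat or uniform series as delimited text
#'
#' Values are written with 12 significant digits so that a write/read
#' round-trip reproduces them exactly.
#'
#' @param x a [beat_series()] or [uniform_series()].
#' @param path output file path.
#' @param sep field delimiter (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, sep = ",") {
  if (inherits(x, "beat_series")) {
    df <- data.frame(Time = x$time, RR = x$ibi, SBP = x$sbp)
  } else if (inherits(x, "uniform_series")) {
    df <- data.frame(Time = series_times(x), RR = x$ibi, SBP = x$sbp)
  } else {
    stop("x must be a beat_series or uniform_series", call. = FALSE)
  }
  df[] <- lapply(df, function(v) formatC(v, digits = 12, format = "g"))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Uniformly resampled bivariate series
#'
#' Two channels (IBI in ms, SBP in mmHg) sampled on a common uniform grid.
#' Constructed by [resample_uniform()] or by the simulator; the constructor
#' validates the invariants shared by all downstream modelling entry points.
#'
#' @param ibi,sbp numeric channels of equal length, finite.
#' @param fs sampling frequency in Hz.
#' @param t0 time of the first sample in seconds.
#' @param meta optional named list of provenance metadata.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(ibi, sbp, fs, t0 = 0, meta = list()) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive sampling frequency in Hz", call. = FALSE)
  }
  ibi <- as.numeric(ibi)
  sbp <- as.numeric(sbp)
  if (length(ibi) != length(sbp)) {
    stop("IBI and SBP channels must have equal length", call. = FALSE)
  }
  if (anyNA(ibi) || anyNA(sbp) || any(!is.finite(c(ibi, sbp)))) {
    stop("uniform series must not contain missing or non-finite values",
         call. = FALSE)
  }
  structure(list(ibi = ibi, sbp = sbp, fs = fs, t0 = as.numeric(t0),
                 meta = meta),
            class = "uniform_series")
}

#' Sample times of a uniform series
#' @param x a [uniform_series()].
#' @return numeric vector of sample times in seconds.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0 + (seq_along(x$ibi) - 1) / x$fs
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("uniform_series: %d samples at %g Hz, t0 = %.3f s\n",
              length(x$ibi), x$fs, x$t0))
  invisible(x)
}

#' Resample a beat series onto a uniform grid
#'
#' Interpolates the IBI and SBP event series onto the grid
#' `t0, t0 + 1/fs, ...` where `t0` is the first beat time. The grid never
#' extends past the last beat: no sample is extrapolated. The default
#' interpolant is a natural cubic spline; `method = "linear"` selects
#' piecewise-linear interpolation.
#'
#' @param beats a [beat_series()].
#' @param fs target sampling frequency in Hz (default 4).
#' @param method `"spline"` (default) or `"linear"`.
#' @return A [uniform_series()].
#' @examples
#' b <- generate_physio_like(300, seed = 1)
#' u <- resample_uniform(b, fs = 4)
#' @export
resample_uniform <- function(beats, fs = 4, method = c("spline", "linear")) {
  stopifnot(inherits(beats, "beat_series"))
  method <- match.arg(method)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be positive", call. = FALSE)
  }
  span <- beats$time[length(beats$time)] - beats$time[1L]
  if (span < 16) {
    stop(sprintf("recording span %.2f s is too short (< 16 s)", span),
         call. = FALSE)
  }
  t0 <- beats$time[1L]
  grid <- seq(t0, beats$time[length(beats$time)] + 1e-12, by = 1 / fs)
  grid <- grid[grid <= beats$time[length(beats$time)] + 1e-9]
  interp <- function(y) {
    if (method == "spline") {
      stats::spline(beats$time, y, xout = grid, method = "natural")$y
    } else {
      stats::approx(beats$time, y, xout = grid)$y
    }
  }
  uniform_series(ibi = interp(beats$ibi), sbp = interp(beats$sbp),
                 fs = fs, t0 = t0,
                 meta = list(interp = method, n_beats = length(beats$time)))
}

#' Extract a time window from a uniform series
#'
#' Returns the sub-series on the half-open interval `[t_start, t_end)`.
#' Window metadata (mean heart rate in bpm, mean SBP, sample count and fs)
#' is attached under `meta`.
#'
#' @param series a [uniform_series()].
#' @param t_start,t_end window limits in seconds (absolute time).
#' @return A [uniform_series()] with window summary metadata.
#' @examples
#' u <- uniform_series(rep(1000, 200), rep(120, 200), fs = 4)
#' w <- window_segment(u, 10, 40)
#' w$meta$mean_hr_bpm
#' @export
window_segment <- function(series, t_start, t_end) {
  stopifnot(inherits(series, "uniform_series"))
  t <- series_times(series)
  t_last <- t[length(t)]
  if (!(t_start < t_end)) stop("t_start must be < t_end", call. = FALSE)
  if (t_start < series$t0 - 1e-9 || t_end > t_last + 1 / series$fs + 1e-9) {
    stop("window outside the series range", call. = FALSE)
  }
  keep <- which(t >= t_start - 1e-9 & t < t_end - 1e-9)
  # modelling entry points enforce their own >= 64-sample floor; here only
  # degenerate windows are rejected
  if (length(keep) < 2L) {
    stop(sprintf("window holds %d samples; it is too short to analyse",
                 length(keep)), call. = FALSE)
  }
  out <- uniform_series(series$ibi[keep], series$sbp[keep], fs = series$fs,
                        t0 = t[keep[1L]])
  out$meta <- list(
    mean_hr_bpm = 60000 / mean(out$ibi),
    mean_sbp_mmhg = mean(out$sbp),
    n = length(keep),
    fs = series$fs,
    t_start = t_start, t_end = t_end)
  out
}
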