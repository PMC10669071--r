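# Unit-root (ADF) and stationarity (KPSS) tests. Both are implemented for
# the constant-only case: the series reaching this gate have already been
# mean-subtracted and wavelet-detrended, so no deterministic trend term is
# included.

# MacKinnon (1994) approximate asymptotic p-value for the ADF t statistic,
# constant-only regression.
.adf_pvalue <- function(stat) {
  if (stat > 2.74) return(1)
  if (stat < -18.83) return(0)
  co <- if (stat <= -1.61) {
    c(2.1659, 1.4412, 0.038269)
  } else {
    c(1.7339, 0.93202, -0.12745, -0.010368)
  }
  stats::pnorm(sum(co * stat^(seq_along(co) - 1)))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Regresses the first difference on a constant, the lagged level and
#' `k` lagged differences; the test statistic is the t ratio of the lagged
#' level. The augmentation order `k` is chosen by AIC over
#' `0..trunc((n-1)^(1/3))` (all candidate regressions fitted on a common
#' sample). The null hypothesis is a unit root; small p-values indicate
#' stationarity. P-values use the MacKinnon (1994) asymptotic
#' approximation for the constant-only case.
#'
#' @param x numeric series, length >= 16.
#' @param k_max maximum augmentation lag; default `trunc((n - 1)^(1/3))`.
#' @return List with `statistic`, `p_value`, `lag`.
#' @export
adf_test <- function(x, k_max = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16L) stop("ADF test needs at least 16 observations", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, lag = 0L,
                degenerate = TRUE))
  }
  if (is.null(k_max)) k_max <- trunc((n - 1)^(1 / 3))
  k_max <- max(0L, min(as.integer(k_max), n %/% 4L))
  dx <- diff(x)
  fit_one <- function(k, common_start) {
    # rows t = common_start..(n-1) of the difference series
    rows <- common_start:(n - 1L)
    y <- dx[rows]
    X <- cbind(1, x[rows])
    if (k > 0) {
      for (i in seq_len(k)) X <- cbind(X, dx[rows - i])
    }
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    res <- y - X %*% beta
    m <- length(y)
    sig2 <- sum(res^2) / (m - ncol(X))
    XtXinv <- chol2inv(qr.R(qrX))
    tstat <- beta[2L] / sqrt(sig2 * XtXinv[2L, 2L])
    # Gaussian AIC with ML variance, comparable across k on the common sample
    aic <- m * log(sum(res^2) / m) + 2 * ncol(X)
    list(t = tstat, aic = aic)
  }
  common_start <- k_max + 1L
  fits <- lapply(0:k_max, fit_one, common_start = common_start)
  k <- which.min(vapply(fits, `[[`, numeric(1), "aic")) - 1L
  # refit the chosen order on its full sample
  best <- fit_one(k, k + 1L)
  list(statistic = unname(best$t), p_value = .adf_pvalue(best$t), lag = k)
}

#' KPSS level-stationarity test
#'
#' Tests the null of stationarity around a constant level. The statistic is
#' the scaled sum of squared partial sums of the demeaned series, with a
#' Bartlett-window long-run variance using bandwidth
#' `trunc(4 * (n/100)^0.25)`. P-values are interpolated from the standard
#' critical-value table and clamped to `[0.01, 0.10]`.
#'
#' @param x numeric series, length >= 16.
#' @return List with `statistic`, `p_value`, `bandwidth`.
#' @export
kpss_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16L) stop("KPSS test needs at least 16 observations", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, bandwidth = 0L,
                degenerate = TRUE))
  }
  e <- x - mean(x)
  s <- cumsum(e)
  l <- trunc(4 * (n / 100)^0.25)
  lrv <- sum(e^2) / n
  if (l > 0) {
    for (j in seq_len(l)) {
      w <- 1 - j / (l + 1)
      lrv <- lrv + 2 * w * sum(e[(j + 1):n] * e[1:(n - j)]) / n
    }
  }
  stat <- sum(s^2) / (n^2 * lrv)
  crit <- c(0.347, 0.463, 0.574, 0.739)
  pval <- c(0.10, 0.05, 0.025, 0.01)
  p <- if (stat <= crit[1L]) 0.10
       else if (stat >= crit[4L]) 0.01
       else stats::approx(crit, pval, xout = stat)$y
  list(statistic = stat, p_value = p, bandwidth = l)
}

#' Stationarity gate for a bivariate series
#'
#' Runs the ADF and KPSS tests on each channel. A channel is declared
#' stationary only when the two tests agree: ADF rejects its unit-root null
#' (`p < alpha`) and KPSS fails to reject its stationarity null
#' (`p > alpha`). The overall verdict is the conjunction over channels.
#' Constant (degenerate) channels fail with a flag, since neither test is
#' defined on them.
#'
#' @param series a [uniform_series()].
#' @param alpha significance level in (0, 0.5); default 0.05.
#' @param verbose print the verdict text.
#' @return An object of class `stationarity_report`: per-channel test
#'   results, `verdict` (named logical per channel), `stationary` (overall
#'   logical) and `degenerate` flags.
#' @examples
#' set.seed(1)
#' u <- uniform_series(rnorm(256), rnorm(256), fs = 4)
#' check_stationarity(u)$stationary
#' @export
check_stationarity <- function(series, alpha = 0.05, verbose = FALSE) {
  stopifnot(inherits(series, "uniform_series"))
  if (alpha <= 0 || alpha >= 0.5) {
    stop("alpha must lie in (0, 0.5)", call. = FALSE)
  }
  if (length(series$ibi) < 64L) {
    stop("stationarity check needs at least 64 samples per channel",
         call. = FALSE)
  }
  channels <- list(ibi = series$ibi, sbp = series$sbp)
  res <- lapply(channels, function(x) {
    adf <- adf_test(x)
    kpss <- kpss_test(x)
    degenerate <- isTRUE(adf$degenerate) || isTRUE(kpss$degenerate)
    ok <- !degenerate && adf$p_value < alpha && kpss$p_value > alpha
    list(adf = adf, kpss = kpss, degenerate = degenerate, stationary = ok)
  })
  verdict <- vapply(res, `[[`, logical(1), "stationary")
  rep <- structure(list(
    channels = res,
    alpha = alpha,
    verdict = verdict,
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    stationary = all(verdict)), class = "stationarity_report")
  if (verbose) {
    cat(if (rep$stationary) "Time series are stationary\n"
        else "Time series are not stationary\n")
  }
  rep
}

#' @export
print.stationarity_report <- function(x, ...) {
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    if (ch$degenerate) {
      cat(sprintf("%s: degenerate (constant) series\n", toupper(nm)))
    } else {
      cat(sprintf(
        "%s: ADF = %.3f (p = %.3f), KPSS = %.3f (p = %.3f) -> %s\n",
        toupper(nm), ch$adf$statistic, ch$adf$p_value, ch$kpss$statistic,
        ch$kpss$p_value, if (ch$stationary) "stationary" else "non-stationary"))
    }
  }
  cat(if (x$stationary) "Time series are stationary\n"
      else "Time series are not stationary\n")
  invisible(x)
}
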