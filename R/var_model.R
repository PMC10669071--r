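# Bivariate VAR(p) estimation and diagnostics. Channel order is fixed as
# (IBI, SBP): coefficient entry [i, j] of lag k couples channel j at lag k
# into channel i, so A_k[1, 2] is the baroreflex (SBP -> IBI) path and
# A_k[2, 1] the mechanical feedforward (IBI -> SBP) path.

.var_design <- function(Y, p, offset = p) {
  # rows t = (offset+1)..n of Y regressed on lags 1..p
  n <- nrow(Y)
  rows <- (offset + 1L):n
  X <- matrix(1, length(rows), 1 + 2 * p)
  for (k in seq_len(p)) {
    X[, (2 * k):(2 * k + 1)] <- Y[rows - k, , drop = FALSE]
  }
  list(Y = Y[rows, , drop = FALSE], X = X, rows = rows)
}

#' Estimate a bivariate VAR(p) model
#'
#' Equation-by-equation least squares of each channel on lags `1..p` of
#' both channels plus an intercept (the intercept is retained for numerical
#' safety but is expected to be ~0 on mean-subtracted input). The residual
#' covariance uses divisor `n_eff - p` where `n_eff = n - p` is the number
#' of regression rows.
#'
#' @param data a [uniform_series()] (channels are taken in the fixed order
#'   IBI, SBP).
#' @param p lag order, >= 1.
#' @return An object of class `var_model`: `p`, `coeffs` (list of `p` 2x2
#'   lag matrices), `intercept`, `sigma` (2x2 residual covariance),
#'   `residuals` (matrix), `n` (sample count used), `fs`, `loglik`, `aic`.
#' @examples
#' sim <- simulate_closed_loop_var(synthetic_preset("baroreflex", n = 2048,
#'                                                  seed = 1))
#' m <- estimate_var(sim, p = 2)
#' m$coeffs[[1]]
#' @export
estimate_var <- function(data, p) {
  stopifnot(inherits(data, "uniform_series"))
  p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1", call. = FALSE)
  Y <- cbind(ibi = data$ibi, sbp = data$sbp)
  n <- nrow(Y)
  if (n <= 8L * (4L * p + 2L)) {
    stop(sprintf("n = %d is too small to estimate a VAR(%d); need n > %d",
                 n, p, 8L * (4L * p + 2L)), call. = FALSE)
  }
  if (stats::sd(Y[, 1]) == 0 || stats::sd(Y[, 2]) == 0) {
    stop("constant channel: VAR estimation is singular", call. = FALSE)
  }
  des <- .var_design(Y, p)
  qrX <- qr(des$X)
  if (qrX$rank < ncol(des$X)) {
    stop("singular regressor matrix in VAR estimation", call. = FALSE)
  }
  B <- qr.coef(qrX, des$Y)               # (1 + 2p) x 2, columns = equations
  res <- des$Y - des$X %*% B
  n_eff <- nrow(des$Y)
  sigma <- crossprod(res) / (n_eff - p)
  coeffs <- lapply(seq_len(p), function(k) {
    t(B[(2 * k):(2 * k + 1), , drop = FALSE])  # row = target, col = source
  })
  coeffs <- lapply(coeffs, function(m) {
    dimnames(m) <- list(c("ibi", "sbp"), c("ibi", "sbp")); m
  })
  sigma_ml <- crossprod(res) / n_eff
  loglik <- -0.5 * n_eff * (2 * log(2 * pi) + log(det(sigma_ml)) + 2)
  k_par <- 4 * p + 2 + 3          # lag coeffs + intercepts + covariance
  structure(list(p = p, coeffs = coeffs,
                 intercept = unname(B[1L, ]),
                 sigma = unname(sigma), residuals = unname(res),
                 n = n_eff, fs = data$fs,
                 loglik = loglik, aic = -2 * loglik + 2 * k_par),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("var_model: bivariate VAR(%d), n = %d\n", x$p, x$n))
  cat("residual covariance:\n")
  print(signif(x$sigma, 4))
  invisible(x)
}

#' Select the VAR order by AIC
#'
#' Fits VAR(p) for `p = 1..p_max` on a common estimation sample (the first
#' `p_max` rows are conditioned out for every candidate, so the AIC values
#' are comparable) and returns the minimizer; ties break to the smallest
#' order.
#'
#' @param data a [uniform_series()].
#' @param p_max largest candidate order; default `min(20, floor(n/40))`.
#' @param detail if `TRUE` return a list with the AIC curve.
#' @return The selected order (integer), or a list with `p`, `aic`
#'   (named numeric over candidates) when `detail = TRUE`.
#' @export
select_order <- function(data, p_max = NULL, detail = FALSE) {
  stopifnot(inherits(data, "uniform_series"))
  Y <- cbind(data$ibi, data$sbp)
  n <- nrow(Y)
  if (is.null(p_max)) p_max <- min(20L, n %/% 40L)
  p_max <- as.integer(p_max)
  if (p_max < 1L || p_max > n %/% 8L) {
    stop(sprintf("p_max must lie in [1, %d]", n %/% 8L), call. = FALSE)
  }
  aic <- vapply(seq_len(p_max), function(p) {
    des <- .var_design(Y, p, offset = p_max)
    B <- qr.coef(qr(des$X), des$Y)
    res <- des$Y - des$X %*% B
    m <- nrow(res)
    sigma_ml <- crossprod(res) / m
    loglik <- -0.5 * m * (2 * log(2 * pi) + log(det(sigma_ml)) + 2)
    -2 * loglik + 2 * (4 * p + 2 + 3)
  }, numeric(1))
  names(aic) <- seq_len(p_max)
  p <- which.min(aic)  # which.min returns the first (smallest p) on ties
  if (detail) list(p = as.integer(p), aic = aic) else as.integer(p)
}

#' Companion-form stability diagnosis
#'
#' Builds the `2p x 2p` companion matrix of the lag polynomial; the model
#' is stable (stationary) if and only if every eigenvalue has modulus < 1.
#'
#' @param model a [estimate_var()] model, or any list with `p` and `coeffs`.
#' @param verbose print the verdict.
#' @return List with `spectral_radius`, `stable`, `eigenvalues`.
#' @examples
#' m <- list(p = 1, coeffs = list(diag(2) * 0.5))
#' diagnose_stability(m)$spectral_radius  # 0.5
#' @export
diagnose_stability <- function(model, verbose = FALSE) {
  p <- model$p
  C <- matrix(0, 2 * p, 2 * p)
  for (k in seq_len(p)) {
    C[1:2, (2 * k - 1):(2 * k)] <- model$coeffs[[k]]
  }
  if (p > 1L) {
    C[3:(2 * p), 1:(2 * p - 2)] <- diag(2 * p - 2)
  }
  ev <- eigen(C, only.values = TRUE)$values
  radius <- max(Mod(ev))
  if (verbose) {
    cat(if (radius < 1) "The model is stable\n" else "The model is not stable\n")
  }
  list(spectral_radius = radius, stable = radius < 1, eigenvalues = ev)
}

#' Multivariate portmanteau test of residual whiteness
#'
#' Ljung-Box-type statistic on the residual autocorrelations up to lag `h`:
#' `Q = n^2 * sum_{l=1..h} tr(C_l' C_0^-1 C_l C_0^-1) / (n - l)`, referred
#' to a chi-square with `4 * (h - p)` degrees of freedom. Residuals are
#' declared white when the p-value exceeds `alpha`.
#'
#' @param model a [estimate_var()] model with residuals.
#' @param h number of autocorrelation lags (default 12); must exceed `p`.
#' @param alpha significance level (default 0.05).
#' @param verbose print the verdict.
#' @return List with `statistic`, `df`, `p_value`, `white`.
#' @export
diagnose_residuals <- function(model, h = 12L, alpha = 0.05,
                               verbose = FALSE) {
  if (is.null(model$residuals)) {
    stop("model carries no residuals", call. = FALSE)
  }
  h <- as.integer(h)
  if (h <= model$p) {
    stop("h must exceed the model order p", call. = FALSE)
  }
  U <- scale(model$residuals, center = TRUE, scale = FALSE)
  n <- nrow(U)
  C0 <- crossprod(U) / n
  C0i <- solve(C0)
  Q <- 0
  for (l in seq_len(h)) {
    Cl <- crossprod(U[(l + 1):n, , drop = FALSE],
                    U[1:(n - l), , drop = FALSE]) / n
    Q <- Q + sum(diag(t(Cl) %*% C0i %*% Cl %*% C0i)) / (n - l)
  }
  Q <- Q * n^2
  df <- 4 * (h - model$p)
  pval <- stats::pchisq(Q, df, lower.tail = FALSE)
  if (verbose) {
    cat(if (pval > alpha) "Model residuals are white noise processes\n"
        else "Model residuals are not white noise processes\n")
  }
  list(statistic = Q, df = df, p_value = pval, white = pval > alpha)
}
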