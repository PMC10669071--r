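test_that("least squares recovers a known diagonal VAR(1)", {
  errs_diag <- errs_off <- numeric(20)
  for (s in 1:20) {
    sp <- simulation_spec(coeffs = list(diag(2) * 0.5), sigma = diag(2),
                          n = 8192, seed = s)
    m <- estimate_var(simulate_closed_loop_var(sp), p = 1)
    A <- m$coeffs[[1]]
    errs_diag[s] <- max(abs(diag(A) - 0.5))
    errs_off[s] <- max(abs(A[1, 2]), abs(A[2, 1]))
  }
  expect_lt(mean(errs_diag), 0.05)
  expect_lt(mean(errs_off), 0.05)
})

test_that("pure white noise yields near-zero coefficients", {
  small <- vapply(1:20, function(s) {
    set.seed(s)
    u <- uniform_series(rnorm(8192), rnorm(8192), fs = 4)
    all(abs(estimate_var(u, 1)$coeffs[[1]]) < 0.1)
  }, logical(1))
  expect_gte(mean(small), 0.9)
})

test_that("estimation preconditions reject undersized or degenerate input", {
  set.seed(5)
  u <- uniform_series(rnorm(24), rnorm(24), fs = 4)
  expect_error(estimate_var(u, 6), "too small")
  const <- uniform_series(rep(1, 256), rnorm(256), fs = 4)
  expect_error(estimate_var(const, 1), "constant|singular")
})

test_that("residuals are orthogonal to every lagged regressor", {
  sp <- synthetic_preset("bidirectional", n = 2048, seed = 3)
  m <- estimate_var(simulate_closed_loop_var(sp), p = 2)
  sim <- simulate_closed_loop_var(sp)
  Y <- cbind(sim$ibi, sim$sbp)
  n <- nrow(Y)
  rows <- 3:n
  for (k in 1:2) {
    for (ch in 1:2) {
      reg <- Y[rows - k, ch]
      expect_lt(max(abs(crossprod(reg, m$residuals))) / n, 1e-8)
    }
  }
})

test_that("AIC order selection finds the true order of a coupled VAR(2)", {
  hits <- vapply(1:50, function(s) {
    sim <- simulate_closed_loop_var(
      synthetic_preset("baroreflex", n = 4096, seed = s))
    select_order(sim, p_max = 12)
  }, integer(1))
  expect_gte(mean(hits == 2L), 0.8)
})

test_that("independent white noise selects a minimal order", {
  picks <- vapply(1:50, function(s) {
    set.seed(s)
    u <- uniform_series(rnorm(2048), rnorm(2048), fs = 4)
    select_order(u, p_max = 12)
  }, integer(1))
  expect_gte(mean(picks <= 2L), 0.8)
})

test_that("the reported AIC curve equals a direct likelihood evaluation", {
  sim <- simulate_closed_loop_var(
    synthetic_preset("bidirectional", n = 2048, seed = 9))
  p_max <- 6L
  sel <- select_order(sim, p_max = p_max, detail = TRUE)
  Y <- cbind(sim$ibi, sim$sbp)
  # independent route: explicit regression per order on the common sample
  for (p in seq_len(p_max)) {
    rows <- (p_max + 1):nrow(Y)
    X <- cbind(1, do.call(cbind, lapply(1:p, function(k) Y[rows - k, ])))
    B <- solve(crossprod(X), crossprod(X, Y[rows, ]))
    E <- Y[rows, ] - X %*% B
    m <- nrow(E)
    S <- crossprod(E) / m
    ll <- -0.5 * m * (2 * log(2 * pi) + log(det(S)) + 2)
    aic <- -2 * ll + 2 * (4 * p + 2 + 3)
    expect_lt(abs(sel$aic[[p]] - aic), 1e-6)
  }
  expect_error(select_order(sim, p_max = 0), "p_max")
})

test_that("coefficient RMSE shrinks as the record grows", {
  rmse_at <- function(n) {
    mean(vapply(1:20, function(s) {
      sp <- synthetic_preset("bidirectional", n = n, seed = s)
      m <- estimate_var(simulate_closed_loop_var(sp), p = 2)
      sqrt(mean((unlist(m$coeffs) - unlist(sp$coeffs))^2))
    }, numeric(1)))
  }
  r <- vapply(c(1024, 4096, 16384), rmse_at, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("companion stability matches a polynomial-root oracle", {
  m1 <- list(p = 1L, coeffs = list(diag(2) * 0.5))
  expect_equal(diagnose_stability(m1)$spectral_radius, 0.5)
  expect_true(diagnose_stability(m1)$stable)

  m2 <- list(p = 1L, coeffs = list(diag(2) * 1.1))
  expect_equal(diagnose_stability(m2)$spectral_radius, 1.1)
  expect_false(diagnose_stability(m2)$stable)

  A1 <- matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2)
  A2 <- matrix(c(0.2, 0, 0, 0.1), 2, 2)
  m3 <- list(p = 2L, coeffs = list(A1, A2))
  radius <- diagnose_stability(m3)$spectral_radius
  # oracle: roots z of det(I - A1 z - A2 z^2); eigenvalues are 1/z
  detpoly <- function(z) {
    M <- diag(2) - A1 * z - A2 * z^2
    M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  }
  # expand det into polynomial coefficients by evaluation at 5 points
  V <- outer(0:4, 0:4, function(i, j) (1 + i)^j)
  cf <- solve(V, vapply(0:4, function(i) detpoly(1 + i), numeric(1)))
  roots <- polyroot(cf)
  expect_lt(abs(radius - max(1 / Mod(roots))), 1e-10)
})

test_that("portmanteau whiteness test has correct null and alternative behaviour", {
  base <- estimate_var(simulate_closed_loop_var(
    synthetic_preset("uncoupled", n = 2048, seed = 1)), p = 1)
  run_with_residuals <- function(make_res) {
    vapply(1:100, function(s) {
      set.seed(s)
      m <- base
      m$residuals <- cbind(make_res(), make_res())
      diagnose_residuals(m, h = 12, alpha = 0.05)$white
    }, logical(1))
  }
  null_white <- run_with_residuals(function() rnorm(2048))
  expect_gte(mean(null_white), 0.9)
  ar_res <- run_with_residuals(function()
    as.numeric(arima.sim(list(ar = 0.6), 2048)))
  expect_lte(mean(ar_res), 0.05)
  expect_error(diagnose_residuals(base, h = 1), "exceed")
})

test_that("verbose diagnostics mirror the console transcript wording", {
  m <- estimate_var(simulate_closed_loop_var(
    synthetic_preset("baroreflex", n = 2048, seed = 2)), p = 2)
  expect_output(diagnose_stability(m, verbose = TRUE), "The model is stable")
  expect_output(diagnose_residuals(m, verbose = TRUE),
                "white noise processes")
})
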