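test_that("a coefficient-free model has H = I and a flat spectrum", {
  m <- list(p = 1L, coeffs = list(matrix(0, 2, 2)),
            sigma = diag(c(2, 3)), fs = 4)
  fm <- to_frequency_domain(m, n_freq = 64)
  expect_lt(max(abs(fm$A)), 1e-14)
  for (i in c(1, 32, 64)) {
    expect_lt(max(Mod(fm$H[, , i] - diag(2))), 1e-12)
    expect_lt(max(Mod(fm$S[, , i] - diag(c(2, 3)))), 1e-12)
  }
})

test_that("the univariate embedding reproduces the closed-form AR(1) spectrum", {
  m <- list(p = 1L, coeffs = list(matrix(c(0.5, 0, 0, 0), 2, 2)),
            sigma = diag(2), fs = 4)
  fm <- to_frequency_domain(m, n_freq = 256)
  want <- ar1_spectrum(0.5, 1, fm$freqs, 4)
  expect_lt(max(abs(Re(fm$S[1, 1, ]) - want) / want), 1e-8)
})

test_that("S = H Sigma H* holds at every frequency for random stable models", {
  for (s in 1:10) {
    m <- random_stable_var1(s)
    fm <- to_frequency_domain(m, n_freq = 128)
    for (i in seq(1, 128, by = 9)) {
      S_rebuilt <- fm$H[, , i] %*% fm$sigma %*% Conj(t(fm$H[, , i]))
      expect_lt(max(Mod(fm$S[, , i] - S_rebuilt)), 1e-10)
      # Hermitian PSD
      expect_lt(max(Mod(fm$S[, , i] - Conj(t(fm$S[, , i])))), 1e-10)
      ev <- eigen(fm$S[, , i], only.values = TRUE)$values
      expect_gte(min(Re(ev)), -1e-10 * sum(Mod(diag(fm$S[, , i]))))
    }
  }
})

test_that("parametric total power matches the sample variance of a long run", {
  sp <- synthetic_preset("bidirectional", n = 65536, seed = 4)
  sim <- simulate_closed_loop_var(sp)
  fm <- analytic_freq_model(sp, n_freq = 4096)
  df <- fm$freqs[2] - fm$freqs[1]
  for (ch in 1:2) {
    power <- (2 / fm$fs) * sum(Re(fm$S[ch, ch, ])) * df
    v <- var(if (ch == 1) sim$ibi else sim$sbp)
    expect_lt(abs(power - v) / v, 0.05)
  }
})

test_that("instantaneous extraction reproduces the hand-worked Cholesky case", {
  m <- list(p = 1L, coeffs = list(matrix(0, 2, 2)),
            sigma = matrix(c(4, 2, 2, 3), 2, 2), fs = 4)
  fm <- to_frequency_domain(m, n_freq = 64)
  # channel 1 (IBI) as source: path ibi->sbp
  fme <- extract_instantaneous(fm, "ibi->sbp")
  expect_equal(fme$b0, 0.5)
  expect_equal(fme$D, matrix(c(1, 0.5, 0, 1), 2, 2))
  expect_equal(diag(fme$sigma), c(4, 2))
  expect_lt(max(abs(fme$D %*% fme$sigma %*% t(fme$D) -
                      matrix(c(4, 2, 2, 3), 2, 2))), 1e-12)
})

test_that("extraction diagonalizes Sigma and leaves S invariant", {
  set.seed(21)
  for (rep in 1:25) {
    sg <- random_spd2()
    m <- random_stable_var1(rep + 100)
    m$sigma <- sg
    fm <- to_frequency_domain(m, n_freq = 64)
    for (path in c("sbp->ibi", "ibi->sbp")) {
      fme <- extract_instantaneous(fm, path)
      expect_lt(abs(fme$sigma[1, 2]), 1e-10)
      expect_lt(max(abs(fme$D %*% fme$sigma %*% t(fme$D) - sg)), 1e-10)
      expect_lt(max(Mod(fme$S - fm$S)), 1e-10)
    }
  }
  # diagonal Sigma: nothing to extract
  m <- random_stable_var1(1)
  m$sigma <- diag(c(1, 2))
  fme <- extract_instantaneous(to_frequency_domain(m, 64))
  expect_equal(fme$b0, 0)
  expect_equal(fme$D, diag(2))
})

test_that("closed-loop transfer matches hand values and vanishes without coupling", {
  # no coupling in the chosen direction
  m <- list(p = 1L, coeffs = list(matrix(c(0.5, 0, 0, 0.5), 2, 2)),
            sigma = diag(2), fs = 4)
  fm <- to_frequency_domain(m, 64)
  tf <- closed_loop_transfer(fm, "sbp->ibi", corrected = FALSE)
  expect_lt(max(tf$gain), 1e-10)

  # coupling 0.3, target autoregression 0.5: gain 0.6 at f = 0
  m2 <- list(p = 1L, coeffs = list(matrix(c(0.5, 0, 0.3, 0.2), 2, 2)),
             sigma = diag(2), fs = 4)
  fm2 <- to_frequency_domain(m2, 64)
  tf2 <- closed_loop_transfer(fm2, "sbp->ibi", corrected = FALSE)
  expect_equal(tf2$gain[1], 0.3 / 0.5, tolerance = 1e-12)
  # opposite arm reads the transposed entries
  tf3 <- closed_loop_transfer(fm2, "ibi->sbp", corrected = FALSE)
  expect_equal(tf3$gain[1], 0 / 0.8, tolerance = 1e-12)
  expect_identical(tf3$units, "mmHg/ms")
})

test_that("correlated innovations make corrected and biased transfers differ", {
  sp <- synthetic_preset("baroreflex", n = 1024, seed = 1)
  fm <- analytic_freq_model(sp, 256, extract_path = "sbp->ibi")
  biased <- closed_loop_transfer(fm, "sbp->ibi", corrected = FALSE)
  corrected <- closed_loop_transfer(fm, "sbp->ibi", corrected = TRUE)
  rel <- abs(corrected$gain - biased$gain) /
    pmax(abs(corrected$gain), 1e-12)
  expect_gt(max(rel), 0.05)
})

test_that("open-loop type I is exact on a truly open loop", {
  # SBP driven by its own noise only, one-way SBP -> IBI coupling
  m <- list(p = 1L, coeffs = list(matrix(c(0.4, 0, 0.6, 0.5), 2, 2)),
            sigma = diag(c(1e-10, 1)), fs = 4)
  fm <- to_frequency_domain(m, 128)
  tf_open <- open_loop_transfer(fm, "type_I")
  tf_true <- closed_loop_transfer(fm, "sbp->ibi", corrected = FALSE)
  expect_lt(max(abs(tf_open$gain - tf_true$gain) / tf_true$gain), 1e-6)

  # uncoupled, diagonal noise: zero cross-spectrum
  m0 <- list(p = 1L, coeffs = list(matrix(0, 2, 2)), sigma = diag(2), fs = 4)
  expect_lt(max(open_loop_transfer(to_frequency_domain(m0, 64),
                                   "type_I")$gain), 1e-12)
})

test_that("band-averaged open-loop estimates dominate closed-loop ones", {
  ok <- matrix(NA, 20, 2)
  for (s in 1:20) {
    sp <- synthetic_preset("bidirectional", n = 8192, seed = s)
    sim <- simulate_closed_loop_var(sp)
    fm <- extract_instantaneous(
      to_frequency_domain(estimate_var(sim, 2), 256), "sbp->ibi")
    coh <- spectral_coherence(fm)
    cl <- closed_loop_transfer(fm, "sbp->ibi", corrected = TRUE)
    o1 <- open_loop_transfer(fm, "type_I")
    o2 <- open_loop_transfer(fm, "type_II")
    bands <- default_bands()
    ok[s, ] <- vapply(seq_along(bands), function(i) {
      b <- bands[[i]]
      g <- function(tf) band_estimate(tf, coh, b, "mean")$value
      g(o1) >= g(o2) - 1e-9 && g(o2) >= g(cl) - 1e-9
    }, logical(1))
  }
  expect_gte(mean(ok), 0.9)
})

test_that("spectral coherence is bounded, zero when uncoupled, one for rank-1 noise", {
  m0 <- list(p = 1L, coeffs = list(matrix(0, 2, 2)), sigma = diag(2), fs = 4)
  coh0 <- spectral_coherence(to_frequency_domain(m0, 64))
  expect_lt(max(coh0$values), 1e-12)

  # single noise source driving both channels: coherence -> 1
  m1 <- list(p = 1L, coeffs = list(matrix(c(0.3, 0, 0.7, 0.4), 2, 2)),
             sigma = matrix(c(1e-12, 0, 0, 1), 2, 2), fs = 4)
  coh1 <- spectral_coherence(to_frequency_domain(m1, 64))
  expect_gt(min(coh1$values), 0.999)

  for (s in 1:10) {
    fm <- to_frequency_domain(random_stable_var1(s), 64)
    v <- spectral_coherence(fm)$values
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("causal coherence isolates the active arm of a one-way loop", {
  # lagged one-way SBP -> IBI coupling, diagonal noise
  m <- list(p = 1L, coeffs = list(matrix(c(0.4, 0, 0.7, 0.5), 2, 2)),
            sigma = diag(2), fs = 4)
  fm <- extract_instantaneous(to_frequency_domain(m, 512), "sbp->ibi")
  ord <- spectral_coherence(fm)
  fwd <- causal_coherence(fm, "sbp->ibi")
  bwd <- causal_coherence(fm, "ibi->sbp")
  expect_lt(max(abs(fwd$values - ord$values)), 0.05)
  expect_lt(max(bwd$values), 0.05)
  expect_true(all(fwd$values >= 0 & fwd$values <= 1))

  # uncoupled: both causal coherences vanish
  m0 <- list(p = 1L, coeffs = list(matrix(0, 2, 2)), sigma = diag(2), fs = 4)
  fm0 <- extract_instantaneous(to_frequency_domain(m0, 64))
  expect_lt(max(causal_coherence(fm0, "sbp->ibi")$values), 1e-12)
  expect_lt(max(causal_coherence(fm0, "ibi->sbp")$values), 1e-12)
})

test_that("suppressing a truly absent path barely changes coherence", {
  m <- list(p = 2L, coeffs = list(matrix(c(0.4, 0, 0.7, 0.6), 2, 2),
                                  matrix(c(-0.1, 0, 0.2, -0.3), 2, 2)),
            sigma = diag(c(1, 0.5)), fs = 4)
  fm <- extract_instantaneous(to_frequency_domain(m, 512), "sbp->ibi")
  ord <- spectral_coherence(fm)
  fwd <- causal_coherence(fm, "sbp->ibi")
  expect_lt(max(abs(fwd$values - ord$values)), 0.05)
})

test_that("noise contributions sum to 100 percent and track coupling strength", {
  # uncoupled: own noise explains everything
  m0 <- list(p = 1L, coeffs = list(matrix(c(0.5, 0, 0, 0.5), 2, 2)),
             sigma = diag(2), fs = 4)
  nc0 <- noise_contribution(
    extract_instantaneous(to_frequency_domain(m0, 64)))
  expect_lt(max(abs(nc0$percent[1, 1, ] - 100)), 1e-8)
  expect_lt(max(abs(nc0$percent[2, 2, ] - 100)), 1e-8)

  for (s in 1:5) {
    m <- random_stable_var1(s)
    nc <- noise_contribution(
      extract_instantaneous(to_frequency_domain(m, 64)))
    sums <- nc$percent[, 1, ] + nc$percent[, 2, ]
    expect_lt(max(abs(sums - 100)), 1e-6)
  }

  # strong one-way coupling: foreign noise dominates the target's spectrum
  sp <- synthetic_preset("baroreflex", n = 1024, seed = 1)
  fm <- analytic_freq_model(sp, 256, extract_path = "sbp->ibi")
  nc <- noise_contribution(fm)
  sbp_res <- which.max(Re(fm$S[2, 2, ]))  # SBP resonance frequency
  expect_gt(nc$percent[1, 2, sbp_res], 50)
})

test_that("frequency-domain entry points validate their preconditions", {
  m_unstable <- list(p = 1L, coeffs = list(diag(2) * 1.2), sigma = diag(2),
                     fs = 4)
  expect_error(to_frequency_domain(m_unstable, 128), "unstable")
  m <- random_stable_var1(2)
  expect_error(to_frequency_domain(m, 32), "n_freq")
  fm <- to_frequency_domain(m, 64)
  expect_error(causal_coherence(fm, "sbp->ibi"), "extract")
  expect_error(noise_contribution(fm), "extract")
  expect_error(closed_loop_transfer(fm, corrected = TRUE), "extract")
  fme <- extract_instantaneous(fm)
  expect_error(extract_instantaneous(fme), "already")
})
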