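# stochastic rate-model simulator and Welch periodogram

test_that("periodogram normalization: white trace is flat at its density", {
  set.seed(2)
  dt <- 1e-3; D <- 0.04
  y <- matrix(rnorm(60000, sd = sqrt(D / dt)), ncol = 1)
  colnames(y) <- "X"
  tr <- structure(list(y = y, dt = dt, duration = 60, seed = 2),
                  class = "rate_trace")
  pg <- periodogram(tr, window = 0.5)
  expect_equal(pg$n_windows, 120)
  sel <- pg$freqs > 5 & pg$freqs < 450
  expect_equal(mean(pg$power[sel, 1]), D, tolerance = 0.05)
  z <- (pg$power[sel, 1] - D) / pg$se[sel, 1]
  expect_gt(mean(abs(z) <= 3), 0.95)
})

test_that("periodogram resolves a pure sinusoid in a single bin", {
  dt <- 1e-3
  t <- seq(0, 20 - dt, by = dt)
  y <- matrix(sin(2 * pi * 40 * t), ncol = 1); colnames(y) <- "X"
  tr <- structure(list(y = y, dt = dt, duration = 20, seed = 1),
                  class = "rate_trace")
  pg <- periodogram(tr, window = 0.5)
  expect_equal(pg$freqs[which.max(pg$power[, 1])], 40)
  expect_error(periodogram(tr, window = 30), "two windows")
})

test_that("zero-connectivity simulation reproduces the Poisson baseline", {
  m <- make_net2(); m$K[] <- 0
  st <- solve_selfconsistent(m)
  tr <- simulate_rates(m, st, duration = 10, dt = 1e-4, seed = 5)
  pg <- periodogram(tr, window = 0.5)
  base <- st$rates / m$sizes
  sel <- pg$freqs > 10 & pg$freqs < 1000
  for (p in 1:2)
    expect_equal(mean(pg$power[sel, p]), base[p], tolerance = 0.05)
})

test_that("simulation is seed-deterministic and linear in the noise", {
  m <- make_net2()
  st <- solve_selfconsistent(m)
  tr1 <- simulate_rates(m, st, duration = 2, dt = 1e-4, seed = 11,
                        burn_in = 0.5)
  tr2 <- simulate_rates(m, st, duration = 2, dt = 1e-4, seed = 11,
                        burn_in = 0.5)
  expect_identical(tr1$y, tr2$y)
  # doubling the noise variance doubles the spectrum (linear system):
  # simulate with rates scaled by 2 in the noise only via doubled D; here we
  # exploit linearity directly: same seed, noise sd scaled by sqrt(2)
  st2 <- st; st2$rates <- st$rates * 2
  # kernels are built from the unchanged working point; only D changes
  kk1 <- popspectra:::.connection_kernels(m, st, 1e-4)
  expect_lt(kk1$truncation_error, 1e-4)
  pg1 <- periodogram(simulate_rates(m, st, 8, 1e-4, seed = 3), 0.5)
  m2 <- m; m2$sizes <- m$sizes / 2     # halved sizes double D
  pg2 <- periodogram(simulate_rates(m2, st, 8, 1e-4, seed = 3), 0.5)
  sel <- pg1$freqs > 20 & pg1$freqs < 400
  ratio <- pg2$power[sel, ] / pg1$power[sel, ]
  expect_equal(median(ratio), 2, tolerance = 0.1)
})

test_that("band-limited Parseval consistency of the periodogram", {
  m <- make_net2()
  st <- solve_selfconsistent(m)
  tr <- simulate_rates(m, st, duration = 10, dt = 1e-4, seed = 8)
  pg <- periodogram(tr, window = 0.5)
  df <- pg$freqs[2] - pg$freqs[1]
  # two-sided integral of the estimated density vs windowed trace variance
  nseg <- floor(0.5 / tr$dt)
  nwin <- floor(nrow(tr$y) / nseg)
  vtot <- mean(vapply(seq_len(nwin), function(w) {
    seg <- tr$y[((w - 1) * nseg + 1):(w * nseg), 1]
    mean((seg - mean(seg))^2)
  }, 1))
  integ <- unname((2 * sum(pg$power[-1, 1]) + pg$power[1, 1]) * df)
  expect_equal(integ, vtot, tolerance = 0.05)
})

test_that("analytic spectra match the simulated periodogram (oracle
           contract, two-population circuit)", {
  m <- make_net2()
  st <- solve_selfconsistent(m)
  grid <- frequency_grid(400, 2)
  spec <- power_spectra(effective_connectivity(m, st, grid = grid))
  tr <- simulate_rates(m, st, duration = 15, dt = 1e-4, seed = 42)
  pg <- periodogram(tr, window = 0.5)
  sel <- which(pg$freqs >= 40 & pg$freqs <= 300)
  for (p in 1:2) {
    th <- vapply(pg$freqs[sel], function(f)
      spec$C[which.min(abs(grid$freqs - f)), p], 1)
    z <- (pg$power[sel, p] - th) / pg$se[sel, p]
    expect_gt(mean(abs(z) <= 3), 0.9)
    expect_lt(abs(median(z)), 1)
  }
})

test_that("delay-draw mode stays close to the averaged-kernel dynamics", {
  m <- make_net2()
  st <- solve_selfconsistent(m)
  set.seed(1)
  kk_avg <- popspectra:::.connection_kernels(m, st, 1e-4, "averaged")
  kk_drw <- popspectra:::.connection_kernels(m, st, 1e-4, "draw",
                                             n_draws = 4000)
  n <- min(nrow(kk_avg$kern), nrow(kk_drw$kern))
  for (c in 1:ncol(kk_avg$kern)) {
    scale <- max(abs(kk_avg$kern[, c]))
    expect_lt(max(abs(kk_avg$kern[1:n, c] - kk_drw$kern[1:n, c])),
              0.05 * scale)
  }
})

test_that("unstable circuits are refused", {
  m <- make_net1(K = 800, W = -0.9, d = 2e-3, d_sd = 0.1e-3)
  st <- solve_selfconsistent(m)
  expect_error(simulate_rates(m, st, duration = 1), "unstable")
  expect_error(simulate_rates(make_net2(), solve_selfconsistent(make_net2()),
                              duration = 1, dt = 1e-3), "tau_s / 5")
})
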