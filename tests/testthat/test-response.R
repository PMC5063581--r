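# transfer functions, delay filtering and the effective connectivity matrix

test_that("delay factor matches quadrature and its analytic limits", {
  quad <- function(d, s, om) {
    lo <- max(0, d - 12 * s); hi <- d + 12 * s   # window holds all the mass
    f <- function(y) exp(-(y - d)^2 / (2 * s^2))
    nrm <- integrate(f, lo, hi, rel.tol = 1e-13)$value
    complex(real = integrate(function(y) cos(om * y) * f(y), lo, hi,
                             rel.tol = 1e-13, subdivisions = 500)$value,
            imaginary = -integrate(function(y) sin(om * y) * f(y), lo, hi,
                                   rel.tol = 1e-13,
                                   subdivisions = 500)$value) / nrm
  }
  cases <- list(c(1.5e-3, 1e-3, 2 * pi * 64), c(0.75e-3, 1e-3, 2 * pi * 275),
                c(1.5e-3, 0.75e-3, 2 * pi * 90), c(3e-3, 0.4e-3, 2 * pi * 33))
  for (cs in cases)
    expect_lt(Mod(delay_factor(cs[1], cs[2], cs[3]) -
                  quad(cs[1], cs[2], cs[3])), 1e-8)
  # omega = 0: normalised density
  expect_equal(delay_factor(1.5e-3, 1e-3, 0), 1 + 0i)
  # point-mass limit: pure phase
  om <- 2 * pi * c(10, 100, 400)
  expect_equal(delay_factor(1.5e-3, 0, om), exp(-1i * om * 1.5e-3))
  expect_lt(max(Mod(delay_factor(1.5e-3, 1e-9, om) -
                    exp(-1i * om * 1.5e-3))), 1e-6)
  # conjugate symmetry
  expect_equal(delay_factor(1e-3, 0.5e-3, -om),
               Conj(delay_factor(1e-3, 0.5e-3, om)))
})

test_that("wider delay distributions compress the response", {
  om <- 2 * pi * c(30, 100, 300)
  sds <- c(0.2, 0.5, 1, 1.5) * 1e-3
  for (o in om) {
    mods <- vapply(sds, function(s) Mod(delay_factor(1.5e-3, s, o)), 1)
    expect_true(all(diff(mods) < 0))
  }
})

test_that("transfer function limits pin its normalization", {
  nrn <- std_neuron()
  for (wp in list(c(4, 6), c(8, 6), c(13.8, 2.7))) {
    d0 <- dnu_dmu(nrn, wp[1], wp[2])
    # omega -> 0 equals the f-I slope
    expect_equal(Re(transfer_function(nrn, wp[1], wp[2], 0)), d0,
                 tolerance = 1e-12)
    H_small <- transfer_function(nrn, wp[1], wp[2], 2 * pi * 0.01)
    expect_equal(Mod(H_small), d0, tolerance = 1e-6)
    # low-pass: strong attenuation at 5 kHz
    H_hi <- transfer_function(nrn, wp[1], wp[2], 2 * pi * 5000)
    expect_lt(Mod(H_hi), 0.05 * d0)
  }
})

test_that("transfer function is conjugate-symmetric and smooth", {
  nrn <- std_neuron()
  om <- 2 * pi * seq(1, 500, by = 1)
  H <- transfer_function(nrn, 8, 6, om)
  Hm <- transfer_function(nrn, 8, 6, -om)
  expect_lt(max(Mod(Hm - Conj(H))), 1e-10)
  # no spikes or sign flips from the special-function evaluation
  expect_true(all(abs(diff(Mod(H))) < 0.05 * max(Mod(H))))
  expect_true(all(Mod(H) > 0))
})

test_that("anatomical matrix follows the indegree-weight product", {
  m <- micro()
  MA <- anatomical_matrix(m)
  expect_equal(MA, m$K * m$W)
  inh <- c(2, 4, 6, 8)
  expect_true(all(MA[, inh] <= 0))
  m0 <- m; m0$K[] <- 0
  expect_true(all(anatomical_matrix(m0) == 0))
})

test_that("effective connectivity reproduces the static gain of the rate map", {
  m <- make_net2()
  st <- solve_selfconsistent(m)
  grid <- frequency_grid(100, 10)
  eff <- effective_connectivity(m, st, grid = grid)
  h <- 1e-6
  for (i in 1:2) for (j in 1:2) {
    up <- working_point(m, st$rates + h * (seq_len(2) == j))
    dn <- working_point(m, st$rates - h * (seq_len(2) == j))
    nrn <- popspectra:::neuron_of(m, i)
    fd <- (siegert_rate(nrn, up$mu[i], up$sigma[i]) -
           siegert_rate(nrn, dn$mu[i], dn$sigma[i])) / (2 * h)
    expect_equal(Re(eff$Md[i, j, 1]), fd, tolerance = 1e-3)
    expect_equal(Im(eff$Md[i, j, 1]), 0, tolerance = 1e-9)
  }
  # mean-channel-only variant matches the mu-restricted gain instead
  eff_mu <- effective_connectivity(m, st, grid = grid,
                                   variance_channel = FALSE)
  for (i in 1:2) for (j in 1:2) {
    gain_mu <- m$neuron$tau_m[i] * m$K[i, j] * m$W[i, j] *
      dnu_dmu(popspectra:::neuron_of(m, i), st$working_point$mu[i],
              st$working_point$sigma[i])
    expect_equal(Re(eff_mu$Md[i, j, 1]), gain_mu, tolerance = 1e-10)
  }
})

test_that("effective connectivity respects structure and symmetry", {
  m <- make_net2()
  st <- solve_selfconsistent(m)
  grid <- frequency_grid(200, 20)
  # zero anatomy -> zero matrix at all frequencies
  m0 <- m; m0$K[] <- 0
  eff0 <- effective_connectivity(m0, st, grid = grid)
  expect_true(all(eff0$Md == 0))
  # existing inhibitory-source connections have negative real part at 0
  eff <- effective_connectivity(micro(), micro_state(), micro_tf(),
                                micro_grid())
  inh0 <- eff$Md[, c(2, 4, 6, 8), 1]
  K_inh <- micro()$K[, c(2, 4, 6, 8)]
  expect_true(all(Re(inh0[K_inh > 0]) < 0))
  # conjugate symmetry inherited from H and the delay filter
  st2 <- solve_selfconsistent(m)
  om <- 2 * pi * 77
  Mp <- popspectra:::.effconn_at(m, st2, om)
  Mm <- popspectra:::.effconn_at(m, st2, -om)
  expect_lt(max(Mod(Mm - Conj(Mp))), 1e-10)
  # grid mismatch is caught
  tf <- transfer_functions(m, st, grid)
  expect_error(effective_connectivity(m, st, tf, frequency_grid(300, 20)),
               "different frequency grid")
})
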