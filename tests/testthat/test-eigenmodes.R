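# per-frequency eigendecomposition, trajectory tracking, mode spectra

test_that("decomposition is bi-orthonormal and reconstructs Md", {
  decomp <- micro_modes()
  eff <- micro_eff()
  for (f in c(1, 65, 240)) {
    U <- decomp$u[, , f]; V <- decomp$v[, , f]
    expect_lt(max(Mod(V %*% U - diag(8))), 1e-8)
    rec <- U %*% diag(decomp$lambda[f, ]) %*% V
    expect_lt(max(Mod(rec - eff$Md[, , f])), 1e-8 * max(Mod(eff$Md[, , f])))
    # propagator eigen-relation P u = u / (1 - lambda)
    P <- solve(diag(8) - eff$Md[, , f])
    for (i in 1:8)
      expect_lt(max(Mod(P %*% decomp$u[, i, f] -
                        decomp$u[, i, f] / (1 - decomp$lambda[f, i]))), 1e-8)
  }
})

test_that("diagonal matrices decompose trivially", {
  d <- c(0.3 + 0.1i, -0.2 + 0i, 0.05 - 0.4i)
  eff <- structure(list(Md = array(diag(d), c(3, 3, 1)),
                        grid = frequency_grid(freqs = 0)),
                   class = "effective_connectivity")
  dec <- decompose_modes(eff)
  expect_equal(sort(Mod(dec$lambda[1, ])), sort(Mod(d)))
  # right eigenvectors are unit vectors (up to mode ordering and phase)
  U <- Mod(dec$u[, , 1])
  expect_equal(apply(U, 2, max), rep(1, 3), tolerance = 1e-12)
  expect_equal(colSums(U), rep(1, 3), tolerance = 1e-12)
})

test_that("trajectories are continuous and spiral towards zero", {
  decomp <- micro_modes()
  lam <- decomp$lambda
  # adjacent-frequency steps are small relative to the trajectory scale
  steps <- apply(lam, 2, function(x) max(Mod(diff(x))))
  expect_true(all(steps < 0.6))
  # all eight trajectories decay towards zero at high frequency
  expect_true(all(Mod(lam[nrow(lam), ]) < 0.3))
  expect_true(all(Mod(lam[nrow(lam), ]) < Mod(lam[1, ])))
})

test_that("mode tracking is stable under population permutation", {
  m <- make_net3(7)$model
  st <- solve_selfconsistent(m)
  grid <- frequency_grid(300, 5)
  lam1 <- decompose_modes(effective_connectivity(m, st, grid = grid))$lambda
  perm <- c(3, 1, 2)
  mp <- m
  mp$labels <- m$labels[perm]; mp$sizes <- m$sizes[perm]
  mp$K <- m$K[perm, perm]; mp$W <- m$W[perm, perm]
  mp$d_mean <- m$d_mean[perm, perm]; mp$d_std <- m$d_std[perm, perm]
  mp$K_ext <- m$K_ext[perm]; mp$neuron <- lapply(m$neuron, `[`, perm)
  mp$mu_ext_extra <- m$mu_ext_extra[perm]
  mp$var_ext_extra <- m$var_ext_extra[perm]
  stp <- solve_selfconsistent(mp)
  lam2 <- decompose_modes(effective_connectivity(mp, stp, grid = grid))$lambda
  # same multiset of trajectories up to mode relabeling: greedy pairing by
  # total trajectory distance
  D <- outer(1:3, 1:3, Vectorize(function(i, j)
    sum(Mod(lam1[, i] - lam2[, j]))))
  worst <- 0
  for (r in 1:3) {
    k <- arrayInd(which.min(D), dim(D))
    worst <- max(worst, D[k[1], k[2]] / nrow(lam1))
    D[k[1], ] <- Inf; D[, k[2]] <- Inf
  }
  expect_lt(worst, 1e-6)
})

test_that("eigenvalues are conjugate-symmetric in frequency", {
  m <- make_net2()
  st <- solve_selfconsistent(m)
  for (f in c(40, 130)) {
    lp <- eigen(popspectra:::.effconn_at(m, st, 2 * pi * f),
                only.values = TRUE)$values
    lm <- eigen(popspectra:::.effconn_at(m, st, -2 * pi * f),
                only.values = TRUE)$values
    # multiset of eigenvalues at -omega equals the conjugated multiset
    o1 <- order(Re(lp), Im(lp)); o2 <- order(Re(lm), -Im(lm))
    expect_lt(max(Mod(lp[o1] - Conj(lm[o2]))), 1e-10)
  }
})

test_that("p-factor and closest approach behave on canonical inputs", {
  expect_equal(p_factor(c(0 + 0i, 0.5 + 0i)), c(1, 2))
  expect_equal(p_factor(1 + 0i), Inf)
  freqs <- seq(0, 100, 1)
  ca <- closest_approach(rep(0 + 0i, length(freqs)), freqs)
  expect_equal(ca$distance, 1)
  expect_equal(ca$frequency, 0)
  # synthetic damped spiral: closest approach where it crosses Re-axis
  lam <- 1.3 * exp(-freqs / 150) * exp(-1i * 2 * pi * freqs / 120)
  ca2 <- closest_approach(lam, freqs)
  truef <- freqs[which.min(Mod(1 - lam))]
  expect_lt(abs(ca2$frequency - truef), 1)
  expect_equal(ca2$side, if (Re(lam[ca2$index]) < 1) "left" else "right")
})

test_that("single-mode approximation is exact for one population and
           the full mode-pair sum reproduces the spectrum", {
  # one population: only one mode, approximation is exact
  m1 <- make_net1()
  st1 <- solve_selfconsistent(m1)
  grid <- frequency_grid(300, 10)
  eff1 <- effective_connectivity(m1, st1, grid = grid)
  D1 <- noise_matrix(st1, m1$sizes)
  full <- power_spectra(eff1, D1)
  approx1 <- mode_spectrum_approx(decompose_modes(eff1), D1, 1)
  expect_equal(unname(approx1[, 1]), unname(full$C[, 1]), tolerance = 1e-10)
  # random 3-population circuit: completeness of the mode-pair expansion
  net <- make_net3(11)
  eff3 <- effective_connectivity(net$model, net$state, grid = grid)
  D3 <- noise_matrix(net$state, net$model$sizes)
  spec3 <- power_spectra(eff3, D3)
  dec3 <- decompose_modes(eff3)
  for (f in seq_along(grid$freqs)) {
    mp <- popspectra:::.mode_pair_spectrum(dec3, D3, f)
    expect_lt(max(abs(mp - spec3$C[f, ])), 1e-8 * max(spec3$C[f, ]))
  }
})

test_that("dominant low-gamma mode approximates the microcircuit spectrum
           near its peak", {
  decomp <- micro_modes()
  spec <- micro_spectra()
  D <- noise_matrix(micro_state(), micro()$sizes)
  pk <- popspectra:::.band_peak(spec, c(30, 90))
  mode <- which.max(p_factor(decomp$lambda[pk$index, ]))
  win <- c(pk$frequency - 6, pk$frequency + 6)
  ap <- mode_spectrum_approx(decomp, D, mode, win)
  sel <- which(spec$grid$freqs >= win[1] & spec$grid$freqs <= win[2])
  # populations with a pronounced peak are tracked within a factor ~2
  for (p in c(1, 3)) {
    rel <- ap[, p] / spec$C[sel, p]
    expect_true(all(rel > 0.3 & rel < 2))
  }
})
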