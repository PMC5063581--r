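# Fixture builders shared across the suite. All networks are built in code;
# the expensive microcircuit pipeline objects are computed once per test run
# and cached in this environment.

.cache <- new.env(parent = emptyenv())

# pins the bundled parameter table; update deliberately if the fixture is
# ever regenerated
fixture_md5 <- "7f7ac38b26beaba6786cbd58f313abf2"

# report every expectation; never abort the run on accumulated failures
options(testthat.progress.max_fails = 10000)

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

std_neuron <- function() {
  list(tau_m = 0.01, tau_s = 0.0005, tau_ref = 0.002,
       V_th = 15, V_reset = 0)
}

# single self-coupled population; inhibitory by default (delayed I-I loop)
make_net1 <- function(K = 60, W = -0.9, d = 1e-3, d_sd = 0,
                      K_ext = 1200, r_ext = 8) {
  network_model(labels = "I", sizes = 500,
                K = matrix(K, 1, 1), W = matrix(W, 1, 1),
                d_mean = matrix(d, 1, 1), d_std = matrix(d_sd, 1, 1),
                K_ext = K_ext, r_ext = r_ext, w_ext = 0.2,
                neuron = std_neuron())
}

# stable two-population E-I circuit used for the simulator oracle
make_net2 <- function() {
  network_model(
    labels = c("E", "I"), sizes = c(800, 200),
    K = matrix(c(80, 60, 100, 50), 2, byrow = TRUE),
    W = matrix(c(0.2, -0.9, 0.2, -0.9), 2, byrow = TRUE),
    d_mean = matrix(c(1.5, 0.8, 1.5, 0.8) * 1e-3, 2, byrow = TRUE),
    d_std = matrix(0.5e-3, 2, 2),
    K_ext = c(900, 700), r_ext = 8, w_ext = 0.2,
    neuron = std_neuron())
}

# random stable 3-population circuit (columns alternate E/I signs),
# constrained to the fluctuation-driven asynchronous-irregular regime the
# linear-response framework describes (subthreshold mean input, moderate
# rates); strongly mean-driven circuits fire near-periodically and violate
# the Poissonian output-noise model by construction
make_net3 <- function(seed) {
  set.seed(seed)
  repeat {
    K <- matrix(stats::runif(9, 20, 120), 3)
    sgn <- c(1, -4, 1)
    W <- matrix(rep(0.2 * sgn, each = 3), 3)
    m <- network_model(
      labels = c("E1", "I1", "E2"), sizes = c(600, 150, 400),
      K = K, W = W,
      d_mean = matrix(stats::runif(9, 0.5e-3, 2e-3), 3),
      d_std = matrix(0.4e-3, 3, 3),
      K_ext = c(900, 800, 850), r_ext = 8, w_ext = 0.2,
      neuron = std_neuron())
    st <- solve_selfconsistent(m)
    if (!st$converged) next
    if (any(st$rates < 0.5) || any(st$rates > 25)) next
    if (any(st$working_point$mu > 0.85 * 15)) next
    ok <- tryCatch({
      grid <- frequency_grid(400, 4)
      eff <- effective_connectivity(m, st, grid = grid)
      stable <- TRUE
      for (f in seq_along(grid$freqs)) {
        lam <- eigen(eff$Md[, , f], only.values = TRUE)$values
        if (any(Re(lam) >= 0.95 & abs(Im(lam)) < 0.1)) stable <- FALSE
      }
      stable
    }, error = function(e) FALSE)
    if (ok) return(list(model = m, state = st))
  }
}

# random complex matrix with spectral radius below `rho`
random_contraction <- function(n, seed, rho = 0.8) {
  set.seed(seed)
  A <- matrix(complex(real = stats::rnorm(n^2), imaginary = stats::rnorm(n^2)),
              n) / sqrt(n)
  A * rho / max(Mod(eigen(A, only.values = TRUE)$values))
}

micro <- function() cached("micro", microcircuit())

micro_state <- function() cached("micro_state",
  solve_selfconsistent(micro()))

micro_grid <- function() cached("micro_grid", frequency_grid(500, 1))

micro_tf <- function() cached("micro_tf",
  transfer_functions(micro(), micro_state(), micro_grid()))

micro_eff <- function() cached("micro_eff",
  effective_connectivity(micro(), micro_state(), micro_tf(), micro_grid()))

micro_spectra <- function() cached("micro_spectra",
  power_spectra(micro_eff(), noise_matrix(micro_state(), micro()$sizes)))

micro_modes <- function() cached("micro_modes",
  decompose_modes(micro_eff()))

# independent Simpson-rule quadrature of the first-passage integrand,
# used as the oracle for siegert_rate (valid for |bounds| <~ 15)
siegert_quad_oracle <- function(neuron, mu, sigma, n_grid = 40001) {
  sh <- sqrt(2) * 1.4603545088095868 / 2 * sqrt(neuron$tau_s / neuron$tau_m)
  y_th <- (neuron$V_th - mu) / sigma + sh
  y_r <- (neuron$V_reset - mu) / sigma + sh
  u <- seq(y_r, y_th, length.out = n_grid)
  f <- exp(u^2) * 2 * pnorm(u * sqrt(2))   # e^{u^2} erfc(-u), tail-safe
  h <- (y_th - y_r) / (n_grid - 1)
  w <- rep(c(4, 2), length.out = n_grid - 2)
  I <- h / 3 * (f[1] + sum(w * f[2:(n_grid - 1)]) + f[n_grid])
  1 / (neuron$tau_ref + neuron$tau_m * sqrt(pi) * I)
}
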