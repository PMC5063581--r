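# Stochastic simulation of the delayed linear rate model with output
# noise: the numerical oracle against which the analytic spectra are
# validated at desk scale.

# per-connection impulse-response kernels on the simulation time grid,
# obtained by inverse FFT of H_i(omega) * delay_filter_ij(omega)
.connection_kernels <- function(m, state, dt, delay_mode = "averaged",
                                n_draws = 100, trunc_rel = 1e-6,
                                variance_channel = TRUE) {
  n <- n_pop(m)
  MA <- m$K * .effective_weights(m, state, variance_channel)
  nk <- 2^14                      # kernel FFT length
  freqs <- seq(0, nk / 2, by = 1) / (nk * dt)   # one-sided
  om <- 2 * pi * freqs
  conn <- which(MA != 0, arr.ind = TRUE)
  kern <- list(); ki <- integer(0); kj <- integer(0)
  H_by_pop <- lapply(seq_len(n), function(i)
    transfer_function(neuron_of(m, i), state$working_point$mu[i],
                      state$working_point$sigma[i], om))
  trunc_err <- 0
  for (r in seq_len(nrow(conn))) {
    i <- conn[r, 1]; j <- conn[r, 2]
    if (delay_mode == "averaged") {
      B <- delay_factor(m$d_mean[i, j], m$d_std[i, j], om)
    } else {                       # Monte-Carlo draws from the delay law
      d <- .rtrunc_gauss(n_draws, m$d_mean[i, j], m$d_std[i, j])
      B <- rowMeans(vapply(d, function(dd) exp(-1i * om * dd),
                           complex(length(om))))
    }
    G <- m$neuron$tau_m[i] * H_by_pop[[i]] * B
    # advance by one sample so that tap m, applied at lag (m+1) dt by the
    # integrator, carries the kernel value at exactly that lag
    G <- G * exp(1i * om * dt)
    # hermitian two-sided spectrum -> real kernel, density scaling 1/(nk dt)
    G2 <- c(G, Conj(G[(nk / 2):2]))
    g <- Re(fft(G2, inverse = TRUE)) / (nk * dt)
    keep <- which(abs(g) >= trunc_rel * max(abs(g)))
    n_taps <- min(max(keep), nk %/% 2)
    if (n_taps < nk %/% 2)
      trunc_err <- max(trunc_err,
                       sum(abs(g[(n_taps + 1):(nk %/% 2)])) /
                         max(sum(abs(g[1:n_taps])), .Machine$double.eps))
    kern[[r]] <- g[1:n_taps] * MA[i, j]
    ki[r] <- i; kj[r] <- j
  }
  if (length(kern) == 0)
    return(list(kern = matrix(0, 1, 0), conn_i = integer(0),
                conn_j = integer(0), truncation_error = 0))
  n_taps <- max(lengths(kern))
  K <- matrix(0, n_taps, length(kern))
  for (r in seq_along(kern)) K[seq_along(kern[[r]]), r] <- kern[[r]]
  list(kern = K, conn_i = ki - 1L, conn_j = kj - 1L,
       truncation_error = trunc_err)
}

.rtrunc_gauss <- function(n, mean, sd) {
  if (sd < 1e-15) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

#' Simulate the delayed linear rate model
#'
#' Euler integration of the fluctuating population rates
#' \eqn{y(t) = r(t) + x(t)}, where \eqn{r_i(t)} is the convolution of the
#' past activity of all presynaptic populations with the connection
#' kernels (transfer function times delay kernel times anatomical weight)
#' and \eqn{x_i} is white noise of spectral density \eqn{\bar r_i/M_i}.
#' By default the delay-distribution averaged kernel is used, so the
#' simulated system is exactly the one whose spectra
#' \code{\link{power_spectra}} predicts; \code{delay_mode = "draw"}
#' instead averages kernels over random delay draws (realism check).
#'
#' @param m a \code{network_model} (must be linearly stable).
#' @param state converged \code{stationary_state}.
#' @param duration simulated time (s).
#' @param dt time step (s); must resolve the synaptic kernel
#'   (\code{dt <= tau_s / 5}).
#' @param seed RNG seed (integer) for reproducibility.
#' @param delay_mode "averaged" (default) or "draw".
#' @param check_stability refuse to simulate a circuit with a linearly
#'   unstable mode (default TRUE).
#' @param burn_in initial stretch (s) discarded from the returned trace.
#' @return object of class \code{rate_trace}: matrix \code{y}
#'   (time x populations, spikes/s fluctuations around the stationary
#'   rate), \code{dt}, \code{duration}, \code{seed},
#'   \code{truncation_error}.
#' @export
simulate_rates <- function(m, state, duration, dt = 1e-4, seed = 1,
                           delay_mode = c("averaged", "draw"),
                           check_stability = TRUE, burn_in = 1,
                           variance_channel = TRUE) {
  delay_mode <- match.arg(delay_mode)
  if (dt > min(m$neuron$tau_s) / 5 + 1e-15)
    stop("dt must be at most tau_s / 5 to resolve the synaptic kernel")
  if (check_stability) {
    grid <- frequency_grid(f_max = 500, df = 2)
    eff <- effective_connectivity(m, state, grid = grid,
                                  variance_channel = variance_channel)
    for (f in seq_along(grid$freqs)) {
      lam <- eigen(eff$Md[, , f], only.values = TRUE)$values
      if (any(Re(lam) >= 1 & abs(Im(lam)) < 0.05))
        stop("circuit has a linearly unstable mode near ",
             grid$freqs[f], " Hz; see find_critical_frequency()")
    }
  }
  set.seed(seed)
  kk <- .connection_kernels(m, state, dt, delay_mode,
                            variance_channel = variance_channel)
  D <- diag(noise_matrix(state, m$sizes))
  n_steps <- round((duration + burn_in) / dt)
  y <- cpp_simulate_rates(kk$kern, kk$conn_i, kk$conn_j, n_pop(m),
                          sqrt(D / dt), dt, n_steps)
  drop <- round(burn_in / dt)
  y <- y[(drop + 1):n_steps, , drop = FALSE]
  colnames(y) <- m$labels
  structure(list(y = y, dt = dt, duration = nrow(y) * dt, seed = seed,
                 truncation_error = kk$truncation_error),
            class = "rate_trace")
}

#' Welch periodogram of a rate trace
#'
#' Averaged periodogram over non-overlapping windows, in the same
#' (two-sided density) normalization as the analytic spectra: a white
#' trace of variance \eqn{D/dt} has flat density \eqn{D}.
#'
#' @param trace a \code{rate_trace} (or a numeric matrix with attribute
#'   dt).
#' @param window window length (s), default 0.5.
#' @return list of class \code{periodogram}: \code{freqs} (Hz),
#'   \code{power} (freq x populations), \code{se} (standard error over
#'   windows), \code{n_windows}.
#' @export
periodogram <- function(trace, window = 0.5) {
  y <- trace$y; dt <- trace$dt
  n_seg <- floor(window / dt)
  n_win <- floor(nrow(y) / n_seg)
  if (n_win < 2) stop("trace must contain at least two windows")
  n_keep <- n_seg %/% 2 + 1
  freqs <- (seq_len(n_keep) - 1) / (n_seg * dt)
  n_popn <- ncol(y)
  acc <- array(0, c(n_keep, n_popn, n_win))
  for (w in seq_len(n_win)) {
    seg <- y[((w - 1) * n_seg + 1):(w * n_seg), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    for (p in seq_len(n_popn)) {
      sp <- Mod(fft(seg[, p]))^2 * dt / n_seg
      acc[, p, w] <- sp[seq_len(n_keep)]
    }
  }
  pow <- apply(acc, c(1, 2), mean)
  se <- apply(acc, c(1, 2), sd) / sqrt(n_win)
  colnames(pow) <- colnames(se) <- colnames(y)
  structure(list(freqs = freqs, power = pow, se = se, n_windows = n_win),
            class = "periodogram")
}
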