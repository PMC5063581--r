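# Linear response: population transfer functions, delay-distribution
# filtering, and the frequency-resolved effective connectivity matrix.

#' Frequency grid
#'
#' Strictly increasing frequency axis shared by all frequency-resolved
#' objects. Always contains 0.
#'
#' @param f_max upper frequency (Hz).
#' @param df step (Hz).
#' @param freqs explicit frequencies; overrides \code{f_max}/\code{df}.
#' @return object of class \code{frequency_grid} with fields \code{freqs}
#'   (Hz) and \code{omega} (rad/s).
#' @export
frequency_grid <- function(f_max = 500, df = 1, freqs = NULL) {
  if (is.null(freqs)) freqs <- seq(0, f_max, by = df)
  freqs <- sort(unique(c(0, freqs)))
  if (any(diff(freqs) <= 0)) stop("frequencies must be strictly increasing")
  structure(list(freqs = freqs, omega = 2 * pi * freqs),
            class = "frequency_grid")
}

# complex error function by Maclaurin series; converges to near machine
# precision for |z| <= ~3.7 (beyond that the continued fraction below is
# used instead)
.erf_series <- function(z) {
  term <- z
  acc <- z
  z2 <- z^2
  for (n in 1:80) {
    term <- term * (-z2) / n
    acc <- acc + term / (2 * n + 1)
  }
  2 / sqrt(pi) * acc
}

# complex scaled complementary error function erfcx(z) = exp(z^2) erfc(z).
# Series route for moderate |z|; Laplace continued fraction for large |z|
# in the right half plane; reflection otherwise.
erfcx_complex <- function(z) {
  out <- complex(length.out = length(z))
  refl <- Re(z) < 0
  zz <- ifelse(refl, -z, z)
  # series route only while 1 - erf(z) retains enough leading digits;
  # beyond that the Laplace continued fraction is accurate
  small <- Mod(zz) < 3.7
  if (any(small))
    out[small] <- exp(zz[small]^2) * (1 - .erf_series(zz[small]))
  if (any(!small)) {
    zb <- zz[!small]
    cf <- complex(length.out = length(zb))   # Laplace continued fraction
    for (k in 60:1) cf <- (k / 2) / (zb + cf)
    out[!small] <- 1 / sqrt(pi) / (zb + cf)
  }
  ifelse(refl, 2 * exp(z^2) - out, out)
}

#' Delay-distribution filter
#'
#' Characteristic function \eqn{E[e^{-i\omega y}]} of the synaptic delay
#' distribution, a Gaussian with mean \code{d} and standard deviation
#' \code{sigma_d} truncated to positive delays. Evaluated through the
#' scaled complementary error function so the Gaussian tail term and the
#' \eqn{e^{-\sigma_d^2\omega^2/2}} envelope cancel analytically (no
#' overflow at large \eqn{\omega\sigma_d}). Entire in \eqn{\omega}, so it
#' can be evaluated at complex frequency for the Laplace-domain stability
#' analysis.
#'
#' @param d mean delay (s), non-negative.
#' @param sigma_d delay standard deviation (s); 0 gives the point-mass
#'   limit \eqn{e^{-i\omega d}}.
#' @param omega angular frequency (rad/s), real or complex, vectorised.
#' @return complex vector.
#' @export
delay_factor <- function(d, sigma_d, omega) {
  stopifnot(d >= 0, sigma_d >= 0)
  if (sigma_d < 1e-15) return(exp(-1i * omega * d))
  # mass below zero is negligible beyond 8 sd: plain Gaussian form
  if (d / sigma_d > 8)
    return(exp(-1i * omega * d - sigma_d^2 * omega^2 / 2))
  zc <- (-d / sigma_d + 1i * omega * sigma_d) / sqrt(2)
  denom <- 2 * pnorm(d / sigma_d)   # erfc(-d/(sigma sqrt(2)))
  erfcx_complex(zc) * exp(-d^2 / (2 * sigma_d^2)) / denom
}

# Phi(a, x) = exp(x^2/4) U(a, -x) and its order-recurrence derivative,
# thin wrappers over the C++ kernel (complex order a, real x)
.phi_pcf <- function(a, x) {
  k <- max(length(a), length(x))
  cpp_pcf_phi(rep_len(as.complex(a), k), rep_len(as.numeric(x), k))
}
.dphi_pcf <- function(a, x) (0.5 + a) * .phi_pcf(a + 1, x)

#' Linear transfer function of a LIF population
#'
#' Complex rate response \eqn{H(\omega)} (spikes/s per mV of mean-input
#' modulation) of a population of LIF neurons with exponentially decaying
#' synaptic currents at working point (\code{mu}, \code{sigma}); the
#' colored-noise effect enters through the same boundary shift as in
#' \code{\link{siegert_rate}}. The response is the parabolic-cylinder
#' ratio form of the Fokker-Planck linear response,
#' multiplied by the synaptic low-pass \eqn{1/(1+i\omega\tau_s)} when
#' \code{synaptic_filter = TRUE} (default), so that \eqn{H} is the filter
#' applied to incoming rate fluctuations.
#'
#' At \eqn{\omega = 0} the analytic slope \code{\link{dnu_dmu}} is used
#' (the ratio form is a removable 0/0 there). Above
#' \eqn{|\omega\tau_m| = 60} the high-frequency \eqn{1/\sqrt{i\omega\tau_m}}
#' asymptotic is used, matched continuously to the exact form at the
#' switch point.
#'
#' @param neuron scalar neuron parameter list (see
#'   \code{\link{siegert_rate}}).
#' @param mu,sigma working point (mV).
#' @param omega angular frequencies (rad/s); real or complex. Real parts
#'   should be non-negative (use conjugate symmetry for negative
#'   frequencies).
#' @param synaptic_filter include the synaptic low-pass (default TRUE).
#' @return complex vector of \eqn{H(\omega)}.
#' @export
transfer_function <- function(neuron, mu, sigma, omega,
                              synaptic_filter = TRUE) {
  tau_m <- neuron$tau_m; tau_s <- neuron$tau_s
  nu <- siegert_rate(neuron, mu, sigma)
  b <- .siegert_bounds(tau_m, tau_s, neuron$V_th, neuron$V_reset, mu, sigma)
  x_t <- sqrt(2) * b$y_th; x_r <- sqrt(2) * b$y_r
  H_exact <- function(om) {   # om complex or real, nonzero
    z <- -0.5 + 1i * om * tau_m
    frac <- (.dphi_pcf(z, x_t) - .dphi_pcf(z, x_r)) /
            (.phi_pcf(z, x_t) - .phi_pcf(z, x_r))
    sqrt(2) / sigma * nu / (1 + 1i * om * tau_m) * frac
  }
  om_switch <- 60 / tau_m
  H_asym_raw <- function(om) sqrt(2) * nu / (sigma * sqrt(1i * om * tau_m))
  out <- complex(length.out = length(omega))
  zero <- omega == 0
  mid <- !zero & Mod(omega) <= om_switch
  if (any(mid)) out[mid] <- H_exact(omega[mid])
  hi <- !zero & Mod(omega) > om_switch
  if (any(hi)) {              # continuous match at the switch point
    cal <- H_exact(om_switch) / H_asym_raw(om_switch)
    out[hi] <- cal * H_asym_raw(omega[hi])
  }
  if (synaptic_filter) out <- out / (1 + 1i * omega * tau_s)
  # refractory compression of the response: the ratio form above describes
  # the non-refractory density flux; scaling by (1 - nu * tau_ref) makes
  # the omega -> 0 limit equal d(siegert_rate)/d(mu) exactly
  out <- out * (1 - nu * neuron$tau_ref)
  if (any(zero)) out[zero] <- dnu_dmu(neuron, mu, sigma)
  if (!all(is.finite(Re(out)) & is.finite(Im(out)))) {
    bad <- which(!(is.finite(Re(out)) & is.finite(Im(out))))[1]
    stop("transfer function evaluation failed at omega = ", omega[bad])
  }
  out
}

#' Transfer functions of all populations on a grid
#'
#' @param m a \code{network_model}.
#' @param state a \code{stationary_state} (converged).
#' @param grid a \code{frequency_grid}.
#' @param synaptic_filter see \code{\link{transfer_function}}.
#' @return object of class \code{transfer_functions}: complex matrix
#'   \code{H} (frequencies x populations) plus the grid.
#' @export
transfer_functions <- function(m, state, grid, synaptic_filter = TRUE) {
  H <- vapply(seq_len(n_pop(m)), function(i)
    transfer_function(neuron_of(m, i), state$working_point$mu[i],
                      state$working_point$sigma[i], grid$omega,
                      synaptic_filter = synaptic_filter),
    complex(length(grid$omega)))
  structure(list(H = H, grid = grid), class = "transfer_functions")
}

#' Anatomical connectivity matrix
#'
#' Elementwise product of indegrees and synaptic weights (mV); columns of
#' inhibitory sources are non-positive.
#'
#' @param m a \code{network_model}.
#' @return real N x N matrix.
#' @export
anatomical_matrix <- function(m) m$K * m$W

# effective synaptic weight per connection: mean channel W plus, when the
# variance channel is on, the noise-transmission admixture W^2 * rho_i
# with rho_i = (dnu/dsigma^2) / (dnu/dmu) of the receiving population.
# With this weight the omega = 0 effective connectivity equals the full
# static gain of the stationary rate map.
.effective_weights <- function(m, state, variance_channel = TRUE) {
  if (!variance_channel) return(m$W)
  wp <- state$working_point
  rho <- vapply(seq_len(n_pop(m)), function(i) {
    nrn <- neuron_of(m, i)
    dmu <- dnu_dmu(nrn, wp$mu[i], wp$sigma[i])
    if (dmu < 1e-12) return(0)          # silent population: no response
    dnu_dsigma2(nrn, wp$mu[i], wp$sigma[i]) / dmu
  }, numeric(1))
  m$W + m$W^2 * rho
}

#' Effective connectivity matrix over frequency
#'
#' The dimensionless frequency-resolved connectivity
#' \deqn{\tilde M_{d,ij}(\omega) = \tau_{m,i} H_i(\omega) K_{ij}
#'   W^{eff}_{ij} B_{ij}(\omega)}
#' where \eqn{H_i} is the transfer function of the *receiving* population
#' and \eqn{B_{ij}} the delay-distribution filter of the connection.
#'
#' By default (\code{variance_channel = TRUE}) the effective weight
#' \eqn{W^{eff}_{ij} = W_{ij} + W_{ij}^2\,
#' (\partial\nu_i/\partial\sigma^2)/(\partial\nu_i/\partial\mu)}
#' includes the noise-transmission channel: a presynaptic rate increment
#' raises both the mean and the variance of the input, and for inhibitory
#' sources the two channels act in opposite directions. With this choice
#' every entry at \eqn{\omega = 0} equals the full static gain
#' \eqn{K_{ij}\,\partial\bar r_i/\partial r_j} of the stationary rate map.
#' \code{variance_channel = FALSE} gives the classical mean-channel-only
#' form \eqn{\tau_m K_{ij} W_{ij} H_i(\omega)}. The variance channel is
#' given the same normalised frequency profile as the mean channel
#' (quasi-static approximation, see the methods vignette).
#'
#' @param m a \code{network_model}.
#' @param state a converged \code{stationary_state}.
#' @param tf optional precomputed \code{transfer_functions} on \code{grid}.
#' @param grid a \code{frequency_grid}.
#' @param variance_channel include the noise-transmission channel
#'   (default TRUE).
#' @return object of class \code{effective_connectivity}: complex array
#'   \code{Md} (N x N x n_freq), the grid, and references to model and
#'   state.
#' @export
effective_connectivity <- function(m, state, tf = NULL,
                                   grid = frequency_grid(),
                                   variance_channel = TRUE) {
  if (is.null(tf)) tf <- transfer_functions(m, state, grid)
  if (!isTRUE(all.equal(tf$grid$freqs, grid$freqs)))
    stop("transfer functions were computed on a different frequency grid")
  n <- n_pop(m); nf <- length(grid$freqs)
  MA <- m$K * .effective_weights(m, state, variance_channel)
  Md <- array(0i, c(n, n, nf))
  for (i in seq_len(n)) {
    pre <- m$neuron$tau_m[i] * tf$H[, i]          # receiving population
    for (j in seq_len(n)) {
      if (MA[i, j] == 0) next
      Md[i, j, ] <- pre * MA[i, j] *
        delay_factor(m$d_mean[i, j], m$d_std[i, j], grid$omega)
    }
  }
  structure(list(Md = Md, grid = grid, model = m, state = state,
                 variance_channel = variance_channel),
            class = "effective_connectivity")
}

# effective connectivity at a single (possibly complex) frequency
.effconn_at <- function(m, state, omega, variance_channel = TRUE) {
  n <- n_pop(m)
  MA <- m$K * .effective_weights(m, state, variance_channel)
  M <- matrix(0i, n, n)
  for (i in seq_len(n)) {
    Hi <- transfer_function(neuron_of(m, i), state$working_point$mu[i],
                            state$working_point$sigma[i], omega)
    for (j in seq_len(n)) {
      if (MA[i, j] == 0) next
      M[i, j] <- m$neuron$tau_m[i] * Hi * MA[i, j] *
        delay_factor(m$d_mean[i, j], m$d_std[i, j], omega)
    }
  }
  M
}
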