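# Stationary mean-field theory: working point (diffusion approximation)
# and self-consistent population firing rates.

# boundary shift accounting for colored (exponentially filtered) synaptic
# noise: thresholds move by sigma * (alpha/2) * sqrt(tau_s/tau_m) with
# alpha = sqrt(2) |zeta(1/2)|
.ALPHA_SHIFT <- sqrt(2) * 1.4603545088095868128

#' Working point of every population
#'
#' Mean and standard deviation of the synaptic input (diffusion
#' approximation) given a vector of presynaptic population rates:
#' \deqn{\mu_i = \tau_m (\sum_j K_{ij} W_{ij} r_j + K_{ext,i} w_{ext} r_{ext}) + \mu^{extra}_i}
#' \deqn{\sigma_i^2 = \tau_m (\sum_j K_{ij} W_{ij}^2 r_j + K_{ext,i} w_{ext}^2 r_{ext}) + v^{extra}_i}
#'
#' @param m a \code{network_model}.
#' @param rates per-population firing rates (spikes/s), all non-negative.
#' @return list with numeric vectors \code{mu} (mV) and \code{sigma} (mV).
#' @export
working_point <- function(m, rates) {
  if (any(rates < 0)) stop("rates must be non-negative")
  tau_m <- m$neuron$tau_m
  mu <- tau_m * (as.numeric((m$K * m$W) %*% rates) +
                 m$K_ext * m$w_ext * m$r_ext) + m$mu_ext_extra
  var <- tau_m * (as.numeric((m$K * m$W^2) %*% rates) +
                  m$K_ext * m$w_ext^2 * m$r_ext) + m$var_ext_extra
  list(mu = mu, sigma = sqrt(pmax(var, 0)))
}

# scaled complementary error function for real x (any sign)
erfcx_real <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  if (any(big)) {            # asymptotic series, avoids 0 * Inf
    xi <- x[big]
    out[big] <- (1 - 0.5 / xi^2 + 0.75 / xi^4) / (xi * sqrt(pi))
  }
  if (any(!big)) out[!big] <- exp(x[!big]^2) * 2 * pnorm(-sqrt(2) * x[!big])
  out
}

# integrand e^{u^2} (1 + erf(u)) = e^{u^2} erfc(-u), evaluated stably
.siegert_integrand <- function(u) {
  f <- numeric(length(u))
  neg <- u <= 0
  f[neg] <- erfcx_real(-u[neg])
  if (any(!neg)) f[!neg] <- 2 * exp(u[!neg]^2) - erfcx_real(u[!neg])
  f
}

# effective (shifted) integration bounds for a given working point
.siegert_bounds <- function(tau_m, tau_s, V_th, V_reset, mu, sigma) {
  sh <- .ALPHA_SHIFT / 2 * sqrt(tau_s / tau_m)
  list(y_th = (V_th - mu) / sigma + sh, y_r = (V_reset - mu) / sigma + sh)
}

#' Stationary firing rate of a LIF neuron under Gaussian input
#'
#' First-passage-time rate of a leaky integrate-and-fire neuron with
#' exponentially decaying synaptic currents driven by input of mean
#' \code{mu} and standard deviation \code{sigma}. The synaptic filtering
#' enters through a shift of threshold and reset by
#' \eqn{\sigma (\alpha/2) \sqrt{\tau_s/\tau_m}} with
#' \eqn{\alpha = \sqrt{2}\,|\zeta(1/2)|}, applied inside the white-noise
#' first-passage integral. The integrand is evaluated through the scaled
#' complementary error function; for strongly subthreshold input (shifted
#' threshold more than 25 noise units above \code{mu}) the closed-form
#' asymptotic of the first-passage integral is used instead of quadrature.
#'
#' @param neuron list with scalar \code{tau_m}, \code{tau_s},
#'   \code{tau_ref} (s), \code{V_th}, \code{V_reset} (mV).
#' @param mu mean input (mV), scalar or vector.
#' @param sigma input standard deviation (mV), positive.
#' @return firing rate(s) in spikes/s; always below \code{1/tau_ref}.
#' @export
siegert_rate <- function(neuron, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  k <- max(length(mu), length(sigma))
  mu <- rep_len(mu, k); sigma <- rep_len(sigma, k)
  vapply(seq_len(k), function(i) {
    b <- .siegert_bounds(neuron$tau_m, neuron$tau_s, neuron$V_th,
                         neuron$V_reset, mu[i], sigma[i])
    if (b$y_th > 25) {       # deeply subthreshold: Kramers-type asymptotic
      return(b$y_th * exp(-b$y_th^2) / (neuron$tau_m * sqrt(pi)))
    }
    I <- integrate(.siegert_integrand, b$y_r, b$y_th,
                   rel.tol = 1e-12, abs.tol = 1e-300)$value
    1 / (neuron$tau_ref + neuron$tau_m * sqrt(pi) * I)
  }, numeric(1))
}

#' Derivative of the stationary rate with respect to the mean input
#'
#' Analytic slope of the f-I curve at the working point; equals the
#' zero-frequency limit of the linear transfer function.
#'
#' @inheritParams siegert_rate
#' @return d(rate)/d(mu) in (spikes/s)/mV.
#' @export
dnu_dmu <- function(neuron, mu, sigma) {
  nu <- siegert_rate(neuron, mu, sigma)
  b <- .siegert_bounds(neuron$tau_m, neuron$tau_s, neuron$V_th,
                       neuron$V_reset, mu, sigma)
  nu^2 * neuron$tau_m * sqrt(pi) / sigma *
    (.siegert_integrand(b$y_th) - .siegert_integrand(b$y_r))
}

#' Derivative of the stationary rate with respect to the input variance
#'
#' Analytic sensitivity of the firing rate to the variance of the synaptic
#' input at fixed mean; the static strength of the variance (noise)
#' transmission channel.
#'
#' @inheritParams siegert_rate
#' @return d(rate)/d(sigma^2) in (spikes/s)/mV^2.
#' @export
dnu_dsigma2 <- function(neuron, mu, sigma) {
  nu <- siegert_rate(neuron, mu, sigma)
  b <- .siegert_bounds(neuron$tau_m, neuron$tau_s, neuron$V_th,
                       neuron$V_reset, mu, sigma)
  # d y / d sigma = -(V - mu)/sigma^2 (the colored-noise shift term is
  # independent of sigma in these units)
  dy_th <- -(neuron$V_th - mu) / sigma^2
  dy_r <- -(neuron$V_reset - mu) / sigma^2
  dnu_dsigma <- -nu^2 * neuron$tau_m * sqrt(pi) *
    (.siegert_integrand(b$y_th) * dy_th - .siegert_integrand(b$y_r) * dy_r)
  dnu_dsigma / (2 * sigma)
}

# neuron parameter list for population i
neuron_of <- function(m, i) lapply(m$neuron, `[`, i)

# rates of all populations at given input rates
.rate_map <- function(m, rates) {
  wp <- working_point(m, rates)
  vapply(seq_len(n_pop(m)), function(i)
    siegert_rate(neuron_of(m, i), wp$mu[i], wp$sigma[i]), numeric(1))
}

#' Self-consistent stationary state of the network
#'
#' Solves the fixed-point equation \eqn{\bar r_i = \nu_i(\mu(\bar r),
#' \sigma(\bar r))} by damped fixed-point iteration (pseudo-time
#' integration), which follows the basin of attraction of the network's
#' operative state rather than jumping across it.
#'
#' @param m a \code{network_model}.
#' @param init initial rate vector; defaults to the rates produced by the
#'   external drive alone.
#' @param tol convergence tolerance on the maximum self-consistency
#'   residual (spikes/s).
#' @param max_iter iteration budget.
#' @param damping initial pseudo-time step in (0, 1]; halved whenever the
#'   residual grows (down to 0.02) and cautiously re-grown after sustained
#'   decrease, so stiff circuits converge without oscillation.
#' @return list of class \code{stationary_state}: \code{rates},
#'   \code{working_point} (list mu, sigma), \code{converged},
#'   \code{residual}, \code{iterations}.
#' @export
solve_selfconsistent <- function(m, init = NULL, tol = 1e-12,
                                 max_iter = 1e5, damping = 0.3) {
  n <- n_pop(m)
  r <- if (is.null(init)) .rate_map(m, numeric(n)) else rep_len(init, n)
  resid <- Inf; it <- 0L; streak <- 0L
  h <- damping
  while (it < max_iter) {
    it <- it + 1L
    nu <- .rate_map(m, r)
    res_new <- max(abs(nu - r))
    if (res_new < tol) { r <- nu; resid <- res_new; break }
    if (res_new > resid) {           # overshoot: damp harder
      h <- max(h / 2, 0.02); streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= 25L) { h <- min(h * 1.3, 1); streak <- 0L }
    }
    resid <- res_new
    r <- r + h * (nu - r)
  }
  structure(list(rates = r, working_point = working_point(m, r),
                 converged = resid < tol, residual = resid,
                 iterations = it),
            class = "stationary_state")
}

#' @export
print.stationary_state <- function(x, ...) {
  cat(sprintf("<stationary_state> %s (residual %.2e, %d iterations)\n",
              if (x$converged) "converged" else "NOT converged",
              x$residual, x$iterations))
  print(data.frame(mu_mV = x$working_point$mu,
                   sigma_mV = x$working_point$sigma,
                   rate_hz = x$rates))
  invisible(x)
}
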