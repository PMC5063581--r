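# Laplace-domain stability of the dynamical modes: complex critical
# frequencies where an eigenvalue trajectory equals one, and detection of
# the oscillatory (Hopf) stability boundary under indegree perturbations.

# eigenvalue of the effective connectivity at complex omega, selected by
# continuity with a reference eigenvalue/eigenvector
.lambda_at <- function(m, state, omega, lambda_ref) {
  M <- .effconn_at(m, state, omega)
  lam <- eigen(M, only.values = TRUE)$values
  lam[which.min(Mod(lam - lambda_ref))]
}

#' Complex critical frequency of a mode
#'
#' Solves \eqn{\lambda_{mode}(\omega') = 1} for complex \eqn{\omega'} by
#' damped Newton iteration (the eigenvalue is analytic in \eqn{\omega}, so
#' a single complex derivative, taken by central differences, suffices).
#' The transfer function and delay filter are evaluated directly at
#' complex frequency (both are analytic continuations of their real-axis
#' forms). The iteration starts from the mode's real-axis closest approach
#' to one; the mode is stable if \eqn{\Im(\omega') > 0} (perturbations
#' decay at rate \eqn{\Im(\omega')} per second while oscillating at
#' \eqn{\Re(\omega')/2\pi} Hz) and linearly unstable if
#' \eqn{\Im(\omega') < 0}.
#'
#' @param m a \code{network_model}.
#' @param state a converged \code{stationary_state}.
#' @param decomp a \code{mode_decomposition} on a real frequency grid.
#' @param mode mode index.
#' @param band optional band (Hz) restricting the starting closest
#'   approach.
#' @param tol residual tolerance on \eqn{|\lambda-1|}.
#' @param max_iter Newton iteration budget.
#' @return object of class \code{critical_point}: \code{mode},
#'   \code{omega_prime} (complex rad/s), \code{frequency}
#'   (\eqn{\Re\omega'/2\pi}, Hz), \code{decay_rate} (\eqn{\Im\omega'},
#'   1/s), \code{stable}, \code{residual}, \code{converged}.
#' @export
find_critical_frequency <- function(m, state, decomp, mode, band = NULL,
                                    tol = 1e-8, max_iter = 100) {
  ca <- closest_approach(decomp$lambda[, mode], decomp$grid$freqs, band)
  starts <- 2 * pi * ca$frequency * c(1, 0.97, 1.03) + 0i
  best <- NULL
  for (om0 in starts) {
    om <- om0
    lam_ref <- ca$lambda
    resid <- Inf
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      lam <- .lambda_at(m, state, om, lam_ref)
      lam_ref <- lam
      resid <- Mod(lam - 1)
      if (resid < tol) { ok <- TRUE; break }
      h <- 1e-6 * max(Mod(om), 1)
      dlam <- (.lambda_at(m, state, om + h, lam_ref) -
               .lambda_at(m, state, om - h, lam_ref)) / (2 * h)
      if (Mod(dlam) == 0) break
      step <- (lam - 1) / dlam
      # damp: never jump more than a quarter of the current frequency scale
      smax <- 0.25 * max(Mod(om), 2 * pi * 10)
      if (Mod(step) > smax) step <- step * smax / Mod(step)
      om <- om - step
    }
    cand <- list(omega_prime = om, residual = resid, converged = ok)
    if (is.null(best) || cand$residual < best$residual) best <- cand
    if (ok) break
  }
  structure(list(mode = mode, omega_prime = best$omega_prime,
                 frequency = Re(best$omega_prime) / (2 * pi),
                 decay_rate = Im(best$omega_prime),
                 stable = Im(best$omega_prime) > 0,
                 residual = best$residual, converged = best$converged,
                 closest_approach = ca),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf(
    "<critical_point> mode %d: omega' = 2pi * %.2f Hz %+.2f i /s -> %s%s\n",
    x$mode, x$frequency, x$decay_rate,
    if (x$stable) "stable" else "linearly unstable",
    if (x$converged) "" else sprintf(" (NOT converged, residual %.2e)",
                                     x$residual)))
  invisible(x)
}

# maximum excess Re(lambda) - 1 over the positive-real-axis crossings of
# all eigenvalue trajectories in `band`: positive iff some trajectory
# encircles the critical value one (oscillatory instability)
.crossing_excess <- function(decomp, band) {
  freqs <- decomp$grid$freqs
  sel <- which(freqs >= band[1] & freqs <= band[2])
  worst <- -Inf
  for (i in seq_len(ncol(decomp$lambda))) {
    lam <- decomp$lambda[sel, i]
    im <- Im(lam); re <- Re(lam)
    k <- which(im[-length(im)] * im[-1] <= 0 & im[-length(im)] != im[-1] &
                 pmax(re[-length(re)], re[-1]) > 0)
    for (j in k) {
      w <- abs(im[j]) / (abs(im[j]) + abs(im[j + 1]))
      worst <- max(worst, (1 - w) * re[j] + w * re[j + 1] - 1)
    }
  }
  worst
}

#' Stability boundary of a connection perturbation
#'
#' Scans the fractional perturbation \eqn{\alpha} of one indegree (working
#' point held fixed) for the oscillatory instability boundary: the value
#' \eqn{\alpha^*} at which an eigenvalue trajectory attains the critical
#' value one at a real frequency, so that the complex critical frequency
#' crosses the real axis (\eqn{\Im(\omega') = 0}) and the circuit would
#' undergo a Hopf bifurcation. The bisection operates on the excess of the
#' trajectory's positive-real-axis crossing over one, which changes sign
#' exactly at the boundary and remains well-conditioned far from it; the
#' complex critical point at the located boundary is returned for
#' verification.
#'
#' @param m a \code{network_model}.
#' @param target,source connection to perturb (indices or labels).
#' @param alpha_range length-2 interval to search.
#' @param band band (Hz) containing the oscillation of interest.
#' @param grid frequency grid.
#' @param tol bisection tolerance on alpha.
#' @return list: \code{alpha_star} (NA if no sign change in range),
#'   \code{bracket}, \code{excess_at_ends}, and \code{critical_point}
#'   (the complex root at the boundary, when found).
#' @export
hopf_scan <- function(m, target, source, alpha_range, band = c(30, 500),
                      grid = frequency_grid(), tol = 1e-4) {
  state <- solve_selfconsistent(m)
  tf <- transfer_functions(m, state, grid)
  dec_at <- function(alpha) {
    mp <- perturb_indegree(m, target, source, alpha)
    decompose_modes(effective_connectivity(mp, state, tf, grid))
  }
  excess_at <- function(alpha) .crossing_excess(dec_at(alpha), band)
  e_lo <- excess_at(alpha_range[1]); e_hi <- excess_at(alpha_range[2])
  ends <- c(e_lo, e_hi)
  if (!is.finite(e_lo) || !is.finite(e_hi) || sign(e_lo) == sign(e_hi))
    return(list(alpha_star = NA_real_, bracket = alpha_range,
                excess_at_ends = ends,
                message = "no stability change inside alpha range"))
  lo <- alpha_range[1]; hi <- alpha_range[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    e_mid <- excess_at(mid)
    if (sign(e_mid) == sign(e_lo)) { lo <- mid; e_lo <- e_mid }
    else hi <- mid
  }
  alpha_star <- (lo + hi) / 2
  # verify with the complex root of the tracked mode at the boundary
  mp <- perturb_indegree(m, target, source, alpha_star)
  decomp <- dec_at(alpha_star)
  ca <- vapply(seq_len(ncol(decomp$lambda)), function(i)
    closest_approach(decomp$lambda[, i], grid$freqs, band)$distance,
    numeric(1))
  cp <- tryCatch(find_critical_frequency(mp, state, decomp,
                                         which.min(ca), band),
                 error = function(e) NULL)
  list(alpha_star = alpha_star, bracket = c(lo, hi),
       excess_at_ends = ends, critical_point = cp)
}
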