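# Noise matrix, propagator and population rate power spectra.

#' Effective noise matrix
#'
#' Diagonal matrix of the white-noise spectral densities generated by the
#' Poisson-like spiking realization of each population's rate signal:
#' \eqn{D_{ii} = \bar r_i / M_i}.
#'
#' @param state a converged \code{stationary_state} (or a rate vector).
#' @param sizes population sizes.
#' @return diagonal real N x N matrix.
#' @export
noise_matrix <- function(state, sizes) {
  rates <- if (inherits(state, "stationary_state")) state$rates else state
  if (any(sizes <= 0)) stop("population sizes must be positive")
  diag(rates / sizes, nrow = length(rates))
}

#' Propagator of the linear rate dynamics
#'
#' \eqn{P(\omega) = (I - \tilde M_d(\omega))^{-1}}, mapping the intrinsic
#' noise onto the observed rate fluctuations.
#'
#' @param eff an \code{effective_connectivity}.
#' @return object of class \code{propagator}: complex array \code{P}
#'   (N x N x n_freq), the grid, and per-frequency condition numbers
#'   (\code{kappa}) of \eqn{I - \tilde M_d}.
#' @export
propagator <- function(eff) {
  n <- dim(eff$Md)[1]; nf <- dim(eff$Md)[3]
  P <- array(0i, c(n, n, nf))
  kappa <- numeric(nf)
  I <- diag(n)
  for (f in seq_len(nf)) {
    A <- I - eff$Md[, , f]
    sv <- svd(A, nu = 0, nv = 0)$d
    kappa[f] <- if (min(sv) > 0) max(sv) / min(sv) else Inf
    Pf <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Pf))
      stop("I - Md is singular at f = ", eff$grid$freqs[f],
           " Hz (eigenvalue 1 on the grid)")
    P[, , f] <- Pf
  }
  structure(list(P = P, grid = eff$grid, kappa = kappa, eff = eff),
            class = "propagator")
}

#' Population rate power spectra
#'
#' Cross-spectral matrix \eqn{C(\omega) = P(\omega) D P^H(\omega)} of the
#' linear rate model with output noise; the diagonal holds the
#' per-population power spectral densities (units (spikes/s)^2 s, i.e.
#' density per Hz in the two-sided convention). For an unconnected circuit
#' the spectrum is the flat Poisson baseline \eqn{\bar r_i / M_i}.
#'
#' @param eff an \code{effective_connectivity}.
#' @param D noise matrix from \code{\link{noise_matrix}}; computed from
#'   the stored state and model when omitted.
#' @return object of class \code{spectra_result}: matrix \code{C}
#'   (n_freq x N) of real spectral densities, full complex cross-spectra
#'   array \code{C_full}, the grid, and population labels.
#' @export
power_spectra <- function(eff, D = NULL) {
  if (is.null(D)) D <- noise_matrix(eff$state, eff$model$sizes)
  prop <- propagator(eff)
  n <- dim(prop$P)[1]; nf <- dim(prop$P)[3]
  C_full <- array(0i, c(n, n, nf))
  C <- matrix(0, nf, n)
  for (f in seq_len(nf)) {
    Pf <- prop$P[, , f]
    Cf <- Pf %*% D %*% Conj(t(Pf))
    C_full[, , f] <- Cf
    C[f, ] <- pmax(Re(diag(Cf)), 0)
  }
  labels <- if (!is.null(eff$model)) eff$model$labels else as.character(1:n)
  colnames(C) <- labels
  structure(list(C = C, C_full = C_full, grid = eff$grid, labels = labels),
            class = "spectra_result")
}

#' @export
print.spectra_result <- function(x, ...) {
  cat(sprintf("<spectra_result> %d populations on %d frequencies (%g-%g Hz)\n",
              ncol(x$C), length(x$grid$freqs), min(x$grid$freqs),
              max(x$grid$freqs)))
  invisible(x)
}

# quadratic refinement of an interior grid maximum on (x, y); returns
# c(x*, y*) of the parabola through the three points
.quad_refine <- function(x, y, k) {
  if (k <= 1 || k >= length(x)) return(c(x[k], y[k]))
  x0 <- x[k]; h1 <- x[k] - x[k - 1]; h2 <- x[k + 1] - x[k]
  d1 <- (y[k] - y[k - 1]) / h1; d2 <- (y[k + 1] - y[k]) / h2
  curv <- (d2 - d1) / ((h1 + h2) / 2)
  if (curv >= 0) return(c(x[k], y[k]))
  slope <- (d1 * h2 + d2 * h1) / (h1 + h2)
  dx <- -slope / curv
  dx <- max(min(dx, max(h1, h2)), -max(h1, h2))
  c(x0 + dx, y[k] + slope * dx + 0.5 * curv * dx^2)
}

#' Locate spectral peaks
#'
#' Local maxima of each population's power spectral density inside a
#' frequency band, found by three-point comparison and refined by a
#' quadratic fit to log-power.
#'
#' @param spec a \code{spectra_result}.
#' @param band length-2 numeric, frequency interval (Hz).
#' @param populations which populations (indices or labels); default all.
#' @return data.frame with columns \code{population}, \code{frequency}
#'   (Hz), \code{height} (spectral density), sorted by height within
#'   population.
#' @export
find_peaks <- function(spec, band = range(spec$grid$freqs),
                       populations = NULL) {
  f <- spec$grid$freqs
  sel <- which(f >= band[1] & f <= band[2])
  if (length(sel) == 0) stop("empty frequency band")
  if (is.null(populations)) populations <- seq_len(ncol(spec$C))
  if (is.character(populations))
    populations <- match(populations, spec$labels)
  out <- list()
  for (p in populations) {
    y <- log(spec$C[, p])
    pk <- sel[-c(1, length(sel))]
    pk <- pk[y[pk] > y[pk - 1] & y[pk] >= y[pk + 1]]
    if (length(pk) == 0) next
    ref <- t(vapply(pk, function(k) .quad_refine(f, y, k), numeric(2)))
    o <- order(ref[, 2], decreasing = TRUE)
    out[[length(out) + 1]] <- data.frame(
      population = spec$labels[p], frequency = ref[o, 1],
      height = exp(ref[o, 2]))
  }
  if (length(out) == 0)
    return(data.frame(population = character(), frequency = numeric(),
                      height = numeric()))
  do.call(rbind, out)
}

# dominant peak frequency of the population-summed spectrum in a band;
# refines the grid to df_fine around the candidate using the full pipeline
.band_peak <- function(spec, band) {
  f <- spec$grid$freqs
  sel <- which(f >= band[1] & f <= band[2])
  if (length(sel) == 0) stop("no grid frequencies inside the band")
  tot <- log(rowSums(spec$C))
  k <- sel[which.max(tot[sel])]
  interior <- k > 1 && k < length(f) && tot[k] >= tot[k - 1] &&
    tot[k] >= tot[k + 1]
  if (!interior) return(list(frequency = f[k], index = k, interior = FALSE))
  r <- .quad_refine(f, tot, k)
  list(frequency = r[1], index = k, interior = TRUE)
}
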