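# Sensitivity of the critical eigenvalue to every anatomical connection:
# the complex sensitivity matrix, its amplitude/frequency projections, and
# minimal-circuit extraction.

#' Sensitivity of an eigenvalue to all indegree perturbations
#'
#' Derivative of the tracked eigenvalue \eqn{\lambda_c(\omega)} with
#' respect to a fractional perturbation of each indegree:
#' \deqn{Z_{kl} = \frac{v_{c,k}\,\tilde M_{kl}\,u_{c,l}}{v_c^T u_c}.}
#' The entries sum to \eqn{\lambda_c} (trace identity) and can be nonzero
#' only where a connection exists.
#'
#' @param eff an \code{effective_connectivity}.
#' @param decomp matching \code{mode_decomposition}.
#' @param mode tracked mode index.
#' @param frequency frequency (Hz) at which to evaluate; snapped to the
#'   nearest grid point.
#' @return object of class \code{sensitivity_map}: \code{frequency},
#'   \code{mode}, \code{lambda_c}, complex matrix \code{Z}, projections
#'   \code{Z_amp}, \code{Z_freq}, and unit vectors \code{k},
#'   \code{k_perp}.
#' @export
sensitivity_measure <- function(eff, decomp, mode, frequency) {
  f <- which.min(abs(decomp$grid$freqs - frequency))
  uc <- decomp$u[, mode, f]; vc <- decomp$v[mode, , f]
  norm_uv <- sum(vc * uc)
  if (Mod(norm_uv) < 1e-12)
    stop("left/right eigenvector product is numerically zero; ",
         "mode not normalizable at ", decomp$grid$freqs[f], " Hz")
  Z <- outer(vc, uc) * eff$Md[, , f] / norm_uv
  map <- structure(
    list(frequency = decomp$grid$freqs[f], mode = mode,
         lambda_c = decomp$lambda[f, mode], Z = Z,
         labels = if (!is.null(eff$model)) eff$model$labels else NULL),
    class = "sensitivity_map")
  proj <- project_amp_freq(map)
  map$Z_amp <- proj$Z_amp; map$Z_freq <- proj$Z_freq
  map$k <- proj$k; map$k_perp <- proj$k_perp
  map
}

#' First-order prediction of a perturbed eigenvalue
#'
#' \eqn{\hat\lambda(\alpha_{kl}) \simeq \lambda + Z_{kl}\,\alpha_{kl}}.
#'
#' @param map a \code{sensitivity_map}.
#' @param target,source connection indices or labels.
#' @param alpha fractional indegree change.
#' @return predicted complex eigenvalue.
#' @export
linear_shift <- function(map, target, source, alpha) {
  k <- .map_index(map, target); l <- .map_index(map, source)
  map$lambda_c + map$Z[k, l] * alpha
}

.map_index <- function(map, pop) {
  if (is.character(pop)) {
    i <- match(pop, map$labels)
    if (is.na(i)) stop("unknown population: ", pop)
    i
  } else as.integer(pop)
}

#' Amplitude / frequency projection of the sensitivity matrix
#'
#' Decomposes each complex entry of Z along the direction
#' \eqn{k = (1-\Re\lambda_c, \Im\lambda_c)/\|\cdot\|} from the critical
#' eigenvalue towards one (controlling peak amplitude) and the
#' perpendicular direction \eqn{k_\perp} (controlling peak frequency).
#' The projection is an isometry:
#' \eqn{(Z^{amp})^2 + (Z^{freq})^2 = |Z|^2} elementwise.
#'
#' @param map a \code{sensitivity_map}.
#' @return list with real matrices \code{Z_amp}, \code{Z_freq} and unit
#'   vectors \code{k}, \code{k_perp}.
#' @export
project_amp_freq <- function(map) {
  lc <- map$lambda_c
  v <- c(1 - Re(lc), Im(lc))
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("critical eigenvalue equals one; projection undefined")
  k <- v / nv
  k_perp <- c(-k[2], k[1])
  Z_amp <- Re(map$Z) * k[1] + Im(map$Z) * k[2]
  Z_freq <- Re(map$Z) * k_perp[1] + Im(map$Z) * k_perp[2]
  list(Z_amp = Z_amp, Z_freq = Z_freq, k = k, k_perp = k_perp)
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map> mode %d at %.2f Hz, lambda_c = %.4f%+.4fi\n",
              x$mode, x$frequency, Re(x$lambda_c), Im(x$lambda_c)))
  top <- order(Mod(x$Z), decreasing = TRUE)[1:min(5, length(x$Z))]
  idx <- arrayInd(top, dim(x$Z))
  lab <- if (!is.null(x$labels)) x$labels else
    as.character(seq_len(nrow(x$Z)))
  cat(" largest |Z| entries:\n")
  for (r in seq_len(nrow(idx)))
    cat(sprintf("  %s <- %s : %.4f%+.4fi\n", lab[idx[r, 1]], lab[idx[r, 2]],
                Re(x$Z[top[r]]), Im(x$Z[top[r]])))
  invisible(x)
}

# full pipeline pieces shared by the convenience wrappers ------------------

# run model -> state -> tf -> eff (+ optionally hold a reference state)
.pipeline <- function(m, grid = frequency_grid(), state = NULL, tf = NULL) {
  if (is.null(state)) {
    state <- solve_selfconsistent(m)
    if (!state$converged)
      warning("stationary state did not converge (residual ",
              signif(state$residual, 3), ")")
  }
  if (is.null(tf)) tf <- transfer_functions(m, state, grid)
  eff <- effective_connectivity(m, state, tf, grid)
  list(state = state, tf = tf, eff = eff)
}

#' Sensitivity map at a spectral peak
#'
#' Convenience wrapper for the full analysis chain: computes the
#' stationary state, transfer functions, spectra and mode decomposition,
#' locates the dominant peak of the population-summed spectrum inside
#' \code{band}, identifies the mode with the largest peak factor
#' \eqn{p(\omega)} there, and returns its sensitivity map at the peak
#' frequency. With \code{band = 0} (or \code{c(0, 0)}) the map of the
#' zero-frequency (slow-fluctuation / stability) mode with the largest
#' real eigenvalue part is returned.
#'
#' @param m a \code{network_model}.
#' @param band length-2 frequency interval (Hz), or 0.
#' @param grid frequency grid (default 0-500 Hz at 1 Hz).
#' @return a \code{sensitivity_map}; the pipeline objects are attached as
#'   attribute \code{"pipeline"} (state, tf, eff, decomp, spectra,
#'   peak_frequency).
#' @export
sensitivity_at_peak <- function(m, band, grid = frequency_grid()) {
  pl <- .pipeline(m, grid)
  decomp <- decompose_modes(pl$eff)
  if (length(band) == 1) band <- c(band, band)
  if (all(band == 0)) {
    mode <- which.max(Re(decomp$lambda[1, ]))
    f_peak <- 0
    spec <- NULL
  } else {
    spec <- power_spectra(pl$eff)
    pk <- .band_peak(spec, band)
    base <- max(diag(noise_matrix(pl$state, m$sizes)))
    sel <- spec$grid$freqs >= band[1] & spec$grid$freqs <= band[2]
    if (max(spec$C[sel, ]) <= 1.0001 * base)
      stop("no spectral peak found in band [", band[1], ", ", band[2], "] Hz")
    f_peak <- pk$frequency
    mode <- which.max(p_factor(decomp$lambda[pk$index, ]))
  }
  map <- sensitivity_measure(pl$eff, decomp, mode, f_peak)
  attr(map, "pipeline") <- list(state = pl$state, tf = pl$tf, eff = pl$eff,
                                decomp = decomp, spectra = spec,
                                peak_frequency = f_peak)
  map
}

# does a reduced model keep all eigenvalue trajectories away from the
# instability at one? (rejects Re >= 1 with small |Im| anywhere on grid)
.mask_stable <- function(m_red, state, tf, grid, im_tol = 0.05) {
  eff <- effective_connectivity(m_red, state, tf, grid)
  nf <- dim(eff$Md)[3]
  for (f in seq_len(nf)) {
    lam <- eigen(eff$Md[, , f], only.values = TRUE)$values
    if (any(Re(lam) >= 1 & abs(Im(lam)) < im_tol)) return(FALSE)
  }
  TRUE
}

#' Minimal oscillation-generating circuit
#'
#' Starting from an unconnected circuit whose missing inputs are replaced
#' by external drive with identical first and second moments (working
#' point preserved), the connectivity mask is filled with the connections
#' carrying the largest absolute entries of \eqn{Z^{amp}} and
#' \eqn{Z^{freq}} at the peak frequency. A candidate connection whose
#' addition would destabilise the reduced circuit (an eigenvalue
#' trajectory attaining \eqn{\Re\lambda \ge 1} with \eqn{|\Im\lambda| <
#' 0.05}) is skipped and the ranking continues. The reduced spectra are
#' then compared to the full-circuit spectra.
#'
#' Recovery metrics, per population participating in the mask:
#' peak-frequency recovery \eqn{100\,\min(f_{red},f_{full}) /
#' \max(f_{red},f_{full})} and log-amplitude recovery defined on
#' \eqn{L = \log_{10}(C_{peak}/\mathrm{baseline})} with the flat Poisson
#' baseline \eqn{\bar r/M} as reference level, as
#' \eqn{100\,\min(L_{red},L_{full})/\max(L_{red},L_{full})}.
#'
#' @param m a \code{network_model}.
#' @param map a \code{sensitivity_map} at the peak frequency (as from
#'   \code{\link{sensitivity_at_peak}}).
#' @param n_amp,n_freq how many top-ranked amplitude / frequency entries
#'   to include.
#' @param band frequency band (Hz) in which the peak is measured.
#' @param grid frequency grid.
#' @return list: logical \code{mask}, \code{model_reduced},
#'   \code{spectra_reduced}, \code{spectra_full}, data.frame
#'   \code{recovery} (population, f_full, f_red, freq_recovery_pct,
#'   amp_recovery_pct), \code{skipped} (connections rejected by the
#'   stability guard).
#' @export
minimal_circuit <- function(m, map, n_amp = 5, n_freq = 8,
                            band = c(30, 90), grid = frequency_grid()) {
  n <- n_pop(m)
  if (n_amp + n_freq > n * n) stop("requested more connections than exist")
  pl <- .pipeline(m, grid)
  state <- pl$state; tf <- pl$tf
  spec_full <- power_spectra(pl$eff)
  # stability guard runs on a coarser grid (4 Hz) for speed
  grid_c <- frequency_grid(max(grid$freqs), 4)
  tf_c <- transfer_functions(m, state, grid_c)
  exists_conn <- m$K > 0
  pick_top <- function(M, n_want, mask, skipped) {
    o <- order(abs(M), decreasing = TRUE)
    o <- o[exists_conn[o]]
    taken <- 0L
    for (idx in o) {
      if (taken >= n_want) break
      if (mask[idx]) next
      cand <- mask; cand[idx] <- TRUE
      m_try <- isolate_subcircuit(m, cand, state$rates)
      if (.mask_stable(m_try, state, tf_c, grid_c)) {
        mask[idx] <- TRUE; taken <- taken + 1L
      } else skipped <- c(skipped, idx)
    }
    list(mask = mask, skipped = skipped)
  }
  mask <- matrix(FALSE, n, n)
  skipped <- integer(0)
  r1 <- pick_top(map$Z_amp, n_amp, mask, skipped)
  r2 <- pick_top(map$Z_freq, n_freq, r1$mask, r1$skipped)
  mask <- r2$mask
  m_red <- isolate_subcircuit(m, mask, state$rates)
  eff_red <- effective_connectivity(m_red, state, tf, grid)
  spec_red <- power_spectra(eff_red)
  parts <- which(apply(mask, 1, any) | apply(mask, 2, any))
  D <- noise_matrix(state, m$sizes)
  rec <- lapply(parts, function(p) {
    pf <- .peak_in_band(spec_full, p, band)
    pr <- .peak_in_band(spec_red, p, band)
    Lf <- log10(pf$height / D[p, p]); Lr <- log10(pr$height / D[p, p])
    data.frame(population = m$labels[p], f_full = pf$frequency,
               f_red = pr$frequency,
               freq_recovery_pct = 100 * min(pf$frequency, pr$frequency) /
                 max(pf$frequency, pr$frequency),
               amp_recovery_pct = if (max(Lf, Lr) > 0)
                 100 * min(Lf, Lr) / max(Lf, Lr) else NA_real_)
  })
  list(mask = mask, model_reduced = m_red, spectra_reduced = spec_red,
       spectra_full = spec_full, recovery = do.call(rbind, rec),
       skipped = skipped)
}

# per-population band maximum with quadratic refinement
.peak_in_band <- function(spec, p, band) {
  f <- spec$grid$freqs
  sel <- which(f >= band[1] & f <= band[2])
  y <- log(spec$C[, p])
  k <- sel[which.max(y[sel])]
  r <- .quad_refine(f, y, k)
  list(frequency = r[1], height = exp(r[2]))
}
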