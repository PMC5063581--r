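# Per-frequency eigendecomposition of the effective connectivity,
# continuous mode tracking, eigenvalue trajectories, and the single-mode
# approximation of the spectrum.

#' Eigenmode decomposition of the effective connectivity
#'
#' Diagonalises \eqn{\tilde M_d(\omega)} at every grid frequency into
#' bi-orthonormal left/right eigenvector pairs (\eqn{v_i^T u_j =
#' \delta_{ij}}) and relabels the modes across frequencies so that each
#' eigenvalue trajectory \eqn{\lambda_i(\omega)} is continuous. Matching
#' between adjacent frequencies is by greedy assignment on the overlap
#' \eqn{|v_i(\omega_k)^T u_j(\omega_{k+1})|} (right eigenvectors are unit
#' norm, so the self-overlap is near 1); if the best overlap falls below
#' \code{overlap_threshold} the affected modes fall back to
#' nearest-eigenvalue matching and the frequency is flagged. Modes are
#' seeded at the first grid frequency in order of descending real part.
#'
#' @param eff an \code{effective_connectivity}.
#' @param overlap_threshold minimum eigenvector overlap for overlap-based
#'   tracking (default 0.5).
#' @return object of class \code{mode_decomposition}: \code{lambda}
#'   (n_freq x N complex), arrays \code{u}, \code{v} (N x N x n_freq,
#'   columns of u / rows of v are modes), the grid, and
#'   \code{degenerate_freqs}.
#' @export
decompose_modes <- function(eff, overlap_threshold = 0.5) {
  n <- dim(eff$Md)[1]; nf <- dim(eff$Md)[3]
  lambda <- matrix(0i, nf, n)
  U <- array(0i, c(n, n, nf)); V <- array(0i, c(n, n, nf))
  degenerate <- numeric(0)
  v_prev <- NULL
  lam_prev <- NULL
  for (f in seq_len(nf)) {
    e <- eigen(eff$Md[, , f])
    u <- e$vectors
    u <- sweep(u, 2, sqrt(colSums(Mod(u)^2)), "/")   # unit-norm right
    v <- solve(u)                                    # rows: v_i^T u_j = d_ij
    if (f == 1) {
      ord <- order(-Re(e$values))
    } else {
      ov <- Mod(v_prev %*% u)                        # ov[i, j]
      ord <- integer(n); used <- logical(n)
      pool <- ov
      ok <- TRUE
      for (rep in seq_len(n)) {
        k <- arrayInd(which.max(pool), dim(pool))
        if (pool[k[1], k[2]] < overlap_threshold) { ok <- FALSE; break }
        ord[k[1]] <- k[2]; used[k[2]] <- TRUE
        pool[k[1], ] <- -Inf; pool[, k[2]] <- -Inf
      }
      if (!ok || any(ord == 0)) {                    # nearest-eigenvalue
        degenerate <- c(degenerate, eff$grid$freqs[f])
        ord <- integer(n); used <- logical(n)
        dd <- Mod(outer(lam_prev, e$values, "-"))
        for (rep in seq_len(n)) {
          k <- arrayInd(which.min(dd), dim(dd))
          ord[k[1]] <- k[2]
          dd[k[1], ] <- Inf; dd[, k[2]] <- Inf
        }
      }
    }
    lambda[f, ] <- e$values[ord]
    U[, , f] <- u[, ord]
    V[, , f] <- v[ord, , drop = FALSE]
    v_prev <- V[, , f]; lam_prev <- lambda[f, ]
  }
  structure(list(lambda = lambda, u = U, v = V, grid = eff$grid,
                 degenerate_freqs = degenerate, eff = eff),
            class = "mode_decomposition")
}

#' @export
print.mode_decomposition <- function(x, ...) {
  cat(sprintf("<mode_decomposition> %d modes on %d frequencies\n",
              ncol(x$lambda), nrow(x$lambda)))
  ca <- vapply(seq_len(ncol(x$lambda)), function(i)
    unlist(closest_approach(x$lambda[, i], x$grid$freqs)[1:2]),
    numeric(2))
  print(data.frame(mode = seq_len(ncol(x$lambda)),
                   f_closest_hz = ca[1, ], dist_to_one = ca[2, ]))
  invisible(x)
}

#' Peak factor of a mode
#'
#' \eqn{p(\omega) = 1/|1-\lambda(\omega)|}, the contribution of a mode's
#' eigenvalue trajectory to the height of the spectrum; approaches 1 as
#' \eqn{\lambda \to 0} and diverges as \eqn{\lambda \to 1}.
#'
#' @param lambda complex eigenvalue trajectory.
#' @return real vector (Inf where \eqn{\lambda = 1}).
#' @export
p_factor <- function(lambda) {
  d <- Mod(1 - lambda)
  ifelse(d == 0, Inf, 1 / d)
}

#' Closest approach of an eigenvalue trajectory to one
#'
#' Frequency at which \eqn{|1-\lambda(\omega)|} is minimal within a band,
#' refined by a quadratic fit; the side classifies whether the closest
#' point lies left (\eqn{Re\,\lambda < 1}, asynchronous-irregular side) or
#' right of the critical value one.
#'
#' @param lambda complex eigenvalue trajectory on \code{freqs}.
#' @param freqs frequency axis (Hz).
#' @param band optional length-2 frequency interval.
#' @return list: \code{frequency} (Hz), \code{distance}
#'   (\eqn{\min|1-\lambda|}), \code{side} ("left"/"right"), \code{lambda}
#'   (eigenvalue at the closest grid point).
#' @export
closest_approach <- function(lambda, freqs, band = NULL) {
  sel <- seq_along(freqs)
  if (!is.null(band)) sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0) stop("empty band")
  d <- Mod(1 - lambda)
  k <- sel[which.min(d[sel])]
  if (k > 1 && k < length(freqs)) {
    r <- .quad_refine(freqs, -d^2, k)        # minimise |1-lambda|^2
    fstar <- r[1]; dstar <- sqrt(max(-r[2], 0))
  } else {
    fstar <- freqs[k]; dstar <- d[k]
  }
  list(frequency = fstar, distance = dstar,
       side = if (Re(lambda[k]) < 1) "left" else "right",
       lambda = lambda[k], index = k)
}

#' Single-mode approximation of the power spectrum
#'
#' Approximates each population's spectrum by the contribution of one
#' (dominant) mode:
#' \eqn{C_{kk}(\omega) \approx |1/(1-\lambda_c)|^2 (v_c^T D v_c^*)
#' |u_{c,k}|^2}. Near a spectral peak where the mode dominates, this
#' tracks the full spectrum.
#'
#' @param decomp a \code{mode_decomposition}.
#' @param D noise matrix.
#' @param mode mode index (column of \code{decomp$lambda}).
#' @param band optional frequency window (Hz); default all.
#' @return matrix (n_freq_in_band x N) of approximate spectral densities,
#'   with attribute \code{"freqs"}.
#' @export
mode_spectrum_approx <- function(decomp, D, mode, band = NULL) {
  freqs <- decomp$grid$freqs
  sel <- seq_along(freqs)
  if (!is.null(band)) sel <- which(freqs >= band[1] & freqs <= band[2])
  n <- dim(decomp$u)[1]
  out <- matrix(0, length(sel), n)
  for (r in seq_along(sel)) {
    f <- sel[r]
    uc <- decomp$u[, mode, f]; vc <- decomp$v[mode, , f]
    alpha2 <- Re(t(vc) %*% D %*% Conj(vc))
    out[r, ] <- as.numeric(alpha2) / Mod(1 - decomp$lambda[f, mode])^2 *
      Mod(uc)^2
  }
  attr(out, "freqs") <- freqs[sel]
  out
}

# full mode-pair reconstruction of the cross-spectral diagonal (all pairs
# i, j); used as the completeness check of the decomposition
.mode_pair_spectrum <- function(decomp, D, f_index) {
  n <- dim(decomp$u)[1]
  acc <- numeric(n)
  lam <- decomp$lambda[f_index, ]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    vi <- decomp$v[i, , f_index]; vj <- decomp$v[j, , f_index]
    ui <- decomp$u[, i, f_index]; uj <- decomp$u[, j, f_index]
    beta <- (t(vi) %*% D %*% Conj(vj)) /
      ((1 - lam[i]) * Conj(1 - lam[j]))
    acc <- acc + Re(as.complex(beta) * ui * Conj(uj))
  }
  acc
}
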