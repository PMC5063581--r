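#' Construct a multi-population network model
#'
#' Bundles the anatomical and physiological description of an N-population
#' circuit of leaky integrate-and-fire neurons: population sizes, the
#' indegree matrix, synaptic weights, delay statistics, external Poisson
#' drive, and neuron parameters. All internal computations use seconds and
#' millivolts; rates are in spikes/s.
#'
#' @param labels character vector of population names (length N).
#' @param sizes integer vector of neuron counts per population.
#' @param K N x N indegree matrix (rows = target, columns = source);
#'   real-valued so that fractional perturbations are exact.
#' @param W N x N synaptic weight matrix in mV (mean membrane-potential
#'   deflection per incoming spike, i.e. PSC amplitude times tau_s / C_m).
#'   Excitatory columns are positive, inhibitory columns negative.
#' @param d_mean,d_std N x N mean and standard deviation of the synaptic
#'   delay distribution in seconds. Delays are truncated-Gaussian
#'   distributed on (0, Inf).
#' @param K_ext external indegrees per population.
#' @param r_ext external Poisson rate (spikes/s) per source.
#' @param w_ext external synaptic weight (mV); defaults to the largest
#'   excitatory weight in W.
#' @param neuron list with per-population (or scalar, recycled) entries
#'   \code{tau_m}, \code{tau_s}, \code{tau_ref} (seconds), \code{V_th},
#'   \code{V_reset} (mV, relative to rest).
#' @param g inhibition/excitation weight ratio (bookkeeping only; the sign
#'   structure lives in \code{W}).
#' @param mu_ext_extra,var_ext_extra additional external mean (mV) and
#'   variance (mV^2) input per population; used to absorb the moments of
#'   removed connections so the working point is preserved (see
#'   \code{\link{isolate_subcircuit}}).
#'
#' @return an object of class \code{network_model}.
#' @export
network_model <- function(labels, sizes, K, W, d_mean, d_std, K_ext, r_ext,
                          w_ext = max(W), neuron, g = NA_real_,
                          mu_ext_extra = NULL, var_ext_extra = NULL) {
  n <- length(labels)
  K <- as.matrix(K); W <- as.matrix(W)
  d_mean <- as.matrix(d_mean); d_std <- as.matrix(d_std)
  neuron <- lapply(neuron, function(x) rep_len(as.numeric(x), n))
  if (is.null(mu_ext_extra)) mu_ext_extra <- numeric(n)
  if (is.null(var_ext_extra)) var_ext_extra <- numeric(n)
  m <- structure(
    list(labels = labels, sizes = as.numeric(sizes), K = K, W = W,
         d_mean = d_mean, d_std = d_std, K_ext = as.numeric(K_ext),
         r_ext = as.numeric(r_ext), w_ext = as.numeric(w_ext),
         neuron = neuron, g = g,
         mu_ext_extra = as.numeric(mu_ext_extra),
         var_ext_extra = as.numeric(var_ext_extra)),
    class = "network_model")
  validate_network_model(m)
  m
}

validate_network_model <- function(m) {
  n <- length(m$labels)
  stopifnot(length(m$sizes) == n, all(dim(m$K) == n), all(dim(m$W) == n),
            all(dim(m$d_mean) == n), all(dim(m$d_std) == n),
            length(m$K_ext) == n, length(m$r_ext) %in% c(1L, n))
  if (any(m$K < 0)) stop("indegrees must be non-negative")
  if (any(m$d_std < 0)) stop("delay standard deviations must be non-negative")
  if (any(m$sizes <= 0)) stop("population sizes must be positive")
  with(m$neuron, {
    if (any(tau_m <= 0) || any(tau_s < 0) || any(tau_ref < 0))
      stop("time constants must be positive")
    if (any(V_th <= V_reset)) stop("V_th must exceed V_reset")
  })
  invisible(m)
}

#' Number of populations of a network model
#' @param m a \code{network_model}.
#' @return integer.
#' @export
n_pop <- function(m) length(m$labels)

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d populations, %d neurons\n",
              n_pop(x), round(sum(x$sizes))))
  cat(" populations:", paste(x$labels, collapse = ", "), "\n")
  cat(sprintf(" connections: %d nonzero indegrees, external rate %g /s\n",
              sum(x$K > 0), x$r_ext[1]))
  invisible(x)
}

#' Load the bundled multi-layer cortical microcircuit
#'
#' Returns the 8-population (layers 2/3, 4, 5, 6; one excitatory and one
#' inhibitory population each, 77169 neurons in total) parameter set of the
#' companion spiking microcircuit model, with the three stabilising
#' modifications applied by default: the indegree from 4I to 4E is reduced
#' by 15%, the standard deviation of every delay distribution is set to
#' 1 ms, and the external input to 4E is reduced by 19%.
#'
#' Indegrees were derived from the published pairwise connection
#' probabilities p via \code{n_syn = log(1-p) / log(1 - 1/(N_post*N_pre))}
#' and \code{K = n_syn / N_post}; the fixture file stores the resulting
#' matrix. Synaptic weights are stored as PSC amplitudes (pA) and converted
#' to mV via \code{w = PSC * tau_s / C_m}; the 4E -> 2/3E projection has
#' doubled weight.
#'
#' @param modified logical; apply the three stabilising modifications
#'   (default \code{TRUE}).
#' @param file path to a network config; defaults to the bundled fixture.
#' @return a \code{network_model}.
#' @export
microcircuit <- function(modified = TRUE, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "microcircuit.yaml",
                        package = "popspectra", mustWork = FALSE)
  if (is.null(file) || !nzchar(file) || !file.exists(file))
    stop("microcircuit fixture not found; the package installation ",
         "is missing inst/extdata/microcircuit.yaml")
  y <- tryCatch(yaml::read_yaml(file),
                error = function(e) stop("failed to parse network config '",
                                         file, "': ", conditionMessage(e)))
  req <- c("labels", "sizes", "indegrees", "K_ext", "r_ext", "PSC_amp_pA",
           "weight_rel", "delay_mean_ms", "delay_std_ms", "neuron")
  miss <- setdiff(req, names(y))
  if (length(miss))
    stop("corrupt network config: missing fields ",
         paste(miss, collapse = ", "))
  as_mat <- function(lst) do.call(rbind, lapply(lst, as.numeric))
  K <- as_mat(y$indegrees)
  nrn <- y$neuron
  w_unit <- y$PSC_amp_pA * (nrn$tau_s_ms * 1e-3) / nrn$C_m_pF * 1e3  # mV
  W <- as_mat(y$weight_rel) * w_unit
  K_ext <- as.numeric(y$K_ext)
  d_std <- as_mat(y$delay_std_ms)
  if (isTRUE(modified)) {
    mod <- y$modifications
    i4E <- match("4E", y$labels); i4I <- match("4I", y$labels)
    K[i4E, i4I] <- K[i4E, i4I] * mod$scale_K_4E_from_4I
    K_ext[i4E] <- K_ext[i4E] * mod$scale_K_ext_4E
    d_std[] <- mod$delay_std_all_ms
  }
  network_model(
    labels = y$labels, sizes = y$sizes, K = K, W = W,
    d_mean = as_mat(y$delay_mean_ms) * 1e-3, d_std = d_std * 1e-3,
    K_ext = K_ext, r_ext = y$r_ext, w_ext = w_unit,
    neuron = list(tau_m = nrn$tau_m_ms * 1e-3, tau_s = nrn$tau_s_ms * 1e-3,
                  tau_ref = nrn$tau_ref_ms * 1e-3, V_th = nrn$V_th_mV,
                  V_reset = nrn$V_reset_mV),
    g = y$g)
}

pop_index <- function(m, pop) {
  if (is.character(pop)) {
    i <- match(pop, m$labels)
    if (any(is.na(i))) stop("unknown population: ", pop[is.na(i)][1])
    i
  } else as.integer(pop)
}

#' Fractionally perturb one indegree
#'
#' Scales the indegree of the connection from population \code{source} to
#' population \code{target} by \code{1 + alpha}, leaving everything else
#' untouched. This is the elementary perturbation probed by the
#' sensitivity measure.
#'
#' @param m a \code{network_model}.
#' @param target,source population index or label (target receives from
#'   source).
#' @param alpha fractional change; must satisfy \code{alpha >= -1}.
#' @return a new \code{network_model}.
#' @export
perturb_indegree <- function(m, target, source, alpha) {
  if (alpha < -1) stop("alpha < -1 would produce a negative indegree")
  i <- pop_index(m, target); j <- pop_index(m, source)
  m$K[i, j] <- m$K[i, j] * (1 + alpha)
  m
}

#' Compensate an indegree perturbation through the external drive
#'
#' Adjusts the external input of \code{m_pert} so that, at the stationary
#' rates of the original model, every population's mean input is restored
#' exactly. By default only the external Poisson indegree (a mean-plus-
#' variance channel) is adjusted, mirroring the experimental protocol of
#' replacing internal synapses by Poisson sources; the residual mismatch in
#' the input standard deviation is reported in the
#' \code{"sigma_residual"} attribute. With \code{two_channel = TRUE} a
#' second, variance-only external channel is used as well, so both moments
#' are restored (up to the non-negativity of the added variance).
#'
#' @param m_orig,m_pert original and perturbed models; they may differ only
#'   in the indegree matrix.
#' @param rates stationary rates of the original model; computed by
#'   \code{\link{solve_selfconsistent}} when omitted.
#' @param two_channel logical; also restore the input variance via a
#'   variance-only channel.
#' @return \code{m_pert} with adjusted external drive; attribute
#'   \code{"sigma_residual"} holds the per-population difference of input
#'   standard deviations (mV) from the original working point.
#' @export
compensate_external <- function(m_orig, m_pert, rates = NULL,
                                two_channel = FALSE) {
  if (!isTRUE(all.equal(m_orig$W, m_pert$W)) ||
      !isTRUE(all.equal(m_orig$K_ext, m_pert$K_ext)))
    stop("models must differ only in the indegree matrix K")
  if (is.null(rates)) rates <- solve_selfconsistent(m_orig)$rates
  dK <- m_pert$K - m_orig$K
  tau_m <- m_pert$neuron$tau_m
  # working-point change at fixed rates, per population
  dmu <- tau_m * as.numeric((dK * m_pert$W) %*% rates)
  dvar <- tau_m * as.numeric((dK * m_pert$W^2) %*% rates)
  # mean channel: external Poisson indegree
  dK_ext <- -dmu / (tau_m * m_pert$w_ext * m_pert$r_ext)
  K_ext_new <- m_pert$K_ext + dK_ext
  if (any(K_ext_new < 0)) {
    bad <- m_pert$labels[which(K_ext_new < 0)[1]]
    stop("compensation would require negative external indegree for ",
         "population ", bad)
  }
  m_pert$K_ext <- K_ext_new
  dvar_ext <- tau_m * dK_ext * m_pert$w_ext^2 * m_pert$r_ext
  var_gap <- dvar + dvar_ext           # residual variance change (mV^2)
  if (two_channel) {
    add <- pmax(-var_gap, -m_pert$var_ext_extra)   # keep channel >= 0
    m_pert$var_ext_extra <- m_pert$var_ext_extra + add
    var_gap <- var_gap + add
  }
  wp <- working_point(m_orig, rates)
  sig_res <- sqrt(pmax(wp$sigma^2 + var_gap, 0)) - wp$sigma
  attr(m_pert, "sigma_residual") <- sig_res
  m_pert
}

#' Isolate a sub-circuit while preserving every working point
#'
#' Zeroes all connections outside \code{keep} and adds, for each removed
#' connection, its mean and variance contribution at the full-circuit
#' stationary rate of the source to the external drive. Every population
#' therefore keeps its working point (mu, sigma) exactly, emulating the
#' replacement of removed inputs by Poisson spike trains with identical
#' first and second moments.
#'
#' @param m a \code{network_model}.
#' @param keep either a logical N x N mask (TRUE = keep), a two-column
#'   matrix/data.frame of (target, source) pairs (indices or labels), or a
#'   vector of population labels/indices, in which case all connections
#'   among that subset are kept.
#' @param rates full-circuit stationary rates; computed when omitted.
#' @return a \code{network_model} with reduced connectivity.
#' @export
isolate_subcircuit <- function(m, keep, rates = NULL) {
  n <- n_pop(m)
  if (is.null(rates)) rates <- solve_selfconsistent(m)$rates
  mask <- matrix(FALSE, n, n)
  if (is.matrix(keep) && is.logical(keep)) {
    mask <- keep
  } else if ((is.matrix(keep) || is.data.frame(keep)) && ncol(keep) == 2) {
    for (r in seq_len(nrow(keep)))
      mask[pop_index(m, keep[[r, 1]]), pop_index(m, keep[[r, 2]])] <- TRUE
  } else {
    idx <- pop_index(m, keep)
    mask[idx, idx] <- TRUE
  }
  drop <- m$K * !mask            # indegrees being removed
  tau_m <- m$neuron$tau_m
  m$mu_ext_extra <- m$mu_ext_extra +
    tau_m * as.numeric((drop * m$W) %*% rates)
  m$var_ext_extra <- m$var_ext_extra +
    tau_m * as.numeric((drop * m$W^2) %*% rates)
  m$K[!mask] <- 0
  m
}

#' Read / write a network model as a plain-text config
#'
#' The config is a YAML file mirroring the \code{network_model} fields
#' (matrices as row-major lists, delays in ms). \code{read_network_config}
#' accepts both files written by \code{write_network_config} and the
#' bundled fixture format.
#'
#' @param path file path.
#' @return \code{read_network_config}: a \code{network_model}.
#' @export
read_network_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$PSC_amp_pA)) return(microcircuit(modified = FALSE,
                                                  file = path))
  as_mat <- function(lst) do.call(rbind, lapply(lst, as.numeric))
  network_model(labels = y$labels, sizes = y$sizes, K = as_mat(y$K),
                W = as_mat(y$W_mV),
                d_mean = as_mat(y$delay_mean_ms) * 1e-3,
                d_std = as_mat(y$delay_std_ms) * 1e-3,
                K_ext = y$K_ext, r_ext = y$r_ext, w_ext = y$w_ext_mV,
                neuron = list(tau_m = y$neuron$tau_m_ms * 1e-3,
                              tau_s = y$neuron$tau_s_ms * 1e-3,
                              tau_ref = y$neuron$tau_ref_ms * 1e-3,
                              V_th = y$neuron$V_th_mV,
                              V_reset = y$neuron$V_reset_mV),
                g = if (is.null(y$g)) NA_real_ else y$g,
                mu_ext_extra = y$mu_ext_extra,
                var_ext_extra = y$var_ext_extra)
}

#' @rdname read_network_config
#' @param m a \code{network_model} to serialise.
#' @export
write_network_config <- function(m, path) {
  as_rows <- function(M) lapply(seq_len(nrow(M)), function(i) M[i, ])
  y <- list(labels = m$labels, sizes = m$sizes, K = as_rows(m$K),
            W_mV = as_rows(m$W),
            delay_mean_ms = as_rows(m$d_mean * 1e3),
            delay_std_ms = as_rows(m$d_std * 1e3),
            K_ext = m$K_ext, r_ext = m$r_ext, w_ext_mV = m$w_ext,
            neuron = list(tau_m_ms = m$neuron$tau_m * 1e3,
                          tau_s_ms = m$neuron$tau_s * 1e3,
                          tau_ref_ms = m$neuron$tau_ref * 1e3,
                          V_th_mV = m$neuron$V_th,
                          V_reset_mV = m$neuron$V_reset),
            g = m$g, mu_ext_extra = m$mu_ext_extra,
            var_ext_extra = m$var_ext_extra)
  yaml::write_yaml(y, path)
  invisible(path)
}
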