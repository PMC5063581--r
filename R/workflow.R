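# Reporting workflows: each mirrors one step of the analysis narrative
# (rates, spectra, eigenvalue trajectories, sensitivity maps,
# perturbation protocol, minimal circuit, stability table, simulation)
# and writes plain-text tables with a commented provenance header.

.default_config <- function() {
  list(model = "microcircuit", f_max = 500, df = 1,
       band_low_gamma = c(30, 90), band_high_gamma = c(150, 400),
       target = NULL, source = NULL, alpha = NULL,
       n_amp = 5, n_freq = 8, duration = 10, dt = 1e-4, seed = 1,
       out_dir = ".", verbose = TRUE)
}

.load_config_model <- function(cfg) {
  if (identical(cfg$model, "microcircuit")) microcircuit()
  else read_network_config(cfg$model)
}

.write_table <- function(df, path, cfg, what) {
  hdr <- c(sprintf("# popspectra %s", what),
           sprintf("# config: %s", paste(
             vapply(names(cfg), function(k)
               paste0(k, "=", paste(format(cfg[[k]]), collapse = ",")),
               character(1)), collapse = " ")),
           sprintf("# generated: seed=%s", cfg$seed))
  con <- file(path, "w")
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  close(con)
  path
}

.say <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

#' Run a named analysis workflow
#'
#' Executes one of the standard workflows on a configured model and
#' writes its result tables to \code{config$out_dir}:
#' \describe{
#'   \item{rates}{working point and self-consistent stationary rates.}
#'   \item{spectra}{power spectral densities plus a peak summary.}
#'   \item{eigenvalues}{per-mode eigenvalue trajectories and
#'     closest-approach summary.}
#'   \item{sensitivity}{Re Z, Im Z, Z_amp, Z_freq at the peak of the
#'     configured band (or at 0 Hz if the band is \code{c(0, 0)}).}
#'   \item{minimal-circuit}{connection mask and recovery table.}
#'   \item{perturb}{perturb one indegree (\code{target}, \code{source},
#'     \code{alpha}) at fixed working point, compare spectra and peaks.}
#'   \item{stability}{per-mode complex critical frequency and
#'     classification.}
#'   \item{simulate}{stochastic rate-model trace and its periodogram.}
#' }
#'
#' @param name workflow name (see above).
#' @param config named list overriding the defaults: \code{model}
#'   ("microcircuit" or a config path), \code{f_max}, \code{df},
#'   \code{band_low_gamma}, \code{band_high_gamma}, \code{target},
#'   \code{source}, \code{alpha}, \code{n_amp}, \code{n_freq},
#'   \code{duration}, \code{dt}, \code{seed}, \code{out_dir},
#'   \code{verbose}.
#' @return invisibly, a list with the written file paths and the main
#'   result object.
#' @export
run_workflow <- function(name, config = list()) {
  cfg <- modifyList(.default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- .load_config_model(cfg)
  grid <- frequency_grid(cfg$f_max, cfg$df)
  out <- file.path(cfg$out_dir, paste0(gsub("-", "_", name), ".tsv"))
  res <- switch(
    name,
    "rates" = {
      st <- solve_selfconsistent(m)
      .say(cfg, "stationary state converged: ", st$converged,
           " (residual ", signif(st$residual, 3), ")")
      df <- data.frame(population = m$labels, mu_mV = st$working_point$mu,
                       sigma_mV = st$working_point$sigma,
                       rate_hz = st$rates)
      .write_table(df, out, cfg, "stationary rates")
      st
    },
    "spectra" = {
      pl <- .pipeline(m, grid)
      spec <- power_spectra(pl$eff)
      df <- data.frame(frequency_hz = grid$freqs, spec$C)
      .write_table(df, out, cfg, "population rate spectra")
      pks <- find_peaks(spec, cfg$band_low_gamma)
      .say(cfg, "low-gamma peaks located: ",
           paste(unique(round(pks$frequency)), collapse = ", "), " Hz")
      .write_table(pks, sub("\\.tsv$", "_peaks.tsv", out), cfg,
                   "spectral peaks")
      spec
    },
    "eigenvalues" = {
      pl <- .pipeline(m, grid)
      decomp <- decompose_modes(pl$eff)
      rows <- lapply(seq_len(ncol(decomp$lambda)), function(i)
        data.frame(mode = i, frequency_hz = grid$freqs,
                   re_lambda = Re(decomp$lambda[, i]),
                   im_lambda = Im(decomp$lambda[, i]),
                   dist_to_one = Mod(1 - decomp$lambda[, i])))
      .write_table(do.call(rbind, rows), out, cfg,
                   "eigenvalue trajectories")
      ca <- do.call(rbind, lapply(seq_len(ncol(decomp$lambda)), function(i) {
        a <- closest_approach(decomp$lambda[, i], grid$freqs)
        data.frame(mode = i, f_closest_hz = a$frequency,
                   distance = a$distance, side = a$side)
      }))
      .write_table(ca, sub("\\.tsv$", "_closest.tsv", out), cfg,
                   "closest approaches")
      decomp
    },
    "sensitivity" = {
      map <- sensitivity_at_peak(m, cfg$band_low_gamma, grid)
      .say(cfg, "peak located at ", round(map$frequency, 1),
           " Hz, mode ", map$mode, " tracked")
      lab <- m$labels
      df <- data.frame(target = rep(lab, ncol(map$Z)),
                       source = rep(lab, each = nrow(map$Z)),
                       re_Z = as.vector(Re(map$Z)),
                       im_Z = as.vector(Im(map$Z)),
                       Z_amp = as.vector(map$Z_amp),
                       Z_freq = as.vector(map$Z_freq))
      .write_table(df, out, cfg, sprintf("sensitivity measure at %.1f Hz",
                                         map$frequency))
      map
    },
    "minimal-circuit" = {
      map <- sensitivity_at_peak(m, cfg$band_low_gamma, grid)
      mc <- minimal_circuit(m, map, cfg$n_amp, cfg$n_freq,
                            cfg$band_low_gamma, grid)
      lab <- m$labels
      conn <- which(mc$mask, arr.ind = TRUE)
      df <- data.frame(target = lab[conn[, 1]], source = lab[conn[, 2]])
      .write_table(df, out, cfg, "minimal circuit connections")
      .write_table(mc$recovery, sub("\\.tsv$", "_recovery.tsv", out), cfg,
                   "minimal circuit recovery")
      mc
    },
    "perturb" = {
      if (is.null(cfg$target) || is.null(cfg$source) || is.null(cfg$alpha))
        stop("perturb workflow needs target, source and alpha in config")
      pl <- .pipeline(m, grid)
      spec0 <- power_spectra(pl$eff)
      mp <- perturb_indegree(m, cfg$target, cfg$source, cfg$alpha)
      # working point held fixed: original state and transfer functions
      eff_p <- effective_connectivity(mp, pl$state, pl$tf, grid)
      spec1 <- power_spectra(eff_p)
      band <- cfg$band_low_gamma
      rows <- lapply(seq_len(n_pop(m)), function(p) {
        p0 <- .peak_in_band(spec0, p, band)
        p1 <- .peak_in_band(spec1, p, band)
        data.frame(population = m$labels[p],
                   f_orig_hz = p0$frequency, f_pert_hz = p1$frequency,
                   height_orig = p0$height, height_pert = p1$height,
                   height_ratio = p1$height / p0$height)
      })
      df <- do.call(rbind, rows)
      .say(cfg, "peak height ratio (median): ",
           signif(stats::median(df$height_ratio), 3))
      .write_table(df, out, cfg,
                   sprintf("perturbation (%s <- %s, alpha = %g)",
                           cfg$target, cfg$source, cfg$alpha))
      list(original = spec0, perturbed = spec1, peaks = df)
    },
    "stability" = {
      pl <- .pipeline(m, grid)
      decomp <- decompose_modes(pl$eff)
      rows <- lapply(seq_len(ncol(decomp$lambda)), function(i) {
        cp <- find_critical_frequency(m, pl$state, decomp, i)
        a <- cp$closest_approach
        data.frame(mode = i, f_closest_hz = a$frequency,
                   distance = a$distance, side = a$side,
                   f_critical_hz = cp$frequency,
                   decay_rate = cp$decay_rate,
                   class = if (cp$stable) "stable" else "unstable",
                   converged = cp$converged)
      })
      df <- do.call(rbind, rows)
      .write_table(df, out, cfg, "mode stability")
      df
    },
    "simulate" = {
      st <- solve_selfconsistent(m)
      tr <- simulate_rates(m, st, cfg$duration, cfg$dt, cfg$seed)
      pg <- periodogram(tr)
      df <- data.frame(frequency_hz = pg$freqs, pg$power)
      .write_table(df, out, cfg, "simulated periodogram")
      list(trace = tr, periodogram = pg)
    },
    stop("unknown workflow: ", name)
  )
  invisible(list(files = out, result = res))
}
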