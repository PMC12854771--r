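#' Configuration of the bidirectional Monte Carlo / cable coupling
#'
#' The coupled run alternates, every `exchange_dt` ms: (a)
#' `sweeps_per_ms * exchange_dt` Monte Carlo sweeps of the membrane patch at
#' the current somatic voltage; (b) injection of the window-mean patch
#' current (scaled by `area_scale` and sign-flipped from membrane to
#' injection convention) into the soma while the solver advances by
#' `exchange_dt`. The end-of-window somatic voltage becomes the patch's
#' membrane potential for the next window.
#'
#' @param exchange_dt Exchange window, ms (must be an integer multiple of
#'   `dt`).
#' @param sweeps_per_ms Monte Carlo sweeps mapped onto 1 ms of physical time
#'   (the kinetic scale of the lattice model; a model choice, see the
#'   methods vignette).
#' @param n_replicas Replica count (replicas share the initial configuration
#'   and differ only by the seed of the patch's random stream).
#' @param temperatures Temperature list for [temperature_scan()], degrees C.
#' @param clamp_pa,clamp_on,clamp_off Somatic current clamp, pA and ms.
#' @param t_stop Simulated time, ms.
#' @param dt Solver step, ms.
#' @param area_scale Factor mapping one patch's current to whole-cell
#'   current.
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(exchange_dt = 0.5, sweeps_per_ms = 2,
                            n_replicas = 100, temperatures = c(40, 30, 20),
                            clamp_pa = 80, clamp_on = 50, clamp_off = 150,
                            t_stop = 600, dt = 0.025, area_scale = 2) {
  check_scalar(exchange_dt, "exchange_dt", lower = 1e-9)
  check_scalar(sweeps_per_ms, "sweeps_per_ms", lower = 1)
  if (!is_count(n_replicas) || n_replicas < 1)
    stop_ionspike("`n_replicas` must be a positive integer",
                  "ionspike_domain_error")
  steps <- exchange_dt / dt
  if (abs(steps - round(steps)) > 1e-9)
    stop_ionspike("`exchange_dt` must be an integer multiple of `dt`",
                  "ionspike_domain_error")
  structure(list(exchange_dt = exchange_dt, sweeps_per_ms = sweeps_per_ms,
                 n_replicas = n_replicas, temperatures = temperatures,
                 clamp_pa = clamp_pa, clamp_on = clamp_on,
                 clamp_off = clamp_off, t_stop = t_stop, dt = dt,
                 area_scale = area_scale),
            class = "coupling_config")
}

#' Two-compartment soma + dendrite grid
#'
#' The simplified cell used by the coupled studies: a soma and a dendrite,
#' each a single control volume.
#'
#' @param soma_diam Soma diameter, um.
#' @param dend_len,dend_diam Dendrite geometry, um.
#' @return A `compartment_grid` with 2 compartments.
#' @export
two_compartment_grid <- function(soma_diam = 20, dend_len = 200,
                                 dend_diam = 2) {
  discretize(make_ball_and_stick(soma_diam, dend_len, dend_diam),
             max_len = dend_len)
}

#' Run a replica ensemble of bidirectionally coupled simulations
#'
#' Per replica `r` the patch's random stream is reseeded with `seed + r - 1`
#' (composition and sensor states are shared) and the coupled loop of
#' [coupling_config()] is run to `t_stop`. A replica whose solver diverges
#' is dropped and reported; the ensemble errors if more than 10% of replicas
#' abort. Aggregates are the pointwise median and first/third quartiles of
#' the somatic voltage over completed replicas.
#'
#' @param patch A `membrane_patch` template.
#' @param gating A `gating_params` (its `v_m` is overridden by the coupling).
#' @param grid A `compartment_grid` (use [two_compartment_grid()] for the
#'   soma+dendrite model).
#' @param membrane A `membrane_params`.
#' @param cfg A `coupling_config`.
#' @param seed Integer base seed.
#' @return An object of class `ensemble_result`: `times`, `v` (time x
#'   replica matrix), `median`, `q1`, `q3`, `window_current` (time x replica
#'   window-mean patch currents), `aborted` (indices), `cfg`, `temperature`.
#' @export
run_coupled <- function(patch, gating, grid, membrane, cfg, seed = 1) {
  stopifnot(inherits(patch, "membrane_patch"),
            inherits(gating, "gating_params"),
            inherits(grid, "compartment_grid"),
            inherits(membrane, "membrane_params"),
            inherits(cfg, "coupling_config"))
  arrays <- build_cable_arrays(grid, membrane)
  soma <- which(grid$region == "soma")[1]
  if (is.na(soma)) soma <- 1L
  stim <- split_stimuli(
    list(stim_clamp(soma, cfg$clamp_pa, cfg$clamp_on, cfg$clamp_off)),
    list(), nrow(grid))
  steps_per_window <- as.integer(round(cfg$exchange_dt / cfg$dt))
  # may be fractional: the compiled loop carries the remainder across windows
  sweeps_per_window <- cfg$sweeps_per_ms * cfg$exchange_dt
  n_windows <- as.integer(round(cfg$t_stop / cfg$exchange_dt))
  vs <- NULL; wc <- NULL; times <- NULL
  aborted <- integer(0)
  for (r in seq_len(cfg$n_replicas)) {
    p_r <- reseed_patch(patch, seed + r - 1L)
    res <- tryCatch(
      cpp_coupled_run(p_r$grid, p_r$channels, p_r$rng, mc_par_list(gating),
                      arrays, stim, membrane$v_init, cfg$dt, n_windows,
                      sweeps_per_window, steps_per_window, cfg$area_scale,
                      as.integer(soma - 1L)),
      error = function(e) e)
    if (inherits(res, "error")) {
      aborted <- c(aborted, r)
      next
    }
    if (is.null(vs)) {
      times <- res$times
      vs <- matrix(NA_real_, length(times), cfg$n_replicas)
      wc <- matrix(NA_real_, length(res$window_current_pA), cfg$n_replicas)
    }
    vs[, r] <- res$v_soma
    wc[, r] <- res$window_current_pA
  }
  if (length(aborted) > cfg$n_replicas * 0.10)
    stop_ionspike(sprintf("%d of %d replicas diverged", length(aborted),
                          cfg$n_replicas), "ionspike_divergence_error")
  ok <- setdiff(seq_len(cfg$n_replicas), aborted)
  vq <- apply(vs[, ok, drop = FALSE], 1, quantile,
              probs = c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(times = times, v = vs, median = vq[2, ], q1 = vq[1, ],
                 q3 = vq[3, ], window_current = wc, aborted = aborted,
                 cfg = cfg, temperature = gating$temperature_c,
                 soma = soma),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "Coupled ensemble: %d replicas at %.1f C over %.0f ms (%d aborted); median v in [%.1f, %.1f] mV\n",
    ncol(x$v), x$temperature, max(x$times), length(x$aborted),
    min(x$median), max(x$median)))
  invisible(x)
}

#' @export
plot.ensemble_result <- function(x, col = "steelblue", ...) {
  plot(x$times, x$median, type = "n", xlab = "time (ms)", ylab = "v (mV)",
       ylim = range(x$q1, x$q3), ...)
  polygon(c(x$times, rev(x$times)), c(x$q1, rev(x$q3)),
          col = grDevices::adjustcolor(col, 0.3), border = NA)
  lines(x$times, x$median, col = col)
  invisible(x)
}

#' Per-spike repolarization time and peak depolarization
#'
#' For every detected spike: the time from the voltage peak until the trace
#' first returns to within `baseline_band` mV of the pre-stimulus baseline.
#' Spikes whose voltage never returns before the next spike (or the end of
#' the trace) are flagged as right-censored and excluded from means.
#'
#' @param trace A `voltage_trace`, or an `ensemble_result` column wrapped via
#'   `list(times=, v=)`.
#' @param baseline_band Return band around baseline, mV.
#' @param baseline Baseline voltage, mV; if `NULL`, the mean over
#'   `times < baseline_window_ms`.
#' @param baseline_window_ms Window used to estimate the baseline.
#' @param threshold,min_isi Spike detection settings.
#' @param compartment Trace column.
#' @return Data frame with one row per spike: `spike_time`, `peak_time`,
#'   `peak_mV`, `repol_ms` (NA when censored), `censored`.
#' @export
repolarization_time <- function(trace, baseline_band = 5, baseline = NULL,
                                baseline_window_ms = 40, threshold = -20,
                                min_isi = 2, compartment = 1) {
  v <- as.matrix(trace$v)[, compartment]
  t <- trace$times
  st <- detect_spikes(trace, threshold = threshold, min_isi = min_isi,
                      compartment = compartment)
  if (length(st) == 0)
    return(data.frame(spike_time = numeric(0), peak_time = numeric(0),
                      peak_mV = numeric(0), repol_ms = numeric(0),
                      censored = logical(0)))
  if (is.null(baseline)) {
    pre <- v[t < baseline_window_ms]
    baseline <- if (length(pre) > 0) mean(pre) else v[1]
  }
  bounds <- c(st, max(t) + 1e-9)
  out <- lapply(seq_along(st), function(k) {
    win <- which(t >= st[k] & t < bounds[k + 1])
    pk <- win[which.max(v[win])]
    after <- win[win >= pk]
    ret <- after[v[after] <= baseline + baseline_band]
    censored <- length(ret) == 0
    data.frame(spike_time = st[k], peak_time = t[pk], peak_mV = v[pk],
               repol_ms = if (censored) NA_real_ else t[ret[1]] - t[pk],
               censored = censored)
  })
  do.call(rbind, out)
}

#' Passive membrane parameters for the coupled membrane study
#'
#' Leak-only membrane (no intrinsic HH channels): in the coupled runs the
#' voltage-gated Na/K currents come from the Monte Carlo membrane patch, so
#' the cell itself is passive.
#'
#' @param e_leak Leak reversal, mV (the resting potential of the passive
#'   cell).
#' @param ... Passed to [membrane_params()].
#' @return A `membrane_params`.
#' @export
passive_membrane_params <- function(e_leak = -65, ...) {
  membrane_params(hh_densities = list(soma = c(gna = 0, gk = 0),
                                      dendrite = c(gna = 0, gk = 0),
                                      axon = c(gna = 0, gk = 0)),
                  e_leak = e_leak, ...)
}

#' Default configuration of the coupled membrane study
#'
#' The shipped study conditions for the bidirectional coupling experiments:
#' a 40x40 patch with 125 Na and 290 K channels in a 40% unsaturated binary
#' lipid mixture; gating midpoints -46 mV (Na) and -31 mV (K); activated
#' sensors favour unsaturated lipid (-0.3 kT_ref) and are penalized next to
#' saturated lipid (+0.2 kT_ref); a passive soma+dendrite two-compartment
#' cell (10 um soma, 100x1 um dendrite); 80 pA somatic clamp from 50 to
#' 150 ms of a 600 ms run; exchange every 0.5 ms with 2 Monte Carlo sweeps
#' per ms and an area scale of 2. See the methods vignette for how these
#' values were chosen.
#'
#' @param n_replicas Replica count.
#' @param seed Seed for the patch composition.
#' @param t_stop Simulated time, ms.
#' @return List with elements `patch`, `gating`, `grid`, `membrane`, `cfg`.
#' @export
coupled_defaults <- function(n_replicas = 100, seed = 1, t_stop = 600) {
  list(
    patch = build_patch(40, 125, 290, frac_unsaturated = 0.4, seed = seed),
    gating = gating_params(v_half = c(na = -46, k = -31),
                           j_sensor_lipid = matrix(c(0, 0.2, 0, -0.3), 2, 2)),
    grid = two_compartment_grid(10, 100, 1),
    membrane = passive_membrane_params(),
    cfg = coupling_config(n_replicas = n_replicas, t_stop = t_stop))
}

#' Temperature scan of the coupled membrane model
#'
#' Runs [run_coupled()] at each configured temperature with matched seeds,
#' applying the temperature to the Monte Carlo gating energetics (the
#' membrane-patch physics the scan is designed to probe). Set
#' `scan_solver_temperature = TRUE` to also drive the cable solver's q10
#' machinery.
#'
#' @inheritParams run_coupled
#' @param scan_solver_temperature Also set the solver temperature (default
#'   `FALSE`).
#' @param baseline_band Passed to [repolarization_time()].
#' @param threshold Spike threshold, mV; defaults to -30, suited to the
#'   patch-driven spikes of the two-compartment coupled cell, whose peaks sit
#'   lower than intrinsic HH spikes.
#' @return An object of class `temperature_scan`: per-temperature
#'   `ensemble_result`s plus a `summary` data frame with, per temperature:
#'   `median_repol_ms`, the median over replicas of the mean uncensored
#'   per-spike repolarization time (NA when no replica repolarizes);
#'   `median_post_repol_ms`, the median over spiking replicas of the
#'   post-stimulus repolarization (time from clamp offset until the somatic
#'   voltage first re-enters the baseline band; replicas that never return,
#'   e.g. because the membrane latches into its depolarized memory state,
#'   contribute the remaining trace length as a right-censored lower bound);
#'   the median peak depolarization; and censored counts. Under latching the
#'   post-stimulus median is the meaningful (conservative) summary; the
#'   per-spike median only sees the replicas that happened to escape.
#' @export
temperature_scan <- function(patch, gating, grid, membrane, cfg, seed = 1,
                             scan_solver_temperature = FALSE,
                             baseline_band = 5, threshold = -30) {
  if (length(cfg$temperatures) < 1)
    stop_ionspike("no temperatures configured", "ionspike_domain_error")
  results <- list()
  summ <- list()
  for (ti in seq_along(cfg$temperatures)) {
    tc <- cfg$temperatures[ti]
    g_t <- gating
    g_t$temperature_c <- tc
    m_t <- membrane
    if (scan_solver_temperature) m_t$temperature_c <- tc
    ens <- run_coupled(patch, g_t, grid, m_t, cfg, seed = seed)
    rep_mean <- rep(NA_real_, ncol(ens$v))
    post_rep <- rep(NA_real_, ncol(ens$v))
    post_cens <- rep(FALSE, ncol(ens$v))
    peak_rep <- rep(NA_real_, ncol(ens$v))
    censored <- 0L
    for (r in seq_len(ncol(ens$v))) {
      if (anyNA(ens$v[, r])) next
      vr <- ens$v[, r]
      rt <- repolarization_time(list(times = ens$times,
                                     v = ens$v[, r, drop = FALSE]),
                                baseline_band = baseline_band,
                                baseline_window_ms = cfg$clamp_on,
                                threshold = threshold)
      if (nrow(rt) == 0) next
      censored <- censored + sum(rt$censored)
      if (any(!rt$censored)) rep_mean[r] <- mean(rt$repol_ms[!rt$censored])
      peak_rep[r] <- max(rt$peak_mV)
      base <- mean(vr[ens$times < cfg$clamp_on])
      post <- which(ens$times >= cfg$clamp_off)
      ret <- post[vr[post] <= base + baseline_band]
      if (length(ret) > 0) {
        post_rep[r] <- ens$times[ret[1]] - cfg$clamp_off
      } else {
        post_rep[r] <- max(ens$times) - cfg$clamp_off
        post_cens[r] <- TRUE
      }
    }
    results[[ti]] <- ens
    summ[[ti]] <- data.frame(
      temperature_c = tc,
      median_repol_ms = median(rep_mean, na.rm = TRUE),
      median_post_repol_ms = median(post_rep, na.rm = TRUE),
      median_peak_mV = median(peak_rep, na.rm = TRUE),
      replicas_with_spikes = sum(!is.na(post_rep)),
      replicas_censored = sum(post_cens & !is.na(post_rep)),
      censored_events = censored)
  }
  names(results) <- as.character(cfg$temperatures)
  structure(list(results = results, summary = do.call(rbind, summ)),
            class = "temperature_scan")
}

#' @export
print.temperature_scan <- function(x, ...) {
  cat("Temperature scan of the coupled membrane model\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
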