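#' Variant-specific synaptic scaling factor from single-channel conductances
#'
#' The scaling factor is the ratio of a variant's single-channel conductance
#' to that of the baseline (Q/R-edited) form: `G = g_md / g_baseline`. The
#' reporting view rounds half-up to one decimal; a second, coarser rounding
#' (nearest integer with ties down, plus the 28.0 -> 30 convention used for
#' the neuronal runs) is stored alongside.
#'
#' @param g_md Variant single-channel conductance, pS.
#' @param g_baseline Baseline single-channel conductance, pS.
#' @param label Variant name.
#' @return An object of class `variant_scaling` with fields `label`, `g_md`,
#'   `g_baseline`, `G` (exact ratio), `G_1dp` (one-decimal view) and
#'   `G_rounded` (integer view used for simulation sweeps).
#' @examples
#' compute_scaling(10.2, 3.3, "wild-type")$G_1dp # 3.1
#' @export
compute_scaling <- function(g_md, g_baseline, label = "variant") {
  check_scalar(g_md, "g_md", lower = 1e-300)
  check_scalar(g_baseline, "g_baseline", lower = 1e-300)
  G <- g_md / g_baseline
  g1 <- round_half_up(G, 1)
  gi <- floor(g1 + 0.5 - 1e-9)       # nearest integer, ties down
  if (isTRUE(all.equal(g1, 28.0))) gi <- 30
  structure(list(label = label, g_md = g_md, g_baseline = g_baseline,
                 G = G, G_1dp = g1, G_rounded = gi),
            class = "variant_scaling")
}

#' @export
print.variant_scaling <- function(x, ...) {
  cat(sprintf("%s: g_MD = %.2f pS, baseline = %.2f pS, G = %.4f (%.1f; %d)\n",
              x$label, x$g_md, x$g_baseline, x$G, x$G_1dp, x$G_rounded))
  invisible(x)
}

#' Read a variant conductance table
#'
#' Delimited text with columns `label`, `g_md_pS` and a logical `baseline`
#' column flagging the reference row. Returns one [compute_scaling()] result
#' per row, as a data frame.
#'
#' @param path File path (tab- or comma-delimited; autodetected).
#' @return Data frame with columns `label`, `g_md_pS`, `baseline`, `G`,
#'   `G_1dp`, `G_rounded`.
#' @export
read_variant_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "g_md_pS", "baseline") %in% names(tab)))
  base <- tab$g_md_pS[which(tab$baseline)[1]]
  if (is.na(base))
    stop_ionspike("variant table must flag one baseline row",
                  "ionspike_validation_error")
  sc <- lapply(seq_len(nrow(tab)), function(i)
    compute_scaling(tab$g_md_pS[i], base, tab$label[i]))
  tab$G <- vapply(sc, `[[`, numeric(1), "G")
  tab$G_1dp <- vapply(sc, `[[`, numeric(1), "G_1dp")
  tab$G_rounded <- vapply(sc, `[[`, numeric(1), "G_rounded")
  tab
}

#' Double-exponential synapse specification
#'
#' Conductance waveform `g(t) = G * weight * N * sum_events
#' (exp(-(t-e)/tau_decay) - exp(-(t-e)/tau_rise))` where `N` normalizes a
#' single event's peak to 1, so `weight` is the peak conductance of one
#' baseline event and `G` the variant scaling factor.
#'
#' @param compartment Target compartment index.
#' @param weight Synaptic weight (peak conductance per event), uS.
#' @param tau_rise,tau_decay Rise/decay time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param e_rev Synaptic reversal potential, mV (0 for the excitatory
#'   receptor modelled here).
#' @param scaling Variant scaling factor `G` (a number or a
#'   `variant_scaling`).
#' @param events Presynaptic event times, ms.
#' @return An object of class `synapse_spec`.
#' @export
synapse_spec <- function(compartment, weight, tau_rise = 0.2, tau_decay = 1.7,
                         e_rev = 0, scaling = 1, events = numeric(0)) {
  if (inherits(scaling, "variant_scaling")) scaling <- scaling$G
  check_scalar(weight, "weight", lower = 1e-300)
  check_scalar(scaling, "scaling", lower = 1e-300)
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop_ionspike("need tau_decay > tau_rise > 0", "ionspike_domain_error")
  structure(list(compartment = as.integer(compartment), weight = weight,
                 tau_rise = tau_rise, tau_decay = tau_decay, e_rev = e_rev,
                 scaling = scaling, events = as.numeric(events)),
            class = "synapse_spec")
}

#' Evaluate the double-exponential synaptic conductance
#'
#' Closed-form evaluation of the event-summed waveform (linear superposition
#' over events); used for analysis and as the reference for the solver's
#' internal state-variable implementation.
#'
#' @param spec A `synapse_spec`.
#' @param events Event times, ms.
#' @param t Evaluation times, ms (vectorized).
#' @return Conductance in uS, same length as `t`; nonnegative.
#' @examples
#' s <- synapse_spec(1, weight = 1.5)
#' tp <- with(s, tau_rise * tau_decay / (tau_decay - tau_rise) *
#'              log(tau_decay / tau_rise))
#' synaptic_conductance(s, 0, tp) # peak = weight * scaling
#' @export
synaptic_conductance <- function(spec, events, t) {
  stopifnot(inherits(spec, "synapse_spec"))
  tr <- spec$tau_rise; td <- spec$tau_decay
  tp <- tr * td / (td - tr) * log(td / tr)
  nrm <- 1 / (exp(-tp / td) - exp(-tp / tr))
  vapply(t, function(ti) {
    d <- ti - events[events <= ti]
    if (length(d) == 0) return(0)
    max(0, spec$scaling * spec$weight * nrm *
          sum(exp(-d / td) - exp(-d / tr)))
  }, numeric(1))
}

#' Synaptic current from conductance and driving force
#'
#' `I = g * (v - e_rev)` converted from uS*mV (= nA) to pA. With the
#' excitatory reversal at 0 mV and `v < 0` the current is negative
#' (inward), i.e. depolarizing.
#'
#' @param g Conductance, uS.
#' @param v Membrane potential, mV.
#' @param e_rev Reversal potential, mV.
#' @return Current in pA.
#' @export
synaptic_current <- function(g, v, e_rev = 0) {
  if (any(g < 0)) stop_ionspike("conductance must be nonnegative",
                                "ionspike_domain_error")
  g * (v - e_rev) * 1e3
}

dendritic_compartments <- function(grid) {
  which(grid$region == "dendrite")
}

as_grid <- function(x, max_len = 20) {
  if (inherits(x, "compartment_grid")) return(x)
  if (inherits(x, "morphology")) return(discretize(x, max_len))
  stop_ionspike("expected a morphology or compartment_grid",
                "ionspike_validation_error")
}

#' Place synapses on the dendritic tree
#'
#' `place_localized()` picks a random dendritic compartment as the cluster
#' center and samples `n` dendritic compartments whose midpoints lie within
#' `radius` um (Euclidean, 3D) of the center, emulating clustered synaptic
#' input on a dendritic branch; if a chosen center has fewer than `n`
#' candidates the center is redrawn (bounded retries). `place_distributed()`
#' samples `n` dendritic compartments uniformly across the whole tree.
#' Both are deterministic per seed; sampling is with replacement when fewer
#' than `n` distinct candidates exist, without otherwise.
#'
#' @param x A `morphology` or `compartment_grid`.
#' @param n Number of synapse locations (default 10).
#' @param radius Cluster radius, um (default 50).
#' @param seed Integer seed.
#' @param max_attempts Center redraws before giving up.
#' @return Data frame with columns `compartment`, `x`, `y`, `z`, and (for the
#'   localized variant) the chosen `center` compartment as an attribute.
#' @export
place_localized <- function(x, n = 10, radius = 50, seed = 1,
                            max_attempts = 25) {
  grid <- as_grid(x)
  dend <- dendritic_compartments(grid)
  if (length(dend) == 0)
    stop_ionspike("morphology has no dendritic compartments",
                  "ionspike_placement_error")
  with_seed(seed, {
    for (a in seq_len(max_attempts)) {
      center <- dend[sample.int(length(dend), 1)]
      d2 <- (grid$x[dend] - grid$x[center])^2 +
            (grid$y[dend] - grid$y[center])^2 +
            (grid$z[dend] - grid$z[center])^2
      cand <- dend[d2 <= radius^2]
      if (length(cand) >= n) {
        pick <- cand[sample.int(length(cand), n)]
        out <- data.frame(compartment = pick, x = grid$x[pick],
                          y = grid$y[pick], z = grid$z[pick])
        attr(out, "center") <- center
        return(out)
      }
    }
    stop_ionspike(sprintf(
      "no dendritic cluster of %d compartments within %.0f um after %d attempts",
      n, radius, max_attempts), "ionspike_placement_error")
  })
}

#' @rdname place_localized
#' @export
place_distributed <- function(x, n = 10, seed = 1) {
  grid <- as_grid(x)
  dend <- dendritic_compartments(grid)
  if (length(dend) == 0)
    stop_ionspike("morphology has no dendritic compartments",
                  "ionspike_placement_error")
  if (n == 0)
    return(data.frame(compartment = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0)))
  with_seed(seed, {
    pick <- if (length(dend) >= n) dend[sample.int(length(dend), n)]
            else dend[sample.int(length(dend), n, replace = TRUE)]
    data.frame(compartment = pick, x = grid$x[pick], y = grid$y[pick],
               z = grid$z[pick])
  })
}

#' Generate Poisson presynaptic spike trains
#'
#' Homogeneous Poisson event times on `[0, duration)`. Correlated input
#' copies one train to all synapses (perfectly synchronous ensemble);
#' uncorrelated input draws independent trains.
#'
#' @param rate Event rate, Hz.
#' @param duration Train duration, ms.
#' @param n Number of synapses/trains.
#' @param correlated Logical.
#' @param seed Integer seed.
#' @return An object of class `input_ensemble`: list with `trains` (list of
#'   sorted event-time vectors, ms), `rate`, `correlated`, `duration`,
#'   `seed`.
#' @export
generate_trains <- function(rate = 10, duration, n, correlated = FALSE,
                            seed = 1) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate < 0)
    stop_ionspike("`rate` must be a nonnegative rate in Hz",
                  "ionspike_domain_error")
  check_scalar(duration, "duration", lower = 0)
  one <- function() {
    if (rate == 0) return(numeric(0))
    # expected count + slack; extend if undershooting
    t <- cumsum(rexp(max(10, ceiling(rate * duration / 1000 * 1.5 + 20)),
                     rate = rate / 1000))
    while (length(t) > 0 && t[length(t)] < duration)
      t <- c(t, t[length(t)] + cumsum(rexp(50, rate = rate / 1000)))
    t[t < duration]
  }
  trains <- with_seed(seed, {
    if (correlated) rep(list(one()), n) else replicate(n, one(), simplify = FALSE)
  })
  structure(list(trains = trains, rate = rate, correlated = correlated,
                 duration = duration, seed = seed),
            class = "input_ensemble")
}

#' @export
print.input_ensemble <- function(x, ...) {
  cat(sprintf("Input ensemble: %d %s Poisson trains at %.1f Hz over %.0f ms (mean %.1f events)\n",
              length(x$trains), if (x$correlated) "correlated" else "independent",
              x$rate, x$duration, mean(lengths(x$trains))))
  invisible(x)
}

#' Run a spike-count experiment for one receptor variant
#'
#' Composes synapse placement, Poisson input, variant-scaled
#' double-exponential synapses, the cable solver, and spike detection.
#' Fully reproducible per seed.
#'
#' @param grid A `compartment_grid` (or `morphology`).
#' @param params A `membrane_params`.
#' @param scaling Scaling factor `G` (number or `variant_scaling`).
#' @param placement `"localized"` or `"distributed"`.
#' @param correlated Logical, input correlation.
#' @param weight Synaptic weight, uS.
#' @param duration Simulated time, ms.
#' @param seed Integer seed (placement uses `seed`, trains `seed + 1`).
#' @param rate Input rate, Hz.
#' @param n_syn Number of synapses (default 10).
#' @param radius Cluster radius for localized placement, um.
#' @param tau_rise,tau_decay Synaptic kinetics, ms.
#' @param e_syn Synaptic reversal, mV.
#' @param dt Solver step, ms.
#' @param threshold,min_isi Spike detection settings.
#' @return List of class `variant_experiment`: `trace` (somatic
#'   `voltage_trace`), `spike_count`, `spike_times`, `locations`, `input`.
#' @export
run_variant_experiment <- function(grid, params, scaling = 1,
                                   placement = c("localized", "distributed"),
                                   correlated = FALSE, weight = 1.5,
                                   duration = 1000, seed = 1, rate = 10,
                                   n_syn = 10, radius = 50,
                                   tau_rise = 0.2, tau_decay = 1.7, e_syn = 0,
                                   dt = 0.025, threshold = -20, min_isi = 2) {
  placement <- match.arg(placement)
  grid <- as_grid(grid)
  if (inherits(scaling, "variant_scaling")) scaling <- scaling$G
  loc <- if (placement == "localized")
    place_localized(grid, n = n_syn, radius = radius, seed = seed)
  else place_distributed(grid, n = n_syn, seed = seed)
  ens <- generate_trains(rate, duration, n_syn, correlated, seed = seed + 1)
  syns <- lapply(seq_len(n_syn), function(i)
    synapse_spec(loc$compartment[i], weight = weight, tau_rise = tau_rise,
                 tau_decay = tau_decay, e_rev = e_syn, scaling = scaling,
                 events = ens$trains[[i]]))
  trace <- run_cable(grid, params, synapses = syns, t_stop = duration,
                     dt = dt, record = "soma")
  st <- detect_spikes(trace, threshold = threshold, min_isi = min_isi)
  structure(list(trace = trace, spike_count = length(st), spike_times = st,
                 locations = loc, input = ens, scaling = scaling,
                 placement = placement, weight = weight, seed = seed),
            class = "variant_experiment")
}

#' @export
print.variant_experiment <- function(x, ...) {
  cat(sprintf("Variant experiment: G = %.2f, %s %s input, weight %.4g uS -> %d spike(s)\n",
              x$scaling, if (x$input$correlated) "correlated" else "uncorrelated",
              x$placement, x$weight, x$spike_count))
  invisible(x)
}

#' Calibrate the baseline synaptic weight
#'
#' Bisection on the synaptic weight for the largest weight (within a
#' relative tolerance) at which the baseline variant (`G = 1`) fires no
#' spikes under uncorrelated Poisson input, while a strong gain-of-function
#' probe (`G = G_probe`) at the same weight fires at least one spike. This
#' establishes the threshold baseline against which variant gain-of-function
#' is measured.
#'
#' @param grid A `compartment_grid` (or `morphology`).
#' @param params A `membrane_params`.
#' @param duration Simulated time per probe run, ms.
#' @param seed Integer seed (fixed across bisection steps).
#' @param G_probe Probe scaling factor (> 1).
#' @param placement,rate,n_syn,radius Passed to [run_variant_experiment()].
#' @param bracket Weight search bracket, uS.
#' @param tol Relative bisection tolerance on the weight.
#' @return The calibrated weight (uS), with attributes `spikes_baseline` and
#'   `spikes_probe`.
#' @export
calibrate_baseline_weight <- function(grid, params, duration = 1000, seed = 1,
                                      G_probe = 30,
                                      placement = "distributed", rate = 10,
                                      n_syn = 10, radius = 50,
                                      bracket = c(1e-5, 1.5), tol = 0.05) {
  if (G_probe <= 1)
    stop_ionspike("`G_probe` must exceed 1", "ionspike_domain_error")
  grid <- as_grid(grid)
  spikes_at <- function(w, G)
    run_variant_experiment(grid, params, scaling = G, placement = placement,
                           correlated = FALSE, weight = w, duration = duration,
                           seed = seed, rate = rate, n_syn = n_syn,
                           radius = radius)$spike_count
  lo <- bracket[1]; hi <- bracket[2]
  if (spikes_at(lo, 1) > 0)
    stop_ionspike("baseline fires even at the lower bracket; widen `bracket`",
                  "ionspike_calibration_error")
  if (spikes_at(hi, 1) == 0) {
    lo <- hi
  } else {
    while ((hi - lo) / lo > tol) {
      mid <- sqrt(lo * hi)
      if (spikes_at(mid, 1) == 0) lo <- mid else hi <- mid
    }
  }
  nb <- spikes_at(lo, 1)
  np <- spikes_at(lo, G_probe)
  if (nb != 0 || np < 1)
    stop_ionspike(sprintf(
      "calibration failed: baseline %d spike(s), probe %d spike(s) at weight %.4g uS",
      nb, np, lo), "ionspike_calibration_error")
  structure(lo, spikes_baseline = nb, spikes_probe = np)
}
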