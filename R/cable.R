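#' Membrane and integration parameters for the cable solver
#'
#' Specific (per-area) electrical properties plus the Hodgkin-Huxley
#' mechanism configuration. The active mechanism is the classic squid Na/K
#' model on the modern voltage scale (rest ~ -65 mV), with per-region maximal
#' densities and a q10 temperature factor on the rate functions.
#'
#' @param c_m Specific membrane capacitance, uF/cm^2.
#' @param r_a Axial resistivity, Ohm*cm.
#' @param g_leak Specific leak conductance, S/cm^2.
#' @param e_leak Leak reversal potential, mV.
#' @param hh_densities Named list per region of `c(gna=, gk=)` maximal
#'   conductances in S/cm^2; regions absent from the list are passive.
#' @param e_na,e_k Na/K reversal potentials, mV.
#' @param v_init Initial membrane potential, mV (default -65).
#' @param temperature_c Solver temperature, degrees C.
#' @param q10 Rate scaling per 10 degrees C.
#' @param t_base Temperature at which the rate functions are tabulated.
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(c_m = 1, r_a = 100, g_leak = 3e-4, e_leak = -54.3,
                            hh_densities = list(
                              soma = c(gna = 0.12, gk = 0.036),
                              axon = c(gna = 0.12, gk = 0.036),
                              dendrite = c(gna = 0, gk = 0)),
                            e_na = 50, e_k = -77,
                            v_init = -65, temperature_c = 6.3, q10 = 3,
                            t_base = 6.3) {
  check_scalar(c_m, "c_m", lower = 1e-12)
  check_scalar(r_a, "r_a", lower = 1e-12)
  check_scalar(g_leak, "g_leak", lower = 0)
  structure(list(c_m = c_m, r_a = r_a, g_leak = g_leak, e_leak = e_leak,
                 hh_densities = hh_densities, e_na = e_na, e_k = e_k,
                 v_init = v_init, temperature_c = temperature_c, q10 = q10,
                 t_base = t_base),
            class = "membrane_params")
}

#' Discretize a morphology into control volumes
#'
#' Splits each segment into `ceiling(length / max_len)` compartments (soma
#' segments always form a single compartment), computing frustum lateral
#' areas and axial conductances from the geometry. Total membrane area is
#' conserved exactly relative to the analytic frustum area. Compartments are
#' ordered parents-first (Hines order).
#'
#' @param morph A `morphology`.
#' @param max_len Maximum compartment length, um.
#' @return An object of class `compartment_grid`: a data frame with one row
#'   per compartment (columns `comp`, `parent` (0 for the root), `segment`,
#'   `region`, `x`, `y`, `z` midpoints, `length`, `area_um2` and `r_frac`,
#'   the geometric factor `4 L / (pi d0 d1)` from which the axial conductance
#'   to the parent is computed once an axial resistivity is supplied).
#' @examples
#' g <- discretize(make_ball_and_stick(20, 200, 2), max_len = 10)
#' nrow(g) # 1 soma + 20 dendrite compartments
#' @export
discretize <- function(morph, max_len = 20) {
  stopifnot(inherits(morph, "morphology"))
  check_scalar(max_len, "max_len", lower = 1e-9)
  validate_morphology(morph)
  lens <- segment_lengths(morph)
  seg_rows <- seq_len(nrow(morph))
  # process segments parents-first
  order_out <- integer(0)
  remaining <- seg_rows
  done <- logical(nrow(morph))
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(i) {
      p <- morph$parent[i]
      p == -1 || done[which(morph$id == p)]
    }, logical(1))]
    order_out <- c(order_out, ready)
    done[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  comp <- list()
  seg_last_comp <- integer(nrow(morph)) # index of distal compartment
  seg_half_r <- numeric(0)              # half axial resistance per compartment
  n <- 0L
  for (i in order_out) {
    L <- lens[i]
    nsub <- if (morph$region[i] == "soma") 1L else as.integer(ceiling(L / max_len))
    f <- seq(0, 1, length.out = nsub + 1)
    xs <- morph$x0[i] + f * (morph$x1[i] - morph$x0[i])
    ys <- morph$y0[i] + f * (morph$y1[i] - morph$y0[i])
    zs <- morph$z0[i] + f * (morph$z1[i] - morph$z0[i])
    ds <- morph$d0[i] + f * (morph$d1[i] - morph$d0[i])
    pseg <- morph$parent[i]
    prev_comp <- if (pseg == -1) 0L else seg_last_comp[which(morph$id == pseg)]
    for (k in seq_len(nsub)) {
      n <- n + 1L
      l <- L / nsub
      da <- ds[k]; db <- ds[k + 1]
      slant <- sqrt(l^2 + ((db - da) / 2)^2)
      area <- pi * (da + db) / 2 * slant
      # frustum axial resistance: R = 4 * r_a * l / (pi * da * db), Ohm with
      # r_a in Ohm*um (conversion applied in build_cable_arrays)
      raxial <- 4 * l / (pi * da * db)
      comp[[n]] <- data.frame(
        comp = n, parent = prev_comp, segment = morph$id[i],
        region = morph$region[i],
        x = (xs[k] + xs[k + 1]) / 2, y = (ys[k] + ys[k + 1]) / 2,
        z = (zs[k] + zs[k + 1]) / 2,
        length = l, area_um2 = area, r_frac = raxial)
      prev_comp <- n
    }
    seg_last_comp[i] <- n
  }
  g <- do.call(rbind, comp)
  structure(g, class = c("compartment_grid", "data.frame"),
            morphology = morph, max_len = max_len)
}

#' @export
print.compartment_grid <- function(x, ...) {
  cat(sprintf("Compartment grid: %d compartments (%s), total area %.1f um^2\n",
              nrow(x),
              paste(sprintf("%d %s", table(x$region), names(table(x$region))),
                    collapse = ", "),
              sum(x$area_um2)))
  invisible(x)
}

# Per-compartment arrays (nF, uS) for the compiled stepper.
build_cable_arrays <- function(grid, params) {
  stopifnot(inherits(grid, "compartment_grid"),
            inherits(params, "membrane_params"))
  area <- grid$area_um2
  cap_nF <- params$c_m * area * 1e-5       # uF/cm^2 * um^2 -> nF
  gl_uS <- params$g_leak * area * 1e-2     # S/cm^2 * um^2 -> uS
  dens <- function(region, what) {
    d <- params$hh_densities[[region]]
    if (is.null(d)) 0 else unname(d[[what]])
  }
  gna <- vapply(grid$region, dens, numeric(1), what = "gna") * area * 1e-2
  gk <- vapply(grid$region, dens, numeric(1), what = "gk") * area * 1e-2
  # axial: r_a Ohm*cm = 1e4 Ohm*um; R_Ohm = r_frac * r_a * 1e4;
  # conductance between midpoints = 1 / (R_child/2 + R_parent/2), in uS
  r_ohm <- grid$r_frac * params$r_a * 1e4
  gax <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$parent[i]
    if (p > 0) gax[i] <- 1e6 / (r_ohm[i] / 2 + r_ohm[p] / 2)
  }
  phi <- params$q10^((params$temperature_c - params$t_base) / 10)
  list(parent = as.integer(grid$parent - 1L), cap_nF = cap_nF,
       g_leak_uS = gl_uS, e_leak = rep(params$e_leak, nrow(grid)),
       g_na_uS = gna, g_k_uS = gk, g_ax_uS = gax,
       e_na = params$e_na, e_k = params$e_k, phi = phi)
}

#' Stimuli for the cable solver
#'
#' `stim_clamp()` injects a constant current into one compartment during a
#' time window; `stim_series()` injects a piecewise-constant current sampled
#' at a fixed interval (the form used to feed Monte Carlo patch currents into
#' the solver); `stim_conductance()` attaches a static point conductance with
#' its own reversal potential.
#'
#' @param compartment Target compartment (1-based row of the grid).
#' @param amp_pA Clamp amplitude, pA.
#' @param onset,offset Clamp window, ms (`offset > onset`).
#' @param t0 Start time of a series, ms.
#' @param dt Sample spacing of a series, ms.
#' @param values_pA Piecewise-constant current samples, pA.
#' @param g_uS Static conductance, uS.
#' @param e_rev Reversal potential of the static conductance, mV.
#' @return A stimulus object understood by [run_cable()].
#' @export
stim_clamp <- function(compartment, amp_pA, onset, offset) {
  if (offset <= onset)
    stop_ionspike("`offset` must exceed `onset`", "ionspike_domain_error")
  structure(list(kind = "clamp", comp = as.integer(compartment),
                 amp_pA = amp_pA, onset = onset, offset = offset),
            class = "cable_stimulus")
}

#' @rdname stim_clamp
#' @export
stim_series <- function(compartment, t0, dt, values_pA) {
  check_scalar(dt, "dt", lower = 1e-12)
  structure(list(kind = "series", comp = as.integer(compartment), t0 = t0,
                 dt = dt, values_pA = as.numeric(values_pA)),
            class = "cable_stimulus")
}

#' @rdname stim_clamp
#' @export
stim_conductance <- function(compartment, g_uS, e_rev) {
  check_scalar(g_uS, "g_uS", lower = 0)
  structure(list(kind = "conductance", comp = as.integer(compartment),
                 g_uS = g_uS, e_rev = e_rev), class = "cable_stimulus")
}

split_stimuli <- function(stimuli, synapses, n_comp) {
  clamps <- list(); series <- list(); statics <- list(); syns <- list()
  for (s in stimuli) {
    if (!inherits(s, "cable_stimulus"))
      stop_ionspike("stimuli must be built with stim_*()",
                    "ionspike_validation_error")
    if (s$comp < 1 || s$comp > n_comp)
      stop_ionspike("stimulus targets a nonexistent compartment",
                    "ionspike_validation_error")
    comp0 <- s$comp - 1L
    if (s$kind == "clamp")
      clamps[[length(clamps) + 1]] <- list(comp = comp0,
                                           amp_nA = s$amp_pA * 1e-3,
                                           onset = s$onset, offset = s$offset)
    else if (s$kind == "series")
      series[[length(series) + 1]] <- list(comp = comp0, t0 = s$t0, dt = s$dt,
                                           values_nA = s$values_pA * 1e-3)
    else
      statics[[length(statics) + 1]] <- list(comp = comp0, g_uS = s$g_uS,
                                             e_rev = s$e_rev)
  }
  for (s in synapses) {
    stopifnot(inherits(s, "synapse_spec"))
    syns[[length(syns) + 1]] <- list(
      comp = s$compartment - 1L, e_rev = s$e_rev,
      g_peak_uS = s$weight * s$scaling,
      tau_rise = s$tau_rise, tau_decay = s$tau_decay,
      events = as.numeric(sort(s$events)))
  }
  list(clamps = clamps, series = series, statics = statics, synapses = syns)
}

#' Integrate the cable equation on a compartment grid
#'
#' Advances `C dv/dt = -I_leak - I_HH - I_syn + I_inj + I_axial` with
#' backward-Euler steps solved exactly for the linearized system by a
#' tree-ordered (Hines) elimination; HH gate variables advance by exponential
#' integration of their rate equations, with rates scaled by
#' `q10^((T - T_base)/10)`.
#'
#' @param grid A `compartment_grid`.
#' @param params A `membrane_params`.
#' @param stimuli List of stimuli from [stim_clamp()], [stim_series()],
#'   [stim_conductance()].
#' @param synapses List of [synapse_spec()] objects carrying event times.
#' @param t_stop Simulated time, ms (0 gives a single sample at `v_init`).
#' @param dt Step, ms.
#' @param record Compartments to record: indices, or `"soma"` (first somatic
#'   compartment) or `"all"`.
#' @param record_every Record every this many steps.
#' @return A `voltage_trace`: list with `times` (ms), `v` (matrix, time x
#'   recorded compartment), `record` indices, `dt`.
#' @examples
#' g <- discretize(make_ball_and_stick(), max_len = 200)
#' tr <- run_cable(g, membrane_params(),
#'                 stimuli = list(stim_clamp(1, 80, 100, 400)),
#'                 t_stop = 500)
#' length(detect_spikes(tr))
#' @export
run_cable <- function(grid, params, stimuli = list(), synapses = list(),
                      t_stop, dt = 0.025, record = "soma", record_every = 1) {
  stopifnot(inherits(grid, "compartment_grid"),
            inherits(params, "membrane_params"))
  check_scalar(t_stop, "t_stop", lower = 0)
  check_scalar(dt, "dt", lower = 1e-9)
  arrays <- build_cable_arrays(grid, params)
  rec <- resolve_record(record, grid)
  stim <- split_stimuli(stimuli, synapses, nrow(grid))
  n_steps <- as.integer(round(t_stop / dt))
  out <- cpp_cable_run(arrays, stim, params$v_init, dt, n_steps,
                       as.integer(rec - 1L), as.integer(record_every))
  structure(list(times = out$times, v = out$v, record = rec, dt = dt,
                 v_final = out$v_final),
            class = "voltage_trace")
}

resolve_record <- function(record, grid) {
  if (identical(record, "soma")) {
    rec <- which(grid$region == "soma")[1]
    if (is.na(rec)) rec <- 1L
  } else if (identical(record, "all")) {
    rec <- seq_len(nrow(grid))
  } else rec <- as.integer(record)
  if (any(rec < 1 | rec > nrow(grid)))
    stop_ionspike("record indices out of range", "ionspike_validation_error")
  rec
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("Voltage trace: %d samples over %.1f ms, %d compartment(s); v in [%.1f, %.1f] mV\n",
              length(x$times), max(x$times), ncol(x$v), min(x$v), max(x$v)))
  invisible(x)
}

#' @export
plot.voltage_trace <- function(x, compartment = 1, ...) {
  matplot(x$times, x$v[, compartment, drop = FALSE], type = "l", lty = 1,
          xlab = "time (ms)", ylab = "v (mV)", ...)
  invisible(x)
}

#' Detect spikes as threshold crossings with a refractory rule
#'
#' Upward crossings of `threshold`; crossings closer than `min_isi` to the
#' previously accepted spike are suppressed. The biological initiation
#' threshold in pyramidal neurons sits around -53..-45 mV; the default
#' counting criterion of -20 mV with a 2 ms refractory window avoids
#' double-counting noisy spike shoulders.
#'
#' @param trace A `voltage_trace` (or a list with `times` and `v`).
#' @param threshold Detection threshold, mV.
#' @param min_isi Minimum inter-spike interval, ms.
#' @param compartment Column of `trace$v` to use.
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, threshold = -20, min_isi = 2,
                          compartment = 1) {
  v <- as.matrix(trace$v)[, compartment]
  t <- trace$times
  if (length(v) < 2) return(numeric(0))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  out <- numeric(0)
  last <- -Inf
  for (i in up) {
    if (t[i] - last >= min_isi) {
      out <- c(out, t[i])
      last <- t[i]
    }
  }
  out
}

#' Write a voltage trace as delimited text with JSON metadata
#'
#' @param trace A `voltage_trace`.
#' @param path Output path (tab-delimited `time_ms`, `v_mV` columns); JSON
#'   metadata goes to `paste0(path, ".json")` when jsonlite is available.
#' @param meta Optional named list merged into the metadata record.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, meta = list()) {
  tab <- data.frame(time_ms = trace$times, trace$v)
  names(tab)[-1] <- paste0("v_mV_comp", trace$record)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(c(list(dt = trace$dt, n = length(trace$times)), meta),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
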