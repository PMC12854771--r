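#' Gating and interaction parameters for the lattice membrane model
#'
#' Collects every energetic and kinetic parameter of the coarse-grained
#' membrane-patch model: the "gating" term (intrinsic sensor activation energy
#' and effective gating charge, i.e. the voltage sensitivity), the
#' "interaction" term (nearest-neighbour couplings between lipids and between
#' voltage sensors and the lipid they face), the thermodynamic state
#' (temperature, membrane potential) and the single-channel electrical
#' parameters used to convert open-channel counts into a current.
#'
#' All energies are in units of `k_B * T_ref` with `T_ref = 303.15` K. The
#' activation energy `eps_g` is, by default, derived from a half-activation
#' voltage via `eps_g = q_gate * v_half * fv_per_mv()`, so that in the
#' zero-coupling limit a single sensor activates with probability 1/2 at
#' `v_m = v_half`.
#'
#' @param temperature_c Simulation temperature, degrees Celsius.
#' @param v_m Membrane potential, mV.
#' @param q_gate Effective gating charge per sensor, units of `e0`; named
#'   vector `c(na=, k=)`.
#' @param v_half Half-activation voltage per selectivity, mV (used only when
#'   `eps_g` is `NULL`).
#' @param eps_g Sensor activation energy per selectivity, `k_B*T_ref`;
#'   overrides `v_half` when supplied.
#' @param j_lipid Symmetric 2x2 lipid-lipid coupling matrix over
#'   (saturated, unsaturated) pairs, `k_B*T_ref`. The default
#'   (like pairs -0.45, unlike +0.45) places the binary mixture's demixing
#'   point inside the 20-40 C window (see the methods vignette).
#' @param j_sensor_lipid 2x2 coupling between a sensor state (rows: resting,
#'   activated) and the lipid species it faces (columns: saturated,
#'   unsaturated), `k_B*T_ref`.
#' @param j_sensor_sensor Optional coupling between activated sensor pairs
#'   within one channel, `k_B*T_ref`; default 0 (channels are allosteric only
#'   through the all-four-activated conduction rule).
#' @param gamma Single-channel conductance per selectivity, pS.
#' @param e_rev Reversal potential per selectivity, mV.
#' @param move_mix Probabilities of the four Monte Carlo move types
#'   (sensor flip, lipid swap, channel translate, channel rotate); must sum
#'   to 1.
#'
#' @return An object of class `gating_params`.
#' @examples
#' p <- gating_params(v_m = -40)
#' p$eps_g
#' @export
gating_params <- function(temperature_c = 30,
                          v_m = -65,
                          q_gate = c(na = 1.5, k = 1.5),
                          v_half = c(na = -45, k = -35),
                          eps_g = NULL,
                          j_lipid = matrix(c(-0.45, 0.45, 0.45, -0.45), 2, 2),
                          j_sensor_lipid = matrix(c(0, 0.1, 0, -0.3), 2, 2),
                          j_sensor_sensor = 0,
                          gamma = c(na = 20, k = 20),
                          e_rev = c(na = 50, k = -77),
                          move_mix = c(sensor = 0.5, swap = 0.3,
                                       translate = 0.15, rotate = 0.05)) {
  check_scalar(temperature_c, "temperature_c", lower = -273.15 + 1e-9)
  check_scalar(v_m, "v_m")
  if (is.null(eps_g)) eps_g <- q_gate * v_half * fv_per_mv()
  stopifnot(length(eps_g) == 2, length(q_gate) == 2, length(gamma) == 2,
            length(e_rev) == 2)
  if (!isTRUE(all.equal(dim(j_lipid), c(2L, 2L))) ||
      !isTRUE(all.equal(j_lipid, t(j_lipid))))
    stop_ionspike("`j_lipid` must be a symmetric 2x2 matrix",
                  "ionspike_domain_error")
  if (!isTRUE(all.equal(dim(j_sensor_lipid), c(2L, 2L))))
    stop_ionspike("`j_sensor_lipid` must be a 2x2 matrix",
                  "ionspike_domain_error")
  if (length(move_mix) != 4 || any(move_mix < 0) ||
      abs(sum(move_mix) - 1) > 1e-8)
    stop_ionspike("`move_mix` must be 4 nonnegative probabilities summing to 1",
                  "ionspike_domain_error")
  structure(list(
    temperature_c = temperature_c, v_m = v_m,
    q_gate = unname(q_gate), eps_g = unname(eps_g),
    j_lipid = j_lipid, j_sensor_lipid = j_sensor_lipid,
    j_sensor_sensor = j_sensor_sensor,
    gamma = unname(gamma), e_rev = unname(e_rev),
    move_mix = unname(move_mix)), class = "gating_params")
}

#' @export
print.gating_params <- function(x, ...) {
  cat("Lattice gating parameters\n")
  cat(sprintf("  T = %.1f C, v_m = %.1f mV\n", x$temperature_c, x$v_m))
  cat(sprintf("  q_gate (Na,K) = (%.2f, %.2f) e0; eps_g = (%.3f, %.3f) kT_ref\n",
              x$q_gate[1], x$q_gate[2], x$eps_g[1], x$eps_g[2]))
  cat(sprintf("  gamma = (%.1f, %.1f) pS; E_rev = (%.1f, %.1f) mV\n",
              x$gamma[1], x$gamma[2], x$e_rev[1], x$e_rev[2]))
  cat(sprintf("  move mix (flip, swap, translate, rotate) = (%s)\n",
              paste(format(x$move_mix), collapse = ", ")))
  invisible(x)
}

# convert params to the list layout the compiled code expects
mc_par_list <- function(params) {
  list(eps_g = params$eps_g, q_gate = params$q_gate,
       j_lipid = params$j_lipid, j_sensor_lipid = params$j_sensor_lipid,
       j_sensor_sensor = params$j_sensor_sensor,
       temperature_c = params$temperature_c, v_m = params$v_m,
       gamma = params$gamma, e_rev = params$e_rev,
       move_mix = params$move_mix)
}

#' Assemble a membrane patch on a square lattice
#'
#' Places `n_na` sodium-selective and `n_k` potassium-selective channels
#' uniformly at random (without overlap) on an `L x L` periodic square
#' lattice and fills the remaining sites with a binary lipid mixture at the
#' requested unsaturated fraction (largest-remainder rounding). All voltage
#' sensors start in the resting state; channel orientations are random.
#'
#' Site codes in the returned grid: 0 saturated lipid, 1 unsaturated lipid,
#' `k + 2` the channel with (1-based) registry row `k + 1`. Coordinates in the
#' channel registry are 0-based lattice indices.
#'
#' @param L Lattice side length.
#' @param n_na,n_k Number of Na- and K-selective channels.
#' @param frac_unsaturated Fraction of lipid sites that are unsaturated, in
#'   \[0, 1\].
#' @param seed Integer seed; identical `(L, n_na, n_k, frac_unsaturated,
#'   seed)` give identical patches, and the patch carries its own random
#'   stream for all subsequent Monte Carlo moves.
#' @return An object of class `membrane_patch`.
#' @examples
#' p <- build_patch(20, n_na = 5, n_k = 5, frac_unsaturated = 0.5, seed = 7)
#' table(p$grid[p$grid < 2])
#' @export
build_patch <- function(L, n_na, n_k, frac_unsaturated = 0.5, seed = 1) {
  if (!is_count(L) || L < 1)
    stop_ionspike("`L` must be a positive integer", "ionspike_domain_error")
  if (!is_count(n_na) || !is_count(n_k))
    stop_ionspike("channel counts must be nonnegative integers",
                  "ionspike_domain_error")
  if (n_na + n_k > L * L)
    stop_ionspike(sprintf("lattice overfull: %d channels on %d sites",
                          n_na + n_k, L * L), "ionspike_capacity_error")
  if (!is.numeric(frac_unsaturated) || length(frac_unsaturated) != 1 ||
      is.na(frac_unsaturated) || frac_unsaturated < 0 || frac_unsaturated > 1)
    stop_ionspike("`frac_unsaturated` must be in [0, 1]",
                  "ionspike_domain_error")
  ncha <- n_na + n_k
  nsite <- L * L
  nlip <- nsite - ncha
  n_unsat <- floor(frac_unsaturated * nlip + 0.5)
  built <- with_seed(seed, {
    sites <- sample.int(nsite, ncha)
    occ <- integer(nsite)                  # grid codes; lattice idx = x + y*L + 1
    occ[sites] <- seq_len(ncha) + 1L       # registry row r -> code r + 1
    lipid_sites <- which(occ == 0L)
    unsat <- lipid_sites[sample.int(nlip, n_unsat)]
    occ[unsat] <- 1L
    list(grid = matrix(occ, L, L),
         channels = list(
           sel = c(rep(0L, n_na), rep(1L, n_k)),
           x = as.integer((sites - 1L) %% L),
           y = as.integer((sites - 1L) %/% L),
           orient = as.integer(sample(0:3, ncha, replace = TRUE)),
           sensors = matrix(0L, ncha, 4)))
  })
  structure(list(
    L = L, grid = built$grid, channels = built$channels,
    counts = c(n_na = n_na, n_k = n_k, n_sat = nlip - n_unsat,
               n_unsat = n_unsat),
    rng = cpp_rng_init(as.integer(seed)),
    build = list(L = L, n_na = n_na, n_k = n_k,
                 frac_unsaturated = frac_unsaturated, seed = seed)),
    class = "membrane_patch")
}

#' @export
print.membrane_patch <- function(x, ...) {
  no <- count_open(x)
  cat(sprintf("Membrane patch %dx%d: %d Na + %d K channels (%d/%d open), %d sat + %d unsat lipids\n",
              x$L, x$L, x$counts["n_na"], x$counts["n_k"], no[1], no[2],
              x$counts["n_sat"], x$counts["n_unsat"]))
  invisible(x)
}

#' Total Hamiltonian of a membrane patch
#'
#' Sums the gating term (per activated sensor, `eps_g - q_gate * v_m * F_v`)
#' and the interaction term (nearest-neighbour couplings: lipid-lipid via
#' `j_lipid`, channel-lipid via `j_sensor_lipid` indexed by the state of the
#' sensor facing that neighbour; each unordered pair counted once). Units:
#' `k_B * T_ref`.
#'
#' @param patch A `membrane_patch`.
#' @param params A `gating_params`.
#' @return Energy in `k_B*T_ref` units.
#' @export
total_energy <- function(patch, params) {
  stopifnot(inherits(patch, "membrane_patch"), inherits(params, "gating_params"))
  cpp_total_energy(patch$grid, patch$channels, patch$rng, mc_par_list(params))
}

#' Run Metropolis Monte Carlo sweeps on a membrane patch
#'
#' Each sweep performs `L^2` attempted moves. A move type is drawn from
#' `params$move_mix`: sensor flip, Kawasaki lipid swap, channel translation
#' into a neighbouring lipid site, or channel rotation by +/-90 degrees.
#' Moves are accepted with the Metropolis probability
#' `min(1, exp(-dH * T_ref / T))`; proposals that would break the lattice
#' invariants (e.g. translating onto another channel) count as attempted and
#' rejected. Composition is conserved exactly.
#'
#' @param patch A `membrane_patch`.
#' @param params A `gating_params`.
#' @param n_sweeps Number of sweeps.
#' @param record_every Record observables every this many sweeps (0 = none).
#' @param record_sensors Also record the sensor bitmask of the first channel
#'   (used by exact-enumeration checks).
#' @return A list with the updated `patch` and a data frame `obs` with columns
#'   sweep, n_open_na, n_open_k, current_pA, energy, n_sensors_active
#'   (and optionally sensors0).
#' @examples
#' p <- build_patch(10, 2, 2, 0.5, seed = 1)
#' r <- mc_run(p, gating_params(v_m = -30), n_sweeps = 50)
#' tail(r$obs, 3)
#' @export
mc_run <- function(patch, params, n_sweeps, record_every = 1,
                   record_sensors = FALSE) {
  stopifnot(inherits(patch, "membrane_patch"), inherits(params, "gating_params"))
  if (!is_count(n_sweeps))
    stop_ionspike("`n_sweeps` must be a nonnegative integer",
                  "ionspike_domain_error")
  out <- cpp_mc_run(patch$grid, patch$channels, patch$rng, mc_par_list(params),
                    as.integer(n_sweeps), as.integer(record_every),
                    isTRUE(record_sensors))
  newp <- patch
  newp$grid <- out$grid
  newp$channels <- out$channels
  newp$rng <- out$rng
  newp$energy <- out$energy
  obs <- as.data.frame(out$obs)
  names(obs) <- c("sweep", "n_open_na", "n_open_k", "current_pA", "energy",
                  "n_sensors_active",
                  if (isTRUE(record_sensors)) "sensors0")
  list(patch = newp, obs = obs)
}

#' @rdname mc_run
#' @export
mc_sweep <- function(patch, params) {
  r <- mc_run(patch, params, n_sweeps = 1, record_every = 1)
  list(patch = r$patch, observables = r$obs[1, ])
}

#' Count conducting (open) channels per selectivity
#'
#' A channel conducts if and only if all four of its voltage sensors are
#' activated.
#'
#' @param patch A `membrane_patch`.
#' @return Named integer vector `c(na=, k=)`.
#' @export
count_open <- function(patch) {
  stopifnot(inherits(patch, "membrane_patch"))
  s <- patch$channels$sensors
  if (nrow(s) == 0) return(c(na = 0L, k = 0L))
  open <- rowSums(s) == 4L
  c(na = sum(open & patch$channels$sel == 0L),
    k = sum(open & patch$channels$sel == 1L))
}

#' Total transmembrane current of a patch
#'
#' `I = sum_X n_open_X * gamma_X * (v_m - e_rev_X)`, with pS*mV scaled to pA
#' (1 pS * 1 mV = 1e-3 pA). Positive current is outward.
#'
#' @param patch A `membrane_patch`.
#' @param params A `gating_params` (supplies `gamma`, `e_rev`, `v_m`).
#' @return Current in pA.
#' @examples
#' # one open Na channel, gamma 20 pS, at -65 mV vs E_Na = +50 mV:
#' # 20 * (-115) * 1e-3 = -2.3 pA
#' @export
patch_current <- function(patch, params) {
  no <- count_open(patch)
  sum(no * params$gamma * (params$v_m - params$e_rev)) * 1e-3
}

#' Set all sensors of every channel to a given state
#'
#' Utility for constructing reference configurations (e.g. the frozen
#' all-open patch used by the static-limit coupling checks).
#'
#' @param patch A `membrane_patch`.
#' @param state `"activated"` or `"resting"`.
#' @return The modified patch.
#' @export
set_sensors <- function(patch, state = c("activated", "resting")) {
  state <- match.arg(state)
  patch$channels$sensors[] <- if (state == "activated") 1L else 0L
  patch
}

#' Reseed a patch's internal random stream
#'
#' Used by replica ensembles: replicas share the initial configuration and
#' differ only by the seed of the patch's Monte Carlo stream.
#'
#' @param patch A `membrane_patch`.
#' @param seed Integer seed.
#' @return The patch with a fresh random stream.
#' @export
reseed_patch <- function(patch, seed) {
  patch$rng <- cpp_rng_init(as.integer(seed))
  patch
}

#' Write patch observables as delimited text with a JSON parameter sidecar
#'
#' @param obs Observable data frame from [mc_run()].
#' @param params The `gating_params` used.
#' @param path Output path for the tab-delimited table; the sidecar is written
#'   to `paste0(path, ".json")` when jsonlite is available.
#' @return `path`, invisibly.
#' @export
write_mc_observables <- function(obs, params, path) {
  write.table(obs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(unclass(params), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
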