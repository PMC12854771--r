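# Independent reference implementations used as oracles. Deliberately plain
# (per-site / per-frame loops) and written against the model definitions, not
# against the package internals.

# Full Hamiltonian of a membrane patch by brute-force enumeration of every
# nearest-neighbour pair and every sensor.
oracle_total_energy <- function(patch, params) {
  L <- patch$L
  grid <- patch$grid
  ch <- patch$channels
  fv <- fv_per_mv()
  # direction deltas: 0:+x 1:+y 2:-x 3:-y (0-based lattice coords)
  dx <- c(1, 0, -1, 0); dy <- c(0, 1, 0, -1)
  sensor_state_facing <- function(ci, d) {
    s <- ((d - ch$orient[ci]) %% 4) + 1
    ch$sensors[ci, s]
  }
  bond <- function(x, y, d) { # energy of bond from 0-based (x,y) toward d
    nx <- (x + dx[d + 1]) %% L; ny <- (y + dy[d + 1]) %% L
    c1 <- grid[x + 1, y + 1]; c2 <- grid[nx + 1, ny + 1]
    ch1 <- c1 >= 2; ch2 <- c2 >= 2
    if (ch1 && ch2) return(0)
    if (!ch1 && !ch2) return(params$j_lipid[c1 + 1, c2 + 1])
    if (ch1) {
      st <- sensor_state_facing(c1 - 1, d)
      return(params$j_sensor_lipid[st + 1, c2 + 1])
    }
    st <- sensor_state_facing(c2 - 1, (d + 2) %% 4)
    params$j_sensor_lipid[st + 1, c1 + 1]
  }
  H <- 0
  for (x in 0:(L - 1)) for (y in 0:(L - 1)) {
    H <- H + bond(x, y, 0) + bond(x, y, 1)
  }
  n_ch <- length(ch$sel)
  for (ci in seq_len(n_ch)) {
    nact <- sum(ch$sensors[ci, ])
    H <- H + nact * (params$eps_g[ch$sel[ci] + 1] -
                       params$q_gate[ch$sel[ci] + 1] * params$v_m * fv)
    H <- H + params$j_sensor_sensor * nact * (nact - 1) / 2
  }
  H
}

# Per-frame brute-force permeation counter (reference for the run-collapsed
# counter in the package).
oracle_count_crossings <- function(traj, pore) {
  box_z <- attr(traj, "box_z")
  events <- list()
  for (id in unique(traj$ion)) {
    sub <- traj[traj$ion == id, ]
    z <- sub$z
    if (!is.null(box_z) && length(z) > 1) {
      dz <- diff(z)
      z <- z + c(0, -box_z * cumsum(round(dz / box_z)))
    }
    lat_ok <- rep(TRUE, nrow(sub))
    if (is.finite(pore$radius))
      lat_ok <- (sub$x - pore$axis_x)^2 + (sub$y - pore$axis_y)^2 <=
        pore$radius^2
    state <- 0L; entry <- NA_real_
    for (k in seq_len(nrow(sub))) {
      if (z[k] < pore$z_lower) {
        if (state == 4L)
          events[[length(events) + 1]] <- data.frame(
            ion = id, direction = "down", entry_time = entry,
            exit_time = sub$time[k])
        state <- 1L
      } else if (z[k] > pore$z_upper) {
        if (state == 3L)
          events[[length(events) + 1]] <- data.frame(
            ion = id, direction = "up", entry_time = entry,
            exit_time = sub$time[k])
        state <- 2L
      } else if (lat_ok[k]) {
        if (state == 1L) { state <- 3L; entry <- sub$time[k] }
        else if (state == 2L) { state <- 4L; entry <- sub$time[k] }
      } else {
        state <- 0L
      }
    }
  }
  if (length(events) == 0)
    return(data.frame(ion = character(0), direction = character(0),
                      entry_time = numeric(0), exit_time = numeric(0)))
  do.call(rbind, events)
}

# gating parameters with every coupling switched off
params_zero_coupling <- function(...) {
  gating_params(j_lipid = matrix(0, 2, 2), j_sensor_lipid = matrix(0, 2, 2),
                ...)
}

# single-compartment HH soma grid
soma_grid <- function(d = 20) {
  discretize(morphology(data.frame(
    id = 1L, parent = -1L, x0 = 0, y0 = 0, z0 = 0, x1 = d, y1 = 0, z1 = 0,
    d0 = d, d1 = d, region = "soma")), max_len = 2 * d)
}

# mean sensor activation with a Monte Carlo standard error from independent
# replicas
activation_stats <- function(patch_args, params, n_sweeps = 1500,
                             burn = 500, n_rep = 6) {
  means <- vapply(seq_len(n_rep), function(r) {
    p <- do.call(build_patch, c(patch_args, list(seed = 1000 + r)))
    n_sens <- 4 * (patch_args$n_na + patch_args$n_k)
    obs <- mc_run(p, params, n_sweeps, record_every = 5)$obs
    mean(obs$n_sensors_active[obs$sweep > burn]) / n_sens
  }, numeric(1))
  list(mean = mean(means), se = stats::sd(means) / sqrt(n_rep))
}

two_state_activation <- function(params, sel = 1) {
  beta <- 303.15 / (params$temperature_c + 273.15)
  d <- params$eps_g[sel] - params$q_gate[sel] * params$v_m * fv_per_mv()
  1 / (1 + exp(d * beta))
}

expect_same_events <- function(a, b) {
  ord <- function(x) x[order(x$ion, x$exit_time, x$direction), ]
  a <- ord(a); b <- ord(b)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a$ion, b$ion)
  expect_equal(a$direction, b$direction)
  expect_equal(a$entry_time, b$entry_time)
  expect_equal(a$exit_time, b$exit_time)
}
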