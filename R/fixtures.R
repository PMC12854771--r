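#' Synthetic drift-diffusion ion trajectories with ground-truth crossings
#'
#' Generates per-ion 1D biased random walks along the pore axis (plus
#' lateral jitter around the axis) and, during generation, tracks the exact
#' crossing events implied by the same state-machine semantics the counter
#' uses, so the counter can be validated against a known truth. Drift is in
#' Angstrom/ns and diffusion in Angstrom^2/ns (per-frame displacement
#' `drift * dt + sqrt(2 * diffusion * dt) * N(0,1)`), scales on which
#' nanosecond-length synthetic runs actually produce crossings.
#'
#' Ions start below the pore (at `z_lower - start_offset`), uniformly spread.
#'
#' @param n_ions Number of ions.
#' @param duration_ns Trajectory length, ns.
#' @param dt_ps Frame interval, ps.
#' @param drift Drift velocity along +z, Angstrom/ns.
#' @param diffusion Diffusion coefficient, Angstrom^2/ns.
#' @param pore A [pore_definition()].
#' @param seed Integer seed.
#' @param start_offset Starting depth below `z_lower`, Angstrom.
#' @param lateral_sd Lateral jitter around the pore axis, Angstrom.
#' @return List with `traj` (a [trajectory_table()]) and `truth` (the exact
#'   event data frame, same layout as [count_crossings()] output).
#' @examples
#' pore <- pore_definition(-10, 10)
#' fix <- make_drift_trajectory(5, duration_ns = 2, dt_ps = 10, drift = 20,
#'                              diffusion = 5, pore = pore, seed = 1)
#' nrow(fix$truth)
#' @export
make_drift_trajectory <- function(n_ions, duration_ns, dt_ps, drift,
                                  diffusion, pore, seed = 1,
                                  start_offset = 15, lateral_sd = 2) {
  stopifnot(inherits(pore, "pore_definition"))
  if (!is_count(n_ions) || n_ions < 1)
    stop_ionspike("`n_ions` must be a positive integer",
                  "ionspike_domain_error")
  check_scalar(duration_ns, "duration_ns", lower = 1e-12)
  check_scalar(dt_ps, "dt_ps", lower = 1e-12)
  check_scalar(diffusion, "diffusion", lower = 0)
  n_frames <- as.integer(floor(duration_ns * 1000 / dt_ps)) + 1L
  dt_ns <- dt_ps / 1000
  out <- with_seed(seed, {
    rows <- vector("list", n_ions)
    truth <- list()
    for (i in seq_len(n_ions)) {
      z0 <- pore$z_lower - start_offset * runif(1, 0.5, 1.5)
      steps <- drift * dt_ns + sqrt(2 * diffusion * dt_ns) *
        rnorm(n_frames - 1)
      z <- c(z0, z0 + cumsum(steps))
      x <- pore$axis_x + rnorm(n_frames, sd = lateral_sd)
      y <- pore$axis_y + rnorm(n_frames, sd = lateral_sd)
      tms <- (seq_len(n_frames) - 1) * dt_ps
      rows[[i]] <- data.frame(time = tms, ion = i, x = x, y = y, z = z)
      # exact per-frame state machine (ground truth)
      reg <- classify_region(x, y, z, pore)
      state <- switch(as.character(reg[1]), "0" = 1L, "2" = 2L, 0L)
      entry <- NA_real_
      for (k in seq_len(n_frames)[-1]) {
        rg <- reg[k]
        if (rg == 0L) {
          if (state == 4L)
            truth[[length(truth) + 1]] <- data.frame(
              ion = i, direction = "down", entry_time = entry,
              exit_time = tms[k])
          state <- 1L
        } else if (rg == 2L) {
          if (state == 3L)
            truth[[length(truth) + 1]] <- data.frame(
              ion = i, direction = "up", entry_time = entry,
              exit_time = tms[k])
          state <- 2L
        } else if (rg == 1L) {
          if (state == 1L) { state <- 3L; entry <- tms[k] }
          else if (state == 2L) { state <- 4L; entry <- tms[k] }
        } else state <- 0L
      }
    }
    list(rows = rows, truth = truth)
  })
  traj <- trajectory_table(do.call(rbind, out$rows),
                           frame_interval_ps = dt_ps)
  truth <- if (length(out$truth) == 0)
    data.frame(ion = character(0), direction = character(0),
               entry_time = numeric(0), exit_time = numeric(0))
  else do.call(rbind, out$truth)
  list(traj = traj, truth = truth)
}
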