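pore <- pore_definition(-10, 10)

make_traj <- function(z, x = 0, y = 0, ion = 1, dt = 10, box_z = NULL) {
  trajectory_table(data.frame(time = (seq_along(z) - 1) * dt, ion = ion,
                              x = x, y = y, z = z),
                   frame_interval_ps = dt, box_z = box_z)
}

test_that("constructed paths produce the expected crossing events", {
  up <- make_traj(c(-20, -12, -5, 0, 6, 12, 20))
  ev <- count_crossings(up, pore)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "up")
  expect_gt(ev$exit_time, ev$entry_time)

  # enters from below, returns below: rejected re-entry
  bounce <- make_traj(c(-20, -5, 0, 5, -2, -15))
  expect_equal(nrow(count_crossings(bounce, pore)), 0)

  # down crossing mirrors up
  down <- make_traj(rev(c(-20, -12, -5, 0, 6, 12, 20)))
  ev <- count_crossings(down, pore)
  expect_equal(ev$direction, "down")

  # lateral excursion beyond the gate radius aborts the passage
  pr <- pore_definition(-10, 10, radius = 4)
  zig <- make_traj(c(-20, -5, 0, 5, 20), x = c(0, 0, 9, 0, 0))
  expect_equal(nrow(count_crossings(zig, pr)), 0)
  ok <- make_traj(c(-20, -5, 0, 5, 20), x = c(0, 0, 2, 0, 0))
  expect_equal(nrow(count_crossings(ok, pr)), 1)

  # a single-frame jump across the whole slab is not a counted passage
  jump <- make_traj(c(-20, -12, 20, 25))
  expect_equal(nrow(count_crossings(jump, pore)), 0)
})

test_that("periodic unwrapping suppresses spurious box-edge events", {
  # ion wraps at the box top (z 55 -> -55 with box 120), far from the pore
  wrapped <- make_traj(c(30, 45, 55, -55, -45, -30), box_z = 120)
  expect_equal(nrow(count_crossings(wrapped, pore)), 0)
})

test_that("optimized counter matches the brute-force per-frame oracle", {
  for (seed in 1:25) {
    drift <- c(-15, 0, 10, 25)[1 + seed %% 4]
    fix <- make_drift_trajectory(8, duration_ns = 1.5, dt_ps = 10,
                                 drift = drift, diffusion = 8, pore = pore,
                                 seed = seed)
    fast <- count_crossings(fix$traj, pore)
    slow <- oracle_count_crossings(fix$traj, pore)
    expect_same_events(fast, slow)
    expect_same_events(fast, fix$truth)
  }
})

test_that("strong drift pushes every ion through exactly once", {
  fix <- make_drift_trajectory(12, duration_ns = 2, dt_ps = 10, drift = 40,
                               diffusion = 0.5, pore = pore, seed = 2)
  ev <- count_crossings(fix$traj, pore)
  expect_equal(sum(ev$direction == "up"), 12)
  expect_equal(sum(ev$direction == "down"), 0)
})

test_that("reversing the trajectory swaps up and down counts exactly", {
  fix <- make_drift_trajectory(10, duration_ns = 2, dt_ps = 10, drift = 12,
                               diffusion = 10, pore = pore, seed = 9)
  fwd <- count_crossings(fix$traj, pore)
  rev_df <- fix$traj[order(fix$traj$ion, -fix$traj$time), ]
  rev_df$time <- ave(rev_df$time, rev_df$ion,
                     FUN = function(t) max(t) + min(t) - t)
  rev_tr <- trajectory_table(rev_df, frame_interval_ps = 10)
  bwd <- count_crossings(rev_tr, pore)
  expect_equal(sum(fwd$direction == "up"), sum(bwd$direction == "down"))
  expect_equal(sum(fwd$direction == "down"), sum(bwd$direction == "up"))
})

test_that("event counts add over concatenated trajectories", {
  f1 <- make_drift_trajectory(6, duration_ns = 1, dt_ps = 10, drift = 30,
                              diffusion = 1, pore = pore, seed = 3)
  f2 <- make_drift_trajectory(6, duration_ns = 1, dt_ps = 10, drift = 30,
                              diffusion = 1, pore = pore, seed = 4)
  # relabel and shift the second block; both blocks start and end far from
  # the pore so no passage spans the seam
  t2 <- f2$traj
  t2$ion <- t2$ion + 100
  t2$time <- t2$time + max(f1$traj$time) + 10
  cat_tr <- trajectory_table(rbind(as.data.frame(f1$traj),
                                   as.data.frame(t2)),
                             frame_interval_ps = 10)
  expect_equal(nrow(count_crossings(cat_tr, pore)),
               nrow(count_crossings(f1$traj, pore)) +
                 nrow(count_crossings(f2$traj, pore)))
})

test_that("conductance arithmetic is exact", {
  ev0 <- data.frame(ion = integer(0), direction = character(0),
                    entry_time = numeric(0), exit_time = numeric(0))
  z <- crossing_conductance(ev0, 500, 600)
  expect_equal(z$current_pA, 0)
  expect_equal(z$g_pS, 0)

  ev <- data.frame(ion = 1:19, direction = "up", entry_time = 0, exit_time = 1)
  r <- crossing_conductance(ev, duration_ns = 500, v_m_mV = 600)
  expect_equal(r$current_pA, 19 * 1.602176634e-19 / 5e-7 * 1e12)
  expect_equal(r$g_pS, r$current_pA / 0.6)
  expect_lt(abs(r$g_pS - 10.15) / 10.15, 0.005)

  both <- rbind(ev, transform(ev, direction = "down"))
  expect_equal(crossing_conductance(both, 500, 600)$current_pA, 0)
  expect_error(crossing_conductance(ev, 500, 0),
               class = "ionspike_domain_error")
})

test_that("block errors recover Poisson statistics of the crossing rate", {
  # regular crossings: one per block, identical block conductances, SE = 0
  n <- 8
  zpath <- c(-20, -5, 0, 5, 20, 25)
  reg <- do.call(rbind, lapply(seq_len(n), function(k)
    data.frame(time = (seq_along(zpath) - 1) * 10 + (k - 1) * 1000,
               ion = k, x = 0, y = 0, z = zpath)))
  # pad so every block holds one crossing and spans are equal
  reg_tr <- trajectory_table(reg, frame_interval_ps = 10)
  be <- block_errors(reg_tr, pore, n_blocks = 2, v_m_mV = 600)
  expect_equal(be$g_se_pS, 0)

  expect_error(block_errors(reg_tr, pore, n_blocks = 1, v_m_mV = 600),
               class = "ionspike_domain_error")

  # Poisson process of crossings: SE within 3x of the propagated theory
  set.seed(42)
  rate_per_ns <- 2
  dur_ns <- 200
  n_ev <- rpois(1, rate_per_ns * dur_ns)
  starts <- sort(runif(n_ev, 0, dur_ns * 1000 - 100))
  po <- do.call(rbind, lapply(seq_along(starts), function(k)
    data.frame(time = starts[k] + (seq_along(zpath) - 1) * 10, ion = k,
               x = 0, y = 0, z = zpath)))
  po <- rbind(po,
              data.frame(time = c(0, dur_ns * 1000), ion = c(9001, 9002),
                         x = 0, y = 0, z = -50))
  po_tr <- trajectory_table(po[order(po$ion, po$time), ],
                            frame_interval_ps = 10)
  nb <- 10
  be <- block_errors(po_tr, pore, n_blocks = nb, v_m_mV = 600)
  t_block_ns <- dur_ns / nb
  g_per_event <- 1.602176634e-19 / (t_block_ns * 1e-9) * 1e12 / 0.6
  se_theory <- g_per_event * sqrt(rate_per_ns * t_block_ns) / sqrt(nb)
  expect_lt(be$g_se_pS, 3 * se_theory)
  expect_gt(be$g_se_pS, se_theory / 3)
  expect_lt(abs(be$g_mean_pS - g_per_event * rate_per_ns * t_block_ns),
            3 * se_theory * sqrt(nb))
})

test_that("trajectory validation rejects unsorted input", {
  bad <- data.frame(time = c(10, 0), ion = 1, x = 0, y = 0, z = 0)
  expect_error(trajectory_table(bad), class = "ionspike_validation_error")
  expect_error(pore_definition(5, -5), class = "ionspike_domain_error")
})
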