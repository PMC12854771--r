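test_that("build_patch conserves composition and is reproducible", {
  p <- build_patch(20, 0, 0, frac_unsaturated = 1, seed = 1)
  expect_equal(sum(p$grid == 1L), 400)
  expect_equal(length(p$channels$sel), 0)

  p <- build_patch(20, 5, 5, frac_unsaturated = 0.5, seed = 7)
  expect_equal(sum(p$grid >= 2L), 10)
  expect_equal(sum(p$grid == 0L), 195)
  expect_equal(sum(p$grid == 1L), 195)
  expect_true(all(rowSums(p$channels$sensors) == 0))
  # registry position matches the grid
  for (i in seq_along(p$channels$sel))
    expect_equal(p$grid[p$channels$x[i] + 1, p$channels$y[i] + 1], i + 1L)

  p2 <- build_patch(20, 5, 5, frac_unsaturated = 0.5, seed = 7)
  expect_identical(p$grid, p2$grid)
  expect_identical(p$channels, p2$channels)

  expect_error(build_patch(2, 5, 0), class = "ionspike_capacity_error")
  expect_error(build_patch(10, 1, 1, frac_unsaturated = 1.2),
               class = "ionspike_domain_error")
})

test_that("total_energy matches limits and the brute-force oracle", {
  pz <- params_zero_coupling()
  p <- build_patch(8, 2, 2, 0.5, seed = 2)
  expect_equal(total_energy(p, pz), 0) # all resting, couplings off

  # one channel, all four sensors activated, v_m = 0: H = 4 * eps_g
  p1 <- set_sensors(build_patch(6, 1, 0, 0.5, seed = 3), "activated")
  pz0 <- params_zero_coupling(v_m = 0)
  expect_equal(total_energy(p1, pz0), 4 * pz0$eps_g[1])

  # random patches against an independent brute-force enumeration
  for (seed in 1:4) {
    pars <- gating_params(v_m = -30 - 5 * seed, j_sensor_sensor = 0.1 * seed)
    p <- build_patch(6, 3, 2, 0.4, seed = seed)
    r <- mc_run(p, pars, 20) # scramble the state away from all-resting
    expect_equal(total_energy(r$patch, pars),
                 oracle_total_energy(r$patch, pars), tolerance = 1e-12)
  }
})

test_that("count_open enforces the strict all-four-sensors rule", {
  p <- build_patch(10, 2, 1, 0.5, seed = 4)
  expect_equal(count_open(p), c(na = 0L, k = 0L))
  p$channels$sensors[1, ] <- c(1L, 1L, 1L, 1L)
  p$channels$sensors[2, ] <- c(1L, 1L, 1L, 0L)
  expect_equal(count_open(p), c(na = 1L, k = 0L))
  # random states match a registry scan
  p$channels$sensors[] <- as.integer(runif(12) < 0.5)
  open <- rowSums(p$channels$sensors) == 4
  expect_equal(unname(sum(count_open(p))), sum(open))
})

test_that("patch_current converts open counts to pA", {
  p <- build_patch(10, 1, 0, 0.5, seed = 5)
  pars <- gating_params(v_m = -65)
  expect_equal(patch_current(p, pars), 0)
  p <- set_sensors(p, "activated")
  expect_equal(patch_current(p, pars), 20 * (-65 - 50) * 1e-3) # -2.3 pA
  pars$v_m <- pars$e_rev[1]
  expect_equal(patch_current(p, pars), 0)
})

test_that("sweeps conserve composition and track energy incrementally", {
  p <- build_patch(12, 4, 4, 0.35, seed = 6)
  pars <- gating_params(v_m = -40)
  before <- c(table(factor(p$grid[p$grid < 2], levels = 0:1)),
              n_ch = sum(p$grid >= 2))
  r <- mc_run(p, pars, 2000)
  after <- c(table(factor(r$patch$grid[r$patch$grid < 2], levels = 0:1)),
             n_ch = sum(r$patch$grid >= 2))
  expect_equal(before, after)
  # channel registry still consistent with the grid
  for (i in seq_along(r$patch$channels$sel))
    expect_equal(r$patch$grid[r$patch$channels$x[i] + 1,
                              r$patch$channels$y[i] + 1], i + 1L)
  # incrementally tracked energy equals a from-scratch recompute
  expect_equal(r$patch$energy, total_energy(r$patch, pars),
               tolerance = 1e-8)
  expect_equal(r$patch$energy, oracle_total_energy(r$patch, pars),
               tolerance = 1e-8)
})

test_that("zero-coupling sensor activation follows the two-state sigmoid", {
  args <- list(L = 10, n_na = 6, n_k = 6, frac_unsaturated = 0.5)
  pars <- params_zero_coupling(v_m = -45, q_gate = c(na = 1.5, k = 1.5),
                               v_half = c(na = -45, k = -45))
  st <- activation_stats(args, pars)
  expect_lt(abs(st$mean - 0.5), 3 * st$se + 1e-6)

  pars$v_m <- -70
  st <- activation_stats(args, pars)
  expect_lt(abs(st$mean - two_state_activation(pars)), 3 * st$se + 1e-6)
})

test_that("mean open count is non-decreasing in v_m at zero coupling", {
  args <- list(L = 10, n_na = 8, n_k = 0, frac_unsaturated = 0.5)
  vms <- c(-75, -55, -45, -35, -15)
  means <- vapply(vms, function(vm) {
    pars <- params_zero_coupling(v_m = vm)
    p <- build_patch(10, 8, 0, 0.5, seed = 8)
    obs <- mc_run(p, pars, 2500, record_every = 5)$obs
    mean(obs$n_open_na[obs$sweep > 500])
  }, numeric(1))
  # allow Monte Carlo jitter at the flat ends
  expect_true(all(diff(means) > -0.15))
  expect_gt(means[5], means[1])
})

test_that("stationary sensor distribution matches exact Boltzmann enumeration", {
  # 3x3 lattice, one channel, only sensor flips: the lipid environment is
  # frozen, so the 16 sensor configurations are exactly enumerable
  pars <- gating_params(v_m = -45,
                        move_mix = c(1, 0, 0, 0))
  p <- build_patch(3, 1, 0, 0.5, seed = 9)
  r <- mc_run(p, pars, 2e5, record_every = 1, record_sensors = TRUE)
  emp <- tabulate(r$obs$sensors0[r$obs$sweep > 2000] + 1, nbins = 16)
  emp <- emp / sum(emp)

  # exact enumeration with the same frozen lipid neighbourhood
  beta <- 303.15 / (pars$temperature_c + 273.15)
  pr <- numeric(16)
  probe <- r$patch
  for (m in 0:15) {
    probe$channels$sensors[1, ] <- as.integer(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0)
    pr[m + 1] <- exp(-beta * oracle_total_energy(probe, pars))
  }
  pr <- pr / sum(pr)
  tv <- 0.5 * sum(abs(emp - pr))
  expect_lt(tv, 0.05) # tighter bound at 1e6 sweeps in the acceptance suite
})

test_that("gating parameter validation rejects malformed inputs", {
  expect_error(gating_params(move_mix = c(0.5, 0.5, 0.5, 0)),
               class = "ionspike_domain_error")
  expect_error(gating_params(j_lipid = matrix(c(0, 1, 0, 0), 2, 2)),
               class = "ionspike_domain_error")
  expect_error(gating_params(temperature_c = -300),
               class = "ionspike_domain_error")
})
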