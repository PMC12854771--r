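test_that("discretize conserves frustum geometry", {
  cyl <- morphology(data.frame(id = 1L, parent = -1L, x0 = 0, y0 = 0, z0 = 0,
                               x1 = 100, y1 = 0, z1 = 0, d0 = 2, d1 = 2,
                               region = "dendrite"))
  g1 <- discretize(cyl, max_len = 100)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$area_um2, pi * 2 * 100)

  g10 <- discretize(cyl, max_len = 10)
  expect_equal(nrow(g10), 10)
  expect_equal(sum(g10$area_um2), pi * 200, tolerance = 1e-6)

  # tapered frustum: area conserved against the closed form
  fr <- morphology(data.frame(id = 1L, parent = -1L, x0 = 0, y0 = 0, z0 = 0,
                              x1 = 50, y1 = 0, z1 = 0, d0 = 4, d1 = 1,
                              region = "dendrite"))
  gf <- discretize(fr, max_len = 3)
  slant <- sqrt(50^2 + (1.5)^2)
  expect_equal(sum(gf$area_um2), pi * 2.5 * slant, tolerance = 1e-6)

  bad <- data.frame(id = 1L, parent = -1L, x0 = 0, y0 = 0, z0 = 0,
                    x1 = 0, y1 = 0, z1 = 0, d0 = 2, d1 = 2,
                    region = "dendrite")
  expect_error(morphology(bad), class = "ionspike_validation_error")
})

test_that("passive single compartment follows the RC charging curve", {
  g <- soma_grid(20)
  pars <- passive_membrane_params(e_leak = -65)
  tr <- run_cable(g, pars, stimuli = list(stim_clamp(1, 50, 0, 200)),
                  t_stop = 50, dt = 0.025)
  area <- g$area_um2
  R <- 1 / (pars$g_leak * area * 1e-2)          # MOhm
  tau <- pars$c_m * area * 1e-5 * R             # ms
  analytic <- -65 + 0.05 * R * (1 - exp(-tr$times / tau))
  expect_lt(max(abs(tr$v[, 1] - analytic)), 0.1)
})

test_that("backward-Euler error decreases with dt on the RC test", {
  g <- soma_grid(20)
  pars <- passive_membrane_params(e_leak = -65)
  area <- g$area_um2
  R <- 1 / (pars$g_leak * area * 1e-2)
  tau <- pars$c_m * area * 1e-5 * R
  err <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    tr <- run_cable(g, pars, stimuli = list(stim_clamp(1, 50, 0, 200)),
                    t_stop = 30, dt = dt)
    analytic <- -65 + 0.05 * R * (1 - exp(-tr$times / tau))
    max(abs(tr$v[, 1] - analytic))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("steady-state cable profile matches the cosh attenuation", {
  cab <- morphology(data.frame(id = 1L, parent = -1L, x0 = 0, y0 = 0, z0 = 0,
                               x1 = 1000, y1 = 0, z1 = 0, d0 = 2, d1 = 2,
                               region = "dendrite"))
  g <- discretize(cab, max_len = 5)
  pars <- passive_membrane_params(e_leak = -65)
  tr <- run_cable(g, pars, stimuli = list(stim_clamp(1, 20, 0, 400)),
                  t_stop = 300, dt = 0.05, record = "all")
  v <- tr$v[nrow(tr$v), ] + 65
  lambda_um <- sqrt((2e-4 / 4) / (pars$r_a * pars$g_leak)) * 1e4
  x <- g$x
  Ltot <- 1000
  theory <- cosh((Ltot - x) / lambda_um) / cosh((Ltot - x[1]) / lambda_um)
  expect_lt(max(abs(v / v[1] - theory)), 0.01)
})

test_that("interior compartments balance axial and membrane current at steady state", {
  cab <- morphology(data.frame(id = 1L, parent = -1L, x0 = 0, y0 = 0, z0 = 0,
                               x1 = 300, y1 = 0, z1 = 0, d0 = 2, d1 = 2,
                               region = "dendrite"))
  g <- discretize(cab, max_len = 10)
  pars <- passive_membrane_params(e_leak = -65)
  tr <- run_cable(g, pars, stimuli = list(stim_clamp(1, 10, 0, 500)),
                  t_stop = 400, dt = 0.05, record = "all")
  v <- tr$v[nrow(tr$v), ]
  arr <- ionspike:::build_cable_arrays(g, pars)
  gax <- arr$g_ax_uS
  par_i <- g$parent
  for (i in 2:(nrow(g) - 1)) {
    children <- which(par_i == i)
    ax <- gax[i] * (v[par_i[i]] - v[i]) +
      sum(gax[children] * (v[children] - v[i]))
    mem <- arr$g_leak_uS[i] * (v[i] - pars$e_leak)
    expect_lt(abs(ax - mem) / max(abs(mem), 1e-12), 1e-6)
  }
})

test_that("resting HH membrane is stable without stimulus", {
  g <- soma_grid(20)
  tr <- run_cable(g, membrane_params(), t_stop = 1000, dt = 0.025)
  v_rest <- tr$v[nrow(tr$v), 1]
  expect_lt(max(abs(tr$v[, 1] - v_rest)), 0.5)
})

test_that("suprathreshold HH soma fires repetitively with plausible spike shape", {
  g <- soma_grid(20)
  tr <- run_cable(g, membrane_params(),
                  stimuli = list(stim_clamp(1, 80, 100, 400)), t_stop = 500)
  st <- detect_spikes(tr)
  expect_gte(length(st), 2)
  expect_gt(max(tr$v[, 1]), 0)
  # width at -20 mV of the first spike under 5 ms
  i0 <- which(tr$times >= st[1])[1]
  above <- tr$v[, 1] >= -20
  i1 <- i0
  while (above[i1 + 1]) i1 <- i1 + 1
  expect_lt(tr$times[i1] - tr$times[i0], 5)
  # spike count is dt-converged
  tr2 <- run_cable(g, membrane_params(),
                   stimuli = list(stim_clamp(1, 80, 100, 400)), t_stop = 500,
                   dt = 0.0125)
  expect_equal(length(detect_spikes(tr2)), length(st))
})

test_that("run_cable handles the degenerate zero-length run", {
  g <- soma_grid(20)
  tr <- run_cable(g, membrane_params(), t_stop = 0)
  expect_equal(length(tr$times), 1)
  expect_equal(tr$v[1, 1], -65)
})

test_that("detect_spikes counts upward crossings with a refractory rule", {
  tt <- seq(0, 30, by = 0.1)
  tri <- -60 + 50 * abs(((tt / 5) %% 2) - 1) # triangle between -60 and -10
  trace <- list(times = tt, v = matrix(tri, ncol = 1))
  expect_equal(length(detect_spikes(trace, threshold = -20, min_isi = 2)), 3)
  expect_equal(length(detect_spikes(trace, threshold = -20, min_isi = 25)), 1)
  flat <- list(times = tt, v = matrix(-65, length(tt), 1))
  expect_equal(length(detect_spikes(flat)), 0)
})
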