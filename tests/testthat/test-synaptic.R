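test_that("scaling factors reproduce the published conductance ratios", {
  rows <- list(list(10.2, "wild-type", 3.1, 3),
               list(3.3, "baseline", 1.0, 1),
               list(11.7, "Q586G", 3.5, 3),
               list(92.4, "Q586E.0", 28.0, 30),
               list(19.8, "Q586E.1", 6.0, 6),
               list(19.8, "Q586E.2", 6.0, 6))
  for (r in rows) {
    sc <- compute_scaling(r[[1]], 3.3, r[[2]])
    expect_equal(sc$G_1dp, r[[3]])
    expect_equal(sc$G_rounded, r[[4]])
    expect_equal(sc$G, r[[1]] / 3.3)
  }
  expect_error(compute_scaling(-1, 3.3), class = "ionspike_domain_error")
  expect_error(compute_scaling(10, 0), class = "ionspike_domain_error")

  tab <- read_variant_table(system.file("extdata", "variants.tsv",
                                        package = "ionspike"))
  expect_equal(tab$G_1dp, c(3.1, 1.0, 3.5, 28.0, 6.0, 6.0))
  expect_equal(tab$G_rounded, c(3, 1, 3, 30, 6, 6))
})

test_that("double-exponential conductance has unit-normalized peak and is linear", {
  s <- synapse_spec(1, weight = 1.5, tau_rise = 0.2, tau_decay = 1.7,
                    scaling = 2)
  tp <- 0.2 * 1.7 / (1.7 - 0.2) * log(1.7 / 0.2)
  expect_equal(synaptic_conductance(s, 0, tp), 2 * 1.5, tolerance = 1e-10)
  # the peak really is the maximum
  tt <- seq(0, 10, by = 0.001)
  g <- synaptic_conductance(s, 0, tt)
  expect_equal(max(g), 2 * 1.5, tolerance = 1e-6)
  expect_equal(tt[which.max(g)], tp, tolerance = 2e-3)
  expect_true(all(g >= 0))
  # superposition: two simultaneous events double the profile
  g2 <- synaptic_conductance(s, c(0, 0), tt)
  expect_equal(g2, 2 * g, tolerance = 1e-12)
  # no events
  expect_equal(synaptic_conductance(s, numeric(0), c(0, 1, 5)), c(0, 0, 0))
  expect_error(synapse_spec(1, weight = 1, tau_rise = 2, tau_decay = 1),
               class = "ionspike_domain_error")
})

test_that("synaptic current has the right sign, scale and reversal", {
  expect_equal(synaptic_current(0, -65), 0)
  expect_equal(synaptic_current(0.002, 0, 0), 0)
  # 0.001 uS * -65 mV = -0.065 nA = -65 pA, inward/depolarizing
  expect_equal(synaptic_current(0.001, -65, 0), -65)
  expect_error(synaptic_current(-0.1, -65), class = "ionspike_domain_error")
})

test_that("localized placement clusters synapses within the radius", {
  bs <- make_ball_and_stick(20, 40, 2)
  loc <- place_localized(bs, n = 2, radius = 50, seed = 1)
  g <- discretize(bs, 20)
  expect_true(all(g$region[loc$compartment] == "dendrite"))

  tree <- discretize(make_random_tree(tree_spec(), seed = 5), 20)
  loc <- place_localized(tree, n = 10, radius = 50, seed = 2)
  ctr <- attr(loc, "center")
  d <- sqrt((loc$x - tree$x[ctr])^2 + (loc$y - tree$y[ctr])^2 +
              (loc$z - tree$z[ctr])^2)
  expect_true(all(d <= 50))
  expect_true(all(tree$region[loc$compartment] == "dendrite"))
  # deterministic per seed
  loc2 <- place_localized(tree, n = 10, radius = 50, seed = 2)
  expect_identical(loc$compartment, loc2$compartment)

  soma_only <- morphology(data.frame(id = 1L, parent = -1L, x0 = 0, y0 = 0,
                                     z0 = 0, x1 = 20, y1 = 0, z1 = 0, d0 = 20,
                                     d1 = 20, region = "soma"))
  expect_error(place_localized(soma_only, n = 2, seed = 1),
               class = "ionspike_placement_error")
  expect_error(place_localized(tree, n = 10, radius = 0.01, seed = 1),
               class = "ionspike_placement_error")
})

test_that("distributed placement is uniform over dendritic compartments", {
  tree <- discretize(make_random_tree(tree_spec(), seed = 6), 20)
  expect_equal(nrow(place_distributed(tree, n = 0, seed = 1)), 0)
  l1 <- place_distributed(tree, n = 10, seed = 3)
  l2 <- place_distributed(tree, n = 10, seed = 3)
  expect_identical(l1, l2)
  # empirical selection frequency uniform within a chi-square tolerance
  dend <- which(tree$region == "dendrite")
  counts <- integer(length(dend))
  names(counts) <- dend
  for (s in 1:400) {
    p <- place_distributed(tree, n = 5, seed = 1000 + s)
    tb <- table(p$compartment)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  chi <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(chi$p.value, 1e-4)
})

test_that("Poisson trains have the right statistics and correlation modes", {
  expect_equal(lengths(generate_trains(0, 1000, 3, FALSE, 1)$trains),
               c(0, 0, 0))
  ens <- generate_trains(10, 1e5, 8, correlated = FALSE, seed = 4)
  counts <- lengths(ens$trains)
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 8))
  expect_true(all(vapply(ens$trains, function(t)
    all(t >= 0 & t < 1e5) && !is.unsorted(t), logical(1))))
  cor_ens <- generate_trains(10, 5000, 5, correlated = TRUE, seed = 5)
  for (i in 2:5) expect_identical(cor_ens$trains[[i]], cor_ens$trains[[1]])
  expect_error(generate_trains(-1, 100, 2), class = "ionspike_domain_error")
})

test_that("variant experiments are reproducible and respond to scaling", {
  grid <- discretize(make_random_tree(tree_spec(), seed = 7), 20)
  pars <- membrane_params()
  e0 <- run_variant_experiment(grid, pars, scaling = 1, weight = 1e-4,
                               placement = "distributed", duration = 400,
                               seed = 1, rate = 0)
  expect_equal(e0$spike_count, 0)

  e1 <- run_variant_experiment(grid, pars, scaling = 1000, weight = 0.005,
                               placement = "distributed", duration = 400,
                               seed = 1)
  expect_gte(e1$spike_count, 1)

  e2 <- run_variant_experiment(grid, pars, scaling = 3, weight = 0.002,
                               placement = "localized", correlated = TRUE,
                               duration = 400, seed = 2)
  e3 <- run_variant_experiment(grid, pars, scaling = 3, weight = 0.002,
                               placement = "localized", correlated = TRUE,
                               duration = 400, seed = 2)
  expect_identical(e2$spike_count, e3$spike_count)
  expect_identical(e2$trace$v, e3$trace$v)
})
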