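# Wall-uptake closure, Graetz reference solver, network absorption,
# depletion experiment and solubility sweeps.

test_that("segment uptake closure matches term-by-term arithmetic", {
  seg <- channel_segments("c", "a", "b", 0.05, 1e-3, shape = "circular",
                          region = "olfactory_coil",
                          epithelium = "olfactory")
  o <- ref_odorant(beta = 1)
  up <- segment_uptake(seg, u = 0.05, o)
  expect_equal(up$k_conv, 0.02196, tolerance = 1e-4)
  expect_equal(up$k_wall, 3.3333e-5, tolerance = 1e-4)
  expect_equal(up$k_tot, 3.3283e-5, tolerance = 1e-3)
  expect_equal(up$ratio, 0.87535, tolerance = 1e-4)

  # insoluble limit: the wall conductance vanishes
  expect_equal(segment_uptake(seg, 0.05, ref_odorant(beta = 1e12))$ratio, 1,
               tolerance = 1e-6)
  # long-column limit: everything is absorbed
  seg_long <- channel_segments("c", "a", "b", 5e4, 1e-3, shape = "circular",
                               region = "olfactory_coil",
                               epithelium = "olfactory")
  expect_lt(segment_uptake(seg_long, 0.05, o)$ratio, 1e-12)
  # disabling uptake short-circuits the wall
  expect_equal(segment_uptake(seg, 0.05, o, enabled = FALSE)$ratio, 1)
  expect_error(segment_uptake(seg, 0, o), "domain")
})

test_that("Graetz solver recovers its classical limits", {
  # no wall uptake: concentration is conserved
  g0 <- graetz_reference_solution(0, zeta_max = 0.3, nr = 64, nx = 150)
  expect_equal(g0$outlet_ratio, 1, tolerance = 1e-12)
  expect_true(all(abs(g0$Cm - 1) < 1e-12))

  # Dirichlet wall: fully developed Sherwood number 3.657
  gd <- graetz_reference_solution(Inf, zeta_max = 0.5, nr = 128, nx = 400)
  expect_equal(gd$sherwood, 3.657, tolerance = 0.01)

  expect_error(graetz_reference_solution(1, nr = 4, nx = 4), "domain")
})

test_that("Graetz outlet ratio converges under grid refinement", {
  r <- vapply(c(1, 2, 4), function(f) {
    graetz_reference_solution(1, 0.5, nr = 64 * f, nx = 200 * f)$outlet_ratio
  }, numeric(1))
  expect_lt(abs(r[2] - r[1]) / r[1], 0.005)
  expect_lt(abs(r[3] - r[2]) / r[2], 0.005)
})

test_that("network absorption composes segment ratios and conserves mass", {
  o <- ref_odorant(beta = 0.01)
  chain <- make_serial_chain()
  fl <- solve_network_flow(chain)
  ab <- solve_network_absorption(chain, fl, o)
  # serial composition: outlet ratio is the product of segment ratios
  expect_equal(ab$outlet_concentration,
               prod(ab$segments$ratio), tolerance = 1e-12)
  expect_lt(ab$mass_balance_error, 1e-9)

  # uptake switched off everywhere
  ab_off <- solve_network_absorption(
    chain, fl, o,
    disabled_regions = c("anterior_respiratory", "dorsal_medial",
                         "olfactory_coil", "posterior_respiratory"))
  expect_equal(ab_off$outlet_concentration, 1, tolerance = 1e-12)
  expect_true(all(ab_off$region_fractions == 0))

  expect_error(solve_network_absorption(chain, fl, o,
                                        disabled_regions = "nostril"),
               "domain")
})

test_that("toy three-region network matches the hand-enumerated balance", {
  o <- ref_odorant(beta = 0.005)
  nw <- make_toy_three()
  fl <- solve_network_flow(nw)
  ab <- solve_network_absorption(nw, fl, o)

  seg <- nw$segments
  r <- vapply(seq_len(3), function(k) {
    segment_uptake(as.list(seg[k, ]), fl$segments$u[k], o)$ratio
  }, numeric(1))
  names(r) <- seg$id
  q <- fl$segments$q / fl$total_flow
  names(q) <- seg$id
  # enumerated mass balance on the two-branch tree
  expected <- c(
    anterior_respiratory = 1 - r[["ant"]],
    olfactory = q[["olf"]] * r[["ant"]] * (1 - r[["olf"]]),
    posterior_respiratory = q[["post"]] * r[["ant"]] * (1 - r[["post"]])
  )
  expect_equal(ab$region_fractions, expected, tolerance = 1e-12)
  expect_equal(ab$outlet_concentration,
               r[["ant"]] * (q[["olf"]] * r[["olf"]] +
                               q[["post"]] * r[["post"]]),
               tolerance = 1e-12)
})

test_that("mass balance holds to 1e-9 on randomized networks", {
  for (seed in 1:5) {
    nw <- random_coil_network(seed + 100)
    fl <- solve_network_flow(nw)
    for (beta in c(1e-4, 0.03, 5)) {
      ab <- solve_network_absorption(nw, fl, ref_odorant(beta))
      expect_lt(ab$mass_balance_error, 1e-9)
      expect_true(all(ab$region_fractions >= 0))
      expect_lte(sum(ab$region_fractions), 1 + 1e-12)
      expect_true(all(ab$segments$c_in <= 1 + 1e-12))
    }
  }
})

test_that("anterior depletion spares the olfactory stream", {
  # insoluble odorant: the two scenarios coincide exactly
  fx <- cat_fixture()
  dep_ins <- anterior_depletion_experiment(fx$network, fx$flow,
                                           ref_odorant(1e12))
  expect_equal(dep_ins$summary$frac_with_anterior,
               dep_ins$summary$frac_without_anterior, tolerance = 1e-9)

  # serial chain: with-anterior olfactory absorption equals the anterior
  # survival times the without-anterior value (closed-form composition)
  chain <- make_serial_chain()
  flc <- solve_network_flow(chain)
  o <- ref_odorant(beta = 0.01)
  dep_c <- anterior_depletion_experiment(chain, flc, o)
  a_ant <- dep_c$with_anterior$region_fractions[["anterior_respiratory"]]
  expect_equal(
    dep_c$summary$frac_with_anterior[dep_c$summary$region == "olfactory"],
    (1 - a_ant) *
      dep_c$summary$frac_without_anterior[dep_c$summary$region ==
                                            "olfactory"],
    tolerance = 1e-12)

  # cat-like network, highly soluble odorant: the olfactory region is
  # proportionally less affected by anterior uptake than the posterior
  # respiratory region
  dep <- anterior_depletion_experiment(fx$network, fx$flow,
                                       ref_odorant(1e-5))
  s <- dep$summary
  red_olf <- s$relative_reduction[s$region == "olfactory"]
  red_post <- s$relative_reduction[s$region == "posterior_respiratory"]
  expect_lt(red_olf, red_post)

  expect_error(anterior_depletion_experiment(make_parallel_pair(),
                                             flc, o),
               "structural")
})

test_that("solubility sweep shows the depletion trade-off", {
  fx <- cat_fixture()
  o <- ref_odorant()
  grid <- 10^seq(-6, 0, by = 0.25)

  # anterior uptake disabled: more soluble always means more olfactory
  # absorption
  sw_off <- solubility_sweep(fx$network, fx$flow, o, grid,
                             disabled_regions = "anterior_respiratory")
  olf_off <- sw_off$curves$fraction[sw_off$curves$region == "olfactory"]
  expect_true(all(diff(olf_off) <= 1e-12))
  expect_false(sw_off$interior_peak)

  # anterior uptake enabled: interior maximum at intermediate solubility
  sw_on <- solubility_sweep(fx$network, fx$flow, o, grid)
  expect_true(sw_on$interior_peak)
  olf_on <- sw_on$curves$fraction[sw_on$curves$region == "olfactory"]
  imax <- which.max(olf_on)
  expect_gt(imax, 1)
  expect_lt(imax, length(grid))

  expect_error(solubility_sweep(fx$network, fx$flow, o, c(0.1, 1, 10)),
               "domain")
})

test_that("shortening the anterior region moves the peak to more-soluble", {
  fx <- cat_fixture()
  short_ant <- build_parallel_coil_network(
    anterior_spec = list(trunk_length = 0.002, trunk_width = 4e-3,
                         dm_passage_length = 0.01, dm_passage_width = 2e-3,
                         bank_n = 6000, bank_length = 0.025,
                         bank_width = 3e-4))
  fl_s <- solve_network_flow(short_ant)
  grid <- 10^seq(-6, 0, by = 0.125)
  o <- ref_odorant()
  pk_full <- solubility_sweep(fx$network, fx$flow, o, grid)$beta_peak
  pk_short <- solubility_sweep(short_ant, fl_s, o, grid)$beta_peak
  expect_lt(pk_short, pk_full)
})
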