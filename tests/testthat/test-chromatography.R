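# Capacity factor, Golay plate height, plate-number curves, species
# comparison.

test_that("capacity factor follows its defining arithmetic", {
  expect_equal(capacity_factor(1, 1, 0.2)$k_prime, 0)
  est <- capacity_factor(1, 0.4, 0.2)
  expect_equal(est$Cm, 0.6)
  expect_equal(est$Ca, 0.4)
  expect_equal(est$k_prime, 0.3, tolerance = 1e-12)
  # linear in the volume ratio
  expect_equal(capacity_factor(1, 0.4, 0.4)$k_prime, 0.6,
               tolerance = 1e-12)
  expect_error(capacity_factor(1, 0, 0.2), "clamp")
  expect_error(capacity_factor(1, 1.2, 0.2), "domain")
})

test_that("Golay plate height matches its limits and direct evaluation", {
  o <- ref_odorant()
  # pure longitudinal diffusion: H = 2 Da / u
  col_thin <- gc_column(Lc = 1, dc = 1e-9)
  expect_equal(golay_plate_height(0.012, o, col_thin, k_prime = 0),
               1.0e-3, tolerance = 1e-6)

  # cat calibration at u = 0.01 m/s (term-by-term hand evaluation)
  col_cat <- gc_column(Lc = 0.181, dc = 5e-4)
  expect_equal(golay_plate_height(0.01, o, col_cat, k_prime = 1),
               2.7195e-3, tolerance = 1e-4)
  expect_error(golay_plate_height(-0.01, o, col_cat, 1), "domain")
})

test_that("closed-form optimum agrees with numerical minimization", {
  o <- ref_odorant()
  # k' = 0: u_opt = sqrt(192) Da / dc and H_min = 2 dc sqrt(2/96)
  col <- gc_column(Lc = 0.181, dc = 5e-4)
  opt0 <- golay_optimum(o, col, k_prime = 0)
  expect_equal(opt0$u_opt, 0.166277, tolerance = 1e-5)
  expect_equal(opt0$H_min, 1.44338e-4, tolerance = 1e-5)

  # independent route: numerical minimization of H(u)
  for (kp in c(0, 0.5, 1, 3)) {
    opt <- golay_optimum(o, col, kp)
    num <- stats::optimize(function(u) golay_plate_height(u, o, col, kp),
                           c(1e-5, 10), tol = 1e-12)
    expect_equal(opt$u_opt, num$minimum, tolerance = 1e-5)
    expect_equal(opt$H_min, num$objective, tolerance = 1e-9)
  }
})

test_that("plate-number curves behave like Lc/H and find the grid peak", {
  o <- ref_odorant()
  col <- gc_column(Lc = 0.181, dc = 5e-4)
  pc <- plate_number_curve(col, o, k_prime = 1)
  # N scales linearly with column length
  pc2 <- plate_number_curve(gc_column(Lc = 0.362, dc = 5e-4), o, 1)
  expect_equal(pc2$N, 2 * pc$N, tolerance = 1e-12)
  expect_equal(pc2$N_peak, 2 * pc$N_peak, tolerance = 1e-12)

  # grid peak vs closed form: within one grid step and 0.1% in H
  step <- pc$u[2] / pc$u[1]
  expect_lt(abs(log(pc$u_peak / pc$u_opt)), log(step))
  expect_equal(0.181 / pc$N_peak, pc$H_min, tolerance = 1e-3)

  # H is convex in u: slopes of successive chords increase
  slopes <- diff(pc$H) / diff(pc$u)
  expect_true(all(diff(slopes) > 0))

  # peak is grid-converged: refining 2000 -> 4000 points moves it < 0.1%
  pc4 <- plate_number_curve(col, o, 1,
                            u_grid = 10^seq(-4, 0, length.out = 4000))
  expect_lt(abs(pc4$N_peak - pc$N_peak) / pc$N_peak, 1e-3)

  expect_error(plate_number_curve(col, o, 1, u_grid = c(0.1, 0.2, 0.4)),
               "domain")
})

test_that("efficiency falls with wider channels and thicker films", {
  o <- ref_odorant()
  base <- golay_optimum(o, gc_column(Lc = 0.1, dc = 5e-4, d = 3e-5), 1)
  wider <- golay_optimum(o, gc_column(Lc = 0.1, dc = 1e-3, d = 3e-5), 1)
  thicker <- golay_optimum(o, gc_column(Lc = 0.1, dc = 5e-4, d = 6e-5), 1)
  longer <- golay_optimum(o, gc_column(Lc = 0.2, dc = 5e-4, d = 3e-5), 1)
  expect_lt(wider$N_max, base$N_max)
  expect_lt(thicker$N_max, base$N_max)
  expect_gt(longer$N_max, base$N_max)
})

test_that("species comparison reports calibrated peaks and ratios", {
  cmp <- species_comparison(list(read_calibration("cat"),
                                 read_calibration("tube")))
  expect_equal(cmp$N_peak_rounded, c(67, 7))
  # identical calibrations give unit ratio
  cmp_id <- species_comparison(list(read_calibration("cat"),
                                    read_calibration("cat")))
  expect_equal(cmp_id$ratio_to_reference, c(1, 1), tolerance = 1e-12)
  # the operating plate number can never exceed the curve's true maximum
  full <- species_comparison(lapply(c("cat", "rat", "human", "tube"),
                                    read_calibration))
  N_max <- vapply(attr(full, "curves"), `[[`, numeric(1), "N_max")
  expect_true(all(full$N_at_operating <= N_max + 1e-9))
  # cat's low coil velocities reach near-peak plates; the tube's DM-speed
  # flow does not (the >100-fold actual-plate gap)
  ratio <- full$N_at_operating[full$name == "cat"] /
    full$N_at_operating[full$name == "tube"]
  expect_equal(ratio, 223.9, tolerance = 1e-3)
})

test_that("tube calibration diameter matches the geometry rule", {
  cal <- read_calibration("tube")
  nw <- build_straight_tube_network(4.4e-6, 0.3, 0.0264)
  expect_equal(cal$column$dc, nw$segments$width, tolerance = 1e-4)
  expect_equal(cal$column$Lc, nw$segments$length, tolerance = 1e-12)
})

test_that("capacity factor wired from network absorption stays finite", {
  fx <- cat_fixture()
  tab <- read_odorant_table(quiet = TRUE)
  for (nm in tab$name) {
    o <- as_odorant(tab, nm)
    if (o$beta < 1e-4) next
    ab <- solve_network_absorption(fx$network, fx$flow, o)
    est <- k_prime_from_absorption(ab, fx$network, fx$flow)
    expect_true(is.finite(est$k_prime))
    expect_gte(est$k_prime, 0)
    # retention grows with mucosal solubility until the clamp engages
  }
  # sanity: a nearly insoluble odorant retains almost nothing
  ab_ins <- solve_network_absorption(fx$network, fx$flow,
                                     ref_odorant(1e6))
  expect_lt(k_prime_from_absorption(ab_ins, fx$network, fx$flow)$k_prime,
            1e-3)
})
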