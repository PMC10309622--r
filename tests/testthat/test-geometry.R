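# Synthetic network generators, validation, morphometrics, serialization.

test_that("straight tube follows the DM inlet-area rule", {
  nw <- build_straight_tube_network(4.4e-6, 0.3, 0.0264)
  seg <- nw$segments
  expect_equal(seg$area, 1.46667e-5, tolerance = 1e-5)
  expect_equal(seg$width, 4.3215e-3, tolerance = 1e-4)
  # circular section: hydraulic diameter equals the diameter
  expect_equal(seg$hyd_diam, seg$width, tolerance = 1e-12)
  expect_equal(seg$region, "olfactory_coil")

  # A = Q/u: doubling the velocity halves the area exactly
  nw2 <- build_straight_tube_network(4.4e-6, 0.6, 0.0264)
  expect_equal(nw2$segments$area, seg$area / 2, tolerance = 1e-12)

  expect_error(build_straight_tube_network(-1e-6, 0.3, 0.02), "domain")
})

test_that("parallel-coil generator honours its structural contract", {
  nw <- build_parallel_coil_network(n_coils = 10)
  coils <- nw$segments[nw$segments$region == "olfactory_coil", ]
  expect_equal(nrow(coils), 10)
  expect_equal(length(unique(coils$length)), 1L)
  expect_equal(length(unique(coils$area)), 1L)
  expect_equal(length(unique(coils$perimeter)), 1L)
  # all coils are fed from the dorsal-medial head
  dm_head <- nw$segments$to[nw$segments$region == "dorsal_medial"]
  expect_true(all(coils$from == dm_head))
  expect_true(validate_network(nw))

  # degenerate case: one coil and no respiratory branch is a serial chain
  chain <- build_parallel_coil_network(
    n_coils = 1,
    anterior_spec = list(trunk_length = 0.005, trunk_width = 4e-3,
                         dm_passage_length = 0.025,
                         dm_passage_width = 2e-3),
    posterior_spec = NULL)
  expect_equal(nrow(chain$segments), 4L)
  deg <- table(c(chain$segments$from, chain$segments$to))
  expect_true(all(deg <= 2)) # pure chain topology

  expect_error(build_parallel_coil_network(n_coils = 0), "domain")
})

test_that("validator rejects broken networks", {
  seg <- channel_segments(c("a", "a"), c("n1", "n1"), c("n2", "n2"),
                          0.01, 1e-3, region = "dorsal_medial",
                          epithelium = "olfactory")
  expect_error(nasal_network(seg, "n1", "n2"), "unique")

  # a dangling segment not on any inlet->outlet path
  seg2 <- rbind(
    channel_segments("a", "n1", "n2", 0.01, 1e-3,
                     region = "dorsal_medial", epithelium = "olfactory"),
    channel_segments("b", "n1", "n3", 0.01, 1e-3,
                     region = "posterior_respiratory",
                     epithelium = "respiratory")
  )
  expect_error(nasal_network(seg2, "n1", "n2"), "structural")
})

test_that("cat-like defaults reproduce the documented epithelium shares", {
  fx <- cat_fixture()
  s <- summary(fx$network)
  expect_gte(s$olfactory_area_share, 0.11)
  expect_lte(s$olfactory_area_share, 0.13)

  pr <- surface_area_profile(fx$network, 0.005)
  # total lateral area is conserved by the binning
  expect_equal(sum(pr$total_area), attr(pr, "total_lateral_area"),
               tolerance = 1e-9)
  occupied <- which(pr$total_area > 0)
  imax <- which.max(pr$frac_olfactory)
  expect_gte(pr$frac_olfactory[imax], 0.45)
  # the olfactory peak is interior: share falls off on both sides
  expect_gt(imax, min(occupied))
  expect_lt(imax, max(occupied))
})

test_that("single-segment profile puts all area in one epithelium class", {
  nw <- build_straight_tube_network(4.4e-6, 0.3, 0.0264,
                                    mucosa = mucosa_spec("respiratory"))
  pr <- surface_area_profile(nw, 0.005)
  nonzero <- pr$total_area > 0
  expect_true(all(pr$frac_respiratory[nonzero] == 1))
  expect_equal(sum(pr$total_area),
               nw$segments$perimeter * nw$segments$length,
               tolerance = 1e-12)
})

test_that("network serialization is deterministic and round-trips", {
  nw1 <- build_parallel_coil_network(n_coils = 5, seed = 42)
  nw2 <- build_parallel_coil_network(n_coils = 5, seed = 42)
  js1 <- write_network_json(nw1)
  js2 <- write_network_json(nw2)
  expect_identical(js1, js2)

  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(nw1, path)
  back <- read_network_json(path)
  expect_equal(back$segments$hyd_diam, nw1$segments$hyd_diam,
               tolerance = 1e-15)
  expect_identical(back$segments$id, nw1$segments$id)
  expect_identical(back$inlet, nw1$inlet)
})

test_that("parallel coils are exchangeable: permuting ids changes nothing", {
  nw <- build_parallel_coil_network(n_coils = 8)
  seg <- nw$segments
  coil_rows <- which(seg$region == "olfactory_coil")
  perm_rows <- seq_len(nrow(seg))
  perm_rows[coil_rows] <- coil_rows[c(5, 3, 8, 1, 7, 2, 6, 4)]
  nw_p <- nasal_network(seg[perm_rows, ], nw$inlet, nw$outlet)

  fl <- solve_network_flow(nw)
  fl_p <- solve_network_flow(nw_p)
  expect_equal(dm_fraction(fl_p, nw_p), dm_fraction(fl, nw),
               tolerance = 1e-12)
  o <- ref_odorant(beta = 0.01)
  ab <- solve_network_absorption(nw, fl, o)
  ab_p <- solve_network_absorption(nw_p, fl_p, o)
  expect_equal(ab_p$region_fractions, ab$region_fractions,
               tolerance = 1e-12)
  expect_equal(ab_p$outlet_concentration, ab$outlet_concentration,
               tolerance = 1e-12)
})

test_that("mean path length averages sampled olfactory paths", {
  fx <- cat_fixture()
  # all cat olfactory paths are identical: dm + coil = 0.031 + 0.15
  expect_equal(mean_path_length(fx$network, n_paths = 10, seed = 1), 0.181,
               tolerance = 1e-12)
  expect_equal(mean_path_length(fx$network, n_paths = 3, seed = 99), 0.181,
               tolerance = 1e-12)

  # two equally likely coil paths of 0.1 and 0.2 m: enumeration gives a
  # mean of dm_length + 0.15 in the large-sample limit
  nw2 <- build_parallel_coil_network(
    n_coils = 2, coil_lengths = c(0.1, 0.2), dm_length = 1e-4,
    posterior_spec = NULL,
    anterior_spec = list(trunk_length = 0.005, trunk_width = 4e-3,
                         dm_passage_length = 0.025,
                         dm_passage_width = 2e-3))
  m <- mean_path_length(nw2, n_paths = 600, seed = 7)
  expect_equal(m, 0.1501, tolerance = 0.05)
  # deterministic given the seed
  expect_identical(m, mean_path_length(nw2, n_paths = 600, seed = 7))

  tube_resp <- build_straight_tube_network(4.4e-6, 0.3, 0.0264,
                                           mucosa_spec("respiratory"))
  tube_resp$segments$region <- "posterior_respiratory"
  expect_error(mean_path_length(tube_resp), "structural")
})
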