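# Synthetic nasal channel networks: generators, validation, morphometrics,
# serialization.  Networks are directed graphs of laminar channel segments
# with region and epithelium labels; they stand in for CT-derived geometry.

REGIONS <- c("anterior_respiratory", "dorsal_medial", "olfactory_coil",
             "posterior_respiratory")
OLFACTORY_REGIONS <- c("dorsal_medial", "olfactory_coil")
EPITHELIA <- c("squamous", "respiratory", "olfactory")

# Cross-section helpers.  Turbinate airways are slit-like; coil channels are
# modelled as rectangular slits of given width and depth:width ratio.
slit_section <- function(width, depth_ratio) {
  list(area = depth_ratio * width^2,
       perimeter = 2 * width * (1 + depth_ratio))
}

circle_section <- function(diameter) {
  list(area = pi * diameter^2 / 4, perimeter = pi * diameter)
}

#' Build a channel-segment table
#'
#' Vectorized constructor for the rows of a network's segment table.  Each
#' segment is a laminar channel with a slit (default, `depth_ratio` deep)
#' or circular cross-section; area, perimeter and hydraulic diameter
#' (`4A/P`) are derived from `width` (the channel width `d_c`, or the
#' diameter for circular sections).
#'
#' @param id,from,to Segment ids and junction node names.
#' @param length Segment length (m).
#' @param width Channel width (m).
#' @param shape `"slit"` or `"circular"`.
#' @param depth_ratio Slit depth:width ratio (default 3).
#' @param region One of `"anterior_respiratory"`, `"dorsal_medial"`,
#'   `"olfactory_coil"`, `"posterior_respiratory"`.
#' @param epithelium One of `"squamous"`, `"respiratory"`, `"olfactory"`.
#' @param mucus_thickness Mucus film thickness (m).
#' @param shape_factor Laminar resistance shape factor (default 1, the
#'   pure hydraulic-diameter approximation).
#' @return A data.frame, one row per segment.
#' @export
channel_segments <- function(id, from, to, length, width,
                             shape = "slit", depth_ratio = 3,
                             region, epithelium, mucus_thickness = 30e-6,
                             shape_factor = 1) {
  check_pos(length, "length")
  check_pos(width, "width")
  check_pos(depth_ratio, "depth_ratio")
  check_pos(mucus_thickness, "mucus_thickness")
  check_pos(shape_factor, "shape_factor")
  if (!all(region %in% REGIONS)) {
    stop_domain("region must be one of: ", paste(REGIONS, collapse = ", "))
  }
  if (!all(epithelium %in% EPITHELIA)) {
    stop_domain("epithelium must be one of: ", paste(EPITHELIA, collapse = ", "))
  }
  d <- data.frame(id = as.character(id), from = as.character(from),
                  to = as.character(to), length = length, width = width,
                  shape = shape, depth_ratio = depth_ratio,
                  region = region, epithelium = epithelium,
                  mucus_thickness = mucus_thickness,
                  shape_factor = shape_factor,
                  stringsAsFactors = FALSE)
  circ <- d$shape == "circular"
  sl <- slit_section(d$width, d$depth_ratio)
  ci <- circle_section(d$width)
  d$area <- ifelse(circ, ci$area, sl$area)
  d$perimeter <- ifelse(circ, ci$perimeter, sl$perimeter)
  d$hyd_diam <- 4 * d$area / d$perimeter
  d
}

#' Assemble a nasal channel network
#'
#' Low-level constructor used by the generators; also usable directly to
#' build toy networks in tests and examples.
#'
#' @param segments A segment table as built by the generators: one row per
#'   channel with columns `id, from, to, length, width, shape, depth_ratio,
#'   region, epithelium, mucus_thickness, shape_factor, area, perimeter,
#'   hyd_diam`.
#' @param inlet,outlet Node names of the external naris and the nasopharynx.
#' @param provenance List recording generator name, parameters and seed.
#' @param validate Run [validate_network()] on the result.
#'
#' @return An object of class `nasal_network`.
#' @export
nasal_network <- function(segments, inlet, outlet, provenance = list(),
                          validate = TRUE) {
  nodes <- unique(c(segments$from, segments$to))
  nw <- structure(
    list(segments = segments, nodes = nodes, inlet = inlet, outlet = outlet,
         provenance = provenance),
    class = "nasal_network"
  )
  if (validate) validate_network(nw)
  nw
}

network_graph <- function(network) {
  igraph::graph_from_data_frame(
    network$segments[, c("from", "to", "id")],
    directed = TRUE,
    vertices = data.frame(name = network$nodes)
  )
}

#' Validate a nasal network
#'
#' Checks the structural invariants every generated network must satisfy:
#' positive dimensions; hydraulic diameter consistent with `4A/P` (and
#' `P^2 = 4 pi A` for circular sections); exactly one inlet and one outlet;
#' weak connectivity; every segment on at least one inlet-to-outlet path;
#' valid region/epithelium labels; and, where dorsal-medial segments exist,
#' every olfactory coil fed from a dorsal-medial segment head.
#'
#' @param network A [nasal_network()].
#' @return `TRUE` invisibly; otherwise a structural error.
#' @export
validate_network <- function(network) {
  seg <- network$segments
  if (nrow(seg) < 1L) stop_structural("network has no segments")
  if (anyDuplicated(seg$id)) stop_structural("segment ids must be unique")
  check_pos(seg$length, "length")
  check_pos(seg$area, "area")
  check_pos(seg$perimeter, "perimeter")
  if (any(abs(seg$hyd_diam - 4 * seg$area / seg$perimeter) >
          1e-12 * seg$hyd_diam)) {
    stop_structural("hydraulic diameter inconsistent with 4A/P")
  }
  circ <- seg$shape == "circular"
  if (any(circ) && any(abs(seg$perimeter[circ]^2 - 4 * pi * seg$area[circ]) >
                       1e-9 * seg$perimeter[circ]^2)) {
    stop_structural("circular segments must satisfy P^2 = 4*pi*A")
  }
  if (!all(seg$region %in% REGIONS)) stop_structural("invalid region label")
  if (!all(seg$epithelium %in% EPITHELIA)) {
    stop_structural("invalid epithelium label")
  }
  nodes <- network$nodes
  indeg <- table(factor(seg$to, levels = nodes))
  outdeg <- table(factor(seg$from, levels = nodes))
  sources <- nodes[indeg == 0]
  sinks <- nodes[outdeg == 0]
  if (!identical(sources, network$inlet)) {
    stop_structural("network must have exactly one inlet (the declared naris)")
  }
  if (!identical(sinks, network$outlet)) {
    stop_structural("network must have exactly one outlet (the nasopharynx)")
  }
  g <- network_graph(network)
  if (!igraph::is_connected(g, mode = "weak")) {
    stop_structural("network must be weakly connected")
  }
  reach_in <- names(igraph::subcomponent(g, network$inlet, mode = "out"))
  reach_out <- names(igraph::subcomponent(g, network$outlet, mode = "in"))
  on_path <- seg$from %in% reach_in & seg$to %in% reach_out
  if (!all(on_path)) {
    stop_structural("every segment must lie on an inlet->outlet path")
  }
  dm_heads <- unique(seg$to[seg$region == "dorsal_medial"])
  coils <- seg$region == "olfactory_coil"
  if (any(coils) && length(dm_heads) > 0 &&
      !all(seg$from[coils] %in% dm_heads)) {
    stop_structural("olfactory coils must be fed from dorsal-medial segments")
  }
  invisible(TRUE)
}

#' Generate a parallel-coil nasal network
#'
#' Builds the synthetic analogue of a mammalian nose with separated
#' respiratory and olfactory flow paths: an anterior trunk splits into a
#' fast, low-surface dorsal-medial (DM) passage and a dense bank of
#' anterior (maxillary) respiratory channels; the DM passage feeds
#' `n_coils` identical parallel olfactory coils, while the respiratory bank
#' feeds a posterior respiratory bank; both reconverge before the
#' nasopharynx outlet.
#'
#' The defaults are the cat-like calibration documented in the package:
#' with restful breathing (22 ml/s) they place ~17% of the flow in the DM
#' stream at ~0.3 m/s, coil velocities of ~0.05 m/s, an olfactory share of
#' lateral surface area of ~12%, and a mean sampled olfactory path length
#' of 0.181 m.
#'
#' @param n_coils Number of parallel olfactory coil channels (>= 1).
#' @param coil_path_length Path length of each coil (m).
#' @param coil_width Slit width of each coil channel (m); this is the GC
#'   channel width `d_c`.
#' @param dm_length,dm_width Length and slit width of the olfactory
#'   dorsal-medial channel feeding the coils (m).
#' @param anterior_spec List describing the anterior region: `trunk_length`,
#'   `trunk_width` (squamous vestibule), `dm_passage_length`,
#'   `dm_passage_width` (anterior DM airway), `bank_n`, `bank_length`,
#'   `bank_width` (maxillary channel bank).
#' @param posterior_spec List describing the posterior respiratory region:
#'   `bank_n`, `bank_length`, `bank_width`, `nasopharynx_length`,
#'   `nasopharynx_width`; or `NULL` to omit the respiratory branch
#'   (degenerate serial topology).
#' @param mucosa_map Named character vector assigning an epithelium class to
#'   each structural role (`trunk`, `dm_passage`, `anterior_bank`, `dm`,
#'   `coil`, `posterior_bank`, `nasopharynx`).
#' @param mucus_thickness Mucus film thickness (m), default 30 um.
#' @param depth_ratio Slit depth:width ratio for all channels.
#' @param coil_lengths Optional vector of per-coil path lengths overriding
#'   `coil_path_length` (length `n_coils`); coils are otherwise identical.
#' @param seed Integer recorded in the provenance block and used for any
#'   stochastic generation steps (the default construction is
#'   deterministic).
#'
#' @return A validated [nasal_network()].
#' @export
build_parallel_coil_network <- function(
    n_coils = 100,
    coil_path_length = 0.15,
    coil_width = 5e-4,
    dm_length = 0.031,
    dm_width = 2e-3,
    anterior_spec = list(trunk_length = 0.005, trunk_width = 4e-3,
                         dm_passage_length = 0.025, dm_passage_width = 2e-3,
                         bank_n = 6000, bank_length = 0.025,
                         bank_width = 3e-4),
    posterior_spec = list(bank_n = 57, bank_length = 0.181,
                          bank_width = 8.8e-4, nasopharynx_length = 0.05,
                          nasopharynx_width = 5e-3),
    mucosa_map = c(trunk = "squamous", dm_passage = "respiratory",
                   anterior_bank = "respiratory", dm = "olfactory",
                   coil = "olfactory", posterior_bank = "respiratory",
                   nasopharynx = "respiratory"),
    mucus_thickness = 30e-6,
    depth_ratio = 3,
    coil_lengths = NULL,
    seed = 1L) {
  if (!is.numeric(n_coils) || n_coils < 1 || n_coils != round(n_coils)) {
    stop_domain("n_coils must be a positive integer")
  }
  n_coils <- as.integer(n_coils)
  if (is.null(coil_lengths)) {
    coil_lengths <- rep(coil_path_length, n_coils)
  }
  if (length(coil_lengths) != n_coils) {
    stop_domain("coil_lengths must have length n_coils")
  }
  a <- anterior_spec
  p <- posterior_spec
  segs <- list(
    channel_segments("trunk", "naris", "ant_junction", a$trunk_length,
                     a$trunk_width, depth_ratio = depth_ratio,
                     region = "anterior_respiratory",
                     epithelium = mucosa_map[["trunk"]],
                     mucus_thickness = mucus_thickness),
    channel_segments("dm_passage", "ant_junction", "dm_head",
                     a$dm_passage_length, a$dm_passage_width,
                     depth_ratio = depth_ratio,
                     region = "anterior_respiratory",
                     epithelium = mucosa_map[["dm_passage"]],
                     mucus_thickness = mucus_thickness),
    channel_segments("dm", "dm_head", "coil_head", dm_length, dm_width,
                     depth_ratio = depth_ratio, region = "dorsal_medial",
                     epithelium = mucosa_map[["dm"]],
                     mucus_thickness = mucus_thickness),
    channel_segments(sprintf("coil_%03d", seq_len(n_coils)),
                     "coil_head", "ethmoid_out", coil_lengths, coil_width,
                     depth_ratio = depth_ratio, region = "olfactory_coil",
                     epithelium = mucosa_map[["coil"]],
                     mucus_thickness = mucus_thickness)
  )
  if (!is.null(p)) {
    if (is.null(a$bank_n) || a$bank_n < 1) {
      stop_domain("anterior bank_n must be >= 1 when a posterior branch is present")
    }
    segs <- c(segs, list(
      channel_segments(sprintf("maxillary_%04d", seq_len(a$bank_n)),
                       "ant_junction", "resp_head", a$bank_length,
                       a$bank_width, depth_ratio = depth_ratio,
                       region = "anterior_respiratory",
                       epithelium = mucosa_map[["anterior_bank"]],
                       mucus_thickness = mucus_thickness),
      channel_segments(sprintf("posterior_%03d", seq_len(p$bank_n)),
                       "resp_head", "ethmoid_out", p$bank_length,
                       p$bank_width, depth_ratio = depth_ratio,
                       region = "posterior_respiratory",
                       epithelium = mucosa_map[["posterior_bank"]],
                       mucus_thickness = mucus_thickness),
      channel_segments("nasopharynx", "ethmoid_out", "pharynx",
                       p$nasopharynx_length, p$nasopharynx_width,
                       depth_ratio = depth_ratio,
                       region = "posterior_respiratory",
                       epithelium = mucosa_map[["nasopharynx"]],
                       mucus_thickness = mucus_thickness)
    ))
    outlet <- "pharynx"
  } else {
    outlet <- "ethmoid_out"
  }
  segments <- do.call(rbind, segs)
  nasal_network(
    segments, inlet = "naris", outlet = outlet,
    provenance = list(
      generator = "parallel_coil",
      parameters = list(n_coils = n_coils,
                        coil_path_length = coil_path_length,
                        coil_width = coil_width, dm_length = dm_length,
                        dm_width = dm_width, anterior_spec = a,
                        posterior_spec = p,
                        mucosa_map = as.list(mucosa_map),
                        mucus_thickness = mucus_thickness,
                        depth_ratio = depth_ratio),
      seed = as.integer(seed)
    )
  )
}

#' Generate an amphibian-like straight-tube network
#'
#' Single circular tube whose cross-sectional area is set by the
#' dorsal-medial stream flow and velocity (`A = Q_dm / u_dm`, diameter
#' `sqrt(4A/pi)`), emulating a DM stream that continues at the same
#' diameter all the way to the pharynx.
#'
#' @param dm_flow DM-stream volumetric flow (m^3/s).
#' @param dm_velocity DM-stream mean velocity (m/s).
#' @param tube_length Straight-line distance between olfactory inlet and
#'   outlet (m).
#' @param mucosa A [mucosa_spec()] for the tube wall.
#'
#' @return A validated [nasal_network()] with one `olfactory_coil` segment.
#' @examples
#' nw <- build_straight_tube_network(4.4e-6, 0.3, 0.0264)
#' nw$segments$width # tube diameter, 4.3215e-3 m
#' @export
build_straight_tube_network <- function(dm_flow, dm_velocity, tube_length,
                                        mucosa = mucosa_spec("olfactory")) {
  check_pos(dm_flow, "dm_flow")
  check_pos(dm_velocity, "dm_velocity")
  check_pos(tube_length, "tube_length")
  area <- dm_flow / dm_velocity
  diameter <- sqrt(4 * area / pi)
  segments <- channel_segments("tube", "naris", "pharynx", tube_length,
                               diameter, shape = "circular",
                               region = "olfactory_coil",
                               epithelium = mucosa$epithelium_class,
                               mucus_thickness = mucosa$mucus_thickness)
  nasal_network(segments, inlet = "naris", outlet = "pharynx",
                provenance = list(generator = "straight_tube",
                                  parameters = list(dm_flow = dm_flow,
                                                    dm_velocity = dm_velocity,
                                                    tube_length = tube_length),
                                  seed = NA_integer_))
}

#' Preset nasal networks
#'
#' Documented parameter sets: `"cat"` (the tuned parallel-coil calibration),
#' `"rat"` and `"human"` (illustrative scaled-down parallel-coil variants;
#' the human preset has a single coil, reflecting the absence of the
#' parallel-GC feature), and `"tube"` (amphibian-like straight tube sized
#' from the cat DM stream).
#'
#' @param species One of `"cat"`, `"rat"`, `"human"`, `"tube"`.
#' @param seed Seed recorded in provenance.
#' @return A [nasal_network()].
#' @export
network_preset <- function(species = c("cat", "rat", "human", "tube"),
                           seed = 1L) {
  species <- match.arg(species)
  switch(
    species,
    cat = build_parallel_coil_network(seed = seed),
    rat = build_parallel_coil_network(
      n_coils = 60, coil_path_length = 0.077, coil_width = 2e-4,
      dm_length = 0.012, dm_width = 1.2e-3,
      anterior_spec = list(trunk_length = 0.003, trunk_width = 2.5e-3,
                           dm_passage_length = 0.01,
                           dm_passage_width = 1.2e-3, bank_n = 3000,
                           bank_length = 0.012, bank_width = 2e-4),
      posterior_spec = list(bank_n = 40, bank_length = 0.09,
                            bank_width = 5e-4, nasopharynx_length = 0.02,
                            nasopharynx_width = 3e-3),
      seed = seed),
    human = build_parallel_coil_network(
      n_coils = 1, coil_path_length = 0.04, coil_width = 1e-3,
      dm_length = 0.0068, dm_width = 3e-3,
      anterior_spec = list(trunk_length = 0.01, trunk_width = 8e-3,
                           dm_passage_length = 0.02, dm_passage_width = 4e-3,
                           bank_n = 300, bank_length = 0.04,
                           bank_width = 1e-3),
      posterior_spec = list(bank_n = 30, bank_length = 0.06,
                            bank_width = 2e-3, nasopharynx_length = 0.03,
                            nasopharynx_width = 8e-3),
      seed = seed),
    tube = build_straight_tube_network(4.4e-6, 0.3, 0.0264)
  )
}

# distance from the inlet to every node along the shortest directed path,
# weighted by segment length
node_distances <- function(network) {
  g <- network_graph(network)
  d <- igraph::distances(g, v = network$inlet, to = igraph::V(g),
                         weights = network$segments$length, mode = "out")
  stats::setNames(as.numeric(d), colnames(d))
}

#' Surface-area profile along the network
#'
#' Apportions each segment's lateral area (perimeter x length) along its
#' span of distance-from-inlet, and reports per-bin total area and the
#' fraction contributed by each epithelium class.  Distance is measured
#' along the shortest inlet-to-segment path, the network analogue of the
#' axial distance-to-nostril coordinate of imaging-based profiles.
#'
#' @param network A [nasal_network()].
#' @param bin_width Bin width (m).
#' @return An object of class `area_profile`: a data.frame with
#'   `bin_center`, `total_area`, and one fraction column per epithelium
#'   class.
#' @export
surface_area_profile <- function(network, bin_width = 0.005) {
  check_pos(bin_width, "bin_width")
  seg <- network$segments
  dist <- node_distances(network)
  start <- dist[seg$from]
  end <- start + seg$length
  lat <- seg$perimeter * seg$length
  n_bins <- ceiling(max(end) / bin_width)
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  # overlap of each segment span with each bin (segments x bins)
  ov <- outer(end, hi, pmin) - outer(start, lo, pmax)
  ov[ov < 0] <- 0
  dens <- lat / seg$length # area per unit distance
  area_by_bin <- colSums(ov * dens)
  cls <- matrix(0, nrow = length(lo), ncol = length(EPITHELIA),
                dimnames = list(NULL, EPITHELIA))
  for (e in EPITHELIA) {
    sel <- seg$epithelium == e
    if (any(sel)) {
      cls[, e] <- colSums(ov[sel, , drop = FALSE] * dens[sel])
    }
  }
  frac <- sweep(cls, 1, ifelse(area_by_bin > 0, area_by_bin, 1), "/")
  out <- data.frame(bin_center = (lo + hi) / 2, total_area = area_by_bin)
  for (e in EPITHELIA) out[[paste0("frac_", e)]] <- frac[, e]
  structure(out, class = c("area_profile", "data.frame"),
            bin_width = bin_width,
            total_lateral_area = sum(lat))
}

#' Mean sampled olfactory path length
#'
#' Samples `n_paths` random walks (with replacement) through the olfactory
#' region (dorsal-medial plus coil segments): each walk starts at an
#' upstream-most olfactory node and, at every junction, chooses uniformly
#' among outgoing olfactory segments (ties broken by segment id order).
#' Returns the arithmetic mean of the walked path lengths.  The default of
#' 10 sampled paths matches the path-averaging procedure used to define the
#' GC column length.
#'
#' @param network A [nasal_network()].
#' @param n_paths Number of sampled paths (>= 1); default 10.
#' @param seed Integer seed making the sample deterministic.
#' @return Mean path length (m).
#' @export
mean_path_length <- function(network, n_paths = 10, seed = 1L) {
  if (!is.numeric(n_paths) || n_paths < 1 || n_paths != round(n_paths)) {
    stop_domain("n_paths must be a positive integer")
  }
  seg <- network$segments
  olf <- seg[seg$region %in% OLFACTORY_REGIONS, , drop = FALSE]
  if (nrow(olf) == 0L) {
    stop_structural("network has no olfactory-region segments")
  }
  olf <- olf[order(olf$id), , drop = FALSE]
  entry <- setdiff(unique(olf$from), unique(olf$to))
  if (length(entry) == 0L) {
    stop_structural("olfactory region has no entry node (flow cycle?)")
  }
  with_seed(seed, {
    lengths <- vapply(seq_len(n_paths), function(i) {
      node <- if (length(entry) == 1L) entry else sample(entry, 1L)
      total <- 0
      repeat {
        nxt <- which(olf$from == node)
        if (length(nxt) == 0L) break
        pick <- if (length(nxt) == 1L) nxt else nxt[sample.int(length(nxt), 1L)]
        total <- total + olf$length[pick]
        node <- olf$to[pick]
      }
      total
    }, numeric(1))
    mean(lengths)
  })
}

#' Serialize a network to JSON
#'
#' Writes nodes, the full segment table and the provenance block.  Output is
#' byte-stable: identical networks serialize to identical files.
#'
#' @param network A [nasal_network()].
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_network_json <- function(network, path = NULL) {
  obj <- list(nodes = network$nodes, inlet = network$inlet,
              outlet = network$outlet, segments = network$segments,
              provenance = network$provenance)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path Path written by [write_network_json()].
#' @return A validated [nasal_network()].
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  nasal_network(obj$segments, obj$inlet, obj$outlet,
                provenance = obj$provenance)
}

#' @export
print.nasal_network <- function(x, ...) {
  seg <- x$segments
  cat(sprintf("<nasal_network> %d segments, %d nodes (%s -> %s)\n",
              nrow(seg), length(x$nodes), x$inlet, x$outlet))
  cat(sprintf("  generator: %s\n",
              x$provenance$generator %||% "unspecified"))
  tab <- table(seg$region)
  cat("  segments by region: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.nasal_network <- function(object, ...) {
  seg <- object$segments
  lat <- seg$perimeter * seg$length
  by_epi <- tapply(lat, seg$epithelium, sum)
  by_reg <- tapply(lat, seg$region, sum)
  out <- list(
    n_segments = nrow(seg),
    total_lateral_area = sum(lat),
    lateral_area_by_epithelium = by_epi,
    lateral_area_by_region = by_reg,
    olfactory_area_share = sum(lat[seg$epithelium == "olfactory"]) / sum(lat)
  )
  class(out) <- "summary.nasal_network"
  out
}

#' @export
print.summary.nasal_network <- function(x, ...) {
  cat(sprintf("Nasal network: %d segments, total lateral area %.4g m^2\n",
              x$n_segments, x$total_lateral_area))
  cat(sprintf("Olfactory epithelium share: %.1f%%\n",
              100 * x$olfactory_area_share))
  cat("Lateral area by epithelium (m^2):\n")
  print(round(x$lateral_area_by_epithelium, 6))
  invisible(x)
}

#' Plot the epithelium area profile of a network
#'
#' @param x A [nasal_network()].
#' @param bin_width Bin width (m) passed to [surface_area_profile()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.nasal_network <- function(x, bin_width = 0.005, ...) {
  pr <- surface_area_profile(x, bin_width)
  graphics::matplot(pr$bin_center * 1e3,
                    100 * cbind(pr$frac_squamous, pr$frac_respiratory,
                                pr$frac_olfactory),
                    type = "l", lty = 1, lwd = 2,
                    col = c("grey50", "steelblue", "firebrick"),
                    xlab = "distance from naris (mm)",
                    ylab = "epithelium share of lateral area (%)", ...)
  graphics::legend("topleft", c("squamous", "respiratory", "olfactory"),
                   col = c("grey50", "steelblue", "firebrick"), lty = 1,
                   lwd = 2, bty = "n")
  invisible(pr)
}
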