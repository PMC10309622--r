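# Pressure-driven laminar flow on the channel network, DM-stream fraction,
# and dimensionless regime numbers (Womersley, Strouhal, Reynolds).

#' Breathing condition
#'
#' @param total_flow Total volumetric flow Q (m^3/s).  Defaults to restful
#'   breathing for a 5.4 kg cat, 22 ml/s; sniffing is about 140 ml/s.
#' @param frequency Breathing frequency (Hz); 1 at rest, about 5 sniffing.
#' @param kinematic_viscosity Air kinematic viscosity (m^2/s).
#' @param air_density Air density (kg/m^3); with the default viscosity this
#'   gives a dynamic viscosity of 1.8e-5 Pa s for the resistance law.
#' @return An object of class `breathing_condition`.
#' @export
breathing_condition <- function(total_flow = 22e-6, frequency = 1,
                                kinematic_viscosity = 1.5e-5,
                                air_density = 1.2) {
  check_pos(total_flow, "total_flow")
  check_pos(frequency, "frequency", allow_zero = TRUE)
  check_pos(kinematic_viscosity, "kinematic_viscosity")
  check_pos(air_density, "air_density")
  structure(list(total_flow = total_flow, frequency = frequency,
                 kinematic_viscosity = kinematic_viscosity,
                 air_density = air_density),
            class = "breathing_condition")
}

#' Solve laminar network flow
#'
#' Solves the linear resistance network with per-segment laminar
#' (Hagen-Poiseuille) resistance `128 mu L / (pi d_h^4)` on the hydraulic
#' diameter, times an optional per-segment shape factor (default 1 — the
#' pure hydraulic-diameter approximation for non-circular sections).  The
#' total inlet flow is prescribed; node pressures are relative to the
#' outlet.
#'
#' @param network A [nasal_network()].
#' @param condition A [breathing_condition()].
#' @return An object of class `flow_solution`: per-segment flows `q` and
#'   mean velocities `u = q/A`, per-node relative pressures, and the
#'   maximum Kirchhoff residual.
#' @export
solve_network_flow <- function(network, condition = breathing_condition()) {
  seg <- network$segments
  Q <- condition$total_flow
  mu <- condition$kinematic_viscosity * condition$air_density
  resist <- 128 * mu * seg$length * seg$shape_factor / (pi * seg$hyd_diam^4)
  g <- 1 / resist
  nodes <- network$nodes
  n <- length(nodes)
  i <- match(seg$from, nodes)
  j <- match(seg$to, nodes)
  G <- Matrix::sparseMatrix(i = c(i, j, i, j), j = c(i, j, j, i),
                            x = c(g, g, -g, -g), dims = c(n, n))
  o <- match(network$outlet, nodes)
  b <- numeric(n)
  b[match(network$inlet, nodes)] <- Q
  p <- numeric(n)
  sol <- tryCatch(
    solve(as.matrix(G[-o, -o, drop = FALSE]), b[-o]),
    error = function(e) {
      stop(sprintf(
        "numerical error: flow system singular (%d nodes, %d segments): %s",
        n, nrow(seg), conditionMessage(e)), call. = FALSE)
    })
  p[-o] <- as.numeric(sol)
  q <- g * (p[i] - p[j])
  u <- q / seg$area
  net_in <- vapply(seq_len(n), function(k) {
    sum(q[j == k]) - sum(q[i == k])
  }, numeric(1))
  net_in[match(network$inlet, nodes)] <-
    net_in[match(network$inlet, nodes)] + Q
  net_in[o] <- net_in[o] - Q
  structure(
    list(segments = data.frame(id = seg$id, q = q, u = u,
                               stringsAsFactors = FALSE),
         node_pressure = stats::setNames(p, nodes),
         total_flow = Q, condition = condition,
         kirchhoff_residual = max(abs(net_in)) / Q),
    class = "flow_solution"
  )
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> Q = %.4g m^3/s over %d segments\n",
              x$total_flow, nrow(x$segments)))
  cat(sprintf("  velocity range: %.4g to %.4g m/s\n",
              min(abs(x$segments$u)), max(abs(x$segments$u))))
  cat(sprintf("  max Kirchhoff residual: %.3g (relative to Q)\n",
              x$kirchhoff_residual))
  invisible(x)
}

#' @export
as.data.frame.flow_solution <- function(x, ...) x$segments

#' Dorsal-medial stream fraction
#'
#' Fraction of the total flow entering the dorsal-medial channel at its
#' upstream junction.
#'
#' @param flow A [solve_network_flow()] result.
#' @param network The network the flow was solved on.
#' @return A number in `[0, 1]`.
#' @export
dm_fraction <- function(flow, network) {
  seg <- network$segments
  dm <- seg$region == "dorsal_medial"
  if (!any(dm)) stop_structural("network has no dorsal-medial segments")
  # upstream-most DM segments: tail node not fed by another DM segment
  entry <- dm & !(seg$from %in% seg$to[dm])
  sum(abs(flow$segments$q[entry])) / flow$total_flow
}

#' Dimensionless flow-regime report
#'
#' Evaluates, per segment, the Womersley number `W0 = R sqrt(2 pi f / nu)`,
#' the Strouhal number `S = 2 pi f L / U` and the Reynolds number
#' `Re = U R / nu`, where `R` is the local hydraulic diameter, `L` the
#' axial distance from the inlet to the segment midpoint, and `U` the local
#' mean velocity.  Quasi-steady flow requires `W0 < 4` and `S < 1`; laminar
#' flow requires `Re < 2300`.  A naris-based global row (the conventional
#' reference location) is included as attribute `naris`.  The axial Peclet
#' number `U L_seg / Da` is logged as a plug-flow validity diagnostic.
#'
#' @param network A [nasal_network()].
#' @param flow A [solve_network_flow()] result.
#' @param condition The [breathing_condition()] used.
#' @param positions Optional axial positions (m, distance from inlet):
#'   rows are restricted to segments whose span contains a position.
#' @param reference_Da Air diffusivity (m^2/s) used for the Peclet
#'   diagnostic.
#' @return A data.frame of class `regime_report`.
#' @export
regime_report <- function(network, flow, condition, positions = NULL,
                          reference_Da = 6e-6) {
  seg <- network$segments
  dist <- node_distances(network)
  mid <- dist[seg$from] + seg$length / 2
  U <- abs(flow$segments$u)
  f <- condition$frequency
  nu <- condition$kinematic_viscosity
  W0 <- seg$hyd_diam * sqrt(2 * pi * f / nu)
  S <- ifelse(U > 0, 2 * pi * f * mid / U, ifelse(f > 0, Inf, 0))
  Re <- U * seg$hyd_diam / nu
  peclet <- U * seg$length / reference_Da
  rep <- data.frame(
    id = seg$id, region = seg$region, distance = as.numeric(mid),
    hyd_diam = seg$hyd_diam, U = U, W0 = W0, S = S, Re = Re,
    peclet = peclet,
    quasi_steady = W0 < 4 & S < 1,
    laminar = Re < 2300,
    stringsAsFactors = FALSE
  )
  if (!is.null(positions)) {
    check_pos(positions, "positions", allow_zero = TRUE)
    start <- dist[seg$from]
    end <- start + seg$length
    if (any(positions > max(end))) {
      stop_domain("positions must lie within the network extent")
    }
    keep <- vapply(seq_len(nrow(seg)), function(k) {
      any(positions >= start[k] & positions <= end[k])
    }, logical(1))
    rep <- rep[keep, , drop = FALSE]
  }
  if (any(rep$peclet <= 10)) {
    warning("some segments have axial Peclet <= 10; ",
            "the plug-flow uptake closure neglects axial diffusion",
            call. = FALSE)
  }
  inlet_seg <- which(network$segments$from == network$inlet)[1]
  attr(rep, "naris") <- list(
    hyd_diam = seg$hyd_diam[inlet_seg],
    W0 = seg$hyd_diam[inlet_seg] * sqrt(2 * pi * f / nu),
    Re = U[inlet_seg] * seg$hyd_diam[inlet_seg] / nu
  )
  class(rep) <- c("regime_report", "data.frame")
  rep
}

#' Export a flow solution as CSV
#'
#' Writes segment id, flow, velocity and Reynolds number.
#'
#' @param flow A [solve_network_flow()] result.
#' @param network The network it was solved on.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(flow, network, path) {
  seg <- network$segments
  out <- data.frame(id = seg$id, region = seg$region,
                    q = flow$segments$q, u = flow$segments$u,
                    Re = abs(flow$segments$u) * seg$hyd_diam /
                      flow$condition$kinematic_viscosity)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
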