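# Odorant uptake along channels under the air/mucus Robin wall condition:
# a plug-flow closure with series wall conductance, a two-dimensional
# Graetz-type reference solver used as its numerical oracle, network-level
# absorption, the anterior-depletion experiment, and solubility sweeps.

# Vectorized outlet/inlet concentration ratio for the plug-flow closure.
# k_wall = Dm/(beta d): conductance of the mucus film at the interface;
# k_conv = Sh Da / d_h: air-side convective conductance (laminar Sherwood);
# combined in series, then integrated along the channel:
# ratio = exp(-P k_tot L / (u A)).
uptake_ratio_vec <- function(perimeter, area, length, hyd_diam, u,
                             mucus_thickness, Da, Dm, beta,
                             enabled = TRUE, sherwood = 3.66) {
  if (any(u <= 0)) stop_domain("u must be > 0")
  k_wall <- Dm / (beta * mucus_thickness)
  k_conv <- sherwood * Da / hyd_diam
  k_tot <- 1 / (1 / k_conv + 1 / k_wall)
  ratio <- exp(-perimeter * k_tot * length / (u * area))
  ifelse(rep_len(enabled, length(ratio)), ratio, 1)
}

#' Outlet/inlet concentration ratio of one channel segment
#'
#' Plug-flow closure with series wall conductance: the mucus-film
#' conductance `k_wall = Dm/(beta d)` in series with the air-side laminar
#' convective conductance `k_conv = Sh Da / d_h` (constant Sherwood number,
#' default 3.66, the fully developed constant-wall-concentration value).
#' The survival ratio over the segment is `exp(-P k_tot L / (u A))`.
#' The two-dimensional Graetz solver [graetz_reference_solution()] bounds
#' the closure's error.
#'
#' @param segment One row of a network's segment table (or any list with
#'   `perimeter`, `area`, `length`, `hyd_diam`, `mucus_thickness`).
#' @param u Mean air velocity in the segment (m/s), > 0.
#' @param odorant An [odorant()].
#' @param enabled If `FALSE`, uptake is switched off and the ratio is 1
#'   (used for region-disabling experiments).
#' @param sherwood Constant Sherwood number of the closure.
#' @return A list of class `segment_uptake` with `ratio`, `k_wall`,
#'   `k_conv`, `k_tot` and the absorbed fraction `1 - ratio`.
#' @examples
#' seg <- list(perimeter = pi * 1e-3, area = pi * 0.25e-6, length = 0.05,
#'             hyd_diam = 1e-3, mucus_thickness = 3e-5)
#' o <- odorant("x", 120, 100, beta = 1, Da = 6e-6, Dm = 1e-9)
#' segment_uptake(seg, u = 0.05, o)$ratio # 0.8754
#' @export
segment_uptake <- function(segment, u, odorant, enabled = TRUE,
                           sherwood = 3.66) {
  check_pos(u, "u")
  k_wall <- odorant$Dm / (odorant$beta * segment$mucus_thickness)
  k_conv <- sherwood * odorant$Da / segment$hyd_diam
  k_tot <- 1 / (1 / k_conv + 1 / k_wall)
  ratio <- uptake_ratio_vec(segment$perimeter, segment$area, segment$length,
                            segment$hyd_diam, u, segment$mucus_thickness,
                            odorant$Da, odorant$Dm, odorant$beta,
                            enabled = enabled, sherwood = sherwood)
  structure(list(ratio = ratio, absorbed = 1 - ratio, k_wall = k_wall,
                 k_conv = k_conv, k_tot = k_tot),
            class = "segment_uptake")
}

#' Graetz-type reference solution in a circular tube
#'
#' Marching finite-volume solution of steady laminar advection-diffusion
#' in a circular tube with parabolic velocity profile and a Robin wall
#' condition `dC/dr = -(K_hat / R) C` at the wall (`K_hat = Inf` gives the
#' classical Dirichlet Graetz problem).  Axial diffusion is neglected, so
#' the solution depends only on `K_hat` and the Graetz coordinate
#' `zeta = x Da / (U R^2)`.  Serves as the independent numerical oracle for
#' the plug-flow closure of [segment_uptake()].
#'
#' @param K_hat Dimensionless wall conductance (Biot-like number)
#'   `k_wall R / Da`; may be `Inf`.
#' @param zeta_max Tube length in Graetz units.  Alternatively give
#'   `peclet` and `length_over_radius`, with
#'   `zeta_max = (L/R) / Pe` and `Pe = U R / Da`.
#' @param nr Number of radial cells.
#' @param nx Number of axial steps (backward-Euler marching).
#' @param peclet,length_over_radius Optional alternative parameterization.
#' @return A list of class `graetz_solution`: `zeta`, mixed-mean
#'   concentration `Cm`, `outlet_ratio`, the local Sherwood number
#'   `sherwood` at the outlet (diameter-based), and the grid parameters.
#' @examples
#' g <- graetz_reference_solution(K_hat = Inf, zeta_max = 0.5,
#'                                nr = 64, nx = 200)
#' g$sherwood # -> 3.657 under refinement
#' @export
graetz_reference_solution <- function(K_hat, zeta_max = 0.5, nr = 128,
                                      nx = 400, peclet = NULL,
                                      length_over_radius = NULL) {
  if (!is.numeric(K_hat) || length(K_hat) != 1L || is.na(K_hat) || K_hat < 0) {
    stop_domain("K_hat must be a non-negative number (Inf allowed)")
  }
  if (!is.null(peclet)) {
    check_pos(peclet, "peclet")
    check_pos(length_over_radius, "length_over_radius")
    zeta_max <- length_over_radius / peclet
  }
  check_pos(zeta_max, "zeta_max")
  if (nr < 8 || nx < 8) stop_domain("grid resolution insufficient (nr, nx >= 8)")
  dr <- 1 / nr
  r <- (seq_len(nr) - 0.5) * dr
  u <- 2 * (1 - r^2)          # parabolic profile, mean velocity 1
  vol <- u * r * dr           # advective weight per cell
  rf <- seq_len(nr - 1) * dr  # interior face radii
  # wall exchange: half-cell diffusion in series with the wall conductance
  K_eff <- if (is.infinite(K_hat)) 2 / dr else 1 / (dr / 2 + 1 / K_hat)
  dz <- zeta_max / nx
  lower <- c(0, -rf / dr)
  upper <- c(-rf / dr, 0)
  diagv <- vol / dz + c(rf / dr, 0) + c(0, rf / dr)
  diagv[nr] <- diagv[nr] + K_eff # wall face at r = 1
  fac <- thomas_factor(lower, diagv, upper)
  C <- rep(1, nr)
  wsum <- sum(vol)
  Cm <- numeric(nx + 1)
  Cm[1] <- 1
  for (step in seq_len(nx)) {
    C <- thomas_solve(fac, vol * C / dz)
    if (any(!is.finite(C))) {
      stop("numerical error: Graetz marching diverged", call. = FALSE)
    }
    Cm[step + 1] <- sum(vol * C) / wsum
  }
  qw <- K_eff * C[nr]
  Cwall <- if (is.infinite(K_hat)) 0 else qw / K_hat
  sherwood <- 2 * qw / (Cm[nx + 1] - Cwall)
  structure(
    list(zeta = seq(0, zeta_max, length.out = nx + 1), Cm = Cm,
         outlet_ratio = Cm[nx + 1], sherwood = sherwood, K_hat = K_hat,
         nr = nr, nx = nx),
    class = "graetz_solution"
  )
}

#' Plug-flow closure outlet ratio in Graetz variables
#'
#' The closure of [segment_uptake()] written in the nondimensional
#' variables of [graetz_reference_solution()]:
#' `ratio = exp(-2 zeta / (2/Sh + 1/K_hat))`.
#'
#' @inheritParams graetz_reference_solution
#' @param sherwood Constant Sherwood number of the closure.
#' @return The outlet/inlet mixed-mean concentration ratio.
#' @export
uptake_closure_ratio <- function(K_hat, zeta_max, sherwood = 3.66) {
  check_pos(zeta_max, "zeta_max")
  K_tot_hat <- 1 / (2 / sherwood + 1 / K_hat)
  exp(-2 * zeta_max * K_tot_hat)
}

#' Solve odorant absorption on a network
#'
#' Sweeps the flow directed acyclic graph in topological order (descending
#' node pressure).  Junction mixing is perfect (flow-weighted mean
#' concentration); each segment attenuates its inlet concentration by the
#' plug-flow closure ratio of [segment_uptake()].  Segments whose region is
#' in `disabled_regions` have uptake switched off.
#'
#' @param network A [nasal_network()].
#' @param flow A [solve_network_flow()] result for that network.
#' @param odorant An [odorant()].
#' @param disabled_regions Character vector of region labels whose uptake
#'   is switched off.
#' @param sherwood Constant Sherwood number of the closure.
#' @return An object of class `absorption_result`: per-segment inlet and
#'   outlet concentrations and absorbed mass share; per-region absorbed
#'   fractions (`anterior_respiratory`, `olfactory` = dorsal-medial plus
#'   coils, `posterior_respiratory`); the outlet concentration; and the
#'   relative mass-balance error.
#' @export
solve_network_absorption <- function(network, flow, odorant,
                                     disabled_regions = character(),
                                     sherwood = 3.66) {
  seg <- network$segments
  if (!identical(seg$id, flow$segments$id)) {
    stop_structural("flow solution does not match network segments")
  }
  bad <- setdiff(disabled_regions, REGIONS)
  if (length(bad)) stop_domain("unknown region label: ",
                               paste(bad, collapse = ", "))
  q <- flow$segments$q
  flip <- q < 0
  from <- ifelse(flip, seg$to, seg$from)
  to <- ifelse(flip, seg$from, seg$to)
  qa <- abs(q)
  ua <- abs(flow$segments$u)
  carries <- qa > 0
  enabled <- !(seg$region %in% disabled_regions)
  ratio <- rep(1, nrow(seg))
  ratio[carries] <- uptake_ratio_vec(
    seg$perimeter[carries], seg$area[carries], seg$length[carries],
    seg$hyd_diam[carries], ua[carries], seg$mucus_thickness[carries],
    odorant$Da, odorant$Dm, odorant$beta,
    enabled = enabled[carries], sherwood = sherwood)
  nodes <- network$nodes
  p <- flow$node_pressure[nodes]
  ord <- order(-p)
  if (p[network$inlet] < max(p)) {
    stop_structural("cycles in flow direction (inlet is not the pressure maximum)")
  }
  conc <- stats::setNames(rep(0, length(nodes)), nodes)
  conc[network$inlet] <- 1
  for (node in nodes[ord]) {
    if (node == network$inlet) next
    inc <- which(to == node & carries)
    if (length(inc)) {
      conc[node] <- sum(qa[inc] * conc[from[inc]] * ratio[inc]) / sum(qa[inc])
    }
  }
  c_in <- conc[from]
  c_out <- c_in * ratio
  absorbed_mass <- qa * c_in * (1 - ratio)
  Q <- flow$total_flow
  region3 <- ifelse(seg$region %in% OLFACTORY_REGIONS, "olfactory",
                    seg$region)
  region_frac <- tapply(absorbed_mass, region3, sum) / Q
  all3 <- c("anterior_respiratory", "olfactory", "posterior_respiratory")
  rf <- stats::setNames(numeric(length(all3)), all3)
  rf[names(region_frac)] <- region_frac
  outlet_conc <- conc[network$outlet]
  balance <- abs(Q - (Q * outlet_conc + sum(absorbed_mass))) / Q
  structure(
    list(segments = data.frame(id = seg$id, region = seg$region,
                               c_in = as.numeric(c_in),
                               c_out = as.numeric(c_out),
                               ratio = ratio,
                               absorbed_share = absorbed_mass / Q,
                               stringsAsFactors = FALSE),
         node_concentration = conc,
         region_fractions = rf,
         outlet_concentration = as.numeric(outlet_conc),
         total_absorbed = sum(absorbed_mass) / Q,
         mass_balance_error = as.numeric(balance),
         odorant = odorant$name, beta = odorant$beta,
         disabled_regions = disabled_regions),
    class = "absorption_result"
  )
}

#' @export
print.absorption_result <- function(x, ...) {
  cat(sprintf("<absorption_result> odorant %s (beta = %.3g)\n",
              x$odorant, x$beta))
  if (length(x$disabled_regions)) {
    cat("  uptake disabled in:", paste(x$disabled_regions, collapse = ", "),
        "\n")
  }
  cat(sprintf("  absorbed: %.2f%% total (outlet C' = %.4g)\n",
              100 * x$total_absorbed, x$outlet_concentration))
  f <- x$region_fractions
  cat(sprintf("  by region: anterior %.2f%%, olfactory %.2f%%, posterior %.2f%%\n",
              100 * f[["anterior_respiratory"]], 100 * f[["olfactory"]],
              100 * f[["posterior_respiratory"]]))
  cat(sprintf("  mass-balance error: %.2g\n", x$mass_balance_error))
  invisible(x)
}

#' Anterior-depletion experiment
#'
#' Runs [solve_network_absorption()] twice — with uptake everywhere, and
#' with uptake switched off in the anterior respiratory region — and
#' reports per-region absorbed fractions for both scenarios together with
#' the relative reduction caused by anterior uptake.  A dorsal-medial
#' stream that bypasses the absorbing anterior surfaces shows up as a much
#' smaller relative reduction for the olfactory region than for the
#' posterior respiratory region.
#'
#' @inheritParams solve_network_absorption
#' @return A list of class `depletion_experiment` with both
#'   `absorption_result`s and a `summary` data.frame (region,
#'   `frac_with_anterior`, `frac_without_anterior`, `relative_reduction`).
#' @export
anterior_depletion_experiment <- function(network, flow, odorant,
                                          sherwood = 3.66) {
  if (!"anterior_respiratory" %in% network$segments$region ||
      !any(network$segments$region %in% OLFACTORY_REGIONS)) {
    stop_structural(
      "depletion experiment needs anterior and olfactory regions present")
  }
  with_ant <- solve_network_absorption(network, flow, odorant,
                                       sherwood = sherwood)
  without_ant <- solve_network_absorption(
    network, flow, odorant, disabled_regions = "anterior_respiratory",
    sherwood = sherwood)
  w <- with_ant$region_fractions
  wo <- without_ant$region_fractions
  rel <- ifelse(wo > 0, (wo - w) / wo, 0)
  structure(
    list(with_anterior = with_ant, without_anterior = without_ant,
         summary = data.frame(region = names(w),
                              frac_with_anterior = as.numeric(w),
                              frac_without_anterior = as.numeric(wo),
                              relative_reduction = as.numeric(rel),
                              stringsAsFactors = FALSE)),
    class = "depletion_experiment"
  )
}

#' @export
print.depletion_experiment <- function(x, ...) {
  cat("<depletion_experiment> absorbed fraction by region\n")
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  %-22s with %.2f%%  without %.2f%%  reduction %.1f%%\n",
                s$region[k], 100 * s$frac_with_anterior[k],
                100 * s$frac_without_anterior[k],
                100 * s$relative_reduction[k]))
  }
  invisible(x)
}

#' Solubility sweep
#'
#' Evaluates network absorption over a grid of air/mucus partition
#' coefficients, holding the odorant's diffusivities fixed, and locates the
#' partition coefficient that maximizes olfactory absorption.  With
#' anterior uptake enabled the olfactory curve typically has an interior
#' maximum at intermediate solubility — the trade-off between mucosal
#' solubility and upstream depletion; with anterior uptake disabled it is
#' monotone (more soluble means more absorbed).
#'
#' @inheritParams solve_network_absorption
#' @param odorant_template An [odorant()] whose `beta` is replaced by each
#'   grid value.
#' @param beta_grid Positive partition-coefficient grid; should span at
#'   least four decades.
#' @return An object of class `solubility_sweep`: a long data.frame
#'   (`beta`, `region`, `fraction`, `scenario`) plus the olfactory-peak
#'   location `beta_peak` (`NA` when the maximum is not interior).
#' @export
solubility_sweep <- function(network, flow, odorant_template, beta_grid,
                             disabled_regions = character(),
                             sherwood = 3.66) {
  check_pos(beta_grid, "beta_grid")
  if (length(beta_grid) < 3) stop_domain("beta_grid needs at least 3 points")
  if (max(beta_grid) / min(beta_grid) < 1e4) {
    stop_domain("beta_grid should span at least 4 decades")
  }
  beta_grid <- sort(beta_grid)
  scen <- if (length(disabled_regions)) "anterior_disabled" else "full_uptake"
  rows <- lapply(beta_grid, function(b) {
    o <- odorant(odorant_template$name, odorant_template$molecular_weight,
                 odorant_template$molar_volume, beta = b,
                 Da = odorant_template$Da, Dm = odorant_template$Dm,
                 quiet = TRUE)
    res <- solve_network_absorption(network, flow, o,
                                    disabled_regions = disabled_regions,
                                    sherwood = sherwood)
    data.frame(beta = b, region = names(res$region_fractions),
               fraction = as.numeric(res$region_fractions),
               scenario = scen, stringsAsFactors = FALSE)
  })
  curves <- do.call(rbind, rows)
  olf <- curves$fraction[curves$region == "olfactory"]
  imax <- which.max(olf)
  # a maximum counts as interior only if it strictly exceeds both curve
  # ends (beyond numerical noise on flat plateaus)
  interior <- imax > 1 && imax < length(beta_grid) &&
    olf[imax] - max(olf[1], olf[length(olf)]) > 1e-9 * olf[imax]
  structure(
    list(curves = curves, beta_grid = beta_grid,
         beta_peak = if (interior) beta_grid[imax] else NA_real_,
         olfactory_peak = olf[imax], interior_peak = interior,
         scenario = scen),
    class = "solubility_sweep"
  )
}

#' @export
print.solubility_sweep <- function(x, ...) {
  cat(sprintf("<solubility_sweep> %d beta values in [%.2g, %.2g] (%s)\n",
              length(x$beta_grid), min(x$beta_grid), max(x$beta_grid),
              x$scenario))
  if (x$interior_peak) {
    cat(sprintf("  olfactory absorption peaks at beta = %.3g (%.2f%%)\n",
                x$beta_peak, 100 * x$olfactory_peak))
  } else {
    cat(sprintf("  olfactory absorption is extremal at the grid edge (%.2f%%)\n",
                100 * x$olfactory_peak))
  }
  invisible(x)
}

#' Plot a solubility sweep
#'
#' @param x A [solubility_sweep()] result.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.solubility_sweep <- function(x, ...) {
  wide <- stats::reshape(x$curves[, c("beta", "region", "fraction")],
                         idvar = "beta", timevar = "region",
                         direction = "wide")
  graphics::matplot(wide$beta, 100 * wide[, -1], type = "l", log = "x",
                    lty = 1, lwd = 2,
                    col = c("steelblue", "firebrick", "grey40"),
                    xlab = "air/mucus partition coefficient beta",
                    ylab = "absorbed fraction (%)", ...)
  graphics::legend("topright",
                   sub("^fraction\\.", "", names(wide)[-1]),
                   col = c("steelblue", "firebrick", "grey40"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(wide)
}

#' Export absorption results as CSV
#'
#' @param result An [solve_network_absorption()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_absorption_csv <- function(result, path) {
  utils::write.csv(result$segments, path, row.names = FALSE)
  invisible(path)
}
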