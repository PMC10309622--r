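# GC-efficiency analysis of olfactory channels: capacity factor, Golay
# plate height, plate-number curves, and cross-species comparison.

#' GC column specification
#'
#' Describes an olfactory channel system as an open-tubular GC column: the
#' mobile phase is the channel air space, the stationary phase the mucus
#' film on its wall.
#'
#' @param Lc Column length (m): the averaged odor path length through the
#'   olfactory region (see [mean_path_length()]).
#' @param dc Averaged channel width of the column (m).
#' @param d Stationary-phase (mucus) film thickness (m), default 30 um.
#' @param Vm_over_Va Stationary-to-mobile volume ratio.  Default `4 d / dc`,
#'   the thin-film value for a circular channel of width `dc`.
#' @return An object of class `gc_column`.
#' @export
gc_column <- function(Lc, dc, d = 30e-6, Vm_over_Va = NULL) {
  check_pos(Lc, "Lc")
  check_pos(dc, "dc")
  check_pos(d, "d")
  if (is.null(Vm_over_Va)) Vm_over_Va <- 4 * d / dc
  check_pos(Vm_over_Va, "Vm_over_Va")
  structure(list(Lc = Lc, dc = dc, d = d, Vm_over_Va = Vm_over_Va),
            class = "gc_column")
}

#' @export
print.gc_column <- function(x, ...) {
  cat(sprintf("<gc_column> Lc = %.4g m, dc = %.4g m, d = %.3g m, Vm/Va = %.3g\n",
              x$Lc, x$dc, x$d, x$Vm_over_Va))
  invisible(x)
}

#' Capacity (retention) factor from inlet/outlet concentrations
#'
#' `k' = (Cm / Ca) (Vm / Va)` with `Cm = Cin - Cout` (stationary-phase
#' concentration) and `Ca = Cout` (mobile-phase concentration), the two
#' sampling planes being the column inlet and outlet.  Note the subscript
#' convention: `Vm` is the volume of the stationary phase and `Va` the
#' volume of the mobile (air) phase.
#'
#' @param Cin,Cout Normalized concentrations at the inlet and outlet
#'   sampling planes, `Cin >= Cout > 0`.
#' @param Vm_over_Va Stationary/mobile volume ratio.
#' @return A list of class `retention_estimate` with `Cin`, `Cout`, `Cm`,
#'   `Ca` and `k_prime`.
#' @examples
#' capacity_factor(1, 0.4, 0.2)$k_prime # 0.3
#' @export
capacity_factor <- function(Cin, Cout, Vm_over_Va) {
  check_pos(Cin, "Cin")
  check_pos(Vm_over_Va, "Vm_over_Va")
  if (!is.numeric(Cout) || any(Cout < 0)) stop_domain("Cout must be >= 0")
  if (any(Cout > Cin)) stop_domain("Cout must not exceed Cin")
  if (any(Cout == 0)) {
    stop_domain("Cout = 0 (total absorption): k' is undefined; ",
                "clamp Cout to at least 1e-9 * Cin before calling ",
                "(see k_prime_from_absorption)")
  }
  structure(list(Cin = Cin, Cout = Cout, Cm = Cin - Cout, Ca = Cout,
                 k_prime = (Cin - Cout) / Cout * Vm_over_Va),
            class = "retention_estimate")
}

#' @export
print.retention_estimate <- function(x, ...) {
  cat(sprintf("<retention_estimate> k' = %.4g (Cin = %.4g, Cout = %.4g)\n",
              x$k_prime, x$Cin, x$Cout))
  invisible(x)
}

#' Wire the capacity factor from a network absorption solution
#'
#' Samples the two concentration planes on the network: the inlet plane at
#' the upstream junction of the dorsal-medial channel, the outlet plane at
#' the downstream end of the olfactory coils (flow-weighted means).  A
#' nearly fully absorbed odorant gives `Cout` close to zero; it is clamped
#' at `clamp * Cin` (documented default 1e-9) so the retention estimate
#' stays finite.
#'
#' @param absorption An [solve_network_absorption()] result.
#' @param network,flow The network and flow it was computed on.
#' @param Vm_over_Va Stationary/mobile volume ratio; default from the coil
#'   geometry `P d / A`.
#' @param clamp Lower bound on `Cout / Cin`.
#' @return A `retention_estimate`.
#' @export
k_prime_from_absorption <- function(absorption, network, flow,
                                    Vm_over_Va = NULL, clamp = 1e-9) {
  seg <- network$segments
  dm <- seg$region == "dorsal_medial"
  olf <- seg$region %in% OLFACTORY_REGIONS
  if (!any(olf)) stop_structural("network has no olfactory-region segments")
  qa <- abs(flow$segments$q)
  s <- absorption$segments
  if (any(dm)) {
    entry <- dm & !(seg$from %in% seg$to[dm])
    Cin <- sum(qa[entry] * s$c_in[entry]) / sum(qa[entry])
  } else {
    entry <- olf & !(seg$from %in% seg$to[olf])
    Cin <- sum(qa[entry] * s$c_in[entry]) / sum(qa[entry])
  }
  term <- olf & !(seg$to %in% seg$from[olf])
  Cout <- sum(qa[term] * s$c_out[term]) / sum(qa[term])
  if (is.null(Vm_over_Va)) {
    k <- which(olf)[1]
    Vm_over_Va <- seg$perimeter[k] * seg$mucus_thickness[k] / seg$area[k]
  }
  Cout <- max(Cout, clamp * Cin)
  capacity_factor(Cin, Cout, Vm_over_Va)
}

golay_coefficients <- function(odorant, column, k_prime) {
  k <- k_prime
  A <- 2 * odorant$Da
  B <- 2 * k * column$d^2 / (3 * (1 + k)^2 * odorant$Dm)
  C <- (11 * k^2 + 6 * k + 1) * column$dc^2 / (96 * (1 + k)^2 * odorant$Da)
  list(A = A, B = B, C = C, BC = B + C)
}

#' Golay plate height
#'
#' Open-tubular plate-height equation
#' `H = 2 Da / u`
#' ` + 2 k' d^2 u / (3 (1+k')^2 Dm)`
#' ` + (11 k'^2 + 6 k' + 1) dc^2 u / (96 (1+k')^2 Da)`:
#' longitudinal diffusion, stationary-phase (mucus film) mass-transfer
#' resistance, and mobile-phase mass-transfer resistance.
#'
#' @param u Mean linear velocity (m/s), > 0; vectorized.
#' @param odorant An [odorant()] supplying `Da` and `Dm`.
#' @param column A [gc_column()] supplying `dc` and `d`.
#' @param k_prime Capacity factor (>= 0).
#' @return Plate height H (m).
#' @examples
#' o <- odorant("x", 120, 100, beta = 1, Da = 6e-6, Dm = 1e-9)
#' col <- gc_column(Lc = 0.181, dc = 5e-4)
#' golay_plate_height(0.01, o, col, k_prime = 1) # 2.7195e-3 m
#' @export
golay_plate_height <- function(u, odorant, column, k_prime) {
  check_pos(u, "u")
  check_pos(k_prime, "k_prime", allow_zero = TRUE)
  co <- golay_coefficients(odorant, column, k_prime)
  co$A / u + co$BC * u
}

#' Closed-form Golay optimum
#'
#' With `H = A/u + (B + C) u` (A = 2 Da; B, C the u-linear Golay
#' coefficients), the optimum is `u_opt = sqrt(A / (B + C))` with
#' `H_min = 2 sqrt(A (B + C))`.
#'
#' @inheritParams golay_plate_height
#' @return A list with `u_opt` (m/s), `H_min` (m) and `N_max = Lc / H_min`.
#' @export
golay_optimum <- function(odorant, column, k_prime) {
  co <- golay_coefficients(odorant, column, k_prime)
  u_opt <- sqrt(co$A / co$BC)
  H_min <- 2 * sqrt(co$A * co$BC)
  list(u_opt = u_opt, H_min = H_min, N_max = column$Lc / H_min)
}

#' Plate-number curve
#'
#' Evaluates `H(u)` and `N(u) = Lc / H(u)` on a velocity grid (default 2000
#' log-spaced points over 1e-4 to 1 m/s, covering both the low cat
#' olfactory velocities and the ~0.3 m/s straight-tube velocity), locates
#' the grid peak, and reports the plate number over an operating velocity
#' or range.  Within a range, the operating ("actual") plate number is the
#' best achievable: `N` at the velocity closest to the optimum inside the
#' range.
#'
#' @inheritParams golay_plate_height
#' @param u_grid Velocity grid (m/s); must be positive and span at least
#'   three decades.
#' @param operating_velocity Single velocity or range `c(lo, hi)` (m/s),
#'   optional.
#' @return An object of class `plate_curve`.
#' @export
plate_number_curve <- function(column, odorant, k_prime = 1, u_grid = NULL,
                               operating_velocity = NULL) {
  if (is.null(u_grid)) {
    u_grid <- 10^seq(-4, 0, length.out = 2000)
  }
  check_pos(u_grid, "u_grid")
  if (max(u_grid) / min(u_grid) < 1e3) {
    stop_domain("u_grid should span at least 3 decades")
  }
  H <- golay_plate_height(u_grid, odorant, column, k_prime)
  N <- column$Lc / H
  ipk <- which.max(N)
  opt <- golay_optimum(odorant, column, k_prime)
  op <- NULL
  if (!is.null(operating_velocity)) {
    check_pos(operating_velocity, "operating_velocity")
    if (length(operating_velocity) == 1L) {
      Nop <- column$Lc / golay_plate_height(operating_velocity, odorant,
                                            column, k_prime)
      op <- list(velocity = operating_velocity, N = Nop, N_range = c(Nop, Nop))
    } else {
      rng <- range(operating_velocity)
      u_best <- min(max(opt$u_opt, rng[1]), rng[2])
      Nends <- column$Lc / golay_plate_height(rng, odorant, column, k_prime)
      Nbest <- column$Lc / golay_plate_height(u_best, odorant, column,
                                              k_prime)
      op <- list(velocity = rng, N = Nbest, N_range = range(Nends))
    }
  }
  structure(
    list(u = u_grid, H = H, N = N,
         u_peak = u_grid[ipk], N_peak = N[ipk],
         u_opt = opt$u_opt, H_min = opt$H_min, N_max = opt$N_max,
         operating = op, column = column, k_prime = k_prime,
         odorant = odorant$name),
    class = "plate_curve"
  )
}

#' @export
print.plate_curve <- function(x, ...) {
  cat(sprintf("<plate_curve> Lc = %.4g m, dc = %.4g m, k' = %.3g\n",
              x$column$Lc, x$column$dc, x$k_prime))
  cat(sprintf("  N_peak = %.4g (rounds to %d) at u = %.4g m/s\n",
              x$N_peak, round(x$N_peak), x$u_peak))
  if (!is.null(x$operating)) {
    v <- x$operating$velocity
    cat(sprintf("  operating u = %s m/s: N = %.4g\n",
                paste(signif(v, 4), collapse = "-"), x$operating$N))
  }
  invisible(x)
}

#' Plot a plate-number curve
#'
#' Log-log plate number against velocity, with the peak and any operating
#' range marked.
#'
#' @param x A [plate_number_curve()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.plate_curve <- function(x, ...) {
  graphics::plot(x$u, x$N, type = "l", log = "xy", lwd = 2,
                 xlab = "linear velocity u (m/s)",
                 ylab = "plate number N", ...)
  graphics::abline(v = x$u_opt, lty = 3)
  if (!is.null(x$operating)) {
    v <- x$operating$velocity
    sel <- x$u >= min(v) & x$u <= max(v)
    if (any(sel)) graphics::lines(x$u[sel], x$N[sel], lwd = 5)
    graphics::points(if (length(v) == 1) v else mean(range(v)),
                     x$operating$N, pch = 19)
  }
  invisible(x)
}

#' Read a species GC calibration
#'
#' Calibration YAMLs ship in `inst/extdata/calibrations/` and encode
#' `{Lc, dc, d, k_prime, Da, Dm, operating_velocity, notes}`.  The values
#' are back-derived to satisfy the documented operating constraints (30 um
#' mucus film, species velocity ranges, the straight-tube diameter rule);
#' see each file's `notes` field.
#'
#' @param name A species name (`"cat"`, `"rat"`, `"human"`, `"tube"`) or a
#'   path to a calibration YAML.
#' @return A list of class `gc_calibration` with `name`, `column`
#'   ([gc_column()]), `odorant` ([odorant()]), `k_prime`,
#'   `operating_velocity`, `reference` flag and `notes`.
#' @export
read_calibration <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "calibrations", paste0(name, ".yaml"),
                package = "nasalGC")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_config("calibration '", name, "' not found")
  }
  y <- yaml::read_yaml(path)
  need <- c("name", "Lc", "dc", "d", "k_prime", "Da", "Dm",
            "operating_velocity")
  missing <- setdiff(need, names(y))
  if (length(missing)) {
    stop_config("calibration ", path, " lacks fields: ",
                paste(missing, collapse = ", "))
  }
  num <- function(z) as.numeric(unlist(z))
  col <- gc_column(num(y$Lc), num(y$dc), num(y$d))
  o <- odorant(paste0(y$name, "-reference"), 120, 100, beta = 1,
               Da = num(y$Da), Dm = num(y$Dm), quiet = TRUE)
  structure(
    list(name = y$name, column = col, odorant = o,
         k_prime = num(y$k_prime),
         operating_velocity = num(y$operating_velocity),
         reference = isTRUE(y$reference), notes = y$notes %||% ""),
    class = "gc_calibration"
  )
}

#' Cross-species GC efficiency comparison
#'
#' Computes a plate curve per calibration and tabulates the optimum
#' velocity, peak plate number, the plate number achievable at the
#' operating velocity ("actual"), and the ratio of each actual plate
#' number to that of the reference calibration.
#'
#' @param calibrations A list of [read_calibration()] objects (or species
#'   names), at least two, exactly one flagged `reference` (otherwise the
#'   first is used).
#' @param u_grid Optional shared velocity grid.
#' @return A data.frame of class `species_comparison`; the underlying
#'   plate curves are attached as attribute `curves`.
#' @export
species_comparison <- function(calibrations, u_grid = NULL) {
  if (length(calibrations) < 2) {
    stop_config("need at least two calibrations to compare")
  }
  calibrations <- lapply(calibrations, function(x) {
    if (is.character(x)) read_calibration(x) else x
  })
  for (cal in calibrations) {
    if (is.null(cal$operating_velocity) ||
        !all(is.finite(cal$operating_velocity))) {
      stop_config("calibration '", cal$name, "' lacks an operating velocity")
    }
  }
  refs <- vapply(calibrations, function(x) isTRUE(x$reference), logical(1))
  iref <- if (any(refs)) which(refs)[1] else 1L
  curves <- lapply(calibrations, function(cal) {
    plate_number_curve(cal$column, cal$odorant, cal$k_prime, u_grid,
                       operating_velocity = cal$operating_velocity)
  })
  names(curves) <- vapply(calibrations, `[[`, character(1), "name")
  N_act <- vapply(curves, function(cv) cv$operating$N, numeric(1))
  out <- data.frame(
    name = names(curves),
    u_opt = vapply(curves, `[[`, numeric(1), "u_opt"),
    N_peak = vapply(curves, `[[`, numeric(1), "N_peak"),
    N_peak_rounded = round(vapply(curves, `[[`, numeric(1), "N_peak")),
    N_at_operating = N_act,
    ratio_to_reference = N_act / N_act[iref],
    reference = seq_along(curves) == iref,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("species_comparison", "data.frame"),
            curves = curves)
}

#' @export
print.species_comparison <- function(x, ...) {
  cat("<species_comparison>\n")
  df <- as.data.frame(x)
  df$u_opt <- signif(df$u_opt, 4)
  df$N_peak <- signif(df$N_peak, 4)
  df$N_at_operating <- signif(df$N_at_operating, 4)
  df$ratio_to_reference <- signif(df$ratio_to_reference, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a plate curve as CSV
#'
#' @param curve A [plate_number_curve()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(u = curve$u, H = curve$H, N = curve$N),
                   path, row.names = FALSE)
  invisible(path)
}
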