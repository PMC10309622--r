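# Odorant physicochemical properties, diffusivity estimation, and the
# dimensionless wall-uptake parameter.

#' Create an odorant
#'
#' Bundles the physicochemical properties that drive odorant transport and
#' retention: diffusivities in air and mucus, and the air/mucus partition
#' coefficient.
#'
#' @param name Character label.
#' @param molecular_weight Molecular weight (g/mol).
#' @param molar_volume Solute molar volume at the normal boiling point
#'   (cm^3/mol), used for diffusivity estimation.
#' @param beta Dimensionless air/mucus partition coefficient: the ratio of
#'   odorant concentration in the air phase to the concentration in the mucus
#'   at the air/mucus interface.  Smaller `beta` means more mucosa-soluble.
#' @param Da Diffusivity in air (m^2/s).  If `NULL`, estimated with
#'   [estimate_air_diffusivity()].
#' @param Dm Diffusivity in mucus (m^2/s).  If `NULL`, set to `default_Dm`.
#' @param default_Dm Fallback mucus diffusivity (m^2/s); 1e-9 is a typical
#'   small-molecule aqueous diffusivity.
#' @param quiet Suppress messages about filled-in diffusivities.
#'
#' @return An object of class `odorant`.
#' @examples
#' odorant("FN-like", 128.2, 135, beta = 0.05, Da = 6e-6, Dm = 1e-9)
#' @export
odorant <- function(name, molecular_weight, molar_volume, beta,
                    Da = NULL, Dm = NULL, default_Dm = 1e-9, quiet = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  check_pos(molecular_weight, "molecular_weight")
  check_pos(molar_volume, "molar_volume")
  check_pos(beta, "beta")
  if (is.null(Da) || is.na(Da)) {
    Da <- wilke_chang(molar_volume)
    if (!quiet) {
      message(sprintf("odorant '%s': Da estimated by Wilke-Chang: %.4g m^2/s",
                      name, Da))
    }
  }
  if (is.null(Dm) || is.na(Dm)) {
    Dm <- default_Dm
    if (!quiet) {
      message(sprintf("odorant '%s': Dm defaulted to %.3g m^2/s", name, Dm))
    }
  }
  check_pos(Da, "Da")
  check_pos(Dm, "Dm")
  structure(
    list(name = name, molecular_weight = molecular_weight,
         molar_volume = molar_volume, beta = beta, Da = Da, Dm = Dm),
    class = "odorant"
  )
}

#' @export
print.odorant <- function(x, ...) {
  cat(sprintf("<odorant> %s\n", x$name))
  cat(sprintf("  MW %.4g g/mol, Vb %.4g cm^3/mol\n",
              x$molecular_weight, x$molar_volume))
  cat(sprintf("  beta %.4g (air/mucus), Da %.4g m^2/s, Dm %.4g m^2/s\n",
              x$beta, x$Da, x$Dm))
  invisible(x)
}

#' Mucosa specification
#'
#' Describes the epithelium lining a channel wall: its class and the
#' thickness of the mucus film that acts as the stationary phase.
#'
#' @param epithelium_class One of `"squamous"`, `"respiratory"`,
#'   `"olfactory"`.
#' @param mucus_thickness Mucus film thickness in metres (default 30 um).
#'
#' @return An object of class `mucosa_spec`.
#' @export
mucosa_spec <- function(epithelium_class = c("respiratory", "olfactory",
                                             "squamous"),
                        mucus_thickness = 30e-6) {
  epithelium_class <- match.arg(epithelium_class)
  check_pos(mucus_thickness, "mucus_thickness")
  structure(list(epithelium_class = epithelium_class,
                 mucus_thickness = mucus_thickness),
            class = "mucosa_spec")
}

# Wilke-Chang correlation, in the units the correlation is stated in:
# D [cm^2/s] = 7.4e-8 (phi * M_B)^0.5 T / (mu_B V_A^0.6)
# with T in K, mu_B in cP, V_A in cm^3/mol.  Returned in m^2/s.
wilke_chang <- function(molar_volume, temperature = 310,
                        carrier_molar_mass = 28.97,
                        carrier_viscosity = 0.0185,
                        association_factor = 1) {
  check_pos(molar_volume, "molar_volume")
  check_pos(temperature, "temperature")
  check_pos(carrier_molar_mass, "carrier_molar_mass")
  check_pos(carrier_viscosity, "carrier_viscosity")
  check_pos(association_factor, "association_factor")
  D_cm2 <- 7.4e-8 * sqrt(association_factor * carrier_molar_mass) *
    temperature / (carrier_viscosity * molar_volume^0.6)
  D_cm2 * 1e-4
}

#' Estimate odorant diffusivity with the Wilke-Chang correlation
#'
#' Applies the Wilke-Chang estimation
#' `D = 7.4e-8 (phi M_B)^0.5 T / (mu_B V_A^0.6)` (in cm^2/s, converted to
#' m^2/s) to the odorant's molar volume.  The correlation was derived for
#' dilute liquid solutions; it is provided here because it is the stated
#' estimation route for air-phase diffusivity in this analysis, and a
#' directly supplied `Da` in an odorant table always takes precedence.
#'
#' @param odorant An [odorant()] or anything with a `molar_volume` field.
#' @param temperature Temperature (K); default 310 (body temperature).
#' @param carrier_molar_mass Carrier (solvent) molar mass M_B (g/mol);
#'   default 28.97 for air.
#' @param carrier_viscosity Carrier viscosity (cP); default 0.0185.
#' @param association_factor Solvent association factor phi (dimensionless).
#'
#' @return Diffusivity in m^2/s.
#' @examples
#' # phi*M_B = 29, T = 298 K, mu = 0.0185 cP, V_A = 100 cm^3/mol
#' o <- list(molar_volume = 100)
#' estimate_air_diffusivity(o, temperature = 298, carrier_molar_mass = 29)
#' @export
estimate_air_diffusivity <- function(odorant, temperature = 310,
                                     carrier_molar_mass = 28.97,
                                     carrier_viscosity = 0.0185,
                                     association_factor = 1) {
  v <- odorant$molar_volume
  if (is.null(v)) stop_domain("odorant must carry a `molar_volume`")
  wilke_chang(v, temperature, carrier_molar_mass, carrier_viscosity,
              association_factor)
}

#' Dimensionless wall-uptake parameter
#'
#' The odorant concentration at the air/mucus interface obeys the Robin
#' condition `dC'/dy' + K C' = 0` with
#' `K = d_in * Dm / (Da * beta * d)`: the ratio of the mucus-film conductance
#' `Dm/(beta d)` to the air-side diffusive conductance scale `Da/d_in`.
#' `K = 0` corresponds to an insoluble odorant (`beta -> Inf`); large `K`
#' to a perfectly absorbing wall.
#'
#' @param d_in Reference length (m): hydraulic diameter of the inlet used for
#'   normalization.
#' @param odorant An [odorant()].
#' @param mucosa A [mucosa_spec()] supplying the mucus thickness `d`.
#'
#' @return An object of class `uptake_parameter` with fields `K` and `d_in`.
#' @examples
#' o <- odorant("x", 120, 100, beta = 1e-3, Da = 6e-6, Dm = 1e-9)
#' wall_uptake_parameter(5e-3, o, mucosa_spec("olfactory"))$K # 27.78
#' @export
wall_uptake_parameter <- function(d_in, odorant, mucosa) {
  check_pos(d_in, "d_in")
  check_pos(odorant$beta, "beta")
  check_pos(odorant$Da, "Da")
  check_pos(odorant$Dm, "Dm")
  check_pos(mucosa$mucus_thickness, "mucus_thickness")
  K <- d_in * odorant$Dm / (odorant$Da * odorant$beta * mucosa$mucus_thickness)
  structure(list(K = K, d_in = d_in), class = "uptake_parameter")
}

#' @export
print.uptake_parameter <- function(x, ...) {
  cat(sprintf("<uptake_parameter> K = %.4g (d_in = %.4g m)\n", x$K, x$d_in))
  invisible(x)
}

#' Read an odorant property table
#'
#' Reads a CSV with header
#' `name,molecular_weight,molar_volume,beta,Da,Dm` (SI units; molar
#' quantities in g/mol and cm^3/mol).  Empty `Da` cells are filled by
#' Wilke-Chang estimation from the molar volume; empty `Dm` cells by
#' `default_Dm`.  Both fills are reported with a message.
#'
#' @param path CSV path.  The default is the packaged fixture table, which
#'   names 2-acetylthiazole (high mucosal solubility) and
#'   2-(1-mercaptoethyl)furan (intermediate solubility) with placeholder
#'   synthetic properties, and spans the partition coefficient over six
#'   log-decades.
#' @param default_Dm Fallback mucus diffusivity (m^2/s).
#' @param quiet Suppress fill-in messages.
#' @inheritParams estimate_air_diffusivity
#'
#' @return A `data.frame` with class `odorant_table`.
#' @export
read_odorant_table <- function(path = system.file("extdata", "odorants.csv",
                                                  package = "nasalGC"),
                               default_Dm = 1e-9, quiet = FALSE,
                               temperature = 310, carrier_molar_mass = 28.97,
                               carrier_viscosity = 0.0185,
                               association_factor = 1) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "molecular_weight", "molar_volume", "beta", "Da", "Dm")
  if (!all(need %in% names(tab))) {
    stop_config("odorant table must have columns ", paste(need, collapse = ","))
  }
  for (col in need[-1]) tab[[col]] <- as.numeric(tab[[col]])
  fill_da <- is.na(tab$Da)
  if (any(fill_da)) {
    tab$Da[fill_da] <- wilke_chang(tab$molar_volume[fill_da], temperature,
                                   carrier_molar_mass, carrier_viscosity,
                                   association_factor)
    if (!quiet) {
      message("Da estimated by Wilke-Chang for: ",
              paste(tab$name[fill_da], collapse = ", "))
    }
  }
  fill_dm <- is.na(tab$Dm)
  if (any(fill_dm)) {
    tab$Dm[fill_dm] <- default_Dm
    if (!quiet) {
      message(sprintf("Dm defaulted to %.3g m^2/s for: %s", default_Dm,
                      paste(tab$name[fill_dm], collapse = ", ")))
    }
  }
  check_pos(tab$molecular_weight, "molecular_weight")
  check_pos(tab$molar_volume, "molar_volume")
  check_pos(tab$beta, "beta")
  check_pos(tab$Da, "Da")
  check_pos(tab$Dm, "Dm")
  class(tab) <- c("odorant_table", "data.frame")
  tab
}

#' Write an odorant property table
#'
#' Numeric fields are written with 17 significant digits so that reading the
#' table back reproduces all values to full double precision.
#'
#' @param table A data.frame with the odorant-table columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_odorant_table <- function(table, path) {
  out <- data.frame(
    name = table$name,
    molecular_weight = format_full(table$molecular_weight),
    molar_volume = format_full(table$molar_volume),
    beta = format_full(table$beta),
    Da = format_full(table$Da),
    Dm = format_full(table$Dm),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one odorant from an odorant table
#'
#' @param table An `odorant_table` from [read_odorant_table()].
#' @param name Row to extract (odorant name).
#' @return An [odorant()] object.
#' @export
as_odorant <- function(table, name) {
  i <- match(name, table$name)
  if (is.na(i)) stop_config("odorant '", name, "' not found in table")
  odorant(table$name[i], table$molecular_weight[i], table$molar_volume[i],
          table$beta[i], table$Da[i], table$Dm[i], quiet = TRUE)
}
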