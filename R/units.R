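## Unit conversions between SI ("characteristic") and simulator working units.
## Internal computation is SI (m, s, Pa, mole fraction); table-style inputs
## are converted once at the boundary.

## molar concentration of water, mol/L: micromolar -> mole fraction uses
## x = c[mol/L] / W. Overridable wherever uM appears.
.WATER_MOLARITY <- 55.5

## 1 Darcy in m^2 (engineering convention, exactly 0.9869 um^2)
.DARCY_M2 <- 0.9869e-12

## factor table: value_in_base_unit = value * factor. uM factors depend on the
## water molarity and are computed on the fly.
.unit_dimension <- c(
  "m2" = "permeability", "um2" = "permeability", "darcy" = "permeability",
  "m2/s" = "diffusivity", "cm2/min" = "diffusivity",
  "uM" = "concentration", "mole_fraction" = "concentration",
  "uM/min" = "conc_rate", "mole_fraction/min" = "conc_rate",
  "Pa.s" = "viscosity", "cP" = "viscosity",
  "m3/s" = "flow", "cm3/min" = "flow",
  "s" = "time", "min" = "time",
  "m" = "length", "um" = "length", "mm" = "length",
  "m3" = "volume", "mm3" = "volume", "cm3" = "volume", "um3" = "volume",
  "1/min" = "frequency", "1/s" = "frequency",
  "1" = "dimensionless"
)

.unit_factor <- function(unit, water_molarity) {
  switch(unit,
    "m2" = 1, "um2" = 1e-12, "darcy" = .DARCY_M2,
    "m2/s" = 1, "cm2/min" = 1e-4 / 60,
    "mole_fraction" = 1, "uM" = 1e-6 / water_molarity,
    "mole_fraction/min" = 1, "uM/min" = 1e-6 / water_molarity,
    "Pa.s" = 1, "cP" = 1e-3,
    "m3/s" = 1, "cm3/min" = 1e-6 / 60,
    "s" = 1, "min" = 60,
    "m" = 1, "um" = 1e-6, "mm" = 1e-3,
    "m3" = 1, "mm3" = 1e-9, "cm3" = 1e-6, "um3" = 1e-18,
    "1/s" = 1, "1/min" = 1 / 60,
    "1" = 1,
    stop("unknown unit tag: '", unit, "'", call. = FALSE)
  )
}

#' Physical quantity with a unit tag
#'
#' A number together with one of the supported unit tags (permeability,
#' diffusivity, concentration, reaction rate, viscosity, volumetric flow,
#' time, length, volume). Not a general units framework: only the tags the
#' lobule model needs.
#'
#' @param value Numeric value (vectorized).
#' @param unit Unit tag, e.g. `"um2"`, `"darcy"`, `"m2/s"`, `"cm2/min"`,
#'   `"uM"`, `"mole_fraction"`, `"Pa.s"`, `"cP"`, `"cm3/min"`, `"min"`,
#'   `"um"`, `"mm3"`.
#' @return An object of class `"quantity"`.
#' @seealso [convert_unit()]
#' @export
#' @examples
#' quantity(1.125, "um2")
quantity <- function(value, unit) {
  unit <- as.character(unit)
  if (is.na(.unit_dimension[unit])) {
    stop("unknown unit tag: '", unit, "'", call. = FALSE)
  }
  structure(list(value = as.numeric(value), unit = unit), class = "quantity")
}

#' @export
print.quantity <- function(x, ...) {
  cat(format(x$value), x$unit, "\n")
  invisible(x)
}

#' Convert a quantity between unit systems
#'
#' Converts between SI and simulator working units within a dimension.
#' Permeability uses 1 Darcy = 0.9869 um^2 exactly; micromolar and mole
#' fraction interconvert through the molar concentration of the solvent
#' (water), `x = c[mol/L] / water_molarity`.
#'
#' @param x A [quantity()], or a plain numeric (then `from` is required).
#' @param to Target unit tag.
#' @param from Source unit tag when `x` is numeric.
#' @param water_molarity Molar concentration of water in mol/L used for the
#'   uM <-> mole-fraction conversion. Default 55.5.
#' @return A `"quantity"` when given one, otherwise a numeric.
#' @export
#' @examples
#' convert_unit(quantity(1.125, "um2"), "darcy")   # ~1.140
#' convert_unit(10, from = "uM", to = "mole_fraction")  # ~1.8e-7
convert_unit <- function(x, to, from = NULL, water_molarity = .WATER_MOLARITY) {
  if (inherits(x, "quantity")) {
    value <- x$value
    from <- x$unit
    wrap <- TRUE
  } else {
    if (is.null(from)) stop("'from' is required for a bare numeric",
                            call. = FALSE)
    value <- as.numeric(x)
    wrap <- FALSE
  }
  dfrom <- .unit_dimension[from]
  dto <- .unit_dimension[to]
  if (is.na(dfrom)) stop("unknown unit tag: '", from, "'", call. = FALSE)
  if (is.na(dto)) stop("unknown unit tag: '", to, "'", call. = FALSE)
  if (dfrom != dto) {
    stop("incompatible dimensions: cannot convert '", from, "' (", dfrom,
         ") to '", to, "' (", dto, ")", call. = FALSE)
  }
  out <- value * .unit_factor(from, water_molarity) /
    .unit_factor(to, water_molarity)
  if (wrap) quantity(out, to) else out
}

#' Medium property table (porosity, permeability, diffusion, viscosity)
#'
#' Base-case single-phase medium properties of the two lattice phases:
#' the sinusoid network (high porosity/permeability) and the hepatocyte
#' tissue continuum. Defaults are the base-case values for a representative
#' human lobule perfused by Newtonian blood.
#'
#' @param phi_sin,phi_tis Porosity (dimensionless, in (0, 1]).
#' @param K_sin_um2,K_tis_um2 Permeability, um^2.
#' @param D_sin_m2s,D_tis_m2s Effective diffusivity of the drug, m^2/s.
#' @param mu_Pas Blood viscosity, Pa s.
#' @return Object of class `"medium_table"` with both the input values and
#'   SI-converted fields (`K_sin_m2`, `K_tis_m2`).
#' @export
#' @examples
#' medium_table()
medium_table <- function(phi_sin = 0.7854, K_sin_um2 = 1.125,
                         D_sin_m2s = 4.2e-10, phi_tis = 0.2382,
                         K_tis_um2 = 7.35e-2, D_tis_m2s = 4.2e-11,
                         mu_Pas = 3.5e-3) {
  stopifnot(phi_sin > 0, phi_sin <= 1, phi_tis > 0, phi_tis <= 1,
            K_sin_um2 > 0, K_tis_um2 > 0, D_sin_m2s >= 0, D_tis_m2s >= 0,
            mu_Pas > 0)
  structure(list(
    phi_sin = phi_sin, K_sin_um2 = K_sin_um2, D_sin_m2s = D_sin_m2s,
    phi_tis = phi_tis, K_tis_um2 = K_tis_um2, D_tis_m2s = D_tis_m2s,
    mu_Pas = mu_Pas,
    K_sin_m2 = convert_unit(K_sin_um2, from = "um2", to = "m2"),
    K_tis_m2 = convert_unit(K_tis_um2, from = "um2", to = "m2")
  ), class = "medium_table")
}

#' @export
print.medium_table <- function(x, ...) {
  cat("Medium property table\n")
  cat(sprintf("  sinusoid: phi %.4f  K %.4g um2 (%.4g Darcy)  D %.3g m2/s\n",
              x$phi_sin, x$K_sin_um2,
              convert_unit(x$K_sin_um2, from = "um2", to = "darcy"),
              x$D_sin_m2s))
  cat(sprintf("  tissue:   phi %.4f  K %.4g um2 (%.4g Darcy)  D %.3g m2/s\n",
              x$phi_tis, x$K_tis_um2,
              convert_unit(x$K_tis_um2, from = "um2", to = "darcy"),
              x$D_tis_m2s))
  cat(sprintf("  blood viscosity: %.3g Pa.s\n", x$mu_Pas))
  invisible(x)
}

#' Michaelis-Menten elimination kinetics
#'
#' Saturable drug elimination parameters, entered in micromolar units and
#' converted to the mole-fraction working units the transport engine uses.
#' For substrate levels far below `Km` the model reduces to a linear rate
#' `vmax/Km` per minute; `mode = "linear"` selects that reduction explicitly.
#'
#' @param vmax_uM_min Maximum elimination rate, uM/min.
#' @param Km_uM Half-saturation constant, uM (> 0).
#' @param mode `"michaelis_menten"` (default) or `"linear"`.
#' @param water_molarity Solvent molarity for the mole-fraction conversion.
#' @return Object of class `"kinetic_params"` with mole-fraction fields
#'   `vmax_mf_min`, `Km_mf` and the derived `k_lin_per_min = vmax/Km`.
#' @seealso [linear_rate()], [reaction_preset()]
#' @export
#' @examples
#' kinetic_params()            # base case: vmax/Km = 6e-3 per min
kinetic_params <- function(vmax_uM_min = 0.06, Km_uM = 10.0,
                           mode = c("michaelis_menten", "linear"),
                           water_molarity = .WATER_MOLARITY) {
  mode <- match.arg(mode)
  if (vmax_uM_min < 0) stop("vmax must be >= 0", call. = FALSE)
  if (Km_uM <= 0) stop("Km must be > 0", call. = FALSE)
  structure(list(
    vmax_uM_min = vmax_uM_min, Km_uM = Km_uM, mode = mode,
    vmax_mf_min = convert_unit(vmax_uM_min, from = "uM/min",
                               to = "mole_fraction/min",
                               water_molarity = water_molarity),
    Km_mf = convert_unit(Km_uM, from = "uM", to = "mole_fraction",
                         water_molarity = water_molarity),
    k_lin_per_min = vmax_uM_min / Km_uM
  ), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Kinetics (%s): vmax %.3g uM/min (%.3g mf/min), Km %.3g uM (%.3g mf), vmax/Km %.3g /min\n",
    x$mode, x$vmax_uM_min, x$vmax_mf_min, x$Km_uM, x$Km_mf, x$k_lin_per_min))
  invisible(x)
}

#' Linear elimination rate vmax/Km
#'
#' @param k A [kinetic_params()] object.
#' @return The first-order rate `vmax/Km` in 1/min (identical in both unit
#'   systems since the concentration unit cancels).
#' @export
#' @examples
#' linear_rate(kinetic_params(0.06, 10))  # 6e-3
linear_rate <- function(k) {
  stopifnot(inherits(k, "kinetic_params"))
  if (k$Km_uM == 0) stop("Km must be > 0", call. = FALSE)
  k$vmax_uM_min / k$Km_uM
}

#' Kinetics presets for the three reaction-rate regimes
#'
#' The transport studies use linear rates 6e-6 ("slow"), 6e-3 ("base") and
#' 6e-1 ("fast") per minute, all at the same half-saturation constant; the
#' preset scales `vmax` accordingly.
#'
#' @param rate `"base"`, `"slow"` or `"fast"`.
#' @param mode Kinetic mode passed to [kinetic_params()].
#' @return A [kinetic_params()] object.
#' @export
#' @examples
#' linear_rate(reaction_preset("slow"))   # 6e-6
reaction_preset <- function(rate = c("base", "slow", "fast"),
                            mode = c("michaelis_menten", "linear")) {
  rate <- match.arg(rate)
  vmax <- switch(rate, base = 0.06, slow = 6e-5, fast = 6.0)
  kinetic_params(vmax_uM_min = vmax, Km_uM = 10.0, mode = match.arg(mode))
}

#' Read a medium/kinetics parameter file
#'
#' YAML key-value file with optional sections `medium` (keys `phi_sin`,
#' `K_sin_um2`, `D_sin_m2s`, `phi_tis`, `K_tis_um2`, `D_tis_m2s`, `mu_Pas`)
#' and `kinetics` (keys `vmax_uM_min`, `Km_uM`, `mode`). Missing keys fall
#' back to the base-case defaults.
#'
#' @param path Path to the YAML file.
#' @return List with elements `medium` ([medium_table()]) and `kinetics`
#'   ([kinetic_params()]).
#' @export
read_parameter_file <- function(path) {
  cfg <- yaml::read_yaml(path)
  med <- do.call(medium_table, cfg$medium %||% list())
  kin <- do.call(kinetic_params, cfg$kinetics %||% list())
  list(medium = med, kinetics = kin)
}
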