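# Physical and physiological parameters of the transcutaneous CO2 transport
# model, and the derivation chain that produces them from primary literature
# constants.
#
# Internal unit system: lengths in cm, time in s, concentration in mol/m^3,
# pressure in mmHg, diffusivity in cm^2/s.  Quantities printed in m/s or
# mL-based units are converted at ingestion.

#' Physical constants used throughout the model
#'
#' @return Named list with `R_gas`, the ideal gas constant in
#'   m^3 mmHg K^-1 mol^-1, and `P_air`, the total air pressure (mmHg) at the
#'   42 degC operating temperature of the device.
#' @export
co2_constants <- function() {
  list(R_gas = 0.0623637, P_air = 831.21, T_blood = 315.15)
}

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Line through two points
#'
#' Exact affine interpolation/extrapolation through two anchor points. Serves
#' both the solubility extrapolation to 42 degC and the skin-conductance
#' interpolation between the published 37 and 43 degC values.
#'
#' @param t1,v1 first anchor (abscissa, value)
#' @param t2,v2 second anchor
#' @param t_query abscissa at which to evaluate the line
#' @return value of the line at `t_query`, in the units of `v1`/`v2`
#' @export
linear_two_point <- function(t1, v1, t2, v2, t_query) {
  stop_if(t1 == t2, "degenerate input: the two anchor abscissae coincide")
  v1 + (v2 - v1) / (t2 - t1) * (t_query - t1)
}

#' Henry coefficient from the Ostwald solubility
#'
#' H = beta * R * T: the dimensionless equilibrium concentration ratio across
#' a liquid/gas interface, from the Ostwald solubility coefficient beta
#' (mol m^-3 mmHg^-1) at absolute temperature T (K).
#'
#' @param beta Ostwald solubility, mol m^-3 mmHg^-1 (>= 0)
#' @param temperature absolute temperature, K (> 0)
#' @param R_gas ideal gas constant, m^3 mmHg K^-1 mol^-1
#' @return dimensionless Henry coefficient
#' @export
henry_from_ostwald <- function(beta, temperature,
                               R_gas = co2_constants()$R_gas) {
  stop_if(beta < 0, "invalid parameter: beta must be non-negative")
  stop_if(temperature <= 0, "invalid parameter: temperature must be positive")
  beta * R_gas * temperature
}

#' Bunsen solubility of CO2 in the stratum corneum
#'
#' alpha = H_skin / P_air, in mL(STPD) per mL solvent per mmHg.
#'
#' @param H_skin dimensionless Henry coefficient of the skin
#' @param P_air total air pressure, mmHg (> 0)
#' @export
bunsen_solubility <- function(H_skin, P_air = co2_constants()$P_air) {
  stop_if(P_air <= 0, "invalid parameter: P_air must be positive")
  H_skin / P_air
}

#' Mass transfer coefficient of the stratum corneum
#'
#' kp = G_per_area * P_air * 1e-2, in m/s, from the volumic skin conductance
#' with respect to pressure difference per surface area
#' (mL s^-1 cm^-2 mmHg^-1). The 1e-2 factor is the unit conversion between
#' the mL/cm^2-based conductance and the m/s-based coefficient.
#'
#' @param G_per_area volumic skin conductance, mL s^-1 cm^-2 mmHg^-1
#' @param P_air total air pressure, mmHg
#' @export
mass_transfer_coefficient <- function(G_per_area,
                                      P_air = co2_constants()$P_air) {
  stop_if(G_per_area < 0 || P_air <= 0, "invalid parameter: inputs must be positive")
  G_per_area * P_air * 1e-2
}

#' Krogh diffusion constant of the stratum corneum
#'
#' Kr = kp * dz_skin / P_air in cm^2 s^-1 mmHg^-1, with the mass transfer
#' coefficient supplied in m/s (converted to cm/s internally) and the stratum
#' corneum thickness in cm.
#'
#' @param kp_sc mass transfer coefficient, m/s
#' @param dz_skin stratum corneum thickness, cm
#' @param P_air total air pressure, mmHg
#' @export
krogh_constant <- function(kp_sc, dz_skin, P_air = co2_constants()$P_air) {
  stop_if(kp_sc < 0 || dz_skin <= 0 || P_air <= 0,
          "invalid parameter: inputs must be positive")
  (kp_sc * 100) * dz_skin / P_air
}

#' Diffusion coefficient of the stratum corneum
#'
#' D_skin = Kr / alpha, in cm^2/s, from the Krogh diffusion constant and the
#' Bunsen solubility.
#'
#' @param Kr Krogh diffusion constant, cm^2 s^-1 mmHg^-1
#' @param alpha Bunsen solubility, mL(STPD) mL^-1 mmHg^-1 (> 0)
#' @export
skin_diffusion <- function(Kr, alpha) {
  stop_if(alpha <= 0, "invalid parameter: alpha must be positive")
  Kr / alpha
}

#' Mean axial velocity from a volumetric flow
#'
#' u = Q / A in cm/s; used for the blood compartment (blood flow over the
#' transverse section) and the collection cell (air flow over the cell
#' cross-section).
#'
#' @param Q volumetric flow, cm^3/s
#' @param A cross-sectional area, cm^2 (> 0)
#' @export
mean_velocity <- function(Q, A) {
  stop_if(A <= 0, "invalid parameter: area must be positive")
  Q / A
}

#' Ostwald solubility of CO2 in blood at 42 degC
#'
#' Linear extrapolation of the published solubility values at 37 degC
#' (3.08e-2) and 40 degC (2.88e-2 mol m^-3 mmHg^-1) to the 42 degC operating
#' temperature of the heated skin.
#'
#' @param rounded if `TRUE`, return the two-significant-digit display value
#'   2.75e-2; the default returns the unrounded extrapolation.
#' @return Ostwald solubility, mol m^-3 mmHg^-1
#' @export
co2_blood_solubility <- function(rounded = FALSE) {
  beta <- linear_two_point(37, 3.08e-2, 40, 2.88e-2, 42)
  if (rounded) signif(beta, 3) else beta
}

#' Solubility used for pressure/concentration conversion
#'
#' The conversion between blood partial pressure and concentration uses the
#' solubility implied by the blood Henry coefficient reported at two decimals
#' (H = 0.54), i.e. beta = H / (R * T). This is the value consistent with the
#' reference capnia levels 40 mmHg = 1.099 mol/m^3 and 50 mmHg =
#' 1.3738 mol/m^3 used to define the simulation scenarios.
#'
#' @return Ostwald solubility, mol m^-3 mmHg^-1
#' @export
co2_conversion_solubility <- function() {
  k <- co2_constants()
  H <- round(henry_from_ostwald(co2_blood_solubility(), k$T_blood), 2)
  H / (k$R_gas * k$T_blood)
}

#' Convert CO2 partial pressure to concentration (and back)
#'
#' Henry's law in the blood: C = beta * P and P = C / beta, with beta the
#' Ostwald solubility of CO2 in blood. The round trip is the identity.
#'
#' @param P partial pressure, mmHg
#' @param C concentration, mol/m^3
#' @param beta Ostwald solubility, mol m^-3 mmHg^-1 (> 0)
#' @return concentration in mol/m^3 (resp. pressure in mmHg)
#' @export
pressure_to_concentration <- function(P, beta = co2_conversion_solubility()) {
  stop_if(beta <= 0, "invalid parameter: beta must be positive")
  beta * P
}

#' @rdname pressure_to_concentration
#' @export
concentration_to_pressure <- function(C, beta = co2_conversion_solubility()) {
  stop_if(beta <= 0, "invalid parameter: beta must be positive")
  C / beta
}

#' Default physical parameters of the four compartments
#'
#' Bundles the characteristic parameters of the blood compartment, the
#' stratum corneum, and the gaseous measurement/collection cells at 42 degC,
#' as used for data generation. Derived skin quantities (conductance at
#' 42 degC, mass transfer coefficient, Krogh constant, Bunsen solubility) are
#' recomputed through the derivation chain; the compartment heights,
#' diffusivities and velocities are the tabulated simulation values.
#'
#' @param Q_air air flow through the collection cell, cm^3/s (default 1
#'   mL/min = 16.7e-3 cm^3/s)
#' @param C_ambient CO2 concentration of the incoming air, mol/m^3. The
#'   default 0 corresponds to a CO2 filter at the collection-cell inlet; set
#'   to 0.01613 to restore the ambient-air value.
#' @return Named list with elements `constants`, `blood`, `skin`, `air` and
#'   the conversion solubility `beta_conv`.
#' @export
capno_params <- function(Q_air = 16.7e-3, C_ambient = 0) {
  k <- co2_constants()
  beta <- co2_blood_solubility()
  blood <- list(
    dz = 0.3, dx = 5, dy = 2,
    D = 2.2e-5,
    u = 1.83e-4,            # tabulated average blood velocity, cm/s
    Q = 1.8e-3, A = 10,
    beta = beta, T = k$T_blood,
    H = henry_from_ostwald(beta, k$T_blood)
  )
  G_cond <- linear_two_point(37, 77e-9, 43, 130e-9, 42)
  kp <- mass_transfer_coefficient(G_cond, k$P_air)
  Kr <- krogh_constant(kp, 1.6e-3, k$P_air)
  alpha <- bunsen_solubility(1.6, k$P_air)
  skin <- list(
    dz = 1.6e-3, dx = 5, dy = 2,
    D = 1e-7,               # tabulated value; skin_diffusion(Kr, alpha) ~ 1.0e-7
    u = 0, H = 1.6,
    G_cond_per_area = G_cond, kp_sc = kp, Kr = Kr, alpha = alpha
  )
  air <- list(
    dz_meas = 0.25, dz_coll = 0.25, dx = 5, dy = 2,
    D = 0.18, u_meas = 0,
    Q_air = Q_air,
    u_coll = mean_velocity(Q_air, 5 * 2),
    H = 1, C_ambient = C_ambient
  )
  list(constants = k, blood = blood, skin = skin, air = air,
       beta_conv = co2_conversion_solubility())
}

#' Write / read a parameter set as a plain-text key = value file
#'
#' Flat serialization of a [capno_params()] list. Keys are
#' `<group>.<field>`; values are written with full precision. All lengths are
#' cm, times s, concentrations mol/m^3, pressures mmHg.
#'
#' @param params parameter list as returned by [capno_params()]
#' @param file path of the text file
#' @export
write_params <- function(params, file) {
  flat <- unlist(params)
  writeLines(sprintf("%s = %.17g", names(flat), flat), file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  lines <- grep("=", readLines(file), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  flat <- stats::setNames(
    vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
    vapply(kv, `[`, character(1), 1)
  )
  out <- capno_params()
  for (nm in names(flat)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(path) == 2 && !is.null(out[[path[1]]]))
      out[[path[1]]][[path[2]]] <- unname(flat[[nm]])
  }
  out
}
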