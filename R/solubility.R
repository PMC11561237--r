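#' Sublimation pressure by Clausius-Clapeyron extrapolation
#'
#' Integrates the Clausius-Clapeyron relation with a constant sublimation
#' enthalpy from the solute's reference vapour-pressure point:
#' `P(T) = P_ref * exp[(dH_sub / R) * (1/T_ref - 1/T)]`.
#'
#' @param temperature Temperature(s), K.
#' @param solute A [solute_params()].  Its `sublimation_enthalpy` must be
#'   set: it is a user-supplied quantity (literature vapour-pressure data
#'   for sparingly volatile solids rarely report it directly), and there is
#'   no sensible default.
#' @return Sublimation pressure(s), Pa.
#' @export
#' @examples
#' sol <- solute_params(3.961e-4, 1, 298.15, sublimation_enthalpy = 100)
#' sublimation_pressure(298.15, sol)   # the reference point, exactly 1 Pa
#' sublimation_pressure(350, sol)      # ~394 Pa
sublimation_pressure <- function(temperature, solute) {
  if (!inherits(solute, "solute_params"))
    stop("'solute' must be a solute_params object", call. = FALSE)
  if (is.null(solute$sublimation_enthalpy))
    stop("sublimation enthalpy is not set on 'solute'; it is a required ",
         "user input (supply 'sublimation_enthalpy' in kJ/mol to ",
         "solute_params())", call. = FALSE)
  if (any(temperature <= 0))
    stop("temperature must be strictly positive", call. = FALSE)
  dH <- solute$sublimation_enthalpy * 1e3   # kJ/mol -> J/mol
  solute$reference_vapor_pressure *
    exp((dH / .Rgas) * (1 / solute$reference_temperature - 1 / temperature))
}

#' Convert solvent mass density to number density
#'
#' `rho_n = (mass density / molar mass) * N_A`, i.e. molecules per cubic
#' metre.  The solubility model divides the sublimation pressure by
#' `rho_n * k_B * T`, so the denominator must be a pressure — hence number
#' density, not mass density.
#'
#' @param mass_density Mass density, g/cm^3.
#' @param molar_mass Molar mass, g/mol.
#' @return Number density, m^-3.
#' @export
#' @examples
#' number_density(0.962, 18.015)  # subcritical water at 363 K, ~3.2e28
number_density <- function(mass_density, molar_mass) {
  if (any(mass_density <= 0) || any(molar_mass <= 0))
    stop("mass density and molar mass must be strictly positive",
         call. = FALSE)
  # g/cm^3 -> kg/m^3 is *1000; g/mol -> kg/mol is /1000
  (mass_density * 1000) / (molar_mass / 1000) * .NAvo
}

#' Mole-fraction solubility from solvation free energy
#'
#' Evaluates the solvation-free-energy route to solid solubility:
#' \deqn{y_2 = \frac{P_2^{sat} \exp[\beta \vartheta^s (P - P_2^{sat})]}
#'                 {\rho_n k_B T \exp(\beta \Delta G^{solv})}}
#' with the sublimation pressure from [sublimation_pressure()], the Poynting
#' factor `exp[v_s (P - P2sat) / (R T)]` correcting the solid's fugacity to
#' the system pressure, and the solvent as an ideal dilute reservoir of
#' number density `rho_n` ([number_density()]).  Molar energies are used
#' throughout (`beta = 1/(R T)` against kJ/mol quantities), which is
#' algebraically identical to the per-particle form with `k_B`.
#'
#' @param temperature Temperature, K.
#' @param pressure System pressure, Pa.
#' @param dG_solv Solvation free energy, kJ/mol.
#' @param solvent_mass_density Solvent mass density, g/cm^3.
#' @param solute A [solute_params()] (with sublimation enthalpy set, unless
#'   `sublimation_pressure_Pa` is supplied).
#' @param sublimation_pressure_Pa Optional: bypass the Clausius-Clapeyron
#'   step and use this sublimation pressure directly, Pa.
#' @return Mole fraction `y2` (dimensionless), with attributes `"psat"`,
#'   `"poynting"`, `"number_density"`.  Values outside (0, 1) raise a
#'   warning, not an error, so parameter sweeps survive unphysical corners.
#' @export
#' @examples
#' sol <- solute_params(3.961e-4, 4.106e-10, 298.15,
#'                      sublimation_enthalpy = 120)
#' mole_fraction_solubility(363.15, 2e6, -35.848, 0.962, sol)
mole_fraction_solubility <- function(temperature, pressure, dG_solv,
                                     solvent_mass_density, solute,
                                     sublimation_pressure_Pa = NULL) {
  if (any(temperature <= 0) || any(pressure <= 0))
    stop("temperature and pressure must be strictly positive", call. = FALSE)
  psat <- if (is.null(sublimation_pressure_Pa))
    sublimation_pressure(temperature, solute) else sublimation_pressure_Pa
  RT <- .Rgas * temperature
  poynting <- exp(solute$molar_volume * (pressure - psat) / RT)
  rho_n <- number_density(solvent_mass_density, solute$solvent_molar_mass)
  y2 <- psat * poynting / (rho_n * .kB * temperature * exp(dG_solv * 1e3 / RT))
  bad <- y2 <= 0 | y2 >= 1
  if (any(bad))
    warning("mole fraction outside (0, 1) at T = ",
            paste(format(temperature[bad]), collapse = ", "),
            " K; inputs are outside the dilute-solution regime",
            call. = FALSE)
  structure(y2, psat = psat, poynting = poynting, number_density = rho_n)
}

#' Absolute average relative deviation (AARD)
#'
#' `100 * mean(|sim - ref| / |ref|)`, the standard percent statistic for
#' validating simulated property sets against reference data.
#'
#' @param simulated,reference Equal-length numeric vectors; `reference`
#'   must be nonzero everywhere.
#' @return AARD in percent.
#' @export
#' @examples
#' aard(c(0.902, 0.896, 0.874, 0.855), c(0.962, 0.946, 0.935, 0.929))
aard <- function(simulated, reference) {
  if (length(simulated) != length(reference) || length(simulated) == 0L)
    stop("'simulated' and 'reference' must have equal nonzero length",
         call. = FALSE)
  if (any(reference == 0))
    stop("reference values must be nonzero", call. = FALSE)
  100 * mean(abs(simulated - reference) / abs(reference))
}

#' Per-temperature solubility table
#'
#' Runs the full solubility chain over every row of a [thermo_table()]:
#' Clausius-Clapeyron sublimation pressure, Poynting factor, solvent number
#' density, and mole-fraction solubility, at a common system pressure.
#'
#' @param table A [thermo_table()].
#' @param solute A [solute_params()] with sublimation enthalpy set.
#' @param pressure System pressure, Pa (e.g. `2e6` for 2 MPa subcritical
#'   water work).
#' @return A `data.frame` of class `solubility_result` with columns
#'   `temperature_K`, `sublimation_pressure_Pa`, `poynting_factor`,
#'   `number_density_m3`, `mole_fraction`; attributes `pressure_Pa` and
#'   `monotonicity` (`"increasing"`, `"decreasing"`, `"neither"`, or
#'   `"undefined"` for a single row, judged on `mole_fraction` vs
#'   temperature).
#' @export
solubility_table <- function(table, solute, pressure) {
  if (!inherits(table, "thermo_table"))
    stop("'table' must be a thermo_table", call. = FALSE)
  y2 <- mole_fraction_solubility(table$temperature_K, pressure,
                                 table$dG_solv_kJ_mol, table$density_g_cm3,
                                 solute)
  out <- data.frame(temperature_K = table$temperature_K,
                    sublimation_pressure_Pa = attr(y2, "psat"),
                    poynting_factor = attr(y2, "poynting"),
                    number_density_m3 = attr(y2, "number_density"),
                    mole_fraction = as.numeric(y2))
  mono <- if (nrow(out) < 2L) "undefined"
  else if (all(diff(out$mole_fraction) > 0)) "increasing"
  else if (all(diff(out$mole_fraction) < 0)) "decreasing"
  else "neither"
  structure(out, pressure_Pa = pressure, monotonicity = mono,
            class = c("solubility_result", "data.frame"))
}

#' @export
print.solubility_result <- function(x, digits = 4, ...) {
  cat(sprintf("Mole-fraction solubility at P = %g Pa\n", attr(x, "pressure_Pa")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("Trend of y2 with temperature:", attr(x, "monotonicity"), "\n")
  invisible(x)
}
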