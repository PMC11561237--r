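#' Thermodynamic truth fixture for the solubility chain
#'
#' Builds a [thermo_table()] from linear temperature models for the
#' solvation free energy and the solvent density, and evaluates the
#' mole-fraction solubility directly (inline, in one expression) at each
#' temperature.  Because the truth is computed by direct evaluation of the
#' same thermodynamic identity the analysis side implements,
#' [solubility_table()] applied to the emitted table must reproduce
#' `true_solubility` to machine precision — the round-trip check that pins
#' the chain's unit handling.
#'
#' @param temperatures Temperatures, K.
#' @param dG_model Length-2 numeric `c(intercept, slope)`: solvation free
#'   energy in kJ/mol as `intercept + slope * T`.
#' @param density_model Length-2 numeric `c(intercept, slope)`: solvent
#'   density in g/cm^3 as `intercept + slope * T`; must stay positive.
#' @param solute A [solute_params()] with sublimation enthalpy set.
#' @param pressure System pressure, Pa.
#' @return A list of class `thermo_truth`: `table` (a [thermo_table()]),
#'   `solute`, `pressure`, `true_solubility` (per-temperature mole
#'   fractions).  Errors if any true mole fraction leaves (0, 1): pick
#'   different parameters rather than emit an unphysical fixture.
#' @export
#' @examples
#' sol <- solute_params(3.961e-4, 4.106e-10, 298.15,
#'                      sublimation_enthalpy = 120)
#' tt <- gen_thermo_truth(seq(363.15, 453.15, length.out = 5),
#'                        dG_model = c(-35, 0), density_model = c(0.9, 0),
#'                        solute = sol, pressure = 2e6)
#' tt$true_solubility
gen_thermo_truth <- function(temperatures, dG_model, density_model, solute,
                             pressure) {
  stopifnot(length(dG_model) == 2L, length(density_model) == 2L)
  dG <- dG_model[1] + dG_model[2] * temperatures
  rho <- density_model[1] + density_model[2] * temperatures
  if (any(rho <= 0))
    stop("density model yields non-positive densities over the grid",
         call. = FALSE)
  tab <- thermo_table(temperatures, dG, rho)

  # direct, self-contained evaluation of the solubility identity
  dH <- solute$sublimation_enthalpy
  if (is.null(dH))
    stop("solute must carry a sublimation enthalpy", call. = FALSE)
  RT <- .Rgas * tab$temperature_K
  psat <- solute$reference_vapor_pressure *
    exp((dH * 1e3 / .Rgas) *
          (1 / solute$reference_temperature - 1 / tab$temperature_K))
  poy <- exp(solute$molar_volume * (pressure - psat) / RT)
  rho_n <- (tab$density_g_cm3 * 1000) / (solute$solvent_molar_mass / 1000) *
    .NAvo
  y2 <- psat * poy /
    (rho_n * .kB * tab$temperature_K * exp(tab$dG_solv_kJ_mol * 1e3 / RT))

  if (any(y2 <= 0 | y2 >= 1))
    stop("parameters give mole fractions outside (0, 1); choose a smaller ",
         "sublimation enthalpy, lower reference pressure, or more negative ",
         "solvation free energy", call. = FALSE)
  structure(list(table = tab, solute = solute, pressure = pressure,
                 true_solubility = y2),
            class = "thermo_truth")
}

#' @export
print.thermo_truth <- function(x, ...) {
  cat("Synthetic thermodynamic truth (", nrow(x$table), " temperatures, P = ",
      format(x$pressure), " Pa)\n", sep = "")
  df <- x$table
  df$true_y2 <- x$true_solubility
  print.data.frame(df, row.names = FALSE, digits = 5)
  invisible(x)
}
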