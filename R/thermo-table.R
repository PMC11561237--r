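#' Per-temperature thermodynamic table
#'
#' Holds, per temperature, the solvation free energy of the solute and the
#' mass density of the pure solvent — the two simulation-side inputs of the
#' solubility chain ([solubility_table()]).
#'
#' @param temperature_K Temperatures, K; strictly positive and unique.
#' @param dG_solv_kJ_mol Solvation free energies, kJ/mol (negative values
#'   mean favourable solvation).
#' @param density_g_cm3 Solvent mass densities, g/cm^3; strictly positive.
#' @return A `data.frame` of class `thermo_table` with those three columns,
#'   sorted by temperature.
#' @export
#' @examples
#' thermo_table(c(363.15, 453.15), c(-35.848, -35.590), c(0.902, 0.781))
thermo_table <- function(temperature_K, dG_solv_kJ_mol, density_g_cm3) {
  tab <- data.frame(temperature_K = as.numeric(temperature_K),
                    dG_solv_kJ_mol = as.numeric(dG_solv_kJ_mol),
                    density_g_cm3 = as.numeric(density_g_cm3))
  if (nrow(tab) == 0L) stop("thermo table has no rows", call. = FALSE)
  bad <- which(!stats::complete.cases(tab))
  if (length(bad))
    stop("non-numeric or missing value in thermo table row ", bad[1],
         call. = FALSE)
  if (any(tab$temperature_K <= 0))
    stop("temperatures must be strictly positive", call. = FALSE)
  if (anyDuplicated(tab$temperature_K)) {
    d <- tab$temperature_K[duplicated(tab$temperature_K)][1]
    stop("duplicate temperature ", d, " K in thermo table", call. = FALSE)
  }
  if (any(tab$density_g_cm3 <= 0))
    stop("densities must be strictly positive", call. = FALSE)
  tab <- tab[order(tab$temperature_K), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("thermo_table", "data.frame")
  tab
}

#' Read a thermodynamic table from CSV
#'
#' Expects exactly the headers `temperature_K`, `dG_solv_kJ_mol`,
#' `density_g_cm3` (extra columns are carried along untouched).  Rows are
#' validated and sorted by temperature.
#'
#' @param path CSV file path.
#' @return A [thermo_table()].
#' @export
read_thermo_table <- function(path) {
  raw <- utils::read.csv(path, check.names = TRUE, colClasses = NA,
                         stringsAsFactors = FALSE)
  need <- c("temperature_K", "dG_solv_kJ_mol", "density_g_cm3")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("thermo CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L)
    stop("thermo CSV has headers but no data rows: ", path, call. = FALSE)
  for (cl in need) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]))
    if (length(bad))
      stop("non-numeric value '", raw[[cl]][bad[1]], "' in column ", cl,
           ", row ", bad[1], " of ", path, call. = FALSE)
    if (anyNA(v))
      stop("missing value in column ", cl, ", row ", which(is.na(v))[1],
           " of ", path, call. = FALSE)
    raw[[cl]] <- v
  }
  tab <- thermo_table(raw$temperature_K, raw$dG_solv_kJ_mol, raw$density_g_cm3)
  extra <- setdiff(names(raw), need)
  if (length(extra)) {
    ord <- order(raw$temperature_K)
    for (cl in extra) tab[[cl]] <- raw[[cl]][ord]
  }
  tab
}

#' Solute parameters for the solubility chain
#'
#' Bundles the solute- and solvent-side constants of the mole-fraction
#' solubility model: the solute molar volume entering the Poynting factor,
#' a sublimation reference point with the sublimation enthalpy used to
#' extrapolate it across temperature (Clausius-Clapeyron), and the solvent
#' molar mass used to turn mass density into number density.
#'
#' @param molar_volume Solute molar volume, m^3/mol.
#' @param reference_vapor_pressure Solid-solute vapour pressure at
#'   `reference_temperature`, Pa.
#' @param reference_temperature Temperature of the reference point, K.
#' @param sublimation_enthalpy Sublimation enthalpy, kJ/mol, assumed
#'   temperature-independent over the extrapolation range.  No default:
#'   it must be supplied by the user (see [sublimation_pressure()]).
#' @param solvent_molar_mass Solvent molar mass, g/mol (default: water).
#' @return An object of class `solute_params`.
#' @export
#' @examples
#' # curcumin-like solute: molar volume and vapour pressure at 25 C
#' solute_params(molar_volume = 3.961e-4,
#'               reference_vapor_pressure = 3.08e-12 * 133.322,
#'               reference_temperature = 298.15,
#'               sublimation_enthalpy = 120)
solute_params <- function(molar_volume, reference_vapor_pressure,
                          reference_temperature,
                          sublimation_enthalpy = NULL,
                          solvent_molar_mass = 18.01528) {
  vals <- c(molar_volume = molar_volume,
            reference_vapor_pressure = reference_vapor_pressure,
            reference_temperature = reference_temperature,
            solvent_molar_mass = solvent_molar_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all solute parameters must be finite and strictly positive",
         call. = FALSE)
  if (!is.null(sublimation_enthalpy) &&
      (!is.finite(sublimation_enthalpy) || sublimation_enthalpy <= 0))
    stop("'sublimation_enthalpy' must be strictly positive (kJ/mol)",
         call. = FALSE)
  structure(list(molar_volume = molar_volume,
                 reference_vapor_pressure = reference_vapor_pressure,
                 reference_temperature = reference_temperature,
                 sublimation_enthalpy = sublimation_enthalpy,
                 solvent_molar_mass = solvent_molar_mass),
            class = "solute_params")
}

#' @export
print.solute_params <- function(x, ...) {
  cat("Solute parameters:\n")
  cat(sprintf("  molar volume:        %.4g m^3/mol\n", x$molar_volume))
  cat(sprintf("  P_ref:               %.4g Pa at %.2f K\n",
              x$reference_vapor_pressure, x$reference_temperature))
  cat(sprintf("  sublimation enthalpy: %s\n",
              if (is.null(x$sublimation_enthalpy)) "<not set>"
              else sprintf("%.4g kJ/mol", x$sublimation_enthalpy)))
  cat(sprintf("  solvent molar mass:  %.5g g/mol\n", x$solvent_molar_mass))
  invisible(x)
}
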