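# Physical constants (CODATA 2018 exact values) and unit conversions.
# Coordinates are carried in angstrom and times in femtoseconds on the
# trajectory side; all thermodynamics is SI internally.  Conversions happen
# only at these constants' call sites, never ad hoc.

.kB <- 1.380649e-23        # Boltzmann constant, J K^-1
.Rgas <- 8.314462618       # molar gas constant, J mol^-1 K^-1
.NAvo <- 6.02214076e23     # Avogadro constant, mol^-1
.mmHg_Pa <- 133.322        # Pa per mmHg
.ang_m <- 1e-10            # m per angstrom
.fs_s <- 1e-15             # s per femtosecond

#' Physical constants used by the package
#'
#' Returns the constants the solubility and diffusion machinery relies on,
#' mainly so scripts can echo them into provenance blocks.
#'
#' @return Named numeric vector: Boltzmann constant (J/K), molar gas
#'   constant (J/mol/K), Avogadro constant (1/mol), Pa per mmHg.
#' @export
#' @examples
#' mdsolv_constants()
mdsolv_constants <- function() {
  c(k_B = .kB, R = .Rgas, N_A = .NAvo, Pa_per_mmHg = .mmHg_Pa)
}

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's RNG
# state afterwards so generators never perturb the session stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
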