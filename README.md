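# mdsolv

Post-simulation analysis for molecular-dynamics studies of solute
extraction in subcritical water: pair structure, diffusion and
solubility, with synthetic ground-truth generators so every estimator is
testable without the original trajectories.

Subcritical water (liquid water from ~90 °C up to the critical point,
under pressure) loses polarity as it heats and becomes an effective green
solvent for non-polar natural products such as curcumin.  MD studies of
such systems are read through three standard quantities, all implemented
here:

* **Radial distribution function.**  Shell-histogram estimator of
  `g(r) = N_ab(r, r+dr) / (rho_y * Vshell)` with exact shell volumes and
  minimum-image distances, plus first-peak extraction (position,
  intensity, prominence floor) and temperature-trend verdicts — the
  hydrogen-bonding readout.
* **Mean square displacement / Einstein relation.**  Time-origin-averaged
  MSD (FFT algorithm, exactly equal to the literal double loop) and an
  OLS fit of `MSD = 6 D t + c` returning the diffusion coefficient as a
  classed model object.
* **Mole-fraction solubility.**  The solvation-free-energy route

  ```
  y2 = P2_sat * exp[v_s (P - P2_sat) / RT] / (rho_n * kB * T * exp(dG_solv / RT))
  ```

  with the sublimation pressure `P2_sat(T)` extrapolated by integrated
  Clausius–Clapeyron from a reference point, the Poynting correction, a
  number-density reading of the solvent density, and the AARD percent
  statistic for density validation.

Trajectories travel as multi-frame XYZ (with box and time on the comment
line) or a LAMMPS text-dump dialect; thermodynamic tables as CSV.
Generators (`gen_brownian`, `gen_ideal_gas`, `gen_pair_gas`,
`gen_lj_fluid`, `gen_thermo_truth`) are seed-deterministic and carry known
ground truth.

## Worked example

```r
library(mdsolv)

## diffusion: Brownian fixture at a known D, then recover it
tr  <- gen_brownian(200, 8.1e-9, timestep = 1000, n_frames = 2000, seed = 42)
fit <- fit_diffusion(compute_msd(tr, "particle"))
fit
#> Einstein-relation fit (window 10-50% of max lag, 400 points)
#>   D = 8.499e-09 m^2/s  (se 5.4e-12)
#>   intercept c = -2.826e-19 m^2
```

The fixture was generated with `D = 8.1e-9 m^2/s`; the fit recovers it to
about 5 % at this reduced size (the full validation scale of 500
particles x 5000 frames recovers within 5 % in at least 9 of 10 seeds).

```r
## structure: dimer gas with a 1.75-angstrom separation
dimers <- gen_pair_gas(200, 1.75, periodic_box(60), seed = 42)
prof   <- compute_rdf(dimers, "A", "B", r_max = 10, bin_width = 0.05)
prof$r_centers[which.max(prof$g)]
#> [1] 1.725
```

The global maximum lands in the bin containing the set separation
(positions are bin centres, so agreement is to half a bin width).

```r
## solubility: packaged per-temperature table, curcumin-like solute
sol <- solute_params(molar_volume = 3.961e-4,
                     reference_vapor_pressure = 3.08e-12 * 133.322,  # mmHg -> Pa
                     reference_temperature = 298.15,
                     sublimation_enthalpy = 120)                     # kJ/mol, user input
tab <- read_thermo_table(system.file("extdata",
         "curcumin_subcritical_water.csv", package = "mdsolv"))
solubility_table(tab, sol, pressure = 2e6)
#> Mole-fraction solubility at P = 2e+06 Pa
#>  temperature_K sublimation_pressure_Pa poynting_factor number_density_m3 mole_fraction
#>          363.1               2.379e-06           1.300         3.015e+28     2.931e-09
#>          393.1               4.937e-05           1.274         2.995e+28     1.864e-08
#>          413.1               2.919e-04           1.259         2.922e+28     6.989e-08
#>          423.1               6.664e-04           1.253         2.858e+28     1.171e-07
#>          453.1               6.374e-03           1.234         2.611e+28     6.096e-07
#> Trend of y2 with temperature: increasing

ok <- !is.na(tab$density_calc_g_cm3)
aard(tab$density_g_cm3[ok], tab$density_calc_g_cm3[ok])
#> [1] 6.503009
```

Solubility rises with temperature — the qualitative signature of
subcritical-water extraction — and the simulated-vs-literature density
AARD is 6.50 %.  Absolute `y2` values depend strongly on the
user-supplied sublimation enthalpy (see the methods vignette).

`run_pipeline()` executes all stages at the study scale and writes CSV
tables plus a JSON report with full provenance; `exec/mdsolv` exposes the
same stages as shell subcommands (`simulate`, `rdf`, `msd`, `solubility`,
`report`).

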