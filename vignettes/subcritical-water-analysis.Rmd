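---
title: "Methods: pair structure, diffusion and solubility for subcritical-water extraction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pair structure, diffusion and solubility for subcritical-water extraction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsolv)
```

## The scientific problem

Subcritical water — liquid water held between roughly 90 °C and its
critical point under enough pressure to stay liquid — is a green
extraction solvent: as temperature rises its dielectric constant falls and
it increasingly dissolves non-polar natural products such as curcumin.
Molecular-dynamics studies of such systems typically answer three
questions from the trajectories:

1. **Structure** — how strongly do solvent and solute associate, read from
   radial distribution functions (RDFs) and the temperature trend of their
   first-peak intensities (a falling water O–H peak means weakening
   hydrogen bonding; a rising solute–water peak means strengthening
   association);
2. **Transport** — how fast the solute diffuses, from the slope of the
   mean square displacement (MSD) via the Einstein relation;
3. **Thermodynamics** — how soluble the solute is, from the solvation free
   energy via a mole-fraction solubility identity, validated against
   literature solvent densities with the AARD statistic.

`mdsolv` implements this post-simulation chain as reusable, tested
components.  Running the force-field MD itself is out of scope: the
package instead ships seed-deterministic synthetic generators whose ground
truth is known exactly, so every estimator can be validated end to end.

## The estimators

### Radial distribution function

For species selections $a$ and $b$ the pair correlation is estimated per
frame by binning minimum-image pair distances into shells $[r, r+\Delta r)$
and normalising with the *exact* shell volume:

$$ g(r) = \frac{N_{ab}(r, r+\Delta r)}
               {n_{\text{pairs}}\; \frac{4}{3}\pi\left[(r+\Delta r)^3 - r^3\right] / V} $$

Two conventions matter and are fixed here:

* **Exact shell volumes.**  The textbook differential $4\pi r^2\,\Delta r$
  agrees with the exact difference of sphere volumes only as
  $\Delta r \to 0$.  Using the exact volume keeps the number-conservation
  identity $\rho_y \sum_r g(r)\,V_{\text{shell}}(r) = \langle$ neighbour
  count within $r_{max}\rangle$ exact at any bin width, which the tests
  exploit.
* **Like-species density.**  For $a = b$ each unordered pair is counted
  once and the partner density is $(N-1)/V$, so the ideal-gas limit is
  exactly 1 (with $N/V$ it would be biased by $1/N$).  This also makes
  $g_{ab} \equiv g_{ba}$.

The default bin width is 0.05 Å.  Peak positions are reported as bin
centres: a first-shell position such as 1.75 Å is therefore resolved to
half a bin width, and tests pin the *bin containing* a known separation
rather than an exact float.  Unwrapped input coordinates are wrapped into
the box before binning; $r_{max}$ may not exceed half the shortest box
edge, beyond which the minimum image is ambiguous.

`first_peak()` returns the first local maximum that strictly exceeds both
neighbours and rises more than a prominence floor (default 0.05 in $g$
units) above the higher of its flanking valleys.  The floor suppresses
single-count shot noise in finitely sampled histograms; for delta-like
fixtures such as the dimer gas, where one stray background pair can fake
an arbitrarily prominent early maximum, the global maximum is the robust
readout and is what the pipeline reports.  `peak_trend()` tabulates
first peaks across temperatures and issues a strict-monotonicity verdict
(`increasing` / `decreasing` / `neither`) on the intensities.

### Mean square displacement and diffusion

The MSD averages $|\mathbf r(t_0 + k\,\Delta t) - \mathbf r(t_0)|^2$ over
all particles of a species and all time origins $t_0$.  With every origin
used (the default) the package computes this through the FFT
autocorrelation decomposition — exactly equivalent to the literal double
loop (the tests assert equality to ~1e-15) but $O(F\log F)$ instead of
$O(F^2)$ per particle, which is what makes the 500-particle × 5000-frame
validation runs affordable.  Per-signal centring is applied first purely
for numerical conditioning; the MSD is translation invariant.

Wrapped trajectories are *refused*, not silently unwrapped: reconstructing
continuous paths from wrapped coordinates without image flags is ambiguous
whenever a particle can cross half a box between frames.

`fit_diffusion()` is ordinary least squares of $\mathrm{MSD} = 6Dt + c$
over a lag window, by default 10–50 % of the largest lag.  The lower edge
excludes the short-lag region absorbed by the intercept $c$; the upper
edge excludes long lags where few origins remain and the estimator
variance grows.  The fit returns a classed model object with
`print`/`summary`/`coef`/`predict`/`residuals`/`plot` methods; $D$ is the
slope divided by 6 (three dimensions), with a standard error propagated
from the residuals.  The standard error describes scatter about the line,
not the full origin-overlap covariance, and is reported as a rough guide
only.

### Solubility from solvation free energy

The mole-fraction solubility of a solid solute in a dense solvent is

$$ y_2 = \frac{P_2^{sat}\,
          \exp\!\left[\beta \vartheta^s (P - P_2^{sat})\right]}
         {\rho\, k_B T\, \exp(\beta \Delta G^{solv})} $$

with $P_2^{sat}$ the sublimation pressure, $\vartheta^s$ the solute molar
volume (Poynting correction of the solid's fugacity to the system pressure
$P$), $\rho$ the solvent **number** density and $\Delta G^{solv}$ the
solvation free energy.  Three clarifications the implementation commits
to:

* $\rho k_B T$ must carry pressure units, which forces the number-density
  reading of $\rho$; mass density in g/cm³ is accepted at the interface
  and converted via the solvent molar mass.
* $\beta$ is kept molar throughout ($1/RT$ against kJ/mol energies),
  algebraically identical to the per-particle form.
* $P_2^{sat}(T)$ is extrapolated from a reference point with the
  integrated Clausius–Clapeyron relation at constant sublimation enthalpy,
  $P = P_{ref}\exp[(\Delta H_{sub}/R)(1/T_{ref} - 1/T)]$.  The enthalpy is
  a **required user input with no default**: literature vapour-pressure
  entries for sparingly volatile solids (curcumin's is
  $3.08\times 10^{-12}$ mmHg at 298.15 K) rarely come with a consistent
  $\Delta H_{sub}$, and silently assuming one would move the answer by
  orders of magnitude.  The demonstration pipeline uses 120 kJ/mol, a
  mid-range value for hydrogen-bonded organic crystals of this size,
  chosen once for the synthetic fixtures and not tuned.

A curcumin-like worked case pins the magnitudes: at 363.15 K and 2 MPa
with $\Delta G^{solv} = -35.848$ kJ/mol, solvent density 0.962 g/cm³,
$\vartheta^s = 3.961\times10^{-4}$ m³/mol and a sublimation pressure of
$2.86\times10^{-3}$ Pa, the chain gives $y_2 \approx 3.3\times10^{-6}$.
(One literature source labels the $3.961\times10^{-4}$ m³ mol⁻¹ figure a
"molar mass"; its units identify it as the molar volume and it is treated
as such here.)  Mole fractions outside $(0,1)$ raise a warning rather than
an error so that exploratory parameter sweeps do not crash.

The AARD validation statistic is
$100 \times \mathrm{mean}_i\,|s_i - r_i| / |r_i|$.  For the packaged
subcritical-water table the reference (denominator) is the literature
density and only the four temperatures with both simulated and literature
values enter; the recomputed value is 6.50 %.

## What the synthetic generators emulate — and what they do not

* `gen_brownian()` draws independent Gaussian steps with per-axis variance
  exactly $2D\,\Delta t$, so MSD$= 6Dt$ holds by construction and a fitted
  $D$ can be compared to the input.  Real MD displacement series are
  velocity-correlated at short lags and hydrodynamically correlated
  between particles; passing the recovery tests therefore validates the
  estimator chain, not any force field.
* `gen_ideal_gas()` is the exact null of pair structure ($g \equiv 1$).
* `gen_pair_gas()` plants dimers at an exact separation — a delta peak for
  peak-location tests.  Dimer centres are *not* kept apart, so the
  background between peaks is nonzero at high pair density.
* `gen_lj_fluid()` equilibrates a Lennard-Jones fluid (reduced units,
  cutoff 2.5 σ) with single-particle Metropolis moves of half-width
  0.15 σ, harvesting 10 configurations 10 sweeps apart at the end of the
  run.  It supplies realistic liquid structure (first shell near 1.1 σ at
  $\rho^* = 0.8$, $T^* = 0.9$) and a dilute limit that converges to
  $e^{-u(r)/T^*}$; it is not a water model and makes no claim about any
  specific solvent.
* `gen_thermo_truth()` builds a thermo table from linear $\Delta G(T)$ and
  $\rho(T)$ models and evaluates the solubility identity directly and
  self-containedly; `solubility_table()` must reproduce it to machine
  precision.  The default demonstration models
  ($\Delta G = -20 - 0.045\,T$ kJ/mol, $\rho = 1.35 - 0.00125\,T$ g/cm³
  over 363–453 K) give a physically plausible, strictly increasing
  $y_2(T)$, mirroring the qualitative behaviour expected of subcritical
  water extraction.

All generators take an explicit seed, restore the caller's RNG state, and
are bitwise reproducible for a given seed.

## Problem sizes and numerical choices

The validation scales, chosen as the package's study conditions:

* Diffusion recovery: 500 particles, 5000 frames at 1 ps spacing, per-axis
  step s.d. ≈ 0.94 Å at $D = 4.4\times10^{-9}$ m²/s; fit window 10–50 %;
  recovered $D$ within 5 % of truth in at least 9 of 10 seeds per
  temperature, with the temperature ranking preserved.  Module tests use
  reduced sizes (30–200 particles, 400–2000 frames) with correspondingly
  looser bounds.
* RDF null: 1000 uniform particles, 50 frames, 30 Å box — $g = 1 \pm 0.1$
  over 2–14 Å at 0.05 Å bins.
* Brute-force cross-checks (pair counts, MSD origins, minimum image) run
  on instances of ≤ 100 particles / ≤ 20 frames where $O(N^2)$ scans are
  exact and cheap.
* Degenerate inputs fail loudly and early: wrapped input to the MSD,
  triclinic dump cells, duplicate temperatures, missing sublimation
  enthalpy, separations beyond half a box edge, empty tables.
* Ties: `minimum_image` maps onto $(-L/2, L/2]$ (the boundary belongs to
  the positive side); monotonicity verdicts are strict, so exact ties
  yield `neither`.

## Design decisions that were genuinely open

* **Unwrapped vs wrapped by construction.**  Brownian fixtures are
  unwrapped (what MSD needs); uniform/dimer/LJ fixtures are wrapped (what
  RDF needs).  Each estimator's precondition is therefore satisfiable by
  construction, and the MSD's refusal of wrapped input is testable.
* **XYZ dialect.**  Plain XYZ has no cell record, so the writer puts
  `box=Lx,Ly,Lz t=<fs> wrapped=0|1` on the comment line and the reader
  requires it.  Orthorhombic cells only, matching the scope of the
  minimum-image implementation; the LAMMPS-dump reader likewise rejects
  triclinic bounds rather than mis-reading them.
* **The model-object idiom.**  The one true model fit in the chain,
  `fit_diffusion()`, returns a classed object with the standard
  `coef`/`predict`/`plot` surface; the other stages return classed tables
  and profiles with `print`/`plot` methods, which fits their
  estimator-not-model character.
* **Command-line interface.**  `exec/mdsolv` is a thin `Rscript` wrapper
  (subcommands `simulate`, `rdf`, `msd`, `solubility`, `report`) over the
  exported functions; all logic lives in the package, logging goes to
  stderr, tables to files, and `run_pipeline()` writes every artefact
  atomically (temp file + rename) with a provenance block carrying the
  seed, the full configuration and package versions.

## Known limitations

* Reproducing any *specific* simulation's RDF intensities or absolute MSD
  curves requires that simulation's trajectories and force field; the
  package validates estimators on synthetic ground truth instead, and the
  packaged thermo table carries published per-temperature inputs, not
  trajectories.
* Published solubility tables for curcumin in subcritical water cannot be
  regenerated from their printed inputs alone: the sublimation enthalpy
  behind their Clausius–Clapeyron step and the per-temperature
  $P_2^{sat}$ values are not printed, and no single constant enthalpy
  through the printed reference point reproduces all rows at once.  The
  solubility identity is therefore validated by the exact synthetic round
  trip and the worked-magnitude case, not against published absolute
  solubilities.
* The MSD assumes uniformly spaced frames; the RDF estimator's cost is
  $O(N^2)$ per frame, adequate to a few thousand particles.
* No triclinic cells, velocities, forces, or binary trajectory formats.
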