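---
title: "Methods: electrolyte activity derivatives and hydration-shell profiling"
author: "halosolv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrolyte activity derivatives and hydration-shell profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halosolv)
```

This vignette documents the models behind `halosolv`, the tunable
parameters and their defaults, the design choices made where conventions
were genuinely open, and what the synthetic-data generators do and do not
establish about real simulation data.

## The scientific setting

Halophilic organisms balance molar external NaCl by accumulating
comparable KCl in their cytoplasm; their proteins carry an unusually high
fraction of acidic (Asp/Glu) residues. Testing hypotheses about why —
competition for water, cooperative cation–carboxylate networks — requires
three quantitative ingredients this package provides: (i) a route from pair
correlations in closed simulation boxes to electrolyte activity
derivatives, so force-field ion–ion interactions can be checked against
experiment; (ii) machinery to optimise a single Lennard-Jones pair
parameter (the K⁺⋯carboxylate-oxygen Rmin) against both the activity
derivative and crystallographic contact distances; and (iii) structural
and dynamical profiling of the protein solvation shell (proximal
densities, hydrogen bonds, shell-resolved diffusion).

## Kirkwood–Buff route to the activity derivative

For species $i,j$ the finite-size-corrected integral is

$$G_{ij}(R) = \int_0^{2R}\left[f_{ij}\,g^{NVT}_{ij}(r) - 1\right]
4\pi r^2\left(1 - \tfrac{3x}{2} + \tfrac{x^3}{2}\right)\mathrm{d}r,
\qquad x = r/(2R),$$

with $R = L/4$ by default (overridable for convergence studies). The
kernel weight equals 1 at $r=0$ and vanishes at $r=2R$; integrating it
alone gives exactly $\tfrac{4}{3}\pi R^3$, which the tests use as a closed
form. The tail factor $f_{ij}$ compensates the closed-ensemble RDF tail,
which converges to $1 \pm O(1/N)$ rather than 1; it is estimated as the
reciprocal of the mean of $g$ over the final 20% of $[0, 2R]$. The window
fraction is a package decision (no established convention exists): late
enough to avoid structured regions, wide enough for a stable mean, and
config-exposed.

Electroneutrality makes single-ion integrals thermodynamically
ill-defined, so a 1:1 electrolyte is treated as a binary mixture of
indistinguishable ions ("cosolvent") and water:
$G_{cc} = (2G_{+-} + G_{++} + G_{--})/4$, $G_{cw} = G_{+w} + G_{-w}$, and

$$a'_c = \frac{1}{1 + \rho_c\,(G_{cc} - G_{cw})},$$

with $\rho_c = (n_+ + n_-)/V$. A non-positive denominator has no
thermodynamic meaning and is treated as an error, not clamped.
`activity_pipeline()` runs this per replica and reports mean ± SEM;
a single replica reports SEM as missing rather than zero.

Numerical choices: the RDF estimator uses exact shell volumes
$\tfrac{4}{3}\pi[(r+dr)^3 - r^3]$, minimum-image distances and the
distinct-pair convention (self pairs excluded); quadrature is trapezoidal
on the bin grid with the two exactly-known endpoint values appended —
RDFs are binned data, so higher-order rules gain nothing. Default bin
widths are 0.02 Å for parameterisation-grade RDFs and 0.05 Å otherwise.

## Pitzer reference model

The mean molal activity coefficient of a 1:1 salt is

$$\ln\gamma_\pm = f^\gamma(I) + B^\gamma(I)\,m + \tfrac{3}{2}C^\phi m^2,
\qquad I = m,$$

with the standard Debye–Hückel term ($b = 1.2$) and the exponential
second-virial term ($\alpha = 2.0$). The molal activity derivative is
$a'^{(b)}_s = 1 + m\,\mathrm{d}\ln\gamma_\pm/\mathrm{d}m$, differentiated
analytically; a central-difference route (step $10^{-4}$ in $\ln b$) is
retained and the two agree below $10^{-6}$ across $b \in [0.01, 3]$.
The potassium acetate preset uses the standard 25 °C ion-interaction
constants ($\beta^0 = 0.1587$, $\beta^1 = 0.3251$, $C^\phi = -0.0066$,
$A_\phi = 0.392$); temperature is fixed at 298 K and $A_\phi$ is an input,
not derived from solvent theory. Presets are data and overridable.

The molar-scale derivative needs a solution-density curve:
$a'_s = a'^{(b)}_s\,\partial\ln b/\partial\ln\rho_s$ with
$\rho_s(b) = b\rho(b)/(1 + bM/1000)$ per kilogram of water. Interpolation
is monotone piecewise-cubic (`monoH.FC`) and extrapolation is forbidden.
The packaged potassium acetate table
(`koac_density_25C_synthetic.csv`) is compiled from standard handbook
densities through an apparent-molar-volume representation
($\phi_V \approx 49.5 + 1.5\sqrt{b}$ cm³/mol); it is a faithful stand-in,
not a transcription of any single literature table, and users with a
preferred source can supply their own CSV. For 1:1 electrolytes the salt
and cosolvent scales share derivatives and activity coefficients, while
activities differ by the factor 2.

## Pair-parameter scan

Unlike-pair LJ parameters default to Lorentz–Berthelot combinations
(arithmetic mean of Rmin, geometric mean of ε); the scanned candidate is a
multiplicative factor on Rmin only, ε staying at its combination-rule
value — the 12/6 powers make Rmin by far the more effective knob, and a
two-parameter scan would square the cost for little gain.

Peak positions are extracted by least-squares fitting
$A\,e^{-(r-\mu)^2/2s^2} + B$ to the first RDF peak. The fit window runs
from the left flank where $g$ first exceeds half the peak value to the
first local minimum after the peak; the constant baseline $B$ absorbs the
$g \approx 1$ background. These window rules are package decisions — only
"a Gaussian fitted to each peak" is conventional. The peak anchor is the
global maximum of the curve (which the fit then refines); delta-like
peaks from scripted placements, too narrow for a meaningful four-parameter
fit (< 5 bins), fall back to the window's centre of mass, accurate to half
a bin.

Selection applies a hard acceptance band (default ±7%, strict `<=` on
unrounded values) to the activity derivative at *every* concentration,
then minimises the mean unsigned relative deviation from the
crystallographic contact distances; ties break toward the smaller factor,
and the result is invariant to candidate ordering. An empty survivor set
is an error, not a silent fallback.

## Solvation-shell structure

The proximal density of species $X$ divides time-averaged shell counts by
the area of the distance-$r$ isosurface:
$\rho_X(r) = \bar n_X(r) / (dr\,\overline{SASA}(r))$, shells
$[r, r+dr)$ with $dr = 0.05$ Å by default, water measured at its oxygen.
$SASA(r)$ is the exposed area of the union of spheres of radius $r$
centred on the protein heavy atoms — a uniform-distance isosurface, not a
rolling-probe SASA with per-atom radii. It is sampled with a deterministic
Fibonacci spiral point set (960 points/atom by default) so results are
reproducible without a seed; the two-sphere closed form
$4\pi r(r + d/2)$ is reproduced within 0.5% at that density. Because the
same geometry enters numerator and denominator, a uniform solvent yields a
flat profile equal to $N/V$ — the package's strongest internal check of
the normalisation. For a rigid protein the SASA curve is computed once;
otherwise per frame and averaged, which is also the convention used for
the hydrogen-bond surface density $\sigma_{HB} = \bar n_{HB}/\overline{SASA}$
(per-frame quantities, then time averages).

A strong hydrogen bond donated by water requires O$_w$⋯acceptor < 3 Å and
an O–H⋯acceptor angle > 135°, maximised over the two hydrogens, strict
inequalities, acceptors being protein N and O. The angle is measured *at
the hydrogen* by default; the common phrasing is ambiguous between that
and the angle between the O–H bond vector and the O⋯A vector, so both are
implemented (`angle_at = "hydrogen"`/`"oxygen"`) with the hydrogen-vertex
convention as default — it is the stricter and more widespread geometric
criterion. The first hydration shell defaults to 4.5 Å from the protein
surface, overridable per protein from the first minimum of $\rho_X(r)$.
Hydrogens are identified by the element field, falling back to a name
prefix of "H".

## Solvation-shell dynamics

Shell populations are tagged at the first analysed frame (proximal
distance ≤ cutoff) and never re-tagged: members that leave the shell stay
in the population, matching the "belong to the shell at $t=0$" definition.
MSDs average over every sliding origin (the spacing of origins is a free
choice; maximal averaging costs little with the compiled kernel) and over
the tagged atoms. The wrapped-coordinate convention uses in-cell positions
verbatim — appropriate at short times and reproducing the saturation of
shell-population curves near $3(L/2)^2$ from confinement — while the
unwrapped convention uses the continuous walk; the Brownian generator
always stores the continuous walk so both views stay retrievable, and
shell-versus-bulk reports quote the unwrapped fit with the wrapped value
alongside. Diffusion coefficients come from ordinary least squares of
MSD on $\tau$ over 20–30 ps ($D =$ slope/6), the window in which dynamics
is diffusive but confinement still marginal; $C$ absorbs short-time
non-diffusive motion. Units are Å²/ps internally and $10^{-5}$ cm²/s at
reporting boundaries.

## Synthetic generators: what they establish

The generators emulate the *statistical structure* of the study's inputs,
not their physics: no force field, no thermostat, no TIP3P structure.

* `gen_ideal_solution()` draws positions i.i.d. uniform per frame, so all
  RDFs are 1 in expectation and the full KB pipeline must return
  $a'_c = 1$; this is an exact oracle for estimator bias. Placements are
  deliberately unthinned — enforcing a minimum separation would break the
  Poisson statistics the oracle relies on; scripted and paired placements
  instead keep a 0.5 Å minimum separation to avoid degenerate geometry.
* `gen_paired_solution()` places a known fraction of cation–anion pairs at
  Gaussian-distributed contact separations, giving a first RDF peak of
  known position for validating the peak fitter. (The RDF peak of a
  Gaussian *distance* distribution sits lower than its mean by
  $\approx 2\sigma^2/r$ — about 0.007 Å at 2.8 Å width 0.1 Å — well inside
  the 0.02 Å recovery tolerance.)
* `gen_brownian()` draws coordinate increments with variance
  $2D\,\Delta t$ per dimension, so the ensemble MSD is exactly $6D\tau$;
  recovery of $D$ through the window fit validates tagging, averaging and
  the fit in one pass.
* `gen_toy_protein_system()` builds a rigid pseudo-protein (central atom
  plus radial carboxylate-like arms with O/N acceptors) and scripts
  solvent at exact distances/angles, including a five-site cation contact
  table whose `r_cryst` are the scripted distances. Waters are rigid
  3-site molecules (O–H 0.9572 Å, 104.52°) so hydrogen-bond geometry is
  exercisable without energetics.

Randomness follows one protocol: a root seed plus deterministic per-stream
child seeds (`derive_seed()`), so replicas mimic independent production
runs while remaining bit-reproducible.

Passing these tests shows the *estimators* are unbiased and correctly
implemented at known ground truth. It does not show that any force field
reproduces real potassium acetate structure, nor does it reproduce
production-scale observables (hydration-peak heights of order
$10^2$ molecules/nm³, sub-3 ions/nm³ cation peaks, percent-level
activity-derivative deviations), which require hundreds of nanoseconds of
sampling; those quantities are covered here by the property suite, not by
re-simulation.

## Problem sizes and other defaults

The packaged demonstrations and checks run at desk scale, chosen as the
smallest sizes at which the statistical assertions are comfortably
resolved: KB replicas of 500+500 ions in a 60 Å box over 200 frames × 3
replicas; peak-fit recovery from 300+300 ions over 150 frames; diffusion
recovery with 500 walkers over 10⁴ steps of 0.1 ps × 3 seeds; uniformity
checks with 1200 solvent particles over 12 frames × 3 replicas. The
pipeline config (`read_run_config()`) exposes all of them.

## Known limitations

* The closed-box KB route inherits the $O(1/N)$ tail ansatz; very small
  or strongly structured systems can push $f_{ij}$ outside its expected
  band, which should be treated as a warning sign rather than corrected.
* The molar-scale conversion is only as good as the density table; the
  packaged potassium acetate curve is handbook-derived, and molar
  derivatives from different literature density sources can differ by a
  few percent at high molality.
* `sasa_at_distance()` scales as (atoms)² × points; it is meant for
  per-shell profiling of single proteins, not for bulk per-frame SASA of
  large complexes.
* The wrapped-MSD convention conflates re-imaging jumps with diffusion at
  intermediate lags; that is why reports carry the unwrapped fit
  alongside.
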