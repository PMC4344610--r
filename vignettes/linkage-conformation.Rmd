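---
title: "Validating glycosidic-linkage conformation against NMR observables"
author: "glycotorsion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating glycosidic-linkage conformation against NMR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotorsion)
```

## The problem

The conformation of a glycosidic linkage C1--O--Cx is described by two
torsional angles, here defined in the NMR-oriented convention
phi = H1--C1--O--Cx and psi = C1--O--Cx--Hx. Molecular simulations of
oligosaccharides produce ensembles of (phi, psi) snapshots; solution NMR
gives two independent, ensemble-averaged windows onto the same
distribution:

* **trans-glycosidic couplings.** A three-bond 13C--1H coupling across the
  glycosidic oxygen depends on the intervening torsion through a Karplus
  relation, J(theta) = A cos^2(theta) + B cos(theta) + C. Because the
  relation is strongly nonlinear, the observable is the average of the
  curve, `<J(theta)>`, never the curve at the average angle.
* **NOEs.** In the isolated two-spin approximation (valid within the linear
  NOE build-up regime), the relative NOE of a proton pair against a
  reference pair is the reciprocal ratio of ensemble-averaged inverse sixth
  powers of the interproton distances, `<r_pair^-6> / <r_ref^-6>`.

`glycotorsion` implements both predictions plus the supporting machinery:
conformer classification on the phi/psi torus, dihedral-driving energy
maps, ensemble I/O, and a synthetic ensemble generator, so that every
stage is testable without any simulation engine.

## Ensemble-averaged couplings

The default Karplus parameterization (`tvaroska1989`,
J = 5.7 cos^2(theta) − 0.6 cos(theta) + 0.5 Hz) is the classical
parameterization for C--O--C--H fragments; coefficients are data, and
alternate sets can be supplied in YAML. Averaging is an explicit weighted
mean over snapshots:

```{r}
pars <- default_karplus_sets()$tvaroska1989
ensemble_j(c(40, 40, 0), pars)          # <J> over three snapshots
karplus_j(mean(c(40, 40, 0)), pars)     # J(<theta>): not the same thing
```

Agreement with experiment is summarized by `compare_couplings()` and
`mean_absolute_deviation()`. The default tolerance of 0.5 Hz is the
experimental uncertainty of J-HMBC-measured long-range couplings; a
deviation at or below it is flagged `within_error`. Headline rounding
follows the conventions of the packaged tables: couplings to 1 decimal,
mean absolute deviations to 2.

The package ships the measured and calculated couplings of five
fucosylated chondroitin sulfate (FCS) oligosaccharide fragments
(`fcs_coupling_table()`, 14 measurable linkage/torsion cells, sources:
experimental, in vacuo, SASA continuum, explicit water). Running the
comparison reproduces the headline deviations — about 0.84 Hz in vacuo
versus 0.34 Hz with continuum solvation — which is the package's built-in
regression anchor:

```{r}
tab <- fcs_coupling_table()
exp_rows <- tab[tab$source == "experimental", ]
sapply(c("in_vacuo", "SASA", "water"), function(src)
  mean_absolute_deviation(compare_couplings(exp_rows, tab[tab$source == src, ])))
```

## Conformer states and populations

Linkages of this family populate a small number of localized states:
phi stays near +30 degrees (exo-anomeric effect) while psi clusters near
+40 (state I), near 0 (state II), or — for sterically permissive linkages —
near the inverted region around ±180 (state III). The package formalizes
the states as circular-distance regions: a center on the torus plus a
per-coordinate acceptance radius (default 35 degrees, following the
region widths visible in typical scatter plots). Because the I and II
acceptance boxes overlap between psi = 5 and 35 degrees, assignment is by
nearest center in combined circular distance, with exact ties broken by
declaration order; each frame therefore receives exactly one label, or
`"unassigned"` outside all radii.

```{r}
classify_conformers(c(30, 30, 30, 30), c(40, 0, -175, 100))
```

## Relative NOEs and inverted conformers

NOE predictions need Cartesian coordinates (a torsion-only ensemble
raises a capability error). For testing and synthetic work the package
builds an idealized five-atom fragment (H1--C1--O--Cx--Hx, C--H 1.09 Å,
C--O 1.43 Å, tetrahedral angles, glycosidic valence angle 117°) that
realizes any requested (phi, psi) exactly; only relative quantities
(torsions and distance ratios) travel downstream, so idealized geometry
is sufficient. Two pseudo-protons ride rigidly with psi at fixed
torsional offsets about the O--Cx bond, standing in for the aglycon ring
protons flanking the linkage carbon: both are far from H1 in states I/II
and approach H1 only in the inverted state III. This reproduces the
diagnostic logic of NOE-based model selection: an ensemble containing
even trace state III predicts an H1--H4-analogue cross-peak, and its
absence from the spectra argues against that ensemble.

```{r}
ref <- proton_pair("H1", "HX"); h4 <- proton_pair("H1", "H4X")
sasa  <- sample_coordinates(mixture_scenario("fuc_gla_sasa_like",
                                             n_frames = 2000, seed = 1))
water <- sample_coordinates(mixture_scenario("fuc_gla_water_like",
                                             n_frames = 2000, seed = 1))
c(sasa  = relative_noe(sasa,  list(h4), ref)$intensity,
  water = relative_noe(water, list(h4), ref)$intensity)
```

`flag_incompatible_noes()` applies the decision rule: a predicted
intensity strictly above 0.05 with an observed intensity of 0 (absent
cross-peak) is flagged, and vice versa. The 0.05 default is the largest
predicted value still treated as consistent with absence.

## The synthetic generator

`state_mixture()` draws i.i.d. snapshots from a mixture of wrapped
Gaussians on the torus. Wrapped Gaussians were chosen over von Mises
components because at the spreads used here the two are practically
identical and the wrapped form inverts trivially for closed-form test
oracles. The default per-coordinate spread is 8 degrees: tight enough to
match the compact clustering that the exo-anomeric effect imposes, and it
places the nearest inter-state decision boundary (20 degrees between
states I and II) at 2.5 standard deviations, so classification leakage
(~0.6% per boundary side) stays well below binomial sampling error at the
ensemble sizes used (n = 10,000, the size of the reference sampling plan:
a 20,000 ps run sampled every 2 ps). All randomness flows through the
model's single seed and the global RNG stream is restored afterwards.

The scenario presets encode the qualitative solvent-model contrast as
documented synthetic weights, not measured populations: `fuc_gla_sasa_like`
keeps 5% of state III (trace inverted conformers under continuum
solvation), `fuc_gla_water_like` sets state III to exactly 0 (inverted
conformers vanish in explicit water), and `fuc_fuc_like` has states I/II
only (axial crowding blocks inversion).

What the generator deliberately does **not** emulate: temporal
autocorrelation (frames are i.i.d., real MD frames are not), correlated
phi/psi fluctuations within a state, anharmonic state shapes, and any
energetics. Passing tests therefore demonstrate the correctness of the
averaging, classification and normalization machinery on ensembles with
known structure — not the realism of any force field or solvent model.

## Conformational maps

`scan_map()` drives both torsions over a uniform grid covering
[−180, 180) (default step 10 degrees, 36 × 36 = 1,296 single-point
evaluations) for any deterministic, 360-degree-periodic energy function,
and reports energies relative to the grid's global minimum. The scan is
rigid by design — no relaxation of other coordinates — which makes it a
rough map-reading tool, not a potential-energy surface; pluggable energy
functions let users substitute something better. `find_minima()` detects
minima on the discrete grid only (8-neighbour comparison with periodic
wrapping, default 5 kcal/mol reporting window), and
`boltzmann_population()` converts minimum energies to occupancies with
R = 0.0019872 kcal/(mol K) at 298 K.

```{r}
map <- scan_map(toy_two_well(), step = 10)
find_minima(map, energy_window = 5)
```

## Numerical choices and edge cases

* Angles are degrees at every API boundary; the working range is
  (−180, 180], with ±180 treated as the same point (circular distance is
  used wherever wrap-around matters).
* Dihedrals follow the IUPAC sign convention (cis = 0, positive =
  clockwise viewed along the central bond). Collinear triples and
  coincident bonded atoms raise classed degenerate-geometry errors rather
  than returning arbitrary values.
* Snapshot weights, where accepted, must be nonnegative with positive
  sum and are renormalized internally; uniform weighting is the default,
  since no reweighting scheme is assumed for supplied ensembles.
* Equilibration handling: `simulation_plan()` carries a discard prefix,
  defaulting to 0 — ensembles handed to the package are taken as already
  production-quality.
* Ensemble sizes in the shipped tests and acceptance script (10,000
  torsion frames; 4,000 coordinate frames for NOE work) match the
  reference sampling plan where the quantity is statistical, and are
  reduced where only machinery is exercised.

## Limitations

The NOE model is isolated two-spin `<r^-6>`: no relaxation matrix, spin
diffusion or mixing-time dependence. The fragment builder is an idealized
linkage, not a sugar-ring builder; ring pucker and substituent effects
are out of scope. The scan module evaluates user-supplied potentials
only — no force field is included. Torsion-table input supports the
coupling and conformer pipeline but, by construction, not NOEs.
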