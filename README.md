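# glycotorsion

Conformational analysis of glycosidic linkages validated against solution
NMR — for carbohydrate modellers who have torsional or Cartesian ensembles
of an oligosaccharide linkage (from MD or any other source) and want to
confront them with measured trans-glycosidic couplings and NOEs.

A glycosidic linkage C1–O–Cx is described by two torsions,
φ = H1–C1–O–Cx and ψ = C1–O–Cx–Hx (the NMR-oriented convention). The
package computes, from an ensemble of snapshots:

* **Ensemble-averaged couplings** — ³J(C–H) across the glycosidic oxygen
  via a Karplus relation, J(θ) = A·cos²θ + B·cosθ + C, averaged as
  ⟨J(θ)⟩ over frames (never J(⟨θ⟩)). Default coefficients are the
  classical C–O–C–H parameterization, J = 5.7cos²θ − 0.6cosθ + 0.5 Hz;
  alternates load from YAML.
* **Relative NOEs** — the isolated two-spin prediction
  ⟨r⁻⁶(pair)⟩ / ⟨r⁻⁶(reference)⟩ from Cartesian frames, plus a screening
  rule for predicted-but-absent cross-peaks.
* **Conformer populations** — classification of (φ, ψ) snapshots into
  labelled circular regions on the torus (defaults: state I at ψ≈+40°,
  II at ψ≈0°, III "inverted" at ψ≈±180°, all at φ≈30°) and exact
  count/fraction reports.
* **Conformational maps** — rigid dihedral-driving scans of a pluggable
  energy function on a 10°-step grid, grid-local minima, Boltzmann
  populations.

Supporting modules read/write multi-MODEL PDB, multi-frame XYZ and
torsion-table CSV ensembles, and generate synthetic ensembles from
wrapped-Gaussian mixtures of conformer states so the whole pipeline is
testable without any simulation engine. The measured coupling and NOE
tables of five fucosylated chondroitin sulfate (FCS) oligosaccharide
fragments ship as packaged data (`fcs_coupling_table()`,
`fcs_noe_table()`).

## Worked example

Compare the packaged experimental couplings with the continuum-solvation
predictions:

```r
library(glycotorsion)
tab <- fcs_coupling_table()
exp_rows <- tab[tab$source == "experimental", ]
cmp <- compare_couplings(exp_rows, tab[tab$source == "SASA", ])
head(as.data.frame(cmp), 4)
#>   compound linkage torsion_kind experimental_hz calculated_hz deviation_hz within_error
#> 1        1 Fuc-GlA          phi             3.8           3.4          0.4         TRUE
#> 2        1 Fuc-GlA          psi             2.5           2.7          0.2         TRUE
#> 3        2 Fuc-GlA          phi             2.7           3.6          0.9        FALSE
#> 4        2 Fuc-GlA          psi             2.9           2.3          0.6        FALSE
round(mean_absolute_deviation(cmp), 2)
#> [1] 0.34
```

The mean absolute deviation over the 14 measurable cells is 0.34 Hz —
below the 0.5 Hz experimental uncertainty of the J-HMBC measurement
(the in-vacuo column gives 0.8 Hz, clearly outside it).

Analyze a synthetic ensemble that keeps trace inverted conformers
(state III), as a continuum-solvation trajectory would:

```r
m <- mixture_scenario("fuc_gla_sasa_like", n_frames = 2000, seed = 1)
tors <- sample_torsions(m)
conformer_populations(classify_conformers(tors$phi_deg, tors$psi_deg),
                      default_conformer_states())
#> Conformer populations over 2000 frames:
#>   I            1480  (0.740)
#>   II            414  (0.207)
#>   III           106  (0.053)
#>   unassigned      0  (0.000)

coords <- sample_coordinates(m)
ref <- proton_pair("H1", "HX")
out <- relative_noe(coords, list(ref, proton_pair("H1", "H2X"),
                                 proton_pair("H1", "H4X")), ref)
out$intensity <- round(out$intensity, 3); out
#>     pair intensity reference
#> 1  H1-HX     1.000     H1-HX
#> 2 H1-H2X     0.057     H1-HX
#> 3 H1-H4X     0.115     H1-HX
```

The 5% of inverted conformers is enough to predict an H1–H4-analogue NOE
of ~0.12 relative to the reference cross-peak; the `fuc_gla_water_like`
preset (no state III) predicts ~0.02, i.e. an absent peak. That contrast
is exactly how NOE data discriminates between candidate ensembles.

`run_config()` + `cmd_analyze()` / `cmd_scan()` run the same computations
as a batch and write a CSV report bundle (time series, classification,
populations, couplings, NOE predictions, comparison tables with per-source
mean absolute deviations, map and minima files), each stamped with the
package version and a config hash.

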