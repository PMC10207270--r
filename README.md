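# ttbscan

Backbone carbonyl groups do more than hydrogen-bond: the lone pair of a
carbonyl oxygen O(i) can donate into the π-hole above the carbonyl carbon
C(i+1) of the next residue — an n→π\* interaction, equivalently a
C=O···C=O **tetrel bond** (TtB). These contacts stack along α-helices at
O···C distances of roughly 2.7–3.4 Å, approaching the carbonyl near the
Bürgi–Dunitz trajectory (~107°), and contribute a complementary,
weak-to-moderate (−0.5 to −3.6 kcal/mol) stabilization of helical peptide
conformations, with clear relevance to stapled-peptide inhibitors of the
p53–MDM2 interaction.

`ttbscan` is an R package for structural biologists and computational
chemists who want to find and score these contacts without running
electronic-structure calculations. It provides:

- **Detection** — parse (multi-model) PDB structures, extract backbone
  C=O units (non-natural residues such as hydrocarbon-staple MK8/0EH/2JH
  included), and flag O···C contacts by distance cutoff and approach-angle
  window (`parse_structure()`, `detect_contacts()`).
- **Energy estimation** — a least-squares calibration of interaction energy
  ΔE (kcal/mol) on the electron density at the contact critical point
  (ρ×100, a.u.), fitted on five small bimolecular model complexes:

  ΔE = a·(ρ×100) + b, with a ≈ −5.47, b ≈ +1.79, |r| ≈ 0.96

  Because the model complexes carry ancillary contacts (LP−π, π−π, CH−π)
  of density comparable to the tetrel bond, only **half** of the predicted
  energy is attributed to the TtB itself
  (`fit_calibration()`, `estimate_ttb_energy()`). When only geometry is
  known, an exponential distance→density surrogate
  (`fit_distance_density()`) bridges from d(O···C) to ρ×100.
- **Ensemble analysis** — per-residue-pair O(i)···C(i+1) distance
  distributions over conformational ensembles (narrow for helical, broad
  for disordered states) and average-linkage hierarchical clustering of
  frames on best-fit Cα/Cβ RMSD with an ε merge threshold
  (`distance_distributions()`, `cluster_frames()`).
- **Synthetic ensembles** — an internal-coordinate (NeRF) backbone builder
  with Gaussian dihedral noise, producing ideal α-helices and
  disordered ensembles for testing and method exploration
  (`helix_spec()`, `build_ensemble()`).

Reference tables of model-complex energies/densities and peptide TtB
records (ATSP, p53, pDIQ clusters and the ATSP crystal structure 4N5T)
are bundled (`ttb_model_complexes()`, `ttb_peptide_contacts()`); they are
consumed as transcribed literature values, never recomputed.

## Worked example

```r
library(ttbscan)

# 1. Calibrate: energy vs density over model complexes 2-6
cal <- default_calibration()
cal
#> ttb_calibration: dE = -5.4651 * rho100 + 1.7919  (n = 5, r = -0.9641)
#>   tetrel-bond share of predicted energy: 0.50

# 2. A contact with rho x 100 = 0.77 (the ATSP TRP-ALA cluster contact):
estimate_ttb_energy(0.77, cal)
#>   rho100_used   dE_line   dE_ttb
#> 1        0.77 -2.416279 -1.20814
```

The full line value (−2.42 kcal/mol) is halved to −1.21, reported as
**−1.2 kcal/mol** — the tetrel-bond share after ancillary contacts are
discounted.

```r
# 3. Scan an ideal 12-residue alpha-helix built from internal coordinates
fr <- build_backbone(helix_spec(n_residues = 12))
ct <- annotate_energies(detect_contacts(fr))
cat(write_contacts(head(ct, 3), "tsv"))
#> chain_i res_i name_i chain_j res_j name_j d_OC  theta  separation rho_est dE_est
#> A       1     ALA    A       2     ALA    2.888 99.297 1          1.13    -2.2
#> A       2     ALA    A       3     ALA    2.888 99.297 1          1.13    -2.2
#> A       3     ALA    A       4     ALA    2.888 99.297 1          1.13    -2.2
```

Every consecutive pair of the ideal helix makes a contact at
d(O···C) = 2.89 Å with an approach angle of 99.3°; the distance→density
surrogate (ρ×100 = 199.5·exp(−1.79·d), rank correlation 0.96 against the
tabulated densities) assigns ρ×100 ≈ 1.13, which the calibration maps to
an estimated TtB energy of −2.2 kcal/mol per contact.

A shell entry point wraps the same pipeline:

```sh
inst/exec/ttbscan scan structure.pdb --cutoff 3.6 --out contacts.tsv
inst/exec/ttbscan estimate --rho 0.77
inst/exec/ttbscan simulate --out helix.pdb --n_residues 12 --n_frames 50 --noise_sigma 5
inst/exec/ttbscan ensemble helix.pdb --epsilon 2
```

## Limitations

- Energies are interpolations on a five-point calibration of small model
  complexes; they inherit its scatter (±0.1–0.2 kcal/mol) and say nothing
  about cooperativity beyond the fitted range.
- The package estimates densities geometrically; it never computes
  wavefunctions, QTAIM critical points or NCI isosurfaces.
- Synthetic ensembles use Gaussian dihedral noise — a deliberately simple,
  non-physical stand-in for real conformational sampling (see the methods
  vignette).
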