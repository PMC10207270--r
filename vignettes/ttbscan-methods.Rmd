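---
title: "Methods: detecting and scoring backbone C=O···C=O tetrel bonds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and scoring backbone C=O···C=O tetrel bonds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttbscan)
```

## The interaction and the model

A backbone carbonyl oxygen can donate lone-pair density into the π\*
orbital of a neighbouring carbonyl carbon. Viewed through electrostatics
this is a tetrel bond: the carbonyl carbon exposes a π-hole above the
molecular plane, and a Lewis base (here another carbonyl oxygen)
approaches it along a trajectory close to the Bürgi–Dunitz angle (~107°).
In α-helices this O(i)→C(i+1) arrangement recurs at every consecutive
residue pair, and its strength — fractions of a kcal/mol to a few
kcal/mol per contact — makes it a plausible complementary stabilizer of
helical conformations alongside the canonical i→i+4 hydrogen bonds.

`ttbscan` treats the problem in three decoupled stages:

1. **Geometry** — find O···C contacts in coordinates.
2. **Density** — assign each contact an electron-density measure ρ×100
   (a.u.), either taken from tabulated reference values or estimated from
   the O···C distance.
3. **Energy** — map density to interaction energy through a linear
   calibration fitted on small model complexes, and attribute half of the
   result to the tetrel bond proper.

The stages are independently testable and independently replaceable;
nothing downstream of stage 1 requires a wavefunction.

## Detection geometry and its parameters

`detect_contacts()` accepts an ordered (donor, acceptor) carbonyl pair
when

- d(O_donor···C_acceptor) ≤ `cutoff` (default **3.6 Å**), and
- θ = ∠(O_donor···C_acceptor=O_acceptor) lies in `angle_window`
  (default **[95°, 125°]**), and
- the residues are at least `min_separation` apart in sequence
  (default 1; inter-chain pairs always pass the separation test).

The cutoff sits slightly above the longest tabulated backbone tetrel-bond
distance (3.376 Å) and near the O/C van-der-Waals sum, so every bundled
reference contact passes while unrelated carbonyl pairs rarely do. The
angle window brackets the Bürgi–Dunitz trajectory; reference tables for
this interaction print no angle criterion, so the window is deliberately
exposed as configuration and θ is reported per contact rather than
silently filtered deep in the pipeline. On an ideal α-helix the
consecutive-pair approach angle computes to ≈99°, comfortably inside the
window. Degenerate geometry (donor O exactly on the acceptor C=O axis) is
handled by clamping the cosine, yielding θ = 0°/180° without
division-by-zero.

Both donation directions are examined; the sign of `separation`
(acceptor index − donor index) records which way the contact points, with
+1 the canonical helical direction.

## The density→energy calibration

`fit_calibration()` is ordinary least squares of ΔE (kcal/mol) on ρ×100
over the bundled model complexes **2–6** — five bimolecular complexes of
a cyclic amide with small Lewis bases, each characterized by a
counterpoise-corrected interaction energy and the density at the
tetrel-bond critical point. Complexes 8–12 (the variants pre-organized by
a bifurcated hydrogen bond to urea) are deliberately held out: they probe
a charge-withdrawn carbonyl and serve as an out-of-sample consistency
check (pairwise stronger binding than their 2–6 counterparts), and
complex 12 — the only case where tetrel and ancillary densities diverge
strongly — is excluded from fitting altogether. On the bundled table the
fit gives slope ≈ −5.47 kcal/mol per ρ×100 unit, intercept ≈ +1.79
kcal/mol, r ≈ −0.96. The Pearson r is reported exactly as computed from
the 1–2-decimal transcribed values and is not forced to match any rounder
summary of the same data.

**Half-energy ancillary partition.** Each model complex binds through the
tetrel bond *and* through ancillary contacts (LP−π, π–π, CH−π) whose
critical-point densities are similar in magnitude to the tetrel-bond
density. Using the raw line as a TtB predictor would therefore
overestimate the interaction. The package adopts the rough but
transparent partition that half of the predicted energy belongs to the
tetrel bond: `dE_ttb = ancillary_fraction × (slope·ρ100 + intercept)`
with `ancillary_fraction = 0.5` by default and configurable per model.
The factor is applied **multiplicatively to the predicted energy**, not
to the input density — the variant that reproduces the tabulated peptide
energies arithmetically — and estimates are rounded only at report time,
to 1 decimal, half away from zero (base R's round-half-to-even would
disagree on exact ties such as −1.755).

Densities outside [0.2, 3.0]×100 a.u. trigger an extrapolation warning
rather than an error: the calibration and the peptide data jointly span
roughly 0.5–1.6, and a warning keeps exploratory use possible while
flagging that the line has no support out there.

## Distance→density surrogate

When only geometry is available, `fit_distance_density()` supplies
ρ×100 ≈ A·exp(−B·d), fitted by nonlinear least squares to the 21 paired
(d, ρ×100) records of the ATSP/p53/pDIQ ensemble clusters. The
exponential form mirrors the near-exponential decay of electron density
with internuclear separation; it is a surrogate, not a physical claim,
and the model records a Spearman rank-correlation self-check (0.96 on
the bundled records) so a silently broken fit is visible. Numerical
choices: starting values come from the log-linear fit; when that start
already interpolates the data (noise-free input, a zero-residual problem
Gauss–Newton handles poorly) it is returned directly; fewer than 5
points, constant distances, or non-decaying fitted parameters are hard
errors.

A second, purely geometric surrogate, `estimate_density_promolecular()`,
sums single-exponential atomic densities ρ_el(r) = A_el·exp(−r/B_el)
over supplied atoms and returns the minimum along the O···C segment —
the saddle-like point between the carbonyls, in the spirit of
promolecular NCI analysis. The per-element constants are a fixed,
documented fixture of this package; only ranks across contacts are
meaningful, and the tests assert exactly that (rank agreement > 0.8 with
tabulated densities at the tabulated distances).

## Ensemble analysis

`distance_distributions()` counts **each frame with identical weight** —
no ensemble reweighting — and summarizes each consecutive pair by median,
IQR and `narrowness = IQR/median`. Narrowness is the dimensionless
contrast statistic: helical ensembles concentrate O(i)···C(i+1) near
2.9 Å (small narrowness) while disordered ensembles spread over several
Å. Pairs missing from a frame are recorded as absent, never as zero.

`cluster_frames()` performs agglomerative **average-linkage** clustering
on pairwise best-fit RMSDs, cutting the tree at height ε (default
**2 Å**). "Hierarchical clustering with an ε stop" does not pin down a
linkage, so the linkage is exposed in the interface; average linkage is
the common trajectory-analysis default and behaves monotonically in ε
(cluster count non-increasing, single cluster as ε→∞ — both asserted as
properties). Clusters are numbered by decreasing population, so
"cluster 1" is always the most populated; centroids are the member
minimizing summed RMSD to co-members. The RMSD kernel is Kabsch
superposition (via bio3d, reflection-guarded); the atom selection is
Cα+Cβ, falling back to Cα with a warning when no Cβ atoms exist —
synthetic backbones and glycine-rich chains would otherwise be
unclusterable.

## What the synthetic generator does and does not emulate

`build_backbone()` constructs chains by natural extension (NeRF) from
fixed covalent geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
C=O 1.231 Å, standard bond angles) and per-residue (φ, ψ) dihedrals.
Defaults φ = −57°, ψ = −47°, ω = 180° give an ideal right-handed α-helix
(rise ≈ 1.55 Å/residue, ≈3.6 residues/turn, consecutive O···C ≈ 2.89 Å).
`build_ensemble()` draws independent frames with Gaussian dihedral noise
of standard deviation `noise_sigma`; per-frame seeds derive from the
master seed through a SplitMix-style integer mixer, so ensembles are
bit-reproducible and extensible without disturbing existing frames.

The generator emulates exactly two features of real ensembles: (i)
near-ideal helical backbones whose consecutive O(i)···C(i+1) distances
fall in the tetrel-bonding band, and (ii) the narrow-versus-broad
distance-distribution contrast between folded and disordered states
(σ = 5° versus σ = 40° in the tests). It does **not** emulate
Ramachandran-basin structure, side chains, sterics (frames can
self-intersect at high σ), solvent, or temperature ladders. Passing
ensemble tests therefore demonstrates the analysis code's behaviour on
controlled input, not force-field realism.

## Problem sizes and numerical conventions

The test suite runs ensembles of 200 frames × 10–12 residues for the
helix/coil contrast, 50-carbonyl frames for the brute-force detection
oracle, 12 frames for clustering properties, and 200 replicates × 20
points for calibration parameter recovery — sizes chosen so each
property is decisively exercised while the whole suite runs in seconds.
Other conventions: coordinates are orthogonal ångströms with no symmetry
expansion; author residue numbering is preserved verbatim; alternate
locations keep the highest-occupancy conformer (ties by altloc letter);
residues are admitted by having atoms named C and O, not by residue name,
so non-natural amino acids pass and only waters and monoatomic ions are
excluded by name. Side-chain carbonyls (ASN/GLN/GLU amide and carboxyl
groups) are **not** extracted: the backbone-only default reflects the
helical n→π\* question the package targets, and reference distance
distributions for this interaction are backbone-consecutive; the
limitation is deliberate and documented rather than configurable.

## Known limitations

- The calibration has five points; its ±0.1–0.2 kcal/mol scatter is the
  floor on the accuracy of any estimate, and the half-energy partition is
  a stated approximation, not a derived quantity.
- The distance→density surrogate collapses all chemical context into
  d(O···C); two contacts at equal distance but different environments get
  equal densities.
- Multi-model PDB parsing assumes a shared atom roster across models (the
  NMR/ensemble convention); heterogeneous rosters are handled only via
  the shared-roster intersection with a warning.
- mmCIF, trajectory binary formats, hydrogen placement and symmetry mates
  are out of scope.
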