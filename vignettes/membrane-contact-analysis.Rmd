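---
title: "Per-residue lipid contact analysis for coarse-grained membrane trajectories"
author: "memcontact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-residue lipid contact analysis for coarse-grained membrane trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcontact)
```

## Scope and model

memcontact post-processes coarse-grained (CG, Martini-style) trajectories of
a peripheral membrane protein — the motivating system is the pleckstrin
homology (PH) domain, a ~120-residue β-barrel that recognises
phosphoinositide (PIP) headgroups on the cytosolic face of membranes —
diffusing over a planar bilayer. The package does not run dynamics. It
consumes bead coordinates plus a topology table that states, for every bead,
which protein residue or lipid molecule it belongs to, the lipid species
(POPC, POPE, POPS, the PIPs POP2/POP3, cholesterol) and the bead class
(backbone/sidechain, lipid headgroup, tail, or the PO4 linker phosphate).
All group membership is explicit in this sidecar table, the way GROMACS
index groups make selections explicit: nothing is ever inferred from bead
names at analysis time (the annotated-GRO reader classifies through a fixed
name table and errors on unknown names).

Five analyses are built on that representation:

1. **Contact fingerprints.** A contact is a binary event per (residue,
   lipid group, frame): one contact is counted at a residue for every frame
   in which any bead of the group lies within the cutoff (default 0.55 nm)
   of any bead of that residue, under the minimum-image convention in all
   three dimensions. Multiple lipids simultaneously within the cutoff still
   count once (a per-molecule multiplicity analysis is intentionally out of
   scope). Counts are totalled across replicates and normalized per group
   by the maximum residue count, so the top-contact residue scores exactly
   1 and an all-zero group stays all-zero with its normalizer flagged.
2. **Segment statistics.** Residues are assigned to the 14 conserved PH
   segments (β1–β7, the six connecting loops, the C-terminal helix) from a
   STRIDE-format record: the seven longest strand runs in sequence order
   become β1–β7, intervening residues become the loop between their
   flanking strands, residues before β1 map to β1 and everything after β7
   to α-C, which automatically folds short structured insertions into the
   surrounding loop. Declarative overrides (residue range → segment) are
   applied last and logged, so manual corrections leave an audit trail
   instead of mutating files. Family-wide frequencies divide summed
   contacts by the residue count of each segment (or by occurrences of
   each amino-acid type), and the threshold table marks, per domain, every
   segment containing a residue at or above a normalized threshold
   (default 0.8).
3. **Orientation.** Per frame, the signed z-distance between the protein
   and membrane geometric centres (minimum-image along z), and the Rzz
   element of the least-squares (Kabsch) rotation from a reference
   orientation fitted on backbone beads, with a reflection guard forcing a
   proper rotation. Membrane symmetry is handled exactly as a leaflet-swap
   correction: Rzz is multiplied by −1 whenever the z-distance is
   negative. The distance–rotation density matrix is the 2D histogram of
   |z-distance| × corrected Rzz (default 50 × 50 bins over 0–8 nm and
   −1–1); out-of-range records are clamped into edge bins and reported.
4. **PIP association.** Per frame, the number of distinct POP2/POP3
   molecules whose PO4 linker bead lies within 0.65 nm of any protein
   bead; the cutoff is wider than the contact cutoff because the linker
   phosphate sits below the headgroup. Replicate mean ± SD is reported on
   a shared time grid.
5. **Lipid RDFs.** A lateral (xy-plane) radial distribution of a species'
   headgroup beads in the bound leaflet around the protein's lateral
   centre, restricted to membrane-bound frames and normalized by the
   species' mean areal density so uniform placement gives g(r) ≈ 1.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| contact cutoff | 0.55 | nm | bead-bead contact distance (5.5 Å) |
| association cutoff | 0.65 | nm | PO4-to-protein association distance |
| window fraction | 0.2 | — | trailing fraction of frames analysed (the final 200 ns of a 1 μs run) |
| threshold | 0.8 | — | normalized-contact level marking a "substantial" residue; applied as ≥ |
| binding distance | 4.5 | nm | \|z-distance\| below which a frame counts as membrane-bound |
| density bins | 50 × 50 | — | distance–rotation histogram resolution |
| RDF extent / bin | 6 / 0.25 | nm | lateral RDF range and resolution |

Two of these deserve comment. The 0.8 rule is implemented as ≥ 0.8 rather
than strictly greater: normalization guarantees the argmax residue scores
exactly 1.0, and with ≥ the segment holding the primary site is always
marked, which matches how the statistic is meant to read. The 4.5 nm
binding criterion is a stand-in (membrane half-thickness plus protein
radius); it is configurable and should be checked against the z-distance
trace on any new system.

## The synthetic generator and its planted truth

Because μs-scale CG trajectories cannot be regenerated at desk scale, every
stage is validated against a deterministic generator whose defaults *are*
the study conditions: 20 replicates of 1000 frames at 1 ns spacing, a
120-residue rigid bead protein over a 16.5 × 16.5 nm symmetric bilayer
(box height 20.5 nm) of 10% POPC / 40% POPE / 15% POPS / 7% PIP2 / 3% PIP3
/ 25% cholesterol at 0.64 nm² per lipid, an approach phase covering the
first fifth of each run with the protein detached (z-distance ≥ 6 nm,
fresh random orientation per frame), then a bound phase with planted
structure:

* **hotspots** — lipid placement probability is multiplied by
  `hotspot_bias` (default 10) within reach of a designated residue set
  (default: the β1-β2 loop, the canonical PIP-binding loop);
* **orientation** — the bound tilt is drawn around `acos(bound_Rzz)`
  (default Rzz 0.9) with angular noise (0.1 rad), the hotspot loop facing
  the bilayer; each replicate adds a fixed tilt-azimuth jitter
  (`replicate_tilt_jitter`, 0.25 rad) so that which non-hotspot residues
  graze the surface varies across replicates — this is the heterogeneity
  that convergence analysis averages out, and without it replicate
  profiles are statistically identical;
* **PIP enrichment** — POP2/POP3 placement probability is multiplied by
  `pip_enrichment_factor` (default 3) within `pip_enrichment_radius`
  (1.5 nm) of the protein's lateral centre.

Lipids are *resampled* every frame from this known spatial mixture rather
than integrated with forces: the analysis stack consumes frames, not
dynamics, and resampling keeps the ground truth analytic. With all biases
set to 1 the generator is an exchangeable null — the bound pose then picks
a uniform tilt azimuth per replicate and anchors on whatever beads end up
lowest, so no residue is geometrically privileged.

What the generator does **not** emulate: lipid diffusion and correlated
motion (frames are independent), protein internal dynamics (the scaffold
is rigid, standing in for an elastic-network-restrained CG protein),
cholesterol flip-flop, electrostatics, and any force field. Passing the
planted-truth tests therefore demonstrates that the *analysis* recovers
known structure from data with the right statistical shape; it says
nothing about the physics of any real system. One visible consequence of
the geometric stand-in: cholesterol and tail beads sit too deep to reach
the 0.55 nm cutoff, so their contact columns are legitimately zero on
synthetic data.

Determinism: replicate r is generated under seed `truth$seed + r`, so a
single root seed fixes every file byte and any replicate can be
regenerated in isolation. Synthetic families derive domain seeds as
`seed + 1000·d` and plant memberships as deterministic rounded counts
(e.g. 34 of 40 domains with a β1-β2 primary site for a planted fraction
0.85), so family-statistic recovery tests the analysis, not membership
sampling.

## Numerical choices

* **Neighbour search.** Contact counting uses a cell list over lipid beads
  (C++), falling back to an exact all-pairs sweep when the box is smaller
  than three cells per axis; both paths are contractually identical to the
  brute-force oracle kept in the test suite, which checks equality (not
  approximate agreement) on random systems with wrapped coordinates.
* **Minimum image.** Orthorhombic boxes only; triclinic input is an
  explicit unsupported-feature error. Component-wise wrapping is the exact
  minimum over images for orthorhombic boxes.
* **Centering.** All protein/membrane centres are geometric: the topology
  deliberately carries no masses, so a centre-of-mass option would be
  false precision. Entities are assumed whole (not split across the
  boundary), as after trajectory centering.
* **Rotation fit.** Kabsch via SVD with the determinant forced to +1;
  configurations whose second singular value vanishes (collinear beads)
  raise a degeneracy error rather than returning an arbitrary rotation.
  Under coordinate noise σ the fitted rotation deviates from the applied
  one at first order (about σ/√(Σr²) radians, ~5×10⁻⁴ for the default
  scaffold at σ = 0.01 nm); tests assert exact recovery to 10⁻⁶ without
  noise and the first-order bound with noise, since no estimator can beat
  noise propagation.
* **Leaflet symmetry.** The corrected density matrix is invariant under
  the *physical* leaflet swap — a 180° rotation about an in-plane axis,
  which negates z-distance and Rzz exactly and leaves bin counts bitwise
  identical. A bare z reflection is not used for this check: it produces
  the protein's enantiomer, and the best-fit proper rotation of an
  enantiomer is not sign-related to the original Rzz.
* **Orientation density axes.** Absolute z-distance is plotted after the
  sign has been consumed by the symmetry correction; whether to plot
  signed or absolute distance is a genuine convention choice, and absolute
  is the one under which the leaflet-swap invariance is exact.
* **RDF convention.** Lateral (2D) about the protein's lateral centre,
  bound-leaflet beads only, annulus-area normalization against the mean
  areal density; this is the convention under which "PIP clustering around
  the protein" is the measured quantity on a planar membrane. A 3D
  spherical mode is provided for comparison. `r_max` may not exceed half
  the smaller lateral box length (annulus areas would be wrong beyond).
* **Ties and degenerate inputs.** Normalization maps all max-tied residues
  to 1.0; all-zero groups divide by nothing and stay zero; an empty
  analysis window, a group selecting zero beads, missing PO4 beads, and
  fewer than seven detectable strands are all explicit validation errors
  or warnings, never silent results.

## Problem sizes used in the tests

The test suite and the acceptance script regenerate everything they
measure. The planted-recovery checks run a 10-domain family at the full
replicate design (20 × 1000 frames per domain); the family-fraction check
runs 40 domains at 4 × 300 frames each, which is ample because per-domain
detection is near-deterministic at hotspot bias 10; RDF flatness is
checked at ≥10⁴ lipid observations. These sizes are the package's choice
of a thorough-but-quick default; all of them scale up by changing the
`synthetic_run_spec`.

## Known limitations

* Binary per-group contacts cannot distinguish one from several lipids of
  a group at a residue in the same frame; the PIP association count (per
  molecule) covers the multivalent question instead.
* Replicates that never bind the membrane contribute their (empty)
  final-window frames to contact totals; with real data, inspect the
  z-distance traces and drop non-binding replicates explicitly if that is
  the intended protocol.
* The segment assigner reconstructs an automatic version of what is, for
  real families, partly a manual curation step; the override mechanism is
  the escape hatch and keeps the audit trail.
* XTC/TRR binary trajectories, PDB trajectories, velocities and triclinic
  boxes are out of scope; convert upstream.
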