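# memcontact

Per-residue lipid contact analysis for coarse-grained membrane
trajectories, built around the way pleckstrin homology (PH) domains
recognise phosphoinositide (PIP) lipids.

Peripheral membrane proteins such as PH domains — ~120-residue β-barrels
of seven strands capped by a C-terminal helix — bind the cytosolic leaflet
through contacts between basic residues and anionic lipid headgroups,
above all PIP2 and PIP3. Microsecond-scale coarse-grained (Martini-style)
simulations are the standard way to map those binding sites, but the
trajectories themselves are only half the work: the science lives in the
post-processing — which residues touch which lipids, how that distributes
over the conserved fold, how the protein sits on the membrane, and whether
PIPs cluster around it. memcontact is that post-processing stack, as a
tested R package, together with a synthetic trajectory generator with
planted ground truth so every stage can be verified by recovery rather
than by eye.

## What it computes

* **Contact fingerprints** — a contact is binary per (residue, lipid
  group, frame): counted when any bead of the group is within 0.55 nm
  (minimum image) of any bead of the residue. With counts `c_r` totalled
  over replicates, the normalized fingerprint is
  `n_r = c_r / max_s c_s` per lipid group, so the top residue scores 1.
  The eight canonical groups are the five phospholipid headgroups, all
  cholesterol particles, the combined PIP headgroups, and all lipid tails.
* **Segment statistics** — residues map to the 14 conserved PH segments
  (β1…β7, six loops, α-C) from STRIDE records; per-segment frequency is
  summed contacts over summed residue counts, and the threshold table
  marks each segment holding a residue with `n_r ≥ 0.8`, the basis for
  family-wide statements like "the β1-β2 region carries the primary PIP
  site in X% of domains".
* **Orientation** — signed protein–membrane z-distance and the Rzz element
  of the least-squares (Kabsch) rotation from a reference orientation;
  Rzz is multiplied by −1 when the z-distance is negative (leaflet
  symmetry), and the distance–rotation density matrix is the 2D histogram
  of |z| × corrected Rzz whose mode is the preferred bound pose.
* **PIP association** — per-frame count of distinct PIP molecules whose
  PO4 linker phosphate lies within 0.65 nm of the protein, with replicate
  mean ± SD: the multivalency readout.
* **Lipid RDFs** — lateral g(r) of each species around the bound protein,
  normalized so uniform placement gives 1: the clustering readout.
* **Synthetic data** — a deterministic generator producing replicate sets
  (default: 20 × 1000-frame runs over a 16.5 × 16.5 nm bilayer of 10%
  POPC / 40% POPE / 15% POPS / 7% PIP2 / 3% PIP3 / 25% cholesterol) with
  planted contact hotspots, a planted bound orientation and planted PIP
  enrichment, plus an exchangeable null when all biases are 1.

## Worked example

Generate five replicates of a synthetic PH-like domain with hotspots
planted in the β1-β2 loop (residues 10–18 here), then recover them:

```r
library(memcontact)
spec <- synthetic_run_spec(n_replicates = 5, n_frames = 400,
                           truth = planted_truth(bound_from_frame = 80,
                                                 seed = 11))
sys <- synthetic_system(spec)
sys
#> synthetic_system: 233 protein beads ( 120 residues ), 2212 lipid beads;
#>   9 hotspot residues in beta1-beta2

mats <- lapply(1:5, function(r)
  residue_group_contacts(generate_replicate(sys, r), sys$topology,
                         replicate_id = r))
norm <- normalize_contacts(aggregate_replicates(mats))
head(sort(norm$values[, "PIP_head"], decreasing = TRUE), 8)
#>     11     12     13     14     15     16     10     17
#> 1.0000 1.0000 1.0000 1.0000 1.0000 1.0000 0.9975 0.9975
```

The top normalized combined-PIP contacts all fall on the planted hotspot
residues (the β1-β2 loop spans residues 10–18 in this scaffold). The
segment-level summary reads the same result as a family statistic:

```r
segments <- assign_segments(data.frame(
  residue_index = seq_along(sys$protein$segments),
  residue_name  = sys$protein$sequence, chain = "A",
  pdb_number    = seq_along(sys$protein$segments),
  state         = sys$protein$states))
threshold_table(norm, segments)
#> threshold_table: 1 domains x 14 segments, threshold 0.8
#>   beta1/beta1-beta2/beta2 primary site: 100.0% of domains
```

The same analyses run file-based (GRO trajectories + TSV topology + STRIDE
records) through `run_pipeline()` or the `exec/memcontact` command-line
driver, which write TSV tables and a JSON manifest with hashes of every
output; identical configuration and seed reproduce identical bytes.

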