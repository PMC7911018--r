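---
title: "Humanizing nanobodies by CDR grafting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Humanizing nanobodies by CDR grafting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhhumanize)
```

## The problem

Camelid heavy-chain-only antibodies contribute a single variable domain
(VHH, nanobody) that binds antigen autonomously. For in-vivo use a VHH
should read as human as possible, but the positions that most distinguish a
VHH from a human VH — the framework-2 hallmark tetrad at conventional
positions 37/44/45/47, FERF in camelids versus VGLW in humans — are also
load-bearing for stability: the FW2 face they sit on is the surface that,
in a conventional antibody, packs against the light chain. Mutating the
tetrad, or grafting CDR loops onto a humanized scaffold, can expose
hydrophobic surface and turn a well-behaved binder into an
aggregation-prone one.

This package implements the computational side of that humanization
workflow: construct the candidate sequences, account for every difference
between them, and predict the structural consequences — solubility
hotspots, contact rewiring, and the conformational heterogeneity of the
candidates' ensembles.

## Sequence layer

### Numbering and regions

Numbering is a simplified, configurable scheme: region boundaries live in
a shipped TSV (`default_scheme()`), not in code. The default intervals are
FW1 1–25, CDR1 26–32, FW2 33–51, CDR2 52–56, FW3 57–94, CDR3 95–102, FW4
103–113. These Chothia-flavoured loop boundaries were chosen so that every
position the field's humanization literature names lands in the region it
is named for: the hallmark tetrad and the fingerprint positions 35 and 50
in FW2, fingerprints 89 and 91 in FW3, position 102 at the CDR3 C-terminus
and the conserved tryptophan slot 103 at the start of FW4. Strict Kabat
intervals would place 35 in CDR1 and 50 in CDR2 and could not reproduce
that accounting; the boundary table is data, so other conventions can be
swapped in without code changes.

Three anchoring rules matter for the bookkeeping downstream:

* FW2 and FW3 are fixed-length; a sequence that cannot fill them fails
  with an error naming the first unanchorable region.
* FW1 and FW4 are right-anchored. A scaffold whose FW4 is one residue
  short therefore simply lacks scheme position 103 — which is exactly how
  a missing FW4-start tryptophan should appear in a position-aligned
  comparison.
* CDR loops fill from their N-terminal boundary; loops longer than their
  slot range receive insertion codes (`100A`, `100B`, …) at a per-loop
  anchor. Insertion codes occur only inside loops.

A raw string does not determine its own loop segmentation, so non-default
loop lengths are passed explicitly (`region_lengths`); the synthetic
generator always emits them alongside its sequences.

### Differences, mutations, grafts

All comparisons are position-wise under the scheme — never by
gap-optimizing alignment. `diff_sequences(a, b)` returns the exact
`mutation_set` that rebuilds `a` from `b` (substitutions, insertions,
deletions), each substitution labeled with its region and its
species-fingerprint class (human-type / llama-type / unclassified) from a
versioned reference table. `apply_mutations()` refuses stale recipes: a
substitution whose `from` residue no longer matches fails, so applying a
set twice is impossible, and `invert_mutations()` restores the original
byte-for-byte. `graft_cdrs()` rebuilds the chimera from the acceptor's
four frameworks and the donor's three loops, renumbers it from scratch and
records per-residue provenance.

### The synthetic reference panel

The package ships a deterministic seven-construct panel
(`vhh_reference_panel()`): a camelid-hallmark donor `A10`, a
human-hallmark acceptor `C8WT`, the acceptor's fully humanized (`C8H`) and
hallmark-camelized (`C8VI`) mutants, the plain graft `A10C`, and two
intermediate chimeras `A10VI` and `A10-HLL`. All sequences are synthetic
stand-ins — no public sequence database entry is reproduced — constructed
so the panel's difference accounting has exact known ground truth: the
donor and acceptor frameworks differ at 14 positions (7 human-type and 7
llama-type fingerprints) plus a Trp insertion at the FW4 start; `A10VI`
differs from `A10` by 4 substitutions (11, 35, 78, 89) and the deletion of
Tyr102; `A10-HLL` differs from `A10C` by 8 substitutions and from `A10VI`
by 4.

One bookkeeping subtlety is worth recording. `A10C` is the pure graft, so
it inherits the donor's full CDR3 (including position 102) and the
acceptor's FW4 (no 103). `A10VI`, by contrast, is defined by its mutation
recipe — four framework substitutions plus the deletion of 102 — rather
than as a second pure graft: a single CDR3 boundary cannot simultaneously
give a graft that keeps the donor's Trp103 and drops its Tyr102. Treating
the intermediate constructs as audited `mutation_set`s (which is how such
genes are actually ordered) keeps every printed count consistent, and the
panel's diffs then satisfy a clean partition: the substitution sets of
(`A10-HLL` vs `A10VI`) and (`A10-HLL` vs `A10C`) are disjoint and their
union is exactly (`A10VI` vs `A10C`), 4 + 8 = 12 positions.

```{r panel}
pan <- vhh_reference_panel()
diff_sequences(pan$A10, pan$C8WT, scope = paste0("FW", 1:4))
```

## Structure layer

Structures are consumed, not generated: the package reads (multi-model)
PDB files into one-conformation `vhh_structure` or N-conformation
`conformation_ensemble` containers and operates on distances and exposure
only.

### Solvent accessibility

SASA is Shrake–Rupley with a deterministic golden-spiral point set:
960 points per atom, probe 1.4 Å, element-based van der Waals radii
(C 1.70, N 1.55, O 1.52, S 1.80 Å). Relative SASA divides by a reference:
the tabulated theoretical residue maxima for all-atom structures, or the
residue's own isolated area (`reference = "isolated"`) for the package's
pseudo-atom fixtures, clipped to [0, 1.5]. The exposure threshold used
everywhere (hotspot membership, patch weighting, hydrophobic-surface
analysis) is relative SASA ≥ 0.25. A note on numerics: translation leaves
the sampled areas exactly unchanged, but rotation re-samples which sphere
points are occluded, so rotational invariance holds only to sampling
accuracy (about 1–3% at 960 points); tests assert it at that tolerance,
and the two-sphere analytic cap area pins the absolute error at < 2%.

### Solubility surrogate and structural correction

Per-residue intrinsic solubility is a documented surrogate scorer: the
negative of Kyte–Doolittle hydropathy, plus half the magnitude of the
Henderson–Hasselbalch side-chain charge at the configured pH (charge
promotes solubility; pH enters only here, default 7), minus half the
centered Chou–Fasman β-sheet propensity; smoothed over a centered
7-residue window and z-scaled per sequence. Negative means poorly
soluble. The surrogate is deliberately simple — the package's
contribution is everything built on top of a per-residue score, which is
scorer-agnostic — and every report labels its numbers
`surrogate-intrinsic` so they cannot be confused with any external
predictor's scale. Externally computed profiles can be imported from TSV
(`read_profile_tsv()`, labeled `external`) and flow through identically.

The structural correction averages intrinsic scores over a spatial patch:
for residue *i*, all residues whose side-chain centroids lie within the
patch radius (default 10 Å, the maximum interaction distance between
residues in space) contribute, weighted 1 if exposed and 0.2 if buried.
Buried residues receive a corrected score but are excluded from hotspot
membership. A uniform profile passes through unchanged whatever the
geometry — the correction redistributes, it does not invent signal.

### Hotspots

Aggregation hotspots are nucleated by the poorest-solubility residues:
seeds are residues with corrected score below −1 on the z scale (the
"poorest residues" rule is a threshold choice and is configurable,
including to intrinsic scores). Members are the solvent-exposed residues
whose side chains lie within the hotspot distance (default 6 Å, minimum
side-chain heavy-atom distance, CA for glycine) of at least one seed;
seeds whose neighborhoods share a member merge by single linkage. Each
hotspot's aggregation propensity is the plain sum of its members'
corrected scores, and hotspots are reported worst-first. Membership is
monotone in the distance cutoff, the score identity holds to machine
precision, and on small structures membership equals an exhaustive
all-pairs distance check — all three are asserted in the test suite.

### Contact maps and active residues

The residue contact rule is a convention, shipped as configuration:
any heavy-atom pair closer than 4.5 Å, excluding sequence neighbors with
|i−j| ≤ 2; over an ensemble the map entry is the fraction of
conformations in contact. The difference between a wild-type and a mutant
map is projected per residue with an L1 row sum (L2 available), and the
"most affected" residues are those above mean + 1 sd of the projection.
Active-residue nomination for docking restraints combines the exposed
hydrophobic set with the most-affected set (union by default, strict
intersection available), keeps only spatially clustered candidates (at
least one fellow candidate within 6 Å) and reports each survivor's
provenance.

### Ensemble clustering

Pairwise RMSD uses closed-form Kabsch superposition on C-alpha atoms
(reflections handled by a determinant sign correction). The clustering
cutoff defaults to the mean RMSD over all unordered conformation pairs,
and clusters are extracted greedily: the conformation with the most
neighbors within the cutoff becomes a center, it and its neighbors are
removed, repeat. Ties break to the lowest frame index — the greedy rule
itself does not specify a tie order, and a deterministic choice makes
reruns byte-identical. Cluster sizes are necessarily non-increasing in
extraction order, and for small ensembles the labels equal an exhaustive
evaluation of the greedy rule. Each cluster is represented by its center;
the overall reference conformation is the center of the largest cluster.
Frame subsampling from a trajectory is the caller's job: the module takes
any multi-model PDB.

## What the synthetic structures do and do not emulate

The structure generator builds circular CA/CB pseudo-atom chains: burial
and loop shielding are realized by occluder pseudo-atoms (residue name
`OCC`, present in every geometric computation but never in residue
reports), ensemble basins are rigid displacements of a loop segment with
isotropic Gaussian jitter, and contact rewiring moves one residue in and
out of a planted spatial cluster. Everything the pipeline's operators
consume — distances, exposure, topology — is exact and known, so every
stage is testable closed-loop: `make_basin_ensemble(proportions =
c(0.85, 0.10, 0.05))` must come back from `gromos_cluster()` as three
clusters with the top one holding 80–90% of frames, the shielded
conformation of `make_shielding_fixture()` must lose hotspot members
relative to its exposed twin, and `make_rewiring_fixture()`'s moved
residue must top the contact-difference projection.

What passing these tests does *not* show: anything about real side-chain
packing, backbone physics, or force-field-dependent conformational
preferences. The fixtures validate the operators' logic and bookkeeping,
not molecular realism; on real structures the thresholds above (exposure
0.25, contact 4.5 Å, hotspot 6 Å, patch 10 Å, seed −1) are conventions a
user should revisit per system.

## Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately modest
sizes — 200-frame ensembles of 60-residue chains for clustering, 28–40
residue toys for hotspot and contact analysis, 100 random matrices for
the clustering oracle — which keeps the full suite around ten seconds
while still exercising every code path at sizes where brute-force oracles
are exact. All randomness flows through explicit seeds (the generators
restore the caller's RNG state), and identical inputs, configuration and
seed give byte-identical outputs end to end.

## Known limitations

* The intrinsic scorer is a surrogate: its absolute numbers are on their
  own z scale and are not comparable to any published predictor's values;
  only ranking and hotspot structure should be interpreted.
* Numbering requires explicit region lengths for non-canonical loops; no
  profile-HMM assignment is attempted, and IMGT/Chothia/Martin server
  parity is out of scope.
* Hotspot seeds below the exposure threshold can nucleate only through
  exposed neighbors; a fully buried poor patch is reported as no hotspot,
  by design.
* Trajectory formats other than multi-model PDB (XTC/DCD), docking
  execution and scoring, and any thermodynamic observable (yields,
  melting temperatures, binding affinities) are outside the package's
  scope.
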