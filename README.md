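# vhhumanize

Nanobody humanization by CDR grafting, with aggregation-risk profiling of
the resulting constructs.

Camelid heavy-chain-only antibodies contribute a single variable domain
(VHH, nanobody) that binds antigen on its own. For therapeutic use a VHH
should be as human as possible, but the four framework-2 positions that
most distinguish it from a human VH — the hallmark tetrad at conventional
positions 37/44/45/47, **FERF** in camelids versus **VGLW** in humans —
sit on the surface that stabilizes the isolated domain. Mutating them, or
grafting CDR loops onto a humanized acceptor scaffold, risks exposing
hydrophobic surface and creating aggregation nuclei.

`vhhumanize` implements the computational workflow around that problem:

* **Sequence annotation** — configurable scheme numbering with
  framework/CDR segmentation, hallmark-tetrad detection
  (camelid / human / hybrid) and species-fingerprint classification of
  framework residues (`number_vhh`, `detect_hallmarks`,
  `classify_residue`).
* **Graft design** — CDR grafting onto an acceptor scaffold, auditable
  mutation sets (apply / invert / stale-detection), variant panels, and
  numbering-aligned difference accounting: `diff_sequences(a, b)` returns
  the exact substitutions, insertions and deletions that rebuild `a` from
  `b`, labeled by region and fingerprint class.
* **Solubility hotspots** — a labeled surrogate per-residue solubility
  score (hydropathy + side-chain charge at pH + β-propensity, z-scaled),
  structural correction over a 10 Å patch weighted by solvent exposure,
  and hotspot detection: solvent-exposed residues within 6 Å of the
  poorest-solubility seeds, merged by single linkage and scored as
  `H = Σ member scores` (`intrinsic_profile`, `structural_correction`,
  `detect_hotspots`). External per-residue profiles can be imported to
  replace the surrogate.
* **Structure analysis** — Shrake–Rupley SASA (960 points, probe 1.4 Å),
  exposed-hydrophobic sets, ensemble contact maps (heavy-atom < 4.5 Å,
  |i−j| > 2), per-residue contact-difference projection
  `d_i = Σ_j |wt_ij − mut_ij|`, and active-residue nomination for docking
  restraints.
* **Ensemble clustering** — pairwise Kabsch-superposed C-alpha RMSD, an
  automatic cutoff equal to the mean pairwise RMSD, and greedy
  neighbor-count (gromos) clustering with representative-conformation
  selection.
* **Synthetic fixtures with ground truth** — generators for VHH-like
  sequences with controllable hallmark/fingerprint states and for toy
  multi-model structures with planted exposure patches, shielding loops,
  contact rewiring and cluster basins, so that every stage is testable
  closed-loop.

All thresholds above are configuration (`vhh_config()`), not code, and
every run can write its fully resolved configuration next to its outputs.

## Worked example

The package ships a deterministic synthetic seven-construct reference
panel: a camelid-hallmark donor (`A10`), a human-hallmark acceptor
scaffold (`C8WT`), and the graft/mutant constructs between them.

```r
library(vhhumanize)
pan <- vhh_reference_panel()

diff_sequences(pan$A10, pan$C8WT, scope = paste0("FW", 1:4))
#> sequence_diff A10 vs C8WT: 14 substitutions, 1 insertions, 0 deletions
#>  scheme_pos from to region fingerprint
#>           1    Q  E    FW1  human-type
#>           5    Q  V    FW1  human-type
#>          11    L  V    FW1  llama-type
#>          35    Y  G    FW2  human-type
#>          37    V  F    FW2  llama-type
#>          44    G  E    FW2  llama-type
#>          45    L  R    FW2  llama-type
#>          47    W  F    FW2  llama-type
#>          50    S  A    FW2  human-type
#>          74    A  K    FW3  human-type
#>          78    L  V    FW3  llama-type
#>          83    K  R    FW3  human-type
#>          89    L  T    FW3  llama-type
#>          91    F  Y    FW3  human-type
```

The two frameworks differ at 14 positions — 7 carrying the human
fingerprint in the donor, 7 the llama one — plus one insertion (the
tryptophan opening FW4, scheme position 103). Hallmarks classify as
expected:

```r
detect_hallmarks(pan$A10)
#> hallmark tetrad 37/44/45/47: FERF -> camelid
```

A planted two-patch structure yields exactly its planted hotspots, scored
as the sum of their members' corrected solubility:

```r
fix <- make_shielding_fixture()
prof <- structural_correction(fix$exposed, fix$profile)
detect_hotspots(fix$exposed, prof)
#> hotspot_set: 2 hotspot(s)
#>   #1 score -4.680, 4 members (seeds: A:6, A:7)
#>   #2 score -4.680, 4 members (seeds: A:26, A:27)
```

(the same profile on the shielded conformation of the same chain yields no
hotspot — the loop hides the patch), and a 200-frame ensemble with basins
planted at 85/10/5% comes back from clustering at the automatic
average-RMSD cutoff as:

```r
bx <- make_basin_ensemble(seed = 1)
m <- rmsd_matrix(bx$ensemble)
gromos_cluster(m, auto_cutoff(m))
#> cluster_result: 200 frames, 3 clusters (cutoff 0.931 A)
#>   sizes: 170, 20, 10
```

A thin shell wrapper (`inst/scripts/vhhpipe.R`) exposes the same stages
as subcommands (`annotate`, `graft`, `hotspots`, `cluster`,
`contactdiff`) over FASTA/PDB files.

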