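---
title: "Methods: pocket characterization and ligand interaction profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pocket characterization and ligand interaction profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketprofiler)
```

This vignette records how the package's quantities are defined, which
parameters matter, and where genuinely open design choices were settled —
in the spirit of the methods sections of mature structural-analysis
packages.

## The object of study

The package operationalizes a ligand-binding niche ("grotto") as a
contiguous, author-numbered residue range of one polymer chain — for the
JAK kinases, the JH1-domain fragments 865–1154 (JAK1) and 842–1130
(JAK2). Working on author numbering keeps every reported residue directly
comparable with the literature (ARG879, GLY962, ...), at the cost that
gaps in the deposited model appear as *missing* numbers, which
`select_pocket()` records rather than renumbers.

Structures are read from standard PDB files. Alternate conformations are
collapsed to the highest-occupancy conformer (ties: alphabetically first
altloc) so that all downstream geometry is single-valued and
deterministic. Only the first MODEL of a multi-model file is used; the
X-ray entries in scope are single-model. Hydrogens, when present, are
ignored by every geometric operation — the criteria below are heavy-atom
criteria precisely because crystallographic inputs usually lack
hydrogens.

## Solvent-accessible surface area

`shrake_rupley()` implements the classic point-sampling SASA. Parameters:

| key | default | meaning |
|---|---|---|
| `sasa.probe` | 1.4 Å | water-sized probe radius |
| `sasa.n_points` | 960 | test points per atom |
| `sasa.radii_set` | `"chothia"` | `"chothia"` or `"bondi"` vdW radii |

The Chothia-type protein set (C 1.87/1.76 for tetrahedral/trigonal
carbons, N 1.65, O 1.40, S 1.85 Å) is the default because it was designed
for proteins; the Bondi element set is available to bracket results from
tools with generic radii. Unknown elements are an error unless a
`default_radius` is supplied — silent guessing would bias totals.

Two numerical choices matter. First, the sphere points come from a
deterministic golden-spiral construction, not random sampling, so a given
input always yields the same area. Second, the point set is expressed in
a molecule-fixed frame (principal axes of the heavy-atom cloud, signs
fixed by coordinate skewness) rather than the laboratory frame; with a
space-fixed point set the total would drift by a few parts per thousand
under rotation of the input, while in the molecule frame SASA is exactly
invariant under rigid motion. For highly symmetric point clouds the frame
is ambiguous and the code falls back to a fixed convention; such inputs do
not arise for real pockets. At 960 points the quadrature error against a
3840-point reference is below 1% on pocket-sized inputs.

SASA is computed on the pocket's atoms in isolation by default, because
the published per-fragment tables label rows by the fragment ranges.
Passing the full structure to `shrake_rupley()` instead gives the
in-context value; whether published fragment SASAs were computed in or out
of chain context is generally not stated, which is why the calibration
tolerance on the real entries is a generous 5%.

## Secondary structure

`assign_sse()` is a three-state Kabsch–Sander assignment. Backbone
hydrogen bonds use the electrostatic criterion
`E = 0.084 * 332 * (1/d(ON) + 1/d(CH) - 1/d(OH) - 1/d(CN))` kcal/mol with
a bond where `E < sse.energy_cutoff` (default −0.5). The amide hydrogen
is rebuilt 1.01 Å from N, antiparallel to the preceding residue's C=O.
Two consecutive i→i+4 bonds make a minimal helix; the standard parallel
and antiparallel ladder patterns make strands; helix takes precedence at
overlaps. Prolines never donate; residues lacking a complete N/CA/C/O
backbone, and residues following a chain break (peptide C–N > 2.5 Å),
are left as coil. Pockets of fewer than five residues are all-coil by
construction.

`group_elements()` turns the per-residue states into numbered elements
with minimum run lengths `sse.min_helix = 4` and `sse.min_strand = 2`
(conventional DSSP-style post-processing). Both are configuration keys
because published element counts depend on them. The original analyses
of the JAK pockets used STRIDE, whose dihedral-augmented criteria are not
fully published; internal counts are therefore reported *alongside*
published counts (17 helices / 13 strands for JAK1), never asserted equal,
and `load_external_sse()` ingests DSSP or STRIDE output directly when
exact reproduction of a third-party assignment is wanted (G, I, H → H;
B, E → E; else C).

## Hydrogen bonds and the contact network

`detect_hbonds()` reports donor–acceptor pairs with heavy-atom distance
≤ `hbonds.d_max` (3.5 Å) and antecedent–donor–acceptor angle ≥
`hbonds.angle_min` (90°). Donor/acceptor typing follows standard
amino-acid chemistry (backbone N donor except proline, backbone O
acceptor, side-chain N/O/S per residue templates; histidine ring
nitrogens count on both sides since protonation is unknown without
hydrogens). Backbone pairs of sequence neighbours (i, i+1) are excluded
as covalently constrained. The published pocket totals (189/198) come
from an unnamed tool with unstated criteria, so both thresholds are
configuration keys and the calibration tolerance is ±10%.

`nonpolar_contact_network()` enumerates unordered pairs of
nonpolar-classified residues at sequence separation ≥ 2 with distance
below `contacts.cutoff` (10 Å — the one distance rule the source tables
state). The distance metric is a genuine free choice, surfaced as
`contacts.metric`:

* `"centroid"` (default) — side-chain heavy-atom centroid, glycine → Cα;
* `"cb"` — Cβ–Cβ;
* `"min"` — minimum heavy-atom distance.

Centroid distances place the distribution maxima of compact pockets in
the observed 7.7–8.3 Å region, which is why they are the default. A
contact is *inside-element* iff both residues belong to the same
secondary-structure element; contacts involving coil residues count as
cross-element. The polarity table keeps glycine nonpolar (it acts as a
hydrophobic contact surface in kinase pockets) and keeps arginine charged
even though published discussion sometimes treats ARG980's aliphatic stem
as hydrophobic; the discrepancy is reported, not reconciled, and the
table is configurable.

Distance statistics use the population (not sample) standard deviation:
the contact set is the full population under study, not a sample from a
larger one.

### Mode detection

The bimodality report needs the locations of histogram maxima at a stated
bin width (0.25 Å) and smoothing factor (3). A plain 3-bin moving average
over 0.25 Å bins is provably unable to resolve two components 0.6 Å
apart with SD 0.2 Å: after coarse binning, the averaging window spans the
whole inter-peak valley and the valley bins average *above* the peak
bins, merging the maxima regardless of sample size. `distance_modes()`
therefore computes the averaged-shifted-histogram estimate at the same
two parameters — the histogram on a fine grid of `bin_width / smooth`
with the equivalent triangular weights, which is the standard debiased
form of histogram smoothing — and scans that curve for local maxima.
Maxima within one bin width of a taller one are merged (apex jitter never
splits a peak), and a maximum other than the global one needs the support
of at least two observations (isolated tail points never register).
Under the two-Gaussian reference simulation (means 7.7/8.3 Å, SD 0.2,
n = 1000) this recovers both modes within one bin across all tested
seeds, while unimodal controls stay unimodal. The coarse-binned histogram
with its plain moving average is still reported for display.

## Ligand interaction profiles

`ligand_profile()` combines three quantities:

* Hydrogen bonds in both directions (protein donor → ligand acceptor and
  ligand donor → protein acceptor) under the same geometric criteria as
  intra-pocket bonds. Ligand N/O atoms are typed from element and
  inferred connectivity (bond = heavy-atom pair < 1.8 Å); a nitrile
  nitrogen — single neighbour at under 1.25 Å — is acceptor-only, which
  is chemically required for ruxolitinib's propanenitrile even though it
  does not change the reported zero bond count.
* Hydrophobic contacts: each nonpolar pocket residue whose *minimum
  heavy-atom distance* to any ligand heavy atom is below `ligand.cutoff`
  (10 Å). The atom-level minimum (not a centroid) matches the atom-level
  nature of published interaction diagrams; a centroid variant is a
  configuration switch away. Only nonpolar-classified residues enter this
  count; polar and charged residues near the ligand are captured by the
  locus instead.
* The binding locus: the `ligand.k_locus = 4` residues of *any* class
  with the smallest minimum distance to the ligand, ties broken by
  residue number.

`interaction_sweep()` flattens a profile into one row per interaction —
the tabular stand-in for 2D interaction diagrams. Ligands are taken from
the complex's HETATM records by explicit hetero code; no docking is
performed, and deposition ambiguities (a complex deposited with one
native ligand but discussed with another) are resolved by the caller,
never guessed.

## Sequence alignment

For two pocket sequences, `align_sequences()` is Needleman–Wunsch with
BLOSUM62 and affine gaps (open 10, extend 0.5), delegated to
`Biostrings::pairwiseAlignment()`; for a two-sequence problem this is the
standard equivalent of a Clustal run, whose exact gap parameters for the
published ~54% figure are unstated — hence the ±3-point calibration
tolerance. Identity uses the shorter-sequence denominator by default;
with near-equal pocket lengths (290/289) the choice is nearly moot, but
it is fixed and documented, and `identity_percent()` exposes the
alignment-length alternative. The conservation line uses the canonical
Clustal strong and weak group tables, which are editable arguments.

## The synthetic generator

`ideal_helix()` places Cα atoms on the parameterized cylinder (radius
2.3 Å, rise 1.5 Å, twist 100°) and the backbone N/C/O at the cylindrical
offsets of the ideal φ = −57°, ψ = −47° helix (derived once from an
internal-coordinate build), so consecutive Cα–Cα distances equal the
closed form √((2r sin(t/2))² + rise²) ≈ 3.83 Å and the Kabsch–Sander
assignment recognizes the interior as helix. `ideal_strand_pair()` builds
an extended chain (φ = −139°, ψ = 135°) and its antiparallel partner by a
two-fold rotation about the sheet normal with a registry offset chosen
once (numerically) to form the alternating inter-strand ladder at the
canonical 4.8 Å separation. `toy_complex()` plants residue–residue
centroid distances, backbone N–H···O=C geometries and ligand proximities
*exactly* (construction tolerance 0.05 Å; ligand proximities by
bisection), with non-planted residues parked on a 30 Å grid far beyond
every cutoff, optional bounded Gaussian noise applied last, and all
randomness drawn from one explicit seed (identical spec + seed gives
byte-identical PDB output).

What the fixtures emulate: mixed helix/strand content, controlled
nonpolar contact geometry, controlled donor–acceptor geometry, a
cavity-adjacent hetero-group ligand, and the 7.7/8.3 Å two-component
contact-distance structure. What they do not emulate: realistic side-chain
rotamers (side chains are coarse Cβ probes), dense packing, crystal
contacts, waters, or chemically realistic ligands. Passing the planted
tests therefore demonstrates that the *measurement machinery* is exact on
known geometry; it does not by itself validate parameter choices against
real crystal structures — that is what the calibration checks against the
deposited JAK entries are for, when those files are supplied.

## Degenerate inputs and tie-breaks

One-residue pockets report zero contacts and bonds with positive SASA;
empty contact classes report n = 0 with undefined mean flagged `NA`
rather than an error; removing an absent hetero code is a no-op; locus
requests larger than the pocket return all residues with a warning.
Alignment traceback ties are resolved by the alignment engine
deterministically; contact pairs are canonicalized with the smaller
residue number first; element ids run in sequence order.

## Problem sizes and limitations

The shipped tests run on pockets of 4–25 residues, 100-fixture
planted-recovery sweeps, 1000-point mixture simulations and alignment
oracle enumerations up to length 6 — sizes chosen so the whole suite
exercises every code path in well under a minute of compute while the
brute-force oracles stay exhaustive. Known limitations: no mmCIF input,
no symmetry mates or assemblies, three-state secondary structure only
(no π/3₁₀ distinction or sheet topology), no salt-bridge/π-stacking
typing, no energy-based H-bond scoring, heavy-atom criteria only, and no
docking — binding poses must come from deposited coordinates or external
tools.
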