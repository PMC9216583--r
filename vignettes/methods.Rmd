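---
title: "Methods: contact-network conservation and alignment curation in psnalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-network conservation and alignment curation in psnalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

psnalign annotates a protein domain superfamily given two inputs the user
supplies: the members' 3D structures (PDB, one domain per file) and a
structure-based multiple sequence alignment whose record identifiers match
the structures. The alignment's residue equivalences are taken as given —
the package consumes, and never produces, the alignment. Secondary
structure is likewise consumed as per-residue H/E/C strings; no DSSP-like
assignment is performed.

## Structure cleaning

Before any geometry is computed, structures are cleaned: heteroatom
residues are dropped; GLX (ambiguous Glu/Gln) and UNK residues are
dropped; non-standard residues with an accepted parent (MSE→MET, SEC→CYS,
PYL→LYS) are mapped, any other non-standard residue is dropped; and a
residue missing any of its four backbone atoms N, Cα, C, O is dropped as
incomplete. "Incomplete" is defined on the backbone only because the
backbone set is exactly what the downstream steps require (Cα for networks
and superposition, the full quartet for well-formed PDB output); residues
with missing *side-chain* atoms are kept, since discarding them would
silently delete sequence positions the alignment refers to. Altloc policy:
the blank/'A' conformer is preferred, otherwise the highest-occupancy
copy. Cleaning is idempotent and every removal is logged.

Residue indices are 1-based positions in the cleaned sequence; alignment
columns are 1-based. The column↔residue map built when the alignment is
read (and re-validated after every curation edit) is the single source of
correspondence used by all modules.

## Contact networks

Two network levels are built per member:

- **backbone**: edge {i, j} iff d(Cα_i, Cα_j) ≤ 7.5 Å,
- **side chain**: edge iff any side-chain atom pair is within 4.5 Å,
  where side-chain atoms are all atoms *except* N, Cα, C, O. OXT is
  treated as backbone (it is chemically a main-chain atom); hydrogens, if
  present, count as side-chain atoms under the strict atom-name reading.

Both comparisons are **inclusive** (≤). "Within a distance of" admits
either reading; inclusive is the conventional one, and the boundary
behaviour (7.49/7.50/7.51 Å) is pinned by tests so the choice is explicit
rather than accidental. A `min_seq_separation` parameter (default 1,
i.e. sequence-adjacent contacts allowed) can be raised to ≥ 2: |i−i+1|
backbone contacts are geometrically guaranteed (Cα–Cα ≈ 3.8 Å) and
therefore carry no information, but the default follows the plain
definition and leaves filtering to the user.

## Conserved interactions

Each member's network is projected onto alignment columns, with dummy
nodes at gap positions; every network edge maps to exactly one column
pair. An interaction is *absolutely conserved* (an ACI) when the same
column pair carries an edge in **every** member — the strict intersection
of column edge sets. A gap at either endpoint in any member therefore
breaks conservation, which is the intended semantics: conservation is a
claim about equivalenced positions. Conservation is defined at the
column-pair level only; the residue *identities* at the endpoints need not
match (that is what the ACR/HCR residue-level calls are for). A relaxed
support fraction (< 1) is available but off by default. The
backbone-and-side-chain "common" set is the exact column-pair
intersection of the two levels.

ACI extraction is set algebra, so the implementation is checked against a
brute-force oracle (enumerate all column pairs, test membership in every
member) and against two structural properties: anti-monotonicity (adding
a member can only shrink the set) and member-order invariance.

Visualization scripts are emitted as deterministic PyMOL command files
(`.pml`), one distance object per ACI per member between the endpoint Cα
atoms — plain-text and diffable, with no dependency on PyMOL itself.

## Alignment statistics

- **ACR**: a column where all members carry the identical residue (full
  occupancy — a single gap disqualifies). **HCR**: majority-residue
  fraction in the closed-open band [0.80, 1.00), gaps counting as
  mismatches. The band edges make ACR and HCR mutually exclusive by
  construction.
- **Gap statistics**: per member, the percentage of gap characters in its
  own row ("gaps contributed" is read as own-row gaps, which is directly
  computable; an induced-gap variant would require attributing shared gap
  columns to members and is not uniquely defined).
- **Secondary-structure conservation**: a column counts as conserved when
  it is fully occupied *and* all members agree on the H/E/C state — the
  strictest reading; a majority-state variant is provided
  (`rule = "majority"`). The SS alphabet is fixed to {H, E, C}; finer
  schemes must be mapped by the caller.

## Superposition and dissimilarity

Pairwise rigid-body superposition is the closed-form Kabsch solution: SVD
of the cross-covariance of the centred point sets with the determinant
correction, so the result is always a proper rotation. Near-collinear
point sets (second singular value ≈ 0) are flagged and a best-effort
result returned. The multi-structure variant iterates
superpose-onto-consensus over the fully occupied columns until the
consensus moves < 1e-4 Å (RMS) or 100 iterations; it requires ≥ 3 fully
occupied columns.

The RMSD matrix uses **pair-specific** superposition over the columns
where both members are present, not the common consensus frame: pairwise
fitting is the less surprising definition for a dissimilarity matrix (an
entry does not change when a third member is added), and the
consensus-frame variant remains available by superposing first and
measuring afterwards. The headline "average Cα RMSD" is the mean of the
off-diagonal upper triangle. Pairs sharing < 3 columns are flagged
missing rather than guessed.

The structural dissimilarity tree is UPGMA (average-linkage
agglomeration of the RMSD matrix, ultrametric branch lengths = merge
height / 2), with members sorted lexicographically before clustering so
ties break deterministically. Agglomeration is delegated to
`stats::hclust`/`ape`; the package pins the expected behaviour with
hand-computed examples.

## Curation procedure

A superfamily qualifies for curation when it has at least 5 members, some
member contributes more than 50% gaps to its row, and conserved secondary
structure is below 30% of columns. The 30% threshold is the default; 40%
is supported as a configurable alternative since both values are in
circulation for this rule, and the choice is left explicit
(`flag_ss_percent`).

Members are clustered on three features — gap %, mean Cα RMSD to the
other members, and length — z-scored first because the units
(%, Å, residues) are incommensurate. A feature whose spread is below
1e-9 is zeroed rather than divided by a machine-noise standard deviation.
k-means uses Lloyd's algorithm with 25 random restarts under a fixed
seed (restarts substitute for a careful seeding rule; the result is
deterministic given the seed). For k above the number of distinct feature
rows, where Lloyd's algorithm is undefined, the inertia is 0 by
definition (each distinct point its own centre) and the curve stays
defined on 1..kmax.

**Elbow selection** is formalized as the maximum perpendicular distance
from the (k, inertia_k) curve — with both axes normalized to [0, 1] so
they are commensurate — to the chord joining its endpoints. If the
inertia is already 0 at k = 1, k = 1 is chosen.

**Classification** codifies the case-by-case handling: each singleton
cluster's member is tested in the fixed order giant (length > 1.5 ×
median) → dwarf (length < 0.5 × median) → structural outlier (mean RMSD
> 10 Å); if at least two clusters with ≥ 2 members remain, the
superfamily is split along them. The 10 Å structural cutoff is anchored
to the documented outlier regime; the 0.5×/1.5× length factors are
engineering defaults, all configurable.

**Actions.** Trimming a giant removes its residues in columns occupied by
at most `trim_occupancy` members (default 1: its private overhang
columns), then drops all-gap columns; removal and splitting drop rows and
then all-gap columns. After editing, the alignment is re-validated
against the (possibly trimmed) structures, and SS strings are subset in
step. Re-running an external aligner on the edited superfamily is out of
scope, so before/after statistics are computed on the edited,
column-degapped alignment; this understates the improvement a true
re-alignment could achieve, and is documented as such.

## The synthetic generator

The generator exists so every module is testable without downloads. It
emulates the *shape* of a superfamily data set — several structures of a
common fold, a consistent structure-based alignment, planted curation
scenarios — not its physics:

- Cα atoms on an ideal helix (rise 1.5 Å/residue, twist 100°/residue,
  radius 2.3 Å), chosen because the resulting contact pattern is
  realistic without real data: consecutive Cα ≈ 3.8 Å, and (i, i+3),
  (i, i+4) pairs fall inside 7.5 Å while (i, i+5) falls outside.
- One pseudo-side-chain CB atom per non-glycine residue, placed 1.2 Å
  radially outward with an alternating ±1.25 Å axial offset. The offsets
  are tuned so roughly half the (i, i+3) CB pairs sit just inside 4.5 Å:
  a purely radial CB at any modest offset leaves *all* CB pairs outside
  the cutoff on this helix, which would make every side-chain test
  vacuous. Glycines get no CB and exercise the isolated-node case.
- Members are rigid-transformed copies (random proper rotation +
  translation) with optional isotropic Gaussian jitter.

Planted scenarios (fixed presets used by the tests and the acceptance
script; all noise-free so ground truth is exact):

- **giant** (`fixture_spec_giant`): 8 members, 12-residue template, a
  15-residue inserted segment in the last member, placed 50 Å along the
  axis so it neither gains nor loses contacts among template residues.
  Secondary structure is deliberately scrambled at 6 template columns
  (members alternate H/C) because a congruent toy family is otherwise
  *too good* to be flagged: the scramble emulates the degraded-alignment
  regime the flagging rule targets (one member > 50% gaps, conserved SS
  < 30%).
- **two_families + dwarf** (`fixture_spec_two_families`): 3 + 3 + 1
  members of a 40-residue template; family B is C-terminally shortened
  by 16 residues *and* hinge-displaced by 20 Å, the dwarf keeps 10
  residues. Shortening is essential, not decorative: with equal lengths
  and gap rows, the two families would have identical
  (gap %, mean RMSD, length) feature rows by symmetry and no clustering
  on these features could separate them. The preset geometry was chosen
  by computing the z-scored feature configuration analytically: the
  three groups (A, B, dwarf) are mutually well separated and the
  inertia curve has its knee at k = 3 (inertia_2/inertia_1 ≈ 0.32, well
  off the endpoint chord).
- **outlier** (`fixture_spec_outlier`): 6 members of a 20-residue
  template; the last member's second half is displaced 45 Å, leaving a
  mean post-superposition RMSD of roughly 15 Å — comfortably past the
  10 Å cutoff rather than marginally so.

What passing tests on these fixtures does **not** show: robustness to
real-world missing density, alternate conformations beyond the altloc
rule, alignments with systematic registration errors, non-helical folds,
or redundancy filtering — real side chains are also far larger than one
pseudo-atom, so absolute side-chain contact counts on real domains will
differ. The fixtures validate the *logic* (set algebra, thresholds,
bookkeeping, recovery of planted signals), and real-data behaviour
inherits only that.

## Problem sizes and budgets

The test suite works at deliberately small scale — fixtures up to 8
members × 60 residues, 50-structure oracle sweeps at 20–100 residues,
100-replicate elbow simulations — which keeps the full suite under a
minute while still exercising every rule and boundary. The acceptance
script re-derives its quantities at the same sizes from a single seed
argument.

## Known limitations

- PDB input only (first MODEL of multi-model files); no mmCIF.
- The alignment is trusted; the package validates consistency but cannot
  detect a *plausible but wrong* alignment.
- Post-curation statistics are computed without re-alignment (above).
- PSNs are unweighted; no interaction strengths, centralities or
  community structure.
- UPGMA is the only tree method; it assumes rate-constancy of structural
  divergence that real superfamilies may violate.
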