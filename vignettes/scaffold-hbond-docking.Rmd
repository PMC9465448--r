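---
title: "Docking fixed-backbone scaffolds by hydrogen-bond geometry matching"
author: "scafdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking fixed-backbone scaffolds by hydrogen-bond geometry matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafdock)
```

## The design problem

Affibodies, DARPins and related small binding scaffolds recognize their
targets through point mutations of a fixed set of surface residues; their
backbones do not move. Conventional rigid-body docking explores poses of a
*fixed sequence*, so it discards orientations that would become excellent
binders after a few mutations. `scafdock` inverts the search: it asks where
hydrogen bonds *could* form — from the scaffold's native side chains, its
backbone, or any polar mutation of its mutable residues — and then places
the antigen so that several such bonds form simultaneously. Every pose is
born with a set of designed hydrogen bonds and the mutations that create
them.

## Hydrogen-bond half-sites

Each polar atom that can take part in an interface hydrogen bond is
abstracted into a *half-site*:

* On the scaffold side, a half-site is a polar hydrogen (donor) or an
  acceptor O/N plus two constructed points on the atom–antecedent axis: a
  **primary point** exactly 1.25 Å beyond the atom — the ideal position of
  the partner atom — and a **secondary point** 1 Å further out that encodes
  the bond's direction. The polar-atom/antecedent table covers the backbone
  (O/C, HN/N, and the terminal OT1/OT2, HN1–HN3 rows when those atoms
  exist) and the side chains of ARG, LYS, ASP, GLU, SER, THR, TYR, ASN,
  GLN, HIS and TRP, with hydroxyl oxygens anchored to the midpoint of their
  hydrogen and the preceding carbon (CHARMM hydrogen naming throughout).
* On the epitope side, a half-site is the polar atom itself (primary) plus
  its antecedent position (secondary). Only residues with solvent-
  accessible surface area above 0.1 Å² contribute, so buried atoms can
  never be targeted; the small positive threshold absorbs the mesh noise of
  a strictly-zero rule.

At every *mutable* paratope residue, half-sites are additionally generated
for up to five structurally diverse rotamers of each polar amino acid, so a
match through such a half-site implies a design mutation.

## Geometric matching

For two half-sites of the same protein, one distance and four angles are
computed: the distance `D` between the primary points and the interior
angles of the quadrilateral S1–P1–P2–S2 (at each primary point, between its
secondary point and the other primary point; at each secondary point,
between its own primary point and the other secondary point). A scaffold
pair matches an epitope pair when

* `|D_scaffold − D_epitope| < d_limit` (default 1.8 Å), and
* the four positionally corresponding angle deviations are each below
  `a_limit` (default 70°).

These windows are the calibrated defaults: they admit about 85% of the
hydrogen bonds observed in antibody–antigen interfaces. Slot 1 is compared
with slot 1 and slot 2 with slot 2; both assignments of a pair combination
are tested and emitted separately when valid.

Type screening precedes geometry. Donor must meet acceptor, and the
amino-acid class pair must be one of: scaffold backbone with anything; any
scaffold side chain except ARG/LYS/GLN with epitope backbone; ARG/LYS with
ASP/GLU in either direction; or the low-entropy set {HIS, ASN, ASP, TYR,
SER, THR, TRP} with itself, excluding ASN with ASP (both carry multiple
polar groups). Pairs of half-sites from the same residue are skipped, and a
scaffold pair may contain at most one positively charged residue — a limit
that counts native and mutated ARG/LYS alike and therefore also bounds
every solution at one positive residue.

Compatible couples are expanded into **solution groups** by maximal-clique
enumeration over the interaction-compatibility graph (vertices are distinct
scaffold–epitope interactions, edges are compatible couples). Each maximal
clique of at least `min_group_size = 3` interactions is one candidate pose;
sub-cliques are not emitted separately, which keeps the solution set from
exploding combinatorially. Groups are ordered largest-first with a
lexicographic tie-break and capped at `max_poses = 2000`.

## Pose realization and filtering

For each group the antigen is rigidly placed by a Kabsch least-squares fit
of its epitope primary atoms onto the matched scaffold primary points
(equal weights, reflection branch corrected). Design rotamers are then
installed on the fixed backbone; a pose is rejected outright if a placed
rotamer clashes with another placed rotamer or with any residue that cannot
change.

Steric clashes use heavy atoms only, with three conditions exactly as
printed: any pair closer than 1.3 Å; more than one pair closer than 1.8 Å;
or a single sub-1.8 Å pair involving a backbone atom. The constants are
deliberately permissive: small residual overlaps are assumed to be
relievable by protein flexibility downstream. The peptide-bond atom pair of
sequence neighbours is excluded from intra-scaffold scans.

A coarse-grained filter runs before all-atom validation. Every residue is
split into backbone and side-chain units, each approximated by a sphere at
the unit's heavy-atom center of mass with radius equal to its farthest
atom. The printed constants are a minimum separation of 3.39 Å and a
minimum of 12 sphere contacts, but the geometric convention behind "apart"
and "in contact" is not fully determined, so both are explicit choices
here: by default a pair *violates separation* when its center distance is
below `r1 + r2 − 3.39` Å (an allowed-overlap budget; the alternative
center-distance reading is available as `sphere_rule = "center"`), and is
*in contact* when the surface gap is at most `contact_pad = 2.0` Å. The pad
is chosen so that two units joined by a designed hydrogen bond — whose
surface gap is about 1.5 Å at ideal geometry — always count as interface
contacts; with small side chains a 1 Å pad would miss them.

Finally each designed bond is re-measured on realized coordinates and must
satisfy the hydrogen-bond criterion (acceptor–hydrogen distance < 2.5 Å
and acceptor–hydrogen–donor angle > 120°, both strict); a pose failing even
one designed bond is rejected. Scaffold–antigen clashes are then
classified: clashes touching the backbone, a non-mutable side chain or a
designed-bond residue are fatal, while clashes confined to other mutable
side chains are recorded for rescue.

## The clash-rescue cascade

Clashing mutable residues are processed in ascending residue order, each
rescue visible to later sites, by the first applicable step:

1. an alternate rotamer of the current amino acid with no steric clash
   against any surrounding residue (within 10 Å of the site's CB — a safe
   superset, since the clash conditions themselves act below 1.8 Å);
2. an ASP rotamer forming a salt bridge (any carboxylate O within 4.0 Å of
   a charged N, the standard geometric criterion) with an antigen ARG/LYS
   not already claimed in this pose;
3. the same with GLU — ASP is preferred as the smaller, lower-entropy side
   chain;
4. a polar rotamer searched in the order SER, THR, ASN, ASP, HIS, required
   to form at least one (SER, THR) or two (ASN, ASP, HIS) valid hydrogen
   bonds with the antigen; an ASN with a single bond is accepted when its
   partner is a backbone atom. GLN and GLU are excluded as high-entropy;
5. a nonpolar rotamer in the order ALA, VAL, LEU, ILE, PHE making at least
   one nonpolar contact (a side-chain C/S atom within 4.5 Å of an antigen
   C/S atom); MET, TRP and TYR are excluded;
6. otherwise the pose is rejected as an irreconcilable clash.

Ties among qualifying rotamers go to library order, so the cascade is fully
deterministic. ARG and LYS are never introduced by any mutation.

## Rotamers

The bundled rotamer table is a backbone-independent set of the classic
staggered chi modes (±60°/180°, ±90° for aromatic chi2) with canonical mode
frequencies; a user-supplied table in the same `AA chi1 … chiN weight`
format — e.g. one derived from the Dunbrack library, which is not
redistributable — plugs in unchanged. Side chains are built onto the fixed
N/CA/C frame from ideal internal coordinates (branch-atom dihedral offsets
taken from crystallographic averages); at GLY sites a CB is first
constructed at the ideal tetrahedral position. "Structurally diverse"
rotamer subsets are chosen by greedy farthest-point selection on side-chain
heavy-atom RMSD after placement, seeded with the most probable rotamer —
deterministic, and within a factor two of the optimal max–min dispersion.

Polar hydrogens are placed at ideal covalent geometry (N–H 1.0 Å, O–H
0.96 Å); rotatable hydroxyls default to the anti conformation. Histidine is
modelled in its ND1-protonated tautomer (HD1 donor, NE2 acceptor), the only
assignment consistent with the half-site table. Chain-start residues (and
residues following a numbering gap) receive no amide HN, because the
preceding carbonyl that orients it does not exist; terminal OT/HN rows are
honored only when the atoms are present in the input.

## Solvent accessibility

Per-residue SASA uses the Shrake–Rupley method on heavy atoms with
element radii C 1.70, N 1.55, O 1.52, S 1.80 Å, probe 1.4 Å, and a
deterministic 960-point golden-spiral lattice per atom; per-atom areas sum
exactly into residues. The test suite checks it against an independent
random-lattice implementation to within 2% per residue.

## The synthetic fixture generator

`make_planted_complex()` builds test systems with analytically known
answers. The scaffold is an ideal α-helix (φ = −57°, ψ = −47°), 20 residues
long, with hydroxyl donors (SER by default) at up to six surface positions
— a caricature of the helical binding face of an affibody. For each planted
bond a 5-residue extended fragment is placed so that its epitope atom sits
*exactly* at the half-site primary point with its antecedent on the
half-site axis, so the planted interactions form a solution group with zero
distance deviation and near-zero angle deviations. Fragments run diagonally
across the helix surface (along the axis with a tangential tilt) so that
their flanking residues create a protein-sized interface — 15 or more
sphere contacts — without touching the neighbouring planted side chains.
The assembled antigen is then displaced by a seeded random rigid motion
that the docking search must undo; generation is a pure function of its
arguments and restores the caller's RNG state.

Optionally, some planted bonds are provided by the seed rotamer of the
donor type at ALA sites (`n_design`), so recovering them forces the
corresponding design mutations; an acceptor-mode variant plants scaffold
hydroxyl-oxygen acceptors against fragment hydroxyl donors, with the
planted hydroxyls turned inward so the acceptor lone-pair axis faces the
solvent.

What the generator does **not** emulate: real side-chain packing density,
backbone flexibility, solvation, long-range electrostatics, or antigens of
realistic size and shape. A passing recovery test therefore demonstrates
the geometric and combinatorial correctness of the pipeline — not
predictive performance on real complexes, which additionally depends on
downstream energy evaluation that is deliberately out of scope here.

## Problem sizes and determinism

The shipped tests and the acceptance script use 20-residue scaffolds with
3–6 planted bonds (hundreds of candidate groups), brute-force oracle
comparisons on instances of up to 12 half-sites, 10,000-transform
superposition checks, and a 300-pose cap for the design-mutation run —
sizes chosen so the whole suite exercises every stage at desk scale. The
core pipeline contains no randomness: identical inputs give byte-identical
summaries. All randomness lives in the fixture generator and is seeded.

## Known limitations

* No energy model: poses are neither minimized nor ranked beyond group
  size; rotamer repacking and scoring are left to downstream tools.
* Hydrophobic interactions are not matched — only hydrogen bonds seed
  poses, so purely apolar epitopes yield nothing.
* The couple enumeration is quadratic in half-site pairs; very large
  mutable paratopes are slow in plain R.
* Proline backbone geometry and non-standard residues are not modelled.
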