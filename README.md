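# scafdock

Simultaneous docking and mutation of fixed-backbone binding scaffolds by
hydrogen-bond geometry matching.

Small alternative binding scaffolds — affibodies, DARPins and their kin —
bind targets through point mutations of a fixed set of surface residues,
without backbone movement. Conventional rigid-body docking explores poses
of a fixed sequence and so rejects orientations that a few mutations would
turn into strong binders. `scafdock` searches the other way around: it
enumerates everywhere a hydrogen bond *could* form — from native side
chains, the backbone, or any polar mutation of the mutable residues — and
places the antigen so that several designed bonds form at once. It is
aimed at protein engineers generating mutated starting poses for
downstream refinement and ranking.

## The algorithm

Every hydrogen-bonding polar atom becomes a *half-site*. On the scaffold a
half-site is the atom plus a primary point **P** (the ideal partner
position, 1.25 Å along the antecedent→atom axis) and a secondary point
**S** (1 Å further, fixing the bond direction); on the epitope it is the
exposed polar atom (primary) plus its antecedent (secondary). For any two
half-sites of one protein the method computes the distance `D = |P1P2|`
and the four interior angles of the quadrilateral S1–P1–P2–S2. A scaffold
pair matches an epitope pair when

    |D_s − D_e| < d_limit          (1.8 Å)
    |∠_s(i) − ∠_e(i)| < a_limit    (70°, for all four angle slots)

subject to donor/acceptor complementarity and amino-acid class rules
(scaffold backbone with anything; non-ARG/LYS/GLN side chains with epitope
backbone; ARG/LYS ↔ ASP/GLU; the low-entropy set HIS/ASN/ASP/TYR/SER/THR/
TRP with itself, except ASN↔ASP; at most one positive residue per couple).
Mutually compatible couples are expanded into maximal cliques of ≥ 3
interactions; each clique is a candidate pose with its design mutations.
The antigen is placed by Kabsch superposition of epitope primaries onto
scaffold primary points, and the pose must survive heavy-atom clash rules
(1.3 Å / 1.8 Å), a coarse-grained sphere filter (3.39 Å separation budget,
≥ 12 sphere contacts) and re-validation of every designed bond (acceptor–H
< 2.5 Å, acceptor–H–donor > 120°). Remaining clashes of mutable side
chains are rescued by an ordered cascade: repack → ASP salt bridge → GLU
salt bridge → polar H-bond mutation (SER, THR, ASN, ASP, HIS) → nonpolar
contact mutation (ALA, VAL, LEU, ILE, PHE) → reject.

See the vignette source (`vignettes/scaffold-hbond-docking.Rmd`) for the
full model, parameter rationale and limitations.

## Worked example

The package ships a generator for synthetic complexes with planted,
analytically known hydrogen bonds. Dock one and look at the result:

```r
library(scafdock)
fx <- make_planted_complex(n_bonds = 3, seed = 7)
res <- dock(fx$scaffold, fx$antigen, fx$paratope, fx$variable, fx$epitope,
            verbose = TRUE)
#> half-sites: 12 scaffold (PBR), 6 epitope (EBA)
#> 60 couples -> 11 solution groups
#> 1 poses accepted / 11 groups

pose <- res$poses[[res$accepted[1]]]
pose
#> dock_pose [accepted]: 3 designed H-bonds, 0 mutation(s), superposition RMSD 0.000 A
pose$hbonds[, c("scaffold_site", "scaffold_atom", "epitope_site",
                "epitope_atom", "dist", "angle")]
#>   scaffold_site scaffold_atom epitope_site epitope_atom dist angle
#> 1           A:2           HG1        B:122            O 1.25   180
#> 2           A:5           HG1        B:142            O 1.25   180
#> 3           A:9           HG1        B:162            O 1.25   180
```

The 12 scaffold half-sites (hydroxyl donor, hydroxyl acceptor, backbone O
and HN for each of three serines) and 6 epitope half-sites combine into 60
geometrically compatible couples and 11 candidate poses. Ten are killed by
the filters (here: failed bond realization or clashes with fixed residues);
the surviving pose recovers the three planted serine→carbonyl bonds at the
ideal 1.25 Å / 180° geometry with zero superposition RMSD — the seeded
rigid displacement of the antigen has been exactly undone. With
`n_design > 0` the same machinery returns poses whose bonds run through
ALA→SER design mutations, and `outdir = "run"` writes pose PDBs, a
mutation TSV and a JSON summary.

A thin command-line front end over the same functions lives in
`inst/scripts/scafdock` (subcommands `dock`, `make-fixture`,
`validate-pose`, YAML config).

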