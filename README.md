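# relmol

`relmol` is a foundational molecular-modelling toolkit for R, aimed at
people who build structure-preparation and energy tools rather than just
run them: it provides the storage model, the file formats, the selection
language and the AMBER-style energetics that such tools are assembled
from.

## The model at its core

A molecule is stored **relationally**, not hierarchically. The molecule
directly owns one columnar component table per molecular-object type —
`atom`, `bond`, `resd`, `angl`, `tors`, `oops`, `tor2`, `ptor` — and a
set of adjacency tables holding ordered relations between types
(atom–bond, residue–atom, ...). A residue never contains atoms, it only
relates to them, so atom iteration and counting never touch residues,
inter-residue bonds are unremarkable, and new object types (say `strd`
for DNA strands) can be registered at run time without changing existing
code. Property and type names are keyed by a positional base-40 hash:
scanning left to right, letters map to their alphabet position (`a`/`A` =
0), digits to themselves, `_` to 36, and the running sum is multiplied by
40 per character — `encode_name("ba") = 1*40 + 0 = 40`.

On top of the model sit:

* readers/writers for PDB/ENT, TRIPOS MOL2, MDL MOL/SDF (V2000) and a
  multi-molecule database loader;
* a SMILES reader and SMARTS substructure matcher;
* an AMBER-style atom-mask language — `":1-10"` selects residues 1–10,
  `"@4 < @5"` all atoms within 5 Å of atom 4;
* bond-order perception (`fixbond`: hard templates, length rule,
  conjugation rule), hydrogen addition, rigid-body transforms;
* solvent shell / cuboid box / truncated-octahedron / cap construction
  and greedy counter-ion placement;
* AMBER parameter parsing (parm.dat and frcmod dialects) with bonded,
  direct nonbonded and Generalized Born energies, where the GB term is

  E_GB = −INVCHG2 · (1 − 1/ε) · Σ_{i<j} q_i q_j / f_GB,
  f_GB = [r_ij² + α_ij² · exp(−r_ij²/(2 α_ij²))]^½,  α_ij² = α_i α_j,

  with ε = 78.5 and INVCHG2 = 18.2223² ≈ 332.05 kcal·Å/(mol·e²);
* an AMBER prmtop/inpcrd topology writer;
* a LEaP-like command interpreter (`run_script()`) and a `relmol` CLI
  (`inst/bin/relmol`).

## A worked example

```r
library(relmol)

ff <- read_frc(text = fx_tiny_frc())        # tiny packaged force field
w1 <- fx_water(); w2 <- fx_water()
mol_translate(w2, c(2.8, 0.5, 0))
dimer <- merge_mols(list(w1, w2), name = "dimer")
enumerate_terms(dimer)
energy_report(dimer, ff)
#> energy (kcal/mol):
#>   bond               0.000000
#>   angle              0.000000
#>   torsion            0.000000
#>   improper           0.000000
#>   elec_direct       -4.893723
#>   vdw                0.952368
#>   egb              228.510307
#>   total            224.568952
```

The bonded terms vanish because the fixture water sits exactly at its
equilibrium geometry; the two waters attract electrostatically (−4.89
kcal/mol) with a small Lennard-Jones repulsion at this close contact. The
GB term is summed exactly as the model defines it — over all distinct
atom pairs, with no bonded exclusions and no self-term — so the large
intramolecular O–H charge products dominate and the term is positive
here; see the methods vignette for why that convention is preserved
as-is.

Selection, line notation and solvation follow the same style:

```r
mol <- read_smiles("CC(=O)[O-]")
length(match_smarts("[#8]", mol))           # 2 oxygens
pep <- fx_peptide()
mask_atom(pep, ":1-2 & !@H*")$atoms         # heavy atoms of residues 1-2
ion <- fx_ion("Na+")
solvate_shell(ion, water_box_template(), closeness = 1.0, extent = 6)
#> 27 water residues retained in the shell
```

From a shell, the same pipeline runs as a script:

```
loadfrc tiny.frcmod
s = load chloride.mol2
solvate s box 5
addions s Na+ auto
saveamberparm s sys.prmtop sys.inpcrd
```

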