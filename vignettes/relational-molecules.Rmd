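---
title: "A relational molecule model and AMBER-style system preparation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A relational molecule model and AMBER-style system preparation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relmol)
```

## The relational model

Most molecular toolkits store a molecule hierarchically: the molecule owns
residues and each residue owns its atoms. That layout makes three common
operations awkward: iterating over atoms requires walking residues first
(so counting atoms is not constant time unless a cache — with its own
consistency problems — is bolted on); inter-residue bonds have no natural
owner; and inserting a new structural level (strands for nucleic acids,
say) forces changes through every piece of iteration code.

`relmol` instead stores a molecule *relationally*. A molecule owns one
**component table** per molecular-object type — atoms, bonds, residues,
angles (`angl`), proper torsions (`tors`), impropers (`oops`), and the two
AMOEBA cross-term types (`tor2`, `ptor`, registered but carrying no
energy model here) — and a set of **adjacency tables** holding ordered
relation lists between two types (atom–bond, residue–atom, atom–atom,
...). A residue never *contains* atoms; it merely relates to them. Atom
iteration touches only the atom table, counting is constant-time, an
inter-residue bond is just a bond, and a ninth type such as `strd` can be
registered at run time (`register_type("strd")`) and related to residues
without touching any existing code path — a property the test suite
checks explicitly.

Component tables are columnar: each property is one flat array keyed by a
hashed name, and vector-valued properties (positions) are flattened into a
single numeric array of length `n * width` rather than a list of
3-vectors. Five property kinds mirror the accessor family `set_i`/`get_i`
(integer), `set_d` (double), `set_s` (string), `set_v` (numeric vector)
and `set_a` (any R value, excluded from file round-trips). All mutation
and traversal goes through lightweight object handles `(molecule, type,
id)` that carry no data themselves.

### Hashed property keys

Property and type names are encoded as positional base-40 integers:
scanning characters left to right, a lowercase or uppercase letter
contributes its position from `a`/`A` (zero-based), a digit its value, an
underscore 36, anything else is skipped, and the running sum is multiplied
by 40 before each new character. So `encode_name("ba")` is `1*40 + 0 =
40`. Two consequences are worth documenting. First, characters encoding to
zero (`a`, `A`, `0`) act as leading zeros, so `"a"`, `"aa"` and `"ab"`,
`"b"` collide; names of equal length never do. Second, R stores the hash
in a double, exact up to 2^53; names of at most 9 characters are encoded
exactly, and the documented cap of 10 admissible characters (40^10 fits a
signed 64-bit integer, which bounds the design) can lose low-order
precision in the 10-character case. Keys are interned per name, so this
never affects lookup correctness inside a session.

### Indexing

All object ids are 1-based, R's native convention, which is also the
external numbering of the mask language (`@4` is the fourth atom).
Zero-based encodings appear in exactly one place — the AMBER topology
writer, whose index arrays store `3*(id-1)` coordinate offsets as the
format requires.

## File formats

`read_pdb()` dispatches on the first four letters of each line, creating
atoms from `ATOM`/`HETATM`, starting a new residue on every change of
`(resSeq, chain)`, turning `CONECT` into bonds and skipping everything
else; parsing is fixed-column first with a whitespace-token fallback, and
elements missing from columns 77–78 are inferred from the atom name. No
bonds are perceived when `CONECT` is absent — `fixbond()` or templates
handle that, and a distance-based perception pass was deliberately left
out to keep reading side-effect-free. `read_mol2()`/`write_mol2()` carry
names, positions, SYBYL types, partial charges (four decimals), bond
orders (aromatic `ar` stored internally as order 4 and localized on
demand) and substructures; `read_sdf()`/`write_sdf()` cover V2000 with
`M  CHG` formal charges and data fields (V3000 errors explicitly);
`load_mdb()` splits multi-record MOL2/SDF files into a name-keyed
database, suffixing duplicates. OFF libraries are out of scope and error.

## SMILES, SMARTS and masks

The SMILES reader supports the organic subset, bracket atoms with
isotope/charge/explicit-H, branches, ring closures (including `%nn`) and
the bond symbols `- = # :`; aromatic lowercase atoms are Kekulized by a
deterministic lowest-index-first matching, and implicit hydrogens are
recorded as the `nh` count property (standard valences B3 C4 N3 O2 P3 S2,
halogens 1, charge-adjusted), realized as atoms only by `addHs()`. Stereo
marks are parsed and ignored with a warning — canonical output and stereo
semantics are non-goals. SMARTS queries support `*`, `#n`, element
symbols, aromatic/aliphatic case, charge, degree `D`, H-count `H`, ring
membership `R`/`R0` and the operators `!`, `&`, `;`, `,`; matching is an
exhaustive backtracking subgraph monomorphism that retains symmetric
duplicates and orders results lexicographically, which is what the
brute-force oracles in the tests expect. Recursive SMARTS are out of
scope and unsupported primitives raise errors rather than matching
silently.

The mask language implements `:` (residues) and `@` (atoms) with
comma-separated ids, ranges and names (`*` suffix wildcard), the
operators `& | !`, parentheses, and the distance postfix `expr < @r` /
`expr > @r` (atom-granular) or `< :r` (whole residues). Whitespace is
insignificant. A `<` selection keeps every atom whose minimum distance to
any core atom is at most `r`; since core atoms are at distance zero they
are included — the convention was genuinely open, so it is the documented
default rather than a silent choice. `>` is the strict complement within
the molecule.

## Solvation geometry

A solvent template is a periodic cell of solvent residues with edge
`solvlen` (the packaged template is a synthetic 216-water cube on a
6×6×6 grid at 3.1 Å spacing — an idealized lattice with TIP3P-like
geometry and charges, *not* an equilibrated liquid; densities and
radial structure of real water are therefore not reproduced, which the
round-trip and filter tests do not depend on). The solute bounding box is
stretched (`extent` for shells, `buffer` for boxes), the template is tiled
from the minimum corner with partial far-face cells included, and each
solvent residue is kept or discarded by a per-residue minimum-distance
filter: discarded if any solvent atom comes closer to a solute atom than
the clash cut, or (shell mode) if its minimum solute distance exceeds
`extent`. The clash cut defaults to `closeness * (r1 + r2)` over van der
Waals radii; the caption-level description leaves the exact combination
open, so an additive variant `r1 + r2 + closeness` is selectable by flag.
The truncated octahedron clips box-tiled centroids to
`|x|+|y|+|z| <= 3a/4` on the cube of side `a` (the largest box edge),
guaranteeing it never places more solvents than the box at equal buffer.
Ion placement is greedy: each ion goes to the coarse-grid point minimizing
its Coulomb energy against everything placed so far, at least 3 Å from
any atom; `auto` mode adds `ceiling(|net charge|/|ion charge|)`
counter-ions and is a no-op with a notice at zero net charge. All
placement is deterministic.

## Force field and energies

`read_frc()` parses both frcmod-style headed sections and the sequential
parm.dat layout (title, masses, hydrophilic line, bonds, angles,
dihedrals, impropers, 10–12, equivalences, `MOD4` + NONBON), including
negative-periodicity multi-term torsions; frcmod input overlays a base
field. Lookups are symmetric for bonds/angles, reversible for torsions
with terminal-`X` wildcards, and permutation-tolerant for impropers
(center third).

The bonded forms are the AMBER conventions — `k(r-r0)^2`,
`k(theta-theta0)^2`, `sum (PK/IDIVF)(1+cos(n phi - gamma))` — adopted
explicitly because the evaluators are named but their formulas are not
prescribed. The direct nonbonded sum runs over pairs `j > i` with 1-2 and
1-3 pairs excluded and 1-4 pairs scaled by 1/1.2 (electrostatics) and
1/2.0 (Lennard-Jones), both configurable; under periodic boundaries the
minimum-image convention with a cutoff below half the shortest box edge
is used. There is no Ewald summation: the periodic electrostatic sum is a
documented truncated direct sum, a deliberate scope reduction.

The Generalized Born term is implemented exactly as the model prints it:

$$E_{GB} = -\mathrm{INVCHG2}\,\Big(1-\tfrac{1}{\varepsilon}\Big)
\sum_{i<j} \frac{q_i q_j}{f_{GB}},\qquad
f_{GB} = \Big[r_{ij}^2 + \alpha_{ij}^2\,
e^{-r_{ij}^2/(2\alpha_{ij}^2)}\Big]^{1/2},\qquad
\alpha_{ij}^2 = \alpha_i\alpha_j$$

with water dielectric 78.5. Two printed choices differ from common GB
practice and are preserved as-is rather than resolved: the sum has no
self-energy (`i = j`) term and no bonded exclusions, and the screening
exponent uses `2*alpha_ij^2` where the literature standard is
`4*alpha_i*alpha_j`; `variant = "standard"` switches to the latter for
comparison. Born radii come from the `born` property when present,
otherwise from a packaged mbondi-like element table, since the model
treats them as inputs.

`INVCHG2`, the Coulomb conversion constant, is defined as the AMBER
charge-unit convention `18.2223^2 = 332.0522` kcal·Å/(mol·e²) — 332.05 at
the model's quoted two-decimal precision — so that prmtop charges
(partial charges × 18.2223) give kcal/mol directly. Recomputing
`K_e e^2 N_A / 10^{-10} / 4184` from CODATA-2018 constants
(`coulomb_constant()`) yields 332.0637; the ~0.014 gap to the historical
AMBER constant is a known property of that convention and is asserted,
not hidden, in the tests.

## Topology output

`write_amber_prmtop()` emits the modern `%FLAG`/`%FORMAT` dialect
(readable by current MD engines and reference parsers; the pre-`%FLAG`
legacy layout is a non-goal), with H/non-H term splitting keyed on
element, exclusion lists counting 1-2/1-3/1-4 with the mandatory zero
placeholder for empty lists, negative third indices suppressing duplicate
1-4 pairs in multi-term and ring torsions, negative third+fourth for
impropers, and box sections when solvation recorded box metadata.
`write_inpcrd()` writes the ASCII restart layout (`%12.7f`, six per
line, trailing box line). The parity test recomputes all energies from
the written arrays alone — charges used exactly as stored — and requires
agreement with the in-memory evaluation to 1e-4 kcal/mol on every
fixture system.

## Command layer

The script interpreter (`run_script()`) registers each command by name in
a single registry with a uniform execute signature, mirroring a
command-pattern plugin design: `source`, `loadfrc`, `load`, `merge`,
`solvate`, `addions`, `moloper` (`fixbond` + `addHs` + charge stub),
`mask`, `energy`, `saveamberparm` and friends; the first failing command
aborts with its line number and a nonzero status. Two commands are
honest stubs by design: `setpchg` applies packaged per-element fallback
charges shifted to the total formal charge (the original tool chain
shells out to an external charge program), and `parmchk` reports missing
parameters rather than generating them. The `relmol` script under
`inst/bin/` is a thin wrapper over `relmol_main()`.

## Numerical choices and test scale

Bond-length perception uses packaged covalent radii with 0.05 Å slack
between order bands; lengths falling between the double and single bands
mark a bond as conjugated, and conjugated systems are Kekulized by
deterministic lowest-index-first matching (aromatic carbons must receive
exactly one double bond; an infeasible system is an error listing the
atoms). `addHs()` places hydrogens on ideal tetrahedral/trigonal/linear
directions at standard X–H lengths and trusts stored `nh` counts from
SMILES; hypervalent P/S are exempt from the over-valence error. `center`
is the unweighted geometric mean; `mass_center()` is the clearly named
weighted variant. Degenerate inputs are handled conservatively: empty
selections error, zero-atom solutes solvate around the origin, and
coordinate-free SMILES molecules get hydrogens on ideal directions at the
origin.

The test suite sizes were chosen to keep the whole suite around a minute
on one core while still being adversarial: 1,000 fuzzed mask expressions
on ~30–90-atom molecules against a loop-based interpreter, 50 random
solutes for the solvation filter oracle (with a 27-water template cell),
direct-sum parity on 120- and 200-atom jittered lattices at absolute
1e-9, 100 random molecules per format round-trip, and topology parity on
six fixture systems including a solvated ion. RDKit, when available
through the system python, cross-checks SMILES atom/bond/implicit-H
counts; the suite stays self-contained without it.

## Known limitations

No Ewald summation, forces or gradients; no AMOEBA parameters or energy;
no pKa-aware protonation or rotamer optimization of added hydrogens; no
canonical SMILES writer or stereochemistry semantics; no recursive
SMARTS; no OFF libraries, mmCIF or compressed input; solvent boxes are
geometric constructions, not equilibrated ensembles; and the charge stub
is a placeholder, not an electronegativity-equalization model.
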