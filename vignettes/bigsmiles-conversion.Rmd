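---
title: "Converting homopolymer repeat-unit SMILES to BigSMILES"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting homopolymer repeat-unit SMILES to BigSMILES}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bigsmilesr)
```

## The problem

SMILES writes a molecule as an ASCII string: atoms in sequence, branches in
parentheses, rings as paired digits. For a polymer, what gets written is the
*repeating unit*, with the two positions where units link -- the
polymerization points -- marked by `*` wildcards. That notation carries no
information about how the units bond. BigSMILES adds it: the polymeric
fragment is wrapped in curly brackets, and bonding descriptors encode the
polymerization chemistry:

* `{$unit$}` -- AA bonding: both ends equivalent (chain-growth/addition,
  e.g. vinyl polymers),
* `{<unit>}` -- AB bonding: two distinct reactive ends
  (step-growth/condensation),
* `{<groupA<,>groupB>}` -- AB with the two reactive end groups resolved
  (e.g. the diol and the diacid residue of a polyester),
* `{<unit1>,<unit2>}` -- the head-to-tail / tail-to-tail pair of a
  ring-opened asymmetric epoxide.

`bigsmilesr` automates the conversion in both directions for homopolymers
with exactly two polymerization points, and ships the validation harness
used to argue that the conversion is correct.

## The conversion pipeline

`smiles_to_bigsmiles()` runs five stages.

**Normalization and filtering.** Typeset whitespace, explicit `-` single
bonds and bracketed `[*]` wildcards are normalized away; strings whose
wildcard count is not exactly two, or which fail the chemical grammar
(tokenization, balanced branches, paired ring labels, monovalent wildcards,
a parse as a connected molecular graph) are rejected with a reason
(`wrong_point_count(n)`, `invalid_grammar`).

**Asterisk relocation.** The BigSMILES curly brackets replace the two chain
ends, so both wildcards must sit at the ends of the string. In a canonical
SMILES of a vinyl monomer the second wildcard typically sits mid-string as
a branch, e.g. `*CC(*)(C)C(=O)OCC(C)C`. The permutative branch swap
(`branch_swap_step()`) exchanges the asterisk branch with the main-chain
remainder to its right -- the remainder becomes a branch, the asterisk
becomes terminal -- repeating until both wildcards are terminal, with ring
labels renumbered to stay unambiguous. The conversion pipeline itself runs
a stronger variant: the unit is first put into a canonical atom ordering
(OpenBabel canonicalization, which also perceives aromaticity so kekulized
spellings converge), then re-linearized by a deterministic writer (below).
This guarantees that *differently ordered spellings of one repeat unit
produce one identical core*, which pure string surgery cannot.

**Classification.** The main chain of the relocated core is the atom run
outside all parentheses. If it consists solely of carbon or silicon the
unit is classed AA (polyolefins and polycarbosilanes, made by
Ziegler-Natta or ring-opening routes); any backbone heteroatom makes it
AB. This is a structural default: units made under special conditions
(ionic routes, specific catalysts) may need manual reclassification, which
is deliberately out of scope.

**Ring-opening exception.** A backbone of exactly C,C,O signals a
polyether from epoxide ring-opening. For an asymmetric epoxide the
orientation of successive units matters, so the unit is emitted as a pair:
the core plus its reversal re-rotated so the backbone again reads C,C,O
(`make_two_unit_variant()`). For a symmetric unit (plain `CCO`) the pair
collapses and a single `{<CCO>}` is emitted.

**End-group search.** An AB unit may decompose into two recognizable
reactive end-group residues. The search (`find_end_groups()`) shifts the
core cyclically one character at a time ("parallel displacement"): a shift
is usable only if the shifted string still obeys the grammar and still
describes the same polymer (see the cycle key below). At each surviving
rotation, ordered template pairs from a YAML config are tried: a fragment
pair matches when fragment one begins and ends with the first template's
anchors and fragment two with the second's (diol/diacid, diamine/diacid,
diol/diisocyanate residue, diol/carbonate). The first hit -- by table
order, then lowest rotation, then leftmost split -- wins, giving
deterministic output. `move_parallel` caps the search: `-1` scans all
rotations, `0` only the unrotated core (a fast path for large simulated
datasets where most units have no recognizable pair anyway). If nothing
matches, the unit stays a plain `{<core>}`; that is a statement about the
template table, not an error.

The packaged template table is an editorial reconstruction assembled from
standard step-growth chemistry; the published source did not print its
list. It is a config file precisely so users can extend it
(`end_group_patterns(path)`).

## Equivalence keys: when are two strings the same polymer?

Two oracles underpin every correctness claim.

* `unit_key()` -- the canonical SMILES of the two-wildcard molecule.
  Identical for any spelling of the same repeat unit (branch order,
  traversal direction, aromatic vs. kekulized).
* `cycle_key()` -- the canonical SMILES of the molecule obtained by
  *replacing the two wildcards with a bond joining their attachment
  atoms*. Rotating a repeat unit changes the molecule but merely cuts the
  same cycle elsewhere, so every valid rotation (and the traversal
  reversal) shares one cycle key, while genuinely different polymers do
  not. Two unit shapes cannot close into a simple ring and receive tagged
  keys instead: both wildcards on one atom (`loop:`), and wildcards on
  adjacent atoms -- every vinyl backbone -- where closing would double an
  existing edge (`fused:`, keyed with marker atoms on the attachments).
  Rotation cannot move a unit between these regimes, so keys stay
  comparable exactly where they should be.

Canonicalization itself is delegated to OpenBabel (via ChemmineOB); this
package's contribution is the string/graph machinery around it. The test
suite cross-checks the cycle-key partition against an independent RDKit
implementation of the same construction.

## The deterministic core writer

The canonical core is produced by re-linearizing the canonicalized graph
with fixed rules:

* the main chain is the shortest path between the two attachment atoms
  (BFS, ties broken by canonical atom order);
* at backbone atoms, side branches are written largest-first and all
  parenthesized -- matching how the published corrected conversions are
  laid out (`CC(C(=O)OCC(C)C)(C)`), and guaranteeing a re-appended `*`
  bonds to the backbone;
* inside a branch, the largest subtree continues the chain, so carbonyls
  print as `(=O)` rather than stranding the chain behind them;
* ring-closure digits take the smallest label not currently open, `%nn`
  above 9;
* of the two possible start terminals, the orientation whose string
  compares smaller wins, with `(` ranked after atom characters so
  `CC(...)` beats `C(...)C`. The comparison is byte-wise, deliberately
  locale-independent.

These conventions make the worked examples byte-exact: the adipate unit
rotates to `{<OCCO<,>C(=O)CCCCC(=O)>}` and the methoxy-epoxide to
`{<CC(COC)O>,<C(COC)CO>}`.

## Back-conversion

`bigsmiles_to_smiles()` inverts the four shapes: the unit (or the
concatenated fragment pair) gets its wildcards back. For the two-unit
variant the first unit -- the original orientation -- is returned. The
round-trip contract is deliberately stated on the *polymer*, not the
string: `cycle_key(to_smiles(convert(s))) == cycle_key(s)`. When no
rotation was used and no two-unit pair emitted, the molecule itself
(`unit_key`) also survives.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `move_parallel` | `-1` | end-group search depth in rotations; `0` = fast path |
| `max_len` | `85` characters | import cut for repeat-unit length, reflecting that very long combinatorial units are rarely synthesizable |
| `chunk_size` | `100000` records | rows per output csv, offset nomenclature `stem_0.csv`, `stem_100000.csv`, ... |
| pattern table | packaged YAML | ordered reactive end-group template pairs |

## What the synthetic generator does and does not emulate

`random_repeat_units()` concatenates 2-6 backbone segments from a small
vocabulary (alkylene, ether, amine, ester, amide, arylene, alicyclic,
fluorinated) and appends the two wildcards. It emulates the *shape* of
homopolymer repeat units -- mixed backbones, branches, rings -- well
enough to stress the relocation, classification and round-trip machinery.
It does not emulate real datasets' distribution of chemistry: no charges,
isotopes, stereo centers, fused polycycles, or pathological-but-legal
spellings. Passing the round-trip property on generated units therefore
demonstrates the machinery's internal consistency, not coverage of every
molecule a 4.9M-record corpus would contain. `randomized_orderings()`
similarly emulates toolkit-reordered spellings by random graph traversal.

## Numerical and degenerate-input choices

* Stereo bond tokens (`/`, `\`) and bracket-atom contents are carried
  verbatim; a rotation separating them from their atom fails the grammar
  gate. Reversal of directional bonds is not re-interpreted -- stereo
  fidelity across reversal is a known limitation.
* Wildcards carrying an explicit non-single bond are rejected
  (`nonsingle_wildcard_bond`): the BigSMILES homopolymer join assumes a
  single bond.
* A shift that would split a two-character token (`Cl`, `Br`, `%nn`) is
  classed invalid rather than attempted; splitting guarantees a syntax
  violation anyway.
* An empty branch, an unattached ring digit, a branch-opening before any
  atom: all named, position-bearing diagnostics rather than crashes.
* OpenBabel failing to produce a canonical string is treated as failing
  the grammar gate.

## Validation harness

`run_validation(p)` packages the three published procedures at fixture
scale: (1) convert the eight corrected ground-truth units and compare
structurally; (2) round-trip every fixture; (3) convert five reordered
spellings per structure and require one identical output. The erroneous
published strings are retained as *negative* fixtures -- they must fail to
parse or fail equivalence, and at least three are structurally infeasible.
The test suite runs these on the packaged records (12 fixtures, 100
generated units, all rotations of cores up to 30 characters); the
published full-corpus figures (4.9M conversions, the 304- and 662-record
expert audits) require external downloads and are intentionally not
reproduced, though `run_validation()` accepts any user-supplied table with
the same columns.

## Known limitations

* Homopolymers with exactly two attachment points only; multi-arm and
  graft units are filtered, as designed.
* The AA/AB rule is purely structural (see above).
* The end-group table is a first-match-wins heuristic; unusual
  condensation chemistries fall back to plain `{<core>}`.
* BigSMILES 1.1 descriptors are accepted on input and folded to 1.0; the
  package always emits 1.0 syntax.
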