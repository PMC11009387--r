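# bigsmilesr

Automated, bidirectional conversion between homopolymer repeating-unit
**SMILES** and **BigSMILES** in R.

A polymer's repeating unit is usually distributed as a SMILES string with
two `*` wildcards marking the polymerization points, e.g.
`*CC(*)(C)C(=O)OCC(C)C` for poly(isobutyl methacrylate). That string says
nothing about how units bond. BigSMILES wraps the unit in a stochastic
object whose bonding descriptors carry the polymerization chemistry:

| shape | meaning |
|---|---|
| `{$unit$}` | AA bonding — chain-growth/addition (backbone of only C/Si) |
| `{<unit>}` | AB bonding — step-growth/condensation |
| `{<a<,>b>}` | AB with the two reactive end groups resolved (diol + diacid, ...) |
| `{<u1>,<u2>}` | head-to-tail / tail-to-tail pair of a ring-opened asymmetric epoxide |

`bigsmilesr` implements the conversion workflow end to end: normalization
of published strings, filtering to exactly two polymerization points,
relocation of the asterisks to the string ends (the permutative branch
swap, backed by a canonical rewrite so reordered spellings of one unit
give one identical output), AA/AB classification from the backbone, the
`*CCO*` ring-opening exception, detection of reactive end-group pairs by
single-character parallel displacement against a configurable YAML
template table, BigSMILES assembly, the reverse (BigSMILES → SMILES)
conversion, and the three-procedure validation harness (ground-truth
agreement, round-trip fidelity, permutation invariance). Batch readers
(csv/tsv/txt/xlsx), chunked dataset writers with offset nomenclature, and
a command-line script mirror the published dataset layout.

Structural equivalence rests on two canonical keys (OpenBabel via
ChemmineOB): `unit_key()` identifies the two-wildcard *molecule*;
`cycle_key()` identifies the *polymer* by bonding the two attachment atoms
together, so every valid rotation of a unit shares one key. See the
methods vignette (`vignettes/bigsmiles-conversion.Rmd`) for the model and
the design choices.

## Worked example

```r
library(bigsmilesr)

smiles_to_bigsmiles(c("*CC(*)(C)C(=O)OCC(C)C",   # vinyl: AA
                      "*OCCOC(=O)CCCCC(=O)*",    # polyester: AB, split
                      "*CC(COC)O*"))             # epoxide: two-unit
#> # A tibble: 3 × 7
#>   smiles                bigsmiles                 variant     rotation_used ...
#> 1 *CC(*)(C)C(=O)OCC(C)C {$CC(C(=O)OCC(C)C)(C)$}   AA                     NA
#> 2 *OCCOC(=O)CCCCC(=O)*  {<OCCO<,>C(=O)CCCCC(=O)>} AB_split               14
#> 3 *CC(COC)O*            {<CC(COC)O>,<C(COC)CO>}   AB_two_unit            NA
```

Row 1: the mid-string asterisk was swapped to the end and the unit classed
AA (all-carbon backbone) — the exact corrected ground-truth string. Row 2:
the backbone contains oxygen (AB); rotating the unit 14 characters exposes
a diol fragment `OCCO` facing a diacid fragment `C(=O)CCCCC(=O)`, written
either side of `<,>`. Row 3: a C,C,O backbone is a ring-opened epoxide;
the unit and its reversed, re-rotated twin express both enchainment
orientations.

Back-conversion and the polymer-level round-trip guarantee:

```r
bigsmiles_to_smiles("{<OCCO<,>C(=O)CCCCC(=O)>}")
#> [1] "*OCCOC(=O)CCCCC(=O)*"
structurally_equivalent("{$CC(C(=O)OCC(C)C)(C)$}", "{$CC(C)(C(=O)OCC(C)C)$}")
#> [1] TRUE
```

Batch work is tibble-first:

```r
tbl <- load_polymer_table("units.csv", max_len = 85)
res <- convert_polymers(tbl, roundtrip = TRUE)
generics::glance(res)   # n_input = n_converted + n_rejected
write_conversion_chunks(res, "out/", chunk_size = 100000, stem = "poly")
ggplot2::autoplot(res)  # outcome mix
```

A thin CLI wraps the same functions
(`inst/scripts/bigsmiles-convert.R`): subcommands `convert`, `roundtrip`,
`validate` (runs the three validation procedures on a file or on the
packaged fixtures) and `fixtures`.

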