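test_that("the four stochastic-object shapes parse and everything else is rejected", {
  p <- parse_bigsmiles("{$CC(OC(=O)CCC)$}")
  expect_equal(p$variant, "AA")
  expect_equal(p$units, "CC(OC(=O)CCC)")

  p <- parse_bigsmiles("{<OCCO<,>C(=O)CCCCC(=O)>}")
  expect_equal(p$variant, "AB_split")
  expect_equal(p$units, c("OCCO", "C(=O)CCCCC(=O)"))

  p <- parse_bigsmiles("{<CC(COC)O>,<C(COC)CO>}")
  expect_equal(p$variant, "AB_two_unit")

  p <- parse_bigsmiles("{<CCCO>}")
  expect_equal(p$variant, "AB_plain")

  # printed typeset spaces and version-1.1 descriptors are folded first
  expect_equal(parse_bigsmiles("{<OCCO <, > C( = O)CCCCC( = O) >}")$variant, "AB_split")
  expect_equal(parse_bigsmiles("{[<]CCCO[>]}")$variant, "AB_plain")

  expect_error(parse_bigsmiles("{$CC(OC(=O)CCC$"), class = "bigsmilesr_parse_error")
  expect_error(parse_bigsmiles("{$CC><$}"), class = "bigsmilesr_parse_error")
  expect_error(parse_bigsmiles("{<a>,<b>,<c>}"), class = "bigsmilesr_parse_error")
})

test_that("back-conversion restores a two-wildcard repeat unit", {
  expect_equal(bigsmiles_to_smiles("{$CC(OC(=O)CCC)$}"), "*CC(OC(=O)CCC)*")
  expect_equal(bigsmiles_to_smiles("{<OCCO<,>C(=O)CCCCC(=O)>}"),
               "*OCCOC(=O)CCCCC(=O)*")
  expect_equal(bigsmiles_to_smiles("{<CC(COC)O>,<C(COC)CO>}"), "*CC(COC)O*")
  out <- bigsmiles_to_smiles("{<CCCO>}")
  expect_true(validate_smiles(out)$valid)
  expect_equal(sum(smiles_tokens(out)$type == "wildcard"), 2L)
  # a structurally infeasible printed string fails loudly
  expect_error(bigsmiles_to_smiles("{$CC(OC(=O)CCC$}"), class = "bigsmilesr_parse_error")
})

test_that("parse inverts assembly on variant and units", {
  cases <- list(
    list(variant = "AA", units = "CC(CC)"),
    list(variant = "AB_plain", units = "CCCO"),
    list(variant = "AB_split", units = c("OCCO", "C(=O)CCCCC(=O)")),
    list(variant = "AB_two_unit", units = c("CC(COC)O", "C(COC)CO"))
  )
  for (cs in cases) {
    p <- parse_bigsmiles(assemble_bigsmiles(cs$variant, cs$units))
    expect_equal(p$variant, cs$variant)
    expect_equal(p$units, cs$units)
  }
})

test_that("structural equivalence tolerates ordering but not AA/AB disagreement", {
  expect_true(structurally_equivalent("{$CC(C(=O)OCC(C)C)(C)$}",
                                      "{$CC(C)(C(=O)OCC(C)C)$}"))
  expect_false(structurally_equivalent("{$CC$}", "{<CC>}"))
  expect_true(structurally_equivalent("*CCCO*", "*CCOC*"))
  # mixed SMILES / BigSMILES comparison converts first
  expect_true(structurally_equivalent("{<CCCO>}", "*COCC*"))
  expect_error(structurally_equivalent("{<CC", "*CC*"),
               class = "bigsmilesr_parse_error")
})

test_that("conversion then back-conversion preserves the polymer on all fixtures", {
  fx <- fixture_units()
  conv <- smiles_to_bigsmiles(fx$unit)
  expect_true(all(conv$status == "converted"))
  back <- bigsmiles_to_smiles(conv$bigsmiles)
  expect_equal(cycle_key(back), cycle_key(fx$unit))
  # when no rotation was needed and no two-unit pair emitted, even the
  # molecule (not just the polymer) survives
  same_mol <- (is.na(conv$rotation_used) | conv$rotation_used == 0L) &
    conv$variant != "AB_two_unit"
  expect_equal(unit_key(back[same_mol]), unit_key(fx$unit[same_mol]))
})
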