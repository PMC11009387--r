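test_that("normalization strips typeset whitespace, single bonds and bracketed wildcards", {
  expect_equal(normalize_smiles("OCCOC( = O)CCCCC( = O)"), "OCCOC(=O)CCCCC(=O)")
  expect_equal(normalize_smiles("C-C"), "CC")
  expect_equal(normalize_smiles("[*]CC[*]"), "*CC*")
  # charges inside bracket atoms are untouched
  expect_equal(normalize_smiles("CC([O-])=O"), "CC([O-])=O")
  expect_equal(normalize_smiles("*CC(OC( = O)CCC)*"), "*CC(OC(=O)CCC)*")
})

test_that("tokenizer splits units into the expected token classes", {
  toks <- smiles_tokens("*CC(OC(=O)CCC)*")
  expect_equal(nrow(toks), 15L)
  expect_equal(which(toks$type == "wildcard"), c(1L, 15L))

  expect_equal(nrow(smiles_tokens("")), 0L)

  toks2 <- smiles_tokens("*CC(*)(C)C(=O)OCC(C)C")
  expect_equal(sum(toks2$type == "wildcard"), 2L)

  # two-character atoms and %nn labels are single tokens
  toks3 <- smiles_tokens("ClC%12CC%12Br")
  expect_equal(toks3$text[1], "Cl")
  expect_true("%12" %in% toks3$text)
  expect_equal(toks3$text[nrow(toks3)], "Br")

  expect_error(smiles_tokens("C[Qx"), "bracket")
})

test_that("detokenizing a token table restores the source string", {
  for (s in c(fixture_units()$unit, "c1ccc2c(c1)cccc2", "C/C=C/C", "[13CH3]O")) {
    expect_identical(detokenize_smiles(smiles_tokens(s)), s)
  }
})

test_that("grammar validation passes well-formed units and names violations", {
  v <- validate_smiles(c("*CC(CC)*", "*CC)C*", "1CC1COC", "*CC(C*", "C()C", "CC*CC"))
  expect_equal(v$valid, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_match(v$diagnostic[2], "unmatched")
  expect_match(v$diagnostic[3], "ring label")
  expect_match(v$diagnostic[4], "unclosed")
  expect_match(v$diagnostic[5], "empty branch")
  expect_match(v$diagnostic[6], "monovalent")
  # every packaged fixture passes
  expect_true(all(validate_smiles(fixture_units()$unit)$valid))
})

test_that("unit keys identify the molecule; cycle keys identify the polymer", {
  expect_false(unit_key("*CCCO*") == unit_key("*CCOC*"))
  expect_equal(cycle_key("*CCCO*"), cycle_key("*CCOC*"))
  expect_equal(cycle_key("*CCCO*"), cycle_key("*COCC*"))
  expect_equal(unit_key("*CC(CC)*"), unit_key("*C(CC)C*"))
  # aromatic and kekulized spellings of one structure share keys
  expect_equal(unit_key("*CC(*)n1c2ccccc2c2ccccc21"),
               unit_key("*CC(*)N1C2=CC=CC=C2C2=CC=CC=C21"))
  ek <- equivalence_key("*CC(CC)*")
  expect_named(ek, c("smiles", "unit_key", "cycle_key"))
  expect_true(is.na(unit_key("*C)C*")))
})

test_that("reverse_unit traverses from the opposite terminal, preserving the molecule", {
  expect_equal(reverse_unit("*CCCO*"), "*OCCC*")
  expect_equal(reverse_unit("*CC(COC)O*"), "*OC(COC)C*")
  expect_equal(reverse_unit("*C*"), "*C*")
  for (u in fixture_units()$unit) {
    rel <- relocate_asterisks(u)
    if (rel$status != "ok") next
    v <- paste0("*", rel$core, "*")
    expect_equal(unit_key(reverse_unit(v)), unit_key(v))
  }
  expect_error(reverse_unit("*CC(*)C"), class = "bigsmilesr_contract")
})

test_that("single-character rotations are validated against grammar and structure", {
  r <- rotate_unit("CCCO", 0:1)
  expect_equal(r$text, c("CCCO", "CCOC"))
  expect_true(all(r$valid))
  r2 <- rotate_unit("CC(C)O", 3)
  expect_false(r2$valid)
  # a shift that moves only a ring digit must not pass as the same polymer
  rr <- unit_rotations("C1CC1CO")
  lead <- substr(rr$text, 1, 1)
  expect_false(any(rr$valid[lead %in% c("(", ")", as.character(0:9), "%")]))
})

test_that("cycle-key equality decisions agree with an independent RDKit oracle", {
  units <- c("*CCCO*", "*CCOC*", "*COCC*", "*CC(COC)O*", "*C(COC)CO*",
             "*CC(OC)O*", "*OCCOC(=O)CCCCC(=O)*", "*CCCCC(=O)OCCOC(=O)*",
             "*CC(CC)*", "*C(CC)C*", "*CC(OC(=O)CCC)*")
  mine <- cycle_key(units)
  theirs <- rdkit_cycle_oracle(units)
  expect_false(any(is.na(mine)))
  expect_false(any(theirs == "NA"))
  # both oracles must induce the same partition into equivalence classes
  for (i in seq_along(units)) {
    for (j in seq_len(i - 1L)) {
      expect_identical(mine[i] == mine[j], theirs[i] == theirs[j],
                       label = paste(units[i], "vs", units[j]))
    }
  }
})
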