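test_that("the two-point filter accepts exactly-two-wildcard valid units", {
  f <- filter_polymerization_points(c("*CC(CC)*", "*CC(*)C*", "CCO", "*CC)C*"))
  expect_equal(f$accepted, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(f$reason[2], "wrong_point_count(3)")
  expect_equal(f$reason[3], "wrong_point_count(0)")
  expect_equal(f$reason[4], "invalid_grammar")
})

test_that("one branch-swap step exchanges the asterisk branch with the chain remainder", {
  expect_equal(branch_swap_step("*CC(*)(C)C(=O)OCC(C)C"),
               "*CC(C(=O)OCC(C)C)(C)*")
  s2 <- branch_swap_step("*CC(*)n1c2ccccc2c2ccccc21")
  expect_equal(s2, "*CC(n1c2ccccc2c2ccccc21)*")
  expect_equal(unit_key(s2), unit_key("*CC(*)n1c2ccccc2c2ccccc21"))
  # identity on already-terminal input
  expect_equal(branch_swap_step("*CC(OC(=O)CCC)*"), "*CC(OC(=O)CCC)*")
  # an asterisk on a ring atom: the ring remainder becomes the branch
  s3 <- branch_swap_step("*C1CCC(*)CC1")
  expect_true(validate_smiles(s3)$valid)
  expect_equal(unit_key(s3), unit_key("*C1CCC(*)CC1"))
})

test_that("asterisk relocation yields a grammar-valid, molecule-preserving core", {
  cases <- c(
    "*CC(OC(=O)CCC)*"          , "CC(OC(=O)CCC)",
    "*CC(*)(Cl)C(=O)OC1CCCCC1" , "CC(C(=O)OC1CCCCC1)(Cl)",
    "*CC(*)(C)C(=O)OCC(C)C"    , "CC(C(=O)OCC(C)C)(C)"
  )
  inp <- cases[c(TRUE, FALSE)]; expct <- cases[c(FALSE, TRUE)]
  rel <- relocate_asterisks(inp)
  expect_equal(rel$core, expct)
  for (u in fixture_units()$unit) {
    r <- relocate_asterisks(u)
    expect_equal(r$status, "ok")
    restored <- paste0("*", r$core, "*")
    expect_true(validate_smiles(restored)$valid)
    expect_equal(unit_key(restored), unit_key(u), label = u)
  }
})

test_that("relocation is idempotent and the string-surgery path terminates", {
  rel <- relocate_asterisks("*CC(OC(=O)CCC)*")
  again <- relocate_asterisks(paste0("*", rel$core, "*"))
  expect_equal(again$core, rel$core)

  set.seed(11)
  units <- random_repeat_units(10, seed = 11)
  # force the asterisks off the ends by random reordering, then relocate
  # with pure string surgery; the swap loop must stop within its bound
  for (u in units) {
    alt <- randomized_orderings(u, 1, seed = 3)
    r <- relocate_asterisks(alt, canonical = FALSE)
    if (r$status == "ok") {
      expect_lte(r$relocation_steps, 2L * nchar(alt))
      expect_equal(unit_key(paste0("*", r$core, "*")), unit_key(u))
    }
  }
})

test_that("wildcards carrying non-single bonds are unconvertible", {
  r <- relocate_asterisks("*CC=*")
  expect_equal(r$status, "rejected")
  expect_equal(r$reason, "nonsingle_wildcard_bond")
})
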