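test_that("the main chain is the depth-zero atom run", {
  expect_equal(extract_main_chain("CC(OC(=O)CCC)")$element, c("C", "C"))
  expect_equal(extract_main_chain("OCCOC(=O)CCCCC(=O)")$element,
               c("O", "C", "C", "O", "C", "C", "C", "C", "C", "C"))
  expect_equal(extract_main_chain("CC(COC)O")$element, c("C", "C", "O"))
  # ring labels and bonds are skipped; bracket atoms report their element
  expect_equal(extract_main_chain("C1CC1[Si](C)C=C")$element,
               c("C", "C", "C", "Si", "C", "C"))
})

test_that("backbones of only carbon/silicon are AA, anything else AB", {
  expect_equal(classify_backbone(extract_main_chain("CC(OC(=O)CCC)")), "AA")
  expect_equal(classify_backbone(extract_main_chain("OCCOC(=O)CCCCC(=O)")), "AB")
  expect_equal(classify_backbone(extract_main_chain("C[Si](C)(C)")), "AA")
  # aromatic carbon counts as carbon
  expect_equal(classify_backbone(extract_main_chain("c1ccc(cc1)C")), "AA")
})

test_that("the ring-opening exception recognizes exactly the C,C,O backbone", {
  expect_true(detect_ring_opening(extract_main_chain("CC(COC)O")))
  expect_false(detect_ring_opening(extract_main_chain("CCCO")))
  expect_false(detect_ring_opening(extract_main_chain("OCC")))
})

test_that("the head/tail variant reverses and reorients an epoxide unit", {
  expect_equal(make_two_unit_variant("CC(COC)O"), "C(COC)CO")
  v <- make_two_unit_variant("CC(C)O")
  expect_equal(v, "C(C)CO")
  expect_equal(cycle_key(paste0("*", v, "*")), cycle_key("*CC(C)O*"))
  expect_equal(make_two_unit_variant("CCO"), "CCO") # symmetric unit
})

test_that("the end-group search decomposes AB units deterministically", {
  hit <- find_end_groups("OCCOC(=O)CCCCC(=O)")
  expect_equal(hit$first, "OCCO")
  expect_equal(hit$second, "C(=O)CCCCC(=O)")
  expect_equal(hit$rotation, 0L)
  expect_equal(hit$pattern, "polyester")

  rot <- find_end_groups("C(=O)CCCCC(=O)OCCO", move_parallel = -1L)
  expect_equal(rot$first, "OCCO")
  expect_equal(rot$second, "C(=O)CCCCC(=O)")
  expect_gt(rot$rotation, 0L)
  expect_null(find_end_groups("C(=O)CCCCC(=O)OCCO", move_parallel = 0L))

  # polyamide and carbonate entries
  amide <- find_end_groups("NCCCCCCNC(=O)CCCCC(=O)")
  expect_equal(amide$pattern, "polyamide")
  carb <- find_end_groups("OCCOC(=O)")
  expect_equal(carb$pattern, "polycarbonate")

  # a quinoxaline-terphenyl backbone has no tabulated end-group pair
  core283 <- relocate_asterisks(
    "*c1ccc(-c2ccc(-c3ccc(-c4cnc5ccc(-c6ccc7ncc(*)nc7c6)cc5n4)cc3)cc2)cc1")$core
  expect_null(find_end_groups(core283))
})

test_that("returned splits reassemble to the same polymer", {
  for (core in c("OCCOC(=O)CCCCC(=O)", "OCCCCOC(=O)CCC(=O)", "NCCCCCCNC(=O)CCCCC(=O)")) {
    hit <- find_end_groups(core)
    expect_false(is.null(hit))
    expect_equal(cycle_key(paste0("*", hit$first, hit$second, "*")),
                 cycle_key(paste0("*", core, "*")))
  }
})

test_that("assembly emits the four descriptor layouts without whitespace", {
  expect_equal(assemble_bigsmiles("AA", "CC(OC(=O)CCC)"), "{$CC(OC(=O)CCC)$}")
  expect_equal(assemble_bigsmiles("AB_split", c("OCCO", "C(=O)CCCCC(=O)")),
               "{<OCCO<,>C(=O)CCCCC(=O)>}")
  expect_equal(assemble_bigsmiles("AB_two_unit", c("CC(COC)O", "C(COC)CO")),
               "{<CC(COC)O>,<C(COC)CO>}")
  expect_equal(assemble_bigsmiles("AB_plain", "CCCO"), "{<CCCO>}")
  expect_error(assemble_bigsmiles("AB_split", "OCCO"), class = "bigsmilesr_contract")
})

test_that("conversion reproduces the corrected vinyl ground truths verbatim", {
  expect_equal(smiles_to_bigsmiles("*CC(*)(C)C(=O)OCC(C)C")$bigsmiles,
               "{$CC(C(=O)OCC(C)C)(C)$}")
  expect_equal(smiles_to_bigsmiles("*CC(*)(Cl)C(=O)OC1CCCCC1")$bigsmiles,
               "{$CC(C(=O)OC1CCCCC1)(Cl)$}")
  expect_equal(smiles_to_bigsmiles("*CC(COC)O*")$bigsmiles,
               "{<CC(COC)O>,<C(COC)CO>}")
  r <- smiles_to_bigsmiles("OCCOC(=O)CCCCC(=O)")
  expect_equal(r$status, "rejected")
  expect_equal(r$reason, "wrong_point_count(0)")
})

test_that("every output string shape matches its declared variant", {
  units <- c(fixture_units()$unit, random_repeat_units(20, seed = 5))
  conv <- smiles_to_bigsmiles(units)
  conv <- conv[conv$status == "converted", ]
  shape <- function(v) switch(v,
    AA = "^\\{\\$[^$<>{},]+\\$\\}$",
    AB_plain = "^\\{<[^$<>{},]+>\\}$",
    AB_split = "^\\{<[^$<>{},]+<,>[^$<>{},]+>\\}$",
    AB_two_unit = "^\\{<[^$<>{},]+>,<[^$<>{},]+>\\}$")
  for (i in seq_len(nrow(conv))) {
    expect_match(conv$bigsmiles[i], shape(conv$variant[i]), label = conv$smiles[i])
    # AA/AB partition follows the backbone composition
    aa <- classify_backbone(extract_main_chain(conv$core[i])) == "AA"
    expect_identical(grepl("$", conv$bigsmiles[i], fixed = TRUE), aa)
  }
})
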