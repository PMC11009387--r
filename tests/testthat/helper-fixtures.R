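# Shared fixture helpers: the packaged reference conversions with their
# typeset artifacts normalized away, ready as two-wildcard units.

fixture_units <- function() {
  fx <- polymer_fixtures()
  fx$unit <- normalize_smiles(fx$reference_smiles)
  implied <- fx$ends_implied & !grepl("*", fx$unit, fixed = TRUE)
  fx$unit[implied] <- paste0("*", fx$unit[implied], "*")
  fx
}

table1_units <- function() {
  fx <- fixture_units()
  fx[fx$provenance == "table1", , drop = FALSE]
}

# asterisk-stripped canonical cores of all fixtures that convert
fixture_cores <- function() {
  fx <- fixture_units()
  rel <- relocate_asterisks(fx$unit)
  rel$core[rel$status == "ok"]
}

# run the packaged RDKit oracle (independent implementation of the
# wildcard-joined cycle construction); returns one key string per input
rdkit_cycle_oracle <- function(units) {
  script <- testthat::test_path("oracle_cycle.py")
  out <- system2("python", args = script, input = units, stdout = TRUE)
  stopifnot(length(out) == length(units))
  out
}
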