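#' Convert repeat-unit SMILES to BigSMILES
#'
#' The full conversion pipeline: normalize, filter to exactly two
#' polymerization points, relocate the asterisks to the string ends
#' (canonical atom ordering, so reordered spellings of one unit give one
#' identical output), classify the backbone as AA or AB, apply the
#' ring-opening two-unit exception for C,C,O backbones, search AB units for
#' a reactive end-group pair by parallel displacement, and assemble the
#' BigSMILES string.
#'
#' @param x Character vector of repeat-unit SMILES (two `*` wildcards each).
#' @param move_parallel End-group search depth: `-1` searches all rotations,
#'   `0` only the unrotated core, a positive value caps the rotation count.
#' @param patterns Reactive end-group table, see [end_group_patterns()].
#' @param ends_implied If `TRUE`, a string containing no asterisk is
#'   interpreted as a preprocessed unit whose two ends are the polymerization
#'   points and the asterisks are re-appended before conversion.
#' @return A tibble with one row per input: `smiles`, `bigsmiles`,
#'   `variant` (`AA`, `AB_plain`, `AB_split`, `AB_two_unit`), `status`
#'   (`converted`/`rejected`), `reason`, `rotation_used`, `core`.
#' @examples
#' smiles_to_bigsmiles("*CC(*)(C)C(=O)OCC(C)C")
#' smiles_to_bigsmiles("OCCOC(=O)CCCCC(=O)", ends_implied = TRUE)
#' @export
smiles_to_bigsmiles <- function(x, move_parallel = -1L,
                                patterns = end_group_patterns(),
                                ends_implied = FALSE) {
  stopifnot(is.character(x))
  rows <- lapply(x, function(s) .convert_one(s, patterns, move_parallel, ends_implied))
  dplyr::bind_rows(rows)
}

.convert_one <- function(s_in, patterns, move_parallel, ends_implied) {
  s <- normalize_smiles(s_in)
  if (ends_implied && !grepl("*", s, fixed = TRUE)) {
    s <- paste0("*", s, "*")
  }
  fail <- function(reason) {
    tibble::tibble(smiles = s_in, bigsmiles = NA_character_,
                   variant = NA_character_, status = "rejected",
                   reason = reason, rotation_used = NA_integer_,
                   core = NA_character_)
  }
  rel <- relocate_asterisks(s)
  if (rel$status[1] != "ok") return(fail(rel$reason[1]))
  core <- rel$core[1]
  if (!nzchar(core)) return(fail("empty_core"))
  mc <- extract_main_chain(core)
  ptype <- classify_backbone(mc)
  rotation <- NA_integer_
  if (ptype == "AA") {
    variant <- "AA"
    big <- assemble_bigsmiles("AA", core)
  } else if (detect_ring_opening(mc)) {
    alt <- make_two_unit_variant(core)
    if (identical(alt, core)) {
      # symmetric unit: head-to-tail and tail-to-tail coincide
      variant <- "AB_plain"
      big <- assemble_bigsmiles("AB_plain", core)
    } else {
      variant <- "AB_two_unit"
      big <- assemble_bigsmiles("AB_two_unit", c(core, alt))
    }
  } else {
    split <- find_end_groups(core, patterns, move_parallel)
    if (is.null(split)) {
      variant <- "AB_plain"
      big <- assemble_bigsmiles("AB_plain", core)
    } else {
      variant <- "AB_split"
      rotation <- split$rotation
      big <- assemble_bigsmiles("AB_split", c(split$first, split$second))
    }
  }
  tibble::tibble(smiles = s_in, bigsmiles = big, variant = variant,
                 status = "converted", reason = NA_character_,
                 rotation_used = rotation, core = core)
}
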