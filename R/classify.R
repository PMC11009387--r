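# Classification of a relocated repeat unit and assembly of the BigSMILES
# string: AA vs AB from the backbone composition, the ring-opening (epoxide)
# two-unit exception, and the parallel-displacement end-group search.

#' Backbone atoms of a repeat-unit core
#'
#' The main chain of a relocated repeat unit is, by construction, the run of
#' atoms outside all parentheses, read between the two (implied) terminal
#' polymerization points. Bond symbols and ring labels are skipped.
#'
#' @param core The asterisk-stripped core string.
#' @return A tibble with columns `element` and `aromatic`, one row per
#'   backbone atom in order.
#' @examples
#' extract_main_chain("CC(OC(=O)CCC)")
#' @export
extract_main_chain <- function(core) {
  stopifnot(is.character(core), length(core) == 1L)
  toks <- smiles_tokens(normalize_smiles(core))
  depth <- cumsum(toks$type == "branch_open") - cumsum(toks$type == "branch_close")
  keep <- depth == 0L & toks$type %in% c("atom", "aromatic_atom", "bracket_atom")
  tibble::tibble(
    element = vapply(toks$text[keep], .element_of, character(1), USE.NAMES = FALSE),
    aromatic = vapply(toks$text[keep], .is_aromatic_token, logical(1), USE.NAMES = FALSE)
  )
}

#' Classify the polymerization type from the backbone
#'
#' A repeat unit whose main chain consists exclusively of carbon or silicon
#' is classed AA (chain-growth / addition; polyolefins and polycarbosilanes
#' are made by Ziegler-Natta or ring-opening polymerization); any
#' heteroatom in the backbone makes it AB (step-growth / condensation).
#' Aromatic carbon counts as carbon. This is a structural default: units
#' polymerized under special conditions (e.g. specific catalysts) may need
#' manual reclassification downstream.
#'
#' @param main_chain A backbone tibble from [extract_main_chain()].
#' @return `"AA"` or `"AB"`.
#' @examples
#' classify_backbone(extract_main_chain("CC(CC)"))
#' @export
classify_backbone <- function(main_chain) {
  stopifnot(nrow(main_chain) > 0L)
  if (all(main_chain$element %in% c("C", "Si"))) "AA" else "AB"
}

#' Detect the ring-opening (asymmetric epoxide) exception
#'
#' Polyethers formed by ring-opening of epoxides have a backbone of exactly
#' C,C,O; for an asymmetric epoxide both head-to-tail and tail-to-tail
#' enchainment matter, so such units are written as a two-unit BigSMILES
#' object rather than searched for end groups.
#'
#' @param main_chain A backbone tibble from [extract_main_chain()].
#' @return `TRUE` for a C,C,O backbone (non-aromatic), else `FALSE`.
#' @export
detect_ring_opening <- function(main_chain) {
  nrow(main_chain) == 3L && !any(main_chain$aromatic) &&
    identical(main_chain$element, c("C", "C", "O"))
}

#' Alternate-orientation unit for ring-opened epoxides
#'
#' Reverses the unit's traversal and rotates the result by single characters
#' until the backbone again reads C,C,O; the pair (core, variant) then
#' expresses the head-to-tail and tail-to-tail configurations. A symmetric
#' unit returns the original core unchanged.
#'
#' @param core A core whose backbone is C,C,O.
#' @return The alternate unit string.
#' @examples
#' make_two_unit_variant("CC(COC)O") # "C(COC)CO"
#' @export
make_two_unit_variant <- function(core) {
  core <- normalize_smiles(core)
  rev <- .reverse_core(core)
  ref <- cycle_key(paste0("*", core, "*"))
  for (k in 0:(nchar(rev) - 1L)) {
    cand <- .rotate_chars(rev, k)
    u <- paste0("*", cand, "*")
    if (!.smiles_ok(u)) next
    mc <- extract_main_chain(cand)
    if (!detect_ring_opening(mc)) next
    if (identical(cycle_key(u), ref)) return(cand)
  }
  core # no valid reoriented reversal: treat as symmetric
}

#' Search for a reactive end-group pair by parallel displacement
#'
#' Iterates rotations `k = 0, 1, 2, ...` of the core (the displacement unit
#' is a single character), skipping rotations that break the grammar or no
#' longer describe the same polymer, and at each surviving rotation tries
#' the pattern-table entries in order, looking for a two-fragment
#' decomposition in which the first fragment fully matches the entry's
#' first template and the second fragment its second template. The first
#' hit -- first table entry, then lowest rotation, then leftmost split
#' point -- is returned; if the search exhausts its rotations the unit is
#' simply an undecomposed AB type.
#'
#' @param core The asterisk-stripped core.
#' @param patterns Pattern table from [end_group_patterns()].
#' @param move_parallel `-1` to search all rotations, `0` for only the
#'   unrotated string (fast path for simulated data), or a positive cap on
#'   the rotation count.
#' @return `NULL`, or a list with `first`, `second`, `rotation`, `pattern`.
#' @examples
#' find_end_groups("OCCOC(=O)CCCCC(=O)")
#' @export
find_end_groups <- function(core, patterns = end_group_patterns(),
                            move_parallel = -1L) {
  core <- normalize_smiles(core)
  n <- nchar(core)
  if (n < 2L) return(NULL)
  ks <- if (move_parallel < 0L) 0:(n - 1L) else 0:min(move_parallel, n - 1L)
  pat <- patterns
  pat$a_head_n <- vapply(pat$a_head, .ntok, integer(1))
  pat$a_tail_n <- vapply(pat$a_tail, .ntok, integer(1))
  pat$b_head_n <- vapply(pat$b_head, .ntok, integer(1))
  pat$b_tail_n <- vapply(pat$b_tail, .ntok, integer(1))
  ref <- NULL # cycle key of the unrotated unit, computed on demand
  for (k in ks) {
    rot <- .rotate_chars(core, k)
    u <- paste0("*", rot, "*")
    if (!.smiles_ok(u)) next
    toks <- smiles_tokens(rot)
    nt <- nrow(toks)
    if (nt < 2L) next
    depth <- cumsum(toks$type == "branch_open") - cumsum(toks$type == "branch_close")
    cuts <- which(depth[-nt] == 0L) # boundary after token t
    if (!length(cuts)) next
    # fragment endpoints must be atoms, and ring labels must not cross
    ring_lab <- ifelse(toks$type == "ring", toks$text, NA_character_)
    ok_cut <- vapply(cuts, function(t) {
      if (toks$type[t] == "bond" || toks$type[t + 1L] == "bond") return(FALSE)
      if (toks$type[t + 1L] %in% c("ring", "branch_close")) return(FALSE)
      labs <- ring_lab[seq_len(t)]
      labs <- labs[!is.na(labs)]
      !length(labs) || all(table(labs) %% 2L == 0L)
    }, logical(1))
    cuts <- cuts[ok_cut]
    if (!length(cuts)) next
    rotation_bad <- FALSE
    for (e in seq_len(nrow(pat))) {
      for (t in cuts) {
        a <- paste(toks$text[seq_len(t)], collapse = "")
        b <- paste(toks$text[seq(t + 1L, nt)], collapse = "")
        hit <- .match_fragment(a, t, pat$a_head[e], pat$a_tail[e], pat$a_exact[e],
                               pat$a_head_n[e], pat$a_tail_n[e]) &&
               .match_fragment(b, nt - t, pat$b_head[e], pat$b_tail[e], pat$b_exact[e],
                               pat$b_head_n[e], pat$b_tail_n[e])
        if (hit) {
          if (is.null(ref)) ref <- cycle_key(paste0("*", core, "*"))
          key <- cycle_key(u)
          if (is.na(key) || is.na(ref) || key != ref) {
            # this rotation altered the structure: skip it entirely
            rotation_bad <- TRUE
            break
          }
          return(list(first = a, second = b, rotation = as.integer(k),
                      pattern = pat$name[e]))
        }
      }
      if (rotation_bad) break
    }
  }
  NULL
}

#' Assemble the final BigSMILES string
#'
#' Curly brackets replace the two polymerization points; `$` descriptors
#' mark AA bonding, `<`/`>` descriptors AB bonding, the `<,>` separator a
#' resolved reactive end-group pair, and a comma between two bracketed
#' units the ring-opening head/tail pair. Output never contains whitespace.
#'
#' @param variant One of `"AA"`, `"AB_plain"`, `"AB_split"`, `"AB_two_unit"`.
#' @param units Character vector: one unit string, or two fragments/units
#'   for the split and two-unit variants.
#' @return The BigSMILES string.
#' @examples
#' assemble_bigsmiles("AA", "CC(OC(=O)CCC)")
#' assemble_bigsmiles("AB_split", c("OCCO", "C(=O)CCCCC(=O)"))
#' @export
assemble_bigsmiles <- function(variant, units) {
  variant <- match.arg(variant, c("AA", "AB_plain", "AB_split", "AB_two_unit"))
  units <- normalize_smiles(units)
  need <- if (variant %in% c("AB_split", "AB_two_unit")) 2L else 1L
  if (length(units) != need || any(!nzchar(units))) {
    rlang::abort(paste0(variant, " needs ", need, " non-empty unit(s)"),
                 class = "bigsmilesr_contract")
  }
  switch(variant,
    AA = paste0("{$", units[1], "$}"),
    AB_plain = paste0("{<", units[1], ">}"),
    AB_split = paste0("{<", units[1], "<,>", units[2], ">}"),
    AB_two_unit = paste0("{<", units[1], ">,<", units[2], ">}")
  )
}
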