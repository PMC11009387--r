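# Structural-equivalence oracles.
#
# Two different spellings of a repeat unit are the same molecule (unit_key),
# and two different rotations of a repeat unit are different molecules but
# the same polymer (cycle_key). Both keys are canonical SMILES computed by
# OpenBabel, which also absorbs aromatic-vs-kekulized spelling differences.

# Canonical SMILES via OpenBabel; NA when the string does not parse.
.ob_canonical <- function(s) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = s),
    error = function(e) ""
  )
  out <- sub("[\t\n].*$", "", out)
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else out
}

#' Canonical molecule key of a repeat unit
#'
#' `unit_key()` is identical for any two SMILES spellings of the same
#' two-wildcard repeat-unit molecule (branch order, traversal direction and
#' aromatic vs. kekulized spelling do not matter). Returns `NA` for strings
#' OpenBabel cannot parse.
#'
#' @param x Character vector of repeat-unit SMILES.
#' @return Character vector of canonical keys.
#' @examples
#' unit_key("*CC(CC)*") == unit_key("*C(CC)C*")
#' @export
unit_key <- function(x) {
  vapply(normalize_smiles(x), .ob_canonical, character(1), USE.NAMES = FALSE)
}

# Remove atoms from a graph, reindexing; returns list(graph, map) where
# map[old id] = new id (NA for dropped atoms).
.drop_atoms <- function(g, ids) {
  keep <- setdiff(g$atoms$id, ids)
  map <- rep(NA_integer_, nrow(g$atoms))
  map[keep] <- seq_along(keep)
  atoms <- g$atoms[keep, , drop = FALSE]
  atoms$id <- seq_len(nrow(atoms))
  bd <- g$bonds[!(g$bonds$a %in% ids | g$bonds$b %in% ids), , drop = FALSE]
  bd$a <- map[bd$a]; bd$b <- map[bd$b]
  deg <- tabulate(c(bd$a, bd$b), nbins = nrow(atoms))
  atoms$degree <- deg
  list(graph = list(atoms = atoms, bonds = bd), map = map)
}

.wildcard_attachments <- function(g) {
  w <- g$atoms$id[g$atoms$wildcard]
  if (length(w) != 2L) {
    rlang::abort(paste0("repeat unit must carry exactly 2 wildcards, found ", length(w)),
                 class = "bigsmilesr_contract")
  }
  adj <- .adjacency(g)
  att <- vapply(w, function(v) .edge_other(g, adj[[v]][1], v), integer(1))
  ord <- vapply(w, function(v) g$bonds$order[adj[[v]][1]], character(1))
  list(wildcards = w, attachments = att, orders = ord)
}

#' Rotation-invariant polymer key of a repeat unit
#'
#' The two polymerization points of a repeat unit are replaced by a bond
#' joining their attachment atoms, closing the unit into a ring, and the
#' ring is canonicalized. Every valid parallel displacement (rotation) of
#' the unit -- and its traversal reversal -- closes into the same ring, so
#' all spellings of one polymer share one `cycle_key`, while genuinely
#' different polymers do not. Two degenerate unit shapes cannot close into
#' a simple ring and receive tagged keys instead: both wildcards on a
#' single backbone atom (`loop:`), and wildcards on two already-bonded
#' atoms, the usual vinyl-backbone case, whose closure would need a double
#' edge (`fused:`, keyed with the attachment atoms marked).
#'
#' @param x Character vector of two-wildcard repeat-unit SMILES.
#' @return Character vector of canonical keys (`NA` if unparseable).
#' @examples
#' cycle_key("*CCCO*") == cycle_key("*CCOC*")
#' unit_key("*CCCO*") == unit_key("*CCOC*")
#' @export
cycle_key <- function(x) {
  vapply(normalize_smiles(x), function(s) {
    chk <- validate_smiles(s)
    if (!chk$valid[1]) return(NA_character_)
    g <- .parse_graph(s)
    wa <- .wildcard_attachments(g)
    if (wa$attachments[1] == wa$attachments[2]) {
      d <- .drop_atoms(g, wa$wildcards)
      key <- .ob_canonical(.write_graph(d$graph))
      return(if (is.na(key)) NA_character_ else paste0("loop:", key))
    }
    bonded <- any((g$bonds$a == wa$attachments[1] & g$bonds$b == wa$attachments[2]) |
                  (g$bonds$b == wa$attachments[1] & g$bonds$a == wa$attachments[2]))
    if (bonded) {
      # closing would double an existing edge: mark the attachments instead
      g$atoms$text[g$atoms$wildcard] <- "[Xe]"
      g$atoms$element[g$atoms$wildcard] <- "Xe"
      g$atoms$wildcard <- FALSE
      key <- .ob_canonical(.write_graph(g))
      return(if (is.na(key)) NA_character_ else paste0("fused:", key))
    }
    d <- .drop_atoms(g, wa$wildcards)
    a1 <- d$map[wa$attachments[1]]; a2 <- d$map[wa$attachments[2]]
    d$graph$bonds <- dplyr::bind_rows(
      d$graph$bonds,
      tibble::tibble(a = a1, b = a2, order = "")
    )
    .ob_canonical(.write_graph(d$graph, start = a1))
  }, character(1), USE.NAMES = FALSE)
}

#' Both equivalence keys of a repeat unit
#'
#' @param x Character vector of two-wildcard repeat-unit SMILES.
#' @return A tibble with columns `smiles`, `unit_key` and `cycle_key`.
#' @export
equivalence_key <- function(x) {
  tibble::tibble(smiles = x, unit_key = unit_key(x), cycle_key = cycle_key(x))
}
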