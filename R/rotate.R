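# String primitives on the asterisk-stripped repeat-unit core: traversal
# reversal and single-character parallel displacement.

# Split a token tibble (a core, no terminal wildcards expected) into
# top-level units: each unit is one backbone atom together with its ring
# labels and branch groups; links[i] is the bond symbol between unit i and
# unit i+1.
.toplevel_units <- function(tokens) {
  n <- nrow(tokens)
  units <- list(); links <- character()
  i <- 1L
  pending <- ""
  while (i <= n) {
    ty <- tokens$type[i]
    if (ty == "bond") { pending <- tokens$text[i]; i <- i + 1L; next }
    if (!ty %in% c("atom", "aromatic_atom", "bracket_atom", "wildcard")) {
      stop("unexpected token \"", tokens$text[i], "\" at top level", call. = FALSE)
    }
    start <- i
    i <- i + 1L
    # ring labels (with optional bond prefix) directly after the atom
    repeat {
      if (i <= n && tokens$type[i] == "ring") { i <- i + 1L; next }
      if (i + 1L <= n && tokens$type[i] == "bond" && tokens$type[i + 1L] == "ring") {
        i <- i + 2L; next
      }
      break
    }
    # branch groups
    while (i <= n && tokens$type[i] == "branch_open") {
      depth <- 1L; i <- i + 1L
      while (i <= n && depth > 0L) {
        if (tokens$type[i] == "branch_open") depth <- depth + 1L
        if (tokens$type[i] == "branch_close") depth <- depth - 1L
        i <- i + 1L
      }
    }
    units[[length(units) + 1L]] <- paste(tokens$text[start:(i - 1L)], collapse = "")
    if (length(units) > 1L) links[[length(units) - 1L]] <- pending
    pending <- ""
  }
  list(units = units, links = links)
}

.reverse_core <- function(core) {
  if (!nzchar(core)) return(core)
  parts <- .toplevel_units(smiles_tokens(core))
  u <- rev(unlist(parts$units))
  l <- rev(parts$links)
  out <- u[1]
  if (length(u) > 1L) {
    for (i in seq_along(l)) out <- paste0(out, l[i], u[i + 1L])
  }
  out
}

#' Rewrite a repeat unit traversed from the opposite terminal
#'
#' Reverses the order of the backbone atoms of a unit whose wildcards sit at
#' both string ends; each backbone atom keeps its ring labels and branches.
#' The result spells the same molecule ([unit_key()] is preserved).
#'
#' @param x Character vector of repeat-unit SMILES with terminal wildcards.
#' @return Character vector of reversed units.
#' @examples
#' reverse_unit("*CC(COC)O*") # "*OC(COC)C*"
#' @export
reverse_unit <- function(x) {
  vapply(normalize_smiles(x), function(s) {
    toks <- smiles_tokens(s)
    n <- nrow(toks)
    if (n < 2L || toks$type[1] != "wildcard" || toks$type[n] != "wildcard") {
      rlang::abort("reverse_unit() needs wildcards at both string ends",
                   class = "bigsmilesr_contract")
    }
    core <- if (n > 2L) paste(toks$text[2:(n - 1L)], collapse = "") else ""
    paste0("*", .reverse_core(core), "*")
  }, character(1), USE.NAMES = FALSE)
}

.rotate_chars <- function(s, k) {
  n <- nchar(s)
  if (n == 0L) return(s)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

#' Parallel displacement of a repeat-unit core
#'
#' Cyclically shifts the asterisk-stripped core by `k` single characters, the
#' displacement unit of the end-group search. A shifted string is valid when
#' it still obeys the chemical grammar (with wildcards re-appended at both
#' ends) *and* still describes the same polymer ([cycle_key()] unchanged) --
#' shifts that strand a parenthesis break the syntax, and shifts that move a
#' ring-closure digit can silently describe a different structure, so both
#' are flagged invalid rather than raising an error.
#'
#' @param s The asterisk-stripped core (single string).
#' @param k Integer vector of shift counts, `0 <= k < nchar(s)`.
#' @return A tibble with columns `k`, `text` and `valid`.
#' @examples
#' rotate_unit("CCCO", 0:3)
#' @export
rotate_unit <- function(s, k) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- normalize_smiles(s)
  ref <- cycle_key(paste0("*", s, "*"))
  texts <- vapply(k, function(kk) .rotate_chars(s, kk), character(1))
  valid <- vapply(texts, function(txt) {
    u <- paste0("*", txt, "*")
    if (!.smiles_ok(u)) return(FALSE)
    key <- cycle_key(u)
    !is.na(key) && !is.na(ref) && key == ref
  }, logical(1), USE.NAMES = FALSE)
  tibble::tibble(k = as.integer(k), text = texts, valid = valid)
}

#' All rotations of a core with validity flags
#'
#' @param s The asterisk-stripped core.
#' @return A tibble with one row per shift `k = 0 .. nchar(s) - 1`.
#' @export
unit_rotations <- function(s) {
  s <- normalize_smiles(s)
  rotate_unit(s, seq_len(nchar(s)) - 1L)
}
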