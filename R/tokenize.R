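#' Normalize a repeat-unit SMILES string
#'
#' Published polymer SMILES often carry typesetting artifacts: spaces inside
#' `( = O)` groups, explicit `-` single bonds, or the bracketed wildcard
#' spelling `[*]`. `normalize_smiles()` rewrites these without touching any
#' chemistry: whitespace is removed, explicit single-bond symbols outside
#' bracket atoms are dropped (single is the default bond and is elided), and
#' bracketed wildcards become the bare asterisk. Bracket atoms, isotopes and
#' charges are preserved verbatim; validity is *not* checked here.
#'
#' @param x Character vector of SMILES strings.
#' @return Character vector of the same length.
#' @examples
#' normalize_smiles("OCCOC( = O)CCCCC( = O)")
#' normalize_smiles(c("C-C", "[*]CC[*]"))
#' @export
normalize_smiles <- function(x) {
  stopifnot(is.character(x))
  out <- gsub("[[:space:] ]+", "", x)
  # bracketed wildcard (optionally with an atom map) -> bare asterisk
  out <- gsub("\\[\\*(:[0-9]+)?\\]", "*", out)
  # drop '-' only outside bracket atoms (inside brackets it is a charge)
  vapply(out, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(chars) == 0L) return("")
    depth <- cumsum(chars == "[") - cumsum(chars == "]")
    inside <- depth > 0 | chars == "]"
    paste(chars[!(chars == "-" & !inside)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# token regex, alternatives tried in order (two-char atoms before one-char)
.tok_pattern <- paste0(
  "\\[[^][]*\\]",        # bracket atom
  "|Cl|Br",              # two-character organic atoms
  "|%[0-9]{2}",          # two-digit ring label
  "|[BCNOPSFI]",         # organic subset
  "|[bcnops]",           # aromatic subset
  "|[0-9]",              # ring label
  "|\\*",                # wildcard / polymerization point
  "|[-=#:/\\\\]",        # bond symbols
  "|[()]"                # branches
)

.tok_type <- function(text) {
  dplyr::case_when(
    text == "*" ~ "wildcard",
    text == "(" ~ "branch_open",
    text == ")" ~ "branch_close",
    grepl("^\\[", text) ~ "bracket_atom",
    text %in% c("Cl", "Br") | grepl("^[BCNOPSFI]$", text) ~ "atom",
    grepl("^[bcnops]$", text) ~ "aromatic_atom",
    grepl("^%?[0-9]+$", text) ~ "ring",
    TRUE ~ "bond"
  )
}

#' Tokenize a normalized SMILES string
#'
#' Splits a SMILES string into the token classes the conversion workflow
#' manipulates: organic-subset atoms (two-character `Cl`/`Br` are single
#' tokens), aromatic atoms, bracket atoms (kept opaque), bond symbols, branch
#' parentheses, ring-closure labels (single digit or `%nn`) and the `*`
#' wildcard marking a polymerization point. Pasting the `text` column back
#' together is the inverse operation (see [detokenize_smiles()]).
#'
#' @param s A single SMILES string (normalized; see [normalize_smiles()]).
#' @return A tibble with columns `pos` (starting character position), `text`
#'   and `type`.
#' @examples
#' smiles_tokens("*CC(OC(=O)CCC)*")
#' @export
smiles_tokens <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  if (nchar(s) == 0L) {
    return(tibble::tibble(pos = integer(), text = character(), type = character()))
  }
  m <- gregexpr(.tok_pattern, s)[[1]]
  if (m[1] == -1L) {
    stop("no SMILES token recognized at position 1 of \"", s, "\"", call. = FALSE)
  }
  txt <- regmatches(s, gregexpr(.tok_pattern, s))[[1]]
  # every character must be covered by some token
  covered <- sum(attr(m, "match.length"))
  if (covered != nchar(s)) {
    bad <- setdiff(seq_len(nchar(s)),
                   unlist(mapply(seq, m, m + attr(m, "match.length") - 1L,
                                 SIMPLIFY = FALSE)))
    ch <- substr(s, bad[1], bad[1])
    if (ch == "[") {
      stop("malformed bracket atom at position ", bad[1], " of \"", s, "\"",
           call. = FALSE)
    }
    stop("unrecognized character \"", ch, "\" at position ", bad[1],
         " of \"", s, "\"", call. = FALSE)
  }
  if (any(grepl("^\\[[^]]*$", txt))) {
    stop("malformed bracket atom in \"", s, "\"", call. = FALSE)
  }
  tibble::tibble(pos = as.integer(m), text = txt, type = .tok_type(txt))
}

#' Reassemble a SMILES string from its tokens
#'
#' @param tokens A token tibble from [smiles_tokens()].
#' @return A single SMILES string.
#' @export
detokenize_smiles <- function(tokens) {
  paste(tokens$text, collapse = "")
}

# Internal: scan a token tibble for grammar violations; returns character
# vector of diagnostics (empty = pass). Positions refer to the source string.
.grammar_issues <- function(tokens) {
  issues <- character()
  n <- nrow(tokens)
  if (n == 0L) return(issues)
  type <- tokens$type
  pos <- tokens$pos
  atomish <- type %in% c("atom", "aromatic_atom", "bracket_atom", "wildcard")

  depth <- 0L
  last_open <- integer()
  for (i in seq_len(n)) {
    if (type[i] == "branch_open") {
      if (i == 1L || !(atomish[i - 1L] || type[i - 1L] %in% c("ring", "branch_close"))) {
        issues <- c(issues, paste0("branch opened with no preceding atom at position ", pos[i]))
      }
      depth <- depth + 1L
      last_open <- c(last_open, pos[i])
    } else if (type[i] == "branch_close") {
      if (depth == 0L) {
        issues <- c(issues, paste0("unmatched ')' at position ", pos[i]))
      } else {
        if (type[i - 1L] == "branch_open") {
          issues <- c(issues, paste0("empty branch at position ", pos[i - 1L]))
        }
        if (type[i - 1L] == "bond") {
          issues <- c(issues, paste0("branch ends in a bond symbol at position ", pos[i - 1L]))
        }
        depth <- depth - 1L
        last_open <- last_open[-length(last_open)]
      }
    } else if (type[i] == "bond") {
      if (i == n || !(atomish[i + 1L] || type[i + 1L] %in% c("ring", "branch_open"))) {
        issues <- c(issues, paste0("dangling bond symbol at position ", pos[i]))
      }
      # a bond may open a branch: "C(=O)" bonds the branch atom to its parent
      if (i == 1L ||
          !(atomish[i - 1L] || type[i - 1L] %in% c("ring", "branch_close", "branch_open"))) {
        issues <- c(issues, paste0("bond with no preceding atom at position ", pos[i]))
      }
    } else if (type[i] == "ring") {
      j <- i - 1L
      while (j >= 1L && type[j] == "bond") j <- j - 1L
      if (j < 1L || !(atomish[j] || type[j] == "ring")) {
        issues <- c(issues, paste0("ring label not attached to an atom at position ", pos[i]))
      }
    }
  }
  if (depth > 0L) {
    issues <- c(issues, paste0("unclosed '(' at position ", last_open[1]))
  }

  # ring labels must pair up
  ring <- tokens$text[type == "ring"]
  if (length(ring)) {
    cnt <- table(ring)
    odd <- names(cnt)[cnt %% 2L == 1L]
    if (length(odd)) {
      issues <- c(issues, paste0("dangling ring label ", paste(odd, collapse = ", ")))
    }
  }
  issues
}

#' Check a SMILES string against the repeat-unit grammar
#'
#' Performs the chemical-grammar gate of the conversion workflow: each string
#' must tokenize, branches must balance and be non-empty, bonds must sit
#' between atoms, ring-closure labels must pair up, and the string must parse
#' into a connected molecular graph in which every `*` wildcard is a
#' monovalent attachment point. Diagnostics are returned, not thrown.
#'
#' @param x Character vector of normalized SMILES strings.
#' @return A tibble with columns `smiles`, `valid` and `diagnostic` (`NA`
#'   when valid; otherwise the first violation, naming the offending
#'   position).
#' @examples
#' validate_smiles(c("*CC(CC)*", "*CC)C*", "1CC1COC"))
#' @export
validate_smiles <- function(x) {
  stopifnot(is.character(x))
  res <- lapply(x, function(s) {
    if (is.na(s)) return("missing input")
    toks <- tryCatch(smiles_tokens(s), error = function(e) conditionMessage(e))
    if (is.character(toks)) return(toks)
    iss <- .grammar_issues(toks)
    if (length(iss)) return(iss[1])
    g <- tryCatch(.graph_from_tokens(toks), error = function(e) conditionMessage(e))
    if (is.character(g)) return(g)
    wdeg <- g$atoms$degree[g$atoms$wildcard]
    if (any(wdeg != 1L)) {
      return("wildcard is not a monovalent attachment point")
    }
    if (!.graph_connected(g)) return("disconnected molecular graph")
    NA_character_
  })
  tibble::tibble(
    smiles = x,
    valid = vapply(res, function(r) is.na(r[1]), logical(1)),
    diagnostic = vapply(res, function(r) r[1], character(1))
  )
}

# Internal fast predicate
.smiles_ok <- function(s) {
  isTRUE(validate_smiles(s)$valid[1])
}
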