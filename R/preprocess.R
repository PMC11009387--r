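# Preprocessing: filter inputs to exactly two polymerization points and
# relocate both asterisks to the string ends, yielding the asterisk-stripped
# core on which classification operates.

.count_wildcards <- function(s) {
  sum(smiles_tokens(s)$type == "wildcard")
}

#' Filter repeat units on their polymerization-point count
#'
#' The workflow handles homopolymer repeat units with exactly two asterisk
#' polymerization points; anything else is filtered out. Grammar-invalid
#' strings (including strings OpenBabel cannot interpret as a molecule) are
#' likewise rejected.
#'
#' @param x Character vector of SMILES strings (normalized internally).
#' @return A tibble with columns `smiles`, `accepted` and `reason`
#'   (`NA` when accepted; otherwise `"wrong_point_count(n)"` or
#'   `"invalid_grammar"`).
#' @examples
#' filter_polymerization_points(c("*CC(CC)*", "*CC(*)C*", "CCO"))
#' @export
filter_polymerization_points <- function(x) {
  x <- normalize_smiles(x)
  res <- vapply(x, function(s) {
    toks <- tryCatch(smiles_tokens(s), error = function(e) NULL)
    if (is.null(toks)) return("invalid_grammar")
    nw <- sum(toks$type == "wildcard")
    if (nw != 2L) return(sprintf("wrong_point_count(%d)", nw))
    if (!.smiles_ok(s)) return("invalid_grammar")
    if (is.na(.ob_canonical(s))) return("invalid_grammar")
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(smiles = x, accepted = is.na(res), reason = res)
}

# --- ring-label hygiene -----------------------------------------------------

# Give every ring-closure pair a unique label so token groups can be
# reordered safely, then compress labels back to smallest-at-reopening.
.relabel_rings_unique <- function(tokens) {
  open <- list(); nxt <- 0L
  txt <- tokens$text
  for (i in which(tokens$type == "ring")) {
    lab <- txt[i]
    if (!is.null(open[[lab]]) && length(open[[lab]])) {
      j <- open[[lab]][1]
      open[[lab]] <- open[[lab]][-1]
      txt[i] <- txt[j] # already renamed at opening
    } else {
      nxt <- nxt + 1L
      new <- if (nxt <= 9L) as.character(nxt) else sprintf("%%%02d", nxt)
      open[[lab]] <- c(open[[lab]], i)
      txt[i] <- new
    }
  }
  tokens$text <- txt
  tokens
}

.compress_ring_labels <- function(tokens) {
  txt <- tokens$text
  assigned <- list()  # original label -> assigned digit (while open)
  in_use <- logical(0)
  for (i in which(tokens$type == "ring")) {
    lab <- txt[i]
    if (!is.null(assigned[[lab]])) {
      d <- assigned[[lab]]
      assigned[[lab]] <- NULL
      in_use[d] <- FALSE
    } else {
      free <- which(!in_use)
      d <- if (length(free)) free[1] else length(in_use) + 1L
      if (d > length(in_use)) in_use <- c(in_use, logical(d - length(in_use)))
      in_use[d] <- TRUE
      assigned[[lab]] <- d
    }
    txt[i] <- if (d <= 9L) as.character(d) else sprintf("%%%02d", d)
  }
  tokens$text <- txt
  tokens
}

# retokenize after textual surgery (positions go stale)
.retok <- function(txt_vector) {
  smiles_tokens(paste(txt_vector, collapse = ""))
}

# --- the permutative branch swap -------------------------------------------

# Find the innermost branch group containing token index i; returns
# c(open, close) token indices, or NULL at top level.
.enclosing_group <- function(tokens, i) {
  depth <- 0L
  for (j in seq(i - 1L, 1L)) {
    if (i == 1L) break
    if (tokens$type[j] == "branch_close") depth <- depth + 1L
    if (tokens$type[j] == "branch_open") {
      if (depth == 0L) {
        # matching close
        d <- 1L; k <- j + 1L
        while (d > 0L) {
          if (tokens$type[k] == "branch_open") d <- d + 1L
          if (tokens$type[k] == "branch_close") d <- d - 1L
          k <- k + 1L
        }
        return(c(j, k - 1L))
      }
      depth <- depth - 1L
    }
  }
  NULL
}

#' One permutative branch-swap step
#'
#' A non-terminal asterisk sits at the tail of some branch (for a vinyl-type
#' canonical SMILES it is the lone branch `(*)`). One swap step exchanges
#' that branch's content with the main-chain remainder to the right of the
#' branch list: the remainder becomes a branch and the asterisk-bearing
#' content moves onto the main chain, ending in the asterisk. Ring labels
#' are renumbered so pairs stay unambiguous. The molecule is unchanged
#' ([unit_key()] preserved).
#'
#' @param s A single repeat-unit SMILES with a non-terminal wildcard.
#' @return The SMILES after one swap step.
#' @examples
#' branch_swap_step("*CC(*)(C)C(=O)OCC(C)C")
#' @export
branch_swap_step <- function(s) {
  s <- normalize_smiles(s)
  tokens <- .relabel_rings_unique(smiles_tokens(s))
  n <- nrow(tokens)
  wpos <- which(tokens$type == "wildcard")
  wpos <- wpos[wpos != 1L & wpos != n]
  if (!length(wpos)) return(detokenize_smiles(.compress_ring_labels(tokens)))
  i <- wpos[1]
  grp <- .enclosing_group(tokens, i)
  if (is.null(grp)) {
    rlang::abort("asterisk is outside all parentheses but not at either end; no main chain to swap",
                 class = "bigsmilesr_no_main_chain")
  }
  gopen <- grp[1]; gclose <- grp[2]
  if (i != gclose - 1L) {
    rlang::abort("asterisk is not at the tail of its branch; no swap applies",
                 class = "bigsmilesr_no_main_chain")
  }
  content <- if (gclose - gopen > 1L) seq(gopen + 1L, gclose - 1L) else integer()
  # parent-level bounds: the group enclosing gopen (or the whole string)
  parent <- .enclosing_group(tokens, gopen)
  pend <- if (is.null(parent)) n else parent[2] - 1L
  # sibling branch groups immediately after this one stay in place
  j <- gclose + 1L
  while (j <= pend && tokens$type[j] == "branch_open") {
    d <- 1L; j <- j + 1L
    while (d > 0L) {
      if (tokens$type[j] == "branch_open") d <- d + 1L
      if (tokens$type[j] == "branch_close") d <- d - 1L
      j <- j + 1L
    }
  }
  siblings <- if (j > gclose + 1L) seq(gclose + 1L, j - 1L) else integer()
  remainder <- if (j <= pend) seq(j, pend) else integer()
  left <- if (gopen > 1L) seq_len(gopen - 1L) else integer()
  tail_idx <- if (pend < n) seq(pend + 1L, n) else integer()
  txt <- tokens$text
  new_txt <- c(
    txt[left],
    if (length(remainder)) c("(", txt[remainder], ")"),
    txt[siblings],
    txt[content],
    txt[tail_idx]
  )
  out <- .compress_ring_labels(.retok(new_txt))
  detokenize_smiles(out)
}

# --- canonical core construction -------------------------------------------

# Orientation comparator: byte-wise (locale-independent) comparison with
# '(' remapped above the letters, so "CC(...)" beats "C(...)C".
.core_less <- function(x, y) {
  xi <- utf8ToInt(chartr("()", "{|", x))
  yi <- utf8ToInt(chartr("()", "{|", y))
  n <- min(length(xi), length(yi))
  if (n > 0L) {
    d <- which(xi[seq_len(n)] != yi[seq_len(n)])
    if (length(d)) return(xi[d[1]] < yi[d[1]])
  }
  length(xi) < length(yi)
}

# Canonical asterisk-stripped core of a two-wildcard unit. The string is
# first canonicalized by OpenBabel (fixing the atom ordering independently
# of the input spelling), then re-linearized by the core writer from each
# attachment terminal; the lexicographically smaller orientation wins.
# Returns list(core, alt) or NULL when OpenBabel cannot parse.
.canonical_unit <- function(s) {
  can <- .ob_canonical(s)
  if (is.na(can)) return(NULL)
  g <- .parse_graph(can)
  wa <- .wildcard_attachments(g)
  d <- .drop_atoms(g, wa$wildcards)
  a1 <- d$map[wa$attachments[1]]; a2 <- d$map[wa$attachments[2]]
  c1 <- .write_core(d$graph, a1, a2)
  if (a1 == a2) return(list(core = c1, alt = c1))
  c2 <- .write_core(d$graph, a2, a1)
  if (.core_less(c2, c1)) list(core = c2, alt = c1) else list(core = c1, alt = c2)
}

#' Relocate both asterisks to the string ends
#'
#' Produces the asterisk-stripped core whose two ends are the polymerization
#' points. With `canonical = TRUE` (the default used by the conversion
#' pipeline) the unit is first put into a canonical atom ordering so that
#' differently-ordered spellings of one repeat unit yield one identical
#' core. With `canonical = FALSE` the original string is kept and the
#' permutative branch swap ([branch_swap_step()]) is applied repeatedly, as
#' when tracing the textual procedure by hand.
#'
#' @param x Character vector of SMILES strings.
#' @param canonical Use the canonical rewrite (default) or pure string
#'   surgery.
#' @return A tibble with columns `smiles`, `core`, `relocation_steps`,
#'   `status` (`"ok"`/`"rejected"`) and `reason`.
#' @examples
#' relocate_asterisks("*CC(*)(C)C(=O)OCC(C)C")
#' @export
relocate_asterisks <- function(x, canonical = TRUE) {
  x <- normalize_smiles(x)
  flt <- filter_polymerization_points(x)
  rows <- lapply(seq_along(x), function(idx) {
    s <- x[idx]
    fail <- function(reason) {
      tibble::tibble(smiles = s, core = NA_character_,
                     relocation_steps = NA_integer_,
                     status = "rejected", reason = reason)
    }
    if (!flt$accepted[idx]) return(fail(flt$reason[idx]))
    g <- .parse_graph(s)
    wa <- .wildcard_attachments(g)
    if (any(nzchar(wa$orders))) return(fail("nonsingle_wildcard_bond"))
    if (canonical) {
      cu <- .canonical_unit(s)
      if (is.null(cu)) return(fail("invalid_grammar"))
      return(tibble::tibble(smiles = s, core = cu$core, relocation_steps = 0L,
                            status = "ok", reason = NA_character_))
    }
    cur <- s; steps <- 0L
    limit <- 2L * nchar(s)
    repeat {
      toks <- smiles_tokens(cur)
      nt <- nrow(toks)
      wp <- which(toks$type == "wildcard")
      if (all(wp %in% c(1L, nt))) break
      if (steps >= limit) return(fail("no_main_chain"))
      cur <- tryCatch(branch_swap_step(cur), error = function(e) NA_character_)
      if (is.na(cur)) return(fail("no_main_chain"))
      steps <- steps + 1L
    }
    toks <- smiles_tokens(cur)
    nt <- nrow(toks)
    if (toks$type[1] != "wildcard" || toks$type[nt] != "wildcard") {
      return(fail("no_main_chain"))
    }
    core <- if (nt > 2L) paste(toks$text[2:(nt - 1L)], collapse = "") else ""
    tibble::tibble(smiles = s, core = core, relocation_steps = steps,
                   status = "ok", reason = NA_character_)
  })
  dplyr::bind_rows(rows)
}
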