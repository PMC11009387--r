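# Parsing homopolymer BigSMILES back to repeat-unit SMILES, and the
# structural-equivalence check used by the validation procedures.

.normalize_bigsmiles <- function(b) {
  b <- gsub("[[:space:] ]+", "", b)
  # version-1.1 bracketed descriptors are accepted and folded to 1.0 forms
  b <- gsub("[$]", "$", b, fixed = TRUE)
  b <- gsub("[<]", "<", b, fixed = TRUE)
  b <- gsub("[>]", ">", b, fixed = TRUE)
  b
}

#' Parse a homopolymer BigSMILES string
#'
#' Recognizes the four stochastic-object shapes this workflow emits:
#' `{$unit$}` (AA), `{<unit>}` (AB), `{<a<,>b>}` (AB with a resolved
#' reactive end-group pair) and `{<u1>,<u2>}` (ring-opening head/tail
#' pair). Whitespace is stripped and version-1.1 bracketed descriptors
#' (`[$]`, `[<]`, `[>]`) are folded to their 1.0 forms first. Anything else
#' is rejected with a diagnostic.
#'
#' @param b A single BigSMILES string.
#' @return A list with `variant`, `units` (1 or 2 fragment strings) and
#'   `descriptors`.
#' @examples
#' parse_bigsmiles("{<OCCO<,>C(=O)CCCCC(=O)>}")
#' @export
parse_bigsmiles <- function(b) {
  stopifnot(is.character(b), length(b) == 1L)
  s <- .normalize_bigsmiles(b)
  n_open <- lengths(regmatches(s, gregexpr("{", s, fixed = TRUE)))
  n_close <- lengths(regmatches(s, gregexpr("}", s, fixed = TRUE)))
  if (n_open != 1L || n_close != 1L || !grepl("^\\{.*\\}$", s)) {
    rlang::abort(paste0("not a single curly-bracketed stochastic object: \"", b, "\""),
                 class = "bigsmilesr_parse_error")
  }
  inner <- substr(s, 2L, nchar(s) - 1L)
  u <- "([^{}<>$,]+)"
  m <- regmatches(inner, regexec(paste0("^\\$", u, "\\$$"), inner))[[1]]
  if (length(m)) {
    return(list(variant = "AA", units = m[2], descriptors = c("$", "$")))
  }
  m <- regmatches(inner, regexec(paste0("^<", u, "<,>", u, ">$"), inner))[[1]]
  if (length(m)) {
    return(list(variant = "AB_split", units = c(m[2], m[3]),
                descriptors = c("<", "<", ">", ">")))
  }
  m <- regmatches(inner, regexec(paste0("^<", u, ">,<", u, ">$"), inner))[[1]]
  if (length(m)) {
    return(list(variant = "AB_two_unit", units = c(m[2], m[3]),
                descriptors = c("<", ">", "<", ">")))
  }
  m <- regmatches(inner, regexec(paste0("^<", u, ">$"), inner))[[1]]
  if (length(m)) {
    return(list(variant = "AB_plain", units = m[2], descriptors = c("<", ">")))
  }
  rlang::abort(paste0("unknown bonding-descriptor layout in \"", b, "\""),
               class = "bigsmilesr_parse_error")
}

#' Convert BigSMILES back to repeat-unit SMILES
#'
#' The inverse direction of the workflow: the curly brackets become the two
#' asterisk polymerization points. For the split variant the two fragments
#' are concatenated; for the two-unit (ring-opening) variant the first unit
#' -- the original orientation -- is returned. The result always passes the
#' grammar check with exactly two wildcards.
#'
#' @param x Character vector of BigSMILES strings.
#' @return Character vector of repeat-unit SMILES.
#' @examples
#' bigsmiles_to_smiles("{<OCCO<,>C(=O)CCCCC(=O)>}")
#' @export
bigsmiles_to_smiles <- function(x) {
  vapply(x, function(b) {
    p <- parse_bigsmiles(b)
    out <- switch(p$variant,
      AA = paste0("*", p$units[1], "*"),
      AB_plain = paste0("*", p$units[1], "*"),
      AB_split = paste0("*", p$units[1], p$units[2], "*"),
      AB_two_unit = paste0("*", p$units[1], "*")
    )
    out <- normalize_smiles(out)
    chk <- validate_smiles(out)
    if (!chk$valid[1]) {
      rlang::abort(paste0("BigSMILES unit is not a valid repeat unit: ",
                          chk$diagnostic[1]),
                   class = "bigsmilesr_parse_error")
    }
    out
  }, character(1), USE.NAMES = FALSE)
}

# Resolve a SMILES or BigSMILES input to (unit, AA-flag) for comparison.
.as_unit <- function(x) {
  if (grepl("{", x, fixed = TRUE)) {
    p <- parse_bigsmiles(x)
    list(unit = bigsmiles_to_smiles(x), aa = p$variant == "AA")
  } else {
    s <- normalize_smiles(x)
    nw <- tryCatch(.count_wildcards(s), error = function(e) -1L)
    if (nw == 0L) s <- paste0("*", s, "*")
    else if (nw != 2L) {
      rlang::abort(paste0("expected a two-wildcard repeat unit: \"", x, "\""),
                   class = "bigsmilesr_parse_error")
    }
    list(unit = s, aa = NA)
  }
}

#' Structural equivalence of two polymer representations
#'
#' Two SMILES or BigSMILES strings are structurally equivalent when they
#' describe the same polymer: their rotation-invariant [cycle_key()]s match
#' and, when both carry bonding descriptors, the AA/AB distinction agrees.
#' The check is tolerant of ordering, rotation, aromatic-vs-kekulized
#' spelling and whitespace. Unparseable input raises a classed error.
#'
#' @param a,b Character vectors (recycled pairwise) of SMILES or BigSMILES.
#' @return Logical vector.
#' @examples
#' structurally_equivalent("{$CC(C(=O)OCC(C)C)(C)$}", "{$CC(C)(C(=O)OCC(C)C)$}")
#' @export
structurally_equivalent <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    ua <- .as_unit(a[i]); ub <- .as_unit(b[i])
    ka <- cycle_key(ua$unit); kb <- cycle_key(ub$unit)
    if (is.na(ka) || is.na(kb)) {
      rlang::abort("input does not parse as a molecule",
                   class = "bigsmilesr_parse_error")
    }
    same <- ka == kb
    if (!is.na(ua$aa) && !is.na(ub$aa)) same <- same && (ua$aa == ub$aa)
    same
  }, logical(1))
}
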