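#' Reactive end-group pattern table
#'
#' The AB-type end-group search asks whether a rotation of the repeat unit
#' decomposes into two fragments that each fully match one of a predefined
#' pair of reactive end-group templates (a diol facing a diacid, a diamine
#' facing a diacid, and so on). Each template anchors both fragment ends: a
#' fragment matches when it begins with `head`, ends with `tail`, and is
#' long enough that the two anchors do not overlap (`exact` templates must
#' equal the anchor outright). The table is ordered -- the first matching
#' entry wins -- and ships as a YAML config users can extend, since the
#' published form lists were assembled editorially from the step-growth
#' literature rather than printed in full.
#'
#' @param path Optional path to a YAML pattern file; defaults to the table
#'   packaged under `inst/extdata/end_group_patterns.yaml`.
#' @return A tibble with columns `name`, `a_head`, `a_tail`, `a_exact`,
#'   `b_head`, `b_tail`, `b_exact`.
#' @examples
#' end_group_patterns()
#' @export
end_group_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "end_group_patterns.yaml", package = "bigsmilesr")
  }
  raw <- yaml::read_yaml(path)
  if (!length(raw)) rlang::abort("end-group pattern table is empty",
                                 class = "bigsmilesr_contract")
  side <- function(entry, which) {
    s <- entry[[which]]
    list(head = s$head, tail = s$tail, exact = isTRUE(s$exact))
  }
  dplyr::bind_rows(lapply(raw, function(e) {
    a <- side(e, "first"); b <- side(e, "second")
    tibble::tibble(name = e$name,
                   a_head = a$head, a_tail = a$tail, a_exact = a$exact,
                   b_head = b$head, b_tail = b$tail, b_exact = b$exact)
  }))
}

.ntok <- function(s) nrow(smiles_tokens(s))

.match_fragment <- function(frag, frag_ntok, head, tail, exact, head_ntok, tail_ntok) {
  if (exact) return(identical(frag, head))
  startsWith(frag, head) && endsWith(frag, tail) &&
    frag_ntok >= head_ntok + tail_ntok
}
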