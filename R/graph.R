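# Molecular-graph layer used by the conversion workflow.
#
# A parsed SMILES is held as a light graph: an atom table (token text kept
# verbatim so bracket atoms, isotopes and charges survive a round trip) and a
# bond table. The writer re-linearizes a graph with deterministic traversal
# rules; chemistry-aware canonical ordering is delegated to OpenBabel (see
# keys.R) and this layer only controls the *spelling* of the output.

.element_of <- function(text) {
  if (text == "*") return("*")
  if (grepl("^\\[", text)) {
    m <- regmatches(text, regexec("^\\[[0-9]*([A-Za-z][a-z]?|\\*)", text))[[1]]
    if (length(m) < 2L) stop("cannot read element from bracket atom ", text, call. = FALSE)
    sym <- m[2]
    if (grepl("^[a-z]", sym)) {
      # aromatic bracket atom such as [nH]; element is the uppercase symbol
      return(toupper(substr(sym, 1, 1)))
    }
    return(sym)
  }
  if (grepl("^[a-z]$", text)) return(toupper(text))
  text
}

.is_aromatic_token <- function(text) {
  grepl("^[bcnops]$", text) || grepl("^\\[[0-9]*[a-z]", text)
}

# Parse a token tibble into a graph. Assumes .grammar_issues() came back
# clean; remaining problems (ring closure onto the same atom) are errors.
.graph_from_tokens <- function(tokens) {
  n_tok <- nrow(tokens)
  atoms <- list()
  bonds_a <- integer(); bonds_b <- integer(); bonds_o <- character()
  prev <- NA_integer_
  stack <- integer()
  pending <- ""
  ring_open <- list() # label -> list(atom, bond)
  add_bond <- function(a, b, o) {
    bonds_a[[length(bonds_a) + 1L]] <<- a
    bonds_b[[length(bonds_b) + 1L]] <<- b
    bonds_o[[length(bonds_o) + 1L]] <<- o
  }
  for (i in seq_len(n_tok)) {
    ty <- tokens$type[i]; tx <- tokens$text[i]
    if (ty %in% c("atom", "aromatic_atom", "bracket_atom", "wildcard")) {
      id <- length(atoms) + 1L
      atoms[[id]] <- list(text = tx,
                          element = .element_of(tx),
                          aromatic = .is_aromatic_token(tx),
                          wildcard = identical(tx, "*"))
      if (!is.na(prev)) add_bond(prev, id, pending)
      pending <- ""
      prev <- id
    } else if (ty == "branch_open") {
      stack <- c(stack, prev)
    } else if (ty == "branch_close") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (ty == "bond") {
      pending <- tx
    } else if (ty == "ring") {
      lab <- tx
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        if (op$atom == prev) stop("ring label ", lab, " closes on its own atom", call. = FALSE)
        o <- if (nzchar(op$bond)) op$bond else pending
        add_bond(op$atom, prev, o)
        ring_open[[lab]] <- NULL
      } else {
        ring_open[[lab]] <- list(atom = prev, bond = pending)
      }
      pending <- ""
    }
  }
  if (length(ring_open)) stop("dangling ring label", call. = FALSE)
  at <- tibble::tibble(
    id = seq_along(atoms),
    text = vapply(atoms, `[[`, character(1), "text"),
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    wildcard = vapply(atoms, `[[`, logical(1), "wildcard")
  )
  bd <- tibble::tibble(a = bonds_a, b = bonds_b, order = bonds_o)
  deg <- tabulate(c(bd$a, bd$b), nbins = nrow(at))
  at$degree <- deg
  list(atoms = at, bonds = bd)
}

.parse_graph <- function(s) {
  .graph_from_tokens(smiles_tokens(s))
}

.adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[i]; b <- g$bonds$b[i]
    adj[[a]] <- c(adj[[a]], i)
    adj[[b]] <- c(adj[[b]], i)
  }
  lapply(adj, function(e) e[order(e)])
}

.edge_other <- function(g, e, v) {
  a <- g$bonds$a[e]
  if (a == v) g$bonds$b[e] else a
}

.graph_connected <- function(g) {
  n <- nrow(g$atoms)
  if (n <= 1L) return(TRUE)
  adj <- .adjacency(g)
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (e in adj[[v]]) {
      w <- .edge_other(g, e, v)
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  all(seen)
}

# Shortest path between two atoms; BFS with ascending atom-id tie-breaking
# so the result is deterministic for a fixed atom numbering.
.shortest_path <- function(g, from, to, adj = .adjacency(g)) {
  if (from == to) return(from)
  n <- nrow(g$atoms)
  parent <- rep(NA_integer_, n)
  seen <- logical(n); seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- sort(vapply(adj[[v]], function(e) .edge_other(g, e, v), integer(1)))
    for (w in nb) {
      if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v
        if (w == to) {
          path <- w
          while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  stop("attachment atoms are not connected", call. = FALSE)
}

# Size of the fragment containing `b` when atom `a` is deleted.
.branch_size <- function(g, a, b, adj) {
  n <- nrow(g$atoms)
  seen <- logical(n); seen[a] <- TRUE; seen[b] <- TRUE
  queue <- b; size <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (e in adj[[v]]) {
      w <- .edge_other(g, e, v)
      if (!seen[w]) { seen[w] <- TRUE; size <- size + 1L; queue <- c(queue, w) }
    }
  }
  size
}

# Emit a SMILES string from a DFS tree + ring-closure edge list.
# tree: list indexed by atom id -> integer vector of ordered child edge ids;
# chain_edge[v] names the one child edge continuing the chain unparenthesized
# (NA: every child is a parenthesized branch, e.g. at the final backbone atom
# so that a re-appended asterisk bonds to the backbone, not to a side chain).
# Digits are allocated smallest-first at the first endpoint reached in
# emission order and recycled after closing.
.emit_smiles <- function(g, root, tree_children, closure_edges,
                         chain_edge = NULL) {
  if (is.null(chain_edge)) {
    chain_edge <- vapply(tree_children, function(k) {
      if (length(k)) k[length(k)] else NA_integer_
    }, integer(1))
  }
  closure_by_atom <- vector("list", nrow(g$atoms))
  for (e in closure_edges) {
    a <- g$bonds$a[e]; b <- g$bonds$b[e]
    closure_by_atom[[a]] <- c(closure_by_atom[[a]], e)
    closure_by_atom[[b]] <- c(closure_by_atom[[b]], e)
  }
  digit_of <- new.env(parent = emptyenv())
  in_use <- logical(0)
  fmt_digit <- function(d) if (d <= 9) as.character(d) else sprintf("%%%02d", d)
  take_digit <- function() {
    free <- which(!in_use)
    d <- if (length(free)) free[1] else length(in_use) + 1L
    if (d > length(in_use)) in_use <<- c(in_use, logical(d - length(in_use)))
    in_use[d] <<- TRUE
    d
  }
  emit <- function(v) {
    out <- g$atoms$text[v]
    for (e in closure_by_atom[[v]]) {
      key <- as.character(e)
      if (is.null(digit_of[[key]])) {
        d <- take_digit()
        digit_of[[key]] <- d
        out <- paste0(out, g$bonds$order[e], fmt_digit(d))
      } else {
        d <- digit_of[[key]]
        out <- paste0(out, fmt_digit(d))
        in_use[d] <<- FALSE
      }
    }
    kids <- tree_children[[v]]
    if (length(kids)) {
      for (e in kids) {
        w <- .edge_other(g, e, v)
        piece <- paste0(g$bonds$order[e], emit(w))
        out <- paste0(out,
                      if (!is.na(chain_edge[v]) && e == chain_edge[v]) piece
                      else paste0("(", piece, ")"))
      }
    }
    out
  }
  emit(root)
}

# Generic writer: DFS from `start`, neighbor order supplied by `order_fun`
# (receives candidate edge ids and the current atom, returns them ordered).
# All children but the last are parenthesized.
.write_graph <- function(g, start = 1L,
                         order_fun = function(edges, v) edges) {
  n <- nrow(g$atoms)
  adj <- .adjacency(g)
  visited <- logical(n)
  edge_used <- logical(nrow(g$bonds))
  tree_children <- vector("list", n)
  closures <- integer()
  dfs <- function(v) {
    visited[v] <<- TRUE
    repeat {
      cand <- adj[[v]][!edge_used[adj[[v]]]]
      cand <- cand[!visited[vapply(cand, function(e) .edge_other(g, e, v), integer(1))]]
      if (!length(cand)) break
      cand <- order_fun(cand, v)
      e <- cand[1]
      w <- .edge_other(g, e, v)
      if (visited[w]) { # raced by a ring
        edge_used[e] <<- TRUE
        closures[[length(closures) + 1L]] <<- e
        next
      }
      edge_used[e] <<- TRUE
      tree_children[[v]] <<- c(tree_children[[v]], e)
      dfs(w)
    }
    # remaining edges to visited atoms are ring closures
    for (e in adj[[v]]) {
      if (!edge_used[e] && visited[.edge_other(g, e, v)]) {
        edge_used[e] <<- TRUE
        closures[[length(closures) + 1L]] <<- e
      }
    }
  }
  dfs(start)
  if (!all(visited)) stop("graph is disconnected; cannot write SMILES", call. = FALSE)
  .emit_smiles(g, start, tree_children, closures)
}

# Core writer: linearize a (wildcard-free) repeat-unit graph from attachment
# atom `from` to attachment atom `to`. The main chain is the shortest path
# between the attachments; at backbone atoms the side branches are written
# largest-first (all parenthesized, matching the layout of published
# corrected BigSMILES); inside a branch the largest subtree continues the
# chain so carbonyls come out as "(=O)".
.write_core <- function(g, from, to) {
  n <- nrow(g$atoms)
  adj <- .adjacency(g)
  path <- .shortest_path(g, from, to, adj)
  on_path <- logical(n); on_path[path] <- TRUE
  visited <- logical(n)
  edge_used <- logical(nrow(g$bonds))
  tree_children <- vector("list", n)
  chain_edge <- rep(NA_integer_, n)
  closures <- integer()
  add_closure <- function(e) {
    edge_used[e] <<- TRUE
    closures[[length(closures) + 1L]] <<- e
  }
  # depth-first expansion of a side branch; path atoms are never entered
  # (edges to them become ring closures, resolved when the path reaches them)
  branch_dfs <- function(v) {
    visited[v] <<- TRUE
    repeat {
      cand <- adj[[v]][!edge_used[adj[[v]]]]
      if (!length(cand)) break
      ws <- vapply(cand, function(e) .edge_other(g, e, v), integer(1))
      blocked <- visited[ws] | on_path[ws]
      for (e in cand[blocked]) add_closure(e)
      cand <- cand[!blocked]; ws <- ws[!blocked]
      if (!length(cand)) break
      sizes <- vapply(ws, function(w) .branch_size(g, v, w, adj), integer(1))
      o <- order(sizes, ws) # ascending size: largest subtree continues the chain
      e <- cand[o[1]]
      edge_used[e] <<- TRUE
      tree_children[[v]] <<- c(tree_children[[v]], e)
      chain_edge[v] <<- e # overwritten each round; ends at the largest child
      branch_dfs(.edge_other(g, e, v))
    }
  }
  for (i in seq_along(path)) {
    v <- path[i]
    visited[v] <- TRUE
    nxt <- if (i < length(path)) path[i + 1L] else NA_integer_
    cand <- adj[[v]][!edge_used[adj[[v]]]]
    ws <- vapply(cand, function(e) .edge_other(g, e, v), integer(1))
    path_edge <- which(ws == nxt)[1]
    side <- setdiff(seq_along(cand), path_edge)
    # closures to visited atoms or to path atoms other than the successor
    side_block <- side[visited[ws[side]] | on_path[ws[side]]]
    for (e in cand[side_block]) add_closure(e)
    side <- setdiff(side, side_block)
    if (length(side)) {
      sizes <- vapply(ws[side], function(w) .branch_size(g, v, w, adj), integer(1))
      side <- side[order(-sizes, ws[side])] # largest branch first
      for (j in side) {
        e <- cand[j]
        edge_used[e] <- TRUE
        tree_children[[v]] <- c(tree_children[[v]], e)
        branch_dfs(ws[j])
      }
    }
    if (!is.na(nxt)) {
      e <- cand[path_edge]
      edge_used[e] <- TRUE
      tree_children[[v]] <- c(tree_children[[v]], e)
      chain_edge[v] <- e
    }
  }
  if (!all(visited)) stop("graph is disconnected; cannot write SMILES", call. = FALSE)
  .emit_smiles(g, path[1], tree_children, closures, chain_edge)
}
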