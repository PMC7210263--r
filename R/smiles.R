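#' SMILES input and output
#'
#' The package reads ordinary (kekulized) SMILES over H, C, N, O as pipeline
#' input and writes fully explicit atom-mapped SMILES for curated reactions:
#' every atom -- hydrogens included -- is a bracket atom carrying a map
#' number, e.g. water is `[O:1]([H:2])[H:3]`. Parsing a written string and
#' re-deriving the graph reproduces the original connectivity; that
#' round-trip is the dialect's contract.
#'
#' @name smiles
NULL

default_valence <- c(H = 1L, C = 4L, N = 3L, O = 2L)

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset over H/C/N/O with branches, ring closures
#' (including `%nn`), bond symbols `-`, `=`, `#`, dots, bracket atoms with
#' charges, explicit H counts and atom maps. Aromatic (lowercase) input is
#' not supported: rings must be kekulized. Implicit hydrogens are added from
#' default valences (C 4, N 3, O 2) minus the bond-order sum.
#'
#' @param s SMILES string.
#' @return A list with `graph` (`mol_graph`, hydrogens explicit), `orders`
#'   (integer bond order per row of `graph$bonds`) and `map` (integer atom
#'   map per atom, `NA` where absent; implicit hydrogens have `NA`).
#' @export
parse_smiles <- function(s) {
  s <- trimws(s)
  if (nchar(s) == 0) stop_rxn("smiles_parse", "empty SMILES")
  chars <- strsplit(s, "")[[1]]
  n <- 0L
  elements <- character(0); charges <- integer(0); maps <- integer(0)
  hcount <- integer(0)      # explicit H count from brackets, NA = implicit
  edges <- matrix(integer(0), ncol = 3)  # i, j, order
  stack <- integer(0)
  prev <- 0L
  pend_order <- NA_integer_
  ring <- list()            # digit -> c(atom, order)
  i <- 1L
  len <- length(chars)
  add_atom <- function(el, chg, map, hc) {
    n <<- n + 1L
    elements[n] <<- el; charges[n] <<- chg; maps[n] <<- map; hcount[n] <<- hc
    if (prev > 0L) {
      o <- if (is.na(pend_order)) 1L else pend_order
      edges <<- rbind(edges, c(prev, n, o))
    }
    prev <<- n
    pend_order <<- NA_integer_
  }
  close_ring <- function(d) {
    if (!is.null(ring[[d]])) {
      opened <- ring[[d]]
      o <- if (!is.na(pend_order)) pend_order
           else if (!is.na(opened[2])) opened[2] else 1L
      edges <<- rbind(edges, c(opened[1], prev, o))
      ring[[d]] <<- NULL
    } else {
      ring[[d]] <<- c(prev, pend_order)
    }
    pend_order <<- NA_integer_
  }
  while (i <= len) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= len && chars[j] != "]") j <- j + 1L
      if (j > len) stop_rxn("smiles_parse", "unterminated bracket atom")
      tok <- paste(chars[(i + 1):(j - 1)], collapse = "")
      m <- regmatches(tok, regexec(
        "^([0-9]*)([A-Z][a-z]?)(H([0-9]*))?(([+-])([0-9]*))?(:([0-9]+))?$", tok))[[1]]
      if (length(m) == 0) stop_rxn("smiles_parse", paste0("bad bracket atom [", tok, "]"))
      el <- m[3]
      hc <- if (m[4] == "") 0L else if (m[5] == "") 1L else as.integer(m[5])
      chg <- if (m[7] == "") 0L
             else (if (m[7] == "+") 1L else -1L) * (if (m[8] == "") 1L else as.integer(m[8]))
      map <- if (m[10] == "") NA_integer_ else as.integer(m[10])
      add_atom(el, chg, map, hc)
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O")) {
      add_atom(ch, 0L, NA_integer_, NA_integer_)
      i <- i + 1L
    } else if (ch == "H") {
      # bare H outside brackets is nonstandard; accept as explicit hydrogen
      add_atom("H", 0L, NA_integer_, 0L)
      i <- i + 1L
    } else if (ch == "=") { pend_order <- 2L; i <- i + 1L
    } else if (ch == "#") { pend_order <- 3L; i <- i + 1L
    } else if (ch == "-") { pend_order <- 1L; i <- i + 1L
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop_rxn("smiles_parse", "unbalanced parentheses")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") { prev <- 0L; pend_order <- NA_integer_; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > len) stop_rxn("smiles_parse", "bad %nn ring closure")
      close_ring(paste(chars[(i + 1):(i + 2)], collapse = ""))
      i <- i + 3L
    } else {
      stop_rxn("smiles_parse", paste0("unsupported SMILES character '", ch, "'"))
    }
  }
  open_rings <- Filter(Negate(is.null), ring)
  if (length(open_rings) > 0) stop_rxn("smiles_parse", "unclosed ring bond")
  if (length(stack) > 0) stop_rxn("smiles_parse", "unbalanced parentheses")
  if (n == 0L) stop_rxn("smiles_parse", "no atoms")
  # implicit hydrogens
  order_sum <- rep(0L, n)
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      order_sum[edges[r, 1]] <- order_sum[edges[r, 1]] + edges[r, 3]
      order_sum[edges[r, 2]] <- order_sum[edges[r, 2]] + edges[r, 3]
    }
  }
  for (a in seq_len(n)) {
    nh <- if (!is.na(hcount[a])) hcount[a]
          else max(0L, default_valence[[elements[a]]] - charges_h_adjust(charges[a]) - order_sum[a])
    if (nh > 0L) {
      for (k in seq_len(nh)) {
        n <- n + 1L
        elements[n] <- "H"; charges[n] <- 0L; maps[n] <- NA_integer_
        edges <- rbind(edges, c(a, n, 1L))
      }
    }
  }
  bonds <- canonical_bonds(edges[, 1:2, drop = FALSE])
  ord <- rep(1L, nrow(bonds))
  if (nrow(edges) > 0) {
    # canonical_bonds reorders rows; rebuild the order lookup by bond key
    keys <- bond_keys(sort_bond_rows(edges[, 1:2, drop = FALSE]))
    ord <- edges[match(bond_keys(bonds), keys), 3]
  }
  list(graph = mol_graph(elements, bonds, charges = charges),
       orders = as.integer(ord), map = maps)
}

# valence reduction for charged atoms: +1 on N raises H capacity, -1 lowers.
# Inputs in scope are neutral; keep the simple convention valence + charge
# for N/C and valence - |charge| sign handling for O.
charges_h_adjust <- function(chg) -chg

#' Convert a SMILES string to a `mol_graph`
#'
#' Convenience wrapper around [parse_smiles()] discarding orders and maps.
#' @param s SMILES string.
#' @return A `mol_graph` with explicit hydrogens.
#' @export
mol_from_smiles <- function(s) parse_smiles(s)$graph

#' Reorder a parsed atom-mapped SMILES into its original index space
#'
#' Atom maps written by this package equal the original atom indices; sorting
#' atoms by map number therefore reconstructs the graph in the index space of
#' the originally optimized reactant, which is what the connectivity-diff
#' analyses consume.
#'
#' @param s Atom-mapped SMILES (every atom mapped).
#' @return A list with `graph` (atoms ordered by map number), `orders`
#'   (bond orders aligned with `graph$bonds`) and `map` (the sorted maps).
#' @export
mapped_graph <- function(s) {
  p <- parse_smiles(s)
  if (anyNA(p$map)) {
    stop_rxn("invalid_input", "all atoms must carry map numbers")
  }
  if (anyDuplicated(p$map) > 0) {
    stop_rxn("invalid_input", "duplicate atom map numbers")
  }
  rank_map <- rank(p$map)  # atom a moves to position rank_map[a]
  g2 <- permute_atoms(p$graph, rank_map)
  # carry orders across the relabeling, keyed per sorted bond pair
  relab <- matrix(as.integer(rank_map[p$graph$bonds]), ncol = 2L)
  ord <- p$orders[match(bond_keys(g2$bonds), bond_keys(sort_bond_rows(relab)))]
  list(graph = g2, orders = as.integer(ord), map = sort(p$map))
}

#' Write a graph as fully explicit (optionally atom-mapped) SMILES
#'
#' Every atom becomes a bracket atom; bond symbols follow `orders` (1 none,
#' 2 `=`, 3 `#`). Disconnected components are joined with `.`. Traversal is
#' a deterministic depth-first walk (lowest index first, neighbors
#' ascending), so identical graphs yield identical strings.
#'
#' @param g A `mol_graph`.
#' @param orders Integer bond orders per row of `g$bonds` (default all 1).
#' @param map Integer map numbers per atom, or `NULL` for no maps.
#' @return SMILES string.
#' @export
write_smiles <- function(g, orders = NULL, map = NULL) {
  if (is.null(orders)) orders <- rep(1L, nrow(g$bonds))
  stopifnot(length(orders) == nrow(g$bonds))
  okey <- bond_keys(g$bonds)
  order_of <- function(i, j) {
    k <- if (i < j) i * 100000L + j else j * 100000L + i
    orders[match(k, okey)]
  }
  atom_token <- function(a) {
    chg <- g$charges[a]
    chg_s <- if (chg == 0L) "" else if (chg > 0L) {
      if (chg == 1L) "+" else paste0("+", chg)
    } else {
      if (chg == -1L) "-" else paste0("-", abs(chg))
    }
    map_s <- if (is.null(map)) "" else paste0(":", map[a])
    paste0("[", g$elements[a], chg_s, map_s, "]")
  }
  bond_token <- function(o) c("", "=", "#")[o]
  n <- n_atoms(g)
  adj <- adjacency_list(g)
  visited <- rep(FALSE, n)
  ring_digit <- 0L
  ring_open <- list()   # per-atom pending ring closure tokens
  for (a in seq_len(n)) ring_open[[a]] <- character(0)
  # pre-pass: find back edges via DFS, assign ring digits
  back_edges <- list()
  seen <- rep(FALSE, n)
  parent <- rep(0L, n)
  for (root in seq_len(n)) {
    if (seen[root]) next
    stack <- root; seen[root] <- TRUE
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE; parent[w] <- v
          stack <- c(stack, w)
        } else if (w != parent[v]) {
          k <- if (v < w) paste(v, w) else paste(w, v)
          back_edges[[k]] <- c(min(v, w), max(v, w))
        }
      }
    }
  }
  is_back <- function(i, j) {
    k <- if (i < j) paste(i, j) else paste(j, i)
    !is.null(back_edges[[k]])
  }
  ring_tok <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)
  ring_assign <- list()
  for (k in names(back_edges)) {
    ring_digit <- ring_digit + 1L
    e <- back_edges[[k]]
    o <- order_of(e[1], e[2])
    tok1 <- paste0(bond_token(o), ring_tok(ring_digit))
    ring_open[[e[1]]] <- c(ring_open[[e[1]]], tok1)
    ring_open[[e[2]]] <- c(ring_open[[e[2]]], tok1)
  }
  emit <- function(v, from) {
    out <- if (from > 0L) bond_token(order_of(from, v)) else ""
    out <- paste0(out, atom_token(v), paste(ring_open[[v]], collapse = ""))
    visited[v] <<- TRUE
    nbrs <- setdiff(adj[[v]], from)
    nbrs <- nbrs[!vapply(nbrs, function(w) is_back(v, w), logical(1))]
    nbrs <- nbrs[!visited[nbrs]]
    if (length(nbrs) > 0) {
      for (k in seq_along(nbrs)) {
        w <- nbrs[k]
        if (visited[w]) next
        branch <- emit(w, v)
        if (k < length(nbrs)) branch <- paste0("(", branch, ")")
        out <- paste0(out, branch)
      }
    }
    out
  }
  parts <- character(0)
  for (root in seq_len(n)) {
    if (!visited[root]) parts <- c(parts, emit(root, 0L))
  }
  paste(parts, collapse = ".")
}
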