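#' Element-labeled molecular connectivity graphs
#'
#' `mol_graph()` builds the package's universal molecular identity carrier: an
#' element-labeled graph whose vertices are atoms (with stable 1-based indices)
#' and whose edges record connectivity only -- a "bond" here ignores bond
#' orders and merely states that two atoms are connected. Hydrogens are always
#' explicit atoms; there is no implicit-hydrogen bookkeeping anywhere in the
#' core. Graphs may be disconnected (multi-molecular product sets).
#'
#' @param elements Character vector of element symbols, one per atom. Only
#'   H, C, N and O are supported.
#' @param bonds Two-column integer matrix of atom index pairs (any order), or
#'   `NULL`/zero-row for a bond-less graph.
#' @param charges Integer formal charges per atom (recycled scalar allowed);
#'   0 for all generated inputs, nonzero values are accepted.
#' @param coords Optional N x 3 numeric matrix of Cartesian coordinates in
#'   Angstrom.
#'
#' @return An object of class `mol_graph`: a list with fields `elements`,
#'   `charges`, `coords` and `bonds` (canonicalized two-column matrix with
#'   `i < j`, rows sorted).
#' @export
mol_graph <- function(elements, bonds = NULL, charges = 0L, coords = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  bad <- setdiff(unique(elements), c("H", "C", "N", "O"))
  if (length(bad) > 0) {
    stop_rxn("unsupported_element",
             paste0("unsupported element(s): ", paste(bad, collapse = ", ")))
  }
  charges <- as.integer(rep_len(charges, n))
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3) {
      stop_rxn("invalid_input", "coords must be an N x 3 matrix")
    }
    storage.mode(coords) <- "double"
  }
  bonds <- canonical_bonds(bonds)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L) || any(bonds > n)) {
      stop_rxn("invalid_input", "bond endpoint out of range")
    }
    if (any(bonds[, 1] == bonds[, 2])) {
      stop_rxn("invalid_input", "self-bonds are not allowed")
    }
    if (anyDuplicated(bond_keys(bonds)) > 0) {
      stop_rxn("invalid_input", "duplicate bonds are not allowed")
    }
  }
  structure(
    list(elements = elements, charges = charges, coords = coords, bonds = bonds),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms (%s), %d bonds\n",
              n_atoms(x), paste0(names(table(x$elements)),
                                 table(x$elements), collapse = " "),
              nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a molecular graph
#' @param g A `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) length(g$elements)

# canonical bond matrix: integer, i < j per row, rows in lexicographic order
canonical_bonds <- function(bonds) {
  if (is.null(bonds) || (is.matrix(bonds) && nrow(bonds) == 0) ||
      length(bonds) == 0) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  swap <- bonds[, 1] > bonds[, 2]
  if (any(swap)) bonds[swap, ] <- bonds[swap, 2:1, drop = FALSE]
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  dimnames(bonds) <- list(NULL, c("i", "j"))
  bonds
}

# unique scalar key per (sorted) bond row; n-independent enough for our sizes
bond_keys <- function(bonds) {
  if (nrow(bonds) == 0) return(integer(0))
  bonds[, 1] * 100000L + bonds[, 2]
}

# sort each row ascending without reordering rows
sort_bond_rows <- function(bonds) {
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  swap <- bonds[, 1] > bonds[, 2]
  if (any(swap)) bonds[swap, ] <- bonds[swap, 2:1, drop = FALSE]
  bonds
}

# degree vector of a graph
graph_degrees <- function(g) {
  tabulate(c(g$bonds[, 1], g$bonds[, 2]), nbins = n_atoms(g))
}

# adjacency list (list of integer neighbor vectors, sorted)
adjacency_list <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  b <- g$bonds
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      i <- b[r, 1]; j <- b[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, sort)
  }
  adj
}

as_igraph <- function(g) {
  igraph::graph_from_edgelist(
    matrix(g$bonds, ncol = 2L), directed = FALSE
  ) -> ig
  # isolated trailing atoms are not covered by the edge list
  miss <- n_atoms(g) - igraph::vcount(ig)
  if (miss > 0) ig <- igraph::add_vertices(ig, miss)
  ig
}

# integer vertex colors combining element and formal charge
atom_colors <- function(g) {
  as.integer(factor(paste(g$elements, g$charges, sep = "/")))
}

#' Default valence limits for H, C, N and O
#'
#' Minimum and maximum connectivity (degree, ignoring bond orders) allowed for
#' each supported element in a chemically plausible product: hydrogen must
#' have exactly one bond, carbon two to four, oxygen one or two, nitrogen one
#' to three.
#'
#' @return A tibble with columns `element`, `min_degree`, `max_degree`.
#' @export
valence_table <- function() {
  tibble::tibble(
    element = c("H", "C", "N", "O"),
    min_degree = c(1L, 2L, 1L, 1L),
    max_degree = c(1L, 4L, 3L, 2L)
  )
}

#' Partition atoms into symmetry equivalence classes
#'
#' Iterated neighborhood (Weisfeiler--Lehman style) color refinement on
#' element labels over connectivity: two atoms share a class iff they receive
#' identical stable colors once refinement converges. Classes are computed for
#' all atoms; the driving-coordinate enumerator consumes the hydrogen classes
#' to drop sets that only differ by substitution of equivalent hydrogens
#' (e.g. the three hydrogens of a methyl group).
#'
#' @param g A `mol_graph`.
#' @return Integer vector of class ids (1-based, numbered by first
#'   occurrence); atoms with equal ids are symmetry-equivalent.
#' @export
symmetry_classes <- function(g) {
  n <- n_atoms(g)
  if (n == 0) return(integer(0))
  adj <- adjacency_list(g)
  col <- as.integer(factor(paste(g$elements, g$charges, sep = "/")))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      paste(col[i], paste(sort(col[adj[[i]]]), collapse = ","), sep = "|")
    }, character(1))
    new_col <- match(sig, unique(sig))
    if (identical(new_col, col)) break
    col <- new_col
  }
  match(col, unique(col))
}

#' Apply a set of bond changes to a graph
#'
#' Returns the formal product graph obtained by removing `breaks` and adding
#' `forms`; the input graph is unchanged. Used to screen proposed driving
#' coordinates for valence feasibility before any path optimization.
#'
#' @param g A `mol_graph`.
#' @param breaks Two-column matrix of bonds to remove; every row must be a
#'   bond of `g`.
#' @param forms Two-column matrix of pairs to connect; every row must be a
#'   non-bonded pair of `g`.
#' @return A new `mol_graph` (coordinates, if any, are dropped: the product
#'   geometry is not implied by the reactant's).
#' @export
apply_changes <- function(g, breaks = NULL, forms = NULL) {
  breaks <- canonical_bonds(breaks)
  forms <- canonical_bonds(forms)
  bk <- bond_keys(g$bonds)
  brk <- bond_keys(breaks)
  frk <- bond_keys(forms)
  if (!all(brk %in% bk)) {
    stop_rxn("invalid_change", "attempt to break a pair that is not a bond")
  }
  if (any(frk %in% bk)) {
    stop_rxn("invalid_change", "attempt to form a pair that is already bonded")
  }
  if (length(intersect(brk, frk)) > 0) {
    stop_rxn("invalid_change", "breaks and forms overlap")
  }
  keep <- !(bk %in% brk)
  new_bonds <- rbind(g$bonds[keep, , drop = FALSE], forms)
  mol_graph(g$elements, new_bonds, charges = g$charges)
}

#' Check valence feasibility of a graph
#'
#' TRUE iff every atom's degree lies within the allowed range for its element.
#' Applied to formal product graphs during driving-coordinate enumeration
#' only; downstream of path optimization no screening is applied, since the
#' real path may add changes beyond the driving coordinates.
#'
#' @param g A `mol_graph`.
#' @param valences Valence limits as returned by [valence_table()].
#' @return Logical scalar.
#' @export
is_valence_feasible <- function(g, valences = valence_table()) {
  idx <- match(g$elements, valences$element)
  if (anyNA(idx)) {
    stop_rxn("unsupported_element", "element not covered by valence table")
  }
  deg <- graph_degrees(g)
  all(deg >= valences$min_degree[idx] & deg <= valences$max_degree[idx])
}

#' Element- and adjacency-preserving isomorphism between two graphs
#'
#' Searches for a bijection between the atoms of `g1` and `g2` that preserves
#' element labels, formal charges and connectivity (bond orders are ignored
#' by construction of `mol_graph`). When several such bijections exist, the
#' one whose image sequence (images of `g1`'s atoms in index order) is
#' lexicographically smallest is returned, which makes downstream atom-map
#' reconstruction deterministic.
#'
#' @param g1,g2 `mol_graph` objects.
#' @return Integer vector `map` with `map[i]` the `g2` index matched to atom
#'   `i` of `g1`, or `NULL` if the graphs are not isomorphic.
#' @export
connectivity_isomorphism <- function(g1, g2) {
  if (n_atoms(g1) != n_atoms(g2)) return(NULL)
  if (!identical(sort(g1$elements), sort(g2$elements))) return(NULL)
  # colors must use a shared encoding across both graphs
  lev <- unique(c(paste(g1$elements, g1$charges, sep = "/"),
                  paste(g2$elements, g2$charges, sep = "/")))
  c1 <- as.integer(factor(paste(g1$elements, g1$charges, sep = "/"), levels = lev))
  c2 <- as.integer(factor(paste(g2$elements, g2$charges, sep = "/"), levels = lev))
  maps <- igraph::graph.get.isomorphisms.vf2(
    as_igraph(g1), as_igraph(g2),
    vertex.color1 = c1, vertex.color2 = c2
  )
  if (length(maps) == 0) return(NULL)
  # the returned sequence indexes g2's vertices with images in g1;
  # invert to get the g1 -> g2 map
  seqs <- lapply(maps, function(m) order(as.integer(m)))
  best <- seqs[[1]]
  for (s in seqs[-1]) {
    cmp <- s - best
    nz <- which(cmp != 0)
    if (length(nz) > 0 && cmp[nz[1]] < 0) best <- s
  }
  best
}

#' Connectivity difference between mapped reactant and product graphs
#'
#' Both graphs must live in the same atom index space (an atom-mapped pair):
#' atom `i` of the reactant is atom `i` of the product. Broken bonds are those
#' present in the reactant but absent in the product; formed bonds the
#' reverse. Bond orders play no role.
#'
#' @param reactant,product `mol_graph` objects over the same atoms.
#' @return A list with two-column matrices `broken` and `formed`.
#' @export
bond_changes <- function(reactant, product) {
  if (n_atoms(reactant) != n_atoms(product) ||
      !identical(reactant$elements, product$elements)) {
    stop_rxn("mapping_mismatch",
             "reactant and product must share the same atom index space")
  }
  rk <- bond_keys(reactant$bonds)
  pk <- bond_keys(product$bonds)
  list(
    broken = reactant$bonds[!(rk %in% pk), , drop = FALSE],
    formed = product$bonds[!(pk %in% rk), , drop = FALSE]
  )
}

#' Split a graph into connected components
#'
#' @param g A `mol_graph`.
#' @return List of `mol_graph` fragments; each carries an attribute
#'   `parent_indices` giving, per fragment atom, its index in `g`.
#' @export
fragments <- function(g) {
  comp <- igraph::components(as_igraph(g))
  lapply(seq_len(comp$no), function(k) {
    idx <- which(comp$membership == k)
    sub_bonds <- g$bonds[g$bonds[, 1] %in% idx & g$bonds[, 2] %in% idx, ,
                         drop = FALSE]
    remap <- match(sub_bonds, idx)
    frag <- mol_graph(
      g$elements[idx],
      if (length(remap) > 0) matrix(remap, ncol = 2L) else NULL,
      charges = g$charges[idx],
      coords = if (!is.null(g$coords)) g$coords[idx, , drop = FALSE] else NULL
    )
    attr(frag, "parent_indices") <- idx
    frag
  })
}

#' Relabel the atoms of a graph
#'
#' @param g A `mol_graph`.
#' @param perm Integer permutation: atom `i` of `g` becomes atom `perm[i]`.
#' @return The relabeled `mol_graph`.
#' @export
permute_atoms <- function(g, perm) {
  perm <- as.integer(perm)
  if (length(perm) != n_atoms(g) || anyDuplicated(perm) > 0 ||
      any(sort(perm) != seq_len(n_atoms(g)))) {
    stop_rxn("invalid_input", "perm must be a permutation of the atom indices")
  }
  inv <- order(perm)
  b <- g$bonds
  nb <- if (nrow(b) > 0) matrix(perm[b], ncol = 2L) else NULL
  mol_graph(g$elements[inv], nb, charges = g$charges[inv],
            coords = if (!is.null(g$coords)) g$coords[inv, , drop = FALSE])
}

# classed conditions so callers can distinguish failure modes
stop_rxn <- function(class, msg) {
  stop(structure(
    class = c(paste0("rxnforge_", class), "rxnforge_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
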