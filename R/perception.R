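#' Perceive connectivity from a 3D geometry
#'
#' Two atoms are bonded iff their distance does not exceed
#' `tol * (r_cov(i) + r_cov(j))` with covalent radii H 0.31, C 0.76, N 0.71,
#' O 0.66 Angstrom. The radii table and tolerance are pinned here and
#' recorded in output metadata by the pipeline.
#'
#' @param elements Element symbols.
#' @param geometry N x 3 coordinate matrix, Angstrom.
#' @param tol Scale factor on the covalent-radius sum (default 1.2).
#' @param charges Formal charges to carry onto the graph.
#' @return A `mol_graph` with `coords` set.
#' @export
perceive_connectivity <- function(elements, geometry, tol = 1.2, charges = 0L) {
  geometry <- as.matrix(geometry)
  if (!all(is.finite(geometry))) stop_rxn("geometry", "non-finite coordinates")
  n <- length(elements)
  if (nrow(geometry) != n) stop_rxn("invalid_input", "geometry/element mismatch")
  if (n == 1) return(mol_graph(elements, NULL, charges, coords = geometry))
  dm <- as.matrix(stats::dist(geometry))
  if (any(dm[upper.tri(dm)] < 0.4)) {
    stop_rxn("geometry", "overlapping atoms (distance < 0.4 Angstrom)")
  }
  rads <- covalent_radii[elements]
  cutoff <- tol * outer(rads, rads, `+`)
  hit <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  mol_graph(elements, if (nrow(hit) > 0) hit else NULL, charges,
            coords = geometry)
}

#' Assign integer bond orders by valence saturation
#'
#' Distributes extra bond order over the edges of a connectivity graph to
#' maximize total valence saturation (targets H 1, C 4, N 3, O 2, shifted by
#' formal charge). The search enumerates assignments over the unsaturated
#' subgraph with branch-and-bound; among maximal assignments the
#' lexicographically smallest (in canonical bond order) is returned, so the
#' result is deterministic. Leftover unsaturation is radical character;
#' adjacent unsaturated atoms are always paired into higher bond orders by
#' the maximization, which is the repair for spurious adjacent radicals.
#'
#' @param g A `mol_graph`.
#' @return Integer vector of bond orders aligned with `g$bonds`.
#' @export
assign_bond_orders <- function(g) {
  targets <- c(H = 1L, C = 4L, N = 3L, O = 2L)
  deg <- graph_degrees(g)
  resid <- pmax(0L, targets[g$elements] + valence_charge_shift(g) - deg)
  m <- nrow(g$bonds)
  orders <- rep(1L, m)
  if (m == 0 || all(resid == 0)) return(orders)
  # only bonds whose both endpoints are unsaturated can take extra order
  cand <- which(resid[g$bonds[, 1]] > 0 & resid[g$bonds[, 2]] > 0)
  if (length(cand) == 0) return(orders)
  best_extra <- rep(0L, length(cand))
  best_sum <- -1L
  nres <- resid
  extra <- rep(0L, length(cand))
  bnd <- g$bonds[cand, , drop = FALSE]
  recurse <- function(pos, cur_sum) {
    # bound: even if all remaining bonds take max extra, can we beat best?
    remaining <- if (pos > length(cand)) 0L else {
      sum(vapply(pos:length(cand), function(q) {
        2L * min(2L, nres[bnd[q, 1]], nres[bnd[q, 2]])
      }, integer(1)))
    }
    if (cur_sum + remaining < best_sum) return()
    if (pos > length(cand)) {
      if (cur_sum > best_sum) {
        best_sum <<- cur_sum
        best_extra <<- extra
      }
      return()
    }
    i <- bnd[pos, 1]; j <- bnd[pos, 2]
    hi <- min(2L, nres[i], nres[j])
    for (x in 0:hi) {   # ascending: first maximal found is lexicographically smallest
      extra[pos] <<- x
      nres[i] <<- nres[i] - x; nres[j] <<- nres[j] - x
      recurse(pos + 1L, cur_sum + 2L * x)
      nres[i] <<- nres[i] + x; nres[j] <<- nres[j] + x
    }
    extra[pos] <<- 0L
  }
  recurse(1L, 0L)
  orders[cand] <- 1L + best_extra
  orders
}

# charge shift of the valence target: N+ gains a bond, O- loses one, etc.
valence_charge_shift <- function(g) {
  ifelse(g$elements %in% c("C", "N"), g$charges, -g$charges)
}

#' Minimal alternating-ring aromaticity flags
#'
#' Marks atoms lying on a cycle whose perceived bond orders alternate
#' single/double around the ring (a Kekule-alternating ring, e.g. benzene).
#' This is deliberately minimal: templates need an aromatic feature, and a
#' Kekule-alternation rule covers the rings that occur in small H/C/N/O
#' molecules without a full aromaticity model.
#'
#' @param g A `mol_graph`.
#' @param orders Bond orders aligned with `g$bonds`.
#' @return Logical vector per atom.
#' @export
aromatic_flags <- function(g, orders) {
  n <- n_atoms(g)
  flags <- rep(FALSE, n)
  if (nrow(g$bonds) < 3 || n < 3) return(flags)
  ig <- as_igraph(g)
  # fundamental cycles from a BFS spanning forest
  okey <- bond_keys(g$bonds)
  order_of <- function(i, j) {
    k <- if (i < j) i * 100000L + j else j * 100000L + i
    orders[match(k, okey)]
  }
  cyc <- tryCatch(find_fundamental_cycles(g), error = function(e) list())
  for (cy in cyc) {
    L <- length(cy)
    if (L < 4 || L %% 2 != 0) next
    ords <- vapply(seq_len(L), function(q) {
      order_of(cy[q], cy[q %% L + 1L])
    }, integer(1))
    if (all(ords %in% c(1L, 2L)) && all(abs(diff(c(ords, ords[1]))) == 1L)) {
      flags[cy] <- TRUE
    }
  }
  flags
}

# fundamental cycles as vertex sequences, via spanning-tree back edges
find_fundamental_cycles <- function(g) {
  n <- n_atoms(g)
  adj <- adjacency_list(g)
  parent <- rep(0L, n); depth <- rep(-1L, n)
  cycles <- list()
  for (root in seq_len(n)) {
    if (depth[root] >= 0) next
    depth[root] <- 0L
    queue <- root
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (depth[w] < 0) {
          depth[w] <- depth[v] + 1L; parent[w] <- v
          queue <- c(queue, w)
        } else if (w != parent[v] && v < w) {
          # back/cross edge: path v->root meets path w->root
          pv <- v; pw <- w
          av <- pv; aw <- pw
          while (depth[av] > depth[aw]) av <- parent[av]
          while (depth[aw] > depth[av]) aw <- parent[aw]
          while (av != aw) { av <- parent[av]; aw <- parent[aw] }
          path_up <- function(x, anc) {
            p <- integer(0)
            while (x != anc) { p <- c(p, x); x <- parent[x] }
            c(p, anc)
          }
          cycles[[length(cycles) + 1L]] <-
            c(path_up(v, av), rev(path_up(w, av)[-length(path_up(w, av))]))
        }
      }
    }
  }
  cycles
}

#' Perceive a molecule from geometry
#'
#' Bundles connectivity perception, bond-order assignment, aromaticity flags
#' and the canonical identity key into a `perceived_mol`.
#'
#' @inheritParams perceive_connectivity
#' @return A `perceived_mol`: list with `graph`, `orders`, `aromatic`,
#'   `identity_key`.
#' @export
perceive_molecule <- function(elements, geometry, tol = 1.2, charges = 0L) {
  g <- perceive_connectivity(elements, geometry, tol, charges)
  orders <- assign_bond_orders(g)
  structure(list(
    graph = g,
    orders = orders,
    aromatic = aromatic_flags(g, orders),
    identity_key = identity_key(g)
  ), class = "perceived_mol")
}

#' Canonical fixed-hydrogen identity key
#'
#' A canonical string identity for a molecule with explicit hydrogens:
#' relabeled copies give equal keys; tautomers (which differ in hydrogen
#' placement) give different keys; resonance forms with the same fixed-H
#' skeleton give equal keys, because bond orders are excluded from the key.
#' Hydrogen positions being explicit atoms in the graph makes the
#' fixed-hydrogen semantics inherent. The serialization is the canonical
#' (element,charge)-colored graph form: canonical atom order, element+charge
#' sequence, and relabeled bond list.
#'
#' @param g A `mol_graph` (or `perceived_mol`, whose graph is used). May be
#'   disconnected; component keys are sorted and joined so the key of a
#'   multi-molecular set is order-independent.
#' @return Identity key string, prefix `RXF1-`.
#' @export
identity_key <- function(g) {
  if (inherits(g, "perceived_mol")) g <- g$graph
  comp <- igraph::components(as_igraph(g))
  if (comp$no > 1) {
    keys <- vapply(fragments(g), identity_key, character(1))
    return(paste(sort(keys), collapse = "."))
  }
  ig <- as_igraph(g)
  colors <- atom_colors(g)
  perm <- igraph::canonical_permutation(ig, colors = colors)$labeling
  # atom i -> canonical position perm[i]
  inv <- order(perm)
  els <- g$elements[inv]
  chg <- g$charges[inv]
  b <- g$bonds
  cb <- if (nrow(b) > 0) canonical_bonds(matrix(perm[b], ncol = 2L)) else b
  chg_s <- if (all(chg == 0L)) "" else paste0(";q", paste(chg, collapse = ","))
  paste0("RXF1-", paste(els, collapse = ""), ";",
         paste(cb[, 1], cb[, 2], sep = "-", collapse = ","), chg_s)
}

#' Atom-mapped SMILES via graph-isomorphism map reconstruction
#'
#' Serializes a perceived molecule with atom-map numbers referring to the
#' atom indices of `original`: the element-preserving connectivity
#' isomorphism between `original` and the perceived graph assigns the maps
#' (bond orders are ignored in the matching but kept in the output). When
#' `original` is a fragment carrying a `parent_indices` attribute, maps
#' refer to the parent index space.
#'
#' @param p A `perceived_mol` (or a `mol_graph`, treated as all-single
#'   orders).
#' @param original The originally-known `mol_graph` defining the index space.
#' @return Atom-mapped SMILES string.
#' @export
atom_mapped_smiles <- function(p, original) {
  if (inherits(p, "mol_graph")) {
    p <- list(graph = p, orders = rep(1L, nrow(p$bonds)))
  }
  phi <- connectivity_isomorphism(original, p$graph)
  if (is.null(phi)) {
    stop_rxn("mapping_failure",
             "perceived molecule is not isomorphic to the original graph")
  }
  labels <- attr(original, "parent_indices") %||% seq_len(n_atoms(original))
  # atom a of p$graph corresponds to original atom phi^-1(a)
  inv <- order(phi)
  map <- labels[inv]
  write_smiles(p$graph, orders = p$orders, map = map)
}

#' Assemble atom-mapped reaction SMILES
#'
#' @param reactant_p Perceived reactant (`perceived_mol`); its atoms define
#'   map numbers 1..N.
#' @param products_p List of perceived product fragments, each with a
#'   `parent_indices` attribute on its graph placing it in the reactant's
#'   atom space.
#' @param reactant_graph The original reactant `mol_graph`.
#' @param product_graphs List of original product fragment graphs (each with
#'   `parent_indices`).
#' @return List with `rsmi` and `psmi` (product fragments joined with `.`).
#' @export
reaction_smiles <- function(reactant_p, products_p, reactant_graph,
                            product_graphs) {
  rsmi <- atom_mapped_smiles(reactant_p, reactant_graph)
  psmis <- vapply(seq_along(products_p), function(k) {
    atom_mapped_smiles(products_p[[k]], product_graphs[[k]])
  }, character(1))
  psmi <- paste(psmis, collapse = ".")
  got <- sort(unlist(lapply(product_graphs, function(gg) {
    attr(gg, "parent_indices") %||% seq_len(n_atoms(gg))
  })))
  want <- seq_len(n_atoms(reactant_graph))
  if (!identical(as.integer(got), as.integer(want))) {
    stop_rxn("mapping_failure",
             "product fragments do not partition the reactant atom set")
  }
  list(rsmi = rsmi, psmi = psmi)
}
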