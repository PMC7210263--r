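# Independent brute-force oracles. These deliberately use literal
# enumeration over permutations / assignments so they share no code path
# with the implementations they check.

all_perms <- function(n) {
  if (n == 0) return(list(integer(0)))
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# all bijections g1 -> g2 atoms preserving element labels (as index maps)
element_preserving_bijections <- function(els1, els2) {
  if (!identical(sort(els1), sort(els2))) return(list())
  blocks <- unique(els1)
  per_block <- lapply(blocks, function(el) {
    i1 <- which(els1 == el); i2 <- which(els2 == el)
    lapply(all_perms(length(i1)), function(p) cbind(i1, i2[p]))
  })
  maps <- list(matrix(integer(0), ncol = 2))
  for (bl in per_block) {
    maps <- unlist(lapply(maps, function(m) {
      lapply(bl, function(b) rbind(m, b))
    }), recursive = FALSE)
  }
  lapply(maps, function(m) {
    map <- integer(length(els1))
    map[m[, 1]] <- m[, 2]
    map
  })
}

adjacency_preserved <- function(g1, g2, map) {
  b1 <- g1$bonds
  if (nrow(b1) != nrow(g2$bonds)) return(FALSE)
  relab <- cbind(map[b1[, 1]], map[b1[, 2]])
  swap <- relab[, 1] > relab[, 2]
  relab[swap, ] <- relab[swap, 2:1, drop = FALSE]
  k1 <- sort(relab[, 1] * 100000L + relab[, 2])
  k2 <- sort(g2$bonds[, 1] * 100000L + g2$bonds[, 2])
  identical(as.integer(k1), as.integer(k2))
}

# automorphism orbits by literal search over all element-preserving perms
brute_orbits <- function(g) {
  n <- n_atoms(g)
  autos <- Filter(function(m) adjacency_preserved(g, g, m),
                  element_preserving_bijections(g$elements, g$elements))
  orbit <- seq_len(n)
  for (m in autos) {
    for (i in seq_len(n)) {
      a <- min(orbit[i], orbit[m[i]])
      orbit[orbit == orbit[i] | orbit == orbit[m[i]]] <- a
    }
  }
  match(orbit, unique(orbit))
}

# all isomorphisms g1 -> g2 by literal search
brute_isomorphisms <- function(g1, g2) {
  Filter(function(m) adjacency_preserved(g1, g2, m),
         element_preserving_bijections(g1$elements, g2$elements))
}

# non-bonded pairs, computed independently of the package internals
nonbonded_pairs_for_test <- function(g) {
  n <- n_atoms(g)
  keys <- g$bonds[, 1] * 100000L + g$bonds[, 2]
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!((i * 100000L + j) %in% keys)) out <- rbind(out, c(i, j))
    }
  }
  out
}

bond_key_vec <- function(mat) {
  if (nrow(mat) == 0) return(integer(0))
  lo <- pmin(mat[, 1], mat[, 2]); hi <- pmax(mat[, 1], mat[, 2])
  unname(sort(lo * 100000L + hi))
}

# lexicographic order of matrix rows
order_of_rows <- function(m) do.call(order, as.data.frame(m))

# exhaustive bond-order assignment search: maximize saturation over
# extra order in {0,1,2} per bond under per-atom residual capacity
brute_order_assignments <- function(g) {
  targets <- c(H = 1L, C = 4L, N = 3L, O = 2L)
  deg <- tabulate(c(g$bonds[, 1], g$bonds[, 2]), nbins = n_atoms(g))
  resid <- pmax(0L, targets[g$elements] - deg)
  m <- nrow(g$bonds)
  if (m == 0) return(list(best = 0L, assignments = list(integer(0))))
  grid <- as.matrix(expand.grid(rep(list(0:2), m)))
  ok <- apply(grid, 1, function(x) {
    load <- tabulate(rep(c(g$bonds[, 1], g$bonds[, 2]), times = c(x, x)),
                     nbins = n_atoms(g))
    all(load <= resid)
  })
  sat <- rowSums(grid) * 2L
  sat[!ok] <- -1L
  best <- max(sat)
  list(best = best,
       assignments = lapply(which(sat == best), function(r) grid[r, ] + 1L))
}
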