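#' Seeded distance-geometry embedding of a molecular graph
#'
#' Generates 3D coordinates for a connectivity graph by minimizing a stress
#' function: bonded pairs are pulled toward the sum of covalent radii, and
#' non-bonded pairs are pushed beyond a separation floor so that perception
#' with the default tolerance recovers the input connectivity. Disconnected
#' fragments are embedded independently and offset along x so they never
#' perceive as bonded. Fully deterministic given `seed`.
#'
#' Multiple seeded random starts emulate a conformer search: each start is
#' relaxed and scored by its residual stress, and the lowest-stress
#' "conformer" is returned.
#'
#' @param g A `mol_graph`.
#' @param seed Integer seed for the random starts.
#' @param n_conformers Number of seeded starts to relax and score.
#' @param max_tries Extra attempts if the relaxed geometry fails the
#'   connectivity round-trip.
#' @return N x 3 coordinate matrix (Angstrom).
#' @export
embed_geometry <- function(g, seed = 1L, n_conformers = 4L, max_tries = 8L) {
  frs <- fragments(g)
  n <- n_atoms(g)
  coords <- matrix(0.0, n, 3)
  xshift <- 0.0
  for (fr in frs) {
    idx <- attr(fr, "parent_indices")
    xyz <- embed_fragment(fr, seed = seed + 7L * idx[1], n_conformers, max_tries)
    xyz[, 1] <- xyz[, 1] - min(xyz[, 1]) + xshift
    coords[idx, ] <- xyz
    xshift <- max(xyz[, 1]) + 10.0
  }
  coords
}

covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)

embed_fragment <- function(g, seed, n_conformers, max_tries) {
  n <- n_atoms(g)
  if (n == 1) return(matrix(0.0, 1, 3))
  rads <- covalent_radii[g$elements]
  B <- g$bonds
  d0 <- rads[B[, 1]] + rads[B[, 2]]
  nb <- nonbonded_pairs(g)
  s0 <- 1.6 * (rads[nb[, 1]] + rads[nb[, 2]])  # floor above the 1.2 cutoff
  obj <- function(x) {
    xy <- matrix(x, n, 3)
    db <- sqrt(rowSums((xy[B[, 1], , drop = FALSE] - xy[B[, 2], , drop = FALSE])^2))
    f <- sum((db - d0)^2)
    if (nrow(nb) > 0) {
      dn <- sqrt(rowSums((xy[nb[, 1], , drop = FALSE] - xy[nb[, 2], , drop = FALSE])^2))
      pen <- pmax(0, s0 - dn)
      f <- f + sum(pen^2)
    }
    f
  }
  grad <- function(x) {
    xy <- matrix(x, n, 3)
    gr <- matrix(0.0, n, 3)
    dvec <- xy[B[, 1], , drop = FALSE] - xy[B[, 2], , drop = FALSE]
    db <- sqrt(rowSums(dvec^2)); db[db == 0] <- 1e-9
    w <- 2 * (db - d0) / db
    gb <- dvec * w
    for (r in seq_len(nrow(B))) {
      gr[B[r, 1], ] <- gr[B[r, 1], ] + gb[r, ]
      gr[B[r, 2], ] <- gr[B[r, 2], ] - gb[r, ]
    }
    if (nrow(nb) > 0) {
      dvn <- xy[nb[, 1], , drop = FALSE] - xy[nb[, 2], , drop = FALSE]
      dn <- sqrt(rowSums(dvn^2)); dn[dn == 0] <- 1e-9
      act <- dn < s0
      if (any(act)) {
        wn <- -2 * (s0[act] - dn[act]) / dn[act]
        gn <- dvn[act, , drop = FALSE] * wn
        ia <- nb[act, 1]; ja <- nb[act, 2]
        for (r in seq_along(ia)) {
          gr[ia[r], ] <- gr[ia[r], ] + gn[r, ]
          gr[ja[r], ] <- gr[ja[r], ] - gn[r, ]
        }
      }
    }
    as.vector(gr)
  }
  best <- NULL; best_f <- Inf
  attempt <- 0L
  total <- n_conformers + max_tries
  while (attempt < total) {
    attempt <- attempt + 1L
    set.seed((seed + attempt * 1013L) %% 2147483647L)
    x0 <- stats::rnorm(3 * n, sd = 0.8 + 0.4 * sqrt(n))
    fit <- stats::optim(x0, obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    xy <- matrix(fit$par, n, 3)
    ok <- tryCatch({
      pg <- perceive_connectivity(g$elements, xy)
      identical(bond_keys(pg$bonds), bond_keys(g$bonds))
    }, error = function(e) FALSE)
    if (ok && fit$value < best_f) {
      best <- xy; best_f <- fit$value
    }
    if (!is.null(best) && attempt >= n_conformers) break
  }
  if (is.null(best)) {
    stop_rxn("preparation", "embedding failed to reproduce connectivity")
  }
  best
}
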