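#' Constraints for driving-coordinate enumeration
#'
#' Defaults encode the search-direction limits used throughout: at most two
#' bonds broken, at most two formed, two to three total changes (single-bond
#' changes are excluded as likely barrierless associations/dissociations),
#' valence screening of the formal product, and pruning of sets that differ
#' only by substitution of symmetry-equivalent hydrogens.
#'
#' @param max_breaks,max_forms Maximum number of bonds broken / formed.
#' @param max_total,min_total Bounds on the total number of changes.
#' @param valences Valence limits, see [valence_table()].
#' @param prune_equivalent_hydrogens Collapse sets related by equivalent-H
#'   substitution to one canonical representative.
#' @param prune_all_equivalent Extend equivalence pruning to all atoms, not
#'   just hydrogens (off by default; yields fewer duplicates).
#' @return A list of class `driving_constraints`.
#' @export
driving_constraints <- function(max_breaks = 2L, max_forms = 2L,
                                max_total = 3L, min_total = 2L,
                                valences = valence_table(),
                                prune_equivalent_hydrogens = TRUE,
                                prune_all_equivalent = FALSE) {
  stopifnot(min_total >= 1L, min_total <= max_total,
            max_breaks >= 0L, max_forms >= 0L)
  structure(list(max_breaks = as.integer(max_breaks),
                 max_forms = as.integer(max_forms),
                 max_total = as.integer(max_total),
                 min_total = as.integer(min_total),
                 valences = valences,
                 prune_equivalent_hydrogens = prune_equivalent_hydrogens,
                 prune_all_equivalent = prune_all_equivalent),
            class = "driving_constraints")
}

# all non-bonded atom pairs of g as a canonical two-column matrix
nonbonded_pairs <- function(g) {
  n <- n_atoms(g)
  if (n < 2) return(matrix(integer(0), ncol = 2L))
  all_pairs <- t(utils::combn(n, 2L))
  keys <- all_pairs[, 1] * 100000L + all_pairs[, 2]
  all_pairs[!(keys %in% bond_keys(g$bonds)), , drop = FALSE]
}

#' Enumerate driving-coordinate sets for a reactant
#'
#' Generates every combination of bond breaks and bond formations satisfying
#' the count bounds whose formal product graph is valence-feasible, with
#' deterministic canonical ordering (sets sorted by their break then form
#' index tuples). With equivalent-hydrogen pruning, each set's signature
#' replaces every hydrogen index by its symmetry class (see
#' [symmetry_classes()]); sets with equal signatures collapse to the
#' lexicographically smallest representative.
#'
#' Valence screening only uses atom degrees, so the check is performed by
#' degree arithmetic over all candidates at once rather than by materializing
#' product graphs; [driving_oracle()] provides the literal implementation.
#'
#' @param reactant A valence-feasible `mol_graph`.
#' @param constraints A [driving_constraints()] object.
#' @return A tibble with one row per driving-coordinate set: list-columns
#'   `breaks` and `forms` (two-column index matrices), integer `n_break`,
#'   `n_form`, and the dedup `signature` string.
#' @export
enumerate_driving_coordinates <- function(reactant,
                                          constraints = driving_constraints()) {
  c_ <- constraints
  if (!is_valence_feasible(reactant, c_$valences)) {
    stop_rxn("invalid_input", "reactant graph is not valence-feasible")
  }
  n <- n_atoms(reactant)
  B <- reactant$bonds
  FP <- nonbonded_pairs(reactant)
  nb <- nrow(B); nf <- nrow(FP)
  deg <- graph_degrees(reactant)
  vt <- c_$valences
  vidx <- match(reactant$elements, vt$element)
  vmin <- vt$min_degree[vidx]; vmax <- vt$max_degree[vidx]

  combos_of <- function(m, k) {
    if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
    if (m < k) return(NULL)
    t(utils::combn(m, k))
  }

  res_breaks <- list(); res_forms <- list(); res_nb <- integer(0); res_nf <- integer(0)
  part <- 0L
  for (k in 0:min(c_$max_breaks, nb)) {
    for (m in 0:min(c_$max_forms, nf)) {
      tot <- k + m
      if (tot < c_$min_total || tot > c_$max_total) next
      bc <- combos_of(nb, k); fc <- combos_of(nf, m)
      if (is.null(bc) || is.null(fc)) next
      nbc <- nrow(bc); nfc <- nrow(fc)
      # cross product by index
      bi <- rep(seq_len(nbc), times = nfc)
      fi <- rep(seq_len(nfc), each = nbc)
      ncand <- length(bi)
      if (ncand == 0) next
      # touched atoms and degree deltas, vectorized over candidates
      w <- 2L * tot
      atoms <- matrix(0L, nrow = ncand, ncol = w)
      signs <- matrix(0L, nrow = ncand, ncol = w)
      col <- 0L
      if (k > 0) for (q in seq_len(k)) {
        rows <- bc[bi, q]
        atoms[, col + 1L] <- B[rows, 1]; signs[, col + 1L] <- -1L
        atoms[, col + 2L] <- B[rows, 2]; signs[, col + 2L] <- -1L
        col <- col + 2L
      }
      if (m > 0) for (q in seq_len(m)) {
        rows <- fc[fi, q]
        atoms[, col + 1L] <- FP[rows, 1]; signs[, col + 1L] <- 1L
        atoms[, col + 2L] <- FP[rows, 2]; signs[, col + 2L] <- 1L
        col <- col + 2L
      }
      # per-slot aggregated degree delta (an atom may occupy several slots)
      bad <- rep(FALSE, ncand)
      for (c1 in seq_len(w)) {
        delta <- integer(ncand)
        for (c2 in seq_len(w)) {
          delta <- delta + signs[, c2] * (atoms[, c2] == atoms[, c1])
        }
        nd <- deg[atoms[, c1]] + delta
        bad <- bad | nd < vmin[atoms[, c1]] | nd > vmax[atoms[, c1]]
      }
      keep <- which(!bad)
      if (length(keep) == 0) next
      part <- part + 1L
      res_breaks[[part]] <- bc[bi[keep], , drop = FALSE]
      res_forms[[part]] <- fc[fi[keep], , drop = FALSE]
      res_nb[part] <- k; res_nf[part] <- m
    }
  }
  if (part == 0L) return(empty_driving_tbl())

  sym <- symmetry_classes(reactant)
  prune_h <- c_$prune_equivalent_hydrogens || c_$prune_all_equivalent
  token <- if (c_$prune_all_equivalent) {
    paste0("c", sym)
  } else {
    ifelse(reactant$elements == "H", paste0("h", sym), paste0("n", seq_len(n)))
  }

  pair_label <- function(idx_mat, pairs) {
    # idx_mat: candidates x q matrix of row indices into `pairs`
    q <- ncol(idx_mat)
    if (q == 0L) return(rep("", nrow(idx_mat)))
    labs <- matrix("", nrow = nrow(idx_mat), ncol = q)
    for (c2 in seq_len(q)) {
      i <- pairs[idx_mat[, c2], 1]; j <- pairs[idx_mat[, c2], 2]
      t1 <- token[i]; t2 <- token[j]
      lo <- pmin(t1, t2); hi <- pmax(t1, t2)
      labs[, c2] <- paste0(lo, "~", hi)
    }
    apply(labs, 1L, function(r) paste(sort(r), collapse = "+"))
  }
  sort_tuple <- function(idx_mat, pairs) {
    q <- ncol(idx_mat)
    if (q == 0L) return(rep("", nrow(idx_mat)))
    mats <- lapply(seq_len(q), function(c2) {
      cbind(pairs[idx_mat[, c2], 1], pairs[idx_mat[, c2], 2])
    })
    vapply(seq_len(nrow(idx_mat)), function(r) {
      rows <- t(vapply(mats, function(mm) mm[r, ], numeric(2)))
      rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
      paste(sprintf("%05d%05d", rows[, 1], rows[, 2]), collapse = "")
    }, character(1))
  }

  all_b <- list(); all_f <- list(); sig <- character(0); ord_key <- character(0)
  nbv <- integer(0); nfv <- integer(0)
  for (p in seq_len(part)) {
    bc <- res_breaks[[p]]; fc <- res_forms[[p]]
    nc <- nrow(bc)
    bsig <- pair_label(bc, B); fsig <- pair_label(fc, FP)
    s <- paste0("B:", bsig, "|F:", fsig)
    okey <- paste0(sort_tuple(bc, B), "|", sort_tuple(fc, FP))
    all_b <- c(all_b, lapply(seq_len(nc), function(r) {
      canonical_bonds(B[bc[r, ], , drop = FALSE])
    }))
    all_f <- c(all_f, lapply(seq_len(nc), function(r) {
      canonical_bonds(FP[fc[r, ], , drop = FALSE])
    }))
    sig <- c(sig, s); ord_key <- c(ord_key, okey)
    nbv <- c(nbv, rep(res_nb[p], nc)); nfv <- c(nfv, rep(res_nf[p], nc))
  }
  o <- order(ord_key)
  all_b <- all_b[o]; all_f <- all_f[o]; sig <- sig[o]
  nbv <- nbv[o]; nfv <- nfv[o]
  if (prune_h) {
    keep <- !duplicated(sig)
    all_b <- all_b[keep]; all_f <- all_f[keep]; sig <- sig[keep]
    nbv <- nbv[keep]; nfv <- nfv[keep]
  }
  tibble::tibble(breaks = all_b, forms = all_f,
                 n_break = nbv, n_form = nfv, signature = sig)
}

empty_driving_tbl <- function() {
  tibble::tibble(breaks = list(), forms = list(),
                 n_break = integer(0), n_form = integer(0),
                 signature = character(0))
}

#' Brute-force driving-coordinate enumeration (test oracle)
#'
#' Same contract as [enumerate_driving_coordinates()], implemented as literal
#' iteration over all subsets of bonds and non-bonded pairs with post-hoc
#' filtering through [apply_changes()] and [is_valence_feasible()]. Intended
#' for small molecules in tests; quadratic-to-combinatorial cost.
#'
#' @inheritParams enumerate_driving_coordinates
#' @return Tibble with the same columns as the main enumerator.
#' @export
driving_oracle <- function(reactant, constraints = driving_constraints()) {
  c_ <- constraints
  if (!is_valence_feasible(reactant, c_$valences)) {
    stop_rxn("invalid_input", "reactant graph is not valence-feasible")
  }
  B <- reactant$bonds
  FP <- nonbonded_pairs(reactant)
  n <- n_atoms(reactant)
  sym <- symmetry_classes(reactant)
  token <- if (c_$prune_all_equivalent) {
    paste0("c", sym)
  } else {
    ifelse(reactant$elements == "H", paste0("h", sym), paste0("n", seq_len(n)))
  }
  sig_of <- function(mat) {
    if (nrow(mat) == 0) return("")
    labs <- vapply(seq_len(nrow(mat)), function(r) {
      t1 <- token[mat[r, 1]]; t2 <- token[mat[r, 2]]
      paste0(min(t1, t2), "~", max(t1, t2))
    }, character(1))
    paste(sort(labs), collapse = "+")
  }
  key_of <- function(mat) {
    if (nrow(mat) == 0) return("")
    paste(sprintf("%05d%05d", mat[, 1], mat[, 2]), collapse = "")
  }
  subsets_of <- function(mat, kmax) {
    out <- list(mat[integer(0), , drop = FALSE])
    for (k in seq_len(min(kmax, nrow(mat)))) {
      ch <- utils::combn(nrow(mat), k)
      for (cc in seq_len(ncol(ch))) {
        out[[length(out) + 1L]] <- mat[ch[, cc], , drop = FALSE]
      }
    }
    out
  }
  rows <- list()
  for (br in subsets_of(B, c_$max_breaks)) {
    for (fm in subsets_of(FP, c_$max_forms)) {
      tot <- nrow(br) + nrow(fm)
      if (tot < c_$min_total || tot > c_$max_total) next
      prod <- apply_changes(reactant, br, fm)
      if (!is_valence_feasible(prod, c_$valences)) next
      rows[[length(rows) + 1L]] <- list(
        breaks = canonical_bonds(br), forms = canonical_bonds(fm),
        n_break = nrow(br), n_form = nrow(fm),
        signature = paste0("B:", sig_of(br), "|F:", sig_of(fm)),
        ord = paste0(key_of(canonical_bonds(br)), "|",
                     key_of(canonical_bonds(fm)))
      )
    }
  }
  if (length(rows) == 0) return(empty_driving_tbl())
  tb <- tibble::tibble(
    breaks = lapply(rows, `[[`, "breaks"),
    forms = lapply(rows, `[[`, "forms"),
    n_break = vapply(rows, `[[`, integer(1), "n_break"),
    n_form = vapply(rows, `[[`, integer(1), "n_form"),
    signature = vapply(rows, `[[`, character(1), "signature"),
    ord = vapply(rows, `[[`, character(1), "ord")
  )
  tb <- tb[order(tb$ord), ]
  if (c_$prune_equivalent_hydrogens || c_$prune_all_equivalent) {
    tb <- tb[!duplicated(tb$signature), ]
  }
  tb$ord <- NULL
  tb
}

#' Serialize driving-coordinate sets for a string-method driver
#'
#' Writes the coordinate-specification text the path-search driver expects:
#' two tokens per change, `BREAK i j` / `ADD i j`, indices 0-based, one
#' change per line, sets separated by blank lines.
#'
#' @param sets Tibble from [enumerate_driving_coordinates()].
#' @return Character vector of lines.
#' @export
format_driving_file <- function(sets) {
  out <- character(0)
  for (r in seq_len(nrow(sets))) {
    b <- sets$breaks[[r]]; f <- sets$forms[[r]]
    lines <- c(
      if (nrow(b) > 0) sprintf("BREAK %d %d", b[, 1] - 1L, b[, 2] - 1L),
      if (nrow(f) > 0) sprintf("ADD %d %d", f[, 1] - 1L, f[, 2] - 1L)
    )
    out <- c(out, lines, "")
  }
  if (length(out) > 0) out <- out[-length(out)]
  out
}
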