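#' Diversity analyses over a reaction table
#'
#' Post-hoc characterization of a curated reaction set: per-reaction
#' bond-change counts (connectivity only), bond-change types (connectivity
#' changes plus pure bond-order changes, labeled by unordered element pair),
#' reactive centers, general reaction templates over the center atoms, and
#' distribution summaries (grouped activation-energy densities and a
#' bivariate Gaussian kernel density over enthalpy and activation energy).
#'
#' Two deliberately different change definitions coexist: bond-change
#' *counts* consider connectivity only, while bond-change *types* also count
#' a change in perceived bond order between a pair that stays bonded.
#'
#' @name analyze
NULL

mapped_pair <- function(rsmi, psmi) {
  r <- mapped_graph(rsmi)
  p <- mapped_graph(psmi)
  if (n_atoms(r$graph) != n_atoms(p$graph) ||
      !identical(r$graph$elements, p$graph$elements)) {
    stop_rxn("invalid_input", "rsmi/psmi do not share an atom map space")
  }
  list(r = r, p = p)
}

#' Number of connectivity changes in a mapped reaction
#'
#' @param rsmi,psmi Atom-mapped reactant and product SMILES.
#' @return Integer: broken plus formed bond count (order changes excluded).
#' @export
count_bond_changes <- function(rsmi, psmi) {
  mp <- mapped_pair(rsmi, psmi)
  ch <- bond_changes(mp$r$graph, mp$p$graph)
  nrow(ch$broken) + nrow(ch$formed)
}

# unordered element-pair label: H last, otherwise alphabetical
pair_label <- function(e1, e2) {
  if (e1 == "H" && e2 != "H") paste0(e2, "-H")
  else if (e2 == "H" && e1 != "H") paste0(e1, "-H")
  else paste(sort(c(e1, e2)), collapse = "-")
}

#' Multiset of bond-change types in a mapped reaction
#'
#' One label per connectivity change plus one per pair that stays bonded
#' with a different perceived bond order on the two sides.
#'
#' @param rsmi,psmi Atom-mapped reactant and product SMILES.
#' @return Character vector of labels like `"C-H"`, `"C-C"`, `"O-H"`.
#' @export
bond_change_types <- function(rsmi, psmi) {
  mp <- mapped_pair(rsmi, psmi)
  els <- mp$r$graph$elements
  ch <- bond_changes(mp$r$graph, mp$p$graph)
  conn <- rbind(ch$broken, ch$formed)
  labs <- if (nrow(conn) > 0) {
    vapply(seq_len(nrow(conn)), function(k) {
      pair_label(els[conn[k, 1]], els[conn[k, 2]])
    }, character(1))
  } else character(0)
  # pure order changes on persistent bonds
  rk <- bond_keys(mp$r$graph$bonds); pk <- bond_keys(mp$p$graph$bonds)
  common <- intersect(rk, pk)
  if (length(common) > 0) {
    ro <- mp$r$orders[match(common, rk)]
    po <- mp$p$orders[match(common, pk)]
    changed <- which(ro != po)
    if (length(changed) > 0) {
      bm <- mp$r$graph$bonds[match(common[changed], rk), , drop = FALSE]
      labs <- c(labs, vapply(seq_len(nrow(bm)), function(k) {
        pair_label(els[bm[k, 1]], els[bm[k, 2]])
      }, character(1)))
    }
  }
  sort(labs)
}

#' Reactive center of a mapped reaction
#'
#' All atoms incident to a connectivity change or a bond-order change.
#'
#' @param rsmi,psmi Atom-mapped reactant and product SMILES.
#' @return Sorted integer vector of atom (map) indices.
#' @export
reactive_center <- function(rsmi, psmi) {
  mp <- mapped_pair(rsmi, psmi)
  ch <- bond_changes(mp$r$graph, mp$p$graph)
  atoms <- c(as.vector(ch$broken), as.vector(ch$formed))
  rk <- bond_keys(mp$r$graph$bonds); pk <- bond_keys(mp$p$graph$bonds)
  common <- intersect(rk, pk)
  if (length(common) > 0) {
    ro <- mp$r$orders[match(common, rk)]
    po <- mp$p$orders[match(common, pk)]
    changed <- common[ro != po]
    if (length(changed) > 0) {
      atoms <- c(atoms, as.vector(mp$r$graph$bonds[match(changed, rk), ,
                                                   drop = FALSE]))
    }
  }
  atoms <- sort(unique(atoms))
  if (length(atoms) == 0) stop_rxn("no_reaction", "no bond or order change")
  atoms
}

# canonical SMARTS-like serialization of the induced center subgraph of one
# side; features: element, charge, aromatic flag, bond type
serialize_center_side <- function(g, orders, aromatic, center) {
  keep <- g$bonds[, 1] %in% center & g$bonds[, 2] %in% center
  sub_bonds <- g$bonds[keep, , drop = FALSE]
  remap <- match(sub_bonds, center)
  sub <- mol_graph(g$elements[center],
                   if (length(remap) > 0) matrix(remap, ncol = 2L) else NULL,
                   charges = g$charges[center])
  sub_orders <- orders[keep]
  sub_arom <- aromatic[center]
  frs <- fragments(sub)
  frag_strings <- vapply(frs, function(fr) {
    idx <- attr(fr, "parent_indices")
    fkeep <- which(sub$bonds[, 1] %in% idx & sub$bonds[, 2] %in% idx)
    f_orders <- sub_orders[fkeep]
    f_arom <- sub_arom[idx]
    # canonical relabeling for label-invariance
    colors <- as.integer(factor(paste(fr$elements, fr$charges, f_arom)))
    perm <- if (n_atoms(fr) > 1) {
      igraph::canonical_permutation(as_igraph(fr), colors = colors)$labeling
    } else 1L
    fr2 <- permute_atoms(fr, perm)
    arom2 <- f_arom[order(perm)]
    relab <- if (nrow(fr$bonds) > 0) {
      matrix(as.integer(perm[fr$bonds]), ncol = 2L)
    } else fr$bonds
    ord2 <- f_orders[match(bond_keys(fr2$bonds), bond_keys(sort_bond_rows(relab)))]
    template_smarts(fr2, ord2, arom2)
  }, character(1))
  paste(sort(frag_strings), collapse = ".")
}

# SMARTS-ish writer: lowercase element for aromatic atoms, ':' bonds between
# aromatic neighbors, '=', '#' for higher orders
template_smarts <- function(g, orders, aromatic) {
  tok <- function(a) {
    el <- g$elements[a]
    if (aromatic[a]) el <- tolower(el)
    chg <- g$charges[a]
    chg_s <- if (chg == 0L) "" else if (chg > 0L) {
      if (chg == 1L) "+" else paste0("+", chg)
    } else {
      if (chg == -1L) "-" else paste0("-", abs(chg))
    }
    paste0("[", el, chg_s, "]")
  }
  okey <- bond_keys(g$bonds)
  btok <- function(i, j) {
    k <- if (i < j) i * 100000L + j else j * 100000L + i
    o <- orders[match(k, okey)]
    if (aromatic[i] && aromatic[j]) ":" else c("", "=", "#")[o]
  }
  write_smiles_tokens(g, tok, btok)
}

# shared DFS serializer used by template_smarts (same traversal rules as
# write_smiles, token functions injected)
write_smiles_tokens <- function(g, atom_token, bond_token_fn) {
  n <- n_atoms(g)
  adj <- adjacency_list(g)
  visited <- rep(FALSE, n)
  seen <- rep(FALSE, n); parent <- rep(0L, n)
  back_edges <- list()
  for (root in seq_len(n)) {
    if (seen[root]) next
    stack <- root; seen[root] <- TRUE
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE; parent[w] <- v; stack <- c(stack, w)
        } else if (w != parent[v]) {
          k <- if (v < w) paste(v, w) else paste(w, v)
          back_edges[[k]] <- c(min(v, w), max(v, w))
        }
      }
    }
  }
  ring_open <- lapply(seq_len(max(n, 1)), function(a) character(0))
  dg <- 0L
  for (k in names(back_edges)) {
    dg <- dg + 1L
    e <- back_edges[[k]]
    t1 <- paste0(bond_token_fn(e[1], e[2]),
                 if (dg < 10L) as.character(dg) else sprintf("%%%02d", dg))
    ring_open[[e[1]]] <- c(ring_open[[e[1]]], t1)
    ring_open[[e[2]]] <- c(ring_open[[e[2]]], t1)
  }
  is_back <- function(i, j) {
    k <- if (i < j) paste(i, j) else paste(j, i)
    !is.null(back_edges[[k]])
  }
  emit <- function(v, from) {
    out <- if (from > 0L) bond_token_fn(from, v) else ""
    out <- paste0(out, atom_token(v), paste(ring_open[[v]], collapse = ""))
    visited[v] <<- TRUE
    nbrs <- setdiff(adj[[v]], from)
    nbrs <- nbrs[!vapply(nbrs, function(w) is_back(v, w), logical(1))]
    nbrs <- nbrs[!visited[nbrs]]
    if (length(nbrs) > 0) {
      for (q in seq_along(nbrs)) {
        w <- nbrs[q]
        if (visited[w]) next
        branch <- emit(w, v)
        if (q < length(nbrs)) branch <- paste0("(", branch, ")")
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

#' Extract the general reaction template of a mapped reaction
#'
#' The induced subgraphs of the reactive-center atoms on the two sides,
#' canonically serialized (reactant fragments `>>` product fragments) using
#' only element identity, formal charge, aromaticity and bond type.
#' Relabeled copies of the same reaction give identical template strings,
#' and spectator atoms outside the center never affect the template.
#'
#' @param rsmi,psmi Atom-mapped reactant and product SMILES.
#' @return Template string.
#' @export
extract_template <- function(rsmi, psmi) {
  mp <- mapped_pair(rsmi, psmi)
  center <- reactive_center(rsmi, psmi)
  r_arom <- aromatic_flags(mp$r$graph, mp$r$orders)
  p_arom <- aromatic_flags(mp$p$graph, mp$p$orders)
  paste0(
    serialize_center_side(mp$r$graph, mp$r$orders, r_arom, center),
    ">>",
    serialize_center_side(mp$p$graph, mp$p$orders, p_arom, center)
  )
}

#' Rank reaction templates by frequency
#'
#' @param reactions Tibble with columns `rsmi`, `psmi`.
#' @return Tibble (`template`, `n`) sorted by count descending, template
#'   string ascending.
#' @export
template_ranking <- function(reactions) {
  if (nrow(reactions) == 0) {
    return(tibble::tibble(template = character(0), n = integer(0)))
  }
  reactions |>
    dplyr::mutate(template = purrr::map2_chr(.data$rsmi, .data$psmi,
                                             extract_template)) |>
    dplyr::count(.data$template) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$template)
}

#' Activation-energy distributions grouped by bond-change count
#'
#' Per-group Gaussian kernel densities, each renormalized to integrate to 1
#' on its evaluation grid (equal-area scaling). Groups with a single
#' reaction use a fixed 1 kcal/mol kernel width (the data-driven bandwidth
#' rule needs at least two points).
#'
#' @param reactions Tibble with columns `rsmi`, `psmi`, `ea`.
#' @param gridsize Density grid size.
#' @return Nested tibble: `n_changes`, `n`, `median_ea`, `density`
#'   (list of tibbles with `ea`, `dens`).
#' @export
ea_by_change_count <- function(reactions, gridsize = 512L) {
  if (nrow(reactions) == 0) {
    return(tibble::tibble(n_changes = integer(0), n = integer(0),
                          median_ea = numeric(0), density = list()))
  }
  reactions |>
    dplyr::mutate(n_changes = purrr::map2_int(.data$rsmi, .data$psmi,
                                              count_bond_changes)) |>
    dplyr::group_by(.data$n_changes) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_ea = stats::median(.data$ea),
      density = list({
        x <- .data$ea
        d <- if (length(x) >= 2 && stats::sd(x) > 0) {
          stats::density(x, n = gridsize)
        } else {
          gx <- seq(x[1] - 4, x[1] + 4, length.out = gridsize)
          list(x = gx, y = stats::dnorm(gx, mean = x[1], sd = 1))
        }
        area <- trapezoid(d$x, d$y)
        tibble::tibble(ea = d$x, dens = d$y / area)
      }),
      .groups = "drop"
    )
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Bivariate Gaussian kernel density over (dh, ea)
#'
#' Product Gaussian kernels with Scott's bandwidth rule per dimension
#' (`sd * n^(-1/6)`) unless `h` is given. The density integrates to 1 over
#' the plane by construction; on the returned grid to within the grid
#' truncation.
#'
#' @param reactions Tibble with columns `dh`, `ea` (kcal/mol), or a
#'   two-column matrix/data frame of coordinates.
#' @param h Bandwidth(s): scalar or length-2 `(h_dh, h_ea)`; required when a
#'   dimension has zero variance (e.g. a single point).
#' @param gridsize Grid points per axis.
#' @param lims Optional `c(xmin, xmax, ymin, ymax)`; default data range
#'   widened by 4 bandwidths.
#' @return An object of class `rxn_kde2d`: list with `x`, `y`, `z`
#'   (gridsize x gridsize), `h`, `n`.
#' @export
kde2d_reactions <- function(reactions, h = NULL, gridsize = 101L, lims = NULL) {
  if (is.data.frame(reactions) && all(c("dh", "ea") %in% names(reactions))) {
    xs <- reactions$dh; ys <- reactions$ea
  } else {
    m <- as.matrix(reactions)
    xs <- m[, 1]; ys <- m[, 2]
  }
  n <- length(xs)
  if (n == 0) stop_rxn("invalid_input", "no points for the KDE")
  if (is.null(h)) {
    sx <- stats::sd(xs); sy <- stats::sd(ys)
    if (n < 2 || is.na(sx) || sx == 0 || sy == 0) {
      stop_rxn("invalid_input",
               "bandwidth h must be given for degenerate samples")
    }
    h <- c(sx, sy) * n^(-1 / 6)   # Scott's rule, product kernel
  }
  h <- rep_len(h, 2L)
  if (is.null(lims)) {
    lims <- c(min(xs) - 4 * h[1], max(xs) + 4 * h[1],
              min(ys) - 4 * h[2], max(ys) + 4 * h[2])
  }
  gx <- seq(lims[1], lims[2], length.out = gridsize)
  gy <- seq(lims[3], lims[4], length.out = gridsize)
  kx <- outer(gx, xs, function(a, b) stats::dnorm(a - b, sd = h[1]))
  ky <- outer(gy, ys, function(a, b) stats::dnorm(a - b, sd = h[2]))
  z <- kx %*% t(ky) / n
  structure(list(x = gx, y = gy, z = z, h = h, n = n), class = "rxn_kde2d")
}

#' @export
print.rxn_kde2d <- function(x, ...) {
  cat(sprintf("<rxn_kde2d> %d points, %dx%d grid, h = (%.4g, %.4g)\n",
              x$n, length(x$x), length(x$y), x$h[1], x$h[2]))
  invisible(x)
}

#' Plot a bivariate reaction-space density
#'
#' @param object An `rxn_kde2d`.
#' @param ... Unused.
#' @return A ggplot (filled raster plus contours).
#' @export
autoplot.rxn_kde2d <- function(object, ...) {
  df <- expand.grid(dh = object$x, ea = object$y)
  df$density <- as.vector(object$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dh, y = .data$ea)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$density), color = "white",
                          linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Enthalpy of reaction (kcal/mol)",
                  y = "Activation energy (kcal/mol)", fill = "Density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot grouped activation-energy distributions
#'
#' @param groups Output of [ea_by_change_count()].
#' @return A ggplot of the equal-area densities, one line per change count.
#' @export
plot_ea_by_change_count <- function(groups) {
  df <- tidyr::unnest(groups, "density")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ea, y = .data$dens,
                                   color = factor(.data$n_changes))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Activation energy (kcal/mol)", y = "Density",
                  color = "Bond changes") +
    ggplot2::theme_minimal()
}

#' Plot bond-change-type counts
#'
#' @param reactions Tibble with `rsmi`, `psmi`.
#' @return A ggplot bar chart of change-type counts.
#' @export
plot_bond_change_types <- function(reactions) {
  labs <- unlist(purrr::map2(reactions$rsmi, reactions$psmi, bond_change_types))
  df <- dplyr::count(tibble::tibble(type = labs), .data$type)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$type, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Bond change type", y = "Count") +
    ggplot2::theme_minimal()
}

#' Plot a template ranking
#'
#' @param ranking Output of [template_ranking()].
#' @param top Number of templates to show.
#' @return A ggplot bar chart of the most frequent templates.
#' @export
plot_template_ranking <- function(ranking, top = 20L) {
  df <- utils::head(ranking, top)
  df$template <- factor(df$template, levels = rev(df$template))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$template)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Reaction examples", y = NULL) +
    ggplot2::theme_minimal()
}
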