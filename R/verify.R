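#' Transition-state verification filters
#'
#' The filter stack deciding whether a proposed reactant/TS/product triple is
#' a verified elementary reaction: the TS must have exactly one imaginary
#' frequency of magnitude at least 100 cm^-1; the TS optimization must not
#' have drifted more than 3 kcal/mol from the highest string-path energy;
#' the imaginary-mode displacements along the changing bonds must exceed
#' those along all unchanged bonds; and both endpoints must be true minima
#' (no imaginary frequencies). A failing check is data, never an error.
#'
#' @name verify
NULL

#' Check the TS imaginary-frequency count and magnitude
#'
#' @param freqs Frequency list in cm^-1, imaginary negative.
#' @param magnitude_min Minimum magnitude for the imaginary mode (cm^-1);
#'   transition states below it typically correspond to conformational
#'   changes. A value of exactly `magnitude_min` passes ("less than" is
#'   strict).
#' @return List with logicals `one_imaginary` and `imag_magnitude_ok` (the
#'   latter is `FALSE` whenever the former is).
#' @export
check_ts_imaginary <- function(freqs, magnitude_min = 100) {
  if (length(freqs) == 0) stop_rxn("invalid_input", "empty frequency list")
  neg <- freqs[freqs < 0]
  one <- length(neg) == 1L
  list(one_imaginary = one,
       imag_magnitude_ok = one && abs(neg[1]) >= magnitude_min)
}

#' Check TS-optimization energy drift against the string path
#'
#' TRUE iff the TS optimization changed the energy by no more than `tol`
#' kcal/mol relative to the highest energy on the string path ("more than"
#' is strict, so a drift of exactly `tol` passes).
#'
#' @param ts_opt_energy Optimized TS electronic energy, hartree.
#' @param string_max_energy Highest node energy on the string path, hartree.
#' @param tol Tolerance in kcal/mol.
#' @return Logical scalar.
#' @export
check_energy_drift <- function(ts_opt_energy, string_max_energy, tol = 3.0) {
  stopifnot(is.finite(ts_opt_energy), is.finite(string_max_energy))
  abs(ts_opt_energy - string_max_energy) * HARTREE_TO_KCAL <= tol
}

#' Check that the imaginary mode matches the bond changes
#'
#' For the unit-normalized imaginary-mode displacement u, the score of an
#' atom pair (i, j) is `|(u_i - u_j) . e_ij|`, the relative displacement
#' projected on the unit inter-atom direction in the TS geometry -- the
#' bond-stretch character of the mode along that pair. The check passes iff
#' the minimum score over changing bonds (the connectivity diff between
#' reactant and product) strictly exceeds the maximum score over all other
#' bonded pairs (union of reactant and product bonds); ties reject. No mass
#' weighting is applied. Scores depend only on relative displacements and
#' internal directions, so they are invariant under rigid rotation and
#' translation of geometry-plus-mode and under a global mode sign flip.
#'
#' @param ts An `optfreq_result` with exactly one imaginary mode.
#' @param reactant_graph,product_graph `mol_graph`s in the TS atom space.
#' @return List with `ok` and a tibble `scores` (i, j, role, score).
#' @export
check_mode_match <- function(ts, reactant_graph, product_graph) {
  imag <- which(ts$frequencies < 0)
  if (length(imag) != 1L) {
    stop_rxn("invalid_input", "mode-match check requires exactly one imaginary mode")
  }
  u <- ts$modes[[imag]]
  geom <- ts$geometry
  ch <- bond_changes(reactant_graph, product_graph)
  changing <- canonical_bonds(rbind(ch$broken, ch$formed))
  if (nrow(changing) == 0) stop_rxn("no_reaction", "no connectivity change")
  all_bonds <- canonical_bonds(rbind(reactant_graph$bonds, product_graph$bonds))
  all_bonds <- all_bonds[!duplicated(bond_keys(all_bonds)), , drop = FALSE]
  unchanged <- all_bonds[!(bond_keys(all_bonds) %in% bond_keys(changing)), ,
                         drop = FALSE]
  score_of <- function(pairs) {
    if (nrow(pairs) == 0) return(numeric(0))
    du <- u[pairs[, 1], , drop = FALSE] - u[pairs[, 2], , drop = FALSE]
    dx <- geom[pairs[, 1], , drop = FALSE] - geom[pairs[, 2], , drop = FALSE]
    nx <- sqrt(rowSums(dx^2))
    abs(rowSums(du * dx) / nx)
  }
  s_ch <- score_of(changing)
  s_un <- score_of(unchanged)
  ok <- if (length(s_un) == 0) all(s_ch > 0) else min(s_ch) > max(s_un)
  scores <- tibble::tibble(
    i = c(changing[, 1], unchanged[, 1]),
    j = c(changing[, 2], unchanged[, 2]),
    role = rep(c("changing", "unchanged"), c(nrow(changing), nrow(unchanged))),
    score = c(s_ch, s_un)
  )
  list(ok = ok, scores = scores)
}

#' Check that an endpoint is a true minimum
#'
#' TRUE iff no negative frequencies. An empty list (single atom: no modes)
#' passes. Any negative value counts as imaginary by default; a leniency
#' window for noisy inputs can be configured via `zero_threshold` (negative
#' values above it are treated as numerically zero).
#'
#' @param r An `optfreq_result` or a bare frequency vector.
#' @param zero_threshold Non-positive number; frequencies in
#'   `[zero_threshold, 0)` are ignored. Default 0 (no leniency).
#' @return Logical scalar.
#' @export
check_minimum <- function(r, zero_threshold = 0) {
  freqs <- if (inherits(r, "optfreq_result")) r$frequencies else r
  all(freqs >= zero_threshold)
}

#' Run the full verification filter stack on a proposed reaction
#'
#' Aggregates all checks into a `verification_report`; `passed` is the
#' conjunction of the five booleans. Failing checks never raise.
#'
#' @param r,ts,p `optfreq_result` records for reactant, TS, product.
#' @param reactant_graph,product_graph Mapped `mol_graph`s (same atom space).
#' @param string A `string_path` for the underlying path search.
#' @param imag_magnitude_min Imaginary-frequency magnitude cutoff, cm^-1.
#' @param drift_tol Energy-drift tolerance, kcal/mol.
#' @param zero_threshold See [check_minimum()].
#' @return A `verification_report`.
#' @export
verify_reaction <- function(r, ts, p, reactant_graph, product_graph, string,
                            imag_magnitude_min = 100, drift_tol = 3.0,
                            zero_threshold = 0) {
  nat <- length(ts$elements)
  if (length(r$elements) != nat || length(p$elements) != nat ||
      n_atoms(reactant_graph) != nat || n_atoms(product_graph) != nat) {
    stop_rxn("invalid_input", "inconsistent atom counts across the triple")
  }
  imag <- check_ts_imaginary(ts$frequencies, imag_magnitude_min)
  drift_kcal <- abs(ts$energy - max(string$node_energies)) * HARTREE_TO_KCAL
  drift_ok <- check_energy_drift(ts$energy, max(string$node_energies), drift_tol)
  mm <- if (imag$one_imaginary) {
    tryCatch(check_mode_match(ts, reactant_graph, product_graph),
             rxnforge_no_reaction = function(e) list(ok = FALSE, scores = NULL))
  } else {
    list(ok = FALSE, scores = NULL)
  }
  minima <- check_minimum(r, zero_threshold) && check_minimum(p, zero_threshold)
  passed <- imag$one_imaginary && imag$imag_magnitude_ok && drift_ok &&
    mm$ok && minima
  structure(list(
    one_imaginary = imag$one_imaginary,
    imag_magnitude_ok = imag$imag_magnitude_ok,
    energy_drift_ok = drift_ok,
    mode_match_ok = mm$ok,
    endpoints_are_minima = minima,
    passed = passed,
    details = list(
      ts_frequencies = ts$frequencies,
      drift_kcal = drift_kcal,
      mode_scores = mm$scores
    )
  ), class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  checks <- c("one_imaginary", "imag_magnitude_ok", "energy_drift_ok",
              "mode_match_ok", "endpoints_are_minima")
  cat("<verification_report>", if (x$passed) "PASSED" else "FAILED", "\n")
  for (ck in checks) {
    cat(sprintf("  %-22s %s\n", ck, if (x[[ck]]) "ok" else "FAIL"))
  }
  invisible(x)
}

#' Tidy a verification report into one row per check
#'
#' @param x A `verification_report`.
#' @param ... Unused.
#' @return A tibble with columns `check` and `passed`.
#' @export
tidy.verification_report <- function(x, ...) {
  checks <- c("one_imaginary", "imag_magnitude_ok", "energy_drift_ok",
              "mode_match_ok", "endpoints_are_minima")
  tibble::tibble(check = checks,
                 passed = vapply(checks, function(ck) isTRUE(x[[ck]]), logical(1)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
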