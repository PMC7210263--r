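#' Unit constants
#'
#' Pinned conversion constants: 1 hartree = 627.5095 kcal/mol, and one
#' wavenumber of harmonic zero-point energy = 0.0028591 kcal/mol (h*c/2
#' folded into the per-mode factor 1/2 * nu * 0.0028591).
#'
#' @name constants
NULL

#' @rdname constants
#' @export
HARTREE_TO_KCAL <- 627.5095

#' @rdname constants
#' @export
WAVENUMBER_TO_KCAL <- 0.0028591

#' Harmonic zero-point energy from frequencies
#'
#' Sum of `0.5 * nu * 0.0028591` kcal/mol over strictly positive
#' frequencies; imaginary (negative) and zero entries are excluded.
#' Frequencies are used unscaled.
#'
#' @param freqs Frequencies in cm^-1 (may be empty or contain negatives).
#' @return ZPE in kcal/mol (0 for an atom with no modes).
#' @export
zpe_from_frequencies <- function(freqs) {
  pos <- freqs[freqs > 0]
  0.5 * sum(pos) * WAVENUMBER_TO_KCAL
}

#' Species energetics record
#'
#' Combines the electronic energy with the harmonic ZPE into the 0 K energy
#' `e0 = e_elec * 627.5095 + zpe` (kcal/mol). No thermal corrections are
#' applied anywhere: frequencies serve only the ZPE and the filters.
#'
#' @param e_elec Electronic energy, hartree.
#' @param freqs Harmonic frequencies in cm^-1 (or an `optfreq_result`).
#' @param level Level-of-theory tag, e.g. `"B97-D3/def2-mSVP"`; activation
#'   energies and enthalpies refuse to mix levels.
#' @return A `species_energetics` list with `e_elec`, `zpe`, `e0`, `level`.
#' @export
species_energetics <- function(e_elec, freqs = numeric(0), level = "unspecified") {
  if (inherits(e_elec, "optfreq_result")) {
    freqs <- e_elec$frequencies
    e_elec <- e_elec$energy
  }
  if (inherits(freqs, "optfreq_result")) freqs <- freqs$frequencies
  zpe <- zpe_from_frequencies(freqs)
  structure(list(e_elec = e_elec, zpe = zpe,
                 e0 = e_elec * HARTREE_TO_KCAL + zpe, level = level),
            class = "species_energetics")
}

check_same_level <- function(...) {
  levels <- unique(vapply(list(...), `[[`, character(1), "level"))
  if (length(levels) > 1) {
    stop_rxn("consistency",
             paste0("level-of-theory mismatch: ", paste(levels, collapse = " vs ")))
  }
}

#' ZPE-corrected activation energy
#'
#' `ts$e0 - r$e0` in kcal/mol. Negative values are retained with a warning
#' (no rejection rule applies to them).
#'
#' @param r,ts `species_energetics` for reactant and transition state.
#' @return Activation energy, kcal/mol.
#' @export
activation_energy <- function(r, ts) {
  check_same_level(r, ts)
  ea <- ts$e0 - r$e0
  if (ea < 0) warning("negative activation energy (", signif(ea, 4), " kcal/mol)")
  ea
}

#' ZPE-corrected reaction enthalpy (0 K)
#'
#' `sum(products$e0) - r$e0` in kcal/mol: the 0 K ZPE-corrected electronic
#' energy difference between the product set and the reactant.
#'
#' @param r Reactant `species_energetics`.
#' @param products List of product `species_energetics` (non-empty).
#' @return Reaction enthalpy, kcal/mol.
#' @export
reaction_enthalpy <- function(r, products) {
  if (inherits(products, "species_energetics")) products <- list(products)
  if (length(products) == 0) stop_rxn("invalid_input", "empty product list")
  do.call(check_same_level, c(list(r), products))
  sum(vapply(products, `[[`, numeric(1), "e0")) - r$e0
}
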