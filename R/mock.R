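#' Mock external engine and fixture generators
#'
#' The quantum-chemistry engine and the string-path optimizer enter the
#' pipeline only through a pluggable executor contract: an executor is a
#' function taking a job (input text plus structured metadata) and returning
#' a status and an output text parseable by the qcio readers. The mock
#' executor implemented here synthesizes physically shaped outputs from
#' planted ground truth -- deterministic given its seed -- so the entire
#' pipeline runs and is testable at desk scale with no external software.
#'
#' Planted energy model: each species has an electronic energy drawn
#' per (identity, level of theory); each reaction path gets a barrier above
#' its endpoints plus a small per-path conformer jitter, so duplicate
#' discoveries of the same reaction differ slightly in barrier height (which
#' is what duplicate retention and final dedup act on). Transition-state
#' imaginary modes are built by translating the rigid fragments of the
#' unchanged-bond graph against each other, so displacement scores on
#' unchanged bonds vanish identically and the mode matches the planted bond
#' changes.
#'
#' @name mock
NULL

# deterministic 31-bit seed from a global seed and a string key
derive_seed <- function(global, key) {
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147480000
  as.integer((h + as.numeric(global) * 7919) %% 2147480000) + 1L
}

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# per-element electronic energy baseline, hartree (shape only; the pipeline
# never interprets absolute energies, only differences)
element_energy <- c(H = -0.5, C = -38.0, N = -54.5, O = -75.0)

mock_species_energy <- function(g, level, seed) {
  base <- sum(element_energy[g$elements]) - 0.02 * nrow(g$bonds)
  key <- paste0("E|", level, "|", identity_key(g))
  base + with_seed(derive_seed(seed, key), stats::runif(1, -0.05, 0.05)) -
    (if (grepl("TZVP", level)) 0.35 else 0)
}

mock_min_frequencies <- function(n_atoms, seed) {
  nm <- max(0L, 3L * n_atoms - 6L)
  if (n_atoms == 2) nm <- 1L
  with_seed(seed, sort(stats::runif(nm, 200, 3600)))
}

random_unit_modes <- function(n_modes, n_atoms, seed) {
  with_seed(seed, lapply(seq_len(n_modes), function(k) {
    m <- matrix(stats::rnorm(3 * n_atoms), n_atoms, 3)
    m / sqrt(sum(m^2))
  }))
}

#' Imaginary-mode displacement matching a set of bond changes
#'
#' Builds a Cartesian displacement that moves the connected components of
#' the unchanged-bond graph as rigid units: unchanged-pair relative
#' displacements are exactly zero while every changing pair, which bridges
#' two components, gets a nonvanishing projection. Returns NULL when some
#' changing pair lies inside a single unchanged component (a ring
#' rearrangement the rigid construction cannot represent).
#'
#' @param geometry TS geometry, N x 3.
#' @param reactant_graph,product_graph Mapped graphs defining the changes.
#' @param seed Seed for the component translation directions.
#' @return Unit-Frobenius-norm N x 3 matrix, or NULL.
#' @export
ts_imaginary_mode <- function(geometry, reactant_graph, product_graph, seed) {
  n <- n_atoms(reactant_graph)
  ch <- bond_changes(reactant_graph, product_graph)
  changing <- canonical_bonds(rbind(ch$broken, ch$formed))
  all_b <- canonical_bonds(rbind(reactant_graph$bonds, product_graph$bonds))
  all_b <- all_b[!duplicated(bond_keys(all_b)), , drop = FALSE]
  unchanged <- all_b[!(bond_keys(all_b) %in% bond_keys(changing)), , drop = FALSE]
  ug <- igraph::graph_from_edgelist(matrix(unchanged, ncol = 2), directed = FALSE)
  miss <- n - igraph::vcount(ug)
  if (miss > 0) ug <- igraph::add_vertices(ug, miss)
  comp <- igraph::components(ug)$membership
  if (any(comp[changing[, 1]] == comp[changing[, 2]])) return(NULL)
  for (attempt in 1:60) {
    tr <- with_seed(derive_seed(seed, paste0("tsmode", attempt)), {
      matrix(stats::rnorm(3 * max(comp)), max(comp), 3)
    })
    u <- tr[comp, , drop = FALSE]
    u <- u - matrix(colMeans(u), n, 3, byrow = TRUE)  # remove net translation
    nrm <- sqrt(sum(u^2))
    if (nrm < 1e-8) next
    u <- u / nrm
    dx <- geometry[changing[, 1], , drop = FALSE] - geometry[changing[, 2], , drop = FALSE]
    du <- u[changing[, 1], , drop = FALSE] - u[changing[, 2], , drop = FALSE]
    sc <- abs(rowSums(du * dx) / sqrt(rowSums(dx^2)))
    if (min(sc) > 0.05) return(u)
  }
  NULL
}

#' Mock engine executor
#'
#' Returns an executor closure satisfying the pipeline's contract:
#' `executor(job)` gives `list(status, output)` with `output` parseable by
#' [parse_optfreq_log()] or [parse_string_output()]. Deterministic given
#' `seed` and the job stream.
#'
#' @param seed Global seed for the planted ground truth.
#' @param ts_fail_rate Fraction of TS-optimization jobs that fail (seeded
#'   per job), emulating unconverged optimizations.
#' @param drift_sd Standard deviation (kcal/mol) of the TS-optimization
#'   energy drift relative to the string maximum (clean default well below
#'   the 3 kcal/mol filter).
#' @return A function of one `job` argument.
#' @export
mock_executor <- function(seed = 1L, ts_fail_rate = 0, drift_sd = 0.3) {
  force(seed); force(ts_fail_rate); force(drift_sd)
  function(job) {
    jseed <- derive_seed(seed, job$key)
    switch(job$type,
      opt_freq = {
        g <- job$meta$graph
        n <- n_atoms(g)
        energy <- mock_species_energy(g, job$meta$level, seed)
        freqs <- mock_min_frequencies(n, jseed)
        modes <- random_unit_modes(length(freqs), n, jseed + 1L)
        list(status = "ok", output = make_mock_optfreq_log(
          energy, g$elements, job$meta$geometry, freqs, modes))
      },
      string = {
        rg <- job$meta$reactant_graph
        pg <- tryCatch(
          apply_changes(rg, job$meta$breaks, job$meta$forms),
          error = function(e) NULL)
        if (is.null(pg)) return(list(status = "failed", output = NULL))
        p_geom <- tryCatch(embed_geometry(pg, seed = jseed),
                           error = function(e) NULL)
        if (is.null(p_geom)) return(list(status = "failed", output = NULL))
        lvl <- job$meta$level
        e_r <- mock_species_energy(rg, lvl, seed)
        e_p <- mock_species_energy(pg, lvl, seed)
        rxn_key <- paste0(identity_key(rg), ">>", identity_key(pg))
        barrier <- with_seed(derive_seed(seed, paste0("BARR|", lvl, "|", rxn_key)),
                             stats::runif(1, 0.015, 0.12))
        jitter <- with_seed(jseed + 2L, stats::runif(1, 0, 0.006))
        e_ts <- max(e_r, e_p) + barrier + jitter
        nn <- 9L
        up <- seq(e_r, e_ts, length.out = 5L)
        down <- seq(e_ts, e_p, length.out = 5L)[-1]
        list(status = "ok", output = make_mock_string_output(
          c(up, down), rg$elements,
          ts_geometry = job$meta$geometry,
          endpoint_geometry = p_geom))
      },
      ts_opt_freq = {
        if (ts_fail_rate > 0 &&
            with_seed(jseed + 3L, stats::runif(1)) < ts_fail_rate) {
          return(list(status = "failed", output = NULL))
        }
        rg <- job$meta$reactant_graph
        pg <- job$meta$product_graph
        geom <- job$meta$geometry
        n <- n_atoms(rg)
        u <- ts_imaginary_mode(geom, rg, pg, jseed + 4L)
        if (is.null(u)) return(list(status = "failed", output = NULL))
        drift <- with_seed(jseed + 5L, stats::rnorm(1, 0, drift_sd)) / HARTREE_TO_KCAL
        energy <- job$meta$string_max_energy + drift
        imag <- with_seed(jseed + 6L, -stats::runif(1, 400, 1600))
        pos <- mock_min_frequencies(n, jseed + 7L)
        if (length(pos) > 0) pos <- pos[-1]
        freqs <- c(imag, pos)
        modes <- c(list(u), random_unit_modes(length(pos), n, jseed + 8L))
        list(status = "ok", output = make_mock_optfreq_log(
          energy, rg$elements, geom, freqs, modes))
      },
      stop_rxn("invalid_input", paste("unknown job type", job$type))
    )
  }
}

# small catalog of reactant SMILES + driving-coordinate choice with at least
# one unchanged bond, used by the defect-injection suite
suite_catalog <- function() {
  list(
    list(smiles = "C",  pick = 1L),   # CH4: break 2 C-H, form H-H
    list(smiles = "CC", pick = 1L),
    list(smiles = "CO", pick = 1L),
    list(smiles = "CCO", pick = 1L)
  )
}

#' Seeded defect-injection suite of reactant/TS/product triples
#'
#' Builds `n_per_class` mock triples per class: `clean` (passes every
#' filter), `two_imag` (two imaginary TS frequencies), `small_imag`
#' (imaginary magnitude below 100 cm^-1), `drift` (TS optimization more
#' than 3 kcal/mol from the string maximum) and `spectator_mode` (imaginary
#' mode localized on an unchanged bond). The planted label is the ground
#' truth the verification stack is judged against.
#'
#' @param seed Suite seed.
#' @param n_per_class Triples per class.
#' @param classes Character vector of classes to generate.
#' @return Tibble with list-columns `r`, `ts`, `p` (`optfreq_result`),
#'   `rg`, `pg` (`mol_graph`), `string` (`string_path`), plus `defect` and
#'   the planted `should_pass`.
#' @export
make_verification_suite <- function(seed = 1L, n_per_class = 10L,
                                    classes = c("clean", "two_imag",
                                                "small_imag", "drift",
                                                "spectator_mode")) {
  catalog <- suite_catalog()
  # embed and enumerate each catalog entry once
  bases <- lapply(seq_along(catalog), function(k) {
    smi <- catalog[[k]]$smiles
    g <- mol_from_smiles(smi)
    sets <- enumerate_driving_coordinates(g)
    dc <- sets[catalog[[k]]$pick, ]
    pg <- apply_changes(g, dc$breaks[[1]], dc$forms[[1]])
    r_geom <- embed_geometry(g, seed = derive_seed(seed, paste0("su-r", k)))
    p_geom <- embed_geometry(pg, seed = derive_seed(seed, paste0("su-p", k)))
    list(g = g, pg = pg, r_geom = r_geom, p_geom = p_geom, smiles = smi)
  })
  rows <- list()
  idx <- 0L
  for (cls in classes) {
    for (q in seq_len(n_per_class)) {
      idx <- idx + 1L
      b <- bases[[(idx - 1L) %% length(bases) + 1L]]
      tseed <- derive_seed(seed, paste0("triple", idx))
      n <- n_atoms(b$g)
      e_r <- -50 - 0.9 * n + with_seed(tseed, stats::runif(1, 0, 0.04))
      e_p <- e_r + with_seed(tseed + 1L, stats::runif(1, -0.04, 0.06))
      barrier <- with_seed(tseed + 2L, stats::runif(1, 0.02, 0.12))
      e_ts <- max(e_r, e_p) + barrier
      r_rec <- parse_optfreq_log(make_mock_optfreq_log(
        e_r, b$g$elements, b$r_geom,
        mock_min_frequencies(n, tseed + 3L),
        random_unit_modes(length(mock_min_frequencies(n, tseed + 3L)), n, tseed + 4L)))
      p_rec <- parse_optfreq_log(make_mock_optfreq_log(
        e_p, b$g$elements, b$p_geom,
        mock_min_frequencies(n, tseed + 5L),
        random_unit_modes(length(mock_min_frequencies(n, tseed + 5L)), n, tseed + 6L)))
      u <- ts_imaginary_mode(b$r_geom, b$g, b$pg, tseed + 7L)
      imag_mag <- with_seed(tseed + 8L, stats::runif(1, 400, 1600))
      ts_energy <- e_ts
      string_max <- e_ts
      pos <- mock_min_frequencies(n, tseed + 9L)
      if (length(pos) > 0) pos <- pos[-1]
      freqs <- c(-imag_mag, pos)
      modes <- c(list(u), random_unit_modes(length(pos), n, tseed + 10L))
      if (cls == "two_imag") {
        freqs <- c(freqs[1], -250.0, freqs[-1])
        modes <- c(modes[1], random_unit_modes(1, n, tseed + 11L), modes[-1])
      } else if (cls == "small_imag") {
        freqs[1] <- -with_seed(tseed + 12L, stats::runif(1, 20, 90))
      } else if (cls == "drift") {
        ts_energy <- string_max +
          (3.0 + with_seed(tseed + 13L, stats::runif(1, 0.5, 5))) / HARTREE_TO_KCAL
      } else if (cls == "spectator_mode") {
        modes[[1]] <- spectator_mode_vector(b$g, b$pg, tseed + 14L)
      }
      ts_rec <- parse_optfreq_log(make_mock_optfreq_log(
        ts_energy, b$g$elements, b$r_geom, freqs, modes))
      up <- seq(e_r, string_max, length.out = 5L)
      down <- seq(string_max, e_p, length.out = 5L)[-1]
      string <- parse_string_output(make_mock_string_output(
        c(up, down), b$g$elements, b$r_geom, b$p_geom))
      rows[[idx]] <- tibble::tibble(
        defect = cls, should_pass = cls == "clean",
        r = list(r_rec), ts = list(ts_rec), p = list(p_rec),
        rg = list(b$g), pg = list(b$pg), string = list(string)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# mode displacing one atom of an unchanged bond, zero on all changing atoms
spectator_mode_vector <- function(rg, pg, seed) {
  n <- n_atoms(rg)
  ch <- bond_changes(rg, pg)
  changing <- canonical_bonds(rbind(ch$broken, ch$formed))
  changing_atoms <- unique(as.vector(changing))
  all_b <- canonical_bonds(rbind(rg$bonds, pg$bonds))
  all_b <- all_b[!duplicated(bond_keys(all_b)), , drop = FALSE]
  unchanged <- all_b[!(bond_keys(all_b) %in% bond_keys(changing)), , drop = FALSE]
  spec_atoms <- setdiff(as.vector(unchanged), changing_atoms)
  if (length(spec_atoms) == 0) {
    stop_rxn("spec", "catalog reaction has no spectator atom for this defect")
  }
  a <- spec_atoms[1]
  u <- matrix(0.0, n, 3)
  u[a, ] <- with_seed(seed, stats::rnorm(3))
  u / sqrt(sum(u^2))
}
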